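---
title: "Methods: nucleosome trajectory analysis in nuctraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome trajectory analysis in nuctraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuctraj)
```

`nuctraj` quantifies the conformational dynamics of nucleosomes from
molecular-dynamics trajectories: how far the DNA ends unwrap from the histone
octamer, which histone residues grip which nucleotides and how persistently,
which hydrogen bonds stabilise the histone core, and how flexible the
disordered tails are in Ramachandran terms. This vignette is the package's
account of the underlying procedures, the tunable parameters, the numerical
choices made where the methods literature leaves the details open, and what
the synthetic validation data do and do not establish.

## Data model

A `structure_model` is a fixed topology (atom names, elements, chains,
residues) plus one coordinate set in Ångström; an `md_trajectory` is a frame
sequence over that topology with a frame spacing `dt_ns` (default 1 ns, the
typical stride at which production frames are saved). Heavy atoms are all
atoms whose element is not H/D; when the element column is absent the element
is derived from the PDB atom name (leading digits stripped, names beginning
with H read as hydrogen — biomolecular names are assumed, so mercury-style
two-letter symbols are out of scope). Chain roles are inferred only where
that is robust: a chain is a DNA strand when more than 90 % of its residues
are standard deoxynucleotides; histone roles (H3/H4/H2A/H2B) must be supplied
by the caller or the fixture, because silent sequence-based assignment across
variants invites misnumbering. Residue numbers are taken from the input
as-is — canonical H2A and H2A.J numbering differ by one near the C-terminus
(G128 vs S127), and renumbering silently would corrupt site references like
S40 or K118.

## The nucleosome reference frame

Base pairing is positional: nucleotide *i* of strand I (5′→3′) pairs with
nucleotide *L*+1−*i* of strand J, and indices are shifted so the dyad
nucleotide is bp 0; the 147 bp core spans −73…+73 and linker positions lie
beyond. A base-pair center is the midpoint of the two glycosidic nitrogens
(N9 purine, N1 pyrimidine) — these atoms exist in every nucleotide, are
well-defined in coarse models, and track the helical axis closely.

The superhelical axis is fitted as the normal of a **pitch-detrended
least-squares plane** through the core bp centers. A naive SVD plane through
a pitched helix is tilted by several degrees because the rise accumulates
along the winding; we therefore regress the out-of-plane component against
the bp index (the rise is linear in the index for an ideal superhelix),
subtract the fitted ramp, and refit, iterating to convergence (≤ 4
iterations). On an ideal superhelix with canonical geometry (radius 41.8 Å,
pitch 25.9 Å, 1.67 turns) this recovers the generating axis to < 0.01°,
where the naive plane is ~2–8° off depending on the fitted range. The axis
sign follows the right-hand rule of the winding with increasing bp index, the
origin is the centroid of the fitted centers, the dyad axis is the in-plane
unit component of (bp 0 center − origin), and the third axis completes a
right-handed triad. The default fit range is −60…+60 bp so that breathing
ends do not perturb the frame; the dyad axis is defined from the bp 0 center
rather than from a pseudo-two-fold symmetry fit because it is computable from
a single frame. Projections onto the nucleosomal plane use (dyad, third) as
(u, v); the dyad and perpendicular planes are defined analogously.

Because production runs typically restrain the octamer only weakly, frames
are rigid-body superposed (`superpose()`, least-squares on the histone-fold
Cα atoms by default) onto a reference frame before any displacement-based
analysis; the per-frame fit RMSD is reported. By default the frame is fitted
once on the reference frame; per-frame refitting is available by simply
calling `fit_frame()` per frame.

## DNA unwrapping

Unwrapping on one side is the length of the contiguous run of core base
pairs, starting at the entry–exit site (|bp| = 73) and scanning toward the
dyad, whose centers lie further than `threshold_A` (default 7 Å) from **all**
base-pair centers of the initial structure, linkers included. Two readings of
"moved away from the positions of every base pair" are possible; the
all-centers minimum-distance reading is the default because it makes the
metric specific to unwrapping: a 2 bp register shift (DNA sliding) lands
every center near a neighbour's initial position and counts as zero, which
the package verifies against a generator decoy. The per-bp self-distance
reading is available via `self_reference = TRUE`. The run is counted from the
end and stops at the first wrapped base pair, since detachment propagates
from the entry–exit site; displaced interior base pairs beyond a wrapped one
are deliberately not counted. Counts are capped at 73 by construction,
proximal = negative indices and distal = positive as a package convention.

## Contacts

An atom–atom contact is an unordered heavy-atom pair at distance strictly
below 4 Å. Contact cardinality is the number of atom pairs, not a binary
per-residue flag, because per-residue contact numbers in nucleosome work
reach tens of pairs. Profiles are per (protein residue × nucleotide) cell:
mean pair count over frames, SD, occupancy (fraction of frames with ≥ 1
pair), and an autocorrelation-corrected SEM (below). *Stable* contacts are
cells with occupancy ≥ 0.25, boundary inclusive ("at least 25 % of frames").
Two-copy handling: profiles are computed per H2A copy and combined either by
per-cell mean (for contact-number comparisons) or by union of presence after
mapping the second copy through the pseudo-dyad (bp negated, strands
swapped); both are available because published figures use both conventions.
Minor-groove-restricted profiles limit the nucleotide atoms to a configurable
name list defaulting to the nucleobase atoms lining the minor groove (purine
N3/C4, pyrimidine O2, and C2 common to both edges). Residue–residue distances
are the arithmetic mean over all heavy-atom cross pairs.

## Hydrogen bonds

A donor–acceptor pair is bonded in a frame when the D–A distance is ≤ 3 Å
(inclusive, the cutoff semantics of the common HBond plugins) and the D–H–A
angle deviates from linearity by ≤ 20°, i.e. angle ≥ 160°; "20° cutoff" is
read as maximum deviation from 180°, the convention of the tool family this
criterion originates from, and both readings are configurable. Hydrogens are
resolved from the topology by distance (nearest H within 1.25 Å of the donor
heavy atom) since PDB-derived models carry no explicit bonds; donors with
multiple hydrogens count as bonded if any H satisfies the angle. Models
without hydrogens waive the angle criterion with a warning. Occupancy is the
fraction of frames with any qualifying D/A combination between the two
residues; residence times are maximal presence runs, optionally bridging
gaps up to `gap_tolerance_frames`, scaled by `dt_ns`. Occupancy is invariant
under frame permutation; residence times are not — the test suite asserts
both directions.

## Torsions

Dihedrals use the conventional signed atan2 construction, degrees in
(−180, 180]; φ(i) = C(i−1)–N(i)–CA(i)–C(i), ψ(i) = N(i)–CA(i)–C(i)–N(i+1),
with chain breaks (peptide C–N above 2.5 Å) leaving the spanning angle
undefined. One mathematical point deserves note: the conventional torsion is
*invariant* under reversing the four atoms (φ(ABCD) = φ(DCBA)); it is mirror
reflection that negates it. The tests pin the conventional behaviour.
Ramachandran states are user-named rectangles on the (φ, ψ) torus,
wrap-aware across the ±180° seam, checked for overlap on a 5° grid; frames
outside every region are "other", and occupancies over regions + "other" sum
to 1. Region boundaries for specific loop conformational modes are
configuration, not constants, because such modes are defined by inspection
of specific systems.

## Autocorrelation-corrected uncertainty

The SEM of a trajectory average is sd/√n_eff with n_eff = n/τ, τ the
integrated autocorrelation time τ = 1 + 2Σρ(k) truncated with Sokal's
self-consistent window (smallest W with W ≥ 5 τ(W)), τ floored at 1 and
capped at n/2. The estimator is validated against the AR(1) closed form
τ = (1+φ)/(1−φ): at φ = 0.9 and n = 10⁵ it lands within a few percent of 19,
and it cross-checks against block averaging (block = 5τ) within ×1.5. The
windowed estimator at n = 5000 has a relative sd near 25–30 %, which is why
the generator-level memory check uses a correspondingly wide band.

## The synthetic generator

`simulate_nucleosome()` emulates the *statistical* structure the analyses
assume, not the physics. The structure is an ideal left-handed superhelix
(radius 41.8 Å, pitch 25.9 Å, 1.67 turns over 147 bp — canonical
nucleosome-core values) with 20 bp linkers extended tangentially at a 3.4
Å/bp rise, three pseudo-atoms per nucleotide (glycosidic N, C1′, one
minor-groove base atom), Cα-only histone folds for eight chains, full-backbone
stretches where analyses need them (H2A L1-loop 36–44 with the serine-40
hydroxyl and its hydrogen; H2B 82–86), and all-atom-like H2A tails, the
C-tail built by internal-coordinate chaining with standard bond geometry.
Phenomenology is scripted: per-side unwrapping schedules displace the outer
k bp radially by the configured amplitude (default test amplitude 12 Å =
threshold + 5, so recovery is not a boundary case); contact and H-bond
occupancies are realised by thresholding a latent unit Gaussian — AR(1) with
the configured persistence — so the marginal probability is exact and
correlated-frame behaviour is available; torsion basins are sampled from a
mixture and realised by rebuilding the tail backbone each frame; everything
else receives stationary AR(1) Gaussian coordinate noise (default sd 0.1 Å),
from which scripted residues are exempt so scripted geometries stay exact.
All randomness flows from one seed; identical config + seed is bit-identical,
which the CLI-level determinism check verifies at file level.

What passing recovery tests shows: the analysis code computes the declared
quantities correctly on data whose ground truth is known, including decoys
(register shift vs unwrapping) and boundary cases. What it does not show:
force-field realism, sequence-dependent DNA geometry, sterics, or that real
trajectories are as well-behaved — a real nucleosome's unwrapping is not a
clean two-state schedule and its contact geometry is not a rigid placement.
The generator's contact placements realistically graze neighbouring
nucleotides (a residue inserted at a base step touches both strands), so
recovery is asserted on the scripted cells.

## Sequence comparison and abundance weighting

Pairwise identity uses Needleman–Wunsch global alignment with match +1,
mismatch 0, linear gap −1 (via Biostrings); identity is reported with the
alignment-length denominator (gap columns counted) as the primary value and
the shorter-sequence denominator alongside, since rounding conventions for
"~94 % identical" differ by one residue either way. Substitutions and indels
are reported in the reference sequence's mature-protein numbering (initiator
methionine handled via the `offset` argument). The packaged H2A sequences
were assembled from the variant-defining residues of canonical H2A isoform 2
and H2A.J (A10V, S40/A40, R99K, the SHHKAKGK→SQKTKSK C-tail with its single
deletion) laid over the canonical human H2A core; every documented site
(S40/E41/R42, N38, K118/K119/K125, the SQ phospho-motif at S122) was checked
against the assembled sequences. The isoform abundance table is a synthetic
PaxDB-style snapshot (flagged `_synthetic` in its filename) constructed so
that serine-40-carrying isoforms hold 20 % of canonical abundance, matching
the proteomics-derived statistic by construction; recomputations from a live
database snapshot will differ with the snapshot.

Phosphoserine support: residue name `SEP` is treated as protein, and
`validate_pser_charges()` checks a charge template for the three constraints
a parameterisation must satisfy — net charge −2 e, backbone charges equal to
the reference force-field values, phosphate oxygens mutually equal — to a
tolerance of 10⁻⁴ e, returning violations as data rather than raising.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at sizes
chosen to make the statistical assertions sharp while staying comfortably
interactive: 500-frame trajectories for unwrapping-state recovery (assert
≥ 95 % frame-wise recovery; observed 100 %), 2000 frames for occupancy
recovery (asserted within 3 binomial SD), 10⁵-point series for τ (15 %
band), 200 random 100-atom configurations for the brute-force contact
oracle. Degenerate inputs raise early and specifically: collinear centers,
reversed residue ranges, unequal strand lengths, thresholds outside their
domains, empty selections (a warning, since empty is a legitimate query
result). Ties and boundaries are pinned by tests: contact cutoff strict
(< 4 Å), stable-contact threshold inclusive (≥ 0.25), D–A cutoff inclusive
(≤ 3 Å).

## Known limitations

- XTC trajectories are not read; convert to DCD or multi-model PDB. All
  supported on-disk formats store Ångström natively.
- Full base-pair reference frames (roll/twist/slide) are out of scope; all
  in-package analyses need only bp centers.
- Sequence comparison is pairwise; multiple alignments are consumed, not
  computed.
- The generator's histone folds are pseudo-atoms at plausible radii, not
  folded domains; analyses that would depend on fold packing geometry beyond
  selections and distances should not be validated against it.
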
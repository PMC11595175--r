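# nuctraj

Analysis of nucleosome molecular-dynamics trajectories in R.

Nucleosomes — ~147 bp of DNA wound in about 1.67 left-handed superhelical
turns around a histone octamer (two copies each of H3, H4, H2A, H2B) — are
the repeating unit of chromatin. Histone variants such as H2A.J differ from
the canonical histones at only a handful of positions (a different C-terminal
tail, A10V in the N-tail, S40A near the L1-loop), yet those substitutions
change how the disordered tails grip the nucleosomal and linker DNA, how far
the DNA ends unwrap, and which hydrogen bonds stabilise the histone core.
`nuctraj` implements the trajectory analyses used to quantify those effects:

- **Nucleosome reference frame** — base pairing, base-pair centers (midpoints
  of the glycosidic nitrogens), a pitch-detrended least-squares fit of the
  superhelical axis, and 2D projections of Cα atoms / bp centers onto the
  nucleosomal, dyad, and perpendicular planes.
- **DNA unwrapping** — per frame and per side (proximal/distal), the number
  of core base pairs, counted from the entry–exit site (±73 bp from the
  dyad), whose centers have moved more than 7 Å away from *every* base-pair
  center of the initial structure (so register shifts/sliding do not count);
  plus unwrapping-state histograms.
- **Protein–DNA contacts** — heavy-atom atom–atom contacts at < 4 Å, per
  (residue × nucleotide) profiles with occupancies, *stable* contacts
  (occupancy ≥ 25 % of frames), two-copy symmetrisation through the
  pseudo-dyad, minor-groove-restricted profiles, and tail aggregates.
- **Hydrogen bonds** — geometric detection (D–A ≤ 3 Å, D–H–A within 20° of
  linear), per-pair occupancy fractions and residence-time analysis with a
  gap tolerance.
- **Backbone torsions** — φ/ψ series, wrap-aware Ramachandran-region
  classification, transition and dwell-time counting.
- **Uncertainty** — every trajectory average carries a SEM of
  `sd / sqrt(n_eff)` with `n_eff = n / τ`, where τ is the integrated
  autocorrelation time estimated with the self-consistent window rule
  (`W = min{W : W ≥ 5 τ(W)}`).
- **Sequence statistics** — global pairwise identity (match +1 / mismatch 0 /
  gap −1), substitution/indel listing in mature-protein numbering, and
  abundance-weighted residue fractions over isoform tables.
- **Synthetic generator** — `synth_config()` / `simulate_nucleosome()` build
  a ground-truth-labelled toy nucleosome (ideal superhelix + 20 bp linkers,
  Cα-only histone folds, all-atom-like tails) with schedulable unwrapping,
  scripted contact/H-bond occupancies, scripted torsion basins, and AR(1)
  coordinate noise, so every analysis stage can be validated against known
  answers.

## Worked example

```r
library(nuctraj)

cfg <- synth_config(
  n_frames = 200, seed = 7,
  unwrap_schedule = data.frame(from = 101, to = 200, side = "distal",
                               k = 13, amplitude_A = 12),
  hbond_script = data.frame(donor_chain = "C", donor_resid = 40,
                            donor_atom = "OG", hydrogen_atom = "HG",
                            acceptor_chain = "C", acceptor_resid = 42,
                            acceptor_atom = "O", occupancy = 0.76,
                            persistence = 0)
)
sim <- simulate_nucleosome(cfg)
sim$trajectory
#> md_trajectory: 200 frames x 2236 atoms, dt = 1 ns

us <- unwrap_count(sim$trajectory, sim$pairs)
unwrap_histogram(us, max_bp = 13)[c(1, 14), ]
#>    state proximal distal
#> 1      0        1    0.5
#> 14    13        0    0.5

bond_occupancy(sim$trajectory, "C", 40, "C", 42,
               donor_atom = "OG", acceptor_atom = "O")
#> bond_series C:40:OG -> C:42:O: occupancy 73% over 200 frames

seqs <- h2a_sequences()
percent_identity(seqs[["cH2A_isoform2"]], seqs[["H2A.J"]])$identity_pct
#> [1] 94.57364
```

Reading the output: the distal DNA arm spends half the trajectory fully
wrapped (state 0) and half unwrapped by 13 bp, exactly as scheduled; the
serine-40 hydroxyl donates a hydrogen bond to the arginine-42 backbone oxygen
in 73 % of frames (146/200 realised draws of the scripted 76 % occupancy);
and the packaged H2A.J sequence is 94.6 % identical to canonical H2A
isoform 2 under the global alignment.

Real trajectories are read with `read_structure()` +
`read_trajectory(format = "dcd")` (or multi-model PDB); atom subsets use a
small selection grammar:

```
expr      := term ("or" term)*
term      := factor ("and" factor)*
factor    := "not" factor | "(" expr ")" | predicate
predicate := chain IDS | resid N|A-B|A:B ... | resname NAMES | name NAMES
           | element SYMS | hydrogen | heavy | protein | nucleic | all
```

e.g. `select_atoms(model, "chain A and resid 64-78 and name CA")`.

A thin CLI for generating labelled synthetic data is installed at
`system.file("cli", "nuctraj", package = "nuctraj")`:

```sh
nuctraj synth --seed 7 --frames 25 --out-prefix toy
```

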
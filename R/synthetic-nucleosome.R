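# Ground-truth-labelled synthetic nucleosome structures and trajectories.
#
# The generator emulates the statistical structure the analyses assume -- a
# 147 bp left-handed superhelix with linker arms, histone-fold pseudo-atom
# chains, flexible tails with scriptable DNA-contact and hydrogen-bond
# patterns, schedulable per-side DNA unwrapping, and stationary AR(1)
# coordinate noise -- and records the ground truth it realised, so every
# analysis stage can be validated against known answers.  It makes no claim
# of physical realism: no force field, no sterics, no sequence-dependent DNA
# geometry.

#' Configuration for the synthetic nucleosome generator
#'
#' All geometry is in Angstrom, time in nanoseconds.  Defaults encode the
#' canonical nucleosome: 147 core bp wrapped in 1.67 left-handed superhelical
#' turns (radius 41.8, pitch 25.9) with 20 bp linkers.
#'
#' @param n_core_bp core base pairs (147).
#' @param linker_bp linker length per side (20).
#' @param radius_A,pitch_A,turns superhelix parameters.
#' @param n_frames,dt_ns trajectory length and frame spacing.
#' @param unwrap_schedule data.frame(`from`, `to`, `side`, `k`, `amplitude_A`):
#'   for frames in `[from, to]`, the outer `k` core bp on `side`
#'   (`"proximal"`/`"distal"`) are displaced outward by `amplitude_A`.
#' @param contact_script data.frame(`chain`, `resid`, `bp`, `strand`,
#'   `occupancy`, `persistence`): per frame the residue is placed in contact
#'   (< 4 A) with the scripted nucleotide with the given marginal probability;
#'   `persistence` is the AR(1) coefficient of the latent on/off process
#'   (0 = independent frames).
#' @param hbond_script data.frame(`donor_chain`, `donor_resid`, `donor_atom`,
#'   `hydrogen_atom`, `acceptor_chain`, `acceptor_resid`, `acceptor_atom`,
#'   `occupancy`, `persistence`): scripted geometric hydrogen bonds
#'   (on: D-A 2.8 A collinear; off: D-A 4.5 A).
#' @param torsion_script list(`chain`, `resid`, `basins` = list of
#'   c(phi, psi), `weights`): the scripted C-tail residue samples its
#'   (phi, psi) basin per frame from the mixture.
#' @param register_shift_bp rotate the whole DNA by this many bp steps about
#'   the superhelical axis in every frame (a sliding decoy that must NOT be
#'   counted as unwrapping).
#' @param tumble if `TRUE`, apply a random rigid rotation + translation to
#'   every frame (removed again by [superpose()]).
#' @param noise_sd_A,noise_ar1 stationary SD and AR(1) coefficient of
#'   per-atom Gaussian coordinate noise (scripted residues are exempt so that
#'   scripted geometries are exact).
#' @param h2a_ntail_seq,h2a_ctail_seq,h2a_ctail_start one-letter tail
#'   sequences of the H2A chains and the residue number of the first C-tail
#'   residue (canonical defaults).
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_core_bp = 147, linker_bp = 20,
                         radius_A = 41.8, pitch_A = 25.9, turns = 1.67,
                         n_frames = 100, dt_ns = 1.0,
                         unwrap_schedule = NULL,
                         contact_script = NULL,
                         hbond_script = NULL,
                         torsion_script = NULL,
                         register_shift_bp = 0,
                         tumble = FALSE,
                         noise_sd_A = 0.1, noise_ar1 = 0.0,
                         h2a_ntail_seq = "SGRGKQGGKARAKAK",
                         h2a_ctail_seq = "KKTESHHKAKGK",
                         h2a_ctail_start = 118,
                         seed = 1) {
  cfg <- list(n_core_bp = n_core_bp, linker_bp = linker_bp,
              radius_A = radius_A, pitch_A = pitch_A, turns = turns,
              n_frames = as.integer(n_frames), dt_ns = dt_ns,
              unwrap_schedule = unwrap_schedule,
              contact_script = contact_script,
              hbond_script = hbond_script,
              torsion_script = torsion_script,
              register_shift_bp = register_shift_bp,
              tumble = tumble,
              noise_sd_A = noise_sd_A, noise_ar1 = noise_ar1,
              h2a_ntail_seq = h2a_ntail_seq,
              h2a_ctail_seq = h2a_ctail_seq,
              h2a_ctail_start = as.integer(h2a_ctail_start),
              seed = as.integer(seed))
  if (cfg$n_frames < 1) stop("n_frames must be >= 1")
  if (!is.null(cfg$unwrap_schedule)) {
    us <- cfg$unwrap_schedule
    stopifnot(all(c("from", "to", "side", "k", "amplitude_A") %in% names(us)))
    if (any(us$to > cfg$n_frames)) stop("unwrap schedule exceeds n_frames")
    if (any(us$amplitude_A <= 0)) stop("unwrap amplitude must be positive")
    if (any(!us$side %in% c("proximal", "distal"))) stop("bad unwrap side")
  }
  for (script in list(cfg$contact_script, cfg$hbond_script)) {
    if (!is.null(script) && any(script$occupancy < 0 | script$occupancy > 1)) {
      stop("scripted occupancies must be in [0, 1]")
    }
  }
  if (!is.null(cfg$torsion_script)) {
    ts <- cfg$torsion_script
    if (abs(sum(ts$weights) - 1) > 1e-8) stop("torsion basin weights must sum to 1")
    if (length(ts$weights) != length(ts$basins)) stop("weights/basins mismatch")
  }
  scripted <- c(
    if (!is.null(cfg$contact_script))
      paste(cfg$contact_script$chain, cfg$contact_script$resid),
    if (!is.null(cfg$hbond_script))
      paste(cfg$hbond_script$donor_chain, cfg$hbond_script$donor_resid),
    if (!is.null(cfg$torsion_script))
      paste(cfg$torsion_script$chain, cfg$torsion_script$resid)
  )
  if (anyDuplicated(scripted)) {
    stop("a residue may appear in at most one script: ",
         scripted[duplicated(scripted)][1])
  }
  class(cfg) <- "synth_config"
  cfg
}

ONE_TO_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# superhelix parametrisation: left-handed (clockwise viewed from +z)
helix_geometry <- function(cfg) {
  half <- (cfg$n_core_bp - 1) / 2        # 73 for 147 bp
  dtheta <- -cfg$turns * 2 * pi / (cfg$n_core_bp - 1)
  list(
    half = half,
    dtheta = dtheta,
    center = function(s) {
      th <- s * dtheta
      cbind(cfg$radius_A * cos(th), cfg$radius_A * sin(th),
            -cfg$pitch_A * th / (2 * pi))
    },
    tangent = function(s) {
      th <- s * dtheta
      v <- cbind(-cfg$radius_A * sin(th) * dtheta,
                 cfg$radius_A * cos(th) * dtheta,
                 -cfg$pitch_A * dtheta / (2 * pi))
      v / sqrt(rowSums(v^2))
    }
  )
}

# analytic curve (core superhelix + tangential linkers) for any bp index
analytic_bp_center <- function(cfg, s) {
  g <- helix_geometry(cfg)
  s <- as.numeric(s)
  core <- abs(s) <= g$half
  out <- matrix(NA_real_, length(s), 3)
  if (any(core)) out[core, ] <- g$center(s[core])
  if (any(!core)) {
    sl <- s[!core]
    end <- sign(sl) * g$half
    rise <- 3.4
    out[!core, ] <- g$center(end) + (abs(sl) - g$half) * rise *
      sign(sl) * g$tangent(end)
  }
  out
}

#' Build the synthetic nucleosome structure
#'
#' DNA: two strands of glycosidic-nitrogen + C1' + one minor-groove base
#' pseudo-atom per nucleotide on an ideal left-handed superhelix with
#' tangentially extended linkers.  Histones: eight chains (A-H =
#' H3,H4,H2A,H2B twice) of Calpha-only folds at inner radius, plus for the
#' H2A chains all-atom-like tails and an L1-loop stretch (full backbone,
#' serine-40 hydroxyl with its hydrogen) and for H2B a serine-84 backbone
#' stretch, so that contact, hydrogen-bond and torsion analyses all have the
#' atoms they read.
#'
#' @param config `synth_config`
#' @return `structure_model` with attribute `truth_axis` (the generating
#'   superhelical axis under the package's winding sign convention).
#' @export
build_nucleosome <- function(config) {
  cfg <- config
  g <- helix_geometry(cfg)
  half <- g$half
  s_all <- seq(-(half + cfg$linker_bp), half + cfg$linker_bp)
  L <- length(s_all)
  centers <- analytic_bp_center(cfg, s_all)
  # per-bp transverse direction: radial, twisted about the local tangent
  radial <- cbind(cos(s_all * g$dtheta), sin(s_all * g$dtheta), 0)
  tang <- rbind(g$tangent(pmax(pmin(s_all, half), -half)))
  twist <- 36 * pi / 180 * s_all
  dvec <- radial * cos(twist) +
    t(vapply(seq_len(L), function(k) cross3(tang[k, ], radial[k, ]),
             numeric(3))) * sin(twist)
  dvec <- dvec / sqrt(rowSums(dvec^2))

  seq_i <- rep(c("DA", "DT", "DG", "DC"), length.out = L)
  comp <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")

  atoms <- list()
  coords <- list()
  add_atom <- function(name, element, chain, resid, resname, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, element = element, chain = chain, resid = resid,
      resname = resname, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
  }
  add_nucleotide <- function(chain, resid, resname, glyc, dview, tview) {
    gly_name <- glycosidic_name(resname)
    mg_name <- if (gly_name == "N9") "N3" else "O2"
    add_atom(gly_name, "N", chain, resid, resname, glyc)
    add_atom("C1'", "C", chain, resid, resname, glyc + 1.2 * tview)
    add_atom(mg_name, if (mg_name == "O2") "O" else "N",
             chain, resid, resname, glyc - 1.5 * dview)
  }
  # strand I (5'->3', resid 1..L), then strand J (resid 1..L, antiparallel)
  for (p in seq_len(L)) {
    add_nucleotide("I", p, seq_i[p], centers[p, ] + 2 * dvec[p, ],
                   dvec[p, ], tang[p, ])
  }
  for (p in seq_len(L)) {
    q <- L + 1 - p  # spatial bp position paired with strand I residue q
    add_nucleotide("J", p, comp[[seq_i[q]]], centers[q, ] - 2 * dvec[q, ],
                   -dvec[q, ], -tang[q, ])
  }

  # histone folds: Calpha arcs at inner radius, one angular sector per chain
  fold_ranges <- list(H3 = c(45, 135), H4 = c(25, 102),
                      H2A = c(16, 117), H2B = c(30, 125))
  chains <- data.frame(
    chain = LETTERS[1:8],
    role = rep(c("H3", "H4", "H2A", "H2B"), 2),
    copy = rep(c(1, 2), each = 4),
    stringsAsFactors = FALSE
  )
  h2a_full_bb <- 36:44       # L1-loop stretch with full backbone
  h2b_full_bb <- 82:86       # S84 stretch
  ctail_anchors <- list()
  for (ci in seq_len(nrow(chains))) {
    ch <- chains$chain[ci]
    role <- chains$role[ci]
    rng <- fold_ranges[[role]]
    phi0 <- (ci - 1) * pi / 4 + 0.2
    zoff <- if (chains$copy[ci] == 1) -8 else 8
    for (r in seq(rng[1], rng[2])) {
      ang <- phi0 + (r - rng[1]) * 0.045
      pos <- c(26 * cos(ang), 26 * sin(ang), zoff + 3 * sin(r / 7))
      resname <- "ALA"
      full_bb <- (role == "H2A" && r %in% h2a_full_bb) ||
                 (role == "H2B" && r %in% h2b_full_bb)
      if (role == "H2A" && r == 40) resname <- "SER"
      if (role == "H2B" && r == 84) resname <- "SER"
      if (role == "H2A" && r == 42) resname <- "ARG"
      if (role == "H2A" && r == 41) resname <- "GLU"
      if (role == "H2A" && r == 38) resname <- "ASN"
      if (full_bb) {
        tvec <- c(-sin(ang), cos(ang), 0)
        add_atom("N", "N", ch, r, resname, pos - 0.9 * tvec)
        add_atom("CA", "C", ch, r, resname, pos)
        add_atom("C", "C", ch, r, resname, pos + 0.9 * tvec + c(0, 0, 0.5))
        add_atom("O", "O", ch, r, resname, pos + 1.2 * tvec + c(0, 0, 1.6))
        if (resname == "SER") {
          up <- c(cos(ang), sin(ang), 0)
          add_atom("CB", "C", ch, r, resname, pos - 1.5 * up)
          add_atom("OG", "O", ch, r, resname, pos - 2.9 * up)
          add_atom("HG", "H", ch, r, resname, pos - 3.85 * up)
        }
      } else {
        add_atom("CA", "C", ch, r, resname, pos)
      }
    }
    if (role == "H2A") {
      # N-tail beads (resid 1..len), parked 10 A outside the proximal linker
      nseq <- strsplit(cfg$h2a_ntail_seq, "")[[1]]
      anchor_s <- if (chains$copy[ci] == 1) -(half + 5) else (half + 5)
      base_pt <- analytic_bp_center(cfg, anchor_s)[1, ] +
        c(0, 0, if (chains$copy[ci] == 1) -12 else 12)
      for (k in seq_along(nseq)) {
        rn <- ONE_TO_THREE[[nseq[k]]]
        pos <- base_pt + c(3.8 * k, 0, 0)
        add_atom("N", "N", ch, k, rn, pos + c(0, -1.2, 0))
        add_atom("CA", "C", ch, k, rn, pos)
        add_atom("C", "C", ch, k, rn, pos + c(1.0, 1.0, 0))
        add_atom("O", "O", ch, k, rn, pos + c(1.0, 2.2, 0))
        if (rn != "GLY") add_atom("CB", "C", ch, k, rn, pos + c(0, 0, 1.5))
        if (rn == "ARG") add_atom("CZ", "C", ch, k, rn, pos + c(0, 0, 2.9))
        if (rn == "LYS") add_atom("NZ", "N", ch, k, rn, pos + c(0, 0, 2.9))
      }
      # C-tail: full backbone built by internal-coordinate chaining from an
      # anchor triple parked 14 A outside the distal linker
      cseq <- strsplit(cfg$h2a_ctail_seq, "")[[1]]
      a_s <- if (chains$copy[ci] == 1) (half + 8) else -(half + 8)
      apt <- analytic_bp_center(cfg, a_s)[1, ] +
        c(0, 0, if (chains$copy[ci] == 1) 14 else -14)
      anchor <- rbind(apt + c(-2.4, 0.8, 0), apt + c(-1.2, -0.4, 0), apt)
      ctail_anchors[[ch]] <- anchor
      bb <- build_backbone(length(cseq),
                           phi = rep(-60, length(cseq)),
                           psi = rep(-45, length(cseq)),
                           anchor = anchor)
      for (k in seq_along(cseq)) {
        rn <- ONE_TO_THREE[[cseq[k]]]
        r <- cfg$h2a_ctail_start + k - 1
        add_atom("N", "N", ch, r, rn, bb$N[k, ])
        add_atom("CA", "C", ch, r, rn, bb$CA[k, ])
        add_atom("C", "C", ch, r, rn, bb$C[k, ])
        add_atom("O", "O", ch, r, rn, bb$O[k, ])
        if (rn != "GLY") add_atom("CB", "C", ch, r, rn, bb$CB[k, ])
        if (rn == "LYS") add_atom("NZ", "N", ch, r, rn,
                                  bb$CB[k, ] + 1.5 * (bb$CB[k, ] - bb$CA[k, ]) /
                                    sqrt(sum((bb$CB[k, ] - bb$CA[k, ])^2)))
        if (rn == "SER") add_atom("OG", "O", ch, r, rn,
                                  bb$CB[k, ] + 1.4 * (bb$CB[k, ] - bb$CA[k, ]) /
                                    sqrt(sum((bb$CB[k, ] - bb$CA[k, ])^2)))
      }
    }
  }

  atoms_df <- do.call(rbind, atoms)
  coords_m <- do.call(rbind, coords)
  roles <- c(setNames(chains$role, chains$chain),
             I = "DNA_strand_I", J = "DNA_strand_J")
  model <- structure_model(atoms_df, coords_m, chain_roles = roles)
  # generating axis, signed by the right-hand rule of the (left-handed)
  # winding with increasing bp index
  attr(model, "truth_axis") <- c(0, 0, -1)
  attr(model, "dyad_resid_I") <- half + cfg$linker_bp + 1
  attr(model, "ctail_anchor") <- ctail_anchors
  model
}

# torsion-driven backbone chaining (standard bond lengths/angles, omega 180)
build_backbone <- function(n_res, phi, psi, anchor) {
  stopifnot(nrow(anchor) == 3)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n_res, 3)
  prevN <- anchor[1, ]; prevCA <- anchor[2, ]; prevC <- anchor[3, ]
  psi_prev <- 150  # pseudo-psi of the anchor residue
  for (k in seq_len(n_res)) {
    N[k, ] <- place_atom(prevN, prevCA, prevC, 1.33, 116.2, psi_prev)
    CA[k, ] <- place_atom(prevCA, prevC, N[k, ], 1.46, 121.7, 180)
    C[k, ] <- place_atom(prevC, N[k, ], CA[k, ], 1.52, 111.0, phi[k])
    O[k, ] <- place_atom(N[k, ], CA[k, ], C[k, ], 1.23, 120.5, psi[k] + 180)
    CB[k, ] <- place_atom(C[k, ], N[k, ], CA[k, ], 1.53, 110.5, 123.0)
    prevN <- N[k, ]; prevCA <- CA[k, ]; prevC <- C[k, ]
    psi_prev <- psi[k]
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

# NeRF atom placement: |cd| = bond, angle(b,c,d) = angle_deg,
# dihedral(a,b,c,d) = torsion_deg
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
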
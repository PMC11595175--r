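# Trajectory synthesis over the synthetic nucleosome structure.

ar1_series <- function(n, phi, sd = 1) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1, sd = sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, sd = sd * sqrt(1 - phi^2))
    for (t in 2:n) z[t] <- phi * z[t - 1] + innov[t - 1]
  }
  z
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulate a synthetic nucleosome trajectory with ground truth
#'
#' Realises the configured phenomenology frame by frame -- register-shift
#' decoy, scheduled per-side DNA unwrapping, scripted residue-nucleotide
#' contacts, scripted hydrogen-bond geometries, scripted backbone torsion
#' basins, stationary AR(1) coordinate noise, and optional rigid-body
#' tumbling -- and records exactly what it did.
#'
#' @param config `synth_config`
#' @return list with elements `trajectory` (`md_trajectory`), `model`
#'   (`structure_model`), `pairs` (`base_pair_table`), and `truth`: per-frame
#'   true unwrap counts per side, scripted contact/H-bond presence matrices,
#'   torsion basin indices, and the generating superhelical axis.
#' @export
simulate_nucleosome <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  model <- build_nucleosome(cfg)
  a <- model$atoms
  base <- model$coords
  nf <- cfg$n_frames
  g <- helix_geometry(cfg)
  half <- g$half

  dna_atoms <- which(a$chain %in% c("I", "J"))
  dyad_resid <- attr(model, "dyad_resid_I")
  Lnt <- max(a$resid[a$chain == "I"])
  # bp index of every DNA atom (strand I: resid - dyad; strand J: antiparallel)
  atom_bp <- rep(NA_integer_, nrow(a))
  atom_bp[a$chain == "I"] <- a$resid[a$chain == "I"] - dyad_resid
  atom_bp[a$chain == "J"] <- (Lnt + 1 - a$resid[a$chain == "J"]) - dyad_resid

  # ---- per-frame scripted state, drawn up front -------------------------
  truth <- list(axis = attr(model, "truth_axis"))
  truth$unwrap <- data.frame(frame = seq_len(nf),
                             proximal = 0L, distal = 0L,
                             amp_proximal = 0, amp_distal = 0)
  if (!is.null(cfg$unwrap_schedule)) {
    for (r in seq_len(nrow(cfg$unwrap_schedule))) {
      row <- cfg$unwrap_schedule[r, ]
      f_rng <- row$from:row$to
      if (row$side == "proximal") {
        truth$unwrap$proximal[f_rng] <- row$k
        truth$unwrap$amp_proximal[f_rng] <- row$amplitude_A
      } else {
        truth$unwrap$distal[f_rng] <- row$k
        truth$unwrap$amp_distal[f_rng] <- row$amplitude_A
      }
    }
  }
  draw_presence <- function(script) {
    if (is.null(script)) return(NULL)
    on <- matrix(FALSE, nf, nrow(script))
    for (r in seq_len(nrow(script))) {
      phi <- if (!is.null(script$persistence)) script$persistence[r] else 0
      z <- if (phi > 0) ar1_series(nf, phi) else stats::rnorm(nf)
      on[, r] <- z <= stats::qnorm(script$occupancy[r])
    }
    on
  }
  truth$contact_on <- draw_presence(cfg$contact_script)
  truth$hbond_on <- draw_presence(cfg$hbond_script)
  if (!is.null(cfg$torsion_script)) {
    ts <- cfg$torsion_script
    truth$torsion_basin <- sample.int(length(ts$weights), nf, replace = TRUE,
                                      prob = ts$weights)
  }

  # ---- static lookup tables ---------------------------------------------
  residue_atoms <- function(ch, rs) which(a$chain == ch & a$resid == rs)
  atom_at <- function(ch, rs, nm) {
    i <- which(a$chain == ch & a$resid == rs & a$name == nm)
    if (length(i) != 1) stop("synthetic model lacks atom ", ch, ":", rs, ":", nm)
    i
  }
  exempt <- integer()
  contact_info <- NULL
  if (!is.null(cfg$contact_script)) {
    cs <- cfg$contact_script
    contact_info <- lapply(seq_len(nrow(cs)), function(r) {
      res_idx <- residue_atoms(cs$chain[r], cs$resid[r])
      if (!length(res_idx)) stop("contact script names missing residue ",
                                 cs$chain[r], ":", cs$resid[r])
      probe_name <- if (any(a$name[res_idx] == "CB")) "CB" else "CA"
      strand_chain <- if (cs$strand[r] == "I") "I" else "J"
      nt_resid <- if (cs$strand[r] == "I") cs$bp[r] + dyad_resid else
        Lnt + 1 - (cs$bp[r] + dyad_resid)
      rn <- a$resname[which(a$chain == strand_chain & a$resid == nt_resid)][1]
      list(res_idx = res_idx,
           probe = atom_at(cs$chain[r], cs$resid[r], probe_name),
           target = atom_at(strand_chain, nt_resid, glycosidic_name(rn)))
    })
    exempt <- c(exempt, unlist(lapply(contact_info, `[[`, "res_idx")))
  }
  hbond_info <- NULL
  if (!is.null(cfg$hbond_script)) {
    hs <- cfg$hbond_script
    hbond_info <- lapply(seq_len(nrow(hs)), function(r) {
      res_idx <- residue_atoms(hs$donor_chain[r], hs$donor_resid[r])
      list(res_idx = res_idx,
           donor = atom_at(hs$donor_chain[r], hs$donor_resid[r], hs$donor_atom[r]),
           hydrogen = atom_at(hs$donor_chain[r], hs$donor_resid[r],
                              hs$hydrogen_atom[r]),
           acceptor = atom_at(hs$acceptor_chain[r], hs$acceptor_resid[r],
                              hs$acceptor_atom[r]))
    })
    exempt <- c(exempt, unlist(lapply(hbond_info, `[[`, "res_idx")))
  }
  tails <- NULL
  if (!is.null(cfg$torsion_script)) {
    ts <- cfg$torsion_script
    cseq <- strsplit(cfg$h2a_ctail_seq, "")[[1]]
    tail_resids <- cfg$h2a_ctail_start + seq_along(cseq) - 1
    if (!ts$resid %in% tail_resids) {
      stop("torsion script residue must lie in the H2A C-tail (",
           min(tail_resids), "-", max(tail_resids), ")")
    }
    anchor <- attr(model, "ctail_anchor")[[ts$chain]]
    tails <- list(chain = ts$chain, resids = tail_resids, seq = cseq,
                  anchor = anchor, scripted_pos = match(ts$resid, tail_resids),
                  basins = ts$basins)
    exempt <- c(exempt, which(a$chain == ts$chain & a$resid >= min(tail_resids)))
  }
  exempt <- unique(exempt)
  noisy <- setdiff(seq_len(nrow(a)), exempt)

  # ---- frame loop --------------------------------------------------------
  coords <- matrix(NA_real_, nf, 3L * nrow(a))
  noise_state <- matrix(stats::rnorm(length(noisy) * 3, sd = cfg$noise_sd_A),
                        ncol = 3)
  for (f in seq_len(nf)) {
    xyz <- base
    if (cfg$register_shift_bp != 0) {
      xyz[dna_atoms, ] <- xyz[dna_atoms, , drop = FALSE] %*%
        rotation_z(cfg$register_shift_bp * g$dtheta)
    }
    for (side in c("proximal", "distal")) {
      k <- truth$unwrap[[side]][f]
      if (k > 0) {
        amp <- truth$unwrap[[paste0("amp_", side)]][f]
        sgn <- if (side == "proximal") -1 else 1
        move <- which(!is.na(atom_bp) & sgn * atom_bp > half - k)
        s_mv <- atom_bp[move]
        disp <- cbind(cos(s_mv * g$dtheta), sin(s_mv * g$dtheta), 0) * amp
        xyz[move, ] <- xyz[move, , drop = FALSE] + disp
      }
    }
    if (f > 1 && cfg$noise_ar1 > 0) {
      noise_state <- cfg$noise_ar1 * noise_state +
        matrix(stats::rnorm(length(noisy) * 3,
                            sd = cfg$noise_sd_A * sqrt(1 - cfg$noise_ar1^2)),
               ncol = 3)
    } else if (f > 1) {
      noise_state <- matrix(stats::rnorm(length(noisy) * 3, sd = cfg$noise_sd_A),
                            ncol = 3)
    }
    if (cfg$noise_sd_A > 0) {
      xyz[noisy, ] <- xyz[noisy, , drop = FALSE] + noise_state
    }
    if (!is.null(tails)) {
      b <- truth$torsion_basin[f]
      phi <- rep(-60, length(tails$resids))
      psi <- rep(-45, length(tails$resids))
      phi[tails$scripted_pos] <- tails$basins[[b]][1]
      psi[tails$scripted_pos] <- tails$basins[[b]][2]
      bb <- build_backbone(length(tails$resids), phi, psi, tails$anchor)
      for (k in seq_along(tails$resids)) {
        r <- tails$resids[k]
        set_atom <- function(nm, pos) {
          i <- which(a$chain == tails$chain & a$resid == r & a$name == nm)
          if (length(i) == 1) xyz[i, ] <<- pos
        }
        set_atom("N", bb$N[k, ]); set_atom("CA", bb$CA[k, ])
        set_atom("C", bb$C[k, ]); set_atom("O", bb$O[k, ])
        set_atom("CB", bb$CB[k, ])
        tip <- bb$CB[k, ] + 1.5 * (bb$CB[k, ] - bb$CA[k, ]) /
          sqrt(sum((bb$CB[k, ] - bb$CA[k, ])^2))
        set_atom("NZ", tip); set_atom("OG", tip)
      }
    }
    if (!is.null(contact_info)) {
      for (r in seq_along(contact_info)) {
        ci <- contact_info[[r]]
        dist_on <- if (truth$contact_on[f, r]) 3.0 else 9.0
        tgt <- xyz[ci$target, ]
        outward <- c(tgt[1], tgt[2], 0)
        outward <- outward / sqrt(sum(outward^2))
        target <- tgt + dist_on * outward
        shift <- target - xyz[ci$probe, ]
        xyz[ci$res_idx, ] <- sweep(xyz[ci$res_idx, , drop = FALSE], 2, -shift)
      }
    }
    if (!is.null(hbond_info)) {
      u <- c(0, 0, 1)
      for (r in seq_along(hbond_info)) {
        hi <- hbond_info[[r]]
        d_on <- if (truth$hbond_on[f, r]) 2.8 else 4.5
        target <- xyz[hi$acceptor, ] + d_on * u
        shift <- target - xyz[hi$donor, ]
        xyz[hi$res_idx, ] <- sweep(xyz[hi$res_idx, , drop = FALSE], 2, -shift)
        xyz[hi$hydrogen, ] <- xyz[hi$donor, ] - 1.0 * u
      }
    }
    if (cfg$tumble) {
      R <- random_rotation()
      tr <- stats::runif(3, -20, 20)
      xyz <- sweep(xyz %*% R, 2, -tr)
    }
    coords[f, ] <- as.vector(t(xyz))
  }

  trajectory <- md_trajectory(model, coords, dt_ns = cfg$dt_ns)
  pairs <- pair_bases(model, dyad_resid)
  list(trajectory = trajectory, model = model, pairs = pairs,
       truth = truth, config = cfg)
}
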
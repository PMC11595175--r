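# Geometric hydrogen-bond analysis.
#
# A bond between donor D (N/O with an attached hydrogen) and acceptor A is
# present when the D-A distance is at most 3 Angstrom and the D-H-A angle
# deviates from linearity by at most 20 degrees (i.e. angle >= 160 degrees),
# the convention of the VMD HBond plugin.  When the model carries no
# hydrogens, the angle criterion is waived with a warning.

hb_angle_deg <- function(d, h, a) {
  v1 <- d - h
  v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# hydrogens within bond_cut of a donor heavy atom (distance-based bonding
# when the topology has no explicit connectivity)
attached_hydrogens <- function(model, coords, donor_idx, bond_cut = 1.25) {
  h_idx <- which(model$atoms$is_hydrogen)
  if (!length(h_idx)) return(integer())
  d <- cross_dist(coords[donor_idx, , drop = FALSE], coords[h_idx, , drop = FALSE])
  h_idx[d[1, ] < bond_cut]
}

#' Detect geometric hydrogen bonds in one frame
#'
#' @param coords n x 3 coordinates of the frame.
#' @param model `structure_model`.
#' @param donors `selection` of donor heavy atoms (N/O); hydrogens are
#'   resolved from the model by distance (< 1.25 Angstrom).
#' @param acceptors `selection` of acceptor heavy atoms.
#' @param d_a_cutoff_A donor-acceptor distance cutoff, inclusive (default 3).
#' @param angle_cutoff_deg maximum deviation of the D-H-A angle from 180
#'   degrees (default 20).
#' @return data.frame with one row per bond: `donor`, `hydrogen`, `acceptor`
#'   atom indices (`hydrogen` is `NA` when the angle criterion was waived).
#' @export
detect_hbonds <- function(coords, model, donors, acceptors,
                          d_a_cutoff_A = 3.0, angle_cutoff_deg = 20.0) {
  di <- setdiff(donors$indices, which(model$atoms$is_hydrogen))
  ai <- setdiff(acceptors$indices, which(model$atoms$is_hydrogen))
  di <- di[model$atoms$element[di] %in% c("N", "O")]
  out <- list()
  model_has_h <- any(model$atoms$is_hydrogen)
  for (d in di) {
    hs <- if (model_has_h) attached_hydrogens(model, coords, d) else integer()
    if (model_has_h && !length(hs)) {
      warning("donor atom ", d, " (", model$atoms$name[d],
              ") has no attachable hydrogen; skipped")
      next
    }
    for (a in setdiff(ai, d)) {
      dda <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (dda > d_a_cutoff_A) next
      if (!model_has_h) {
        out[[length(out) + 1L]] <- c(d, NA_integer_, a)
        next
      }
      for (h in hs) {
        ang <- hb_angle_deg(coords[d, ], coords[h, ], coords[a, ])
        if (180 - ang <= angle_cutoff_deg) {
          out[[length(out) + 1L]] <- c(d, h, a)
          break
        }
      }
    }
  }
  if (!model_has_h && length(di)) {
    warning("model has no hydrogens; D-H-A angle criterion waived")
  }
  res <- if (length(out)) as.data.frame(do.call(rbind, out)) else
    data.frame(V1 = integer(), V2 = integer(), V3 = integer())
  names(res) <- c("donor", "hydrogen", "acceptor")
  res
}

#' Hydrogen-bond presence series and occupancy between two residues
#'
#' Scans all donor/acceptor combinations between the two residues (or a fixed
#' atom pair when `donor_atom`/`acceptor_atom` are given) in every frame; the
#' bond is counted present in a frame when any combination qualifies.
#'
#' @param trajectory `md_trajectory`
#' @param donor_chain,donor_resid residue donating the hydrogen.
#' @param acceptor_chain,acceptor_resid accepting residue.
#' @param donor_atom,acceptor_atom optional atom names fixing the pair (e.g.
#'   a serine `OG` donating to a backbone `O`).
#' @param d_a_cutoff_A,angle_cutoff_deg geometric criteria (3 Angstrom, 20
#'   degrees).
#' @return object of class `bond_series`: logical `present` per frame,
#'   `occupancy` fraction, `dt_ns`, and the residue/atom spec.
#' @export
bond_occupancy <- function(trajectory, donor_chain, donor_resid,
                           acceptor_chain, acceptor_resid,
                           donor_atom = NULL, acceptor_atom = NULL,
                           d_a_cutoff_A = 3.0, angle_cutoff_deg = 20.0) {
  model <- trajectory$model
  a <- model$atoms
  don_expr <- paste("chain", donor_chain, "and resid", donor_resid, "and heavy")
  acc_expr <- paste("chain", acceptor_chain, "and resid", acceptor_resid, "and heavy")
  donors <- select_atoms(model, don_expr)
  acceptors <- select_atoms(model, acc_expr)
  if (!is.null(donor_atom)) {
    donors$indices <- donors$indices[a$name[donors$indices] %in% donor_atom]
  }
  donors$indices <- donors$indices[a$element[donors$indices] %in% c("N", "O")]
  if (!is.null(acceptor_atom)) {
    acceptors$indices <- acceptors$indices[a$name[acceptors$indices] %in% acceptor_atom]
  }
  acceptors$indices <- acceptors$indices[a$element[acceptors$indices] %in% c("N", "O")]
  nf <- n_frames(trajectory)
  present <- logical(nf)
  if (!length(donors$indices) || !length(acceptors$indices)) {
    warning("residue pair has no donor/acceptor atoms; occupancy is 0")
  } else {
    for (f in seq_len(nf)) {
      hb <- suppressWarnings(detect_hbonds(
        frame_coords(trajectory, f), model, donors, acceptors,
        d_a_cutoff_A = d_a_cutoff_A, angle_cutoff_deg = angle_cutoff_deg))
      present[f] <- nrow(hb) > 0
    }
  }
  structure(
    list(present = present, occupancy = mean(present), dt_ns = trajectory$dt_ns,
         donor = paste0(donor_chain, ":", donor_resid,
                        if (!is.null(donor_atom)) paste0(":", donor_atom)),
         acceptor = paste0(acceptor_chain, ":", acceptor_resid,
                           if (!is.null(acceptor_atom)) paste0(":", acceptor_atom))),
    class = "bond_series"
  )
}

#' @export
print.bond_series <- function(x, ...) {
  cat("bond_series ", x$donor, " -> ", x$acceptor, ": occupancy ",
      round(100 * x$occupancy, 1), "% over ", length(x$present), " frames\n", sep = "")
  invisible(x)
}

#' Residence-time analysis of a bond presence series
#'
#' Maximal runs of presence, optionally bridging interruptions of up to
#' `gap_tolerance_frames` absent frames, converted to times with the frame
#' spacing.
#'
#' @param series `bond_series` (or a logical vector plus `dt_ns`).
#' @param gap_tolerance_frames non-negative integer; absences up to this long
#'   inside a run do not terminate it (default 0).
#' @param dt_ns frame spacing when `series` is a bare logical vector.
#' @return list with `runs_frames`, `mean_ns`, `max_ns`, `n_events`.
#' @export
residence_times <- function(series, gap_tolerance_frames = 0, dt_ns = NULL) {
  if (inherits(series, "bond_series")) {
    present <- series$present
    dt_ns <- series$dt_ns
  } else {
    present <- as.logical(series)
    if (is.null(dt_ns)) dt_ns <- 1.0
  }
  if (!length(present)) stop("empty presence series")
  if (gap_tolerance_frames < 0) stop("gap tolerance must be non-negative")
  r <- rle(present)
  # absorb short absence gaps between presence runs
  if (gap_tolerance_frames > 0 && length(r$lengths) > 2) {
    vals <- r$values
    lens <- r$lengths
    interior <- which(!vals & lens <= gap_tolerance_frames &
                        seq_along(vals) > 1 & seq_along(vals) < length(vals))
    vals[interior] <- TRUE
    r <- rle(inverse.rle(list(lengths = lens, values = vals)))
  }
  runs <- r$lengths[r$values]
  if (!length(runs)) {
    return(list(runs_frames = integer(), mean_ns = NA_real_, max_ns = NA_real_,
                n_events = 0L))
  }
  list(runs_frames = as.integer(runs),
       mean_ns = mean(runs) * dt_ns,
       max_ns = max(runs) * dt_ns,
       n_events = length(runs))
}
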
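# DNA unwrapping analysis.
#
# Unwrapping on one side is the length of the contiguous run of core base
# pairs, starting at the entry-exit site (|bp| = 73) and moving toward the
# dyad, whose centers have moved away from the positions of every base pair in
# the initial structure by more than a threshold (7 Angstrom by default).  The
# "every base pair" reading (minimum distance over ALL initial centers,
# including the linkers) deliberately keeps register shifts / DNA sliding from
# counting as unwrapping.

#' Superpose every frame onto a reference frame
#'
#' Rigid-body least-squares superposition of each frame onto the chosen
#' reference frame using a fit selection (typically the histone-fold Calpha
#' atoms).  Required before unwrapping analysis, since the octamer is only
#' weakly restrained during production and may tumble.
#'
#' @param trajectory `md_trajectory`
#' @param reference_frame 1-based index of the frame superposed onto.
#' @param fit_selection `selection` of at least 3 atoms used for the fit.
#' @return `md_trajectory` with superposed coordinates and a per-frame fit
#'   RMSD (Angstrom) in attribute/element `fit_rmsd`.
#' @export
superpose <- function(trajectory, reference_frame = 1, fit_selection) {
  stopifnot(inherits(trajectory, "md_trajectory"), inherits(fit_selection, "selection"))
  idx <- fit_selection$indices
  if (length(idx) < 3) stop("fit selection must contain at least 3 atoms, got ",
                            length(idx))
  xyz_inds <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  ref <- trajectory$coords[reference_frame, ]
  fitted <- bio3d::fit.xyz(
    fixed = ref, mobile = trajectory$coords,
    fixed.inds = xyz_inds, mobile.inds = xyz_inds
  )
  if (!is.matrix(fitted)) fitted <- matrix(fitted, nrow = 1)
  rmsd <- vapply(seq_len(nrow(fitted)), function(i) {
    d <- fitted[i, xyz_inds] - ref[xyz_inds]
    sqrt(mean(colSums(matrix(d^2, nrow = 3))))
  }, numeric(1))
  out <- md_trajectory(trajectory$model, fitted, dt_ns = trajectory$dt_ns)
  out$fit_rmsd <- rmsd
  out
}

#' Per-frame, per-side DNA unwrapping counts
#'
#' For each frame and each side (proximal = negative bp indices, distal =
#' positive), scans the core base pairs from the entry-exit end (|bp| = 73)
#' toward the dyad.  A base pair is displaced when the minimum distance from
#' its center to the reference set of initial-structure centers exceeds
#' `threshold_A`; the count is the length of the contiguous displaced run from
#' the end.
#'
#' @param trajectory superposed `md_trajectory`
#' @param pairs `base_pair_table`
#' @param threshold_A displacement threshold, Angstrom (default 7).
#' @param reference_frame frame whose centers define the initial structure.
#' @param self_reference if `TRUE`, use the alternative reading where each base
#'   pair is compared only with its own initial position rather than with
#'   every initial center (default `FALSE`).
#' @return data.frame of class `unwrap_series` with columns `frame`,
#'   `proximal`, `distal`; attributes `threshold_A`, `reference_frame`, `dt_ns`.
#' @export
unwrap_count <- function(trajectory, pairs, threshold_A = 7.0,
                         reference_frame = 1, self_reference = FALSE) {
  if (threshold_A <= 0) stop("threshold_A must be positive")
  core <- which(pairs$core)
  if (!length(core)) stop("base-pair table has no core base pairs")
  ref_centers <- bp_centers(trajectory, pairs, reference_frame)
  bp <- pairs$bp
  nf <- n_frames(trajectory)
  prox <- integer(nf)
  dist <- integer(nf)
  # Side scans: proximal from bp -73 up to -1, distal from +73 down to +1.
  scan_prox <- core[order(bp[core])]
  scan_prox <- scan_prox[bp[scan_prox] < 0]
  scan_dist <- core[order(bp[core], decreasing = TRUE)]
  scan_dist <- scan_dist[bp[scan_dist] > 0]
  for (f in seq_len(nf)) {
    centers <- bp_centers(trajectory, pairs, f)
    displaced <- if (self_reference) {
      sqrt(rowSums((centers - ref_centers)^2)) > threshold_A
    } else {
      min_cross_dist(centers, ref_centers) > threshold_A
    }
    prox[f] <- run_from_end(displaced[scan_prox])
    dist[f] <- run_from_end(displaced[scan_dist])
  }
  out <- data.frame(frame = seq_len(nf), proximal = prox, distal = dist)
  attr(out, "threshold_A") <- threshold_A
  attr(out, "reference_frame") <- reference_frame
  attr(out, "dt_ns") <- trajectory$dt_ns
  class(out) <- c("unwrap_series", "data.frame")
  out
}

# length of the leading TRUE run
run_from_end <- function(displaced) {
  if (!length(displaced) || !displaced[1]) return(0L)
  r <- rle(displaced)
  as.integer(r$lengths[1])
}

# per-row minimum Euclidean distance from rows of a to rows of b
min_cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Histogram of unwrapping states
#'
#' Normalised frequency of each unwrapping state 0..`max_bp`, per side.
#'
#' @param series `unwrap_series` from [unwrap_count()]
#' @param max_bp largest state reported (default: observed maximum).
#' @return data.frame with columns `state`, `proximal`, `distal`; each side
#'   column sums to 1.
#' @export
unwrap_histogram <- function(series, max_bp = NULL) {
  if (!nrow(series)) stop("empty unwrapping series")
  if (is.null(max_bp)) max_bp <- max(series$proximal, series$distal)
  states <- 0:max_bp
  tab <- function(x) {
    counts <- tabulate(factor(x, levels = states), nbins = length(states))
    counts / length(x)
  }
  data.frame(state = states, proximal = tab(series$proximal),
             distal = tab(series$distal))
}
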
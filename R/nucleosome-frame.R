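# Base pairing, base-pair centers, and the nucleosome reference frame.
#
# The frame is spanned by the superhelical axis (normal of the least-squares
# plane through the core base-pair centers), the dyad axis (in-plane unit
# vector from the origin to the dyad base-pair center) and a third axis
# completing a right-handed triad.  Projections of Calpha atoms and bp centers
# onto planes of this frame are the standard way nucleosome conformations are
# overlaid and compared.

#' Pair the two DNA strands into base pairs
#'
#' Nucleotide i of strand I (5'->3') is paired with nucleotide L+1-i of strand
#' J, and base-pair indices are shifted so the dyad nucleotide gets index 0.
#' Core positions are -73..+73 (147 bp); indices beyond +-73 are linker.
#'
#' @param model `structure_model` with chain roles `DNA_strand_I` and
#'   `DNA_strand_J` assigned.
#' @param dyad_resid residue number, on strand I, of the dyad nucleotide.
#' @return data.frame of class `base_pair_table` with columns `bp` (signed
#'   index), `resid_i`, `resname_i`, `resid_j`, `resname_j`, `core` (logical).
#' @export
pair_bases <- function(model, dyad_resid) {
  ch_i <- chains_with_role(model, "DNA_strand_I")
  ch_j <- chains_with_role(model, "DNA_strand_J")
  if (length(ch_i) != 1 || length(ch_j) != 1) {
    stop("model must have exactly one DNA_strand_I and one DNA_strand_J chain")
  }
  a <- model$atoms
  res_i <- unique(a[a$chain == ch_i, c("resid", "resname")])
  res_j <- unique(a[a$chain == ch_j, c("resid", "resname")])
  res_i <- res_i[order(res_i$resid), ]
  res_j <- res_j[order(res_j$resid), ]
  L <- nrow(res_i)
  if (L != nrow(res_j)) {
    stop("strand lengths differ: strand I has ", L, " nucleotides, strand J has ",
         nrow(res_j))
  }
  pos_dyad <- match(dyad_resid, res_i$resid)
  if (is.na(pos_dyad)) stop("dyad residue ", dyad_resid, " not on strand I")
  tbl <- data.frame(
    bp = seq_len(L) - pos_dyad,
    chain_i = ch_i,
    resid_i = res_i$resid,
    resname_i = res_i$resname,
    chain_j = ch_j,
    resid_j = res_j$resid[L + 1 - seq_len(L)],
    resname_j = res_j$resname[L + 1 - seq_len(L)],
    stringsAsFactors = FALSE
  )
  tbl$core <- abs(tbl$bp) <= 73
  class(tbl) <- c("base_pair_table", "data.frame")
  tbl
}

# Glycosidic nitrogen of a nucleotide: N9 for purines, N1 for pyrimidines.
glycosidic_name <- function(resname) {
  ifelse(toupper(resname) %in% c("DA", "DG", "A", "G"), "N9", "N1")
}

#' Base-pair centers for one frame
#'
#' The center of a base pair is the midpoint of the glycosidic nitrogens (N9
#' of purines, N1 of pyrimidines) of its two nucleotides.
#'
#' @param trajectory `md_trajectory`
#' @param pairs `base_pair_table` from [pair_bases()]
#' @param frame 1-based frame index
#' @return matrix with one row per base pair (ordered as `pairs`), columns
#'   x, y, z; row names are the bp indices.
#' @export
bp_centers <- function(trajectory, pairs, frame = 1) {
  xyz <- frame_coords(trajectory, frame)
  a <- trajectory$model$atoms
  akey <- paste(a$chain, a$resid, a$name)
  glyc_index <- function(side) {
    ch <- pairs[[paste0("chain_", side)]]
    rn <- pairs[[paste0("resid_", side)]]
    nm <- glycosidic_name(pairs[[paste0("resname_", side)]])
    idx <- match(paste(ch, rn, nm), akey)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop("nucleotide ", ch[bad], ":", rn[bad], " (",
           pairs[[paste0("resname_", side)]][bad],
           ") lacks its glycosidic nitrogen ", nm[bad])
    }
    idx
  }
  centers <- (xyz[glyc_index("i"), , drop = FALSE] +
              xyz[glyc_index("j"), , drop = FALSE]) / 2
  dimnames(centers) <- list(pairs$bp, c("x", "y", "z"))
  centers
}

#' Fit the nucleosome reference frame
#'
#' The superhelical axis is the normal of a pitch-detrended least-squares
#' plane through the core base-pair centers: after an initial SVD plane fit,
#' the helical rise (the linear trend of the out-of-plane component against
#' the unwrapped winding angle) is removed and the plane refitted, which for
#' an ideal superhelix recovers the generating axis essentially exactly
#' rather than the tilted naive plane normal.  The sign follows the
#' right-hand rule of the winding of the centers with increasing bp index;
#' the origin is the centroid of the core centers; the dyad axis is the
#' in-plane unit component of (dyad center - origin); the third axis
#' completes a right-handed orthonormal triad.
#'
#' @param centers bp-center matrix from [bp_centers()] (row names = bp index).
#' @param core_range length-2 integer interval of bp indices used for the fit
#'   (default -60..60, excluding the breathing ends).
#' @return object of class `nucleosome_frame` with `origin`,
#'   `axis_superhelical`, `axis_dyad`, `axis_third`.
#' @export
fit_frame <- function(centers, core_range = c(-60, 60)) {
  bp <- as.integer(rownames(centers))
  use <- bp >= core_range[1] & bp <= core_range[2]
  if (sum(use) < 10) stop("need at least 10 core bp centers, got ", sum(use))
  pts <- centers[use, , drop = FALSE]
  ord <- order(bp[use])
  pts <- pts[ord, , drop = FALSE]
  origin <- colMeans(pts)
  centered <- sweep(pts, 2, origin)
  sv <- svd(centered)
  if (sv$d[2] < 1e-8 * sv$d[1]) stop("degenerate (collinear) base-pair centers")
  normal <- sv$v[, 3]
  # Remove the helical rise along the current normal and refit; repeat.
  s_idx <- sort(bp[use])  # rise is linear in bp index for an ideal superhelix
  detrended <- centered
  for (iter in 1:4) {
    z <- as.numeric(detrended %*% normal)
    co <- stats::coef(stats::lm.fit(cbind(1, s_idx), z))
    detrended <- detrended - outer(as.numeric(co[1] + co[2] * s_idx), normal)
    detrended <- sweep(detrended, 2, colMeans(detrended))
    sv2 <- svd(detrended)
    new_normal <- sv2$v[, 3]
    if (sum(new_normal * normal) < 0) new_normal <- -new_normal
    if (sum(abs(new_normal - normal)) < 1e-12) { normal <- new_normal; break }
    normal <- new_normal
  }
  # Right-hand rule over the winding: sum of successive cross products.
  p <- centered
  w <- c(0, 0, 0)
  for (k in seq_len(nrow(p) - 1)) w <- w + cross3(p[k, ], p[k + 1, ])
  if (sum(w * normal) < 0) normal <- -normal
  if (!any(bp == 0)) stop("centers do not include the dyad (bp 0)")
  d <- centers[which(bp == 0), ] - origin
  d_in <- d - sum(d * normal) * normal
  nd <- sqrt(sum(d_in^2))
  if (nd < 1e-8) stop("dyad center coincides with the origin; dyad axis undefined")
  axis_dyad <- d_in / nd
  axis_third <- cross3(normal, axis_dyad)
  structure(
    list(origin = unname(origin),
         axis_superhelical = unname(normal),
         axis_dyad = unname(axis_dyad),
         axis_third = unname(axis_third)),
    class = "nucleosome_frame"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.nucleosome_frame <- function(x, ...) {
  cat("nucleosome_frame\n  origin:", round(x$origin, 3), "\n")
  cat("  superhelical axis:", round(x$axis_superhelical, 4), "\n")
  cat("  dyad axis:        ", round(x$axis_dyad, 4), "\n")
  invisible(x)
}

#' Project points onto a plane of the nucleosome frame
#'
#' Planes: `nucleosomal_plane` is perpendicular to the superhelical axis with
#' (u, v) along (dyad, third) axes; `dyad_plane` is perpendicular to the third
#' axis with (u, v) along (dyad, superhelical); `perpendicular_plane` is
#' perpendicular to the dyad axis with (u, v) along (third, superhelical).
#'
#' @param points n x 3 matrix (Angstrom).
#' @param frame `nucleosome_frame`.
#' @param plane plane name.
#' @return data.frame with columns `u`, `v` (Angstrom).
#' @export
project_points <- function(points, frame,
                           plane = c("nucleosomal_plane", "dyad_plane",
                                     "perpendicular_plane")) {
  plane <- match.arg(plane)
  stopifnot(inherits(frame, "nucleosome_frame"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  axes <- switch(plane,
    nucleosomal_plane = list(frame$axis_dyad, frame$axis_third),
    dyad_plane = list(frame$axis_dyad, frame$axis_superhelical),
    perpendicular_plane = list(frame$axis_third, frame$axis_superhelical)
  )
  rel <- sweep(points, 2, frame$origin)
  data.frame(u = as.numeric(rel %*% axes[[1]]),
             v = as.numeric(rel %*% axes[[2]]))
}
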
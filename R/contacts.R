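# Protein-DNA atom-atom contact analysis.
#
# A contact is an unordered heavy-atom pair closer than a cutoff (4 Angstrom,
# strict).  Profiles count contacts per (protein residue x nucleotide) cell,
# averaged over frames, with per-cell occupancy (fraction of frames with at
# least one contacting pair) and an autocorrelation-corrected SEM.

cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Count atom-atom contacts in one frame
#'
#' @param coords n x 3 coordinate matrix of the model (one frame).
#' @param model `structure_model` the selections refer to.
#' @param selection_a,selection_b disjoint `selection`s; hydrogens are dropped
#'   from both before counting.
#' @param cutoff_A contact cutoff, Angstrom; pairs at distance strictly less
#'   than the cutoff count (default 4).
#' @return list with `count` (integer) and `pairs` (two-column matrix of atom
#'   indices, a from `selection_a`, b from `selection_b`).
#' @export
frame_contacts <- function(coords, model, selection_a, selection_b, cutoff_A = 4.0) {
  ia <- setdiff(selection_a$indices, which(model$atoms$is_hydrogen))
  ib <- setdiff(selection_b$indices, which(model$atoms$is_hydrogen))
  if (length(intersect(ia, ib))) {
    stop("selections overlap in ", length(intersect(ia, ib)), " atoms")
  }
  if (!length(ia) || !length(ib)) {
    return(list(count = 0L, pairs = matrix(integer(), ncol = 2,
                                           dimnames = list(NULL, c("a", "b")))))
  }
  d <- cross_dist(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE])
  hit <- which(d < cutoff_A, arr.ind = TRUE)
  pairs <- cbind(a = ia[hit[, 1]], b = ib[hit[, 2]])
  list(count = nrow(pairs), pairs = pairs)
}

# Atom indices per nucleotide of the base-pair table, heavy atoms only,
# optionally restricted to a named atom set (e.g. minor-groove atoms).
nucleotide_atom_groups <- function(model, pairs, atom_names = NULL) {
  a <- model$atoms
  groups <- list()
  labels <- character()
  for (k in seq_len(nrow(pairs))) {
    for (side in c("i", "j")) {
      ch <- pairs[[paste0("chain_", side)]][k]
      rn <- pairs[[paste0("resid_", side)]][k]
      sel <- which(a$chain == ch & a$resid == rn & !a$is_hydrogen)
      if (!is.null(atom_names)) sel <- sel[a$name[sel] %in% atom_names]
      lab <- paste0(pairs$bp[k], "/", if (side == "i") "I" else "J")
      groups[[lab]] <- sel
      labels <- c(labels, lab)
    }
  }
  groups
}

# Protein residue grouping of a selection: list of atom-index vectors named
# "chain resid resname", heavy atoms only.
protein_residue_groups <- function(model, selection) {
  a <- model$atoms
  idx <- setdiff(selection$indices, which(a$is_hydrogen))
  if (!length(idx)) stop("protein selection contains no heavy atoms")
  key <- paste(a$chain[idx], a$resid[idx], a$resname[idx])
  ord <- order(match(key, unique(key)))
  split(idx[ord], factor(key[ord], levels = unique(key)))
}

#' Residue-by-nucleotide contact profile over a trajectory
#'
#' For every frame, counts heavy-atom contact pairs between each protein
#' residue of `protein_sel` and each nucleotide of the base-pair table, then
#' summarises per cell: mean, SD over frames, occupancy (fraction of frames
#' with >= 1 pair), and SEM corrected for autocorrelation via
#' [series_stats()].
#'
#' @param trajectory `md_trajectory`
#' @param protein_sel `selection` of protein atoms.
#' @param pairs `base_pair_table`; use `bp_range` to restrict the nucleotide
#'   axis.
#' @param cutoff_A contact cutoff (strict; default 4 Angstrom).
#' @param bp_range optional length-2 interval of bp indices to include.
#' @param atom_names optional character vector restricting nucleotide atoms
#'   (e.g. [minor_groove_atoms()] for a minor-groove profile).
#' @param copy_label free-text label for which H2A copy the profile covers.
#' @return object of class `contact_profile`: matrices `mean`, `sd`, `sem`,
#'   `occupancy` (residues x nucleotides), the per-frame `counts` array, and
#'   bookkeeping fields.
#' @export
contact_profile <- function(trajectory, protein_sel, pairs, cutoff_A = 4.0,
                            bp_range = NULL, atom_names = NULL,
                            copy_label = "copy1") {
  model <- trajectory$model
  if (!is.null(bp_range)) {
    pairs <- pairs[pairs$bp >= bp_range[1] & pairs$bp <= bp_range[2], ]
  }
  res_groups <- protein_residue_groups(model, protein_sel)
  nuc_groups <- nucleotide_atom_groups(model, pairs, atom_names = atom_names)
  prot_idx <- unlist(res_groups, use.names = FALSE)
  nuc_idx <- unlist(nuc_groups, use.names = FALSE)
  nres <- length(res_groups)
  nnuc <- length(nuc_groups)
  # indicator matrices for cell aggregation by matrix product
  P <- matrix(0, length(prot_idx), nres)
  P[cbind(seq_along(prot_idx), rep(seq_len(nres), lengths(res_groups)))] <- 1
  N <- matrix(0, length(nuc_idx), nnuc)
  N[cbind(seq_along(nuc_idx), rep(seq_len(nnuc), lengths(nuc_groups)))] <- 1
  nf <- n_frames(trajectory)
  counts <- array(0, dim = c(nres, nnuc, nf),
                  dimnames = list(names(res_groups), names(nuc_groups), NULL))
  empty_nuc <- lengths(nuc_groups) == 0
  for (f in seq_len(nf)) {
    xyz <- frame_coords(trajectory, f)
    if (!length(nuc_idx)) next
    d <- cross_dist(xyz[prot_idx, , drop = FALSE], xyz[nuc_idx, , drop = FALSE])
    counts[, , f] <- t(P) %*% (d < cutoff_A) %*% N
  }
  mean_m <- apply(counts, c(1, 2), mean)
  sd_m <- apply(counts, c(1, 2), stats::sd)
  if (nf == 1) sd_m[] <- 0
  occ_m <- apply(counts > 0, c(1, 2), mean)
  sem_m <- matrix(0, nres, nnuc, dimnames = dimnames(mean_m))
  for (i in seq_len(nres)) for (j in seq_len(nnuc)) {
    s <- counts[i, j, ]
    sem_m[i, j] <- if (nf >= 10 && stats::sd(s) > 0) series_stats(s)$sem else {
      if (nf > 1) stats::sd(s) / sqrt(nf) else 0
    }
  }
  structure(
    list(mean = mean_m, sd = sd_m, sem = sem_m, occupancy = occ_m,
         counts = counts, n_frames = nf, cutoff_A = cutoff_A,
         copy_label = copy_label, bp = pairs$bp, atom_names = atom_names),
    class = "contact_profile"
  )
}

#' @export
print.contact_profile <- function(x, ...) {
  cat("contact_profile [", x$copy_label, "]: ", nrow(x$mean), " residues x ",
      ncol(x$mean), " nucleotides over ", x$n_frames, " frames (cutoff ",
      x$cutoff_A, " A)\n", sep = "")
  invisible(x)
}

#' Stable contacts of a profile
#'
#' Cells whose occupancy (fraction of frames with any atom pair in contact) is
#' at least the threshold; the canonical stability threshold is 25 percent of
#' frames, boundary inclusive.
#'
#' @param profile `contact_profile`
#' @param threshold occupancy threshold in (0, 1] (default 0.25).
#' @return data.frame with columns `residue`, `nucleotide`, `occupancy`.
#' @export
stable_contacts <- function(profile, threshold = 0.25) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  hit <- which(profile$occupancy >= threshold, arr.ind = TRUE)
  out <- data.frame(
    residue = rownames(profile$occupancy)[hit[, 1]],
    nucleotide = colnames(profile$occupancy)[hit[, 2]],
    occupancy = profile$occupancy[hit]
  )
  out[order(out$residue, out$nucleotide), , drop = FALSE]
}

# map a nucleotide label "bp/strand" to its symmetry mate "-bp/other strand"
symmetry_map_labels <- function(labels) {
  parts <- strsplit(labels, "/", fixed = TRUE)
  vapply(parts, function(p) {
    paste0(-as.integer(p[1]), "/", if (p[2] == "I") "J" else "I")
  }, character(1))
}

#' Symmetrise two per-copy contact profiles
#'
#' Maps the second copy's nucleotide axis through the nucleosome pseudo-dyad
#' (bp index negated, strands swapped) onto the first copy's axis, then
#' combines: `mode = "mean"` averages the per-cell statistics over the two
#' copies; `mode = "union_presence"` reports a cell present when either copy
#' has non-zero occupancy (occupancy = per-cell maximum).
#'
#' @param profile_copy1,profile_copy2 `contact_profile`s with residue axes of
#'   equal length (variant-aware alignment is the caller's responsibility).
#' @param mode `"mean"` or `"union_presence"`.
#' @return `contact_profile` (without per-frame counts) labelled `"combined"`;
#'   for `union_presence` an additional logical `presence` matrix is set.
#' @export
symmetrize_profile <- function(profile_copy1, profile_copy2,
                               mode = c("mean", "union_presence")) {
  mode <- match.arg(mode)
  p1 <- profile_copy1
  p2 <- profile_copy2
  if (nrow(p1$mean) != nrow(p2$mean)) {
    stop("residue axes differ in length (", nrow(p1$mean), " vs ", nrow(p2$mean), ")")
  }
  mapped <- symmetry_map_labels(colnames(p2$mean))
  common <- intersect(colnames(p1$mean), mapped)
  if (!length(common)) stop("no overlapping nucleotide positions after mapping")
  j1 <- match(common, colnames(p1$mean))
  j2 <- match(common, mapped)
  take <- function(m, j) m[, j, drop = FALSE]
  out <- list(n_frames = p1$n_frames + p2$n_frames, cutoff_A = p1$cutoff_A,
              copy_label = "combined", atom_names = p1$atom_names)
  if (mode == "mean") {
    out$mean <- (take(p1$mean, j1) + take(p2$mean, j2)) / 2
    out$sd <- (take(p1$sd, j1) + take(p2$sd, j2)) / 2
    out$sem <- sqrt(take(p1$sem, j1)^2 + take(p2$sem, j2)^2) / 2
    out$occupancy <- (take(p1$occupancy, j1) + take(p2$occupancy, j2)) / 2
  } else {
    out$occupancy <- pmax(take(p1$occupancy, j1), take(p2$occupancy, j2))
    out$presence <- take(p1$occupancy, j1) > 0 | take(p2$occupancy, j2) > 0
    out$mean <- pmax(take(p1$mean, j1), take(p2$mean, j2))
    out$sd <- pmax(take(p1$sd, j1), take(p2$sd, j2))
    out$sem <- pmax(take(p1$sem, j1), take(p2$sem, j2))
  }
  colnames(out$mean) <- common
  structure(out, class = "contact_profile")
}

#' Aggregate contacts over a tail residue interval
#'
#' Sums the per-frame contact counts over all residues in the interval and all
#' nucleotides, then reports the mean total and its autocorrelation-corrected
#' SEM.  Used for statements like "the tails account for around 130 atom-atom
#' contacts".
#'
#' @param profile `contact_profile` carrying per-frame counts.
#' @param resid_range length-2 residue-number interval (on the profile's
#'   residue axis).
#' @return list with `mean`, `sem`, `series` (per-frame totals) and
#'   `residues` used.
#' @export
tail_aggregate <- function(profile, resid_range) {
  if (is.null(profile$counts)) stop("profile carries no per-frame counts")
  res_ids <- as.integer(vapply(strsplit(rownames(profile$mean), " "), `[`, "", 2))
  use <- which(res_ids >= resid_range[1] & res_ids <= resid_range[2])
  if (!length(use)) stop("no profile residues in interval ",
                         resid_range[1], "-", resid_range[2])
  series <- apply(profile$counts[use, , , drop = FALSE], 3, sum)
  st <- if (length(series) >= 10 && stats::sd(series) > 0) series_stats(series) else
    list(mean = mean(series),
         sem = if (length(series) > 1) stats::sd(series) / sqrt(length(series)) else 0)
  list(mean = st$mean, sem = st$sem, series = series,
       residues = rownames(profile$mean)[use])
}

#' Mean heavy-atom distance between two residues, per frame
#'
#' The distance between two residues is the arithmetic mean over all
#' heavy-atom cross pairs.
#'
#' @param trajectory `md_trajectory`
#' @param chain_a,resid_a,chain_b,resid_b residue addresses.
#' @return numeric vector, one mean distance (Angstrom) per frame.
#' @export
residue_pair_distance <- function(trajectory, chain_a, resid_a, chain_b, resid_b) {
  a <- trajectory$model$atoms
  ia <- which(a$chain == chain_a & a$resid == resid_a & !a$is_hydrogen)
  ib <- which(a$chain == chain_b & a$resid == resid_b & !a$is_hydrogen)
  if (!length(ia)) stop("residue ", chain_a, ":", resid_a, " has no heavy atoms")
  if (!length(ib)) stop("residue ", chain_b, ":", resid_b, " has no heavy atoms")
  vapply(seq_len(n_frames(trajectory)), function(f) {
    xyz <- frame_coords(trajectory, f)
    mean(cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE]))
  }, numeric(1))
}

#' Default minor-groove-facing nucleobase atom names
#'
#' Atoms of the nucleobases lining the DNA minor groove: purine N3 and C4 and
#' pyrimidine O2 (plus C2 common to both edges).  Used to restrict contact
#' profiles to minor-groove insertions such as the H2A N-tail arginine anchor.
#'
#' @return character vector of atom names.
#' @export
minor_groove_atoms <- function() c("N3", "C2", "O2", "C4")
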
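# Backbone torsion analysis: phi/psi series, Ramachandran-state
# classification, and transition counting for peptide-plane flips.

#' Signed dihedral angle over a trajectory
#'
#' Conventional atan2 dihedral of four atoms, in degrees in (-180, 180].
#' Near-collinear inner triples make the angle undefined; those frames are
#' returned as `NA` with a warning.
#'
#' @param trajectory `md_trajectory`
#' @param atom_indices integer vector of four distinct atom indices.
#' @return numeric vector, one angle (degrees) per frame.
#' @export
torsion <- function(trajectory, atom_indices) {
  stopifnot(length(atom_indices) == 4, !anyDuplicated(atom_indices))
  n <- n_frames(trajectory)
  out <- numeric(n)
  for (f in seq_len(n)) {
    xyz <- frame_coords(trajectory, f)
    out[f] <- dihedral_xyz(xyz[atom_indices[1], ], xyz[atom_indices[2], ],
                           xyz[atom_indices[3], ], xyz[atom_indices[4], ])
  }
  if (anyNA(out)) warning("dihedral undefined (collinear atoms) in ",
                          sum(is.na(out)), " frame(s)")
  out
}

# atan2 dihedral for one quadruple, degrees in (-180, 180]
dihedral_xyz <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) return(NA_real_)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi series for a residue interval
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).  Terminal
#' residues yield only the defined angle; a chain break (peptide C-N distance
#' above 2.5 Angstrom in the first frame) leaves the spanning angle undefined
#' with a warning.
#'
#' @param trajectory `md_trajectory`
#' @param chain chain id.
#' @param resid_range length-2 residue-number interval.
#' @return data.frame with columns `frame`, `resid`, `phi`, `psi` (degrees,
#'   `NA` where undefined).
#' @export
phi_psi <- function(trajectory, chain, resid_range) {
  a <- trajectory$model$atoms
  resids <- sort(unique(a$resid[a$chain == chain &
                                  a$resid >= resid_range[1] &
                                  a$resid <= resid_range[2]]))
  if (!length(resids)) stop("no residues of chain ", chain, " in interval")
  find <- function(r, nm) {
    i <- which(a$chain == chain & a$resid == r & a$name == nm)
    if (length(i) == 1) i else NA_integer_
  }
  xyz1 <- frame_coords(trajectory, 1)
  peptide_ok <- function(c_prev, n_this) {
    !is.na(c_prev) && !is.na(n_this) &&
      sqrt(sum((xyz1[c_prev, ] - xyz1[n_this, ])^2)) <= 2.5
  }
  nf <- n_frames(trajectory)
  rows <- list()
  for (r in resids) {
    Ni <- find(r, "N"); CAi <- find(r, "CA"); Ci <- find(r, "C")
    Cprev <- find(r - 1, "C"); Nnext <- find(r + 1, "N")
    phi <- rep(NA_real_, nf); psi <- rep(NA_real_, nf)
    if (!anyNA(c(Ni, CAi, Ci))) {
      if (!is.na(Cprev)) {
        if (peptide_ok(Cprev, Ni)) {
          phi <- suppressWarnings(torsion(trajectory, c(Cprev, Ni, CAi, Ci)))
        } else {
          warning("chain break before residue ", chain, ":", r, "; phi undefined")
        }
      }
      if (!is.na(Nnext)) {
        if (peptide_ok(Ci, Nnext)) {
          psi <- suppressWarnings(torsion(trajectory, c(Ni, CAi, Ci, Nnext)))
        } else {
          warning("chain break after residue ", chain, ":", r, "; psi undefined")
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(frame = seq_len(nf), resid = r,
                                            phi = phi, psi = psi)
  }
  do.call(rbind, rows)
}

# wrap-aware membership of (phi, psi) in a rectangle on the torus
in_region <- function(phi, psi, region) {
  wrap_in <- function(x, lo, hi) {
    x <- (x + 180) %% 360 - 180
    if (lo <= hi) x >= lo & x <= hi
    else x >= lo | x <= hi  # interval crossing the +-180 seam
  }
  wrap_in(phi, region$phi[1], region$phi[2]) &
    wrap_in(psi, region$psi[1], region$psi[2])
}

#' Classify phi/psi frames into named Ramachandran regions
#'
#' Regions are named rectangles on the (phi, psi) torus (each a list with
#' `phi = c(lo, hi)`, `psi = c(lo, hi)`, wrap-aware); frames outside every
#' region are labelled `"other"`.  Regions may not overlap.
#'
#' @param phi,psi numeric vectors of equal length (degrees).
#' @param regions named list of regions.
#' @return list with `labels` (character per frame), `transitions` (number of
#'   label changes), `dwell_frames` (run lengths per state), `occupancy`
#'   (fraction of frames per label, including `"other"`).
#' @export
classify_states <- function(phi, psi, regions) {
  stopifnot(length(phi) == length(psi), length(regions) >= 1,
            !is.null(names(regions)))
  # overlap check on a coarse torus grid
  grid <- expand.grid(phi = seq(-177.5, 177.5, by = 5),
                      psi = seq(-177.5, 177.5, by = 5))
  cover <- rowSums(sapply(regions, function(r) in_region(grid$phi, grid$psi, r)))
  if (any(cover > 1)) stop("regions overlap on the torus")
  labels <- rep("other", length(phi))
  for (nm in names(regions)) {
    hit <- in_region(phi, psi, regions[[nm]]) & labels == "other"
    labels[hit] <- nm
  }
  labels[is.na(phi) | is.na(psi)] <- NA_character_
  ok <- !is.na(labels)
  trans <- if (sum(ok) > 1) sum(labels[ok][-1] != labels[ok][-sum(ok)]) else 0L
  r <- rle(labels[ok])
  occ <- table(factor(labels[ok], levels = c(names(regions), "other")))
  list(labels = labels,
       transitions = as.integer(trans),
       dwell_frames = setNames(as.integer(r$lengths), r$values),
       occupancy = setNames(as.numeric(occ) / max(sum(ok), 1),
                            c(names(regions), "other")))
}
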
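# Independent oracles and small fixtures used across the suite.

# Brute-force contact count: explicit loop over atoms of A against B.
bf_contact_count <- function(xa, xb, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(xa))) {
    d <- sqrt((xa[i, 1] - xb[, 1])^2 + (xa[i, 2] - xb[, 2])^2 +
                (xa[i, 3] - xb[, 3])^2)
    n <- n + sum(d < cutoff)
  }
  n
}

# Brute-force mean cross-pair distance between two atom sets.
bf_mean_pair_distance <- function(xa, xb) {
  tot <- 0
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    tot <- tot + sqrt(sum((xa[i, ] - xb[j, ])^2))
  }
  tot / (nrow(xa) * nrow(xb))
}

# Independent dihedral formula: angle between the two plane normals, signed
# by the triple product (deliberately a different construction from the
# package's atan2-on-projections form).
bf_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(p2 - p1, p3 - p2)
  n2 <- cr(p3 - p2, p4 - p3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(min(max(cosphi, -1), 1)) * 180 / pi
  if (sum(cr(n1, n2) * (p3 - p2)) < 0) phi <- -phi
  if (phi <= -180) phi <- phi + 360
  phi
}

# Minimal hand-built protein/DNA model from an atom spec data.frame with
# columns name, element, chain, resid, resname, x, y, z.
toy_model <- function(spec, chain_roles = NULL) {
  structure_model(
    spec[, c("name", "element", "chain", "resid", "resname")],
    as.matrix(spec[, c("x", "y", "z")]),
    chain_roles = chain_roles
  )
}

toy_row <- function(name, element, chain, resid, resname, x, y, z) {
  data.frame(name = name, element = element, chain = chain, resid = resid,
             resname = resname, x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# One-frame trajectory around a model (optionally n identical frames).
toy_trajectory <- function(model, n = 1, dt_ns = 1) {
  md_trajectory(model, matrix(rep(as.vector(t(model$coords)), n),
                              nrow = n, byrow = TRUE), dt_ns = dt_ns)
}

# A small default synthetic system reused by several files (cheap: 1 frame).
synth_one_frame <- function(...) {
  simulate_nucleosome(synth_config(n_frames = 1, noise_sd_A = 0, seed = 1, ...))
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

quad_trajectory <- function(p) {
  m <- toy_model(do.call(rbind, lapply(1:4, function(i)
    toy_row(paste0("C", i), "C", "A", i, "ALA", p[i, 1], p[i, 2], p[i, 3]))))
  toy_trajectory(m)
}

hb_model <- function(da_dist, angle_deg) {
  # donor N at origin with H along +x; acceptor O placed so that the
  # D-H-A angle equals angle_deg at the given D-A distance
  h <- c(1, 0, 0)
  if (angle_deg == 180) {
    acc <- c(da_dist, 0, 0)  # exactly collinear, exact D-A distance
  } else {
    # direction from H making angle_deg with H->D ( = -x ), in the xz-plane
    dir <- c(-cos(angle_deg * pi / 180), 0, sin(angle_deg * pi / 180))
    # find t > 0 so that |h + t*dir| = da_dist (distance from donor at origin)
    roots <- Re(polyroot(c(1 - da_dist^2, 2 * dir[1], 1)))
    t <- max(roots)
    acc <- h + t * dir
  }
  toy_model(rbind(
    toy_row("N", "N", "A", 1, "ASN", 0, 0, 0),
    toy_row("H", "H", "A", 1, "ASN", 1, 0, 0),
    toy_row("O", "O", "B", 2, "SER", acc[1], acc[2], acc[3])
  ))
}

hb_present <- function(m, ...) {
  hb <- suppressWarnings(detect_hbonds(m$coords, m, select_atoms(m, "chain A"),
                                       select_atoms(m, "chain B"), ...))
  nrow(hb) > 0
}
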
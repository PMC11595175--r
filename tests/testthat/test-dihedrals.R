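test_that("planar trans and cis geometries give 180 and 0 degrees", {
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(torsion(quad_trajectory(trans), 1:4), 180)
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(torsion(quad_trajectory(cis), 1:4), 0)
})

test_that("torsion matches two independent formulations on random quadruples", {
  set.seed(31)
  for (i in 1:100) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    tr <- quad_trajectory(p)
    got <- torsion(tr, 1:4)
    expect_equal(got, bf_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    # cross-check against bio3d's implementation
    expect_equal(got, bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("torsion is rigid-motion invariant, reversal-invariant, mirror-odd", {
  set.seed(32)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    base <- torsion(quad_trajectory(p), 1:4)
    R <- random_rotation_matrix()
    moved <- sweep(p %*% R, 2, -runif(3, -10, 10))
    expect_equal(torsion(quad_trajectory(moved), 1:4), base, tolerance = 1e-8)
    # the conventional signed dihedral reads the same from either chain end
    expect_equal(torsion(quad_trajectory(p[4:1, ]), 1:4), base, tolerance = 1e-8)
    # a mirror reflection flips the sign
    mirrored <- p %*% diag(c(1, 1, -1))
    if (abs(abs(base) - 180) > 1e-6) {
      expect_equal(torsion(quad_trajectory(mirrored), 1:4), -base,
                   tolerance = 1e-8)
    }
  }
})

test_that("collinear quadruples are flagged as undefined", {
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_warning(out <- torsion(quad_trajectory(line), 1:4), "collinear")
  expect_true(is.na(out))
})

test_that("phi/psi follow the backbone convention on the synthetic C-tail", {
  sim <- synth_one_frame()
  pp <- phi_psi(sim$trajectory, "C", c(118, 129))
  # generator builds the tail with phi = -60, psi = -45
  expect_equal(unique(round(stats::na.omit(pp$phi), 6)), -60)
  expect_equal(unique(round(stats::na.omit(pp$psi), 6)), -45)
  # the last residue has no following N: psi undefined there
  expect_true(all(is.na(pp$psi[pp$resid == 129])))
  expect_false(any(is.na(pp$phi[pp$resid == 129])))
  expect_error(phi_psi(sim$trajectory, "C", c(4000, 4100)), "no residues")
})

test_that("an ideal alpha-helical stretch returns canonical angles", {
  bb <- nuctraj:::build_backbone(6, phi = rep(-57, 6), psi = rep(-47, 6),
                                 anchor = rbind(c(-2.4, 0.8, 0),
                                                c(-1.2, -0.4, 0), c(0, 0, 0)))
  spec <- do.call(rbind, lapply(1:6, function(k) rbind(
    toy_row("N", "N", "A", k, "ALA", bb$N[k, 1], bb$N[k, 2], bb$N[k, 3]),
    toy_row("CA", "C", "A", k, "ALA", bb$CA[k, 1], bb$CA[k, 2], bb$CA[k, 3]),
    toy_row("C", "C", "A", k, "ALA", bb$C[k, 1], bb$C[k, 2], bb$C[k, 3])
  )))
  tr <- toy_trajectory(toy_model(spec))
  pp <- phi_psi(tr, "A", c(2, 5))
  expect_equal(mean(pp$phi, na.rm = TRUE), -57, tolerance = 2)
  expect_equal(mean(pp$psi, na.rm = TRUE), -47, tolerance = 2)
})

test_that("state classification counts transitions and respects regions", {
  regions <- list(alpha = list(phi = c(-100, -20), psi = c(-80, 0)),
                  beta = list(phi = c(-180, -120), psi = c(120, 180)))
  cl <- classify_states(rep(-60, 5), rep(-45, 5), regions)
  expect_equal(cl$transitions, 0)
  expect_equal(unname(cl$occupancy["alpha"]), 1)

  phi <- c(-60, -150, -60, -150)
  psi <- c(-45, 150, -45, 150)
  cl2 <- classify_states(phi, psi, regions)
  expect_equal(cl2$labels, c("alpha", "beta", "alpha", "beta"))
  expect_equal(cl2$transitions, 3)
  expect_equal(sum(cl2$occupancy), 1)

  overlapping <- list(a = list(phi = c(-100, 0), psi = c(-100, 0)),
                      b = list(phi = c(-50, 50), psi = c(-50, 50)))
  expect_error(classify_states(0, 0, overlapping), "overlap")

  # wrap-aware region crossing the +-180 seam
  seam <- list(ext = list(phi = c(150, -150), psi = c(150, -150)))
  cl3 <- classify_states(c(179, -179, 0), c(170, -170, 0), seam)
  expect_equal(cl3$labels, c("ext", "ext", "other"))
})

test_that("a scripted basin flip is detected at the right frame", {
  ts <- list(chain = "C", resid = 124, basins = list(c(-60, -45), c(-150, 150)),
             weights = c(0.5, 0.5))
  sim <- simulate_nucleosome(synth_config(n_frames = 120, seed = 33,
                                          torsion_script = ts))
  pp <- phi_psi(sim$trajectory, "C", c(124, 124))
  regions <- list(alpha = list(phi = c(-100, -20), psi = c(-80, 0)),
                  beta = list(phi = c(-180, -120), psi = c(120, 180)))
  cl <- classify_states(pp$phi, pp$psi, regions)
  want <- c("alpha", "beta")[sim$truth$torsion_basin]
  expect_equal(cl$labels, want)
  expect_equal(cl$transitions, sum(diff(sim$truth$torsion_basin) != 0))
  # basin occupancies match the generator's mixing fraction
  expect_equal(unname(cl$occupancy["alpha"]),
               mean(sim$truth$torsion_basin == 1), tolerance = 1e-12)
  expect_lt(abs(cl$occupancy[["alpha"]] - 0.5), 3 * sqrt(0.25 / 120))
})
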
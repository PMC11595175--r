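sim0 <- synth_one_frame()

test_that("base pairing is antiparallel and dyad-centred", {
  p <- sim0$pairs
  expect_equal(range(p$bp), c(-93, 93))
  expect_equal(sum(p$core), 147)
  expect_equal(p$resid_i[p$bp == 0], 94)
  expect_equal(p$resid_j, rev(p$resid_i))  # bijection, 5'->3' reversed

  duplex <- toy_model(rbind(
    toy_row("N1", "N", "I", 1, "DT", 0, 0, 0),
    toy_row("N9", "N", "I", 2, "DA", 1, 0, 0),
    toy_row("N1", "N", "I", 3, "DC", 2, 0, 0),
    toy_row("N9", "N", "J", 1, "DG", 2, 3, 0),
    toy_row("N1", "N", "J", 2, "DT", 1, 3, 0),
    toy_row("N9", "N", "J", 3, "DA", 0, 3, 0)
  ))
  tbl <- pair_bases(duplex, dyad_resid = 2)
  expect_equal(tbl$bp, c(-1, 0, 1))

  uneven <- toy_model(rbind(
    toy_row("N1", "N", "I", 1, "DT", 0, 0, 0),
    toy_row("N1", "N", "I", 2, "DT", 1, 0, 0),
    toy_row("N9", "N", "J", 1, "DA", 0, 3, 0)
  ))
  expect_error(pair_bases(uneven, 1), "lengths differ")
})

test_that("bp centers are glycosidic-nitrogen midpoints on the analytic curve", {
  duplex <- toy_model(rbind(
    toy_row("N9", "N", "I", 1, "DA", 0, 0, 0),
    toy_row("N1", "N", "J", 1, "DT", 2, 0, 0)
  ))
  tr <- toy_trajectory(duplex)
  ctr <- bp_centers(tr, pair_bases(duplex, 1), 1)
  expect_equal(unname(ctr[1, ]), c(1, 0, 0))

  ctr0 <- bp_centers(sim0$trajectory, sim0$pairs, 1)
  analytic <- nuctraj:::analytic_bp_center(sim0$config, as.integer(rownames(ctr0)))
  expect_lt(max(sqrt(rowSums((ctr0 - analytic)^2))), 0.1)

  broken <- toy_model(rbind(
    toy_row("C1'", "C", "I", 1, "DA", 0, 0, 0),  # DA lacking N9
    toy_row("N1", "N", "J", 1, "DT", 2, 0, 0)
  ))
  expect_error(bp_centers(toy_trajectory(broken), pair_bases(broken, 1), 1),
               "glycosidic")
})

circle_centers <- function(n = 141, radius = 41.8) {
  s <- seq(-(n - 1) / 2, (n - 1) / 2)
  th <- pi / 2 - s * 2 * pi / n   # bp 0 on +y
  m <- cbind(radius * cos(th), radius * sin(th), 0)
  rownames(m) <- s
  m
}

test_that("frame fit on a flat circle recovers the analytic axes", {
  ctr <- circle_centers()  # 141 points uniformly covering the full circle
  fr <- fit_frame(ctr, core_range = c(-70, 70))
  expect_equal(abs(fr$axis_superhelical), c(0, 0, 1), tolerance = 1e-6)
  expect_equal(fr$axis_dyad, c(0, 1, 0), tolerance = 1e-6)
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-6)
  # orthonormal right-handed triad
  B <- rbind(fr$axis_superhelical, fr$axis_dyad, fr$axis_third)
  expect_equal(B %*% t(B), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(det(B), 1, tolerance = 1e-8)
})

test_that("frame fit recovers the generating superhelical axis within 2 degrees", {
  ctr <- bp_centers(sim0$trajectory, sim0$pairs, 1)
  fr <- fit_frame(ctr)
  cosang <- sum(fr$axis_superhelical * sim0$truth$axis)
  expect_gt(cosang, cos(2 * pi / 180))
  # mean out-of-plane component of core centers stays below half a pitch
  core <- ctr[abs(as.integer(rownames(ctr))) <= 73, ]
  z <- abs(sweep(core, 2, fr$origin) %*% fr$axis_superhelical)
  expect_lt(mean(z), sim0$config$pitch_A / 2)
})

test_that("frame fit is equivariant under rigid motion and scale-stable", {
  ctr <- bp_centers(sim0$trajectory, sim0$pairs, 1)
  fr <- fit_frame(ctr)
  set.seed(42)
  for (i in 1:20) {
    R <- random_rotation_matrix()
    tr <- runif(3, -50, 50)
    moved <- sweep(ctr %*% R, 2, -tr)
    rownames(moved) <- rownames(ctr)
    fr2 <- fit_frame(moved)
    expect_equal(fr2$axis_superhelical, as.numeric(fr$axis_superhelical %*% R),
                 tolerance = 1e-8)
    expect_equal(fr2$axis_dyad, as.numeric(fr$axis_dyad %*% R), tolerance = 1e-8)
    expect_equal(fr2$origin, as.numeric(fr$origin %*% R + tr), tolerance = 1e-8)
  }
  doubled <- ctr * 2
  rownames(doubled) <- rownames(ctr)
  fr3 <- fit_frame(doubled)
  expect_equal(fr3$axis_superhelical, fr$axis_superhelical, tolerance = 1e-8)

  line <- cbind(1:20, 0, 0)
  rownames(line) <- -10:9
  expect_error(fit_frame(line, core_range = c(-10, 10)), "collinear")
})

test_that("projections use the documented plane conventions", {
  ctr <- circle_centers()
  fr <- fit_frame(ctr, core_range = c(-60, 60))
  expect_equal(unlist(project_points(rbind(fr$origin), fr, "nucleosomal_plane")),
               c(u = 0, v = 0), tolerance = 1e-10)
  p <- fr$origin + 5 * fr$axis_dyad
  expect_equal(unlist(project_points(rbind(p), fr, "nucleosomal_plane")),
               c(u = 5, v = 0), tolerance = 1e-8)
  expect_equal(unlist(project_points(rbind(fr$origin + 3 * fr$axis_superhelical),
                                     fr, "dyad_plane")),
               c(u = 0, v = 3), tolerance = 1e-8)
  expect_error(project_points(rbind(p), fr, "sideways_plane"))
})

test_that("in-plane distances are preserved when the cloud and frame co-rotate", {
  set.seed(7)
  cloud <- matrix(rnorm(60, sd = 20), ncol = 3)
  ctr <- circle_centers()
  fr <- fit_frame(ctr, core_range = c(-60, 60))
  base_uv <- project_points(cloud, fr, "nucleosomal_plane")
  d0 <- dist(base_uv)
  for (i in 1:20) {
    R <- random_rotation_matrix()
    moved_ctr <- ctr %*% R
    rownames(moved_ctr) <- rownames(ctr)
    fr2 <- fit_frame(moved_ctr, core_range = c(-60, 60))
    uv <- project_points(cloud %*% R, fr2, "nucleosomal_plane")
    expect_equal(as.numeric(dist(uv)), as.numeric(d0), tolerance = 1e-8)
  }
})
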
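two_cloud_model <- function(na, nb, spread = 8) {
  spec <- rbind(
    do.call(rbind, lapply(seq_len(na), function(i)
      toy_row("CA", "C", "A", i, "ALA",
              rnorm(1, 0, spread), rnorm(1, 0, spread), rnorm(1, 0, spread)))),
    do.call(rbind, lapply(seq_len(nb), function(i)
      toy_row("N9", "N", "B", i, "DA",
              rnorm(1, 0, spread), rnorm(1, 0, spread), rnorm(1, 0, spread))))
  )
  toy_model(spec)
}

test_that("contact counting is strict at the cutoff", {
  m <- toy_model(rbind(toy_row("CA", "C", "A", 1, "ALA", 0, 0, 0),
                       toy_row("N9", "N", "B", 1, "DA", 3.9, 0, 0)))
  sa <- select_atoms(m, "chain A")
  sb <- select_atoms(m, "chain B")
  expect_equal(frame_contacts(m$coords, m, sa, sb)$count, 1)
  m$coords[2, 1] <- 4.0
  expect_equal(frame_contacts(m$coords, m, sa, sb)$count, 0)
  expect_error(frame_contacts(m$coords, m, sa, sa), "overlap")
})

test_that("contact counts equal the brute-force double loop on random clouds", {
  set.seed(101)
  for (rep in 1:25) {
    m <- two_cloud_model(30, 30)
    sa <- select_atoms(m, "chain A")
    sb <- select_atoms(m, "chain B")
    got <- frame_contacts(m$coords, m, sa, sb, cutoff_A = 4)$count
    want <- bf_contact_count(m$coords[sa$indices, ], m$coords[sb$indices, ], 4)
    expect_identical(got, as.integer(want))
    # symmetry in the two selections
    expect_identical(frame_contacts(m$coords, m, sb, sa)$count, got)
  }
})

test_that("contacts are additive over a partition and monotone in the cutoff", {
  set.seed(102)
  m <- two_cloud_model(25, 40)
  sa <- select_atoms(m, "chain A")
  sb <- select_atoms(m, "chain B")
  s1 <- select_atoms(m, "chain B and resid 1-20")
  s2 <- select_atoms(m, "chain B and resid 21-40")
  full <- frame_contacts(m$coords, m, sa, sb)$count
  expect_equal(frame_contacts(m$coords, m, sa, s1)$count +
                 frame_contacts(m$coords, m, sa, s2)$count, full)
  prev <- -1L
  for (cutoff in c(2, 4, 6, 10)) {
    n <- frame_contacts(m$coords, m, sa, sb, cutoff_A = cutoff)$count
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("hydrogens never count as contacts", {
  m <- toy_model(rbind(toy_row("CA", "C", "A", 1, "ALA", 0, 0, 0),
                       toy_row("H1", "H", "B", 1, "DA", 1, 0, 0),
                       toy_row("N9", "N", "B", 1, "DA", 2, 0, 0)))
  n <- frame_contacts(m$coords, m, select_atoms(m, "chain A"),
                      select_atoms(m, "chain B"))$count
  expect_equal(n, 1)  # only CA-N9; CA-H1 excluded
})

test_that("a static profile has exact means and zero spread", {
  m <- toy_model(rbind(
    toy_row("CB", "C", "A", 7, "LYS", 0, 0, 0),
    toy_row("N9", "N", "I", 1, "DA", 3, 0, 0),
    toy_row("N1", "N", "J", 1, "DT", 30, 0, 0)
  ), chain_roles = c(A = "H2A", I = "DNA_strand_I", J = "DNA_strand_J"))
  tr <- toy_trajectory(m, n = 10)
  pairs <- pair_bases(m, 1)
  prof <- contact_profile(tr, select_atoms(m, "chain A"), pairs)
  expect_equal(prof$mean["A 7 LYS", "0/I"], 1)
  expect_equal(prof$sd["A 7 LYS", "0/I"], 0)
  expect_equal(prof$sem["A 7 LYS", "0/I"], 0)
  expect_equal(prof$occupancy["A 7 LYS", "0/I"], 1)
  expect_equal(prof$mean["A 7 LYS", "0/J"], 0)
  expect_error(contact_profile(tr, select_atoms(m, "chain I"), pairs),
               NA)  # DNA-vs-DNA profiles are odd but not an error path here
})

test_that("scripted occupancies are recovered and row sums are consistent", {
  cs <- data.frame(chain = "C", resid = 129, bp = 80, strand = "I",
                   occupancy = 0.3, persistence = 0)
  sim <- simulate_nucleosome(synth_config(n_frames = 400, seed = 11,
                                          contact_script = cs))
  sel <- select_atoms(sim$model, "chain C and resid 118-129")
  prof <- contact_profile(sim$trajectory, sel, sim$pairs, bp_range = c(70, 93))
  occ <- prof$occupancy["C 129 LYS", "80/I"]
  expect_equal(occ, mean(sim$truth$contact_on[, 1]))
  expect_lt(abs(occ - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
  # per-residue totals equal an independently computed sum over nucleotides
  totals <- rowSums(prof$mean)
  per_frame <- apply(prof$counts, c(1, 3), sum)
  expect_equal(totals, rowMeans(per_frame))
})

test_that("stable contacts use an inclusive 25 percent threshold", {
  fake <- structure(list(
    occupancy = matrix(c(0.25, 0.249, 0.9, 0), 2, 2,
                       dimnames = list(c("A 1 ALA", "A 2 ALA"), c("0/I", "1/I"))),
    mean = matrix(0, 2, 2)), class = "contact_profile")
  sc <- stable_contacts(fake)
  expect_setequal(paste(sc$residue, sc$nucleotide),
                  c("A 1 ALA 0/I", "A 1 ALA 1/I"))
  expect_error(stable_contacts(fake, threshold = 0), "0, 1")
  expect_error(stable_contacts(fake, threshold = 1.2), "0, 1")
})

test_that("designed occupancy tiers are kept or dropped at the 25% threshold", {
  cs <- data.frame(chain = c("C", "C", "C"), resid = c(125, 127, 129),
                   bp = c(70, 75, 80), strand = "I",
                   occupancy = c(0.1, 0.3, 0.9), persistence = 0)
  sim <- simulate_nucleosome(synth_config(n_frames = 300, seed = 12,
                                          contact_script = cs))
  sel <- select_atoms(sim$model, "chain C and (resid 125 or resid 127 or resid 129)")
  prof <- contact_profile(sim$trajectory, sel, sim$pairs, bp_range = c(60, 93))
  sc <- stable_contacts(prof)
  scripted <- paste0(c("C 125 LYS", "C 127 LYS", "C 129 LYS"), "|",
                     cs$bp, "/", cs$strand)
  called <- paste0(sc$residue, "|", sc$nucleotide)
  expect_false(scripted[1] %in% called)   # 0.1 dropped
  expect_true(all(scripted[2:3] %in% called))  # 0.3, 0.9 kept
})

test_that("symmetrisation maps bp index negation with strand swap", {
  mk_prof <- function(occ, cols) {
    structure(list(
      occupancy = matrix(occ, 1, length(cols),
                         dimnames = list("C 129 LYS", cols)),
      mean = matrix(occ, 1, length(cols), dimnames = list("C 129 LYS", cols)),
      sd = matrix(0, 1, length(cols), dimnames = list("C 129 LYS", cols)),
      sem = matrix(0, 1, length(cols), dimnames = list("C 129 LYS", cols)),
      n_frames = 10, cutoff_A = 4, copy_label = "x"),
      class = "contact_profile")
  }
  cols <- c("70/I", "-70/J")
  p1 <- mk_prof(c(1, 0), cols)    # copy1 touches +70/I only
  p2 <- mk_prof(c(0, 1), cols)    # copy2 touches -70/J only -> maps to +70/I
  un <- symmetrize_profile(p1, p2, mode = "union_presence")
  expect_true(un$presence[, "70/I"])
  expect_equal(un$occupancy[, "70/I"], 1)

  # symmetric profile is a fixed point of mean-combination with itself
  p_sym <- mk_prof(c(0.4, 0.4), cols)
  m <- symmetrize_profile(p_sym, p_sym, mode = "mean")
  expect_equal(m$mean[, "70/I"], 0.4)
  expect_equal(m$mean[, "-70/J"], 0.4)

  # randomized profiles: union presence equals the cell-wise OR oracle
  set.seed(13)
  cols2 <- as.vector(outer(c(-3, -1, 0, 2), c("I", "J"), paste, sep = "/"))
  o1 <- runif(length(cols2)) < 0.5
  o2 <- runif(length(cols2)) < 0.5
  q1 <- mk_prof(as.numeric(o1), cols2)
  q2 <- mk_prof(as.numeric(o2), cols2)
  un2 <- symmetrize_profile(q1, q2, mode = "union_presence")
  mapped <- vapply(strsplit(colnames(un2$mean), "/"), function(p)
    paste0(-as.integer(p[1]), "/", ifelse(p[2] == "I", "J", "I")), "")
  want <- o1[match(colnames(un2$mean), cols2)] | o2[match(mapped, cols2)]
  expect_equal(unname(un2$presence[1, ]), unname(want))

  p_short <- mk_prof(c(1, 0), cols)
  rownames(p_short$mean) <- rownames(p_short$occupancy) <- "C 1 ALA"
  big <- mk_prof(c(1, 0, 0), c("70/I", "-70/J", "0/I"))
  big$mean <- rbind(big$mean, big$mean)
  expect_error(symmetrize_profile(big, p1), "residue axes")
})

test_that("tail aggregation sums the interval and propagates uncertainty", {
  m <- toy_model(rbind(
    toy_row("CB", "C", "A", 120, "LYS", 0, 0, 0),
    toy_row("CB", "C", "A", 121, "LYS", 0, 2, 0),
    toy_row("N9", "N", "I", 1, "DA", 3, 0, 0),
    toy_row("N1", "N", "J", 1, "DT", 30, 0, 0)
  ), chain_roles = c(A = "H2A", I = "DNA_strand_I", J = "DNA_strand_J"))
  tr <- toy_trajectory(m, n = 12)
  prof <- contact_profile(tr, select_atoms(m, "chain A"), pair_bases(m, 1))
  ta <- tail_aggregate(prof, c(118, 129))
  expect_equal(ta$mean, 2)  # both CB atoms touch the DA nucleotide
  expect_equal(ta$sem, 0)
  expect_error(tail_aggregate(prof, c(300, 310)), "no profile residues")
})

test_that("designed tail/non-tail contact split is recovered", {
  cs <- data.frame(chain = c("C", "C"), resid = c(129, 5), bp = c(80, -80),
                   strand = "I", occupancy = c(0.6, 0.4), persistence = 0)
  sim <- simulate_nucleosome(synth_config(n_frames = 500, seed = 9,
                                          contact_script = cs))
  sel <- select_atoms(sim$model, "chain C and (resid 118-129 or resid 1-15)")
  prof <- contact_profile(sim$trajectory, sel, sim$pairs)
  ctail <- tail_aggregate(prof, c(118, 129))
  ntail <- tail_aggregate(prof, c(1, 15))
  share <- ctail$mean / (ctail$mean + ntail$mean)
  truth_share <- sum(sim$truth$contact_on[, 1]) / sum(sim$truth$contact_on)
  expect_equal(share, truth_share, tolerance = 0.03)
  expect_equal(share, 0.6, tolerance = 3 * sqrt(0.6 * 0.4 / 500) + 0.03)
})

test_that("residue pair distances match hand arithmetic and brute force", {
  m <- toy_model(rbind(
    toy_row("CA", "C", "A", 1, "ALA", 0, 0, 0),
    toy_row("CB", "C", "A", 1, "ALA", 2, 0, 0),
    toy_row("CA", "C", "A", 2, "ALA", 10, 0, 0)
  ))
  tr <- toy_trajectory(m)
  expect_equal(residue_pair_distance(tr, "A", 1, "A", 2), 9.0)

  single <- toy_model(rbind(toy_row("CA", "C", "A", 1, "ALA", 0, 0, 0),
                            toy_row("CA", "C", "A", 2, "ALA", 0, 5, 0)))
  expect_equal(residue_pair_distance(toy_trajectory(single), "A", 1, "A", 2), 5.0)

  set.seed(14)
  spec <- rbind(
    do.call(rbind, lapply(1:10, function(i)
      toy_row(paste0("C", i), "C", "A", 1, "ALA", rnorm(1), rnorm(1), rnorm(1)))),
    do.call(rbind, lapply(1:10, function(i)
      toy_row(paste0("C", i), "C", "A", 2, "ALA", rnorm(1, 5), rnorm(1), rnorm(1))))
  )
  mr <- toy_model(spec)
  got <- residue_pair_distance(toy_trajectory(mr), "A", 1, "A", 2)
  want <- bf_mean_pair_distance(mr$coords[1:10, ], mr$coords[11:20, ])
  expect_equal(got, want, tolerance = 1e-12)

  h_only <- toy_model(rbind(toy_row("H1", "H", "A", 3, "ALA", 0, 0, 0),
                            toy_row("CA", "C", "A", 4, "ALA", 1, 0, 0)))
  expect_error(residue_pair_distance(toy_trajectory(h_only), "A", 3, "A", 4),
               "no heavy atoms")
})

test_that("the minor-groove-restricted profile is a cell-wise subset", {
  cs <- data.frame(chain = "C", resid = 129, bp = 80, strand = "I",
                   occupancy = 0.8, persistence = 0)
  sim <- simulate_nucleosome(synth_config(n_frames = 60, seed = 15,
                                          contact_script = cs))
  sel <- select_atoms(sim$model, "chain C and resid 118-129")
  full <- contact_profile(sim$trajectory, sel, sim$pairs, bp_range = c(70, 93))
  mg <- contact_profile(sim$trajectory, sel, sim$pairs, bp_range = c(70, 93),
                        atom_names = minor_groove_atoms())
  expect_true(all(mg$mean <= full$mean + 1e-12))
  expect_true(all(mg$occupancy <= full$occupancy + 1e-12))
})
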
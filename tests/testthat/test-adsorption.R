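test_that("centre-of-mass separation handles point masses exactly", {
  surf <- test_surface()  # z0 = 15
  top1 <- make_point_topology(1)
  tr <- make_traj(replicate(4, matrix(c(0, 0, surf$z0 + 7), 1, 3),
                            simplify = FALSE), top1, surf)
  sep <- com_separation(tr)
  expect_equal(sep$series$separation, rep(7, 4))
  # two equal masses at z0+4 and z0+10 average to 7
  top2 <- make_point_topology(2)
  tr2 <- make_traj(list(rbind(c(0, 0, surf$z0 + 4), c(3, 0, surf$z0 + 10))),
                   top2, surf)
  expect_equal(com_separation(tr2)$series$separation, 7)
  expect_error(com_separation(make_traj(list(matrix(0, 1, 3)), top1)),
               "surface")
})

test_that("separation histograms are normalised and centred on the truth", {
  g <- samch3_run()
  sep <- com_separation(g$trajectory, bin_width = 0.5)
  expect_equal(sum(sep$histogram$probability), 1, tolerance = 1e-12)
  mode_bin <- sep$histogram$bin_mid[which.max(sep$histogram$probability)]
  truth_d <- density(g$truth$frames$com_z)
  truth_mode <- truth_d$x[which.max(truth_d$y)]
  expect_lt(abs(mode_bin - truth_mode), 0.75)  # within 1.5 bins of truth mode
})

test_that("closest-residue counts sum to the frame count", {
  g <- samch3_run()
  tab <- closest_residue_table(com_separation(g$trajectory))
  expect_equal(sum(tab$count), n_frames(g$trajectory))
})

test_that("per-frame closest distance is the minimum residue separation", {
  g <- samch3_run()
  tr <- subset_frames(g$trajectory, 1:20)
  sep <- com_separation(tr)
  prof_like <- vapply(1:20, function(f) {
    xyz <- frame_coords(tr, f)
    heavy <- tr$topology$atoms$element != "H"
    min(xyz[heavy, 3]) - tr$surface$z0
  }, numeric(1))
  expect_equal(sep$series$closest_distance, prof_like, tolerance = 1e-12)
})

test_that("residue profiles report nearest heavy atoms with frame spread", {
  surf <- test_surface()
  top <- make_point_topology(1)
  # rigid pose repeated: sd must be zero
  tr <- make_traj(replicate(5, matrix(c(1, 1, surf$z0 + 4), 1, 3),
                            simplify = FALSE), top, surf)
  prof <- residue_surface_profile(tr)
  expect_equal(prof$sd_separation, 0)
  # two atoms in one residue: profile takes the nearer one
  top2 <- make_point_topology(2)
  top2$atoms$author_index <- c(1L, 1L)
  top2$residues <- top2$residues[1, ]
  tr2 <- make_traj(list(rbind(c(0, 0, surf$z0 + 3), c(0, 0, surf$z0 + 5))),
                   top2, surf)
  expect_equal(residue_surface_profile(tr2)$mean_separation, 3)
})

test_that("tilting the generator brings the designed terminus closest", {
  surf <- build_sam_surface(8, 8, "OH")
  spec <- scenario_spec(
    segments = NULL, k_ads = 1, k_des = 0, z_adsorbed = 9, z_bulk = 25,
    noise_sd = 0.3, tilt_deg = 25, n_frames = 150, seed = 13
  )
  g <- suppressMessages(generate_trajectory(spec, surf))
  prof <- residue_surface_profile(g$trajectory)
  # the N-terminal quarter must contain the closest residue on average
  expect_lt(which.min(prof$mean_separation), 8)
})

test_that("contact probabilities match planted rates exactly", {
  surf <- test_surface()
  top <- make_point_topology(1)
  below <- replicate(10, matrix(c(0, 0, surf$z0 + 2), 1, 3), simplify = FALSE)
  above <- replicate(10, matrix(c(0, 0, surf$z0 + 12), 1, 3), simplify = FALSE)
  expect_equal(contact_probability(make_traj(below, top, surf))$probability$probability, 1)
  expect_equal(contact_probability(make_traj(above, top, surf))$probability$probability, 0)
  expect_error(contact_probability(make_traj(below, top, surf), cutoff = -1),
               "positive")
  # planted stochastic rate: estimate equals the empirical truth
  set.seed(21)
  p <- 0.3; n <- 2000
  hit <- runif(n) < p
  frames <- lapply(hit, function(h) {
    matrix(c(0, 0, surf$z0 + if (h) 2 else 10), 1, 3)
  })
  est <- contact_probability(make_traj(frames, top, surf))$probability$probability
  expect_equal(est, mean(hit))
  expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("generator contact rates are recovered from coordinates", {
  g <- samch3_run()
  est <- contact_probability(g$trajectory)$probability$probability
  expect_equal(est, g$truth$contacts$contact_rate, tolerance = 1e-12)
})

test_that("contact fingerprints cluster by residue sets", {
  surf <- test_surface()
  mk_fp_traj <- function(fps) {
    top <- make_point_topology(ncol(fps))
    frames <- lapply(seq_len(nrow(fps)), function(i) {
      cbind(seq_len(ncol(fps)) * 5, 0,
            surf$z0 + ifelse(fps[i, ], 2, 10))
    })
    contact_probability(make_traj(frames, top, surf))
  }
  # all frames identical: one cluster with probability 1
  same <- mk_fp_traj(matrix(TRUE, 6, 3))
  cc <- cluster_contacts(same)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$population, 1)
  # disjoint 60/40 fingerprints -> two clusters
  fps <- rbind(
    matrix(rep(c(TRUE, FALSE, FALSE, FALSE), 6), 6, 4, byrow = TRUE),
    matrix(rep(c(FALSE, FALSE, TRUE, TRUE), 4), 4, 4, byrow = TRUE)
  )
  cc2 <- cluster_contacts(mk_fp_traj(fps))
  expect_equal(cc2$population, c(0.6, 0.4))
  # single-linkage merge at Hamming distance 1 (hand enumeration):
  # {1}, {1,2} merge; {3,4} stays apart
  fps3 <- rbind(
    matrix(rep(c(TRUE, FALSE, FALSE, FALSE), 3), 3, 4, byrow = TRUE),
    matrix(rep(c(TRUE, TRUE, FALSE, FALSE), 2), 2, 4, byrow = TRUE),
    matrix(rep(c(FALSE, FALSE, TRUE, TRUE), 2), 2, 4, byrow = TRUE)
  )
  cc3 <- cluster_contacts(mk_fp_traj(fps3), merge_distance = 1)
  expect_equal(nrow(cc3), 2L)
  expect_equal(cc3$n_frames, c(5L, 2L))
  # populations sum to the adsorbed-frame fraction
  fps4 <- rbind(fps3, matrix(FALSE, 3, 4))
  cc4 <- cluster_contacts(mk_fp_traj(fps4))
  expect_equal(sum(cc4$population), 7 / 10)
  # no adsorbed frames: empty result with a warning
  none <- mk_fp_traj(matrix(FALSE, 3, 4))
  expect_warning(out <- cluster_contacts(none), "No adsorbed")
  expect_equal(nrow(out), 0L)
})

test_that("the adsorbed filter keeps exactly the frames in surface contact", {
  g <- samch3_run()
  filt <- adsorbed_filter(g$trajectory)
  expect_equal(n_frames(filt), n_frames(g$trajectory))  # always adsorbed
  # peptide parked far above the plane: nothing kept
  surf <- test_surface()
  top <- make_point_topology(1)
  far <- make_traj(replicate(3, matrix(c(0, 0, surf$z0 + 50), 1, 3),
                             simplify = FALSE), top, surf)
  expect_warning(kept <- adsorbed_filter(far), "No adsorbed")
  expect_equal(n_frames(kept), 0L)
})

test_that("two-state generator adsorption is recovered by the filter", {
  surf <- build_sam_surface(6, 6, "OH")
  g <- suppressMessages(generate_trajectory(
    scenario_preset("samoh-like", n_frames = 1500, seed = 31), surf
  ))
  est <- mean(attr(adsorbed_filter(g$trajectory), "adsorbed"))
  truth <- mean(g$truth$frames$adsorbed)
  se <- sqrt(truth * (1 - truth) / 1500)
  expect_lt(abs(est - truth), max(3 * se, 1e-9))
})
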
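test_that("the switching function matches its closed forms", {
  expect_equal(switching(0), 1)
  expect_equal(switching(2.5), 8 / 12)  # removable singularity -> n/m
  # r = r0/2: (1 - 2^-8) / (1 - 2^-12), plain arithmetic oracle
  expect_equal(switching(1.25), (1 - 2^-8) / (1 - 2^-12), tolerance = 1e-12)
  # continuity at r0
  eps <- 1e-9
  expect_lt(abs(switching(2.5 - eps) - 2 / 3), 1e-8)
  expect_lt(abs(switching(2.5 + eps) - 2 / 3), 1e-8)
  # monotone decreasing on a grid
  grid <- switching(seq(0, 10, by = 0.05))
  expect_true(all(diff(grid) <= 1e-12))
  expect_true(all(grid >= 0 & grid <= 1))
  expect_error(switching(-0.1), "non-negative")
  expect_error(switching_params(n = 12, m = 8), "m > n")
})

test_that("helical hydrogen-bond counts follow the switching oracle", {
  seq_str <- ab1040_sequence(as_string = TRUE)
  # fully extended chain: every term below 0.01
  ext <- build_chain_from_dihedrals(seq_str, pi * 0.99, pi * 0.99)
  tr_ext <- ps_trajectory(ext$topology, ext$coords)
  hb_ext <- helical_hbond_counts(tr_ext)
  expect_lt(hb_ext$n_alpha_hb, 27 * 0.01)
  expect_lt(hb_ext$n_310_hb, 28 * 0.01)
  # ideal helix: every O(i)..H(i+4) pair sits at the same distance, so the
  # count is (N-4) times the switching value there (frozen via the
  # geometric construction: d = 2.1074 A)
  hel <- ideal_dihedrals("helix")
  ch <- build_chain_from_dihedrals(seq_str, hel["phi"], hel["psi"])
  at <- ch$topology$atoms
  o <- ch$coords[at$name == "O", ]; h <- ch$coords[at$name == "H", ]
  d14 <- sqrt(sum((o[1, ] - h[5, ])^2))
  hb <- helical_hbond_counts(ps_trajectory(ch$topology, ch$coords))
  expect_equal(hb$n_alpha_hb, 27 * switching(d14), tolerance = 1e-9)
  expect_gt(hb$n_alpha_hb, 0.8 * 27)
})

test_that("a single pair at the switching distance contributes n/m", {
  seq5 <- "AAAAA"  # exactly one i -> i+4 pair
  hel <- ideal_dihedrals("helix")
  ch <- build_chain_from_dihedrals(seq5, hel["phi"], hel["psi"])
  at <- ch$topology$atoms
  o1 <- which(at$name == "O" & at$author_index == 1)
  h5 <- which(at$name == "H" & at$author_index == 5)
  # move H5 radially to exactly 2.5 A from O1
  v <- ch$coords[h5, ] - ch$coords[o1, ]
  ch$coords[h5, ] <- ch$coords[o1, ] + v / sqrt(sum(v^2)) * 2.5
  hb <- helical_hbond_counts(ps_trajectory(ch$topology, ch$coords))
  expect_equal(hb$n_alpha_hb, 2 / 3, tolerance = 1e-12)
})

test_that("the dihedral offset spans its analytic range", {
  # 31 residues at the strand references: DH = 2(N-1) = 60
  d_ref <- tibble::tibble(phi = rep(-2.36, 31), psi = rep(2.36, 31))
  d_ref$phi[1] <- NA; d_ref$psi[31] <- NA
  expect_equal(as.numeric(dihedral_offset(d_ref)), 60)
  # anti-reference angles: DH = 0
  d_anti <- tibble::tibble(
    phi = wrap_angle_test(-2.36 + pi) * rep(1, 31),
    psi = wrap_angle_test(2.36 + pi) * rep(1, 31)
  )
  d_anti$phi[1] <- NA; d_anti$psi[31] <- NA
  expect_equal(as.numeric(dihedral_offset(d_anti)), 0, tolerance = 1e-9)
  # uniform random dihedrals: E[DH] = N - 1 = 30
  set.seed(5)
  n_draws <- 1e4
  dh <- vapply(seq_len(n_draws), function(i) {
    as.numeric(dihedral_offset(tibble::tibble(
      phi = c(NA, runif(30, -pi, pi)),
      psi = c(runif(30, -pi, pi), NA)
    )))
  }, numeric(1))
  # each DH is a sum of 60 iid (1+cos(U))/2 terms: var = 60 * (1/2) / 4
  se <- sqrt(60 * 0.5 / 4 / n_draws)
  expect_lt(abs(mean(dh) - 30), 3 * se)
  expect_true(all(dh >= 0 & dh <= 60))
})

test_that("gyration descriptors satisfy their tensor identities", {
  # two points 2 A apart: Rg = 1
  g2 <- gyration(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(g2$rg, 1)
  expect_equal(g2$gmax, 1)
  expect_equal(g2$gmid, 0)
  # collinear rod: only one non-zero axis
  rod <- cbind(seq(0, 10, by = 1), 0, 0)
  gr <- gyration(rod)
  expect_equal(gr$gmid, 0, tolerance = 1e-10)
  expect_equal(gr$gmin, 0, tolerance = 1e-10)
  # eigenvalue partition of Rg^2 on random clouds
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rnorm(30 * 3, sd = 3), 30, 3)
    g <- gyration(m)
    expect_equal(g$gmax^2 + g$gmid^2 + g$gmin^2, g$rg^2,
                 tolerance = 1e-6 * g$rg^2)
    expect_true(g$gmax >= g$gmid && g$gmid >= g$gmin && g$gmin >= 0)
  }
  expect_error(gyration(matrix(0, 1, 3)), "At least 2")
})

test_that("per-frame conformation metrics are internally consistent", {
  g <- samch3_run()
  tr <- subset_frames(g$trajectory, 1:30)
  m <- conformation_metrics(tr)
  expect_equal(nrow(m), 30L)
  expect_true(all(m$dh >= 0 & m$dh <= 60))
  expect_equal(m$gmax^2 + m$gmid^2 + m$gmin^2, m$rg^2,
               tolerance = 1e-6 * max(m$rg^2))
  # helical frames must show several alpha hydrogen bonds
  expect_true(all(m$n_alpha_hb > 4))
})
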
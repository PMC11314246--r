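test_that("isolated and non-overlapping spheres match closed forms", {
  s1 <- shrake_rupley_sasa(matrix(0, 1, 3), radii = 1.9)
  exact <- 4 * pi * (1.9 + 1.4)^2
  expect_lt(abs(s1$total - exact) / exact, 0.005)
  s2 <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(100, 0, 0)),
                           radii = c(1.9, 1.5))
  exact2 <- 4 * pi * (3.3^2 + 2.9^2)
  expect_lt(abs(s2$total - exact2) / exact2, 0.005)
  expect_equal(sum(s2$per_atom), s2$total)
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), 1.9, n_points = 50),
               "92")
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), -1), "positive")
})

test_that("overlapping sphere pairs match the spherical-cap formula", {
  r1 <- 1.9 + 1.4; r2 <- 1.6 + 1.4
  for (d in c(2.0, 3.0, 4.5)) {
    s <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)),
                            radii = c(1.9, 1.6), n_points = 4000)
    # analytic exposed area of two intersecting spheres
    cap <- function(ra, rb) {
      h <- ra - (d^2 + ra^2 - rb^2) / (2 * d)
      4 * pi * ra^2 - 2 * pi * ra * h
    }
    exact <- cap(r1, r2) + cap(r2, r1)
    expect_lt(abs(s$total - exact) / exact, 0.01)
  }
})

test_that("surface area never grows as two groups approach", {
  dists <- c(20, 10, 6, 4, 3, 2)
  areas <- vapply(dists, function(d) {
    shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)),
                       radii = c(1.9, 1.9))$total
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("nonpolar solvation is exactly gamma times SASA", {
  expect_equal(nonpolar_solvation(1000), 5)
  expect_equal(nonpolar_solvation(0), 0)
  expect_equal(nonpolar_solvation(500, gamma = 0.01), 5)
  expect_error(nonpolar_solvation(-1), "non-negative")
})

test_that("pair energies reproduce the 12-6 and Coulomb closed forms", {
  a <- tibble::tibble(charge = 1, sigma = 3, epsilon = 0.1)
  b <- tibble::tibble(charge = -1, sigma = 3, epsilon = 0.1)
  at <- function(x) matrix(c(x, 0, 0), 1, 3)
  # Coulomb constant: +1/-1 at 3.3206 A gives exactly -100 kcal/mol
  expect_equal(mm_energy(at(0), a, at(3.3206), b)$eelec, -100)
  expect_equal(mm_energy(at(0), a, at(3), b)$evdw, 0, tolerance = 1e-12)
  expect_equal(mm_energy(at(0), a, at(2^(1 / 6) * 3), b)$evdw, -0.1)
  # mixed sigma/epsilon pairs follow Lorentz-Berthelot
  c_par <- tibble::tibble(charge = 0, sigma = 4, epsilon = 0.4)
  mix_sigma <- (3 + 4) / 2
  e <- mm_energy(at(0), a, at(2^(1 / 6) * mix_sigma), c_par)
  expect_equal(e$evdw, -sqrt(0.1 * 0.4), tolerance = 1e-12)
  expect_error(mm_energy(at(0), a[, 1:2], at(1), b), "charge")
})

test_that("the non-interacting limit gives a vanishing adsorption energy", {
  surf <- test_surface("CH3", 3, 3)
  top <- make_point_topology(2)
  frames <- replicate(3, rbind(c(0, 0, surf$z0 + 200),
                               c(3, 0, surf$z0 + 200)), simplify = FALSE)
  tr <- make_traj(frames, top, surf)
  e <- adsorption_free_energy(tr)
  g <- glance(e)
  expect_lt(abs(g$dg_ads), 0.05)
  expect_lt(abs(g$d_emm), 1e-6)
})

test_that("a planted contact pair reproduces the hand-computed energy", {
  surf <- build_sam_surface(1, 1, "CH3", terminal_z = 15)
  top <- make_point_topology(1)
  top$atoms$charge <- 0.3
  r <- 4.2  # atom straight above the single surface carbon
  tr <- make_traj(list(matrix(c(0, 0, 15 + r), 1, 3)), top, surf)
  e <- tidy(adsorption_free_energy(tr))
  sig <- (3.4 + 3.75) / 2
  eps <- sqrt(0.1 * 0.195)
  evdw_ref <- 4 * eps * ((sig / r)^12 - (sig / r)^6)
  expect_equal(e$d_evdw, evdw_ref, tolerance = 1e-6)
  expect_equal(e$d_eelec, 0)  # CH3 terminus is neutral
  expect_equal(e$d_eint, 0)
  expect_equal(e$dg_ads, e$d_emm + e$d_gsolv, tolerance = 1e-12)
})

test_that("single-trajectory bookkeeping holds on synthetic frames", {
  g <- samch3_run()
  tr <- subset_frames(g$trajectory, 1:3)
  e <- tidy(adsorption_free_energy(tr))
  expect_true(all(e$d_eint == 0))
  expect_equal(e$dg_ads, e$d_emm + e$d_gsolv, tolerance = 1e-12)
  expect_equal(e$d_emm, e$d_evdw + e$d_eelec, tolerance = 1e-12)
  # contact desolvates the surface: nonpolar term must be negative here
  # (buried area shrinks the complex SASA below the sum of the parts)
  expect_true(all(e$d_gsa < 0))
})

test_that("the Born-style polar backend perturbs only the polar column", {
  surf <- build_sam_surface(2, 2, "OH", terminal_z = 15)
  top <- make_point_topology(1)
  top$atoms$charge <- 1
  tr <- make_traj(list(matrix(c(0, 0, 19), 1, 3)), top, surf)
  plain <- tidy(adsorption_free_energy(tr))
  born <- tidy(adsorption_free_energy(tr,
                                      polar_backend = born_polar_backend()))
  expect_equal(plain$d_gpb, 0)
  expect_false(isTRUE(all.equal(born$d_gpb, 0)))
  expect_equal(born$d_evdw, plain$d_evdw)
  expect_equal(born$dg_ads, born$d_emm + born$d_gsolv, tolerance = 1e-12)
})
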
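test_that("the geometric ladder reproduces its defining identities", {
  lad <- build_ladder(300, 440, 12)
  expect_equal(nrow(lad), 12L)
  expect_equal(lad$beta[1], 1)
  expect_equal(lad$beta[12], 300 / 440)
  expect_true(all(diff(lad$beta) < 0))
  expect_equal(lad$beta, 300 / lad$temperature, tolerance = 1e-12)
  expect_error(build_ladder(440, 300, 12), "Tmax > T0")
  expect_error(build_ladder(300, 440, 1), "2 replicas")
})

test_that("energy scaling follows the solute-tempering rule", {
  d <- energy_decomposition(10, 20, 5)
  expect_equal(scale_energy(d, 1), 35)                 # identity replica
  expect_equal(scale_energy(d, 0.64), 6.4 + 16 + 5)    # sqrt(0.64) = 0.8
  expect_equal(scale_energy(energy_decomposition(0, 0, 7.5), 0.3), 7.5)
  expect_error(scale_energy(d, 0), "beta")
  expect_error(scale_energy(d, 1.2), "beta")
  expect_error(energy_decomposition(Inf, 0, 0), "finite")
})

test_that("exchange probabilities are symmetric and bounded", {
  d1 <- energy_decomposition(3, -2, 1)
  d2 <- energy_decomposition(8, 4, 1)
  # equal betas or identical configurations give probability 1
  expect_equal(exchange_probability(d1, d2, 0.9, 0.9), 1)
  expect_equal(exchange_probability(d1, d1, 1, 0.7), 1)
  set.seed(14)
  for (i in 1:20) {
    da <- energy_decomposition(rnorm(1, 0, 5), rnorm(1, 0, 5), rnorm(1))
    db <- energy_decomposition(rnorm(1, 0, 5), rnorm(1, 0, 5), rnorm(1))
    ba <- runif(1, 0.5, 1); bb <- runif(1, 0.5, 1)
    p_ab <- exchange_probability(da, db, ba, bb)
    p_ba <- exchange_probability(db, da, bb, ba)
    expect_equal(p_ab, p_ba)
    expect_gte(p_ab, 0); expect_lte(p_ab, 1)
  }
})

test_that("empirical acceptance matches the enumerated Boltzmann average", {
  # two-configuration system: each replica samples its own scaled
  # Boltzmann distribution over configurations {A, B}; the mean exchange
  # acceptance has a 4-term closed form
  d_a <- energy_decomposition(0, 0, 0)
  d_b <- energy_decomposition(2, 1, 0)
  beta_i <- 1; beta_j <- 0.7
  kt <- 0.0019872041 * 300
  w <- function(d, b) exp(-scale_energy(d, b) / kt)
  p_i <- w(d_a, beta_i) / (w(d_a, beta_i) + w(d_b, beta_i))
  p_j <- w(d_a, beta_j) / (w(d_a, beta_j) + w(d_b, beta_j))
  cfg <- list(d_a, d_b)
  exact <- 0
  for (xi in 1:2) for (xj in 1:2) {
    pr <- (if (xi == 1) p_i else 1 - p_i) * (if (xj == 1) p_j else 1 - p_j)
    exact <- exact + pr *
      exchange_probability(cfg[[xi]], cfg[[xj]], beta_i, beta_j)
  }
  set.seed(15)
  n <- 4000
  xi <- ifelse(runif(n) < p_i, 1L, 2L)
  xj <- ifelse(runif(n) < p_j, 1L, 2L)
  acc <- vapply(seq_len(n), function(k) {
    exchange_probability(cfg[[xi[k]]], cfg[[xj[k]]], beta_i, beta_j)
  }, numeric(1))
  se <- sd(acc) / sqrt(n)
  expect_lt(abs(mean(acc) - exact), 3 * se)
})

test_that("a single replica records no exchanges", {
  lad <- build_ladder(300, 600, 6)
  r <- toy_rest_run(lad, n_steps = 200, exchange = FALSE, seed = 1)
  expect_equal(sum(tidy(r)$attempts), 0L)
  expect_equal(r$crossings, 0L)  # 5 kcal barrier is not crossed unaided
})

test_that("solute tempering enhances barrier crossing", {
  lad <- build_ladder(300, 600, 6)
  wins <- 0L
  for (seed in 1:10) {
    with_ex <- toy_rest_run(lad, n_steps = 1500, seed = seed)
    without <- toy_rest_run(lad, n_steps = 1500, seed = seed,
                            exchange = FALSE)
    expect_gte(with_ex$crossings, without$crossings)
    if (with_ex$crossings > without$crossings) wins <- wins + 1L
  }
  expect_gte(wins, 8L)  # enhancement in almost every seed
})

test_that("toy REST runs are seed-reproducible", {
  lad <- build_ladder(300, 600, 4)
  r1 <- toy_rest_run(lad, n_steps = 300, seed = 9)
  r2 <- toy_rest_run(lad, n_steps = 300, seed = 9)
  expect_identical(r1$samples, r2$samples)
  expect_identical(tidy(r1), tidy(r2))
})
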
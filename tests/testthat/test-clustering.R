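test_that("Kabsch RMSD is zero under rigid transforms", {
  set.seed(3)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(a, a), 0)
  for (i in 1:10) {
    expect_lt(kabsch_rmsd(a, random_rigid(a)), 1e-9)
  }
  expect_error(kabsch_rmsd(a, a[1:5, ]), "equal")
})

test_that("Kabsch RMSD agrees with the quaternion closed form", {
  set.seed(4)
  for (i in 1:50) {
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
    expect_equal(kabsch_rmsd(a, b), horn_rmsd(a, b), tolerance = 1e-4)
  }
})

test_that("Kabsch RMSD is the minimum over sampled rotations", {
  set.seed(5)
  a <- matrix(rnorm(18), 6, 3)
  b <- matrix(rnorm(18), 6, 3)
  r_opt <- kabsch_rmsd(a, b)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  for (i in 1:200) {
    br <- random_rigid(bc)
    brc <- sweep(br, 2, colMeans(br))
    expect_gte(sqrt(mean(rowSums((ac - brc)^2))) + 1e-10, r_opt)
  }
})

test_that("Daura clustering handles its degenerate limits", {
  one <- matrix(rnorm(12), 4, 3)
  same <- replicate(7, one, simplify = FALSE)
  cl <- daura_cluster(same, cutoff = 0.5)
  expect_equal(cl$n_conf, 1L)
  expect_equal(cl$populations, 1)
  # frames pairwise farther than the cutoff: all singletons (distinct
  # shapes -- pure translations would superpose to RMSD zero)
  apart <- c(ref_shapes(), list(scaled = ref_shapes()$rod * 3,
                                flat = cbind(c(0, 30, 0, 30), c(0, 0, 9, 9), 0)))
  seps <- combn(5, 2, function(ij) kabsch_rmsd(apart[[ij[1]]], apart[[ij[2]]]))
  expect_gt(min(seps), 1)
  cl2 <- daura_cluster(apart, cutoff = 1)
  expect_equal(cl2$n_conf, 5L)
  expect_equal(cl2$populations, rep(0.2, 5))
})

test_that("every frame lies within the cutoff of its cluster centre", {
  set.seed(6)
  frames <- replicate(15, matrix(rnorm(12, sd = 2), 4, 3), simplify = FALSE)
  cutoff <- 2.5
  cl <- daura_cluster(frames, cutoff = cutoff)
  for (i in seq_along(frames)) {
    ctr <- frames[[cl$centers[cl$assignments[i]]]]
    expect_lte(kabsch_rmsd(frames[[i]], ctr), cutoff)
  }
  expect_equal(sum(cl$populations), 1)
})

test_that("clustering matches the brute-force reference on random sets", {
  set.seed(7)
  for (inst in 1:25) {
    n <- sample(5:15, 1)
    frames <- replicate(n, matrix(rnorm(12, sd = 1.5), 4, 3),
                        simplify = FALSE)
    cutoff <- runif(1, 1, 3)
    cl <- daura_cluster(frames, cutoff = cutoff)
    ref <- brute_daura(frames, cutoff)
    # same partition (cluster ids may be permuted by ranking)
    expect_equal(length(unique(cl$assignments)), length(ref$centers))
    same_part <- outer(cl$assignments, cl$assignments, "==") ==
      outer(ref$assignment, ref$assignment, "==")
    expect_true(all(same_part))
  }
})

test_that("clustering is invariant to a global rigid transform", {
  set.seed(8)
  frames <- replicate(10, matrix(rnorm(12, sd = 1.5), 4, 3),
                      simplify = FALSE)
  cl1 <- daura_cluster(frames, cutoff = 2)
  moved <- lapply(frames, random_rigid)
  cl2 <- daura_cluster(moved, cutoff = 2)
  expect_equal(cl1$assignments, cl2$assignments)
})

test_that("raising the cutoff never increases the cluster count", {
  set.seed(9)
  frames <- replicate(12, matrix(rnorm(12, sd = 2), 4, 3), simplify = FALSE)
  n_at <- vapply(c(0.5, 1, 2, 4, 8),
                 function(co) daura_cluster(frames, cutoff = co)$n_conf,
                 integer(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("conformational entropy follows the Shannon form and its bounds", {
  expect_equal(conformational_entropy(1), 0)
  expect_equal(conformational_entropy(c(0.5, 0.5)), log(2))
  expect_equal(conformational_entropy(rep(1 / 263, 263)), log(263))
  expect_error(conformational_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(conformational_entropy(c(0.4, 0.4)), "sum to 1")
  set.seed(10)
  for (i in 1:20) {
    k <- sample(2:30, 1)
    p <- rexp(k); p <- p / sum(p)
    s <- conformational_entropy(p)
    expect_gte(s, 0)
    expect_lte(s, log(k) + 1e-12)
  }
})

test_that("combined overlap is 1 for identical ensembles, 0 for disjoint", {
  set.seed(11)
  sh <- ref_shapes()
  jitter4 <- function() matrix(rnorm(12, sd = 0.05), 4, 3)
  sys_rod <- replicate(8, sh$rod + jitter4(), simplify = FALSE)
  sys_sq <- replicate(8, sh$square + jitter4(), simplify = FALSE)
  ov_same <- combined_overlap(list(a = sys_rod, b = sys_rod), cutoff = 2)
  expect_equal(ov_same$overlap, 1)
  ov_far <- combined_overlap(list(a = sys_rod, b = sys_sq), cutoff = 2)
  expect_equal(ov_far$overlap, 0)
  expect_error(combined_overlap(list(a = sys_rod)), "two")
})

test_that("a planted shared fraction is recovered by the overlap score", {
  set.seed(12)
  base <- function() matrix(rnorm(12, sd = 0.05), 4, 3)
  sh <- ref_shapes()
  x <- sh$rod; y <- sh$square; z <- sh$tetra
  n <- 40; shared <- 12  # 30% shared conformation z
  sys_a <- c(replicate(n - shared, x + base(), simplify = FALSE),
             replicate(shared, z + base(), simplify = FALSE))
  sys_b <- c(replicate(n - shared, y + base(), simplify = FALSE),
             replicate(shared, z + base(), simplify = FALSE))
  ov <- combined_overlap(list(a = sys_a, b = sys_b), cutoff = 1)
  expect_equal(ov$overlap, 0.3, tolerance = 1e-9)
})

test_that("the equilibration curve counts thermally relevant clusters", {
  # single repeated conformation: curve constant at 1
  one <- matrix(rnorm(12), 4, 3)
  same <- replicate(30, one, simplify = FALSE)
  eq <- equilibration_curve(same, window = 10, cutoff = 1)
  expect_true(all(eq$n_low_energy == 1))
  # stationary two-state ensemble: curve plateaus
  set.seed(13)
  a <- ref_shapes()$rod
  b <- ref_shapes()$square
  frames <- lapply(1:60, function(i) {
    (if (i %% 2 == 0) a else b) + matrix(rnorm(12, sd = 0.05), 4, 3)
  })
  eq2 <- equilibration_curve(frames, window = 15, cutoff = 1)
  expect_equal(eq2$n_low_energy[nrow(eq2)], eq2$n_low_energy[nrow(eq2) - 1])
  expect_equal(eq2$n_low_energy[nrow(eq2)], 2L)
  # population ratio below exp(-2 / kB 300K) = 0.0349 is excluded
  rare <- c(replicate(59, a + matrix(rnorm(12, sd = 0.05), 4, 3),
                      simplify = FALSE),
            list(b))
  eq3 <- equilibration_curve(rare, window = 60, cutoff = 1)
  expect_equal(eq3$n_low_energy[nrow(eq3)], 1L)
})
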
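test_that("tau counts relabelled group-B units in the front block", {
  expect_equal(tau_fraction(1:5, 2, 3), 0)
  expect_equal(tau_fraction(c(4:6, 1:3), 3, 3), 1)     # full swap, n_A = n_B
  expect_equal(tau_fraction(c(1, 4, 2, 3, 5), 2, 3), 0.5)
})

test_that("permutation centering obeys its algebraic identities", {
  p <- c(0.2, 0.7, 0.5)
  expect_equal(permutation_centering(0, 20, 30, p), p)
  expect_equal(permutation_centering(1, 10, 10, p), 1 - p)
  expect_equal(permutation_centering(0.37, 20, 30, rep(0.5, 4)),
               rep(0.5, 4))
})

test_that("identity permutation zeroes the estimated-centered statistic", {
  set.seed(59)
  s <- rand_sample(6, 7, d = 3)
  expect_equal(permuted_statistic(s, 1:13, center = "estimated"), 0,
               tolerance = 1e-10)
  # under null centering the identity reproduces the observed statistic
  expect_equal(permuted_statistic(s, 1:13, center = "null"),
               oracle_wald(s), tolerance = 1e-8)
})

test_that("permuted statistic reproduces an independent brute-force oracle", {
  s <- tg1(1:3, 4:6)
  pm <- c(4, 2, 6, 1, 3, 5)     # fixed listed permutation of {1..6}
  for (ctr in c("null", "estimated"))
    expect_equal(permuted_statistic(s, pm, center = ctr),
                 oracle_perm_stat(s, pm, center = ctr), tolerance = 1e-10)
  set.seed(61)
  for (i in 1:8) {
    s <- rand_sample(5, 6, d = 2, tied = i %% 2 == 0)
    pm <- sample(11)
    ctr <- c("null", "estimated")[1 + i %% 2]
    expect_equal(permuted_statistic(s, pm, center = ctr),
                 oracle_perm_stat(s, pm, center = ctr), tolerance = 1e-10)
    sub <- sample(1:2, 1)
    expect_equal(permuted_statistic(s, pm, subset = sub, center = ctr),
                 oracle_perm_stat(s, pm, subset = sub, center = ctr),
                 tolerance = 1e-10)
  }
})

test_that("compiled permutation null equals the R single-permutation path", {
  set.seed(67)
  s <- rand_sample(8, 10, d = 3, tied = TRUE)
  plan <- permutation_plan(18, B = 25, seed = 3)
  for (ctr in c("null", "estimated")) {
    nul <- permutation_null(s, plan, center = ctr)
    expect_length(nul$w_values, 26)
    expect_true(all(nul$w_values >= 0))
    expect_true(all(nul$tau_values >= 0 &
                      nul$tau_values <= min(1, s$n_B / s$n_A)))
    for (j in c(1, 7, 26)) {
      expect_equal(nul$w_values[j],
                   permuted_statistic(s, plan$perms[, j], center = ctr),
                   tolerance = 1e-10)
    }
  }
  # identity slot: zero under estimated centering
  nul <- permutation_null(s, plan, center = "estimated")
  expect_equal(nul$w_values[26], 0, tolerance = 1e-10)
})

test_that("permutation p-values follow the documented conventions", {
  nul <- structure(list(w_values = c(1, 2, 3, 0), tau_values = rep(0, 4),
                        B = 3L, include_identity = TRUE),
                   class = "permutation_null")
  expect_equal(permutation_pvalue(0, nul), 1)
  expect_equal(permutation_pvalue(10, nul), 1 / 4)   # floor 1/(B+1)
  expect_equal(permutation_pvalue(2, nul), 3 / 4)
  # plain vector: complete null, direct exceedance count
  expect_equal(permutation_pvalue(2, c(0, 1, 2, 3)), 0.5)
  expect_equal(permutation_pvalue(0, c(0, 1, 2, 3)), 1)
})

test_that("identical seed and plan reproduce p-values bit for bit", {
  set.seed(71)
  s <- rand_sample(10, 10, d = 2)
  p1 <- relef_test(s, calibration = "permutation",
                   plan = permutation_plan(20, B = 199, seed = 5))
  p2 <- relef_test(s, calibration = "permutation",
                   plan = permutation_plan(20, B = 199, seed = 5))
  expect_identical(p1$p_permutation, p2$p_permutation)
})

test_that("permutation null approaches the chi-square law as N grows", {
  # distributional statement about the estimated (tau-mixture) centering
  ks_dist <- function(N, seed) {
    cfg <- model1_config(d = 2, rho = 0, n_A = N * 2 / 5, n_B = N * 3 / 5,
                         K = 1, seed = 1, calibration = "chi2")
    d <- replicate(3, {
      s <- generate_model1(cfg)
      plan <- permutation_plan(N, B = 999, seed = seed)
      w <- sort(permutation_null(s, plan, center = "estimated")$w_values)
      max(abs(seq_along(w) / length(w) - pchisq(w, 2)))
    })
    mean(d)
  }
  set.seed(73)
  k60 <- ks_dist(60, 11)
  k200 <- ks_dist(200, 12)
  k600 <- ks_dist(600, 13)
  expect_lt(k200, 0.08)          # close to chi-square already at N = 200
  expect_lt(k600, k60)           # sup-distance shrinks along the grid
})

test_that("permutation p-value is empirically super-uniform under the null", {
  set.seed(79)
  cfg <- model1_config(d = 2, rho = 0.2, n_A = 20, n_B = 30, K = 2000,
                       B = 199, seed = 83, calibration = "permutation")
  r <- type1_experiment(cfg)
  bound <- 0.05 + 1 / (cfg$B + 1) + 3 * sqrt(0.05 * 0.95 / cfg$K)
  expect_lte(r$rate, bound)
})
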
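test_that("Model-1 marginals follow the target beta distribution", {
  cfg <- model1_config(d = 2, rho = 0, n_A = 5000, n_B = 5000, K = 1,
                       seed = 1, calibration = "chi2")
  s <- generate_model1(cfg, rep_seed = 109)
  x <- s$values[, 1]
  # Beta(3,4): mean 3/7, var 3*4/(49*8)
  se <- sqrt(3 * 4 / (49 * 8) / length(x))
  expect_lt(abs(mean(x) - 3 / 7), 3 * se)
  expect_gt(stats::ks.test(x, stats::pbeta, 3, 4)$p.value, 0.001)
})

test_that("the shifted group-B marginal uses shape a + delta", {
  cfg <- model1_config(d = 2, d0 = 1, delta = 3, rho = 0,
                       n_A = 4000, n_B = 4000, K = 1, seed = 1,
                       calibration = "chi2")
  s <- generate_model1(cfg, rep_seed = 113)
  xB2 <- s$values[s$n_A + seq_len(s$n_B), 2]
  expect_gt(stats::ks.test(xB2, stats::pbeta, 6, 4)$p.value, 0.001)
  # true relative effect by quadrature: integral of F_A dF_B
  p_true <- stats::integrate(function(x) pbeta(x, 3, 4) * dbeta(x, 6, 4),
                             0, 1)$value
  expect_gt(p_true, 0.5)
  p_emp <- relative_effects(s)$p_hat[2]
  expect_lt(abs(p_emp - p_true), 0.03)
})

test_that("AR(1) copula induces the Gaussian-copula Spearman correlation", {
  cfg <- model1_config(d = 2, rho = 0.8, n_A = 3000, n_B = 3000, K = 1,
                       seed = 1, calibration = "chi2")
  s <- generate_model1(cfg, rep_seed = 127)
  rs <- stats::cor(s$values[, 1], s$values[, 2], method = "spearman")
  rs_theory <- (6 / pi) * asin(0.8 / 2)
  expect_gt(rs, 0.7)
  expect_lt(abs(rs - rs_theory), 0.05)
})

test_that("experiments are reproducible from (seed, cfg) and validate inputs", {
  cfg <- model1_config(d = 2, rho = 0, n_A = 10, n_B = 10, K = 50,
                       seed = 131, calibration = "chi2")
  expect_equal(generate_model1(cfg, rep_seed = 5)$values,
               generate_model1(cfg, rep_seed = 5)$values)
  r1 <- type1_experiment(cfg)
  r2 <- type1_experiment(cfg)
  expect_identical(r1$rate, r2$rate)
  expect_equal(r1$se, sqrt(r1$rate * (1 - r1$rate) / 50))

  expect_error(power_experiment(cfg), "d0 < d")
  cfg2 <- model1_config(d = 2, d0 = 1, delta = 2, rho = 0, n_A = 10,
                        n_B = 10, K = 10, seed = 1, calibration = "chi2")
  expect_error(type1_experiment(cfg2), "d0 == d")
  cfg3 <- model1_config(d = 2, d0 = 0, delta = 2, rho = 0, n_A = 10,
                        n_B = 10, K = 10, seed = 1, calibration = "chi2")
  expect_error(fwer_experiment(cfg3), "d0 >= 1")
})

test_that("alpha = 0 never rejects", {
  cfg <- model1_config(d = 2, rho = 0, n_A = 10, n_B = 10, K = 30,
                       alpha = 0, seed = 137, calibration = "chi2")
  expect_equal(type1_experiment(cfg)$rate, 0)
})

test_that("global power is nondecreasing in delta", {
  rates <- vapply(c(1, 3), function(delta) {
    cfg <- model1_config(d = 5, d0 = 4, delta = delta, rho = 0.2,
                         n_A = 20, n_B = 30, K = 250, seed = 139,
                         calibration = "chi2")
    power_experiment(cfg)$rate
  }, numeric(1))
  expect_gt(rates[2], rates[1])
})

test_that("FWER at d = 1 with all nulls equals the global type-I rate", {
  cfg <- model1_config(d = 1, rho = 0, n_A = 15, n_B = 15, K = 200,
                       seed = 149, calibration = "chi2")
  expect_identical(fwer_experiment(cfg)$rate, type1_experiment(cfg)$rate)
})
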
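test_that("within-group split matches the published design sizes", {
  set.seed(151)
  s <- two_group_sample(matrix(rnorm(388 * 3), 388),
                        rep(c("ctrl", "case"), c(264, 124)),
                        levels = c("ctrl", "case"))
  plan <- two_stage_plan(screen_n = c(176, 84), seed = 17)
  parts <- split_sample(s, plan)
  expect_equal(c(parts$screen$n_A, parts$screen$n_B), c(176, 84))
  expect_equal(c(parts$confirm$n_A, parts$confirm$n_B), c(88, 40))
  # disjoint and exhaustive: every unit value appears exactly once
  all_vals <- sort(c(parts$screen$values[, 1], parts$confirm$values[, 1]))
  expect_equal(all_vals, sort(s$values[, 1]))
  # same seed, same split
  parts2 <- split_sample(s, plan)
  expect_identical(parts$screen$values, parts2$screen$values)
})

test_that("fractional split rounds per group and guards tiny stages", {
  set.seed(157)
  s <- rand_sample(30, 12, d = 2)
  parts <- split_sample(s, two_stage_plan(screen_fraction = 2 / 3, seed = 1))
  expect_equal(c(parts$screen$n_A, parts$screen$n_B), c(20, 8))
  expect_error(
    split_sample(rand_sample(3, 3), two_stage_plan(screen_fraction = 0.9,
                                                   seed = 1)),
    "at least 2")
})

test_that("screening ranks coordinates by ascending Wilcoxon p-value", {
  set.seed(163)
  n <- 40
  vals <- cbind(rnorm(n),                      # null coordinate
                c(rnorm(20), rnorm(20) + 10),  # complete separation
                rnorm(n))
  s <- two_group_sample(vals, rep(c("A", "B"), each = 20),
                        levels = c("A", "B"))
  scr <- screen_loci(s)
  expect_equal(scr$coordinate[1], 2)           # separated locus first
  expect_equal(nrow(scr), 3)                   # m = d returns all, ordered
  expect_true(!is.unsorted(scr$p_value))
  expect_equal(nrow(screen_loci(s, m = 1)), 1)
})

test_that("a null coordinate ranks mid-list on average over replicates", {
  set.seed(167)
  ranks <- replicate(40, {
    cfg <- model1_config(d = 5, d0 = 1, delta = 2, rho = 0,
                         n_A = 15, n_B = 15, K = 1, seed = 1,
                         calibration = "chi2")
    s <- generate_model1(cfg)
    which(screen_loci(s)$coordinate == 1)   # position of the null locus
  })
  expect_gt(mean(ranks), 3)   # shifted loci crowd it towards the back
})

test_that("confirming one locus reduces to the single permutation test", {
  set.seed(173)
  s <- rand_sample(15, 15, d = 3)
  plan <- permutation_plan(30, B = 199, seed = 23)
  ct <- confirm_loci(s, selected = 2, plan = plan)
  single <- relef_test(restrict_coords(s, 2), calibration = "permutation",
                       plan = plan)
  expect_equal(unname(ct$adjusted_p), single$p_permutation)
  # permutation p-values have the plan's granularity
  expect_true(all(abs(ct$subset_p * 200 - round(ct$subset_p * 200)) < 1e-9))
})

test_that("pipeline detects strongly shifted loci on confirmation data", {
  set.seed(179)
  cfg <- model1_config(d = 20, d0 = 10, delta = 3, rho = 0.1,
                       n_A = 264, n_B = 124, K = 1, seed = 1,
                       calibration = "chi2")
  s <- generate_model1(cfg, rep_seed = 181)
  parts <- split_sample(s, two_stage_plan(screen_n = c(176, 84), seed = 29))
  scr <- screen_loci(parts$screen, m = 10)
  expect_gt(sum(scr$coordinate > 10), 7)       # screening finds shifts
  plan <- permutation_plan(128, B = 399, seed = 31)
  ct <- confirm_loci(parts$confirm, scr$coordinate, plan = plan)
  expect_gt(sum(ct$adjusted_p < 0.05), 7)      # most confirmed
})
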
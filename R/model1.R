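#' Configuration of a Model-1 simulation experiment
#'
#' Model 1 draws each observational unit as a d-variate vector with
#' beta marginals coupled by a Gaussian copula whose correlation matrix
#' has AR(1) structure R(l, r) = rho^|l - r| (dependence decaying with
#' coordinate distance, mimicking co-methylation decaying with genomic
#' distance). Coordinates 1..d0 are true nulls: Beta(a_base, b_shape) in
#' both groups. The remaining d1 = d - d0 coordinates keep
#' Beta(a_base, b_shape) in group A but shift the first shape to
#' a_base + delta in group B.
#'
#' @param d number of coordinates.
#' @param d0 number of true null coordinates (default `d`).
#' @param delta first-shape shift in group B on non-null coordinates
#'   (>= 0).
#' @param rho AR(1) copula correlation in \[0, 1).
#' @param n_A,n_B group sizes (defaults 20 and 30, the moderate regime;
#'   the large regime is 100 and 150).
#' @param K Monte-Carlo replications.
#' @param B random permutations per replicate (permutation calibration).
#' @param alpha nominal level (default 0.05).
#' @param seed master seed; per-replicate seeds are pre-drawn from it so
#'   replicates are independent and order-insensitive.
#' @param calibration `"chi2"` or `"permutation"`.
#' @param center permutation-statistic centering (`"null"` or
#'   `"estimated"`), see [permuted_statistic()].
#' @param a_base,b_shape beta shape parameters (defaults 3 and 4).
#' @return An object of class `model1_config`.
#' @export
model1_config <- function(d, d0 = d, delta = 0, rho = 0,
                          n_A = 20L, n_B = 30L, K = 1000L, B = 9999L,
                          alpha = 0.05, seed,
                          calibration = c("chi2", "permutation"),
                          center = c("null", "estimated"),
                          a_base = 3, b_shape = 4) {
  calibration <- match.arg(calibration)
  center <- match.arg(center)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(d >= 1L, d0 >= 0L, d0 <= d, delta >= 0, rho >= 0, rho < 1,
            n_A >= 2L, n_B >= 2L, K >= 1L, B >= 1L, alpha >= 0, alpha <= 1)
  structure(list(d = as.integer(d), d0 = as.integer(d0), delta = delta,
                 rho = rho, n_A = as.integer(n_A), n_B = as.integer(n_B),
                 K = as.integer(K), B = as.integer(B), alpha = alpha,
                 seed = as.integer(seed), calibration = calibration,
                 center = center, a_base = a_base, b_shape = b_shape),
            class = "model1_config")
}

# Cholesky factor of the AR(1) correlation matrix rho^|l-r|
.ar1_chol <- function(d, rho) {
  if (d == 1L) return(matrix(1, 1, 1))
  R <- rho^abs(outer(seq_len(d), seq_len(d), "-"))
  chol(R)
}

#' Draw one Model-1 two-group sample
#'
#' Per unit: a d-variate standard Gaussian with AR(1) correlation is
#' mapped coordinate-wise through the standard normal cdf and then
#' through the beta quantile function of the coordinate's marginal
#' (shapes per [model1_config()]).
#'
#' @param cfg a [model1_config()].
#' @param rep_seed optional seed set before drawing (used by the
#'   experiment loops for per-replicate streams); when NULL the current
#'   RNG stream is used.
#' @return a [two_group_sample()] with groups labelled `"A"` and `"B"`.
#' @export
generate_model1 <- function(cfg, rep_seed = NULL) {
  stopifnot(inherits(cfg, "model1_config"))
  if (!is.null(rep_seed)) set.seed(as.integer(rep_seed))
  N <- cfg$n_A + cfg$n_B
  U <- stats::pnorm(matrix(stats::rnorm(N * cfg$d), N, cfg$d) %*%
                      .ar1_chol(cfg$d, cfg$rho))
  X <- matrix(0, N, cfg$d)
  shifted <- seq_len(cfg$d) > cfg$d0
  rows_B <- cfg$n_A + seq_len(cfg$n_B)
  for (l in seq_len(cfg$d)) {
    X[, l] <- stats::qbeta(U[, l], cfg$a_base, cfg$b_shape)
    if (shifted[l])
      X[rows_B, l] <- stats::qbeta(U[rows_B, l], cfg$a_base + cfg$delta,
                                   cfg$b_shape)
  }
  two_group_sample(X, rep(c("A", "B"), c(cfg$n_A, cfg$n_B)),
                   levels = c("A", "B"),
                   coord_names = paste0("coord", seq_len(cfg$d)))
}

# shared Monte-Carlo loop; decide(sample) must return TRUE on rejection
.mc_rate <- function(cfg, decide) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$K)
  hits <- vapply(seq_len(cfg$K), function(k) {
    set.seed(rep_seeds[k])
    decide(generate_model1(cfg))
  }, logical(1))
  rate <- mean(hits)
  structure(list(rate = rate, se = sqrt(rate * (1 - rate) / cfg$K),
                 K = cfg$K, cfg = cfg),
            class = "experiment_result")
}

# global-test rejection indicator for one replicate (continues the
# replicate's RNG stream for the permutation plan)
.global_reject <- function(sample, cfg) {
  pr <- .pooled_midranks(sample)
  st <- cpp_sample_stats(pr, cfg$n_A, cfg$n_B)
  N <- cfg$n_A + cfg$n_B
  full <- list(seq_len(cfg$d))
  obs <- cpp_wald_subsets(st$p_hat, st$v_hat, full, N, .RANK_TOL)
  if (cfg$calibration == "chi2")
    return(chi2_pvalue(obs$statistic[1], obs$df[1]) <= cfg$alpha)
  perms <- replicate(cfg$B, sample.int(N))
  ctr_ref <- if (cfg$center == "null") rep(0.5, cfg$d)
             else as.numeric(st$p_hat)
  nul <- cpp_perm_null(pr, perms, cfg$n_A, cfg$n_B, ctr_ref, full,
                       .RANK_TOL)
  p <- (1 + sum(nul$w[, 1] >= obs$statistic[1])) / (cfg$B + 1)
  p <= cfg$alpha
}

#' Empirical type-I error of the global test
#'
#' Fraction of K Model-1 replicates (all coordinates true nulls) in
#' which the global test rejects at level alpha.
#'
#' @param cfg a [model1_config()] with `d0 == d`.
#' @return An `experiment_result` with `rate`, `se` (binomial standard
#'   error), `K`.
#' @export
type1_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "model1_config"))
  if (cfg$d0 != cfg$d)
    stop("type-I experiment needs d0 == d (all nulls true)", call. = FALSE)
  .mc_rate(cfg, function(s) .global_reject(s, cfg))
}

#' Empirical power of the global test
#'
#' Rejection rate of the global test over K replicates with d1 > 0
#' shifted coordinates.
#'
#' @param cfg a [model1_config()] with `d0 < d` and `delta > 0`.
#' @return an `experiment_result`.
#' @export
power_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "model1_config"))
  if (cfg$d0 >= cfg$d || cfg$delta <= 0)
    stop("power experiment needs d0 < d and delta > 0", call. = FALSE)
  .mc_rate(cfg, function(s) .global_reject(s, cfg))
}

#' Empirical family-wise error rate of the closed test
#'
#' Fraction of K replicates in which the closed procedure rejects at
#' least one true null coordinate (coordinates 1..d0). The permutation
#' calibration reuses one plan per replicate across all subsets.
#'
#' @param cfg a [model1_config()] with `d0 >= 1`.
#' @return an `experiment_result`.
#' @export
fwer_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "model1_config"))
  if (cfg$d0 < 1L)
    stop("FWER experiment needs at least one true null (d0 >= 1)",
         call. = FALSE)
  subsets <- .all_subsets(cfg$d)
  # membership[s, l]: does subset s contain coordinate l
  membership <- t(vapply(subsets, function(s) seq_len(cfg$d) %in% s,
                         logical(cfg$d)))
  nulls <- seq_len(cfg$d0)
  N <- cfg$n_A + cfg$n_B
  .mc_rate(cfg, function(sample) {
    pr <- .pooled_midranks(sample)
    st <- cpp_sample_stats(pr, cfg$n_A, cfg$n_B)
    obs <- cpp_wald_subsets(st$p_hat, st$v_hat, subsets, N, .RANK_TOL)
    if (cfg$calibration == "chi2") {
      subset_p <- mapply(chi2_pvalue, obs$statistic, obs$df)
    } else {
      perms <- replicate(cfg$B, sample.int(N))
      ctr_ref <- if (cfg$center == "null") rep(0.5, cfg$d)
                 else as.numeric(st$p_hat)
      nul <- cpp_perm_null(pr, perms, cfg$n_A, cfg$n_B, ctr_ref,
                           subsets, .RANK_TOL)
      exceed <- colSums(nul$w >= rep(obs$statistic, each = nrow(nul$w)))
      subset_p <- (1 + exceed) / (cfg$B + 1)
    }
    rejected_S <- subset_p <= cfg$alpha
    # coordinate l rejected iff every subset containing it is rejected
    any(vapply(nulls, function(l) all(rejected_S[membership[, l]]),
               logical(1)))
  })
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Empirical rate %.4f (binomial SE %.4f, K = %d)\n",
              x$rate, x$se, x$K))
  invisible(x)
}
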
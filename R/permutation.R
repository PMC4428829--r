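#' Monte-Carlo permutation plan
#'
#' Draws B random permutations of 1..N (uniformly, with replacement
#' among all N! permutations) and appends the identity, giving B + 1
#' evaluations of the permuted statistic. The same plan is reused for
#' every coordinate subset in closed testing, which cuts compute and
#' induces positive dependence among subset p-values — harmless for the
#' closure principle.
#'
#' @param N total number of observational units.
#' @param B number of random permutations (default 9999).
#' @param seed integer seed; every stochastic entry point in the package
#'   requires one.
#' @param include_identity append the identity permutation (default
#'   TRUE).
#' @return An object of class `permutation_plan`: list with `perms`
#'   (N x (B + identity) integer matrix, one permutation per column,
#'   identity last when included), `B`, `N`, `seed`, `include_identity`.
#' @export
permutation_plan <- function(N, B = 9999L, seed, include_identity = TRUE) {
  stopifnot(N >= 2L, B >= 1L)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  perms <- replicate(B, sample.int(N))
  if (include_identity) perms <- cbind(perms, seq_len(N))
  structure(list(perms = perms, B = as.integer(B), N = as.integer(N),
                 seed = as.integer(seed),
                 include_identity = isTRUE(include_identity)),
            class = "permutation_plan")
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Fraction of group-B units relabelled into pseudo-group A
#'
#' For a permutation pi of the canonical unit order (group A first), tau
#' is the fraction of original-group-B units among the first n_A
#' positions of the permuted order. tau parametrizes the mixture
#' distributions of the pseudo-groups and hence the centering of the
#' permuted statistic.
#'
#' @param perm integer permutation of 1..(n_A + n_B).
#' @param n_A,n_B group sizes.
#' @return tau in \[0, min(1, n_B/n_A)\].
#' @export
tau_fraction <- function(perm, n_A, n_B) {
  stopifnot(length(perm) == n_A + n_B)
  sum(perm[seq_len(n_A)] > n_A) / n_A
}

#' Centering vector of the permuted statistic
#'
#' The permuted relative-effect estimator is not centered at 1/2 but at
#' the tau-dependent mixture
#' c = tau (1 + n_A/n_B) 1_d / 2 + (1 - tau (1 + n_A/n_B)) p-hat,
#' evaluated at the observed-data estimate p-hat. At tau = 0 (identity)
#' the centering equals p-hat itself; for a full group swap with
#' n_A = n_B it equals 1 - p-hat; p-hat = 1/2 is a fixed point.
#'
#' @param tau output of [tau_fraction()].
#' @param n_A,n_B group sizes.
#' @param p_hat observed relative-effect vector (or a
#'   [relative_effects()] object).
#' @return numeric centering vector of length d.
#' @export
permutation_centering <- function(tau, n_A, n_B, p_hat) {
  if (inherits(p_hat, "relative_effects")) p_hat <- p_hat$p_hat
  a <- tau * (1 + n_A / n_B)
  a * 0.5 + (1 - a) * p_hat
}

# pooled midranks, computed once per sample (permutation-invariant)
.pooled_midranks <- function(sample) {
  apply(sample$values, 2L, midranks)
}

#' Studentized permuted statistic (single permutation)
#'
#' Pure-R reference implementation of the permuted quadratic form
#' W^pi = N (p-hat^pi - c)' (V-hat^pi)^+ (p-hat^pi - c) restricted to a
#' subset: relabels units by `perm` into pseudo-groups of sizes n_A and
#' n_B, recomputes relative effects and the placement covariance on the
#' permuted data, and centers at c. The simulation harnesses use an
#' equivalent compiled batch engine; this function is the readable
#' single-permutation form.
#'
#' Two centerings are available. `"null"` (default) centers at the
#' hypothesized value 1/2 of the tested subset — the fixed point of the
#' tau-mixture under the null — which makes the resulting permutation
#' test finite-sample exact when both groups share one distribution.
#' `"estimated"` centers at [permutation_centering()], the tau-dependent
#' mixture around the observed p-hat from the asymptotic theory; under
#' that centering the identity permutation's statistic is exactly 0.
#' Both permutation distributions converge to chi-square with |S|
#' degrees of freedom under the null.
#'
#' @param sample a [two_group_sample()].
#' @param perm integer permutation of 1..N (canonical order, A first).
#' @param subset coordinate indices (default all).
#' @param stat_family `"relative_effect"` or `"wmw"` (numerically
#'   identical under the 1/2-tie kernel).
#' @param center `"null"` or `"estimated"` (see Details).
#' @return the non-negative permuted statistic.
#' @export
permuted_statistic <- function(sample, perm, subset = seq_len(sample$d),
                               stat_family = c("relative_effect", "wmw"),
                               center = c("null", "estimated")) {
  stat_family <- match.arg(stat_family)
  center <- match.arg(center)
  n_A <- sample$n_A; n_B <- sample$n_B
  stopifnot(length(perm) == n_A + n_B,
            setequal(perm, seq_len(n_A + n_B)))
  perm_sample <- two_group_sample(
    sample$values[perm, , drop = FALSE],
    rep(levels(sample$group), c(n_A, n_B)),
    levels = levels(sample$group),
    coord_names = sample$coord_names)
  eff_pi <- relative_effects(perm_sample)
  cov_pi <- covariance_estimate(placements(perm_sample))
  ctr <- if (center == "null") {
    rep(0.5, sample$d)
  } else {
    tau <- tau_fraction(perm, n_A, n_B)
    permutation_centering(tau, n_A, n_B, relative_effects(sample)$p_hat)
  }
  v <- if (stat_family == "wmw") eff_pi$u_hat else eff_pi$p_hat
  ctr <- if (stat_family == "wmw") 1 - ctr else ctr
  si <- studentizing_inverse(cov_pi, subset)
  diff <- v[subset] - ctr[subset]
  max(as.numeric((n_A + n_B) * crossprod(diff, si$inverse %*% diff)), 0)
}

#' Permutation null distribution of the studentized statistic
#'
#' Evaluates the permuted statistic for every permutation in a plan
#' (compiled engine), restricted to a coordinate subset. See
#' [permuted_statistic()] for the two available centerings; the default
#' null centering yields a finite-sample exact test under marginal
#' homogeneity and reproduces the method's published operating
#' characteristics.
#'
#' @param sample a [two_group_sample()].
#' @param plan a [permutation_plan()] with `N == n_A + n_B`.
#' @param subset coordinate indices (default all).
#' @param stat_family statistic family (value identical for both).
#' @param center `"null"` or `"estimated"`.
#' @return An object of class `permutation_null`: list with `w_values`
#'   (one per plan column, identity last when included), `tau_values`,
#'   `B`, `include_identity`, `center`.
#' @export
permutation_null <- function(sample, plan, subset = seq_len(sample$d),
                             stat_family = c("relative_effect", "wmw"),
                             center = c("null", "estimated")) {
  stat_family <- match.arg(stat_family)
  center <- match.arg(center)
  stopifnot(inherits(plan, "permutation_plan"),
            plan$N == sample$n_A + sample$n_B)
  subset <- as.integer(subset)
  pr <- .pooled_midranks(sample)
  ctr_ref <- if (center == "null") rep(0.5, sample$d)
             else relative_effects(sample)$p_hat
  res <- cpp_perm_null(pr, plan$perms, sample$n_A, sample$n_B,
                       ctr_ref, list(subset), .RANK_TOL)
  structure(list(w_values = as.numeric(res$w[, 1L]),
                 tau_values = as.numeric(res$tau),
                 B = plan$B, include_identity = plan$include_identity,
                 center = center),
            class = "permutation_null")
}

#' Monte-Carlo permutation p-value
#'
#' For a Monte-Carlo [permutation_null()] built from B random
#' permutations plus the identity:
#' p = (1 + #\{random pi: W^pi >= w_obs\}) / (B + 1). The identity slot
#' always counts as an exceedance (the observed configuration is one of
#' the B + 1 evaluations), so p lies in (0, 1\] with granularity
#' 1/(B + 1) and never returns 0; with w_obs = 0 every permuted value
#' exceeds and p = 1. A plain numeric vector is instead taken as a
#' complete null distribution and p is the direct exceedance fraction
#' (floored at 1/length so it stays positive).
#'
#' @param w_obs observed statistic.
#' @param null a [permutation_null()], or a plain numeric vector of
#'   permuted statistics forming the complete null.
#' @return p-value in (0, 1\].
#' @export
permutation_pvalue <- function(w_obs, null) {
  if (inherits(null, "permutation_null")) {
    w <- null$w_values
    if (null$include_identity) w <- w[-length(w)]   # identity slot last
    if (length(w) == 0L) stop("empty permutation null", call. = FALSE)
    (1 + sum(w >= w_obs)) / (length(w) + 1)
  } else {
    w <- as.numeric(null)
    if (length(w) == 0L) stop("empty permutation null", call. = FALSE)
    max(1L, sum(w >= w_obs)) / length(w)
  }
}
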
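# Brute-force oracles, kept deliberately independent of the package's
# rank-based computation paths: everything here works from the raw data
# by direct enumeration of pairs or direct ecdf evaluation.

# relative effect by the pairwise 1/2-tie kernel double sum
oracle_p_hat <- function(xA, xB) {
  s <- 0
  for (a in xA) for (b in xB) s <- s + (a < b) + 0.5 * (a == b)
  s / (length(xA) * length(xB))
}

# normalized (mid-) ecdf of sample `ref` evaluated at x
oracle_necdf <- function(x, ref) {
  (sum(ref < x) + 0.5 * sum(ref == x)) / length(ref)
}

# placements by direct cross-group ecdf evaluation
oracle_placements <- function(sample) {
  vA <- sample$values[seq_len(sample$n_A), , drop = FALSE]
  vB <- sample$values[sample$n_A + seq_len(sample$n_B), , drop = FALSE]
  yA <- vA; yB <- vB
  for (l in seq_len(ncol(vA))) {
    yA[, l] <- vapply(vA[, l], oracle_necdf, numeric(1), ref = vB[, l])
    yB[, l] <- vapply(vB[, l], oracle_necdf, numeric(1), ref = vA[, l])
  }
  list(y_A = yA, y_B = yB)
}

# studentizing covariance from oracle placements
oracle_v_hat <- function(sample) {
  pl <- oracle_placements(sample)
  N <- sample$n_A + sample$n_B
  (N / sample$n_A) * cov(pl$y_A) + (N / sample$n_B) * cov(pl$y_B)
}

# spectral pseudoinverse (independent of the package's path)
oracle_pinv <- function(m, tol_rel = 1e-10) {
  sv <- svd(m)
  keep <- sv$d > tol_rel * max(sv$d)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# observed quadratic form from oracle ingredients
oracle_wald <- function(sample, subset = seq_len(sample$d)) {
  vA <- sample$values[seq_len(sample$n_A), , drop = FALSE]
  vB <- sample$values[sample$n_A + seq_len(sample$n_B), , drop = FALSE]
  p <- vapply(seq_len(ncol(vA)),
              function(l) oracle_p_hat(vA[, l], vB[, l]), numeric(1))
  V <- oracle_v_hat(sample)
  diff <- p[subset] - 0.5
  N <- sample$n_A + sample$n_B
  as.numeric(N * t(diff) %*%
               oracle_pinv(V[subset, subset, drop = FALSE]) %*% diff)
}

# permuted studentized statistic: direct implementation of the
# centered quadratic form on the relabelled raw data
oracle_perm_stat <- function(sample, perm, subset = seq_len(sample$d),
                             center = "null") {
  n_A <- sample$n_A; n_B <- sample$n_B
  vals <- sample$values[perm, , drop = FALSE]
  pseudo <- two_group_sample(vals, rep(c("A", "B"), c(n_A, n_B)),
                             levels = c("A", "B"))
  vA <- pseudo$values[seq_len(n_A), , drop = FALSE]
  vB <- pseudo$values[n_A + seq_len(n_B), , drop = FALSE]
  p_pi <- vapply(seq_len(ncol(vA)),
                 function(l) oracle_p_hat(vA[, l], vB[, l]), numeric(1))
  V_pi <- oracle_v_hat(pseudo)
  vA0 <- sample$values[seq_len(n_A), , drop = FALSE]
  vB0 <- sample$values[n_A + seq_len(n_B), , drop = FALSE]
  p_obs <- vapply(seq_len(ncol(vA0)),
                  function(l) oracle_p_hat(vA0[, l], vB0[, l]), numeric(1))
  tau <- sum(perm[seq_len(n_A)] > n_A) / n_A
  a <- tau * (1 + n_A / n_B)
  ctr <- if (center == "null") rep(0.5, length(p_obs))
         else a / 2 + (1 - a) * p_obs
  diff <- (p_pi - ctr)[subset]
  N <- n_A + n_B
  as.numeric(N * t(diff) %*%
               oracle_pinv(V_pi[subset, subset, drop = FALSE]) %*% diff)
}

# convenience: build a d=1 sample from two vectors
tg1 <- function(xA, xB) {
  two_group_sample(cbind(c(xA, xB)),
                   rep(c("A", "B"), c(length(xA), length(xB))),
                   levels = c("A", "B"))
}

# random two-group sample, optionally with heavy ties
rand_sample <- function(n_A, n_B, d = 1, tied = FALSE) {
  n <- n_A + n_B
  vals <- if (tied) matrix(sample(1:4, n * d, replace = TRUE), n, d)
          else matrix(rnorm(n * d), n, d)
  two_group_sample(vals, rep(c("A", "B"), c(n_A, n_B)),
                   levels = c("A", "B"))
}
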
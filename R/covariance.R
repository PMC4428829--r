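#' Placement-based studentizing covariance estimator
#'
#' Estimates the d x d covariance matrix of sqrt(N) (p-hat - p_AB) from
#' the placements: v-hat(l, r) = (N/n_A) c-hat_A(l, r) +
#' (N/n_B) c-hat_B(l, r), where c-hat_i is the unbiased sample
#' covariance (divisor n_i - 1) of the placement columns of group i.
#' Because the relative-effect and Mann-Whitney statistics differ only
#' in sign of the centered vector under the 1/2-tie kernel, the same
#' matrix studentizes both families.
#'
#' A coordinate whose placements are constant in both groups (complete
#' separation) contributes a zero row/column; this is not an error but
#' drives rank deficiency handled downstream by the pseudoinverse.
#'
#' @param pl a [placements()] object.
#' @param n_A,n_B group sizes (defaults taken from `pl`).
#' @return An object of class `covariance_estimate`: list with `v_hat`
#'   (symmetric d x d), `n_A`, `n_B`, `rank` (numerical rank of
#'   `v_hat`).
#' @export
covariance_estimate <- function(pl, n_A = pl$n_A, n_B = pl$n_B) {
  stopifnot(inherits(pl, "placements"), n_A >= 2L, n_B >= 2L)
  N <- n_A + n_B
  v_hat <- (N / n_A) * stats::cov(pl$y_A) + (N / n_B) * stats::cov(pl$y_B)
  v_hat <- (v_hat + t(v_hat)) / 2        # enforce exact symmetry
  structure(list(v_hat = unname(v_hat), n_A = n_A, n_B = n_B,
                 rank = .sym_rank(v_hat)),
            class = "covariance_estimate")
}

# relative eigenvalue tolerance for rank / pseudoinverse decisions
.RANK_TOL <- 1e-10

.sym_rank <- function(m, tol_rel = .RANK_TOL) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev, 0)
  if (mx <= 0) return(0L)
  sum(ev > tol_rel * mx)
}

#' Studentizing (pseudo)inverse of a covariance submatrix
#'
#' Returns the Moore-Penrose pseudoinverse of the S x S submatrix of the
#' studentizing covariance, with eigenvalues below
#' `1e-10 * largest eigenvalue` treated as zero, and the numerical rank
#' as the effective degrees of freedom. For a well-conditioned submatrix
#' this is the ordinary inverse with `effective_df = |S|`; flat
#' directions are projected out, which keeps the quadratic form defined
#' and conservative.
#'
#' @param cov a [covariance_estimate()].
#' @param subset non-empty integer vector of coordinate indices.
#' @return list with `inverse` (|S| x |S| matrix) and `effective_df`
#'   (integer; 0 means the statistic is undefined on this subset).
#' @export
studentizing_inverse <- function(cov, subset = seq_len(nrow(cov$v_hat))) {
  stopifnot(inherits(cov, "covariance_estimate"))
  d <- nrow(cov$v_hat)
  subset <- as.integer(subset)
  if (length(subset) == 0L || any(subset < 1L) || any(subset > d))
    stop("`subset` must be a non-empty subset of 1..d", call. = FALSE)
  m <- cov$v_hat[subset, subset, drop = FALSE]
  eg <- eigen(m, symmetric = TRUE)
  mx <- max(eg$values, 0)
  keep <- eg$values > .RANK_TOL * mx
  r <- sum(keep & mx > 0)
  if (r == 0L) {
    return(list(inverse = matrix(0, length(subset), length(subset)),
                effective_df = 0L))
  }
  v <- eg$vectors[, keep, drop = FALSE]
  inv <- v %*% (t(v) / eg$values[keep])
  list(inverse = (inv + t(inv)) / 2, effective_df = as.integer(r))
}
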
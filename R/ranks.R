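#' Mid-ranks of a numeric vector
#'
#' Ordinary ranks with ties replaced by the average rank of each tie
#' group. Mid-ranks realize the normalized (mid-) empirical cdf: for a
#' sample of size n, the normalized ecdf evaluated at the k-th sample
#' point equals (midrank_k - 1/2)/n.
#'
#' @param x numeric vector, all values finite.
#' @return numeric vector of mid-ranks; the output always sums to
#'   n(n+1)/2.
#' @examples
#' midranks(c(5, 5, 7))       # 1.5 1.5 3
#' midranks(c(0.3, 0.1, 0.3, 0.9))
#' @export
midranks <- function(x) {
  if (length(x) < 1L) stop("empty input", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite values in input", call. = FALSE)
  rank(x, ties.method = "average")
}

#' Empirical relative effects per coordinate
#'
#' Estimates the vector of coordinate-wise relative effects
#' p_AB = P(X_A < X_B) + P(X_A = X_B)/2 by the rank formula
#' p-hat(l) = (Rbar_B(l) - (n_B + 1)/2) / n_A, where Rbar_B(l) is the
#' mean pooled mid-rank of group B in coordinate l. This equals the
#' normalized-ecdf integral of F-hat_A with respect to F-hat_B. The
#' Mann-Whitney functional is reported with the 1/2-weight-at-ties
#' kernel throughout, so u_hat = 1 - p_hat identically (also on tied
#' data).
#'
#' @param sample a [two_group_sample()].
#' @return An object of class `relative_effects`: list with `p_hat` and
#'   `u_hat` (numeric vectors of length d, entries in \[0, 1\]), `n_A`,
#'   `n_B`, `coord_names`.
#' @examples
#' s <- two_group_sample(cbind(c(1, 3, 2, 4)), rep(c("A", "B"), 2))
#' relative_effects(s)$p_hat   # 0.75
#' @export
relative_effects <- function(sample) {
  stopifnot(inherits(sample, "two_group_sample"))
  n_A <- sample$n_A; n_B <- sample$n_B
  pooled <- apply(sample$values, 2L, midranks)
  rbar_B <- colMeans(pooled[.rows_B(sample), , drop = FALSE])
  p_hat <- (rbar_B - (n_B + 1) / 2) / n_A
  structure(
    list(p_hat = unname(p_hat), u_hat = unname(1 - p_hat),
         n_A = n_A, n_B = n_B, coord_names = sample$coord_names),
    class = "relative_effects")
}

#' @export
print.relative_effects <- function(x, ...) {
  cat("Relative effects p_AB (", x$n_A, "vs", x$n_B, "units):\n")
  print(stats::setNames(round(x$p_hat, 4), x$coord_names))
  invisible(x)
}

#' Placements: cross-group normalized-ecdf transforms
#'
#' For each unit, the placement in coordinate l is the normalized
#' empirical cdf of the *other* group evaluated at that unit's value:
#' y_Ak(l) = F-hat_B(l)(x_Ak(l)) and y_Bk(l) = F-hat_A(l)(x_Bk(l)).
#' Computed from ranks as y_Ak = (pooled midrank - within-A midrank)/n_B
#' (and symmetrically for B). Placements are the building blocks of the
#' studentizing covariance matrix.
#'
#' @param sample a [two_group_sample()].
#' @return An object of class `placements`: list with matrices `y_A`
#'   (n_A x d) and `y_B` (n_B x d), entries in \[0, 1\], plus `n_A`,
#'   `n_B`. Column means of `y_B` equal `p_hat`; column means of `y_A`
#'   equal `1 - p_hat`.
#' @export
placements <- function(sample) {
  stopifnot(inherits(sample, "two_group_sample"))
  n_A <- sample$n_A; n_B <- sample$n_B
  iA <- .rows_A(sample); iB <- .rows_B(sample)
  pooled <- apply(sample$values, 2L, midranks)
  within_A <- apply(sample$values[iA, , drop = FALSE], 2L, midranks)
  within_B <- apply(sample$values[iB, , drop = FALSE], 2L, midranks)
  y_A <- (pooled[iA, , drop = FALSE] - within_A) / n_B
  y_B <- (pooled[iB, , drop = FALSE] - within_B) / n_A
  structure(list(y_A = unname(y_A), y_B = unname(y_B),
                 n_A = n_A, n_B = n_B),
            class = "placements")
}
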
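#' Plan for the two-stage screening/confirmation design
#'
#' Confirmatory locus discovery on large panels splits the units once:
#' a screening sub-sample ranks loci by univariate Wilcoxon p-values,
#' and the disjoint confirmation sub-sample runs the closed multivariate
#' test on the top-m loci. Because the stages use disjoint units, the
#' confirmation p-values are valid despite the data-driven selection.
#'
#' @param screen_fraction length-2 numeric (fractions of groups A and B
#'   assigned to screening, each in (0, 1)); counts are rounded. A
#'   single number is recycled.
#' @param screen_n optional length-2 integer vector of explicit
#'   screening counts per group, overriding the fractions (useful to
#'   mirror a published design exactly).
#' @param m number of top-ranked loci carried to confirmation (default
#'   10).
#' @param seed integer seed for the random within-group split.
#' @return An object of class `two_stage_plan`.
#' @export
two_stage_plan <- function(screen_fraction = c(2/3, 2/3), screen_n = NULL,
                           m = 10L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  screen_fraction <- rep_len(screen_fraction, 2L)
  stopifnot(all(screen_fraction > 0), all(screen_fraction < 1), m >= 1L)
  if (!is.null(screen_n)) {
    screen_n <- as.integer(rep_len(screen_n, 2L))
    stopifnot(all(screen_n >= 2L))
  }
  structure(list(screen_fraction = screen_fraction, screen_n = screen_n,
                 m = as.integer(m), seed = as.integer(seed)),
            class = "two_stage_plan")
}

#' Random within-group split into screening and confirmation samples
#'
#' @param sample a [two_group_sample()].
#' @param plan a [two_stage_plan()].
#' @return list with `screen` and `confirm`, both `two_group_sample`s;
#'   together they partition the input units.
#' @export
split_sample <- function(sample, plan) {
  stopifnot(inherits(sample, "two_group_sample"),
            inherits(plan, "two_stage_plan"))
  n <- c(sample$n_A, sample$n_B)
  ns <- if (!is.null(plan$screen_n)) plan$screen_n
        else as.integer(round(plan$screen_fraction * n))
  if (any(ns < 2L) || any(n - ns < 2L))
    stop("each stage must retain at least 2 units per group ",
         "(screen ", paste(ns, collapse = "/"),
         ", confirm ", paste(n - ns, collapse = "/"), ")", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(plan$seed)
  sel_A <- sort(sample(seq_len(n[1]), ns[1]))
  sel_B <- sort(sample(n[1] + seq_len(n[2]), ns[2]))
  take <- function(rows) two_group_sample(
    sample$values[rows, , drop = FALSE],
    as.character(sample$group)[rows],
    levels = levels(sample$group),
    coord_names = sample$coord_names)
  scr <- c(sel_A, sel_B)
  list(screen = take(scr), confirm = take(setdiff(seq_len(sum(n)), scr)))
}

#' Univariate Wilcoxon screening of coordinates
#'
#' Applies the two-sided two-sample Wilcoxon rank-sum test to every
#' coordinate of the screening sample and returns the m coordinates with
#' the smallest p-values (ascending order, ties broken by coordinate
#' index). Exact enumeration is used when the smaller group has at most
#' 10 untied units, otherwise the normal approximation with tie and
#' continuity correction; only the ranking matters for selection.
#'
#' @param sample a [two_group_sample()] (the screening stage).
#' @param m number of coordinates to return (default all, ranked).
#' @return data frame with columns `coordinate` (index), `name`,
#'   `p_value`, ordered by ascending p-value.
#' @export
screen_loci <- function(sample, m = sample$d) {
  stopifnot(inherits(sample, "two_group_sample"), m >= 1L, m <= sample$d)
  iA <- .rows_A(sample); iB <- .rows_B(sample)
  pv <- vapply(seq_len(sample$d), function(l) {
    x <- sample$values[iA, l]; y <- sample$values[iB, l]
    exact <- min(length(x), length(y)) <= 10 &&
      !anyDuplicated(c(x, y))
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  ord <- order(pv, seq_along(pv))[seq_len(m)]
  data.frame(coordinate = ord, name = sample$coord_names[ord],
             p_value = pv[ord])
}

#' Confirmatory closed test on screened loci
#'
#' Restricts the confirmation sample to the selected coordinates and
#' runs the closed multivariate permutation (or chi-square) test,
#' yielding multiplicity-adjusted p-values that account for the m
#' confirmed hypotheses.
#'
#' @param confirm_sample a [two_group_sample()] disjoint from the
#'   screening stage.
#' @param selected coordinate indices (or names) chosen at screening.
#' @param alpha FWER level.
#' @param plan a [permutation_plan()] on the confirmation sample size
#'   (NULL for chi-square calibration).
#' @param calibration `"permutation"` (default) or `"chi2"`.
#' @param center permutation-statistic centering, see
#'   [permuted_statistic()].
#' @return a [closed_test()] result on the selected coordinates.
#' @export
confirm_loci <- function(confirm_sample, selected, alpha = 0.05,
                         plan = NULL,
                         calibration = c("permutation", "chi2"),
                         center = c("null", "estimated")) {
  calibration <- match.arg(calibration)
  center <- match.arg(center)
  sub <- restrict_coords(confirm_sample, selected)
  closed_test(sub, alpha = alpha, calibration = calibration, plan = plan,
              center = center)
}
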
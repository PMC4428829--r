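#' Two-group multivariate sample
#'
#' Container for an N x d matrix of numeric observations (rows =
#' observational units, columns = coordinates, e.g. methylation
#' beta-values per CpG locus) together with a two-level group label.
#' Internally rows are stored in canonical order (all group-A units
#' first), which the permutation machinery relies on.
#'
#' @param values numeric matrix or data frame, N rows (units) by d
#'   columns (coordinates). No missing values allowed.
#' @param group vector of length N with exactly two distinct labels.
#' @param levels optional length-2 vector naming which label is group A
#'   (first element) and which is group B. Defaults to the sorted unique
#'   labels. The orientation matters: the relative effect reported is
#'   p_AB = P(X_A < X_B) + P(X_A = X_B)/2.
#' @param coord_names optional coordinate identifiers; defaults to the
#'   column names of `values`.
#'
#' @return An object of class `two_group_sample` with components
#'   `values` (canonically ordered matrix), `group` (factor with levels
#'   A-label, B-label), `n_A`, `n_B`, `d`, `coord_names`.
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 1), 10))
#' s <- two_group_sample(x, rep(c("ctrl", "case"), each = 10),
#'                       levels = c("ctrl", "case"))
#' s$n_A
#' @export
two_group_sample <- function(values, group, levels = NULL,
                             coord_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` contains missing or non-finite entries", call. = FALSE)
  if (length(group) != nrow(values))
    stop("length(group) must equal nrow(values)", call. = FALSE)
  lv <- unique(as.character(group))
  if (length(lv) != 2L)
    stop("`group` must have exactly 2 levels, found: ",
         paste(lv, collapse = ", "), call. = FALSE)
  if (is.null(levels)) levels <- sort(lv)
  if (!setequal(levels, lv))
    stop("`levels` must name the two observed group labels", call. = FALSE)
  group <- factor(as.character(group), levels = levels)
  ord <- order(group)          # stable: A block first, original order kept
  values <- values[ord, , drop = FALSE]
  group <- group[ord]
  n_A <- sum(group == levels[1L])
  n_B <- sum(group == levels[2L])
  if (n_A < 2L || n_B < 2L)
    stop("each group needs at least 2 units (n_A = ", n_A,
         ", n_B = ", n_B, ")", call. = FALSE)
  if (is.null(coord_names)) coord_names <- colnames(values)
  if (is.null(coord_names)) coord_names <- paste0("V", seq_len(ncol(values)))
  colnames(values) <- coord_names
  structure(
    list(values = values, group = group, n_A = n_A, n_B = n_B,
         d = ncol(values), coord_names = coord_names),
    class = "two_group_sample")
}

#' @export
print.two_group_sample <- function(x, ...) {
  cat("Two-group sample: N =", x$n_A + x$n_B,
      "(", levels(x$group)[1], "=", x$n_A, ",",
      levels(x$group)[2], "=", x$n_B, "), d =", x$d, "coordinates\n")
  invisible(x)
}

# rows (canonical indices) of each group
.rows_A <- function(sample) seq_len(sample$n_A)
.rows_B <- function(sample) sample$n_A + seq_len(sample$n_B)

#' Swap the group labels of a sample
#'
#' Returns the same data with the roles of A and B exchanged; the
#' relative effect of the swapped sample is 1 - p_AB.
#' @param sample a [two_group_sample()].
#' @return a `two_group_sample` with roles exchanged.
#' @export
swap_groups <- function(sample) {
  lv <- levels(sample$group)
  two_group_sample(sample$values, as.character(sample$group),
                   levels = rev(lv), coord_names = sample$coord_names)
}

#' Restrict a sample to a subset of coordinates
#' @param sample a [two_group_sample()].
#' @param subset integer indices or coordinate names to keep.
#' @return a `two_group_sample` on the selected coordinates.
#' @export
restrict_coords <- function(sample, subset) {
  if (is.character(subset))
    subset <- match(subset, sample$coord_names)
  if (anyNA(subset) || any(subset < 1L) || any(subset > sample$d))
    stop("unknown coordinate in `subset`", call. = FALSE)
  two_group_sample(sample$values[, subset, drop = FALSE],
                   as.character(sample$group),
                   levels = levels(sample$group),
                   coord_names = sample$coord_names[subset])
}
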
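#' Read a delimited two-group table
#'
#' Reads a CSV/TSV file with a header, one row per observational unit
#' (or one row per locus with `transpose = TRUE`, the common layout of
#' methylation matrices), a group column, and numeric coordinate
#' columns. Rows with missing values in the selected coordinates are
#' dropped with a message reporting the count.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param group_col name of the group column.
#' @param levels optional length-2 vector: first element is group A (the
#'   reference of p_AB), second group B. The orientation is logged since
#'   p_AB and p_BA mirror around 1/2.
#' @param coords optional coordinate (column) selection; default all
#'   non-group columns.
#' @param transpose set TRUE when the file is loci-by-samples; the group
#'   labels must then be supplied via `levels`-named columns is not
#'   supported — transpose applies to the numeric block only, with
#'   `group_col` read from the first row. Rarely needed; see vignette.
#' @param sep field separator override.
#' @return a [two_group_sample()].
#' @export
read_two_group_table <- function(path, group_col = "group", levels = NULL,
                                 coords = NULL, transpose = FALSE,
                                 sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (transpose) {
    # loci-by-samples: first column = locus names, first data row after
    # transposition must carry the group labels via `group_col` row name
    rn <- df[[1L]]
    m <- t(as.matrix(df[, -1L, drop = FALSE]))
    colnames(m) <- rn
    df <- as.data.frame(m, check.names = FALSE)
  }
  if (!group_col %in% names(df))
    stop("group column `", group_col, "` not found; columns: ",
         paste(utils::head(names(df), 10), collapse = ", "), call. = FALSE)
  grp <- as.character(df[[group_col]])
  lv <- unique(grp)
  if (length(lv) != 2L)
    stop("group column `", group_col, "` has ", length(lv),
         " levels (", paste(lv, collapse = ", "), "); exactly 2 required",
         call. = FALSE)
  if (is.null(coords)) coords <- setdiff(names(df), group_col)
  missing_coords <- setdiff(coords, names(df))
  if (length(missing_coords))
    stop("unknown coordinate column(s): ",
         paste(missing_coords, collapse = ", "), call. = FALSE)
  vals <- df[, coords, drop = FALSE]
  for (cc in coords) {
    v <- suppressWarnings(as.numeric(vals[[cc]]))
    if (all(is.na(v)) && !all(is.na(vals[[cc]])))
      stop("coordinate column `", cc, "` is not numeric", call. = FALSE)
    vals[[cc]] <- v
  }
  keep <- stats::complete.cases(vals)
  if (any(!keep))
    message("dropped ", sum(!keep), " row(s) with missing values")
  if (is.null(levels)) levels <- sort(lv)
  message("group A (reference of p_AB) = `", levels[1],
          "`, group B = `", levels[2], "`")
  two_group_sample(as.matrix(vals[keep, , drop = FALSE]), grp[keep],
                   levels = levels, coord_names = coords)
}

#' Write a test or experiment result as a tidy delimited table
#'
#' Closed-test results get one row per coordinate (name, raw p, adjusted
#' p, rejected); global tests a single row; experiment results one row
#' per configuration cell. Numbers are written with 15 significant
#' digits so a round-trip through [utils::read.csv()] reproduces them.
#'
#' @param result a `relef_test`, `closed_test_result` or
#'   `experiment_result` (or a data frame of stacked experiment rows).
#' @param path output file; `.tsv` extension selects tab separation.
#' @return the data frame written, invisibly.
#' @export
write_results <- function(result, path) {
  df <- results_frame(result)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) formatC(x, digits = 15,
                                                  format = "g"))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Coerce a result object to its tidy data frame form
#' @param result see [write_results()].
#' @return a data frame.
#' @export
results_frame <- function(result) {
  if (is.data.frame(result)) return(result)
  if (inherits(result, "closed_test_result")) {
    d <- length(result$adjusted_p)
    data.frame(
      coordinate = result$coord_names,
      raw_p = unname(result$subset_p[as.character(seq_len(d))]),
      adjusted_p = result$adjusted_p,
      rejected = result$rejected)
  } else if (inherits(result, "relef_test")) {
    data.frame(
      subset = paste(result$subset, collapse = ";"),
      statistic = result$statistic,
      effective_df = result$effective_df,
      p_asymptotic = result$p_asymptotic,
      p_permutation = result$p_permutation)
  } else if (inherits(result, "experiment_result")) {
    cfg <- result$cfg
    data.frame(d = cfg$d, d0 = cfg$d0, delta = cfg$delta, rho = cfg$rho,
               n_A = cfg$n_A, n_B = cfg$n_B,
               calibration = cfg$calibration,
               rate = result$rate, se = result$se, K = result$K)
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }
}
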
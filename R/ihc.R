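#' IHC H-score
#'
#' The H-score summarizes immunohistochemical staining from the percentage of
#' tumor cells at each intensity bucket (0 negative, 1+ weak, 2+ intermediate,
#' 3+ strong):
#' `H = 1 * pct1 + 2 * pct2 + 3 * pct3`, ranging 0-300, with 300 reached only
#' when 100% of cells stain at 3+.
#'
#' @param data Data frame with numeric columns `pct0`, `pct1`, `pct2`, `pct3`
#'   (percentages of cells per intensity), each row one sample.
#' @param renormalize If TRUE, rows are rescaled to sum to exactly 100 before
#'   scoring (useful for tables rounded to integers); otherwise rows whose
#'   percentages do not sum to 100 within `tol` are an error.
#' @param tol Tolerance on the 100% sum check.
#' @return `data` with an added `h_score` column.
#' @examples
#' h_score(tibble::tibble(pct0 = 40, pct1 = 20, pct2 = 30, pct3 = 10))
#' @export
h_score <- function(data, renormalize = FALSE, tol = 1e-6) {
  stopifnot(is.data.frame(data))
  need <- c("pct0", "pct1", "pct2", "pct3")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  m <- as.matrix(data[need])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) || any(m > 100))
    abort("percentages must be finite and in [0, 100]")
  tot <- rowSums(m)
  if (isTRUE(renormalize)) {
    if (any(tot <= 0)) abort("cannot renormalize a row of all-zero percentages")
    m <- 100 * m / tot
  } else if (any(abs(tot - 100) > tol)) {
    bad <- which(abs(tot - 100) > tol)
    abort(paste0("percentages must sum to 100 (rows ",
                 paste(utils::head(bad, 5), collapse = ", "), ")"))
  }
  dplyr::mutate(data, h_score = as.numeric(1 * m[, "pct1"] + 2 * m[, "pct2"] +
                                             3 * m[, "pct3"]))
}

#' Pharmacodynamic change between two H-scores
#'
#' Absolute and relative change from baseline to an on-treatment measurement.
#' The relative change is `NA` (undefined) when the baseline score is 0.
#'
#' @param data Data frame with the two score columns.
#' @param baseline,on_treatment Column names (strings) of the baseline and
#'   on-treatment scores; both must be non-negative.
#' @return `data` with added columns `change_abs` and `change_rel`.
#' @examples
#' pd_change(tibble::tibble(baseline = 100, on_treatment = 50))
#' @export
pd_change <- function(data, baseline = "baseline", on_treatment = "on_treatment") {
  stopifnot(is.data.frame(data))
  for (cl in c(baseline, on_treatment)) {
    if (!cl %in% names(data)) abort(paste0("column `", cl, "` not found"))
    if (!is.numeric(data[[cl]]) || any(data[[cl]] < 0, na.rm = TRUE))
      abort(paste0("column `", cl, "` must be numeric and non-negative"))
  }
  b <- data[[baseline]]; o <- data[[on_treatment]]
  dplyr::mutate(data,
                change_abs = o - b,
                change_rel = ifelse(b == 0, NA_real_, (o - b) / b))
}
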
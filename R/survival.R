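#' Stratify patients into responders and non-responders
#'
#' Patients who progress before the first-scan landmark are non-responders:
#' `NR` iff the progression event occurred with PFS below
#' `pfs_responder_min` (2 months by default); `Resp` iff PFS reached the
#' landmark (event or censored); `indeterminate` iff censored before the
#' landmark — such a patient cannot be shown to have progressed and is
#' excluded from NR/Resp contrasts.
#'
#' @param data Clinical data frame.
#' @param time,event Columns (tidy-eval) holding PFS in months (>= 0) and the
#'   progression indicator (1 = progressed, 0 = censored).
#' @param cfg [threshold_config()].
#' @return `data` with an added factor column `response`
#'   (NR/Resp/indeterminate).
#' @examples
#' cl <- tibble::tibble(pfs_months = c(1.9, 2, 1.5), event = c(1, 1, 0))
#' stratify_response(cl)
#' @export
stratify_response <- function(data, time = pfs_months, event = event,
                              cfg = threshold_config()) {
  stopifnot(is.data.frame(data))
  validate_thresholds(cfg)
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  if (any(t < 0) || any(!is.finite(t))) abort("PFS times must be finite and >= 0")
  if (!all(e %in% c(0, 1))) abort("event flags must be 0 or 1")
  dplyr::mutate(data, response = factor(
    dplyr::case_when(
      e == 1 & t < cfg$pfs_responder_min ~ "NR",
      t >= cfg$pfs_responder_min ~ "Resp",
      TRUE ~ "indeterminate"
    ),
    levels = c("NR", "Resp", "indeterminate")
  ))
}

km_median <- function(time, surv) {
  i <- which(surv <= 0.5 + 1e-12)
  if (length(i) == 0) NA_real_ else min(time[i])
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator, optionally per group. The median is the earliest
#' time at which the survival curve falls to 0.5 or below; `NA` when the
#' curve never reaches 0.5.
#'
#' @param data Data frame of survival records.
#' @param time,event Columns (tidy-eval): follow-up time and event indicator
#'   (1 = event, 0 = censored).
#' @param group Optional grouping column (tidy-eval).
#' @return A `lum_km` object; `tidy()` gives the step function (`group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`), `glance()` per-group
#'   `n`, `events` and `median`.
#' @examples
#' d <- tibble::tibble(t = 1:4, e = 1)
#' glance(kaplan_meier(d, t, e))
#' @export
kaplan_meier <- function(data, time = pfs_months, event = event, group = NULL) {
  stopifnot(is.data.frame(data))
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  if (length(t) < 1) abort("need at least one record")
  if (any(t < 0) || any(!is.finite(t))) abort("times must be finite and >= 0")
  if (!all(e %in% c(0, 1))) abort("event flags must be 0 or 1")
  gq <- enquo(group)
  if (rlang::quo_is_null(gq)) {
    g <- factor(rep("all", length(t)))
  } else {
    g <- factor(dplyr::pull(data, !!gq))
  }
  fits <- lapply(levels(g), function(lv) {
    survival::survfit(survival::Surv(t[g == lv], e[g == lv]) ~ 1)
  })
  names(fits) <- levels(g)
  structure(list(fits = fits, groups = levels(g)), class = "lum_km")
}

#' @exportS3Method generics::tidy
tidy.lum_km <- function(x, ...) {
  purrr::imap(x$fits, function(f, nm) {
    tibble::tibble(group = nm, time = f$time, n_risk = f$n.risk,
                   n_event = f$n.event, n_censor = f$n.censor,
                   survival = f$surv)
  }) |> purrr::list_rbind()
}

#' @exportS3Method generics::glance
glance.lum_km <- function(x, ...) {
  purrr::imap(x$fits, function(f, nm) {
    tibble::tibble(group = nm, n = sum(f$n), events = sum(f$n.event),
                   median = km_median(f$time, f$surv))
  }) |> purrr::list_rbind()
}

#' @export
print.lum_km <- function(x, ...) {
  cat("<Kaplan-Meier estimate>\n")
  print(glance(x))
  invisible(x)
}

#' Log-rank comparison of two survival groups
#'
#' Standard two-group log-rank test (hypergeometric variance at each distinct
#' event time) with a hazard ratio summarized from the observed/expected
#' event ratios, `HR = (O1/E1) / (O2/E2)`, oriented first group level vs
#' second. Per-group Kaplan-Meier medians are attached.
#'
#' @param data Data frame of survival records.
#' @param time,event,group Columns (tidy-eval); `group` must have exactly two
#'   observed levels and there must be at least one event overall.
#' @return A `lum_survcomp` object; `glance()` returns a one-row tibble with
#'   `statistic`, `p_value`, `hazard_ratio`, `groups`; `tidy()` the per-group
#'   observed/expected/median table.
#' @examples
#' d <- tibble::tibble(t = c(1, 2, 3, 4, 5, 6), e = 1,
#'                     g = rep(c("a", "b"), each = 3))
#' glance(km_logrank(d, t, e, g))
#' @export
km_logrank <- function(data, time = pfs_months, event = event, group) {
  stopifnot(is.data.frame(data))
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  if (nlevels(g) != 2) abort("`group` must have exactly two observed levels")
  if (any(table(g) == 0)) abort("both groups must be non-empty")
  if (sum(e) < 1) abort("need at least one event")
  sd_ <- survival::survdiff(survival::Surv(t, e) ~ g)
  obs <- sd_$obs; expd <- sd_$exp
  hr <- (obs[1] / expd[1]) / (obs[2] / expd[2])
  km <- kaplan_meier(tibble::tibble(t = t, e = e, g = g), t, e, g)
  structure(list(
    statistic = unname(sd_$chisq),
    df = 1,
    p_value = pchisq(unname(sd_$chisq), df = 1, lower.tail = FALSE),
    hazard_ratio = unname(hr),
    groups = levels(g),
    observed = unname(obs),
    expected = unname(expd),
    n = unname(table(g)),
    km = km
  ), class = "lum_survcomp")
}

#' @exportS3Method generics::glance
glance.lum_survcomp <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 hazard_ratio = x$hazard_ratio,
                 groups = paste(x$groups, collapse = " vs "))
}

#' @exportS3Method generics::tidy
tidy.lum_survcomp <- function(x, ...) {
  med <- glance(x$km)
  tibble::tibble(group = x$groups, n = as.integer(x$n),
                 observed = x$observed, expected = x$expected,
                 median = med$median[match(x$groups, med$group)])
}

#' @export
print.lum_survcomp <- function(x, ...) {
  cat("<log-rank comparison: ", paste(x$groups, collapse = " vs "), ">\n", sep = "")
  cat(sprintf("  chisq = %.4g on %d df, p = %.4g, HR = %.4g\n",
              x$statistic, x$df, x$p_value, x$hazard_ratio))
  print(tidy(x))
  invisible(x)
}

#' Cross-tabulate response class against best overall response
#'
#' Builds the NR/Resp x cBOR contingency table (indeterminate patients are
#' excluded, as are cBOR categories with no observations) and tests
#' independence with a two-sided chi-square test.
#'
#' @param data Data frame containing both columns.
#' @param response,cbor Columns (tidy-eval): the [stratify_response()] label
#'   and the RECIST confirmed best overall response (CR/PR/SD/PD/NE).
#' @return List with `table` (counts) and `test` (tibble: `statistic`, `df`,
#'   `p_value`).
#' @export
response_vs_cbor <- function(data, response = response, cbor = cbor) {
  stopifnot(is.data.frame(data))
  r <- as.character(dplyr::pull(data, {{ response }}))
  b <- as.character(dplyr::pull(data, {{ cbor }}))
  keep <- r %in% c("NR", "Resp")
  tab <- table(response = r[keep], cbor = b[keep])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  list(table = tab, test = chi_square_independence(tab))
}
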
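#' Plot Kaplan-Meier curves
#'
#' Step-function survival curves per group from a [kaplan_meier()] fit.
#'
#' @param object A `lum_km` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lum_km <- function(object, ...) {
  d <- tidy(object)
  d0 <- dplyr::bind_rows(
    tibble::tibble(group = unique(d$group), time = 0, survival = 1),
    d[c("group", "time", "survival")]
  )
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Progression-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential expression result
#'
#' @param de Result of [differential_expression_paired()].
#' @param cfg [threshold_config()]; supplies the fold-change guide lines.
#' @return A ggplot.
#' @export
plot_volcano <- function(de, cfg = threshold_config()) {
  stopifnot(is.data.frame(de), all(c("log2fc", "fdr", "significant") %in% names(de)))
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-cfg$de_lfc_cut, cfg$de_lfc_cut),
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Scatter plot of luminal classification scores
#'
#' ERalpha activity vs luminal TF score per sample, with the cohort medians
#' as dotted guides and points colored by Lum-high/Lum-low class.
#'
#' @param classified Output of [classify_luminal()].
#' @return A ggplot.
#' @export
plot_luminal_scores <- function(classified) {
  stopifnot(is.data.frame(classified), "lum_class" %in% names(classified))
  med <- attr(classified, "medians")
  score_cols <- setdiff(names(classified), c("sample", "lum_class"))[1:2]
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = .data[[score_cols[1]]],
                               y = .data[[score_cols[2]]],
                               colour = .data$lum_class)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = med[1], linetype = "dotted") +
    ggplot2::geom_hline(yintercept = med[2], linetype = "dotted") +
    ggplot2::labs(x = "ERalpha activity score", y = "Luminal TF score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot motif enrichment scores
#'
#' %TP - %FP enrichment score against -log10 Fisher p per motif.
#'
#' @param enr Result of [motif_enrichment()].
#' @return A ggplot.
#' @export
plot_motif_enrichment <- function(enr) {
  stopifnot(is.data.frame(enr), all(c("motif", "score", "p_value") %in% names(enr)))
  ggplot2::ggplot(enr, ggplot2::aes(x = .data$score,
                                    y = -log10(pmax(.data$p_value, 1e-300)))) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$motif), vjust = -0.6, size = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "%TP - %FP", y = "-log10 p (one-sided Fisher)") +
    ggplot2::theme_minimal()
}
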
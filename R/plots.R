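#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Regional association plot
#'
#' -log10(p) against position for one summary-statistics table.
#'
#' @param object A `sumstats` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sumstats <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6,
                                   y = -log10(.data$pvalue))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  title = attr(object, "trait_name")) +
    ggplot2::theme_minimal()
}

#' Posterior-probability bar chart for a colocalization result
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("pp0", "pp1", "pp2", "pp3", "pp4")],
    dplyr::everything(), names_to = "hypothesis", values_to = "posterior")
  ggplot2::ggplot(df, ggplot2::aes(.data$hypothesis, .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-endpoint MR estimates
#'
#' @param mr_table Tibble with `endpoint`, `beta`, `se` (one protein).
#' @return A ggplot.
#' @export
plot_mr_forest <- function(mr_table) {
  df <- dplyr::mutate(mr_table,
                      lo = .data$beta - 1.96 * .data$se,
                      hi = .data$beta + 1.96 * .data$se)
  ggplot2::ggplot(df, ggplot2::aes(.data$beta, .data$endpoint)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "MR estimate (per protein SD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Pleiotropy pyramid plot
#'
#' Protein counts per pleiotropy tier, kidney-specific apex first.
#'
#' @param profiles Output of [classify_pleiotropy()] (row-bound).
#' @return A ggplot.
#' @export
plot_pleiotropy_pyramid <- function(profiles) {
  df <- pleiotropy_pyramid(profiles)
  ggplot2::ggplot(df, ggplot2::aes(.data$n_proteins,
                                   stats::reorder(.data$tier, .data$n_proteins))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "proteins", y = NULL) +
    ggplot2::theme_minimal()
}
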
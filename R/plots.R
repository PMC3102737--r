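# ggplot2 figures for the main result types.

#' Plot a beta-value histogram
#'
#' @param dist A [beta_distribution()] tibble, or a
#'   [methylation_profile()] (binned with `bins`).
#' @param bins Bin count used when a profile is given.
#' @return A ggplot object.
#' @export
plot_beta_distribution <- function(dist, bins = 20L) {
  if (inherits(dist, "methylation_profile")) dist <- beta_distribution(dist, bins)
  ggplot2::ggplot(dist, ggplot2::aes(x = (.data$lo + .data$hi) / 2, y = .data$count)) +
    ggplot2::geom_col(width = 1 / nrow(dist), fill = "grey35") +
    ggplot2::labs(x = expression(beta ~ value), y = "CpG sites") +
    ggplot2::theme_minimal()
}

#' Plot a cross-line overlap spectrum
#'
#' @param spectrum An [overlap_spectrum()] tibble.
#' @return A ggplot object.
#' @export
plot_overlap_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$k, y = .data$n_probes)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "lines sharing the DMR", y = "probes") +
    ggplot2::theme_minimal()
}

#' @method autoplot overlap_spectrum
#' @export
autoplot.overlap_spectrum <- function(object, ...) plot_overlap_spectrum(object)

#' Plot passage cohorts of ES-iPS-DMRs
#'
#' Stacked per-passage bars coloured by cohort (passage of first
#' appearance), with the total count overlaid as a line: the signature
#' appearance/disappearance display of the convergence analysis.
#'
#' @param track A [build_cohorts()] result.
#' @return A ggplot object.
#' @export
plot_cohorts <- function(track) {
  counts <- track |>
    dplyr::filter(.data$called) |>
    dplyr::count(.data$passage, .data$first_passage, name = "n") |>
    dplyr::mutate(cohort = factor(paste0("P", .data$first_passage),
                                  levels = paste0("P", sort(unique(.data$first_passage)))))
  totals <- counts |>
    dplyr::group_by(.data$passage) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$passage), y = .data$n)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$cohort)) +
    ggplot2::geom_line(data = totals, ggplot2::aes(group = 1), colour = "red") +
    ggplot2::geom_point(data = totals, colour = "red") +
    ggplot2::labs(x = "passage", y = "ES-iPS-DMRs", fill = "appeared at",
                  title = attr(track, "line")) +
    ggplot2::theme_minimal()
}

#' @method autoplot cohort_track
#' @export
autoplot.cohort_track <- function(object, ...) plot_cohorts(object)

#' Plot difference values across passages
#'
#' One line per probe of `beta(sample) - beta(ESC average)` against passage;
#' convergence shows as the bundle collapsing toward zero.
#'
#' @param dp A [difference_profile()] tibble.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_difference_profile <- function(dp, alpha = 0.2) {
  ggplot2::ggplot(dp, ggplot2::aes(x = .data$passage, y = .data$delta,
                                   group = .data$probe_id)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "passage", y = "difference value (sample - ESC)") +
    ggplot2::theme_minimal()
}

#' @method autoplot difference_profile
#' @export
autoplot.difference_profile <- function(object, ...) plot_difference_profile(object)
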
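#' Forest-style plot of posterior device summaries
#'
#' Posterior mean GUS per device with its central credible interval,
#' ordered by mean usability.
#'
#' @param object A `gus_summary` from [summarize_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gus_summary
#' @export
autoplot.gus_summary <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      device = factor(.data$device,
                                      levels = rev(.data$device)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$device)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$cri_low,
                                          xmax = .data$cri_high)) +
    ggplot2::labs(x = "Estimated GUS (points, 95% CrI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Rank-probability histograms
#'
#' One panel per device showing the posterior probability of each rank
#' (rank 1 = highest usability), the standard presentation of a Bayesian
#' ranking analysis.
#'
#' @param object A `gus_rank_matrix` from [rank_probabilities()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gus_rank_matrix
#' @export
autoplot.gus_rank_matrix <- function(object, ...) {
  df <- rank_long(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rank),
                                   y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~device) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Rank (1 = highest GUS)", y = "Probability") +
    ggplot2::theme_minimal()
}
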
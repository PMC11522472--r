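#' Plot publicity categories per subset
#'
#' Stacked counts of clonotype publicity categories per repertoire subset,
#' split by source cohort.
#'
#' @param pub Publicity tibble from [publicity()].
#' @return A ggplot object.
#' @export
plot_publicity <- function(pub) {
  pub %>%
    mutate(category = factor(.data$category,
                             levels = c("extremely_public", "public",
                                        "private", "ultraprivate")),
           subset = factor(.data$subset, levels = .subsets)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$subset,
                                 fill = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~source_cohort) +
    ggplot2::labs(x = "repertoire subset", y = "clonotypes",
                  fill = "publicity") +
    ggplot2::theme_minimal()
}

#' Plot convergence against frequency for tracked clonotypes
#'
#' One point per amino-acid clonotype found in the subset: mean
#' convergence (distinct nucleotide sequences per repertoire) against mean
#' frequency, on a log frequency scale.
#'
#' @param hits Amino-acid-level hits from [track_clonotypes()].
#' @param subset Repertoire subset.
#' @return A ggplot object.
#' @export
plot_convergence_frequency <- function(hits, subset = "TN") {
  pts <- hits %>%
    filter(.data$subset == !!subset, .data$found) %>%
    group_by(.data$query_id, .data$source_cohort) %>%
    summarise(convergence = mean(.data$convergence),
              frequency = mean(.data$frequency), .groups = "drop")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$convergence,
                                    y = .data$frequency,
                                    colour = .data$source_cohort)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = paste0(subset, " repertoires"),
                  x = "mean convergence",
                  y = "mean clonotype frequency",
                  colour = "source cohort") +
    ggplot2::theme_minimal()
}

#' Plot per-donor tracking rates
#'
#' @param rates A `tracking_rate` object.
#' @return A ggplot object.
#' @export
plot_tracking_rate <- function(rates) {
  ggplot2::ggplot(rates$per_donor,
                  ggplot2::aes(x = .data$source_donor,
                               y = .data$rate_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = rates$mean, linetype = 2) +
    ggplot2::labs(x = "source donor", y = "tracking rate (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-donor cluster occupancy by cohort
#'
#' @param fractions Tibble from [cluster_fractions()].
#' @return A ggplot object.
#' @export
plot_cluster_composition <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = factor(.data$cluster),
                               y = .data$fraction,
                               colour = .data$cohort)) +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          position = ggplot2::position_dodge(0.7)) +
    ggplot2::geom_point(position =
                          ggplot2::position_jitterdodge(0.1, 0, 0.7),
                        alpha = 0.6) +
    ggplot2::labs(x = "expression cluster", y = "fraction of donor cells",
                  colour = "cohort") +
    ggplot2::theme_minimal()
}
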
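#' Plot observed vs expected panel burden
#'
#' One panel-burden summary per population: the observed number of panel
#' mutation events per individual (point) against the expectation interval
#' of the coverage-adjusted random expectation (box, with the expected
#' mean as center line), both normalized by population sample size.
#'
#' @param object A `burden_fit` from [burden_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_fit
#' @export
autoplot.burden_fit <- function(object, ...) {
  df <- tidy(object) |>
    mutate(obs_norm = .data$x_obs / .data$n,
           exp_norm = .data$expected / .data$n,
           lo_norm = .data$interval_lo / .data$n,
           hi_norm = .data$interval_hi / .data$n,
           label = sprintf("P = %.3g", .data$p_poisson))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population)) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$exp_norm, ymin = .data$lo_norm,
                   ymax = .data$hi_norm),
      width = 0.5, fill = "grey85", colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_norm),
                        colour = "red3", size = 3) +
    ggplot2::geom_text(ggplot2::aes(y = .data$hi_norm,
                                    label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = NULL,
                  y = "panel mutation events per individual",
                  title = "Observed panel burden vs random expectation") +
    ggplot2::theme_minimal()
}

#' Plot per-sample exome-wide mutation burden by population
#'
#' Distribution of the number of truncating mutation events per individual
#' exome-wide across populations.
#'
#' @param pb A `population_burden` tibble (or the `exome_counts` table of
#'   a run bundle, with columns `population` and `M`).
#' @return A ggplot object.
#' @export
plot_exome_burden <- function(pb) {
  ggplot2::ggplot(as_tibble(pb),
                  ggplot2::aes(x = .data$population, y = .data$M)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL,
                  y = "truncating mutation events per individual (exome-wide)") +
    ggplot2::theme_minimal()
}

#' Plot carrier prevalence by population
#'
#' @param fit A `burden_fit`.
#' @return A ggplot object showing the percentage of individuals carrying
#'   at least one panel truncating mutation.
#' @export
plot_carrier_prevalence <- function(fit) {
  ggplot2::ggplot(tidy(fit),
                  ggplot2::aes(x = .data$population,
                               y = .data$carrier_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% mutation carriers") +
    ggplot2::theme_minimal()
}
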
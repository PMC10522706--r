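#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest-style plot of a non-inferiority battery
#'
#' One row per metric, showing the bootstrapped median confidence
#' intervals of the inter-expert and model-expert agreement series,
#' coloured by pairing, with the non-inferiority decision in the label.
#'
#' @param object A `noninf_battery` from [run_noninferiority_battery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noninf_battery <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$p_raw)) |>
    tidyr::pivot_longer(
      cols = c("median_inter", "median_model"),
      names_to = "pairing", values_to = "median"
    ) |>
    dplyr::mutate(
      lower = ifelse(.data$pairing == "median_inter",
                     .data$ci_inter_lower, .data$ci_model_lower),
      upper = ifelse(.data$pairing == "median_inter",
                     .data$ci_inter_upper, .data$ci_model_upper),
      pairing = ifelse(.data$pairing == "median_inter",
                       "inter-expert", "model-expert"),
      label = sprintf("%s (p[adj] = %.3g%s)", .data$metric, .data$p_adjusted,
                      ifelse(.data$non_inferior, ", non-inferior", ""))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median, y = .data$label,
                                   colour = .data$pairing)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~metric, scales = "free", ncol = 2) +
    ggplot2::labs(x = "median agreement (bootstrapped 95% CI)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volume-agreement scatter plot
#'
#' Per-case lesion volumes of two raters with the identity line and the
#' Spearman rank correlation in the subtitle — the standard check that a
#' model reproduces expert volumes, not just voxel overlap.
#'
#' @param volumes A data frame with per-case volumes.
#' @param x,y Names of the two volume columns (strings).
#' @return A ggplot object.
#' @export
plot_volume_agreement <- function(volumes, x, y) {
  rho <- spearman_rho(volumes[[x]], volumes[[y]])
  ggplot2::ggplot(volumes, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "steelblue",
                         fill = "grey80") +
    ggplot2::geom_point(colour = "black") +
    ggplot2::labs(
      x = paste(x, "volume [ml]"), y = paste(y, "volume [ml]"),
      subtitle = sprintf("Spearman R = %.2f", rho)
    ) +
    ggplot2::theme_minimal()
}

#' Per-case volume table of a cohort
#'
#' @param cases Cohort list from [generate_cohort()] or [read_cohort()].
#' @return A tibble with `case_id` and one ml-volume column per mask role.
#' @export
cohort_volumes <- function(cases) {
  purrr::map(cases, function(case) {
    vols <- purrr::map_dbl(case$masks, volume_ml)
    tibble::tibble(case_id = case$case_id, role = names(vols), volume_ml = vols)
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_wider(names_from = "role", values_from = "volume_ml")
}
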
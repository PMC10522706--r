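#' Configuration for the non-inferiority battery
#'
#' Margins follow the published defaults: model-expert agreement may be no
#' worse than 20% of the metric range for dimensionless metrics in
#' `[0, 1]`, at most 3 ml larger for the absolute volume difference, and at
#' most 3 mm larger for the 95th-percentile Hausdorff distance. These
#' bounds represent the normal variation of agreement among experienced
#' raters (see [derive_margins()] for deriving them from data).
#'
#' @param alpha One-sided significance level.
#' @param margin_relative Margin for unit-interval metrics.
#' @param margin_avd_ml Margin for AVD, in ml.
#' @param margin_hd95_mm Margin for HD95, in mm.
#' @param n_boot Bootstrap resamples for the median CIs (>= 1000).
#' @param ci_level Confidence level of the bootstrap CIs.
#' @param seed Integer seed for the bootstrap.
#' @param normality_alpha Level of the Shapiro gate selecting the test.
#' @param zero_handling Zero handling of the signed-rank test,
#'   `"discard"` or `"pratt"`.
#' @param holm_family_size Family size for the Holm correction; defaults to
#'   the number of tests in the run, override when the run is part of a
#'   larger family.
#' @return A list of class `noninf_config`.
#' @export
noninferiority_config <- function(alpha = 0.05,
                                  margin_relative = 0.2,
                                  margin_avd_ml = 3,
                                  margin_hd95_mm = 3,
                                  n_boot = 10000,
                                  ci_level = 0.95,
                                  seed = 1L,
                                  normality_alpha = 0.05,
                                  zero_handling = c("discard", "pratt"),
                                  holm_family_size = NULL) {
  zero_handling <- match.arg(zero_handling)
  stopifnot(alpha > 0, alpha < 1, margin_relative > 0, margin_avd_ml > 0,
            margin_hd95_mm > 0, n_boot >= 1000, ci_level > 0, ci_level < 1)
  structure(list(
    alpha = alpha, margin_relative = margin_relative,
    margin_avd_ml = margin_avd_ml, margin_hd95_mm = margin_hd95_mm,
    n_boot = n_boot, ci_level = ci_level, seed = as.integer(seed),
    normality_alpha = normality_alpha, zero_handling = zero_handling,
    holm_family_size = holm_family_size
  ), class = "noninf_config")
}

margin_for <- function(metric, range, cfg) {
  if (range == "unit_interval") return(cfg$margin_relative)
  if (metric == "AVD") return(cfg$margin_avd_ml)
  if (metric == "HD95") return(cfg$margin_hd95_mm)
  stop(sprintf("no margin defined for metric '%s'", metric), call. = FALSE)
}

#' One-sided non-inferiority p-value for paired agreement series
#'
#' Builds per-case differences oriented so that positive values support
#' non-inferiority — for higher-is-better metrics
#' `delta_i = model_i - inter_i + margin`, for lower-is-better metrics
#' `delta_i = inter_i - model_i + margin` — and tests H1: median(delta) > 0.
#' When the Shapiro test does not reject normality of the deltas at
#' `normality_alpha`, a one-sided paired t-test is used; otherwise the
#' one-sided Wilcoxon signed-rank test.
#'
#' @param inter,model Paired agreement values (same cases, same order);
#'   pairs with an NA on either side are dropped (pairwise-complete).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param margin Positive non-inferiority margin, in the metric's units.
#' @param normality_alpha Shapiro gate level.
#' @param zero_handling Passed to [wilcoxon_signed_rank_one_sided()].
#' @return List with `p`, `test_used` (`"wilcoxon"`, `"paired_t"`, or
#'   `"degenerate"`), `n_used`, `deltas`.
#' @export
noninferiority_p <- function(inter, model,
                             direction = c("higher_better", "lower_better"),
                             margin, normality_alpha = 0.05,
                             zero_handling = "discard") {
  direction <- match.arg(direction)
  if (length(inter) != length(model)) {
    stop("`inter` and `model` must be paired vectors of equal length",
         call. = FALSE)
  }
  ok <- !is.na(inter) & !is.na(model)
  inter <- inter[ok]
  model <- model[ok]
  n <- length(inter)
  if (n < 5L) {
    stop(sprintf("need at least 5 usable pairs, got %d", n), call. = FALSE)
  }
  deltas <- if (direction == "higher_better") {
    model - inter + margin
  } else {
    inter - model + margin
  }
  # snap float-level residuals to zero so a model sitting exactly on the
  # margin boundary is recognised as the degenerate null
  deltas[abs(deltas) <= 1e-10 * margin] <- 0
  if (all(deltas == 0)) {
    return(list(p = 1, test_used = "degenerate", n_used = n, deltas = deltas,
                note = "all oriented differences zero"))
  }
  normal_p <- suppressWarnings(shapiro_normality_p(deltas))
  if (normal_p >= normality_alpha) {
    p <- stats::t.test(deltas, alternative = "greater", mu = 0)$p.value
    return(list(p = p, test_used = "paired_t", n_used = n, deltas = deltas))
  }
  w <- wilcoxon_signed_rank_one_sided(deltas, zero_handling = zero_handling)
  list(p = w$p, test_used = "wilcoxon", n_used = n, deltas = deltas)
}

#' Non-inferiority test for one metric
#'
#' Runs [noninferiority_p()] and adds medians and bootstrap CIs of both
#' agreement series. The adjusted p-value is filled in by
#' [run_noninferiority_battery()], which owns the multiplicity family.
#'
#' @param inter,model Paired agreement values.
#' @param metric Metric name (one of the battery names).
#' @param direction,range Metric orientation and range class, as in
#'   [metric_battery()].
#' @param cfg A [noninferiority_config()].
#' @param margin Margin override; defaults to the config margin for the
#'   metric's family.
#' @return A one-row tibble with medians, CIs, margin, test, raw p.
#' @export
noninferiority_test <- function(inter, model, metric, direction, range,
                                cfg = noninferiority_config(),
                                margin = NULL) {
  if (is.null(margin)) margin <- margin_for(metric, range, cfg)
  res <- noninferiority_p(inter, model, direction, margin,
                          normality_alpha = cfg$normality_alpha,
                          zero_handling = cfg$zero_handling)
  ok <- !is.na(inter) & !is.na(model)
  mkey <- sum(utf8ToInt(metric))
  ci_i <- bootstrap_median_ci(inter[ok], n_boot = cfg$n_boot,
                              level = cfg$ci_level,
                              seed = derive_seed(cfg$seed, mkey, 1L))
  ci_m <- bootstrap_median_ci(model[ok], n_boot = cfg$n_boot,
                              level = cfg$ci_level,
                              seed = derive_seed(cfg$seed, mkey, 2L))
  tibble::tibble(
    metric = metric, n_cases_used = res$n_used,
    median_inter = ci_i$median, ci_inter_lower = ci_i$lower,
    ci_inter_upper = ci_i$upper,
    median_model = ci_m$median, ci_model_lower = ci_m$lower,
    ci_model_upper = ci_m$upper,
    margin = margin, test_used = res$test_used,
    p_raw = res$p, p_adjusted = NA_real_, non_inferior = NA
  )
}

#' Run the non-inferiority battery over an agreement table
#'
#' For every metric present in the agreement table, compares the
#' model-expert agreement series with the inter-expert series of the same
#' comparison rater: pairwise-complete deletion of cases with an undefined
#' value on either side, margin from the metric family, Shapiro-gated
#' one-sided test, then a Holm-Bonferroni adjustment across all p-values
#' of the run. A metric is declared non-inferior when its adjusted p-value
#' is below `cfg$alpha`.
#'
#' @param agreement A long agreement table as produced by
#'   [evaluate_cohort()]: columns `case_id`, `pairing` (`"inter_expert"` /
#'   `"model_expert"`), `metric`, `value`, `defined`.
#' @param cfg A [noninferiority_config()].
#' @param battery Battery tibble giving direction/range per metric.
#' @return An object of class `noninf_battery`: the per-metric results
#'   tibble (see [noninferiority_test()]) with `p_adjusted` and
#'   `non_inferior` filled in, plus the config as attribute. Metrics with
#'   fewer than 5 usable pairs are reported with NA p-values.
#' @export
run_noninferiority_battery <- function(agreement,
                                       cfg = noninferiority_config(),
                                       battery = metric_battery()) {
  stopifnot(all(c("case_id", "pairing", "metric", "value") %in% names(agreement)))
  if (!"defined" %in% names(agreement)) agreement$defined <- !is.na(agreement$value)
  wide <- agreement |>
    dplyr::mutate(value = ifelse(.data$defined, .data$value, NA_real_)) |>
    dplyr::select("case_id", "pairing", "metric", "value") |>
    tidyr::pivot_wider(names_from = "pairing", values_from = "value")
  if (!all(c("inter_expert", "model_expert") %in% names(wide))) {
    stop("agreement table must contain both 'inter_expert' and 'model_expert' pairings",
         call. = FALSE)
  }
  metrics <- battery$metric[battery$metric %in% unique(wide$metric)]
  rows <- purrr::map(metrics, function(m) {
    sub <- dplyr::filter(wide, .data$metric == m)
    spec <- dplyr::filter(battery, .data$metric == m)
    n_ok <- sum(!is.na(sub$inter_expert) & !is.na(sub$model_expert))
    if (n_ok < 5L) {
      return(tibble::tibble(
        metric = m, n_cases_used = n_ok,
        median_inter = NA_real_, ci_inter_lower = NA_real_,
        ci_inter_upper = NA_real_, median_model = NA_real_,
        ci_model_lower = NA_real_, ci_model_upper = NA_real_,
        margin = margin_for(m, spec$range, cfg), test_used = "none",
        p_raw = NA_real_, p_adjusted = NA_real_, non_inferior = NA
      ))
    }
    noninferiority_test(sub$inter_expert, sub$model_expert, m,
                        spec$direction, spec$range, cfg = cfg)
  })
  out <- dplyr::bind_rows(rows)
  tested <- !is.na(out$p_raw)
  m_family <- max(cfg$holm_family_size %||% 0L, sum(tested))
  if (any(tested)) {
    adj <- holm_bonferroni(out$p_raw[tested])
    if (m_family > sum(tested)) {
      # family larger than the run: rescale per Holm with the declared size
      o <- order(out$p_raw[tested])
      p_sorted <- out$p_raw[tested][o]
      adj_sorted <- pmin(1, cummax(p_sorted * (m_family - seq_along(p_sorted) + 1L)))
      adj <- adj_sorted[order(o)]
    }
    out$p_adjusted[tested] <- adj
    out$non_inferior[tested] <- adj < cfg$alpha
  }
  structure(out, class = c("noninf_battery", class(out)), config = cfg)
}

#' @export
print.noninf_battery <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Non-inferiority battery: %d metrics, alpha = %g (Holm-adjusted)\n",
    nrow(x), cfg$alpha
  ))
  NextMethod()
  invisible(x)
}

#' Derive non-inferiority margins from inter-expert variability
#'
#' Estimates the margins as the average difference in inter-expert
#' agreements: for each metric, the mean absolute per-case difference
#' between two inter-expert agreement series (for example expert B vs the
#' reference and expert C vs the reference), then averaged over the
#' metrics of each family (unit-interval metrics; SI-unit metrics AVD and
#' HD95). This is one reading of "average difference in inter-expert
#' agreement"; the rounded defaults of [noninferiority_config()] remain
#' the operative margins unless you pass the derived ones explicitly.
#'
#' @param agreement_a,agreement_b Two long agreement tables (columns
#'   `case_id`, `metric`, `value`, `defined`), one per inter-expert
#'   pairing, covering the same cases.
#' @param battery Battery tibble classifying metrics into families.
#' @return A tibble with columns `family`, `margin_derived`,
#'   `margin_default`, `n_metrics`.
#' @export
derive_margins <- function(agreement_a, agreement_b,
                           battery = metric_battery()) {
  prep <- function(tab, val_name) {
    if (!"defined" %in% names(tab)) tab$defined <- !is.na(tab$value)
    tab |>
      dplyr::mutate(value = ifelse(.data$defined, .data$value, NA_real_)) |>
      dplyr::select("case_id", "metric", !!val_name := "value")
  }
  joined <- dplyr::inner_join(prep(agreement_a, "value_a"),
                              prep(agreement_b, "value_b"),
                              by = c("case_id", "metric"))
  if (nrow(joined) == 0L) {
    stop("agreement tables share no (case, metric) entries", call. = FALSE)
  }
  per_metric <- joined |>
    dplyr::filter(!is.na(.data$value_a), !is.na(.data$value_b)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean_abs_diff = mean(abs(.data$value_a - .data$value_b)),
                     .groups = "drop") |>
    dplyr::left_join(dplyr::select(battery, "metric", "range"), by = "metric") |>
    dplyr::mutate(family = ifelse(.data$range == "unit_interval",
                                  "unit_interval", "si_units"))
  out <- per_metric |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(margin_derived = mean(.data$mean_abs_diff),
                     n_metrics = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(margin_default = ifelse(.data$family == "unit_interval", 0.2, 3))
  if (any(out$margin_derived == 0)) {
    warning("derived margin of 0: the two inter-expert series are identical")
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a non-inferiority battery
#'
#' @param x A `noninf_battery`.
#' @param ... Unused.
#' @return The per-metric results as a plain tibble.
#' @export
tidy.noninf_battery <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a non-inferiority battery
#'
#' @param x A `noninf_battery`.
#' @param ... Unused.
#' @return A one-row tibble: metrics tested, number non-inferior, alpha,
#'   bootstrap settings.
#' @export
glance.noninf_battery <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_metrics = nrow(x),
    n_tested = sum(!is.na(x$p_raw)),
    n_non_inferior = sum(x$non_inferior, na.rm = TRUE),
    alpha = cfg$alpha,
    n_boot = cfg$n_boot,
    ci_level = cfg$ci_level
  )
}
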
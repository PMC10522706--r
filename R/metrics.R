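#' The agreement-metric battery
#'
#' Returns the specification of the seven metrics used to compare an ordered
#' (prediction, reference) mask pair:
#'
#' * volume metrics: volumetric similarity (`VS`, dimensionless) and absolute
#'   volume difference (`AVD`, ml);
#' * overlap metrics: `Dice`, `Precision`, `Recall` (dimensionless);
#' * distance metrics: 95th-percentile Hausdorff distance (`HD95`, mm) and
#'   surface Dice at tolerance (`SDT`, dimensionless).
#'
#' The direction column records whether larger values mean better agreement;
#' downstream non-inferiority testing orients its hypotheses from it, so
#' callers cannot accidentally invert a metric.
#'
#' @param tolerance_mm Tolerance for the surface Dice, in mm. The default of
#'   5 mm suits structures whose outer border carries most of the
#'   inter-rater variability, such as ischemic-core hypodensity.
#' @return A tibble with columns `metric`, `direction` (`"higher_better"` /
#'   `"lower_better"`), `range`, `units`, `tolerance_mm` (NA except SDT).
#' @export
metric_battery <- function(tolerance_mm = 5) {
  if (!is.numeric(tolerance_mm) || length(tolerance_mm) != 1L ||
      is.na(tolerance_mm) || tolerance_mm <= 0) {
    stop("`tolerance_mm` must be a positive number", call. = FALSE)
  }
  tibble::tibble(
    metric = c("VS", "AVD", "Dice", "Precision", "Recall", "HD95", "SDT"),
    direction = c("higher_better", "lower_better", "higher_better",
                  "higher_better", "higher_better", "lower_better",
                  "higher_better"),
    range = c("unit_interval", "nonnegative_real", "unit_interval",
              "unit_interval", "unit_interval", "nonnegative_real",
              "unit_interval"),
    units = c("dimensionless", "ml", "dimensionless", "dimensionless",
              "dimensionless", "mm", "dimensionless"),
    tolerance_mm = c(NA, NA, NA, NA, NA, NA, tolerance_mm)
  )
}

#' Voxelwise confusion counts for a mask pair
#'
#' @param pred,ref [seg_mask()] objects on the same grid; `pred` is the
#'   prediction, `ref` the reference.
#' @return A one-row tibble with integer columns `tp`, `fp`, `fn`, `tn`
#'   summing to the grid's voxel count.
#' @export
confusion_counts <- function(pred, ref) {
  assert_compatible(pred, ref)
  p <- pred$voxels
  r <- ref$voxels
  tp <- sum(p & r)
  fp <- sum(p & !r)
  fn <- sum(!p & r)
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = prod(pred$shape) - tp - fp - fn)
}

metric_row <- function(metric, value, defined = TRUE, note = NA_character_) {
  tibble::tibble(metric = metric, value = value, defined = defined, note = note)
}

#' Overlap and volume metrics
#'
#' `dice_coef()` is 2TP / (2TP + FP + FN); `precision_coef()` TP / (TP + FP);
#' `recall_coef()` TP / (TP + FN); `volumetric_similarity()`
#' 1 - |Vp - Vr| / (Vp + Vr) on ml volumes; `absolute_volume_difference()`
#' |Vp - Vr| in ml.
#'
#' Empty-mask conventions (annotators may legitimately segment nothing):
#' if both masks are empty the pair agrees perfectly, so Dice, precision,
#' recall and VS are 1 and AVD is 0. If exactly one is empty, Dice and VS
#' are 0; precision is undefined when the prediction is empty and recall
#' undefined when the reference is empty (a 0/0 ratio), signalled via
#' `defined = FALSE` rather than dropped silently.
#'
#' @param pred,ref [seg_mask()] objects on the same grid.
#' @return A one-row tibble: `metric`, `value`, `defined`, `note`.
#' @name overlap_metrics
NULL

#' @rdname overlap_metrics
#' @export
dice_coef <- function(pred, ref) {
  cc <- confusion_counts(pred, ref)
  denom <- 2 * cc$tp + cc$fp + cc$fn
  if (denom == 0) {
    return(metric_row("Dice", 1, note = "both masks empty"))
  }
  metric_row("Dice", 2 * cc$tp / denom)
}

#' @rdname overlap_metrics
#' @export
precision_coef <- function(pred, ref) {
  cc <- confusion_counts(pred, ref)
  if (cc$tp + cc$fp == 0) {
    if (cc$fn == 0) {
      return(metric_row("Precision", 1, note = "both masks empty"))
    }
    return(metric_row("Precision", NA_real_, defined = FALSE,
                      note = "empty prediction"))
  }
  metric_row("Precision", cc$tp / (cc$tp + cc$fp))
}

#' @rdname overlap_metrics
#' @export
recall_coef <- function(pred, ref) {
  cc <- confusion_counts(pred, ref)
  if (cc$tp + cc$fn == 0) {
    if (cc$fp == 0) {
      return(metric_row("Recall", 1, note = "both masks empty"))
    }
    return(metric_row("Recall", NA_real_, defined = FALSE,
                      note = "empty reference"))
  }
  metric_row("Recall", cc$tp / (cc$tp + cc$fn))
}

#' @rdname overlap_metrics
#' @export
volumetric_similarity <- function(pred, ref) {
  assert_compatible(pred, ref)
  vp <- volume_ml(pred)
  vr <- volume_ml(ref)
  if (vp + vr == 0) {
    return(metric_row("VS", 1, note = "both masks empty"))
  }
  metric_row("VS", 1 - abs(vp - vr) / (vp + vr))
}

#' @rdname overlap_metrics
#' @export
absolute_volume_difference <- function(pred, ref) {
  assert_compatible(pred, ref)
  metric_row("AVD", abs(volume_ml(pred) - volume_ml(ref)))
}

#' Surface voxels of a mask
#'
#' Foreground voxels with at least one face-adjacent (6-connected)
#' neighbour that is background or lies outside the grid. A structure
#' touching the image edge therefore has surface there.
#'
#' @param mask A [seg_mask()].
#' @return Integer matrix of 1-based voxel indices, one row per surface
#'   voxel, columns `i`, `j`, `k`; zero rows for an empty mask.
#' @export
surface_voxels <- function(mask) {
  stopifnot_mask(mask)
  surf <- surface_mask_cpp(as.vector(mask$voxels), as.integer(mask$shape))
  idx <- which(array(surf, dim = mask$shape), arr.ind = TRUE)
  colnames(idx) <- c("i", "j", "k")
  idx
}

#' Directed surface-to-surface distances
#'
#' For every voxel in `a_surface`, the Euclidean distance in mm from its
#' centre to the centre of the nearest voxel in `b_surface`, with the
#' spacing applied per axis before the norm. Computed with an exact
#' separable distance transform; agrees with the all-pairs definition.
#'
#' @param a_surface,b_surface Integer index matrices as returned by
#'   [surface_voxels()]; `b_surface` must be non-empty.
#' @param spacing_mm Positive spacing triple.
#' @param shape Grid shape; defaults to the tight bounding box of both sets.
#' @return Numeric vector of distances, one per row of `a_surface`.
#' @export
directed_surface_distances <- function(a_surface, b_surface, spacing_mm,
                                       shape = NULL) {
  a_surface <- rbind(a_surface)
  b_surface <- rbind(b_surface)
  if (nrow(b_surface) == 0L) {
    stop("distances are undefined: target surface is empty", call. = FALSE)
  }
  if (nrow(a_surface) == 0L) return(numeric(0))
  if (is.null(shape)) {
    shape <- pmax(apply(a_surface, 2, max), apply(b_surface, 2, max))
  }
  seeds <- array(FALSE, dim = shape)
  seeds[b_surface] <- TRUE
  d2 <- array(edt_squared_cpp(as.vector(seeds), as.integer(shape),
                              as.numeric(spacing_mm)),
              dim = shape)
  sqrt(d2[a_surface])
}

directed_distance_pair <- function(pred, ref) {
  sp <- surface_voxels(pred)
  sr <- surface_voxels(ref)
  list(
    pred_to_ref = directed_surface_distances(sp, sr, pred$spacing_mm,
                                             shape = pred$shape),
    ref_to_pred = directed_surface_distances(sr, sp, pred$spacing_mm,
                                             shape = pred$shape),
    n_pred = nrow(sp), n_ref = nrow(sr)
  )
}

#' 95th-percentile Hausdorff distance
#'
#' The maximum of the two directed 95th-percentile surface distances
#' (prediction to reference and reference to prediction), percentiles taken
#' with linear interpolation between order statistics. With
#' `method = "pooled"` the 95th percentile of the pooled directed distances
#' is used instead; the max-of-directed form is the default and the one
#' pinned by the package's brute-force oracle tests.
#'
#' Both masks empty is perfect agreement (0 mm); exactly one empty leaves
#' the distance undefined (`defined = FALSE`, note `"empty mask"`).
#'
#' @param pred,ref [seg_mask()] objects on the same grid.
#' @param percentile Percentile of the directed distances, default 0.95.
#' @param method `"max_directed"` (default) or `"pooled"`.
#' @return A one-row tibble: `metric`, `value` (mm), `defined`, `note`.
#' @export
hd95 <- function(pred, ref, percentile = 0.95,
                 method = c("max_directed", "pooled")) {
  method <- match.arg(method)
  assert_compatible(pred, ref)
  np <- sum(pred$voxels)
  nr <- sum(ref$voxels)
  if (np == 0 && nr == 0) {
    return(metric_row("HD95", 0, note = "both masks empty"))
  }
  if (np == 0 || nr == 0) {
    return(metric_row("HD95", NA_real_, defined = FALSE, note = "empty mask"))
  }
  dd <- directed_distance_pair(pred, ref)
  v <- if (method == "max_directed") {
    max(stats::quantile(dd$pred_to_ref, percentile, names = FALSE, type = 7),
        stats::quantile(dd$ref_to_pred, percentile, names = FALSE, type = 7))
  } else {
    stats::quantile(c(dd$pred_to_ref, dd$ref_to_pred), percentile,
                    names = FALSE, type = 7)
  }
  metric_row("HD95", v)
}

#' Surface Dice at tolerance
#'
#' Fraction of surface voxels of either mask lying within `tolerance_mm` of
#' the other mask's surface (also called the normalised surface Dice):
#' surface voxels closer than the tolerance count as surface true
#' positives. Both masks empty gives 1; exactly one empty gives 0.
#'
#' @param pred,ref [seg_mask()] objects on the same grid.
#' @param tolerance_mm Positive tolerance in mm (default 5).
#' @return A one-row tibble: `metric`, `value`, `defined`, `note`.
#' @export
surface_dice_at_tolerance <- function(pred, ref, tolerance_mm = 5) {
  assert_compatible(pred, ref)
  if (!is.numeric(tolerance_mm) || length(tolerance_mm) != 1L ||
      is.na(tolerance_mm) || tolerance_mm <= 0) {
    stop("`tolerance_mm` must be a positive number", call. = FALSE)
  }
  np <- sum(pred$voxels)
  nr <- sum(ref$voxels)
  if (np == 0 && nr == 0) {
    return(metric_row("SDT", 1, note = "both masks empty"))
  }
  if (np == 0 || nr == 0) {
    return(metric_row("SDT", 0, note = "empty mask"))
  }
  dd <- directed_distance_pair(pred, ref)
  v <- (sum(dd$pred_to_ref <= tolerance_mm) + sum(dd$ref_to_pred <= tolerance_mm)) /
    (dd$n_pred + dd$n_ref)
  metric_row("SDT", v)
}

#' Evaluate the full metric battery on one mask pair
#'
#' Applies every metric in `battery` to the ordered (prediction, reference)
#' pair, with the documented empty-mask conventions. The surface distances
#' are computed once and shared between HD95 and SDT.
#'
#' @param pred,ref [seg_mask()] objects on the same grid.
#' @param battery A battery tibble from [metric_battery()]; rows may be
#'   dropped or reordered to select a subset.
#' @return A tibble with one row per battery row: `metric`, `value`,
#'   `defined`, `units`, `note`.
#' @examples
#' m <- seg_mask(array(1, c(4, 4, 4)))
#' evaluate_pair(m, m)
#' @export
evaluate_pair <- function(pred, ref, battery = metric_battery()) {
  assert_compatible(pred, ref)
  np <- sum(pred$voxels)
  nr <- sum(ref$voxels)
  need_dist <- any(battery$metric %in% c("HD95", "SDT")) && np > 0 && nr > 0
  dd <- if (need_dist) directed_distance_pair(pred, ref) else NULL

  one <- function(metric, tolerance_mm) {
    switch(metric,
      VS = volumetric_similarity(pred, ref),
      AVD = absolute_volume_difference(pred, ref),
      Dice = dice_coef(pred, ref),
      Precision = precision_coef(pred, ref),
      Recall = recall_coef(pred, ref),
      HD95 = if (is.null(dd)) hd95(pred, ref) else {
        metric_row("HD95", max(
          stats::quantile(dd$pred_to_ref, 0.95, names = FALSE, type = 7),
          stats::quantile(dd$ref_to_pred, 0.95, names = FALSE, type = 7)
        ))
      },
      SDT = if (is.null(dd)) surface_dice_at_tolerance(pred, ref, tolerance_mm) else {
        metric_row("SDT", (sum(dd$pred_to_ref <= tolerance_mm) +
                           sum(dd$ref_to_pred <= tolerance_mm)) /
                          (dd$n_pred + dd$n_ref))
      },
      stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
    )
  }
  res <- purrr::map2(battery$metric, battery$tolerance_mm, one)
  dplyr::bind_rows(res) |>
    dplyr::mutate(units = battery$units, .after = "value")
}
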
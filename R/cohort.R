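#' Lesion-cohort generation parameters
#'
#' Describes the synthetic ground-truth lesions: irregular (smoothed)
#' ellipsoids placed on a voxel grid. The default desk-scale grid is
#' 64 x 64 x 32 voxels at (3.6, 3.6, 3.0) mm — a coarse version of a head
#' CT grid with thick slices along the third axis — so a full multi-rater
#' cohort evaluates in seconds. Default target volumes of 5–30 ml match
#' the interquartile range of expert-annotated ischemic-core volumes.
#'
#' @param grid_shape Integer triple of grid dimensions.
#' @param spacing_mm Positive voxel spacing triple in mm.
#' @param n_lesions Number of lesions per case (>= 0).
#' @param radii_mm_range Range the per-axis ellipsoid radii are drawn from
#'   before rescaling to the target volume; controls axis ratios.
#' @param center_jitter_mm Uniform jitter of lesion centres around the grid
#'   centre, per axis, in mm.
#' @param target_volume_ml_range Range the target lesion volume is drawn
#'   from, in ml.
#' @param shape_irregularity Amplitude of the smooth level-set perturbation
#'   that roughens the ellipsoid boundary (0 = exact ellipsoids).
#' @return A list of class `lesion_params`.
#' @export
lesion_params <- function(grid_shape = c(64, 64, 32),
                          spacing_mm = c(3.6, 3.6, 3.0),
                          n_lesions = 1,
                          radii_mm_range = c(8, 30),
                          center_jitter_mm = 15,
                          target_volume_ml_range = c(5, 30),
                          shape_irregularity = 0.15) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            n_lesions >= 0, all(radii_mm_range > 0),
            diff(radii_mm_range) >= 0, center_jitter_mm >= 0,
            all(target_volume_ml_range > 0), shape_irregularity >= 0)
  extent <- grid_shape * spacing_mm
  r_max <- (3 / (4 * pi) * max(target_volume_ml_range) * 1000)^(1 / 3)
  if (2.5 * r_max > min(extent)) {
    stop(sprintf(
      "largest target volume (%.0f ml, radius ~%.0f mm) does not fit the %s mm grid",
      max(target_volume_ml_range), r_max, paste(round(extent), collapse = "x")
    ), call. = FALSE)
  }
  structure(list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    n_lesions = as.integer(n_lesions), radii_mm_range = radii_mm_range,
    center_jitter_mm = center_jitter_mm,
    target_volume_ml_range = target_volume_ml_range,
    shape_irregularity = shape_irregularity
  ), class = "lesion_params")
}

#' Simulated annotator model
#'
#' Parameterises one simulated rater. Each true lesion (connected
#' component) is annotated at all with probability `sensitivity`; annotated
#' components are rescaled toward `volume_bias` times their true volume
#' and their boundary is displaced by a smooth random field of scale
#' `boundary_jitter_mm`. An experienced, unbiased rater is
#' `rater_model("A")`; a low-sensitivity under-segmenter (a rater who
#' frequently finds no lesion and outlines conservatively when they do)
#' would have e.g. `sensitivity = 0.55, volume_bias = 0.35`.
#'
#' The simulated "model" prediction is just another rater model: the
#' downstream statistics only ever see agreement values.
#'
#' @param rater_id Short identifier string.
#' @param boundary_jitter_mm Non-negative scale of the random boundary
#'   displacement, in mm.
#' @param volume_bias Positive multiplier for systematic over- or
#'   under-segmentation (1 = unbiased).
#' @param sensitivity Probability in `[0, 1]` of annotating a true lesion.
#' @param seed_offset Integer decorrelating this rater's randomness from
#'   other raters within the same case.
#' @return A list of class `rater_model`.
#' @export
rater_model <- function(rater_id, boundary_jitter_mm = 2,
                        volume_bias = 1, sensitivity = 1,
                        seed_offset = 0L) {
  stopifnot(is.character(rater_id), boundary_jitter_mm >= 0,
            volume_bias > 0, sensitivity >= 0, sensitivity <= 1)
  structure(list(
    rater_id = rater_id, boundary_jitter_mm = boundary_jitter_mm,
    volume_bias = volume_bias, sensitivity = sensitivity,
    seed_offset = as.integer(seed_offset)
  ), class = "rater_model")
}

#' Default rater panel for simulated cohorts
#'
#' Three raters plus a model stand-in, emulating the agreement structure
#' of a multi-expert stroke-lesion annotation study: a reference rater A
#' (unbiased, tight boundaries), a test rater B (slight over-segmenter
#' with looser boundaries), a test rater C (strong under-segmenter who
#' misses small lesions — median annotated volume well below the
#' reference), and a model with the reference rater's characteristics but
#' independent randomness.
#'
#' @return Named list of [rater_model()]s: `A`, `B`, `C`, `model`.
#' @export
default_rater_panel <- function() {
  list(
    A = rater_model("A", boundary_jitter_mm = 3, volume_bias = 1.0,
                    sensitivity = 1.0, seed_offset = 1L),
    B = rater_model("B", boundary_jitter_mm = 6, volume_bias = 1.15,
                    sensitivity = 1.0, seed_offset = 2L),
    C = rater_model("C", boundary_jitter_mm = 6, volume_bias = 0.35,
                    sensitivity = 0.55, seed_offset = 3L),
    model = rater_model("model", boundary_jitter_mm = 3, volume_bias = 1.0,
                        sensitivity = 1.0, seed_offset = 4L)
  )
}

# smooth unit-variance random field: iid normal noise on a coarse grid with
# cell size corr_mm, trilinearly interpolated to the full grid
smooth_noise_field <- function(shape, spacing_mm, corr_mm = 12) {
  extent <- shape * spacing_mm
  cdim <- pmax(2L, as.integer(ceiling(extent / corr_mm)) + 1L)
  coarse <- array(stats::rnorm(prod(cdim)), dim = cdim)
  out <- coarse
  for (ax in 1:3) {
    pos <- ((seq_len(shape[ax]) - 1) * spacing_mm[ax]) / corr_mm + 1
    pos <- pmin(pos, dim(out)[1] - 1e-9)
    i0 <- pmax(1L, pmin(as.integer(floor(pos)), dim(out)[1] - 1L))
    w <- pos - i0
    d <- dim(out)
    m <- matrix(out, nrow = d[1])
    interp <- m[i0, , drop = FALSE] * (1 - w) + m[i0 + 1L, , drop = FALSE] * w
    out <- aperm(array(interp, dim = c(shape[ax], d[2], d[3])), c(2, 3, 1))
  }
  s <- stats::sd(out)
  if (s > 0) out <- out / s
  out
}

#' Generate a synthetic ground-truth lesion mask
#'
#' The union of `n_lesions` irregular ellipsoids: per-axis radii are drawn
#' from `radii_mm_range`, rescaled to hit a target volume drawn from
#' `target_volume_ml_range`, centres jittered around the grid centre, and
#' the ellipsoid level set perturbed by a smooth random field so lesion
#' boundaries are not analytic surfaces. Deterministic given `seed`.
#'
#' @param params A [lesion_params()].
#' @param seed Integer seed.
#' @return A [seg_mask()]; empty when `n_lesions = 0`.
#' @export
generate_truth <- function(params, seed) {
  stopifnot(inherits(params, "lesion_params"))
  local_seed(derive_seed(seed, 101L), {
    shape <- params$grid_shape
    sp <- params$spacing_mm
    vox <- array(FALSE, dim = shape)
    if (params$n_lesions == 0L) return(seg_mask(vox, sp))
    coords <- lapply(1:3, function(ax) (seq_len(shape[ax]) - 1) * sp[ax])
    center0 <- vapply(coords, function(x) mean(range(x)), 0)
    for (l in seq_len(params$n_lesions)) {
      radii <- stats::runif(3, params$radii_mm_range[1], params$radii_mm_range[2])
      v_target <- stats::runif(1, params$target_volume_ml_range[1],
                               params$target_volume_ml_range[2]) * 1000
      scale <- (v_target / (4 / 3 * pi * prod(radii)))^(1 / 3)
      radii <- radii * scale
      center <- center0 + stats::runif(3, -params$center_jitter_mm,
                                       params$center_jitter_mm)
      a1 <- ((coords[[1]] - center[1]) / radii[1])^2
      a2 <- ((coords[[2]] - center[2]) / radii[2])^2
      a3 <- ((coords[[3]] - center[3]) / radii[3])^2
      q <- outer(outer(a1, a2, `+`), a3, `+`)
      f <- 1 - q
      if (params$shape_irregularity > 0) {
        f <- f + params$shape_irregularity *
          smooth_noise_field(shape, sp, corr_mm = max(radii) / 1.5)
      }
      vox <- vox | (f > 0)
    }
    seg_mask(vox, sp)
  })
}

#' Simulate one rater's annotation of a ground-truth mask
#'
#' Per connected component of the truth: the component is dropped with
#' probability `1 - sensitivity`; surviving components are re-thresholded
#' on their signed distance transform plus a smooth random displacement
#' field of scale `boundary_jitter_mm`, with the threshold chosen so the
#' annotated volume is `volume_bias` times the true component volume.
#' Perturbing the signed distance field (rather than flipping voxels)
#' keeps annotations compact and surface-like, as hand drawings are.
#' Deterministic given `(seed, seed_offset)`.
#'
#' @param truth A [seg_mask()].
#' @param rater A [rater_model()].
#' @param seed Integer seed (shared across raters of a case; the rater's
#'   `seed_offset` decorrelates them).
#' @return A [seg_mask()] on the same grid.
#' @export
apply_rater <- function(truth, rater, seed) {
  stopifnot_mask(truth)
  stopifnot(inherits(rater, "rater_model"))
  shape <- truth$shape
  sp <- truth$spacing_mm
  local_seed(derive_seed(seed, 202L, rater$seed_offset), {
    lab <- array(label_components_cpp(as.vector(truth$voxels),
                                      as.integer(shape)), dim = shape)
    ncomp <- max(lab)
    out <- array(FALSE, dim = shape)
    if (ncomp == 0L) return(seg_mask(out, sp))
    for (cid in seq_len(ncomp)) {
      keep <- stats::runif(1) <= rater$sensitivity
      noise <- if (rater$boundary_jitter_mm > 0) {
        rater$boundary_jitter_mm * smooth_noise_field(shape, sp)
      } else 0
      if (!keep) next
      comp <- lab == cid
      n_comp <- sum(comp)
      d_out <- sqrt(edt_squared_cpp(as.vector(comp), as.integer(shape), sp))
      d_in <- sqrt(edt_squared_cpp(as.vector(!comp), as.integer(shape), sp))
      g <- array(d_out - d_in, dim = shape) + noise
      # target volume: biased, with symmetric log-normal noise whose CV
      # grows with the jitter relative to the component's radius
      r_eq <- (3 * n_comp * prod(sp) / (4 * pi))^(1 / 3)
      cv <- 0.8 * rater$boundary_jitter_mm / r_eq
      mult <- exp(stats::rnorm(1, 0, cv))
      k <- max(1L, min(length(g),
                       as.integer(round(rater$volume_bias * mult * n_comp))))
      thr <- sort(as.vector(g), partial = k)[k]
      out <- out | (g <= thr)
    }
    seg_mask(out, sp)
  })
}

#' Generate a multi-rater synthetic cohort
#'
#' One ground-truth mask per case plus one annotation per rater and one
#' model prediction, all seeded reproducibly from the master seed (per-case
#' seeds are derived from it, and each rater's `seed_offset` decorrelates
#' raters within a case).
#'
#' @param n_cases Number of cases.
#' @param params A [lesion_params()].
#' @param raters Named list of [rater_model()]s (the human raters).
#' @param model_rater A [rater_model()] standing in for the model.
#' @param seed Master integer seed.
#' @return A list of cases; each case is a list with `case_id` and
#'   `masks`, a named list holding `truth`, one mask per rater id, and
#'   `model`.
#' @export
generate_cohort <- function(n_cases, params = lesion_params(),
                            raters = default_rater_panel()[c("A", "B", "C")],
                            model_rater = default_rater_panel()$model,
                            seed = 1L) {
  stopifnot(n_cases >= 1, length(raters) >= 2)
  purrr::map(seq_len(n_cases), function(i) {
    cs <- derive_seed(seed, 7L, i)
    truth <- generate_truth(params, cs)
    masks <- c(
      list(truth = truth),
      purrr::map(raters, ~ apply_rater(truth, .x, cs)),
      list(model = apply_rater(truth, model_rater, cs))
    )
    names(masks) <- c("truth", names(raters), "model")
    list(case_id = sprintf("case_%03d", i), masks = masks)
  })
}

#' Write a cohort to a NIfTI directory tree
#'
#' Lays out `dir/case_XXX/<role>.nii.gz` plus a `manifest.json` recording
#' the seed and all generation parameters.
#'
#' @param cases Cohort list from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param manifest Optional named list stored as `manifest.json`.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cases, dir, manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (case in cases) {
    cdir <- file.path(dir, case$case_id)
    dir.create(cdir, showWarnings = FALSE)
    for (role in names(case$masks)) {
      write_mask(case$masks[[role]], file.path(cdir, paste0(role, ".nii.gz")))
    }
  }
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory with one `case_*` subdirectory per case.
#' @param roles Optional character vector restricting which role files to
#'   read (without extension); default reads every `.nii`/`.nii.gz`.
#' @return A cohort list in the [generate_cohort()] format.
#' @export
read_cohort <- function(dir, roles = NULL) {
  cdirs <- sort(list.dirs(dir, recursive = FALSE))
  cdirs <- cdirs[grepl("^case_", basename(cdirs))]
  if (length(cdirs) == 0L) {
    stop(sprintf("no case_* subdirectories under '%s'", dir), call. = FALSE)
  }
  purrr::map(cdirs, function(cd) {
    files <- list.files(cd, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    role_names <- sub("\\.nii(\\.gz)?$", "", basename(files))
    if (!is.null(roles)) {
      keep <- role_names %in% roles
      files <- files[keep]
      role_names <- role_names[keep]
    }
    masks <- purrr::map(files, read_mask)
    names(masks) <- role_names
    list(case_id = basename(cd), masks = masks)
  })
}

#' Evaluate agreement pairings across a cohort
#'
#' For every case, runs the metric battery on the two pairings of the
#' study design: the comparison rater against the reference rater
#' (`inter_expert`) and the comparison rater against the model
#' (`model_expert`). The comparison rater takes the prediction slot in
#' both pairings, so precision/recall are oriented consistently.
#'
#' @param cases Cohort list ([generate_cohort()] / [read_cohort()]).
#' @param reference Role name of the reference rater (default `"A"`).
#' @param comparison Role name of the comparison (test) rater (default `"B"`).
#' @param model Role name of the model prediction (default `"model"`).
#' @param battery Battery tibble from [metric_battery()].
#' @return A long agreement tibble: `case_id`, `pairing`, `metric`,
#'   `value`, `units`, `defined`, `note`, with the role mapping in
#'   attribute `"roles"`.
#' @export
evaluate_cohort <- function(cases, reference = "A", comparison = "B",
                            model = "model", battery = metric_battery()) {
  if (length(unique(c(reference, comparison, model))) != 3L) {
    stop("reference, comparison, and model roles must be distinct",
         call. = FALSE)
  }
  need <- c(reference, comparison, model)
  has_all <- vapply(cases, function(case) all(need %in% names(case$masks)), TRUE)
  if (!any(has_all)) {
    stop(sprintf("no case carries all required masks (%s)",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(!has_all)) {
    warning(sprintf(
      "skipping %d case(s) with missing masks: %s", sum(!has_all),
      paste(vapply(cases[!has_all], `[[`, "", "case_id"), collapse = ", ")
    ))
    cases <- cases[has_all]
  }
  rows <- purrr::map(cases, function(case) {
    inter <- evaluate_pair(case$masks[[comparison]], case$masks[[reference]],
                           battery)
    modl <- evaluate_pair(case$masks[[comparison]], case$masks[[model]],
                          battery)
    dplyr::bind_rows(
      dplyr::mutate(inter, pairing = "inter_expert"),
      dplyr::mutate(modl, pairing = "model_expert")
    ) |>
      dplyr::mutate(case_id = case$case_id)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select("case_id", "pairing", "metric", "value", "units",
                  "defined", "note")
  attr(out, "roles") <- list(reference = reference, comparison = comparison,
                             model = model)
  out
}
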
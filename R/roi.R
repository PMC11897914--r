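#' Fit-quality (COD) pixel filter
#'
#' Pixels whose coefficient of determination falls below the threshold
#' are excluded from analysis; these correspond to specular reflections
#' or areas where hemoglobin absorption is not dominant. Retention is
#' `cod >= threshold` (strict `< threshold` exclusion) intersected with
#' the validity mask.
#'
#' @param maps A [parameter_maps()] with the `cod` map filled.
#' @param threshold COD threshold, default 0.7.
#' @return H x W logical matrix of retained pixels.
#' @export
apply_cod_filter <- function(maps, threshold = 0.7) {
  stopifnot(inherits(maps, "parameter_maps"))
  if (is.null(maps$cod)) stop("maps do not contain a COD map")
  keep <- maps$valid_mask & !is.na(maps$cod) & maps$cod >= threshold
  keep
}

#' Extract ROI observations from parameter maps
#'
#' Intersects a region-of-interest mask (e.g. the segmented artery)
#' with the COD/validity filter and emits one long-format row per
#' retained pixel and parameter, keyed by patient, group and phase —
#' the observation unit of the downstream mixed model — plus a per-ROI
#' summary (mean, SD with denominator n-1, pixel count).
#'
#' @param maps A [parameter_maps()].
#' @param roi_mask H x W logical (or 0/1) matrix; nonzero = ROI.
#' @param patient_id,group,phase Metadata labels for the rows.
#' @param cod_threshold COD threshold passed to [apply_cod_filter()].
#' @return List with `observations` (data frame: `patient_id`, `group`,
#'   `phase`, `parameter`, `value`, `pixel_id`) and `summary` (data
#'   frame per parameter).
#' @export
roi_extract <- function(maps, roi_mask, patient_id, group, phase,
                        cod_threshold = 0.7) {
  stopifnot(inherits(maps, "parameter_maps"))
  roi_mask <- roi_mask != 0
  if (!all(dim(roi_mask) == dim(maps$valid_mask)))
    stop("ROI mask shape does not match the parameter maps")
  keep <- roi_mask & apply_cod_filter(maps, cod_threshold)
  if (!any(keep))
    stop("empty ROI: no pixels survive the validity/COD filter")
  idx <- which(keep)
  param_names <- c("oxygenation", "hb_rel", "cod", "superficial", "deep")
  obs <- list()
  summ <- list()
  for (p in param_names) {
    m <- maps[[p]]
    if (is.null(m)) next
    v <- m[idx]
    ok <- !is.na(v)
    if (!any(ok)) next
    obs[[p]] <- data.frame(patient_id = patient_id, group = group,
                           phase = phase, parameter = p,
                           value = v[ok], pixel_id = idx[ok])
    summ[[p]] <- data.frame(patient_id = patient_id, group = group,
                            phase = phase, parameter = p,
                            mean = mean(v[ok]), sd = stats::sd(v[ok]),
                            n = sum(ok))
  }
  list(observations = do.call(rbind, c(obs, make.row.names = FALSE)),
       summary = do.call(rbind, c(summ, make.row.names = FALSE)))
}

#' Bind observation tables
#'
#' @param ... `roi_extract()` results or observation data frames.
#' @return One long-format observation data frame.
#' @export
bind_observations <- function(...) {
  parts <- lapply(list(...), function(x)
    if (is.data.frame(x)) x else x$observations)
  do.call(rbind, c(parts, make.row.names = FALSE))
}

#' Simulate an observation table from the hierarchical pixel model
#'
#' Draws ROI pixel values directly from the generating model of the
#' phantom cohort: a per-patient random baseline (SD `sigma_u`), a
#' fixed pre/post effect `delta`, and independent pixel noise (SD
#' `sigma_e`). Used for calibration studies of the mixed model (type-I
#' error, power) where rendering full images for hundreds of
#' replicates would add nothing.
#'
#' @param n_patients Number of patients.
#' @param n_pixels Retained ROI pixels per phase.
#' @param delta True post-minus-pre effect (0 for a null scenario).
#' @param baseline Grand mean of the parameter.
#' @param sigma_u Between-patient baseline SD.
#' @param sigma_e Within-ROI pixel SD.
#' @param parameter Parameter label for the rows.
#' @param group Group label.
#' @param seed Integer seed.
#' @return Observation data frame as produced by [roi_extract()].
#' @export
simulate_observations <- function(n_patients = 5, n_pixels = 200,
                                  delta = 0, baseline = 0.60,
                                  sigma_u = 0.10, sigma_e = 0.03,
                                  parameter = "oxygenation",
                                  group = "cabg", seed = 1L) {
  with_seed(seed, {
    u <- stats::rnorm(n_patients, 0, sigma_u)
    rows <- lapply(seq_len(n_patients), function(i) {
      pre <- baseline + u[i] + stats::rnorm(n_pixels, 0, sigma_e)
      post <- baseline + u[i] + delta + stats::rnorm(n_pixels, 0, sigma_e)
      data.frame(
        patient_id = sprintf("P%02d", i), group = group,
        phase = rep(c("pre", "post"), each = n_pixels),
        parameter = parameter, value = c(pre, post),
        pixel_id = rep(seq_len(n_pixels), 2L))
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
}
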
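#' Default phantom configuration
#'
#' Parameters of the simulated cardiac scene: a curved vessel (the
#' imaged coronary artery) crossing a perfused tissue background. Units:
#' oxygenation values are fractions of total hemoglobin; `*_tot` values
#' are the product of hemoglobin volume fraction and photon path length
#' (a.u. x cm), the quantity the Beer-Lambert fit actually recovers;
#' `g_mean` is the constant scattering-loss offset of the absorbance
#' model; lengths are pixels.
#'
#' Defaults encode the simulated study conditions: background tissue
#' oxygenation 0.50, vessel oxygenation 0.60 before surgery, a bypass
#' effect of +0.12 on vessel oxygenation (`delta`, matching the reported
#' magnitude of the post-bypass oxygenation increase), and an
#' inter-patient baseline SD of 0.10 (`patient_ox_sd`, matching the
#' spread of reported pre-surgery baselines).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of phantom parameters.
#' @export
phantom_params <- function(...) {
  p <- list(
    background_ox = 0.50,   # tissue oxygenation fraction
    vessel_ox_pre = 0.60,   # vessel oxygenation before bypass
    delta = 0.12,           # bypass-induced vessel oxygenation change
    ox_shift = 0,           # per-patient baseline offset (set by cohorts)
    background_tot = 0.002, # f_Hb * L of background tissue, a.u.
    vessel_tot = 0.005,     # f_Hb * L inside the vessel, a.u.
    g_mean = 0.20,          # scattering offset G, a.u.
    vessel_width = 12,      # full width of the pure-vessel core, px
    vessel_edge = 6,        # soft partial-volume ramp width, px
    vessel_amp = 0.18,      # vessel curvature amplitude, fraction of height
    vessel_freq = 1.2,      # curvature periods across the field
    ox_jitter = 0.03,       # SD of smooth spatial oxygenation variation
    tot_jitter = 0.15,      # relative SD of smooth hemoglobin variation
    g_jitter = 0.05,        # SD of smooth G variation
    smooth_sigma = 8,       # correlation length of the smooth fields, px
    n_specular = 2,         # number of specular highlight patches
    specular_radius = 4     # highlight radius, px
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown phantom parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}

#' Generate a ground-truth phantom scene
#'
#' Builds per-pixel chromophore coefficient maps (`c_hbo2`, `c_hb`, the
#' products of volume fraction and path length) and a scattering offset
#' map, with a curved vessel whose oxygenation depends on scenario and
#' phase: for `scenario = "cabg"` the post-phase vessel oxygenation
#' exceeds the pre-phase by `params$delta`; for `"control"` the two
#' phases share identical generating parameters. Using the same seed for
#' both phases of a patient reproduces the same spatial fields, so the
#' noise-free ground-truth difference equals `delta` exactly.
#'
#' @param height,width Scene size in pixels.
#' @param scenario `"cabg"` or `"control"`.
#' @param phase `"pre"` or `"post"`.
#' @param params A [phantom_params()] list.
#' @param seed Integer seed; scenes are deterministic given the seed.
#' @param patient_id,group Labels carried into downstream observation
#'   tables.
#' @return An object of class `ground_truth_scene` with fields
#'   `c_hbo2`, `c_hb`, `g_offset` (H x W matrices), `vessel_mask`,
#'   `specular_mask` (logical matrices), `oxygenation` (derived map),
#'   and the phase/patient/group labels.
#' @export
make_phantom <- function(height, width, scenario = c("cabg", "control"),
                         phase = c("pre", "post"), params = phantom_params(),
                         seed = 1L, patient_id = "P1", group = NULL) {
  scenario <- match.arg(scenario)
  phase <- match.arg(phase)
  if (is.null(group)) group <- scenario
  if (params$vessel_width >= min(height, width))
    stop("vessel width must be smaller than the scene")
  with_seed(seed, {
    h <- height; w <- width
    # smooth heterogeneity fields (shared across phases for a fixed seed)
    f_ox_bg <- smooth_field(h, w, params$smooth_sigma)
    f_ox_v <- smooth_field(h, w, params$smooth_sigma)
    f_tot_bg <- smooth_field(h, w, params$smooth_sigma)
    f_tot_v <- smooth_field(h, w, params$smooth_sigma)
    f_g <- smooth_field(h, w, params$smooth_sigma)
    phase0 <- stats::runif(1, 0, 2 * pi)

    # curved vessel centerline and soft partial-volume profile
    x <- seq_len(w)
    center <- h / 2 + params$vessel_amp * h *
      sin(2 * pi * params$vessel_freq * x / w + phase0)
    d <- abs(outer(seq_len(h), center, "-"))          # h x w distance map
    half <- params$vessel_width / 2
    edge <- params$vessel_edge
    wv <- ifelse(d <= half, 1,
                 ifelse(d >= half + edge, 0,
                        0.5 * (1 + cos(pi * (d - half) / edge))))
    vessel_mask <- d <= half

    vessel_ox <- switch(scenario,
      cabg = params$vessel_ox_pre + if (phase == "post") params$delta else 0,
      control = params$vessel_ox_pre)
    ox_bg <- clamp(params$background_ox + params$ox_shift +
                     params$ox_jitter * f_ox_bg, 0.02, 0.98)
    ox_v <- clamp(vessel_ox + params$ox_shift +
                    params$ox_jitter * f_ox_v, 0.02, 0.98)
    ox <- (1 - wv) * ox_bg + wv * ox_v

    tot_bg <- params$background_tot * pmax(1 + params$tot_jitter * f_tot_bg, 0.1)
    tot_v <- params$vessel_tot * pmax(1 + params$tot_jitter * f_tot_v, 0.1)
    tot <- (1 - wv) * tot_bg + wv * tot_v

    g <- pmax(params$g_mean + params$g_jitter * f_g, 0)

    # specular highlights: small discs kept clear of the vessel profile
    specular_mask <- matrix(FALSE, h, w)
    if (params$n_specular > 0) {
      rr <- params$specular_radius
      tries <- 0
      placed <- 0
      while (placed < params$n_specular && tries < 50 * params$n_specular) {
        tries <- tries + 1
        cy <- stats::runif(1, 1 + rr, h - rr)
        cx <- stats::runif(1, 1 + rr, w - rr)
        if (abs(cy - center[round(cx)]) < half + edge + rr + 2) next
        disc <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+") <= rr^2
        specular_mask <- specular_mask | disc
        placed <- placed + 1
      }
    }
    specular_mask <- specular_mask & !vessel_mask

    structure(list(
      height = h, width = w,
      c_hbo2 = ox * tot, c_hb = (1 - ox) * tot, g_offset = g,
      oxygenation = ox,
      vessel_mask = vessel_mask, specular_mask = specular_mask,
      scenario = scenario, phase = phase,
      patient_id = patient_id, group = group, seed = seed,
      params = params), class = "ground_truth_scene")
  })
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf(
    "ground_truth_scene %s/%s/%s: %d x %d px, vessel %d px, specular %d px\n",
    x$patient_id, x$scenario, x$phase, x$height, x$width,
    sum(x$vessel_mask), sum(x$specular_mask)))
  invisible(x)
}

#' Render a scene into a reflectance cube (forward Beer-Lambert model)
#'
#' Per pixel and band, absorbance is the linear Beer-Lambert combination
#' `a = c_hbo2 * mu_HbO2 + c_hb * mu_Hb + G` and reflectance is
#' `r = exp(-a)`, in (0, 1]. Specular pixels are overwritten with a
#' near-unity flat reflectance (a saturated highlight), which later
#' yields a near-flat spectrum with an ill-determined fit; the COD
#' filter removes these pixels without special-casing.
#'
#' @param scene A [make_phantom()] scene.
#' @param library A [chromophore_library()].
#' @param camera A [camera_model()].
#' @param mode Chromophore resampling mode, see [resample_chromophores()].
#' @return A [spectral_cube()] at stage `"reflectance"`.
#' @export
forward_reflectance <- function(scene, library, camera, mode = "peak") {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (any(scene$c_hbo2 < 0) || any(scene$c_hb < 0))
    stop("scene chromophore coefficients must be non-negative")
  mu <- resample_chromophores(library, camera, mode = mode)
  b <- n_bands(camera)
  h <- scene$height; w <- scene$width
  data <- array(NA_real_, c(h, w, b))
  for (i in seq_len(b)) {
    a <- scene$c_hbo2 * mu[i, 1L] + scene$c_hb * mu[i, 2L] + scene$g_offset
    data[, , i] <- exp(-a)
  }
  if (any(scene$specular_mask)) {
    idx <- which(scene$specular_mask)
    for (i in seq_len(b)) {
      plane <- data[, , i]
      plane[idx] <- 0.995
      data[, , i] <- plane
    }
  }
  spectral_cube(data, "reflectance", camera)
}
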
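#' Random-intercept mixed model for a pre/post comparison
#'
#' Fits `value ~ phase + (1 | patient_id)` by REML: the bypass phase
#' (pre vs post) as a categorical fixed effect and patient as a random
#' intercept, absorbing the high inter-patient baseline variability of
#' the perfusion parameters. The p-value for the phase coefficient is
#' a large-sample z (Wald) test; with very few patients this is
#' anti-conservative, so [compare_groups()] also reports a patient-
#' level paired t-test as a robustness line.
#'
#' @param table Observation data frame (columns `patient_id`, `phase`,
#'   `parameter`, `value`).
#' @param parameter Which parameter to model.
#' @return An `lmm_result`: list with `beta0`, `beta1` (phase = post
#'   effect), `se`, `p_value`, `sigma_u`, `sigma_e`, `n_obs`,
#'   `n_patients`, `converged`.
#' @export
fit_lmm <- function(table, parameter = "oxygenation") {
  d <- table[table$parameter == parameter & is.finite(table$value), ]
  if (!nrow(d)) stop("no observations for parameter '", parameter, "'")
  d$phase <- factor(d$phase, levels = c("pre", "post"))
  pats <- unique(d$patient_id)
  if (length(pats) < 2L)
    stop("need at least 2 patients: the patient random effect is ",
         "unidentifiable from one")
  both <- tapply(d$phase, d$patient_id, function(p) all(c("pre", "post") %in% p))
  if (!all(both))
    stop("every patient needs observations in both phases; missing for: ",
         paste(names(both)[!both], collapse = ", "))

  fit <- suppressMessages(
    lme4::lmer(value ~ phase + (1 | patient_id), data = d, REML = TRUE))
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- cf[["phasepost"]] / se[[2L]]
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- sqrt(vc$vcov[vc$grp == "patient_id"][1L])
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  # a boundary (singular) fit is a converged fit with sigma_u = 0
  conv <- !length(setdiff(msgs, grep("boundary", msgs, value = TRUE)))
  structure(list(
    beta0 = unname(cf[[1L]]), beta1 = unname(cf[["phasepost"]]),
    se = unname(se[[2L]]), p_value = 2 * stats::pnorm(-abs(z)),
    sigma_u = sigma_u, sigma_e = stats::sigma(fit),
    n_obs = nrow(d), n_patients = length(pats), converged = conv,
    parameter = parameter), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf(
    "lmm_result [%s]: beta1 = %.4g (se %.3g), p = %.3g; sigma_u = %.3g, sigma_e = %.3g; %d obs / %d patients%s\n",
    x$parameter, x$beta1, x$se, x$p_value, x$sigma_u, x$sigma_e,
    x$n_obs, x$n_patients, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Pre/post comparison report per group and parameter
#'
#' For every group and parameter: the mean change +/- SD across
#' patients (each patient contributing its post-minus-pre difference of
#' ROI means), the mixed-model phase effect with its standard error and
#' z-test p-value, a patient-level paired t-test as a robustness check,
#' and a significance flag at `alpha`. Oxygenation rows are reported in
#' percent (x100); all other parameters in a.u. No multiple-testing
#' correction is applied across parameters.
#'
#' @param table Long observation data frame (see [roi_extract()],
#'   [bind_observations()]).
#' @param alpha Significance level on the mixed-model p-value,
#'   default 0.01.
#' @return List with `report` (one row per group x parameter) and
#'   `long` (violin-plot-ready observation data).
#' @export
compare_groups <- function(table, alpha = 0.01) {
  stopifnot(all(c("patient_id", "group", "phase", "parameter", "value")
                %in% names(table)))
  out <- list()
  for (g in unique(table$group)) {
    tg <- table[table$group == g, ]
    for (p in unique(tg$parameter)) {
      tp <- tg[tg$parameter == p & is.finite(tg$value), ]
      if (!nrow(tp)) next
      pm <- stats::aggregate(value ~ patient_id + phase, tp, mean)
      wide <- merge(pm[pm$phase == "pre", c("patient_id", "value")],
                    pm[pm$phase == "post", c("patient_id", "value")],
                    by = "patient_id", suffixes = c("_pre", "_post"))
      change <- wide$value_post - wide$value_pre
      lmm <- tryCatch(fit_lmm(tp, p), error = function(e) NULL)
      tt_p <- if (nrow(wide) >= 2L && stats::sd(change) > 0)
        stats::t.test(change)$p.value else NA_real_
      scale <- if (p == "oxygenation") 100 else 1
      out[[length(out) + 1L]] <- data.frame(
        group = g, parameter = p,
        units = if (p == "oxygenation") "percent" else "a.u.",
        n_patients = nrow(wide),
        mean_change = mean(change) * scale,
        sd_change = if (nrow(wide) >= 2L) stats::sd(change) * scale else NA_real_,
        beta1 = if (!is.null(lmm)) lmm$beta1 * scale else NA_real_,
        se = if (!is.null(lmm)) lmm$se * scale else NA_real_,
        p_value = if (!is.null(lmm)) lmm$p_value else NA_real_,
        p_paired_t = tt_p,
        significant = if (!is.null(lmm)) lmm$p_value < alpha else NA,
        converged = if (!is.null(lmm)) lmm$converged else NA)
    }
  }
  report <- do.call(rbind, c(out, make.row.names = FALSE))
  list(report = report, long = table, alpha = alpha)
}
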
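# Steady-state kinase kinetics: calibration, initial velocities,
# Michaelis-Menten, IC50, Cheng-Prusoff K_I and the active-site-corrected
# turnover number.

#' Calibrate fluorescence counts against phosphopeptide concentration
#'
#' Ordinary least-squares line through fluorescence readings of fully
#' phosphorylated peptide standards at known concentrations, giving the
#' counts-per-uM conversion applied to progress curves.
#'
#' @param conc_uM Known phosphopeptide concentrations (uM), at least two
#'   distinct values.
#' @param counts Mean fluorescence intensity counts at each standard.
#' @return Object of class `fluor_calibration`: list with `slope`
#'   (counts/uM), `intercept` (counts), `r2`.
#' @export
calibrate_fluorescence <- function(conc_uM, counts) {
  if (length(conc_uM) != length(counts)) stop("conc_uM and counts lengths differ")
  if (length(unique(conc_uM)) < 2L) {
    stop("calibration requires at least two distinct standard concentrations")
  }
  fit <- stats::lm(counts ~ conc_uM)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) stop("calibration slope is not positive")
  r2 <- if (length(conc_uM) > 2L) suppressWarnings(summary(fit))$r.squared else 1
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2),
            class = "fluor_calibration")
}

#' Convert fluorescence counts to product concentration
#'
#' Exact inverse of the forward calibration line.
#'
#' @param calibration A [calibrate_fluorescence()] model.
#' @param counts Fluorescence counts.
#' @return Product concentration (uM).
#' @export
counts_to_uM <- function(calibration, counts) {
  stopifnot(inherits(calibration, "fluor_calibration"))
  (counts - calibration$intercept) / calibration$slope
}

#' Estimate the initial velocity of a progress curve
#'
#' Fits a straight line over an automatically selected early window of the
#' progress curve. The default policy selects the longest prefix window
#' (minimum `min_points` points) whose linear fit has r-squared at or above
#' `r2_min`, restricted to points where accumulated product does not exceed
#' `max_conversion` of the peptide substrate concentration (so that
#' substrate depletion does not bias the slope). Windows with no detectable
#' trend (flat blank curves) are accepted with velocity ~ 0.
#'
#' @param time_s Time points (seconds, strictly increasing).
#' @param product_uM Product concentration (uM) at each time point.
#' @param peptide_conc_uM Peptide substrate concentration (uM); `Inf`
#'   disables the conversion cap.
#' @param r2_min Minimum r-squared for an acceptable window.
#' @param max_conversion Maximum fraction of substrate converted within the
#'   fitting window.
#' @param min_points Minimum number of points per window.
#' @param window Optional manual override: integer vector of point indices
#'   to fit, bypassing the automatic policy.
#' @return Object of class `rate_estimate`: list with `v0` (uM/s, clamped
#'   at zero), `slope` (raw fitted slope), `window` (start/end times, s),
#'   `n_points`, `r2`.
#' @export
estimate_initial_velocity <- function(time_s, product_uM,
                                      peptide_conc_uM = Inf,
                                      r2_min = 0.99,
                                      max_conversion = 0.10,
                                      min_points = 4L,
                                      window = NULL) {
  if (length(time_s) != length(product_uM)) stop("time and signal lengths differ")
  if (any(diff(time_s) <= 0)) stop("time points must be strictly increasing")
  if (!is.null(window)) {
    idx <- sort(as.integer(window))
    return(.window_fit(time_s, product_uM, idx))
  }
  cap <- which(product_uM > max_conversion * peptide_conc_uM)
  last <- if (length(cap)) max(min_points, min(cap) - 1L) else length(time_s)
  last <- min(last, length(time_s))
  if (last < min_points) {
    stop(sprintf(
      "initial-velocity estimation failed: only %d usable points before %.0f%% conversion (need %d)",
      last, 100 * max_conversion, min_points))
  }
  best <- NULL
  for (n in seq(last, min_points)) {
    est <- .window_fit(time_s, product_uM, seq_len(n))
    if (est$r2 >= r2_min || est$flat) { best <- est; break }
  }
  if (is.null(best)) {
    stop(sprintf(
      paste0("initial-velocity estimation failed: no prefix window of >= %d ",
             "points reaches r2 >= %.3g (best r2 over %d points: %.3f)"),
      min_points, r2_min, min_points,
      .window_fit(time_s, product_uM, seq_len(min_points))$r2))
  }
  best
}

.window_fit <- function(time_s, product_uM, idx) {
  t <- time_s[idx]; y <- product_uM[idx]
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  # flat curve (blank control): slope indistinguishable from zero
  se <- suppressWarnings(summary(fit))$coefficients["t", "Std. Error"]
  flat <- is.finite(se) && se > 0 && abs(slope) < 2 * se
  structure(list(v0 = max(slope, 0),
                 slope = slope,
                 window = c(t_start = t[1], t_end = t[length(t)]),
                 n_points = length(idx),
                 r2 = r2,
                 flat = flat),
            class = "rate_estimate")
}

#' Fit the Michaelis-Menten equation to initial velocities
#'
#' Nonlinear least squares of v = Vmax [S] / (Km + [S]) against initial
#' velocities measured over a substrate (ATP or peptide) concentration
#' series, via Levenberg-Marquardt with positivity bounds. Start values are
#' Km = median([S]) and Vmax = max(v); the apparent turnover number is
#' Vmax / [TKD] after nM -> uM reconciliation.
#'
#' @param s_uM Substrate concentrations (uM).
#' @param v0 Initial velocities (uM/s).
#' @param tkd_conc_nM Enzyme (TKD) concentration (nM) used in the assay.
#' @return Object of class `mm_fit`: list with `km` (uM), `vmax` (uM/s),
#'   `km_se`, `vmax_se`, `apparent_kcat` (s^-1), `fitted`, `residuals`.
#' @export
fit_michaelis_menten <- function(s_uM, v0, tkd_conc_nM) {
  if (length(s_uM) != length(v0)) stop("substrate and velocity lengths differ")
  if (length(unique(s_uM)) < 4L) {
    warning("fewer than 4 distinct substrate levels; Km will be poorly determined")
  }
  df <- data.frame(s = s_uM, v = v0)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = df,
                      start = list(vmax = max(v0), km = stats::median(s_uM)),
                      lower = c(vmax = 1e-12, km = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e)))
  co <- summary(fit)$coefficients
  km <- co["km", "Estimate"]; vmax <- co["vmax", "Estimate"]
  if (km > 10 * max(s_uM) || km < min(s_uM[s_uM > 0]) / 10) {
    warning(sprintf("fitted Km (%.3g uM) lies far outside the substrate range %.3g-%.3g uM",
                    km, min(s_uM), max(s_uM)))
  }
  structure(list(km = km, vmax = vmax,
                 km_se = co["km", "Std. Error"],
                 vmax_se = co["vmax", "Std. Error"],
                 apparent_kcat = vmax / (tkd_conc_nM / 1000),
                 tkd_conc_nM = tkd_conc_nM,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit)),
            class = "mm_fit")
}

#' Fit a one-parameter IC50 dose-response curve
#'
#' Fits the single-site competition model
#' rate = 100 / (1 + \[TKI\]/IC50)
#' to rates normalised to 100% at zero inhibitor (top fixed at 100, bottom
#' at 0, Hill slope 1). When the assay does not cross 50% inhibition the
#' result is returned as a censored bound rather than a point estimate.
#'
#' @param inhibitor_nM Inhibitor concentrations (nM); may include 0.
#' @param rate_pct Rates as percent of the uninhibited rate.
#' @return Object of class `ic50_fit`: list with `ic50` (nM, `NA` when
#'   censored without an estimate), `ic50_se`, `censored`, `bound`
#'   (`">max_dose"` / `"<min_dose"` or `NA`).
#' @export
fit_ic50 <- function(inhibitor_nM, rate_pct) {
  if (length(inhibitor_nM) != length(rate_pct)) stop("dose and rate lengths differ")
  pos <- inhibitor_nM > 0
  if (sum(pos) < 4L) warning("fewer than 4 non-zero inhibitor levels")
  if (all(rate_pct[pos] > 80)) {
    return(structure(list(ic50 = NA_real_, ic50_se = NA_real_, censored = TRUE,
                          bound = sprintf(">%g", max(inhibitor_nM))),
                     class = "ic50_fit"))
  }
  if (all(rate_pct[pos] < 20)) {
    return(structure(list(ic50 = NA_real_, ic50_se = NA_real_, censored = TRUE,
                          bound = sprintf("<%g", min(inhibitor_nM[pos]))),
                     class = "ic50_fit"))
  }
  df <- data.frame(d = inhibitor_nM, r = rate_pct)
  start_ic50 <- stats::approx(rate_pct[pos], inhibitor_nM[pos], xout = 50,
                              ties = mean)$y
  if (!is.finite(start_ic50) || start_ic50 <= 0) {
    start_ic50 <- stats::median(inhibitor_nM[pos])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ 100 / (1 + d / ic50), data = df,
                      start = list(ic50 = start_ic50),
                      lower = c(ic50 = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("IC50 fit failed to converge: ", conditionMessage(e)))
  co <- summary(fit)$coefficients
  # censored when the top tested dose inhibits < 50%
  top_rate <- rate_pct[which.max(inhibitor_nM)]
  structure(list(ic50 = co["ic50", "Estimate"],
                 ic50_se = co["ic50", "Std. Error"],
                 censored = top_rate > 50,
                 bound = if (top_rate > 50) sprintf(">%g", max(inhibitor_nM)) else NA_character_),
            class = "ic50_fit")
}

#' Estimate the inhibition constant from an IC50 vs ATP series
#'
#' For a reversible ATP-competitive inhibitor, the measured IC50 rises
#' linearly with ATP concentration:
#' IC50 = K_I (1 + \[ATP\]/K_M,ATP).
#' With `km_atp` supplied, K_I is the single free parameter (least squares
#' on the known regressor); otherwise an ordinary linear regression of IC50
#' on \[ATP\] gives K_I as the intercept and K_I/K_M,ATP as the slope.
#' A series whose IC50 does not depend on \[ATP\] (slope indistinguishable
#' from zero, or negative) is flagged `noncompetitive`: either
#' non-competitive inhibition or inhibitor depletion by inactive protein,
#' and no K_M can be inferred from it.
#'
#' @param atp_uM ATP concentrations (uM), at least 3 levels.
#' @param ic50_nM Measured IC50 (nM) at each ATP concentration.
#' @param km_atp Known Michaelis constant for ATP (uM), or `NULL` for the
#'   joint two-parameter fit.
#' @return Object of class `ki_fit`: list with `ki` (nM), `ki_se`,
#'   `km_atp` (uM; supplied or inferred, `NA` when flagged), `method`,
#'   `noncompetitive` flag.
#' @export
fit_ki_cheng_prusoff <- function(atp_uM, ic50_nM, km_atp = NULL) {
  if (length(atp_uM) != length(ic50_nM)) stop("ATP and IC50 lengths differ")
  if (length(unique(atp_uM)) < 3L) stop("need at least 3 distinct ATP levels")
  if (!is.null(km_atp)) {
    x <- 1 + atp_uM / km_atp
    ki <- sum(ic50_nM * x) / sum(x^2)
    resid <- ic50_nM - ki * x
    ki_se <- sqrt(sum(resid^2) / (length(x) - 1) / sum(x^2))
    if (ki <= 0) stop("fitted K_I is not positive")
    return(structure(list(ki = ki, ki_se = ki_se, km_atp = km_atp,
                          method = "one-parameter", noncompetitive = FALSE),
                     class = "ki_fit"))
  }
  fit <- stats::lm(ic50_nM ~ atp_uM)
  co <- suppressWarnings(summary(fit))$coefficients
  intercept <- co[1, "Estimate"]; slope <- co[2, "Estimate"]
  slope_p <- co[2, "Pr(>|t|)"]
  if (intercept <= 0) {
    stop("fitted intercept (K_I) is not positive; series inconsistent with competitive inhibition")
  }
  noncomp <- slope <= 0 || (is.finite(slope_p) && slope_p > 0.05)
  structure(list(ki = intercept,
                 ki_se = co[1, "Std. Error"],
                 km_atp = if (noncomp) NA_real_ else intercept / slope,
                 method = "joint-linear",
                 noncompetitive = noncomp),
            class = "ki_fit")
}

#' Predict an IC50 from the Cheng-Prusoff relation
#'
#' Forward evaluation of IC50 = K_I (1 + \[ATP\]/K_M,ATP) for a reversible
#' ATP-competitive inhibitor.
#'
#' @param ki_nM Inhibition constant (nM).
#' @param km_atp_uM Michaelis constant for ATP (uM).
#' @param atp_uM ATP concentration (uM).
#' @return Predicted IC50 (nM).
#' @examples
#' predict_ic50(5.3, 23, 1000) # ~235.8 nM
#' @export
predict_ic50 <- function(ki_nM, km_atp_uM, atp_uM) {
  if (any(c(ki_nM, km_atp_uM) <= 0) || any(atp_uM < 0)) {
    stop("ki_nM and km_atp_uM must be positive, atp_uM non-negative")
  }
  ki_nM * (1 + atp_uM / km_atp_uM)
}

#' Correct the apparent turnover number for the active enzyme fraction
#'
#' Covalent-inhibitor endpoint titration: afatinib is potent enough that its
#' IC50 often falls below half the nominal TKD concentration, in which case
#' the IC50 reflects titration of the active enzyme rather than binding
#' affinity. Assuming the afatinib IC50 equals 50% of the active TKD
#' concentration, active \[TKD\] = 2 x IC50, and
#' corrected k_cat = apparent k_cat x \[TKD\] / (2 x IC50,afatinib).
#'
#' @param apparent_kcat Apparent turnover number (s^-1), computed per total
#'   enzyme.
#' @param tkd_conc_nM Nominal TKD concentration (nM) in the afatinib IC50
#'   assay.
#' @param afatinib_ic50_nM Afatinib IC50 (nM) at the same TKD concentration
#'   (assay scale, i.e. before any presentation rescaling).
#' @return Object of class `active_site_correction`: list with
#'   `active_conc_nM`, `active_fraction`, `corrected_kcat` and the inputs.
#'   An active fraction above 1 triggers a warning but the correction is
#'   still reported.
#' @examples
#' correct_kcat(0.91, 100, 36)$corrected_kcat # ~1.26
#' @export
correct_kcat <- function(apparent_kcat, tkd_conc_nM, afatinib_ic50_nM) {
  if (any(c(apparent_kcat, tkd_conc_nM, afatinib_ic50_nM) <= 0)) {
    stop("all inputs must be positive")
  }
  active <- 2 * afatinib_ic50_nM
  frac <- active / tkd_conc_nM
  if (frac > 1) {
    warning(sprintf(
      "active fraction %.2f exceeds 1 (afatinib IC50 above [TKD]/2); correction still reported",
      frac))
  }
  structure(list(apparent_kcat = apparent_kcat,
                 tkd_conc_nM = tkd_conc_nM,
                 afatinib_ic50_nM = afatinib_ic50_nM,
                 active_conc_nM = active,
                 active_fraction = frac,
                 corrected_kcat = apparent_kcat / frac),
            class = "active_site_correction")
}

#' Fold-change table with unpaired t-tests from summary statistics
#'
#' Computes per-variant fold changes of a measured quantity (e.g. IC50 for a
#' given inhibitor, or K_M,ATP) relative to a reference variant, with the SD
#' of the ratio by first-order (delta-method) error propagation and a
#' two-sided unpaired Welch t-test from the summary means, SDs and ns.
#'
#' @param table Data frame with columns `variant`, `mean`, `sd`, `n`.
#' @param reference_variant Name of the reference variant (fold = 1).
#' @return Data frame with columns `variant`, `mean`, `sd`, `n`, `fold`,
#'   `fold_sd`, `t`, `df`, `p`. Rows with `n < 2` or missing SD get `NA`
#'   tests.
#' @export
fold_change_table <- function(table, reference_variant) {
  stopifnot(all(c("variant", "mean", "sd", "n") %in% names(table)))
  ref <- table[table$variant == reference_variant, , drop = FALSE]
  if (nrow(ref) != 1L) stop("reference variant not found (or not unique) in table")
  m0 <- ref$mean; s0 <- ref$sd; n0 <- ref$n
  if (!is.finite(m0) || m0 == 0) stop("reference mean is zero or missing; fold undefined")
  out <- table
  out$fold <- table$mean / m0
  out$fold_sd <- out$fold * sqrt((table$sd / table$mean)^2 + (s0 / m0)^2)
  tt <- mapply(function(m1, s1, n1) {
    if (!is.finite(s1) || !is.finite(s0) || n1 < 2 || n0 < 2) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    se2 <- s1^2 / n1 + s0^2 / n0
    if (se2 == 0) return(c(0, n1 + n0 - 2, 1))
    t <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s0^2 / n0)^2 / (n0 - 1))
    c(t, df, 2 * stats::pt(-abs(t), df))
  }, table$mean, table$sd, table$n)
  out$t <- tt[1, ]; out$df <- tt[2, ]; out$p <- tt[3, ]
  out
}
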
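## Radiotracer influx rates, saturation fits and fluorescence AUC.
##
## Influx rate (per well):
##   rate = counts (cpm) x [substrate] (pM) / (total counts (cpm/L) x time (min))
## which is pmol well^-1 min^-1 when total counts are per litre of medium.
## Saturation models:
##   Michaelis-Menten  v = vmax S / (Km + S)
##   Hill-with-leak    I = iU + Imax S^nH / (K0.5^nH + S^nH)
## Inward currents are negative by convention; Imax is fitted with free sign.

#' Radiotracer influx rate
#'
#' @param counts_cpm counts per well (cpm), >= 0.
#' @param conc_pM substrate concentration (pM).
#' @param total_cpm_per_L initial total counts (cpm/L), > 0.
#' @param time_min uptake time (min), > 0.
#' @return influx rate(s), pmol well^-1 min^-1.
#' @export
influx_rate <- function(counts_cpm, conc_pM, total_cpm_per_L, time_min) {
  if (any(time_min <= 0)) stop("uptake time must be positive")
  if (any(total_cpm_per_L <= 0)) stop("initial total counts must be positive")
  if (any(counts_cpm < 0)) stop("counts must be non-negative")
  counts_cpm * conc_pM / (total_cpm_per_L * time_min)
}

#' Background-subtract and expression-normalize uptake rates
#'
#' corrected = (rate - mean background) / expression factor, per condition.
#' Negative corrected rates are retained (not truncated) and flagged, so
#' downstream averaging stays unbiased.
#'
#' @param rates data.frame with columns `condition`, `rate` (or a bare
#'   numeric vector for a single unnamed condition).
#' @param background data.frame with columns `condition`, `rate` holding
#'   background (e.g. empty-vector) wells; or a numeric vector.
#' @param expression_factors named numeric (> 0) per condition, or a single
#'   number; default 1.
#' @return data.frame condition, rate, corrected, flagged_negative.
#' @export
subtract_background_and_normalize <- function(rates, background,
                                              expression_factors = 1) {
  if (!is.data.frame(rates)) {
    rates <- data.frame(condition = "all", rate = as.numeric(rates))
  }
  if (!is.data.frame(background)) {
    background <- data.frame(condition = "all",
                             rate = as.numeric(background))
  }
  conds <- unique(rates$condition)
  missing_bg <- setdiff(conds, unique(background$condition))
  if (length(missing_bg) > 0L) {
    stop("no background wells for condition(s): ",
         paste(missing_bg, collapse = ", "))
  }
  fac <- if (length(expression_factors) == 1L && is.null(names(expression_factors))) {
    stats::setNames(rep(expression_factors, length(conds)), conds)
  } else expression_factors
  missing_fac <- setdiff(conds, names(fac))
  if (length(missing_fac) > 0L) {
    stop("no expression factor for condition(s): ",
         paste(missing_fac, collapse = ", "))
  }
  if (any(fac <= 0)) stop("expression factors must be positive")
  bg_mean <- tapply(background$rate, background$condition, mean)
  corrected <- (rates$rate - bg_mean[rates$condition]) /
    fac[rates$condition]
  data.frame(condition = rates$condition, rate = rates$rate,
             corrected = as.numeric(corrected),
             flagged_negative = as.numeric(corrected) < 0)
}

## ---- saturation fits ---------------------------------------------------

.saturation_fit <- function(model, parameters, se, residuals, converged,
                            data, diagnostics = NULL) {
  structure(list(model = model, parameters = parameters, se = se,
                 residuals = residuals,
                 rss = sum(residuals^2),
                 converged = converged, data = data,
                 diagnostics = diagnostics),
            class = "SaturationFit")
}

#' @export
print.SaturationFit <- function(x, ...) {
  cat("SaturationFit <", x$model, ">",
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  print(round(rbind(estimate = x$parameters, se = x$se), 6))
  invisible(x)
}

## Half-max crossing by linear interpolation; fallback to median S.
.half_max_S <- function(S, v, v0 = 0, vmax = max(v)) {
  o <- order(S)
  S <- S[o]; v <- v[o]
  target <- v0 + (vmax - v0) / 2
  dif <- v - target
  sgn <- if (vmax >= v0) 1 else -1
  cross <- which(sgn * dif[-1] >= 0 & sgn * dif[-length(dif)] < 0)
  if (length(cross) == 0L) return(stats::median(S))
  i <- cross[1]
  S[i] + (target - v[i]) * (S[i + 1] - S[i]) / (v[i + 1] - v[i])
}

#' Fit the Michaelis-Menten saturation model
#'
#' Trust-region least squares (`minpack.lm::nlsLM`) with data-driven
#' starts: vmax from the high-concentration plateau, Km from the half-max
#' crossing. Non-convergence is flagged, never silently clamped.
#'
#' @param S substrate concentrations (same unit as the reported Km,
#'   typically uM); at least 4 distinct values.
#' @param v rates at `S`.
#' @param weights optional per-point weights (default unweighted).
#' @return a `SaturationFit` with parameters `Km`, `vmax`.
#' @export
fit_mm <- function(S, v, weights = NULL) {
  stopifnot(length(S) == length(v))
  if (length(unique(S)) < 4L) stop("need >= 4 distinct concentrations")
  o <- order(S)
  vmax0 <- mean(v[o][S[o] >= sort(unique(S), decreasing = TRUE)[2]])
  Km0 <- max(.half_max_S(S, v, 0, vmax0), min(S[S > 0]) / 10)
  df <- data.frame(S = S, v = v)
  if (is.null(weights)) weights <- rep(1, length(S))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * S / (Km + S), data = df,
                      start = list(vmax = vmax0, Km = Km0),
                      weights = weights,
                      lower = c(-Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-12,
                                                           ptol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(.saturation_fit("MM", c(Km = NA_real_, vmax = NA_real_),
                           c(Km = NA_real_, vmax = NA_real_),
                           rep(NA_real_, length(S)), FALSE, df,
                           conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 2),
                                                     names(cf)))
  .saturation_fit("MM",
                  c(Km = unname(cf["Km"]), vmax = unname(cf["vmax"])),
                  c(Km = unname(se["Km"]), vmax = unname(se["vmax"])),
                  stats::resid(fit), TRUE, df)
}

#' Fit the 4-parameter Hill-with-leak model
#'
#' I = iU + Imax S^nH / (K0.5^nH + S^nH), fitted by trust-region least
#' squares with data-driven starts (iU from the lowest-S current, Imax
#' from the plateau, K0.5 from the half-max crossing, nH = 1). With
#' `fix_nH = 1` and `fix_iU = 0` the model reduces to Michaelis-Menten.
#'
#' For proton activation pass `S = ph_to_uM(pH)`.
#'
#' @param S substrate concentrations (uM); >= 5 distinct values for the
#'   free 4-parameter fit.
#' @param I substrate-induced currents (nA; inward negative).
#' @param fix_nH,fix_iU optionally fix the Hill coefficient and/or leak
#'   offset (NULL = free).
#' @param weights optional per-point weights.
#' @return a `SaturationFit` with parameters `iU`, `Imax`, `K05`, `nH`.
#' @export
fit_hill_leak <- function(S, I, fix_nH = NULL, fix_iU = NULL,
                          weights = NULL) {
  stopifnot(length(S) == length(I))
  free_n <- 4L - (!is.null(fix_nH)) - (!is.null(fix_iU))
  if (length(unique(S)) < free_n + 1L) {
    stop("need more distinct concentrations than free parameters")
  }
  o <- order(S)
  iU0 <- if (is.null(fix_iU)) I[o][1] else fix_iU
  Imax0 <- mean(I[o][S[o] >= sort(unique(S), decreasing = TRUE)[2]]) - iU0
  if (Imax0 == 0) Imax0 <- max(abs(I - iU0)) * sign(sum(I - iU0) + 1e-30)
  K0 <- max(.half_max_S(S, I, iU0, iU0 + Imax0), min(S[S > 0]) / 10)
  df <- data.frame(S = S, I = I)
  if (is.null(weights)) weights <- rep(1, length(S))
  start <- list(Imax = Imax0, K05 = K0)
  lower <- c(Imax = -Inf, K05 = 1e-12)
  upper <- c(Imax = Inf, K05 = Inf)
  form <- "I ~ iU + Imax * S^nH / (K05^nH + S^nH)"
  if (is.null(fix_iU)) {
    start$iU <- iU0; lower <- c(lower, iU = -Inf); upper <- c(upper, iU = Inf)
  } else form <- sub("iU", fix_iU, form, fixed = TRUE)
  if (is.null(fix_nH)) {
    start$nH <- 1; lower <- c(lower, nH = 0.05); upper <- c(upper, nH = 20)
  } else form <- gsub("nH", fix_nH, form, fixed = TRUE)
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(form), data = df, start = start,
                      weights = weights,
                      lower = unname(lower[names(start)]),
                      upper = unname(upper[names(start)]),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-12,
                                                           ptol = 1e-12)),
    error = function(e) e)
  par_names <- c("iU", "Imax", "K05", "nH")
  if (inherits(fit, "error")) {
    p <- stats::setNames(rep(NA_real_, 4), par_names)
    return(.saturation_fit("Hill-leak", p, p, rep(NA_real_, length(S)),
                           FALSE, df, conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  full <- c(iU = if (is.null(fix_iU)) unname(cf["iU"]) else fix_iU,
            Imax = unname(cf["Imax"]), K05 = unname(cf["K05"]),
            nH = if (is.null(fix_nH)) unname(cf["nH"]) else fix_nH)
  se_fit <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) stats::setNames(
                       rep(NA_real_, length(cf)), names(cf)))
  se <- stats::setNames(rep(NA_real_, 4), par_names)
  se[names(se_fit)[names(se_fit) %in% par_names]] <-
    se_fit[names(se_fit) %in% par_names]
  if (is.null(fix_nH) && (full["nH"] < 0.3 || full["nH"] > 4)) {
    warning("fitted Hill coefficient ", round(full["nH"], 3),
            " outside the plausible bracket (0.3, 4)")
  }
  .saturation_fit("Hill-leak", full, se, stats::resid(fit), TRUE, df)
}

#' Proton concentration (uM) from pH
#'
#' \[H+\] = 10^(6 - pH) uM.
#'
#' @param pH numeric pH values.
#' @return concentrations in uM.
#' @export
ph_to_uM <- function(pH) 10^(6 - pH)

#' Predict from a saturation fit
#'
#' @param object a `SaturationFit`.
#' @param S concentrations to predict at.
#' @param ... unused.
#' @return predicted rates/currents.
#' @export
predict.SaturationFit <- function(object, S, ...) {
  p <- object$parameters
  if (object$model == "MM") {
    p[["vmax"]] * S / (p[["Km"]] + S)
  } else {
    p[["iU"]] + p[["Imax"]] * S^p[["nH"]] / (p[["K05"]]^p[["nH"]] +
                                               S^p[["nH"]])
  }
}

#' Area under a baseline-corrected fluorescence trace
#'
#' Trapezoidal integral of (F - mean baseline F) over the response window.
#'
#' @param time time points (s), increasing.
#' @param F fluorescence samples.
#' @param baseline_window c(t0, t1): window (inclusive) defining baseline,
#'   must precede the response window.
#' @param response_window c(t0, t1); default from end of baseline to the
#'   last sample.
#' @return area (fluorescence x s).
#' @export
fluorescence_auc <- function(time, F, baseline_window,
                             response_window = NULL) {
  stopifnot(length(time) == length(F))
  bl <- time >= baseline_window[1] & time <= baseline_window[2]
  if (!any(bl)) stop("baseline window contains no samples")
  if (is.null(response_window)) {
    response_window <- c(baseline_window[2], max(time))
  }
  if (response_window[1] < baseline_window[2]) {
    stop("baseline window must precede the response window")
  }
  rw <- time >= response_window[1] & time <= response_window[2]
  if (sum(rw) < 2L) stop("response window contains fewer than 2 samples")
  pracma::trapz(time[rw], F[rw] - mean(F[bl]))
}

#' Write a saturation-fit report
#'
#' JSON parameters + convergence flag, and a TSV of per-point residuals.
#'
#' @param fit a `SaturationFit`.
#' @param prefix output path prefix (writes `<prefix>.json`,
#'   `<prefix>_residuals.tsv`).
#' @return written paths, invisibly.
#' @export
write_fit_report <- function(fit, prefix) {
  j <- paste0(prefix, ".json")
  jsonlite::write_json(list(model = fit$model,
                            parameters = as.list(fit$parameters),
                            se = as.list(fit$se),
                            rss = fit$rss,
                            converged = fit$converged,
                            diagnostics = fit$diagnostics),
                       j, auto_unbox = TRUE, digits = NA, null = "null")
  t <- paste0(prefix, "_residuals.tsv")
  utils::write.table(cbind(fit$data, residual = fit$residuals), t,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(j, t))
}
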
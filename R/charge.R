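## Pre-steady-state charge-movement analysis for two-electrode voltage
## clamp records.
##
## Per voltage step the current is decomposed as
##   I(t) = A_c exp(-t/tau_c) + A_p exp(-t/tau_p) + I_ss,   tau_c < tau_p,
## where the faster component is deemed the membrane-capacitive transient
## and the slower one the transporter charge relaxation. The transporter
## charge is Q = A_p tau_p, and Q(V) follows the Boltzmann relation
##   (Q - Qhyp)/Qmax = 1 / (1 + exp[z (Vm - V0.5) F / RT]),
## with Qmax = Qdep - Qhyp. Derived quantities: N_T = Qmax/(|z| e),
## turnover = -Imax/Qmax.

FARADAY <- 96485.33212   # C/mol
GAS_R <- 8.31446262      # J/(mol K)
ELEM_CHARGE <- 1.6e-19   # C

#' Construct a VoltageStepTrace
#'
#' @param time_ms uniformly sampled time points (ms).
#' @param current_nA current samples (nA; inward negative).
#' @param Vh,Vt holding and test potential (mV).
#' @param onset_ms,offset_ms step onset/offset times (ms).
#' @param meta list of metadata: `pH`, `substrate_uM`, `T_K`,
#'   `sampling_Hz`, `filter_Hz`, ...
#' @return object of class `VoltageStepTrace`.
#' @export
voltage_step_trace <- function(time_ms, current_nA, Vh, Vt, onset_ms,
                               offset_ms, meta = list()) {
  stopifnot(length(time_ms) == length(current_nA))
  dt <- diff(time_ms)
  if (length(dt) > 0L && diff(range(dt)) > 1e-6 * stats::median(dt)) {
    stop("trace is not uniformly sampled")
  }
  if (onset_ms >= offset_ms) stop("step onset must precede offset")
  if (!is.null(meta$sampling_Hz) && !is.null(meta$filter_Hz) &&
      meta$sampling_Hz < 2 * meta$filter_Hz) {
    stop("sampling rate below twice the filter cutoff")
  }
  structure(list(time_ms = time_ms, current_nA = current_nA, Vh = Vh,
                 Vt = Vt, onset_ms = onset_ms, offset_ms = offset_ms,
                 meta = meta),
            class = "VoltageStepTrace")
}

#' @export
print.VoltageStepTrace <- function(x, ...) {
  cat("VoltageStepTrace: Vh", x$Vh, "mV -> Vt", x$Vt, "mV,",
      length(x$time_ms), "samples, step", x$onset_ms, "-", x$offset_ms,
      "ms\n")
  invisible(x)
}

#' Steady-state current of a voltage step
#'
#' Mean current over a window (default 10 ms) centered at the midpoint of
#' the step.
#'
#' @param trace a `VoltageStepTrace`.
#' @param window_ms averaging window width, default 10.
#' @return mean current (nA).
#' @export
steady_state_current <- function(trace, window_ms = 10) {
  stopifnot(inherits(trace, "VoltageStepTrace"))
  dur <- trace$offset_ms - trace$onset_ms
  if (dur < 3 * window_ms) {
    stop("step duration (", dur, " ms) shorter than 3x the averaging window")
  }
  mid <- (trace$onset_ms + trace$offset_ms) / 2
  sel <- trace$time_ms >= mid - window_ms / 2 &
    trace$time_ms <= mid + window_ms / 2
  if (!any(sel)) stop("averaging window contains no samples")
  mean(trace$current_nA[sel])
}

#' Substrate-induced current per test potential
#'
#' Difference of steady-state currents with and without substrate on
#' matched test-potential grids.
#'
#' @param with_substrate,without_substrate data.frames with columns `Vt`
#'   and `I` (steady-state current, nA), or lists of `VoltageStepTrace`
#'   (steady-state currents are computed first).
#' @return data.frame Vt, I_with, I_without, dI.
#' @export
substrate_induced_current <- function(with_substrate, without_substrate) {
  as_iv <- function(x) {
    if (is.data.frame(x)) return(x)
    data.frame(Vt = vapply(x, `[[`, 0, "Vt"),
               I = vapply(x, steady_state_current, 0))
  }
  a <- as_iv(with_substrate); b <- as_iv(without_substrate)
  miss <- c(setdiff(a$Vt, b$Vt), setdiff(b$Vt, a$Vt))
  if (length(miss) > 0L) {
    stop("unmatched test potentials: ", paste(sort(miss), collapse = ", "),
         " mV")
  }
  b <- b[match(a$Vt, b$Vt), ]
  data.frame(Vt = a$Vt, I_with = a$I, I_without = b$I, dI = a$I - b$I)
}

## Single- or double-exponential-plus-constant fit on one segment.
## t is relative to the step edge (t = 0 at onset); samples before
## `exclude` are dropped but amplitudes refer to t = 0. Starting values
## come from classic exponential peeling: the slow component is estimated
## from a log-linear fit over the late decay, the fast one from the early
## residual after subtracting it.
.nls_ctl <- function() minpack.lm::nls.lm.control(maxiter = 500,
                                                  ftol = 1e-13,
                                                  ptol = 1e-13)

## Robust A exp(-t/tau) + c fit: baseline from the tail, tau from the
## time at which the running-median-smoothed deviation falls to 1/e.
.fit_1exp <- function(ts, Is) {
  n_tail <- max(3L, round(length(Is) * 0.1))
  Iss0 <- mean(Is[seq.int(length(Is) - n_tail + 1L, length(Is))])
  y <- Is - Iss0
  A0 <- y[1]
  ysm <- if (length(y) >= 9L) stats::runmed(abs(y), 5L) else abs(y)
  i_e <- which(ysm <= abs(A0) / exp(1))[1]
  tau0 <- if (!is.na(i_e) && i_e > 1L) max(ts[i_e] - ts[1],
                                           (ts[2] - ts[1]) / 2) else
    (max(ts) - min(ts)) / 5
  df <- data.frame(t = ts, I = Is)
  tryCatch(
    minpack.lm::nlsLM(I ~ A * exp(-t / tau) + c, data = df,
                      start = list(A = A0 * exp(ts[1] / tau0), tau = tau0,
                                   c = Iss0),
                      lower = c(-Inf, 1e-6, -Inf), control = .nls_ctl()),
    error = function(e) NULL)
}

## Two-exponential-plus-constant fit, staged: the dominant component is
## fitted first, a second exponential is fitted to its residual to seed
## the remaining parameters, then all five are refined jointly.
.fit_2exp <- function(ts, Is) {
  f1 <- .fit_1exp(ts, Is)
  if (is.null(f1)) return(NULL)
  c1 <- stats::coef(f1)
  r <- Is - stats::fitted(f1)
  f2 <- .fit_1exp(ts, r)
  if (!is.null(f2)) {
    c2 <- stats::coef(f2)
    start <- list(A1 = c1[["A"]], tau1 = c1[["tau"]], A2 = c2[["A"]],
                  tau2 = max(c2[["tau"]], c1[["tau"]] * 1e-3),
                  Iss = c1[["c"]] + c2[["c"]])
  } else {
    start <- list(A1 = c1[["A"]], tau1 = c1[["tau"]], A2 = c1[["A"]] / 10,
                  tau2 = c1[["tau"]] * 5, Iss = c1[["c"]])
  }
  df <- data.frame(t = ts, I = Is)
  tryCatch(
    minpack.lm::nlsLM(I ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2) + Iss,
                      data = df, start = start,
                      lower = c(-Inf, 1e-6, -Inf, 1e-6, -Inf),
                      control = .nls_ctl()),
    error = function(e) NULL)
}

.exp_fit <- function(t, I, exclude, n_exp = 2L) {
  keep <- t >= exclude
  ts <- t[keep]; Is <- I[keep]
  if (n_exp == 1L) .fit_1exp(ts, Is) else .fit_2exp(ts, Is)
}

#' Isolate the transporter charge relaxation from a voltage step
#'
#' After discarding `exclude` ms following the step edge, fits
#' I(t) = A_c exp(-t/tau_c) + A_p exp(-t/tau_p) + I_ss with tau_c <
#' tau_p; the faster component is deemed capacitive and the slower one is
#' returned as the transporter relaxation. If the two time constants are
#' separated by less than 3x (or a single exponential describes the data
#' as well), the record is flagged accordingly.
#'
#' @param trace a `VoltageStepTrace`.
#' @param exclude dead time after the step edge to discard (ms),
#'   default 0.4.
#' @param edge which step edge to analyse: "on" (onset) or "off" (offset).
#' @param tau_c_split when only a single exponential is supported by the
#'   data, a component with tau <= `tau_c_split` (ms) is classified as
#'   capacitive (transporter charge 0), otherwise as the transporter
#'   relaxation. Default 2 ms.
#' @return object of class `TransientFit`: `A_c`, `tau_c`, `A_p`, `tau_p`
#'   (amplitudes in nA at the step edge, taus in ms), `I_ss`, `converged`,
#'   `resolvable`, `Vt`, plus the analysed segment (`t`, relative ms, and
#'   `transport_component`, nA) for numerical cross-checks.
#' @export
isolate_transient <- function(trace, exclude = 0.4, edge = c("on", "off"),
                              tau_c_split = 2) {
  stopifnot(inherits(trace, "VoltageStepTrace"))
  edge <- match.arg(edge)
  if (exclude < 0) stop("exclude must be non-negative")
  t0 <- if (edge == "on") trace$onset_ms else trace$offset_ms
  tend <- if (edge == "on") trace$offset_ms else max(trace$time_ms)
  sel <- trace$time_ms >= t0 & trace$time_ms < tend
  t <- trace$time_ms[sel] - t0
  I <- trace$current_nA[sel]
  if (sum(t >= exclude) < 8L) stop("too few samples after the dead time")

  ## zero-amplitude step (e.g. Vt = Vh): nothing relaxes, charge is zero
  Is <- I[t >= exclude]
  iss_rough <- mean(Is[seq.int(max(1L, length(Is) - 9L), length(Is))])
  if (max(abs(Is - iss_rough)) <= 1e-10 * (1 + abs(iss_rough))) {
    return(structure(list(A_c = 0, tau_c = NA_real_, A_p = 0, tau_p = 1,
                          I_ss = iss_rough, converged = TRUE,
                          resolvable = TRUE, flag = NA_character_,
                          Vt = trace$Vt, edge = edge, t = t,
                          transport_component = I - iss_rough),
                     class = "TransientFit"))
  }

  fit2 <- .exp_fit(t, I, exclude, n_exp = 2L)
  fit1 <- .exp_fit(t, I, exclude, n_exp = 1L)
  use2 <- !is.null(fit2)
  if (use2 && !is.null(fit1)) {
    ## prefer the single-exponential description unless the second
    ## component buys a clearly better fit
    rss2 <- sum(stats::resid(fit2)^2)
    rss1 <- sum(stats::resid(fit1)^2)
    if (rss1 <= rss2 * 1.01) use2 <- FALSE
  }
  if (!use2 && is.null(fit1)) {
    return(structure(list(A_c = NA_real_, tau_c = NA_real_, A_p = NA_real_,
                          tau_p = NA_real_, I_ss = NA_real_,
                          converged = FALSE, resolvable = FALSE,
                          flag = "fit did not converge",
                          Vt = trace$Vt, edge = edge, t = t,
                          transport_component = rep(NA_real_, length(t))),
                     class = "TransientFit"))
  }
  if (use2) {
    cf <- stats::coef(fit2)
    ## order components: faster = capacitive
    if (cf["tau1"] <= cf["tau2"]) {
      A_c <- cf[["A1"]]; tau_c <- cf[["tau1"]]
      A_p <- cf[["A2"]]; tau_p <- cf[["tau2"]]
    } else {
      A_c <- cf[["A2"]]; tau_c <- cf[["tau2"]]
      A_p <- cf[["A1"]]; tau_p <- cf[["tau1"]]
    }
    I_ss <- cf[["Iss"]]
    resolvable <- tau_p / tau_c >= 3
    flag <- if (!resolvable) "components unresolvable (tau ratio < 3)" else
      NA_character_
  } else {
    ## single resolvable component: classify by its time constant
    cf <- stats::coef(fit1)
    I_ss <- cf[["c"]]
    if (cf[["tau"]] <= tau_c_split) {
      A_c <- cf[["A"]]; tau_c <- cf[["tau"]]
      A_p <- 0; tau_p <- 1
    } else {
      A_c <- 0; tau_c <- NA_real_
      A_p <- cf[["A"]]; tau_p <- cf[["tau"]]
    }
    resolvable <- TRUE
    flag <- NA_character_
  }
  ## a "relaxation" slower than the analysed window is indistinguishable
  ## from baseline and carries no integrable transporter charge
  if (is.finite(tau_p) && tau_p > 1.5 * (max(t) - exclude)) {
    A_p <- 0; tau_p <- 1
  }
  cap <- if (is.na(tau_c)) rep(0, length(t)) else A_c * exp(-t / tau_c)
  structure(list(A_c = A_c, tau_c = tau_c, A_p = A_p, tau_p = tau_p,
                 I_ss = I_ss, converged = TRUE, resolvable = resolvable,
                 flag = flag, Vt = trace$Vt, edge = edge, t = t,
                 transport_component = I - cap - I_ss),
            class = "TransientFit")
}

#' @export
print.TransientFit <- function(x, ...) {
  cat("TransientFit (", x$edge, "-step, Vt ", x$Vt, " mV): ", sep = "")
  if (!x$converged) cat("NOT CONVERGED\n") else {
    cat(sprintf("A_p %.3g nA, tau_p %.3g ms, A_c %.3g nA, I_ss %.3g nA%s\n",
                x$A_p, x$tau_p, x$A_c, x$I_ss,
                if (!x$resolvable) "  [UNRESOLVABLE]" else ""))
  }
  invisible(x)
}

#' Integrate the transporter charge of a relaxation component
#'
#' Closed form Q = A_p tau_p of the fitted exponential (nA ms -> nC via
#' /1000), with an optional trapezoidal cross-check on the isolated
#' component samples.
#'
#' @param fit a `TransientFit`.
#' @param cross_check also return the numerical integral (default TRUE).
#' @return charge Q (nC); attribute `numeric_nC` carries the trapezoidal
#'   value when requested. NA with a warning when the component was
#'   flagged unresolvable or the fit failed.
#' @export
integrate_charge <- function(fit, cross_check = TRUE) {
  stopifnot(inherits(fit, "TransientFit"))
  if (!fit$converged || !fit$resolvable) {
    warning("charge undefined: ", fit$flag)
    return(NA_real_)
  }
  q <- fit$A_p * fit$tau_p / 1000
  if (cross_check) {
    num <- pracma::trapz(fit$t, fit$transport_component) / 1000
    ## tail beyond the record, from the fitted exponential
    tail_q <- fit$A_p * fit$tau_p *
      exp(-max(fit$t) / fit$tau_p) / 1000
    head_q <- fit$A_p * fit$tau_p * (1 - exp(-min(fit$t) / fit$tau_p)) / 1000
    attr(q, "numeric_nC") <- num + tail_q + head_q
  }
  q
}

#' Fit the Boltzmann Q-V relation
#'
#' Q(V) = Qhyp + Qmax / (1 + exp\[z (V - V0.5) F / RT\]); Qmax = Qdep -
#' Qhyp is enforced by the parameterization. Starts are data-driven (limb
#' means, interpolated midpoint, slope-based valence).
#'
#' @param Vt test potentials (mV), >= 6 spanning the inflection.
#' @param Q integrated charges (nC) at `Vt`.
#' @param T_K absolute temperature (K), default 295.15.
#' @return object of class `ChargeMovement`: the data plus fitted `Qmax`,
#'   `Qhyp`, `Qdep`, `V05`, `z`, `r2`, `se`, `converged`, and a
#'   `saturation_warning` when neither limb approaches saturation.
#' @export
fit_boltzmann <- function(Vt, Q, T_K = 295.15) {
  stopifnot(length(Vt) == length(Q))
  if (length(unique(Vt)) < 6L) stop("need >= 6 test potentials")
  if (T_K <= 0) stop("temperature must be positive")
  kT <- FARADAY / (GAS_R * T_K * 1000)  # per mV
  o <- order(Vt)
  Vs <- Vt[o]; Qs <- Q[o]
  n <- length(Vs)
  lo <- mean(Qs[1:2]); hi <- mean(Qs[(n - 1):n])
  ## If Q rises with V the depolarizing limb is the high-V limb (z < 0).
  Qh0 <- if (hi >= lo) lo else hi
  Qd0 <- if (hi >= lo) hi else lo
  Qmax0 <- Qd0 - Qh0
  if (Qmax0 == 0) Qmax0 <- diff(range(Qs)) + 1e-12
  V0 <- .half_max_S(Vs - min(Vs), Qs, Qh0, Qd0) + min(Vs)
  slope <- tryCatch(stats::coef(stats::lm(Qs ~ Vs))[["Vs"]],
                    error = function(e) 0)
  z0 <- -4 * slope / (Qmax0 * kT)
  if (!is.finite(z0) || z0 == 0) z0 <- if (hi >= lo) -1 else 1
  df <- data.frame(V = Vt, Q = Q)
  fit <- tryCatch(
    minpack.lm::nlsLM(Q ~ Qhyp + Qmax / (1 + exp(z * (V - V05) * kT)),
                      data = df,
                      start = list(Qhyp = Qh0, Qmax = Qmax0, V05 = V0,
                                   z = z0),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-13,
                                                           ptol = 1e-13)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(Vt = Vt, Q = Q, Qmax = NA_real_, Qhyp = NA_real_,
                          Qdep = NA_real_, V05 = NA_real_, z = NA_real_,
                          T_K = T_K, r2 = NA_real_,
                          se = NULL, converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "ChargeMovement"))
  }
  cf <- stats::coef(fit)
  pred <- stats::fitted(fit)
  r2 <- 1 - sum((Q - pred)^2) / sum((Q - mean(Q))^2)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  ## saturation check: both limbs should be within 10% of their asymptote
  frac <- (c(lo, hi) - min(cf[["Qhyp"]], cf[["Qhyp"]] + cf[["Qmax"]])) /
    abs(cf[["Qmax"]])
  sat_warn <- !(min(frac) < 0.1 && max(frac) > 0.9)
  structure(list(Vt = Vt, Q = Q,
                 Qmax = cf[["Qmax"]], Qhyp = cf[["Qhyp"]],
                 Qdep = cf[["Qhyp"]] + cf[["Qmax"]],
                 V05 = cf[["V05"]], z = cf[["z"]], T_K = T_K, r2 = r2,
                 se = se, converged = TRUE,
                 saturation_warning = sat_warn),
            class = "ChargeMovement")
}

#' @export
print.ChargeMovement <- function(x, ...) {
  cat("ChargeMovement Q-V fit",
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  if (x$converged) {
    cat(sprintf("  Qmax %.4g nC  Qhyp %.4g nC  V0.5 %.4g mV  z %.4g  r2 %.5f\n",
                x$Qmax, x$Qhyp, x$V05, x$z, x$r2))
    if (isTRUE(x$saturation_warning)) {
      cat("  warning: saturation not reached on both limbs\n")
    }
  }
  invisible(x)
}

#' Transporter number and turnover from a Q-V fit
#'
#' N_T = Qmax / (|z| e) with e = 1.6e-19 C (|z| keeps counts positive
#' regardless of the valence sign convention; the signed z stays in the
#' fit record); turnover = -Imax / Qmax, in s^-1 when Imax is nA and Qmax
#' nC.
#'
#' @param fit a converged `ChargeMovement`.
#' @param Imax_nA maximal transport current (nA; inward negative).
#' @return list of class `DerivedTransportParams`: `N_T`,
#'   `turnover_per_s`, `Qmax_nC`, `z`, `Imax_nA`, `e`.
#' @export
derived_params <- function(fit, Imax_nA) {
  stopifnot(inherits(fit, "ChargeMovement"))
  if (!fit$converged) stop("Q-V fit did not converge")
  if (!is.finite(fit$z) || fit$z == 0) {
    stop("transporter number undefined for z = 0")
  }
  N_T <- abs(fit$Qmax) * 1e-9 / (abs(fit$z) * ELEM_CHARGE)
  structure(list(N_T = N_T,
                 turnover_per_s = -Imax_nA / fit$Qmax,
                 Qmax_nC = fit$Qmax, z = fit$z, Imax_nA = Imax_nA,
                 e = ELEM_CHARGE),
            class = "DerivedTransportParams")
}

#' @export
print.DerivedTransportParams <- function(x, ...) {
  cat(sprintf("N_T = %.4g transporters; turnover = %.4g s^-1 (Qmax %.4g nC, z %.3g, Imax %.4g nA)\n",
              x$N_T, x$turnover_per_s, x$Qmax_nC, x$z, x$Imax_nA))
  invisible(x)
}

#' Full Q-V analysis of a set of voltage-step traces
#'
#' Convenience chain: isolate the transporter relaxation of the chosen
#' step edge of every trace, integrate the charge, and fit the Boltzmann
#' relation.
#'
#' @param traces list of `VoltageStepTrace`.
#' @param exclude dead time (ms) passed to [isolate_transient()].
#' @param edge "on" or "off".
#' @param T_K temperature (K).
#' @return list: `qv` (data.frame Vt, Q_nC), `fit` (`ChargeMovement`),
#'   `transients` (list of `TransientFit`).
#' @export
charge_movement_analysis <- function(traces, exclude = 0.4,
                                     edge = c("on", "off"), T_K = 295.15) {
  edge <- match.arg(edge)
  tr <- lapply(traces, isolate_transient, exclude = exclude, edge = edge)
  Q <- vapply(tr, function(f) {
    q <- suppressWarnings(integrate_charge(f, cross_check = FALSE))
    as.numeric(q)
  }, 0)
  Vt <- vapply(traces, `[[`, 0, "Vt")
  ok <- is.finite(Q)
  fit <- fit_boltzmann(Vt[ok], Q[ok], T_K = T_K)
  list(qv = data.frame(Vt = Vt, Q_nC = Q), fit = fit, transients = tr)
}

#' Qmax-pH profile normalized to a reference pH
#'
#' Per-cell normalization Qmax(pH)/Qmax(reference pH); V0.5 is reported
#' unnormalized. Proton concentrations are 10^(6 - pH) uM.
#'
#' @param fits data.frame with columns `cell`, `pH`, `Qmax`, `V05` (one
#'   row per cell x pH), or a list of `ChargeMovement` with `pH`/`cell`
#'   entries in a parallel data.frame.
#' @param reference_pH default 5.5.
#' @return data.frame cell, pH, H_uM, qmax_norm, V05.
#' @export
qmax_ph_profile <- function(fits, reference_pH = 5.5) {
  stopifnot(is.data.frame(fits),
            all(c("cell", "pH", "Qmax", "V05") %in% names(fits)))
  out <- lapply(split(fits, fits$cell), function(d) {
    ref <- d$Qmax[d$pH == reference_pH]
    if (length(ref) != 1L) {
      stop("cell ", d$cell[1], ": no (unique) measurement at reference pH ",
           reference_pH)
    }
    data.frame(cell = d$cell, pH = d$pH, H_uM = ph_to_uM(d$pH),
               qmax_norm = d$Qmax / ref, V05 = d$V05)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
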
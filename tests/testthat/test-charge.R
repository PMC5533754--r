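make_trace <- function(I_fun, Vh = -50, Vt = 50, dur = 200, pre = 50,
                       post = 200, fs = 5000) {
  dt <- 1000 / fs
  t <- seq(0, pre + dur + post - dt, by = dt)
  voltage_step_trace(t, I_fun(t), Vh, Vt, pre, pre + dur,
                     meta = list(sampling_Hz = fs, filter_Hz = 500))
}

test_that("steady-state current averages the 10 ms mid-step window", {
  tr <- make_trace(function(t) rep(100, length(t)))
  expect_equal(steady_state_current(tr), 100)
  # decaying transient has vanished by mid-step
  tr2 <- make_trace(function(t) 100 + 50 * exp(-pmax(t - 50, 0) / 2))
  expect_lt(abs(steady_state_current(tr2) - 100), 0.1)
  # linear ramp averages to its midpoint value
  tr3 <- make_trace(function(t) 2 * t)
  expect_equal(steady_state_current(tr3), 2 * 150, tolerance = 1e-3)
  expect_error(steady_state_current(make_trace(function(t) t, dur = 20)),
               "3x")
})

test_that("substrate-induced current is the paired steady-state difference", {
  base <- data.frame(Vt = seq(-150, 50, by = 20), I = seq(-150, 50, by = 20))
  expect_true(all(substrate_induced_current(base, base)$dI == 0))
  plus <- base; plus$I <- plus$I - 50
  expect_true(all(substrate_induced_current(plus, base)$dI == -50))
  expect_error(substrate_induced_current(base, base[-3, ]), "-110")
})

test_that("a pure slow exponential is returned with negligible fast term", {
  tr <- make_trace(function(t) {
    ifelse(t >= 50 & t < 250, 200 * exp(-(t - 50) / 10) - 30, -30)
  })
  f <- isolate_transient(tr)
  expect_true(f$converged)
  expect_true(f$resolvable)
  expect_equal(f$A_p, 200, tolerance = 0.01)
  expect_equal(f$tau_p, 10, tolerance = 0.01)
  expect_lt(abs(f$A_c), 0.01 * abs(f$A_p))
  expect_equal(f$I_ss, -30, tolerance = 0.01)
})

test_that("two well-separated components are recovered under noise", {
  set.seed(81)
  f0 <- function(t) {
    on <- t >= 50 & t < 250
    tt <- pmax(t - 50, 0)
    ifelse(on, 4000 * exp(-tt / 0.5) + 200 * exp(-tt / 10) + 20, 20) +
      rnorm(length(t), 0, 2)
  }
  f <- isolate_transient(make_trace(f0))
  expect_true(f$resolvable)
  expect_equal(f$tau_p, 10, tolerance = 0.05)
  expect_equal(f$tau_c, 0.5, tolerance = 0.2)
  expect_equal(f$A_p, 200, tolerance = 0.05)
})

test_that("near-equal time constants are flagged unresolvable", {
  tr <- make_trace(function(t) {
    on <- t >= 50 & t < 250
    tt <- pmax(t - 50, 0)
    ifelse(on, 1000 * exp(-tt / 5) + 800 * exp(-tt / 10) + 10, 10)
  })
  f <- isolate_transient(tr)
  expect_false(f$resolvable)
  expect_match(f$flag, "unresolvable")
  expect_warning(q <- integrate_charge(f), "undefined")
  expect_true(is.na(q))
})

test_that("charge integration has the closed form A_p tau_p", {
  tr <- make_trace(function(t) {
    ifelse(t >= 50 & t < 250, 100 * exp(-(t - 50) / 10), 0)
  })
  f <- isolate_transient(tr)
  q <- integrate_charge(f)
  expect_equal(as.numeric(q), 1.0, tolerance = 1e-6)
  # numerical cross-check agrees within 1% on a 20-tau window
  expect_equal(attr(q, "numeric_nC"), as.numeric(q), tolerance = 0.01)
  # zero-amplitude component integrates to zero
  flat <- make_trace(function(t) rep(5, length(t)))
  expect_equal(as.numeric(integrate_charge(isolate_transient(flat))), 0)
})

test_that("Boltzmann Q-V fit recovers exact data and honours identities", {
  Vt <- seq(-110, 90, by = 20)
  kT <- 96485.33212 / (8.31446262 * 295.15 * 1000)
  qv <- function(V) 5 + 80 / (1 + exp(-2 * (V - 60) * kT))
  fit <- fit_boltzmann(Vt, qv(Vt))
  expect_true(fit$converged)
  expect_equal(fit$Qmax, 80, tolerance = 1e-6)
  expect_equal(fit$V05, 60, tolerance = 1e-6)
  expect_equal(fit$z, -2, tolerance = 1e-6)
  expect_equal(fit$Qdep - fit$Qhyp, fit$Qmax, tolerance = 1e-9)
  # at V = V0.5 the normalized charge is exactly 1/2
  q_at_mid <- fit$Qhyp + fit$Qmax / 2
  expect_equal(qv(60), q_at_mid, tolerance = 1e-6)
  expect_error(fit_boltzmann(Vt[1:4], qv(Vt[1:4])), "6 test potentials")
})

test_that("the Q-V fit absorbs constant charge offsets into Qhyp", {
  Vt <- seq(-110, 90, by = 20)
  kT <- 96485.33212 / (8.31446262 * 295.15 * 1000)
  Q <- 80 / (1 + exp(-2 * (Vt - 60) * kT)) +
    with_seed(82, rnorm(length(Vt), 0, 1))
  f1 <- fit_boltzmann(Vt, Q)
  f2 <- fit_boltzmann(Vt, Q + 37)
  expect_equal(f2$Qhyp, f1$Qhyp + 37, tolerance = 1e-6)
  expect_equal(f2$Qmax, f1$Qmax, tolerance = 1e-6)
  expect_equal(f2$V05, f1$V05, tolerance = 1e-6)
  expect_equal(f2$z, f1$z, tolerance = 1e-6)
})

test_that("derived transporter number and turnover match hand arithmetic", {
  fake <- structure(list(Qmax = 3.2, z = 2, converged = TRUE),
                    class = "ChargeMovement")
  d <- derived_params(fake, Imax_nA = -100)
  expect_equal(d$N_T, 1.0e10)
  fake2 <- structure(list(Qmax = 80, z = -2, converged = TRUE),
                     class = "ChargeMovement")
  d2 <- derived_params(fake2, Imax_nA = -2000)
  expect_equal(d2$turnover_per_s, 25)
  # doubling Qmax doubles N_T and halves turnover
  fake3 <- structure(list(Qmax = 160, z = -2, converged = TRUE),
                     class = "ChargeMovement")
  d3 <- derived_params(fake3, Imax_nA = -2000)
  expect_equal(d3$N_T, 2 * d2$N_T)
  expect_equal(d3$turnover_per_s, d2$turnover_per_s / 2)
  fake0 <- structure(list(Qmax = 80, z = 0, converged = TRUE),
                     class = "ChargeMovement")
  expect_error(derived_params(fake0, -100), "z = 0")
})

test_that("Qmax-pH profiles normalize per cell to the reference pH", {
  fits <- data.frame(cell = rep(c("c1", "c2"), each = 3),
                     pH = rep(c(5.5, 6.5, 7.5), 2),
                     Qmax = c(80, 60, 30, 100, 70, 20),
                     V05 = c(60, 40, 20, 55, 35, 15))
  prof <- qmax_ph_profile(fits)
  expect_equal(prof$qmax_norm[prof$pH == 5.5], c(1, 1))
  expect_equal(prof$qmax_norm[prof$cell == "c1" & prof$pH == 7.5], 30 / 80)
  expect_equal(prof$V05, fits$V05)
  expect_equal(prof$H_uM, ph_to_uM(fits$pH))
  # flat Qmax gives a flat profile at 1
  flat <- fits; flat$Qmax <- 50
  expect_true(all(qmax_ph_profile(flat)$qmax_norm == 1))
  expect_error(qmax_ph_profile(fits[fits$pH > 6, ]), "reference")
})

test_that("a linear Qmax-proton dependence is recovered from the profile", {
  pH <- seq(5.5, 7.5, by = 0.5)
  H <- ph_to_uM(pH)
  b <- 20
  fits <- data.frame(cell = "c1", pH = pH, Qmax = 10 + b * H, V05 = 60)
  prof <- qmax_ph_profile(fits)
  ref <- 10 + b * ph_to_uM(5.5)
  co <- coef(lm(qmax_norm ~ H_uM, data = prof))
  expect_equal(unname(co[2]), b / ref, tolerance = 1e-9)
})
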
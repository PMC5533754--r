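test_that("generators regenerate bit-identically from their ground truth", {
  h <- make_ideal_helix(8, n_frames = 4, thermal_sd = 5, seed = 91)
  expect_identical(regenerate(h$ground_truth)$trajectory$xyz,
                   h$trajectory$xyz)

  pre <- rotamer_preset_5state()
  r <- simulate_rotamer_markov(pre$states, pre$rates, 500, seed = 92)
  r2 <- regenerate(r$ground_truth)
  expect_identical(r2$chi1, r$chi1)
  expect_identical(r2$states, r$states)

  s <- make_metal_site(5, angular_jitter_sd = 7, n_frames = 3, seed = 93)
  expect_identical(regenerate(s$ground_truth)$trajectory$xyz,
                   s$trajectory$xyz)

  p <- tevc_params_default(); p$noise_frac <- 0.02
  sim <- simulate_tevc(params = p, seed = 94)
  sim2 <- regenerate(sim$ground_truth)
  expect_identical(sim2$traces[[3]]$current_nA, sim$traces[[3]]$current_nA)

  u <- simulate_uptake(seed = 95)
  expect_identical(regenerate(u$ground_truth)$plate$counts_cpm,
                   u$plate$counts_cpm)
})

test_that("ground truth serializes and reloads alongside datasets", {
  h <- make_ideal_helix(6, n_frames = 2, thermal_sd = 2, seed = 96)
  d <- withr::local_tempdir()
  write_ground_truth(h$ground_truth, d)
  gt <- read_ground_truth(d)
  expect_equal(gt$generator, "make_ideal_helix")
  expect_equal(gt$seed, 96)
  expect_identical(regenerate(gt)$trajectory$xyz, h$trajectory$xyz)
})

test_that("generator outputs satisfy the reader invariants unmodified", {
  expect_silent(validate_trajectory(
    make_ideal_helix(10, n_frames = 3, thermal_sd = 4, seed = 97)$trajectory))
  expect_silent(validate_trajectory(make_metal_site(6)$trajectory))
  expect_silent(validate_trajectory(
    make_gate_states(c("open", "closed"))$trajectory))
  r <- simulate_rotamer_markov(rbind(c(0, 0)), matrix(0, 1, 1), 100,
                               seed = 98)
  expect_true(all(r$chi1 > -180 & r$chi1 <= 180))
})

test_that("the RNG state of the session is never disturbed", {
  set.seed(1234)
  before <- .Random.seed
  invisible(make_ideal_helix(5, n_frames = 2, thermal_sd = 3, seed = 99))
  invisible(simulate_uptake(seed = 100))
  expect_identical(.Random.seed, before)
})

test_that("flip injection validates its event schedule", {
  h <- make_ideal_helix(10, n_frames = 50)
  expect_error(inject_flips(h, data.frame(resno = 3, start = 45,
                                          duration = 10)), "bounds")
  expect_error(inject_flips(h, data.frame(resno = c(3, 3),
                                          start = c(5, 10),
                                          duration = c(10, 5))),
               "overlapping")
  expect_error(inject_flips(h, data.frame(resno = 10, start = 1,
                                          duration = 5)), "out of range")
})

test_that("a single-state chain yields one cluster and no transitions", {
  r <- simulate_rotamer_markov(rbind(c(-60, 180)), matrix(0, 1, 1), 300,
                               within_state_sd = 5, seed = 101)
  cl <- cluster_rotamers(r$chi1, r$chi2)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(sum(transition_counts(r$states)$counts), 0L)
})

test_that("noise-free TEVC generation is inverted exactly by the analysis", {
  p <- tevc_params_default()
  p$C_m_nF <- 0  # no capacitive transient: pure transporter relaxation
  sim <- simulate_tevc(params = p, seed = 102)
  for (i in c(1, 3, 11)) {
    f <- isolate_transient(sim$traces[[i]])
    q <- as.numeric(integrate_charge(f, cross_check = FALSE))
    expect_equal(q, sim$true_dQ$dQ_nC[i],
                 tolerance = 1e-6 * max(1e-12, abs(sim$true_dQ$dQ_nC[i])))
  }
})

test_that("ON and OFF charges cancel on two-state traces", {
  p <- tevc_params_default(); p$noise_frac <- 0.02
  sim <- simulate_tevc(params = p, seed = 103)
  tr <- sim$traces[[1]]  # largest charge movement
  qon <- as.numeric(integrate_charge(isolate_transient(tr, edge = "on"),
                                     cross_check = FALSE))
  qoff <- as.numeric(integrate_charge(isolate_transient(tr, edge = "off"),
                                      cross_check = FALSE))
  expect_lt(abs(qon + qoff) / abs(qon), 0.02)
})

test_that("TEVC traces round-trip through the CSV + sidecar format", {
  p <- tevc_params_default(); p$noise_frac <- 0.01
  sim <- simulate_tevc(params = p, seed = 104)
  d <- withr::local_tempdir()
  write_tevc_traces(sim, d)
  back <- read_tevc_traces(d)
  expect_equal(length(back), length(sim$traces))
  vt_back <- vapply(back, `[[`, 0, "Vt")
  i <- which(vt_back == sim$traces[[1]]$Vt)
  expect_equal(back[[i]]$current_nA, sim$traces[[1]]$current_nA,
               tolerance = 1e-9)
  expect_equal(back[[i]]$meta$T_K, 295.15)
})

test_that("noiseless uptake plates invert to the exact Km and vmax", {
  p <- uptake_params_default(); p$noise <- "none"
  u <- simulate_uptake(p, seed = 105)
  an <- analyze_uptake(u$plate)
  expect_equal(an$fit$parameters[["Km"]], 2, tolerance = 1e-6)
  expect_equal(an$fit$parameters[["vmax"]], 10, tolerance = 1e-6)
})

test_that("zero-vmax plates contain background-only counts", {
  p <- uptake_params_default(); p$vmax <- 0; p$noise <- "none"
  u <- simulate_uptake(p, seed = 106)
  tw <- u$plate[!u$plate$is_background, ]
  bw <- u$plate[u$plate$is_background, ]
  expect_equal(tw$counts_cpm, bw$counts_cpm)
})

test_that("Hill current generation is inverted by the leak-model fit", {
  sim <- simulate_hill_currents(list(noise_frac = 0), seed = 107)
  f <- fit_hill_leak(sim$data$S_uM, sim$data$I_nA)
  expect_equal(f$parameters[["K05"]], 1, tolerance = 1e-6)
  expect_equal(f$parameters[["nH"]], 1.5, tolerance = 1e-6)
  expect_equal(f$parameters[["iU"]], -20, tolerance = 1e-5)
  expect_equal(f$parameters[["Imax"]], -200, tolerance = 1e-5)
})
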
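test_that("generators are pure functions of their seed", {
  a <- make_psc_trace(40, seed = 7)
  b <- make_psc_trace(40, seed = 7)
  expect_identical(a$trace$data, b$trace$data)
  expect_false(identical(a$trace$data,
                         make_psc_trace(40, seed = 8)$trace$data))

  t1 <- make_trajectory(duration_s = 60, seed = 5)
  t2 <- make_trajectory(duration_s = 60, seed = 5)
  expect_identical(t1$trajectory, t2$trajectory)

  s1 <- make_current_step_traces(seed = 9, noise_sd_mV = 0.5)
  s2 <- make_current_step_traces(seed = 9, noise_sd_mV = 0.5)
  expect_identical(s1$traces[[1]]$data, s2$traces[[1]]$data)
})

test_that("the PSC kernel peaks at exactly the requested amplitude", {
  t <- seq(0, 100, by = 0.001)
  k <- psc_kernel(t, 1, 10)
  expect_equal(max(k), 1, tolerance = 1e-8)
  expect_equal(psc_kernel(-5, 1, 10), 0)
  expect_error(psc_kernel(1, 10, 10))
})

test_that("null traces are unconnected; detection matches its false-positive rate", {
  nulls <- vapply(1:200, function(s) {
    tr <- make_psc_trace(0, noise_sd_pA = 5, n_trials = 10, seed = s)
    expect_false(tr$truth$connected)
    detect_connection(tr$trace)$connected
  }, logical(1))
  # analytic false-positive rate of the one-sided 2-SD rule on the window
  # mean: the response window averages m samples of white noise with
  # variance sigma^2/n_trials, the baseline SD estimate is nearly exact
  # (1000 samples), so P(FP) ~ pnorm(-2 * sqrt(m)) ~ 0 for m = 481.
  # Any positive call would exceed a 4-sigma fluke.
  expect_lt(mean(nulls), 0.02)
})

test_that("amplitude and connectivity are recovered across the tested range", {
  # criterion: >= 95% sensitivity at amplitude >= 5x noise SD
  res <- lapply(1:100, function(s) {
    amp <- stats::runif(1, 25, 60)
    noise <- stats::runif(1, 2, 5)
    tr <- make_psc_trace(amp, noise_sd_pA = noise, n_trials = 10,
                         seed = 1000 + s)
    call <- detect_connection(tr$trace)
    tibble::tibble(amp = amp, noise = noise, connected = call$connected,
                   err = call$amplitude - tr$truth$window_amplitude_pA)
  })
  res <- dplyr::bind_rows(res)
  strong <- res[res$amp >= 5 * res$noise, ]
  expect_gte(mean(strong$connected), 0.95)
  # estimator bias below noise SD / sqrt(n_trials)
  expect_lt(abs(mean(res$err)), mean(res$noise) / sqrt(10))
})

test_that("paired-cell generation recovers programmed ratios", {
  for (ratio in c(1, 0.5, 0.1)) {
    pc <- make_paired_cells(ratio, base_amplitude_pA = 50, noise_sd_pA = 2,
                            n_trials = 10, seed = round(100 * ratio))
    r <- pair_ratio(pc$pair, "vH-NAc", "vH-BA")
    expect_false(r$censored)
    expect_equal(r$ratio, ratio, tolerance = 0.15)
  }
  # zero ratio: measured numerator is spurious noise; the reverse ratio is
  # censored when the measured denominator is exactly zero, and tiny when
  # noise leaves a residual
  pc0 <- make_paired_cells(0, base_amplitude_pA = 50, noise_sd_pA = 0,
                           n_trials = 1, seed = 3)
  expect_equal(pc0$pair$amplitude_pA[2], 0, tolerance = 1e-9)
  r0 <- pair_ratio(pc0$pair, "vH-BA", "vH-NAc")
  expect_true(r0$censored)
})

test_that("trajectory generator ground truth equals the scored occupancy", {
  tr <- make_trajectory(duration_s = 300, rate_Hz = 10, stim_bias = 0.8,
                        seed = 21)
  occ <- occupancy_metrics(tr$trajectory)
  # same discretisation: agreement to machine precision
  expect_identical(occ$stim_fraction, tr$truth$realised_stim_fraction)
  expect_identical(occ$distance_cm, tr$truth$distance_cm)

  # programmed bias is recovered within a few percent over a long session
  tr2 <- make_trajectory(duration_s = 900, rate_Hz = 10, stim_bias = 0.7,
                         seed = 22)
  expect_lt(abs(tr2$truth$realised_stim_fraction - 0.7), 0.02)

  # symmetric bias stays near one half
  tr3 <- make_trajectory(duration_s = 900, rate_Hz = 10, stim_bias = 0.5,
                         seed = 23)
  expect_lt(abs(tr3$truth$realised_stim_fraction - 0.5), 0.03)

  expect_error(make_trajectory(duration_s = 0.05, rate_Hz = 10, seed = 1),
               "at least two")
  # all samples inside the arena
  expect_true(all(tr$trajectory$x_cm >= 0 & tr$trajectory$x_cm <= 24))
  expect_true(all(tr$trajectory$y_cm >= 0 & tr$trajectory$y_cm <= 16))
})

test_that("current-step generator honours its membrane parameters", {
  st <- make_current_step_traces(resting_mV = -65, input_resistance_MOhm = 200,
                                 sag_mV = 0, steps_pA = -50, seed = 4)
  ip <- intrinsic_properties(st$traces, st$injected_currents_pA)
  expect_equal(ip$resting_mV, -65)
  expect_equal(ip$input_resistance_MOhm, 200, tolerance = 1e-3)
})
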
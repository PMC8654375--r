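flat_trace <- function(n = 4000, value = 0, rate = 10000, onset = 150, ...) {
  sweep_trace(rep(value, n), rate, onset, ...)
}

test_that("connection detection applies the strict 2-SD criterion", {
  # flat zero trace: degenerate SD, no response, not connected
  expect_false(detect_connection(flat_trace())$connected)

  # noisy baseline with an injected -25 pA square response, SD 5 pA
  set.seed(1)
  rate <- 10000
  v <- rnorm(4001, 0, 5)
  t <- (seq_along(v) - 1) / 10   # ms
  v[t >= 152 & t <= 200] <- v[t >= 152 & t <= 200] - 25
  tr <- sweep_trace(v, rate, 150, polarity = "inward")
  call <- detect_connection(tr)
  expect_true(call$connected)
  expect_lt(abs(call$amplitude - 25), 3 * 5 / sqrt(20))

  # a deflection of exactly 2 SD is not connected (strict inequality);
  # baseline of 500 x (+1), 500 x (-1) and one 0 has mean 0 and SD exactly 1
  base <- c(rep(c(1, -1), 500), 0)
  mk <- function(defl) {
    v <- rep(0, 4001)
    v[seq_along(base) + 400] <- base       # samples at 40-140 ms
    v[(0:4000) / 10 >= 152 & (0:4000) / 10 <= 200] <- -defl
    sweep_trace(v, 10000, 150, polarity = "inward",
                baseline_window_ms = c(40, 140))
  }
  exact <- detect_connection(mk(2))
  expect_equal(exact$baseline_sd, 1)
  expect_false(exact$connected)
  expect_true(detect_connection(mk(2.01))$connected)
})

test_that("response window outside the record is rejected", {
  tr <- flat_trace(n = 1600)  # 160 ms record, onset 150, window to 200 ms
  expect_error(detect_connection(tr), "beyond the end")
})

test_that("amplitude is the 2 ms window mean around the peak", {
  # noiseless rectangular 50 pA response: flat peak, amplitude exactly 50
  v <- rep(0, 4001)
  t <- (0:4000) / 10
  v[t >= 155 & t <= 180] <- -50
  tr <- sweep_trace(v, 10000, 150, polarity = "inward")
  expect_equal(measure_amplitude(tr)$amplitude, 50)

  # double-exponential kernel: compare to a brute-force evaluation
  rise <- 1; decay <- 10; peak <- 40
  kern <- function(t) {
    tpk <- rise * decay / (decay - rise) * log(decay / rise)
    norm <- exp(-tpk / decay) - exp(-tpk / rise)
    ifelse(t >= 0, (exp(-t / decay) - exp(-t / rise)) / norm, 0)
  }
  v <- -peak * kern(t - 153)
  tr <- sweep_trace(v, 10000, 150, polarity = "inward")
  m <- measure_amplitude(tr)
  # oracle: peak sample then 2 ms window mean, computed directly
  tpk_t <- t[which.min(v)]
  oracle <- abs(mean(v[t >= tpk_t - 1 & t <= tpk_t + 1]))
  expect_equal(m$amplitude, oracle, tolerance = 1e-12)
  expect_lt(m$amplitude, peak)        # window mean sits just below the peak
  expect_gt(m$amplitude, 0.9 * peak)

  # invariant to a constant baseline offset
  tr_off <- sweep_trace(v - 113, 10000, 150, polarity = "inward")
  expect_equal(measure_amplitude(tr_off)$amplitude, m$amplitude,
               tolerance = 1e-9)

  # peak at the record edge: truncated window is flagged
  v_edge <- c(rep(0, 3990), seq(0, -60, length.out = 11))
  tr_edge <- sweep_trace(v_edge, 10000, 150, polarity = "inward",
                         response_window_ms = c(2, 250))
  expect_true(measure_amplitude(tr_edge)$truncated)
})

test_that("pair ratios are exact, reciprocal, and censored at zero", {
  pair <- tibble::tibble(label = c("vH-NAc", "vH-BA"),
                         amplitude_pA = c(30, 60), pair_id = "p1")
  r <- pair_ratio(pair, "vH-NAc", "vH-BA")
  expect_equal(r$ratio, 0.5)
  expect_equal(r$log10_ratio, log10(0.5))
  expect_false(r$censored)

  equal <- tibble::tibble(label = c("a", "b"), amplitude_pA = c(42, 42))
  expect_equal(pair_ratio(equal, "a", "b")$ratio, 1)

  fwd <- pair_ratio(pair, "vH-NAc", "vH-BA")$ratio
  rev <- pair_ratio(pair, "vH-BA", "vH-NAc")$ratio
  expect_equal(fwd * rev, 1)

  zero <- tibble::tibble(label = c("a", "b"), amplitude_pA = c(10, 0))
  z <- pair_ratio(zero, "a", "b")
  expect_true(z$censored)
  expect_true(is.na(z$ratio))
})

test_that("intrinsic properties follow Ohm's law on the smallest step", {
  # -40 pA with R = 150 MOhm: -6 mV steady deflection, recovered exactly on
  # a noiseless, sag-free fixture
  st <- make_current_step_traces(resting_mV = -70, input_resistance_MOhm = 150,
                                 sag_mV = 0, steps_pA = c(-40, -80, 300),
                                 seed = 1)
  ip <- intrinsic_properties(st$traces, st$injected_currents_pA)
  expect_equal(ip$resting_mV, -70)
  expect_equal(ip$input_resistance_MOhm, 150, tolerance = 1e-3)
  expect_equal(ip$sag_mV, 0, tolerance = 1e-6)
  # suprathreshold step spikes; counts match the generator's ground truth
  expect_equal(ip$spikes_per_step$n_spikes, st$truth$n_spikes[[1]])
  expect_gt(ip$spikes_per_step$n_spikes[3], 0)

  # sag recovered approximately when present
  st2 <- make_current_step_traces(sag_mV = 4, steps_pA = -40, seed = 2)
  ip2 <- intrinsic_properties(st2$traces, st2$injected_currents_pA)
  expect_gt(ip2$sag_mV, 2)

  # no hyperpolarising step: flagged NA
  st3 <- make_current_step_traces(steps_pA = 300, seed = 3)
  expect_warning(
    ip3 <- intrinsic_properties(st3$traces, st3$injected_currents_pA),
    "hyperpolarising")
  expect_true(is.na(ip3$input_resistance_MOhm))
})

test_that("occupancy is time-weighted, side-complete and validated", {
  # trajectory entirely in the stimulation half
  tr <- tibble::tibble(time_s = 0:10, x_cm = 20, y_cm = 8)
  attr(tr, "arena") <- list(width_cm = 24, height_cm = 16)
  attr(tr, "stim_side") <- "right"
  occ <- occupancy_metrics(tr)
  expect_equal(occ$stim_fraction, 1)
  expect_equal(occ$distance_cm, 0)

  # mirror-symmetric trajectory: exactly half the dwell on each side
  tr2 <- tibble::tibble(time_s = 0:10,
                        x_cm = c(rep(c(6, 18), 5), 6), y_cm = 8)
  attr(tr2, "arena") <- list(width_cm = 24, height_cm = 16)
  attr(tr2, "stim_side") <- "right"
  occ2 <- occupancy_metrics(tr2)
  expect_equal(occ2$stim_fraction, 0.5)
  expect_equal(occ2$stim_fraction + occ2$control_fraction, 1)
  expect_equal(occ2$distance_cm, 12 * 10)

  bad <- tibble::tibble(time_s = c(0, 2, 1), x_cm = 1, y_cm = 1)
  expect_error(occupancy_metrics(bad), "strictly increasing")
  expect_error(occupancy_metrics(tr[1, ]), "at least two")
})
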
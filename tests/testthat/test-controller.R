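test_that("oscillator reaches the analytic steady state under constant input", {
  omega <- 2 * pi
  st <- list(x = 0, xdot = 0, omega = omega)
  F0 <- 7
  for (i in 1:5000) st <- oscillator_step(st, F0, 0.005)
  expect_equal(st$x, omega * F0 / omega^2, tolerance = 1e-9)  # k F0 / omega^2
  expect_equal(st$xdot, 0, tolerance = 1e-9)
  expect_error(oscillator_step(st, 1, 0), "positive")
})

test_that("free response matches the underdamped closed form", {
  omega <- 2 * pi
  dt <- 1e-3 * (2 * pi / omega)
  o <- oscillator_filter(rep(0, 5000), omega, dt, x0 = 0, xdot0 = omega)
  tt <- seq_len(5000) * dt
  a <- omega / 2
  wd <- omega * sqrt(3) / 2  # decay omega/2, ringing omega sqrt(3)/2
  exact <- omega * exp(-a * tt) * (cos(wd * tt) - a / wd * sin(wd * tt))
  expect_lt(max(abs(o$xdot - exact)) / max(abs(exact)), 1e-3)
})

test_that("with k = omega a resonant sinusoid passes at unit gain, zero phase", {
  for (omega in c(2 * pi, 2 * pi / 3)) {
    dt <- 1e-3 * (2 * pi / omega)
    tt <- seq(dt, 80 * pi / omega, by = dt)
    o <- oscillator_filter(sin(omega * tt), omega, dt)
    sel <- tt > 40 * pi / omega  # past the transient
    z <- sum(o$xdot[sel] * exp(-1i * omega * tt[sel])) /
      sum(sin(omega * tt[sel]) * exp(-1i * omega * tt[sel]))
    expect_equal(Mod(z), 1, tolerance = 0.01)
    expect_lt(abs(Arg(z)), 0.02)
  }
})

test_that("actuation is the gained half-period difference", {
  K <- 3; T <- 1
  t <- seq(0, 5, by = 0.01)
  xd <- sin(2 * pi * t / T)
  xd_del <- sin(2 * pi * (t - T / 2) / T)
  sf <- compute_actuation(xd, xd_del, K)
  expect_equal(sf, -2 * K * sin(2 * pi * t / T), tolerance = 1e-12)
  expect_equal(compute_actuation(0.7, 0.7, K), 0)
})

test_that("trigger rule enforces both stimulation-frequency bounds", {
  cfg <- controller_config(gain = 1, period = 1)
  # below sf_min: never fires
  expect_false(should_stimulate(10, -Inf, 0.5, cfg))
  # SF = 10 Hz: fires every ~0.1 s
  tl <- -Inf; times <- c()
  for (t in seq(0, 1, by = 0.001)) {
    if (should_stimulate(t, tl, 10, cfg)) { times <- c(times, t); tl <- t }
  }
  expect_equal(length(times), 10, tolerance = 1)
  expect_equal(min(diff(times)), 0.1, tolerance = 0.01)
  # SF far above sf_max: interval clipped at 1/20 s
  tl <- -Inf; times <- c()
  for (t in seq(0, 1, by = 0.001)) {
    if (should_stimulate(t, tl, 100, cfg)) { times <- c(times, t); tl <- t }
  }
  expect_true(all(diff(times) >= 1 / 20))
})

test_that("period estimate is the median of recent inter-burst intervals", {
  est <- update_period_estimate(c(0, 1, 2, 3), current_T = 5)
  expect_equal(est$T, 1)
  expect_equal(est$omega, 2 * pi)
  est2 <- update_period_estimate(c(0, 1, 1.9, 2.9, 4.0), current_T = 5, m = 3)
  expect_equal(est2$T, 1.0)  # median of 0.9, 1.0, 1.1
  est3 <- update_period_estimate(c(2), current_T = 5)
  expect_equal(est3$T, 5)
})

test_that("aDFC locks to the rhythm and stimulates in antiphase", {
  sts <- bursting_fixture(duration = 120, period = 1, seed = 5)
  fr <- firing_rate(sts)
  res <- run_controller(fr, controller_config(gain = 5, period = 1.3))
  # period estimate converges to the true 1 s after the first bursts
  expect_equal(tail(res$trace$T_history, 1), 1, tolerance = 0.1)
  ph <- stim_phases(res$schedule$times[res$schedule$times > 10],
                    res$trace$burst_times, function(s) 1)
  cm <- circular_mean(ph)
  expect_gt(cm, pi / 2)
  expect_lt(cm, 3 * pi / 2)
})

test_that("a silent firing-rate stream produces no stimuli", {
  fr <- adfc:::new_firing_rate(rep(0, 2000), 0.01, 0.1, 0)
  res <- run_controller(fr, controller_config(gain = 5, period = 1))
  expect_length(res$schedule$times, 0)
})

test_that("controller is quiescent on constant (asynchronous) activity", {
  fr <- adfc:::new_firing_rate(c(rep(0, 50), rep(8, 5950)), 0.01, 0.1, 0)
  res <- run_controller(fr, controller_config(gain = 5, period = 1))
  # the step transient may trigger a handful of stimuli, then SF -> 0
  expect_lt(length(res$schedule$times), 10)
  expect_true(all(res$schedule$times < 10))
  expect_lt(max(abs(res$trace$sf[res$trace$t > 10])), 1)
})

test_that("the schedule is causal: truncating the input preserves the past", {
  sts <- bursting_fixture(duration = 60, seed = 6)
  fr <- firing_rate(sts)
  cfg <- controller_config(gain = 5, period = 1.2)
  full <- run_controller(fr, cfg)
  half_values <- fr$values[fr$t <= 30]
  half <- run_controller(adfc:::new_firing_rate(half_values, fr$dt,
                                                fr$window, fr$t0), cfg)
  expect_equal(half$schedule$times,
               full$schedule$times[full$schedule$times <= 30])
  expect_equal(half$trace$sf, full$trace$sf[seq_along(half$trace$sf)])
})

test_that("all stimulus trains respect the refractory bound 1/sf_max", {
  sts <- bursting_fixture(duration = 60, seed = 8)
  fr <- firing_rate(sts)
  for (adaptive in c(TRUE, FALSE)) {
    res <- run_controller(fr, controller_config(gain = 50, period = 1,
                                                adaptive = adaptive))
    if (length(res$schedule$times) > 1)
      expect_true(all(diff(res$schedule$times) > 1 / 20 - 1e-9))
  }
})

test_that("aDFC converges to DFC behaviour on a stationary rhythm", {
  sts <- bursting_fixture(duration = 120, period = 1, jitter_sd = 0, seed = 2)
  fr <- firing_rate(sts)
  ad <- run_controller(fr, controller_config(gain = 5, period = 1.4))
  df <- run_controller(fr, controller_config(gain = 5, period = 1,
                                             adaptive = FALSE))
  # after adaptation settles, the two stimulate at the same rate and phase
  late <- function(x) x$schedule$times[x$schedule$times > 30]
  expect_equal(length(late(ad)), length(late(df)), tolerance = 0.15 * length(late(df)))
  pa <- stim_phases(late(ad), ad$trace$burst_times, function(s) 1)
  pd <- stim_phases(late(df), df$trace$burst_times, function(s) 1)
  d <- abs(circular_mean(pa) - circular_mean(pd))
  expect_lt(min(d, 2 * pi - d), 0.5)
})

test_that("Poisson schedules have the right count and interval law", {
  expect_length(generate_poisson_schedule(0, 100)$times, 0)
  expect_error(generate_poisson_schedule(-1, 10), "nonnegative")
  n <- length(generate_poisson_schedule(5, 100, seed = 3)$times)
  expect_gt(n, 500 - 4 * sqrt(500))
  expect_lt(n, 500 + 4 * sqrt(500))
  # reproducibility
  expect_identical(generate_poisson_schedule(5, 50, seed = 7)$times,
                   generate_poisson_schedule(5, 50, seed = 7)$times)
  # interval distribution
  big <- generate_poisson_schedule(5, 2100, seed = 9)
  iv <- diff(big$times)
  expect_gt(stats::ks.test(iv, stats::pexp, 5)$p.value, 0.01)
})
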
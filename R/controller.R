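#' Controller configuration
#'
#' Parameters of the delayed-feedback stimulation controllers. `gain` maps
#' the actuation signal to a stimulation frequency (stimuli/s per unit of
#' filtered-rate difference); `period` is the initial oscillation period
#' estimate T (seconds), normally taken from pre-experiment monitoring of
#' the network; with `adaptive = TRUE` (aDFC) the period and the oscillator
#' natural frequency are re-estimated online from detected network bursts,
#' with `adaptive = FALSE` (DFC) they stay fixed. Stimulation frequency is
#' bounded to `(sf_min, sf_max)`: below `sf_min` no stimulus is sent (low
#' background actuation must not trigger stimulation), above `sf_max` the
#' rate is clipped (the actuation chain has finite latency).
#'
#' @param gain stimulation gain K, > 0.
#' @param period initial period T in seconds, > 0.
#' @param adaptive logical: re-tune T and omega online from bursts (aDFC)?
#' @param sf_min,sf_max stimulation-frequency bounds in Hz (defaults 1, 20).
#' @param burst_threshold burst-detection threshold on the firing rate, Hz.
#' @param burst_min_interval minimum spacing of detected bursts, s.
#' @param fr_window firing-rate smoothing window the controller expects, s.
#' @param positive_only clip negative actuation to zero before applying the
#'   gain (used by the in silico closed loop).
#' @param m_intervals number of recent inter-burst intervals whose median
#'   gives the period estimate.
#' @param amplitude stimulus amplitude recorded in the schedule (device or
#'   model units).
#' @return a `controller_config` list.
#' @export
controller_config <- function(gain, period, adaptive = TRUE,
                              sf_min = 1, sf_max = 20,
                              burst_threshold = 10, burst_min_interval = 0.1,
                              fr_window = 0.1, positive_only = FALSE,
                              m_intervals = 3, amplitude = 1) {
  if (gain <= 0) stop("gain must be positive")
  if (period <= 0) stop("period must be positive")
  if (!(sf_min > 0 && sf_min < sf_max)) stop("need 0 < sf_min < sf_max")
  structure(list(gain = gain, period = period, adaptive = adaptive,
                 sf_min = sf_min, sf_max = sf_max,
                 burst_threshold = burst_threshold,
                 burst_min_interval = burst_min_interval,
                 fr_window = fr_window, positive_only = positive_only,
                 m_intervals = m_intervals, amplitude = amplitude),
            class = "controller_config")
}

#' Stimulation schedules
#'
#' Ordered stimulus times with amplitudes, the output of every stimulation
#' protocol.
#'
#' @param times strictly increasing stimulus times, s.
#' @param amplitude scalar or per-stimulus amplitudes.
#' @param protocol label: one of `"DFC"`, `"aDFC"`, `"Poisson"`.
#' @return a `stim_schedule`.
#' @export
stim_schedule <- function(times, amplitude = 1, protocol = "aDFC") {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("stimulus times must be strictly increasing")
  structure(list(times = times,
                 amplitude = rep_len(amplitude, length(times)),
                 protocol = protocol),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %s: %d stimuli%s\n", x$protocol,
              length(x$times),
              if (length(x$times))
                sprintf(" over %.3g s (mean %.3g Hz)",
                        diff(range(x$times)),
                        length(x$times) / max(diff(range(x$times)), 1e-12))
              else ""))
  invisible(x)
}

#' @rdname stim_schedule
#' @param x a `stim_schedule`.
#' @param path CSV file (`time_s,amplitude,protocol`).
#' @export
write_schedule_csv <- function(x, path) {
  utils::write.csv(data.frame(time_s = x$times, amplitude = x$amplitude,
                              protocol = x$protocol),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stim_schedule
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stim_schedule(df$time_s, df$amplitude,
                if (nrow(df)) df$protocol[1] else "aDFC")
}

# Exact zero-order-hold propagator of the critically-tuned damped oscillator
#   x'' + omega x' + omega^2 x = u(t),  u held constant over each step.
# Underdamped pair at -omega/2 +/- i omega sqrt(3)/2; coefficients give
#   [x, xdot]_{n+1} = Ad [x, xdot]_n + Bd u_n
osc_coefficients <- function(omega, dt) {
  a <- omega / 2
  wd <- omega * sqrt(3) / 2
  e <- exp(-a * dt)
  cth <- cos(wd * dt)
  sth <- sin(wd * dt)
  a11 <- e * (cth + a / wd * sth)
  a12 <- e * sth / wd
  a21 <- -e * omega^2 / wd * sth
  a22 <- e * (cth - a / wd * sth)
  list(a11 = a11, a12 = a12, a21 = a21, a22 = a22,
       b1 = (1 - a11) / omega^2, b2 = -a21 / omega^2)
}

#' One step of the damped-oscillator filter
#'
#' Advances the second-order filter `x'' + omega x' + omega^2 x = k FR(t)`
#' by `dt`, holding the input constant over the step (exact discretisation
#' of the linear system, so the update is unconditionally stable). The
#' derivative `xdot` is the filter output used by the controller. The input
#' scaling defaults to `k = omega`, which keeps the output amplitude
#' invariant across networks with different oscillation periods: a unit
#' sinusoidal input at the natural frequency yields a unit `xdot` with zero
#' phase lag.
#'
#' @param state list with `x`, `xdot`, `omega`, and optionally `k`
#'   (default `omega`).
#' @param fr_sample input firing-rate sample, Hz.
#' @param dt time step, s.
#' @return updated state list.
#' @export
oscillator_step <- function(state, fr_sample, dt) {
  if (dt <= 0) stop("dt must be positive")
  k <- state$k %||% state$omega
  co <- osc_coefficients(state$omega, dt)
  u <- k * fr_sample
  x_new <- co$a11 * state$x + co$a12 * state$xdot + co$b1 * u
  xdot_new <- co$a21 * state$x + co$a22 * state$xdot + co$b2 * u
  state$x <- x_new
  state$xdot <- xdot_new
  state
}

#' Run the damped-oscillator filter over a whole signal
#'
#' Vectorised convenience around [oscillator_step()] with fixed `omega`.
#'
#' @param values input samples (firing rate, Hz).
#' @param omega natural frequency, rad/s.
#' @param dt sample step, s.
#' @param k input scaling; defaults to `omega`.
#' @param x0,xdot0 initial conditions.
#' @return list of vectors `x`, `xdot` aligned with `values`.
#' @export
oscillator_filter <- function(values, omega, dt, k = omega,
                              x0 = 0, xdot0 = 0) {
  co <- osc_coefficients(omega, dt)
  n <- length(values)
  x <- numeric(n)
  xd <- numeric(n)
  xp <- x0
  xdp <- xdot0
  for (i in seq_len(n)) {
    u <- k * values[i]
    x[i] <- co$a11 * xp + co$a12 * xdp + co$b1 * u
    xd[i] <- co$a21 * xp + co$a22 * xdp + co$b2 * u
    xp <- x[i]
    xdp <- xd[i]
  }
  list(x = x, xdot = xd)
}

#' Delayed-feedback actuation signal
#'
#' The raw actuation: `SF = K * (xdot(t - T/2) - xdot(t))`. Subtracting the
#' half-period-delayed oscillation from the current one makes the signal
#' maximal exactly in antiphase with an ongoing oscillation of period T, so
#' stimuli are delivered where they counteract the rhythm; for a constant
#' (asynchronous) input the difference vanishes and the controller is
#' quiescent.
#'
#' @param xdot_now current filter output.
#' @param xdot_delayed filter output half a period ago (zero before start).
#' @param gain stimulation gain K.
#' @return stimulation-frequency value, Hz (may be negative; bounding is
#'   applied by [should_stimulate()]).
#' @export
compute_actuation <- function(xdot_now, xdot_delayed, gain) {
  gain * (xdot_delayed - xdot_now)
}

#' Stimulus trigger rule
#'
#' A stimulus fires when the bounded stimulation frequency exceeds
#' `sf_min` and at least `1/SF` has elapsed since the previous stimulus;
#' values above `sf_max` are clipped to `sf_max`, so the inter-stimulus
#' interval never drops below `1/sf_max`.
#'
#' @param t current time, s.
#' @param t_last_stim time of the previous stimulus (use `-Inf` at start).
#' @param sf current actuation value, Hz.
#' @param config a [controller_config()].
#' @return logical.
#' @export
should_stimulate <- function(t, t_last_stim, sf, config) {
  sf_eff <- min(sf, config$sf_max)
  sf_eff > config$sf_min && (t - t_last_stim) > 1 / sf_eff
}

#' Online period estimate from burst times
#'
#' The adaptive component of aDFC: the oscillation period T is the median of
#' the last `m` inter-burst intervals, and the oscillator natural frequency
#' follows as `omega = 2 pi / T`. With fewer than two bursts the current
#' values are kept. The median makes the estimate robust to an occasional
#' missed or spurious burst without any extra outlier rule.
#'
#' @param burst_times ordered burst times seen so far, s.
#' @param current_T current period estimate, s.
#' @param m number of recent intervals to aggregate (default 3).
#' @return list `T` (s) and `omega` (rad/s).
#' @export
update_period_estimate <- function(burst_times, current_T, m = 3) {
  if (length(burst_times) < 2)
    return(list(T = current_T, omega = 2 * pi / current_T))
  iv <- diff(burst_times)
  iv <- utils::tail(iv, m)
  T_new <- stats::median(iv)
  list(T = T_new, omega = 2 * pi / T_new)
}

# Incremental controller engine. Kept internal so the offline runner and the
# closed-loop simulation share one code path. `n_hint` preallocates traces.
controller_init <- function(config, dt, t0 = 0, n_hint = 1024L) {
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$dt <- dt
  e$t0 <- t0
  e$T <- config$period
  e$omega <- 2 * pi / config$period
  e$co <- osc_coefficients(e$omega, dt)
  e$x <- 0
  e$xdot <- 0
  e$i <- 0L
  e$xdot_hist <- numeric(n_hint)
  e$xdot_del <- numeric(n_hint)
  e$sf <- numeric(n_hint)
  e$T_hist <- numeric(n_hint)
  e$omega_hist <- numeric(n_hint)
  e$fr_prev <- 0
  e$burst_times <- numeric(0)
  e$last_burst <- -Inf
  e$stim_times <- numeric(0)
  e$t_last_stim <- -Inf
  e
}

controller_grow <- function(e, n) {
  for (f in c("xdot_hist", "xdot_del", "sf", "T_hist", "omega_hist")) {
    v <- get(f, e)
    length(v) <- n
    assign(f, v, e)
  }
}

# consume one firing-rate sample at time t; returns TRUE when a stimulus
# is triggered at this step
controller_step <- function(e, fr_sample, t) {
  cfg <- e$config
  i <- e$i + 1L
  if (i > length(e$xdot_hist)) controller_grow(e, 2L * length(e$xdot_hist))

  # online burst detection (upward threshold crossing, debounced)
  if (fr_sample > cfg$burst_threshold && e$fr_prev <= cfg$burst_threshold &&
      (t - e$last_burst) >= cfg$burst_min_interval) {
    e$burst_times <- c(e$burst_times, t)
    e$last_burst <- t
    if (cfg$adaptive) {
      est <- update_period_estimate(e$burst_times, e$T, cfg$m_intervals)
      if (est$omega != e$omega) {
        e$omega <- est$omega
        e$co <- osc_coefficients(e$omega, e$dt)
      }
      e$T <- est$T
    }
  }
  e$fr_prev <- fr_sample

  # damped-oscillator filter (input scaling k = omega)
  u <- e$omega * fr_sample
  x_new <- e$co$a11 * e$x + e$co$a12 * e$xdot + e$co$b1 * u
  e$xdot <- e$co$a21 * e$x + e$co$a22 * e$xdot + e$co$b2 * u
  e$x <- x_new
  e$xdot_hist[i] <- e$xdot

  # half-period delayed output, linear interpolation, zeros before start
  tau <- (t - e$T / 2 - e$t0) / e$dt + 1   # fractional history index
  xd_del <- if (tau < 1) 0 else {
    j <- floor(tau)
    w <- tau - j
    a <- e$xdot_hist[j]
    b <- if (j + 1 <= i) e$xdot_hist[j + 1] else e$xdot_hist[j]
    (1 - w) * a + w * b
  }
  e$xdot_del[i] <- xd_del

  sf <- compute_actuation(e$xdot, xd_del, cfg$gain)
  if (cfg$positive_only) sf <- max(sf, 0)
  e$sf[i] <- sf
  e$T_hist[i] <- e$T
  e$omega_hist[i] <- e$omega
  e$i <- i

  fire <- should_stimulate(t, e$t_last_stim, sf, cfg)
  if (fire) {
    e$stim_times <- c(e$stim_times, t)
    e$t_last_stim <- t
  }
  fire
}

controller_finalize <- function(e, protocol) {
  i <- e$i
  idx <- seq_len(i)
  trace <- list(t = e$t0 + (idx - 1) * e$dt,
                xdot = e$xdot_hist[idx], xdot_delayed = e$xdot_del[idx],
                sf = e$sf[idx], T_history = e$T_hist[idx],
                omega_history = e$omega_hist[idx],
                burst_times = e$burst_times)
  class(trace) <- "controller_trace"
  list(schedule = stim_schedule(e$stim_times, e$config$amplitude, protocol),
       trace = trace)
}

#' @export
print.controller_trace <- function(x, ...) {
  cat(sprintf("<controller_trace> %d samples, %d bursts, final T = %.3g s\n",
              length(x$t), length(x$burst_times),
              utils::tail(x$T_history, 1)))
  invisible(x)
}

#' Run a delayed-feedback controller over a firing-rate stream
#'
#' Streams once through the samples of `fr` in time order (no lookahead:
#' the schedule up to time t depends only on samples at or before t).
#' Each sample is filtered by the damped oscillator, the half-period-delayed
#' output is subtracted to form the actuation signal, and stimuli are
#' emitted under the bounded trigger rule. Network bursts are detected
#' online by threshold crossing; when `config$adaptive` is set (aDFC) every
#' detected burst re-tunes the period T and natural frequency omega from
#' the recent inter-burst intervals.
#'
#' @param fr a [firing_rate()] signal (uniformly sampled).
#' @param config a [controller_config()].
#' @return list with `schedule` (a [stim_schedule()]) and `trace`
#'   (time grid, `xdot`, `xdot_delayed`, `sf`, `T_history`,
#'   `omega_history`, `burst_times`).
#' @examples
#' sts <- generate_bursting(bursting_model(n_channels = 8, period = 1,
#'                                         duration = 20, seed = 1))
#' fr <- firing_rate(sts)
#' res <- run_controller(fr, controller_config(gain = 5, period = 1.2))
#' res$schedule
#' @export
run_controller <- function(fr, config) {
  stopifnot(inherits(fr, "firing_rate"), inherits(config, "controller_config"))
  e <- controller_init(config, fr$dt, fr$t0, length(fr$values))
  for (i in seq_along(fr$values)) controller_step(e, fr$values[i], fr$t[i])
  controller_finalize(e, if (config$adaptive) "aDFC" else "DFC")
}

#' Poisson (random) stimulation schedule
#'
#' Open-loop control protocol: a homogeneous Poisson process of stimuli at
#' `rate` over `[0, duration]`. Used as the randomised comparison arm for
#' the feedback controllers, typically at the mean rate of a preceding
#' aDFC trial.
#'
#' @param rate mean stimulation frequency, Hz (>= 0).
#' @param duration schedule length, s.
#' @param seed RNG seed.
#' @param amplitude stimulus amplitude.
#' @return a [stim_schedule()] with protocol `"Poisson"`.
#' @export
generate_poisson_schedule <- function(rate, duration, seed = 1,
                                      amplitude = 1) {
  if (rate < 0) stop("rate must be nonnegative")
  if (rate == 0) return(stim_schedule(numeric(0), amplitude, "Poisson"))
  times <- with_seed(seed, {
    n <- stats::qpois(1 - 1e-12, rate * duration) + 10L
    tt <- cumsum(stats::rexp(n, rate))
    while (tt[length(tt)] < duration)
      tt <- c(tt, tt[length(tt)] + cumsum(stats::rexp(n, rate)))
    tt[tt <= duration]
  })
  stim_schedule(times, amplitude, "Poisson")
}
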
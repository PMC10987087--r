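#' Instantaneous population firing rate
#'
#' Counts spikes from active channels in a causal (trailing) square window of
#' width `window` ending at each sample, normalised to spikes per active
#' electrode per second. The causal alignment matches the real-time
#' constraint of the online controller: the value at time `t` uses only
#' spikes at or before `t`. The sample grid starts at `t_start` of the
#' recording and steps by `dt`.
#'
#' @param x a [spike_train_set()] with at least one active channel.
#' @param window smoothing window width in seconds (default 0.1 s).
#' @param dt sample interval in seconds; must not exceed `window`.
#' @return a `firing_rate` object: fields `values` (Hz), `dt`, `window`, `t0`
#'   and `t` (sample times).
#' @examples
#' sts <- spike_train_set(list(e1 = c(0.05)), 0, 1, activity_threshold = 0)
#' fr <- firing_rate(sts)
#' max(fr$values)  # 10 Hz: one spike / (1 electrode x 0.1 s)
#' @export
firing_rate <- function(x, window = 0.1, dt = 0.01) {
  stopifnot(inherits(x, "spike_train_set"))
  if (dt <= 0) stop("dt must be positive")
  if (window < dt) stop("window must be >= dt")
  na <- n_active(x)
  if (na == 0) stop("no active channels: cannot define a population rate")
  pooled <- sort(unlist(active_spikes(x), use.names = FALSE))
  t <- seq(x$t_start, x$t_end, by = dt)
  # spikes in (t - window, t]: cumulative counts at t minus at t - window;
  # the epsilon keeps grid-aligned spikes on a consistent side of the
  # boundary under floating-point arithmetic
  eps <- 1e-9
  counts <- findInterval(t + eps, pooled) - findInterval(t - window + eps, pooled)
  new_firing_rate(counts / (na * window), dt, window, x$t_start)
}

new_firing_rate <- function(values, dt, window, t0) {
  structure(list(values = as.numeric(values), dt = dt, window = window,
                 t0 = t0, t = t0 + (seq_along(values) - 1) * dt),
            class = "firing_rate")
}

#' @export
print.firing_rate <- function(x, ...) {
  cat(sprintf("<firing_rate> %d samples @ %g s, window %g s, mean %.3g Hz\n",
              length(x$values), x$dt, x$window, mean(x$values)))
  invisible(x)
}

#' Average firing rate of a recording
#'
#' Total spike count on active channels divided by the number of active
#' channels and the recording duration: the mean number of spikes per
#' electrode per second.
#'
#' @param x a [spike_train_set()].
#' @return rate in Hz per active electrode; 0 for a spike-free recording
#'   with active channels flagged.
#' @export
average_firing_rate <- function(x) {
  stopifnot(inherits(x, "spike_train_set"))
  if (duration(x) <= 0) stop("recording has zero duration")
  na <- n_active(x)
  if (na == 0) stop("no active channels")
  sum(vapply(active_spikes(x), length, 1L)) / (na * duration(x))
}

#' Detect network bursts in a firing-rate signal
#'
#' A network burst (NB) is a transient population-wide synchronous event.
#' One event is registered per upward crossing of `threshold` by the firing
#' rate; crossings closer than `min_interval` to the previously accepted
#' event are discarded, which debounces the detector against rate ripple on
#' the flank of a single burst.
#'
#' @param fr a [firing_rate()] signal.
#' @param threshold detection threshold in Hz (typically 10 Hz).
#' @param min_interval minimum spacing between accepted events, seconds.
#' @return a `burst_events` object: `times` (s), plus the parameters used.
#'   Empty `times` for a sub-threshold signal.
#' @export
detect_bursts <- function(fr, threshold = 10, min_interval = 0.1) {
  stopifnot(inherits(fr, "firing_rate"))
  if (threshold <= 0) stop("threshold must be positive")
  if (min_interval < 0) stop("min_interval must be nonnegative")
  above <- fr$values > threshold
  up <- which(above & !c(FALSE, above[-length(above)]))
  times <- fr$t[up]
  keep <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= min_interval) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  structure(list(times = keep, threshold = threshold,
                 min_interval = min_interval),
            class = "burst_events")
}

#' @export
print.burst_events <- function(x, ...) {
  cat(sprintf("<burst_events> %d events (threshold %g Hz, min interval %g s)\n",
              length(x$times), x$threshold, x$min_interval))
  invisible(x)
}
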
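#' Chi synchrony of a spike train set
#'
#' Variance-ratio synchrony of the population. Each active channel is turned
#' into a binary occupancy signal \eqn{V_i(t)}: 1 wherever a square box of
#' width `box_width` centred on any spike covers the sample, else 0, sampled
#' on a regular grid of step `grid_dt`. The measure compares the variance of
#' the population-mean signal with the mean per-channel variance,
#' \deqn{\chi^2 = \frac{\mathrm{Var}\left(\frac{1}{N}\sum_i V_i(t)\right)}
#'                    {\frac{1}{N}\sum_i \mathrm{Var}(V_i(t))},}
#' so it quantifies co-activation of channels while ignoring how many spikes
#' each channel contributes per activation. \eqn{\chi = 1} for identical
#' trains; for N independent trains \eqn{\chi \approx N^{-1/2}}; 0 when the
#' population mean is constant (perfectly interleaved activity).
#'
#' @param x a [spike_train_set()] with at least 2 active channels.
#' @param box_width occupancy box width in seconds (default 0.05 s).
#' @param grid_dt sampling grid for the binarised signals (default 1 ms).
#' @return chi in \[0, 1\] (up to numerical tolerance), with the squared
#'   value in attribute `"chi_sq"`. `NA` with a warning when every channel
#'   has zero variance (all silent or all saturated): synchrony is undefined
#'   there rather than a division by zero.
#' @export
chi_synchrony <- function(x, box_width = 0.05, grid_dt = 0.001) {
  stopifnot(inherits(x, "spike_train_set"))
  if (n_active(x) < 2) stop("chi synchrony needs >= 2 active channels")
  if (duration(x) <= box_width) stop("recording shorter than the occupancy box")
  t <- seq(x$t_start, x$t_end, by = grid_dt)
  n <- length(t)
  sp <- active_spikes(x)
  N <- length(sp)
  mean_sig <- numeric(n)
  var_sum <- 0
  for (s in sp) {
    v <- occupancy_signal(s, t, box_width / 2)
    mean_sig <- mean_sig + v
    var_sum <- var_sum + stats::var(v)
  }
  mean_sig <- mean_sig / N
  denom <- var_sum / N
  if (denom == 0) {
    warning("all channels have zero-variance occupancy; synchrony undefined")
    return(structure(NA_real_, chi_sq = NA_real_))
  }
  chi_sq <- stats::var(mean_sig) / denom
  structure(sqrt(chi_sq), chi_sq = chi_sq)
}

# binary occupancy of one spike train on grid t: 1 iff some spike lies
# within +/- half_width of the sample
occupancy_signal <- function(spikes, t, half_width) {
  if (!length(spikes)) return(numeric(length(t)))
  idx <- findInterval(t, spikes)               # last spike <= t
  prev_ok <- idx >= 1 & (t - spikes[pmax(idx, 1)]) <= half_width
  nxt <- pmin(idx + 1, length(spikes))
  next_ok <- idx < length(spikes) & (spikes[nxt] - t) <= half_width
  as.numeric(prev_ok | next_ok)
}

#' Firing rate and synchrony in sliding windows
#'
#' Evaluates the average firing rate and chi synchrony in a moving window,
#' the representation used for state clustering of multi-stable recordings.
#' Windows advance by `step` (half the window width is the conventional
#' choice); each row is stamped with the window centre.
#'
#' @param x a [spike_train_set()].
#' @param window window width in seconds; must not exceed the recording.
#' @param step window advance in seconds; defaults to `window / 2`.
#' @param box_width passed to [chi_synchrony()].
#' @return a data.frame with columns `t` (window centre, s), `firing_rate`
#'   (Hz), `synchrony`.
#' @export
sliding_window_metrics <- function(x, window, step = window / 2,
                                   box_width = 0.05) {
  stopifnot(inherits(x, "spike_train_set"))
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  if (window > duration(x)) stop("window longer than the recording")
  starts <- seq(x$t_start, x$t_end - window, by = step)
  rows <- lapply(starts, function(t0) {
    w <- crop_spikes(x, t0, t0 + window)
    data.frame(t = t0 + window / 2,
               firing_rate = average_firing_rate(w),
               synchrony = as.numeric(chi_synchrony(w, box_width)))
  })
  do.call(rbind, rows)
}
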
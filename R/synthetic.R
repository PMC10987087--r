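#' Quasiperiodic network-bursting model
#'
#' Parameter set of the synthetic spike-train generator that emulates the
#' statistical structure of cultured networks on multi-electrode arrays:
#' population-wide bursts recurring quasiperiodically (period in the
#' seconds range with Gaussian jitter), sparse background firing between
#' bursts, and partial channel participation per burst.
#'
#' @param n_channels number of recording channels.
#' @param period mean burst period T, s.
#' @param jitter_sd SD of Gaussian jitter on burst onsets, s.
#' @param burst_duration burst width, s (must be < period).
#' @param burst_rate within-burst per-channel firing rate, Hz.
#' @param background_rate per-channel rate outside bursts, Hz.
#' @param participation probability a channel takes part in a given burst.
#' @param duration recording length, s.
#' @param seed RNG seed.
#' @return a `bursting_model` list.
#' @export
bursting_model <- function(n_channels = 16, period = 1.5, jitter_sd = 0.05,
                           burst_duration = 0.25, burst_rate = 40,
                           background_rate = 0.5, participation = 0.9,
                           duration = 60, seed = 1) {
  if (any(c(burst_rate, background_rate) < 0)) stop("rates must be >= 0")
  if (burst_duration <= 0 || burst_duration >= period)
    stop("need 0 < burst_duration < period")
  if (participation < 0 || participation > 1)
    stop("participation must be in [0, 1]")
  structure(as.list(environment()), class = "bursting_model")
}

# Poisson spikes on [t0, t1] at constant rate (uses the current RNG stream)
poisson_spikes <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

#' Generate a quasiperiodic bursting recording
#'
#' Burst onsets are laid down every `period` seconds with Gaussian jitter
#' (sorted, so jitter never reorders onsets); during each burst the
#' participating channels fire as a Poisson process at `burst_rate`, and all
#' channels fire background Poisson spikes at `background_rate` throughout.
#' The rectangular burst envelope is the simplest shape that reproduces the
#' metrics' behaviour on real bursting cultures.
#'
#' @param model a [bursting_model()].
#' @return a [spike_train_set()], reproducible under the model seed.
#' @export
generate_bursting <- function(model) {
  stopifnot(inherits(model, "bursting_model"))
  with_seed(model$seed, {
    onsets <- generate_onsets(model$period, model$jitter_sd, model$duration)
    synth_spikes(model, onsets)
  })
}

generate_onsets <- function(period, jitter_sd, duration) {
  base <- seq(period / 2, duration, by = period)
  on <- sort(base + stats::rnorm(length(base), 0, jitter_sd))
  on[on >= 0 & on <= duration]
}

# shared spike-laying given burst onsets; assumes RNG already seeded
synth_spikes <- function(model, onsets) {
  sp <- vector("list", model$n_channels)
  for (ch in seq_len(model$n_channels)) {
    s <- poisson_spikes(model$background_rate, 0, model$duration)
    for (on in onsets) {
      if (stats::runif(1) <= model$participation) {
        s <- c(s, poisson_spikes(model$burst_rate, on,
                                 min(on + model$burst_duration,
                                     model$duration)))
      }
    }
    sp[[ch]] <- sort(s)
  }
  names(sp) <- sprintf("ch%02d", seq_len(model$n_channels))
  spike_train_set(sp, 0, model$duration, activity_threshold = 0)
}

#' Generate a multi-stable recording with ground-truth state labels
#'
#' Concatenates bursting regimes with stated dwell durations, emulating
#' networks that spontaneously transition between firing regimes (for
#' example synchronous bursting versus asynchronous sparse firing). The
#' returned labels give the true state timeline for validating state
#' clustering.
#'
#' @param models list of [bursting_model()] objects, one per regime; each
#'   model's `duration` is its dwell time.
#' @param seed RNG seed (overrides the per-model seeds).
#' @return list with `spikes` (a [spike_train_set()]) and `labels`
#'   (data.frame `state`, `t_start`, `t_end`).
#' @export
generate_multistable <- function(models, seed = 1) {
  if (length(models) < 2) stop("need >= 2 regimes")
  n_ch <- unique(vapply(models, function(m) m$n_channels, 1))
  if (length(n_ch) != 1) stop("all regimes must share n_channels")
  with_seed(seed, {
    offset <- 0
    sp <- replicate(n_ch, numeric(0), simplify = FALSE)
    labs <- NULL
    for (k in seq_along(models)) {
      m <- models[[k]]
      onsets <- generate_onsets(m$period, m$jitter_sd, m$duration)
      seg <- synth_spikes(m, onsets)
      for (ch in seq_len(n_ch))
        sp[[ch]] <- c(sp[[ch]], seg$spikes[[ch]] + offset)
      labs <- rbind(labs, data.frame(state = k, t_start = offset,
                                     t_end = offset + m$duration))
      offset <- offset + m$duration
    }
    names(sp) <- sprintf("ch%02d", seq_len(n_ch))
    list(spikes = spike_train_set(sp, 0, offset, activity_threshold = 0),
         labels = labs)
  })
}

#' Generate a bursting recording with linearly drifting period
#'
#' Burst period interpolates linearly from `T_start` to `T_end` over the
#' recording: a stress input for the fixed-delay controller, whose stimulus
#' phase sweeps the whole cycle when the rhythm drifts away from its preset
#' period, while the adaptive controller re-tunes and stays in antiphase.
#'
#' @param T_start,T_end initial and final burst periods, s (> 0).
#' @param duration recording length, s.
#' @param model a [bursting_model()] supplying the remaining parameters
#'   (its `period` and `duration` are ignored).
#' @return a [spike_train_set()].
#' @export
generate_drifting_period <- function(T_start, T_end, duration,
                                     model = bursting_model()) {
  if (T_start <= 0 || T_end <= 0) stop("periods must be positive")
  m <- model
  m$duration <- duration
  with_seed(m$seed, {
    onsets <- numeric(0)
    t <- T_start / 2
    while (t <= duration) {
      onsets <- c(onsets, t + stats::rnorm(1, 0, m$jitter_sd))
      t <- t + T_start + (T_end - T_start) * t / duration
    }
    onsets <- sort(onsets[onsets >= 0 & onsets <= duration])
    synth_spikes(m, onsets)
  })
}
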
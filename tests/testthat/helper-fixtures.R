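# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# N independent homogeneous Poisson trains (for synchrony scaling checks)
independent_trains <- function(n_channels, rate = 3, duration = 60,
                               seed = 1) {
  with_seed(seed, {
    sp <- replicate(n_channels,
                    sort(stats::runif(stats::rpois(1, rate * duration),
                                      0, duration)),
                    simplify = FALSE)
    names(sp) <- paste0("ch", seq_len(n_channels))
    spike_train_set(sp, 0, duration, activity_threshold = 0)
  })
}

# standard synchronous bursting fixture
bursting_fixture <- function(duration = 60, period = 1, jitter_sd = 0.02,
                             seed = 1, n_channels = 16) {
  generate_bursting(bursting_model(
    n_channels = n_channels, period = period, jitter_sd = jitter_sd,
    burst_duration = 0.2, burst_rate = 40, background_rate = 0.5,
    participation = 0.95, duration = duration, seed = seed))
}

# two-regime recording: synchronous bursting dwell, then an asynchronous
# regime with only weak residual bursting; regime variability (participation,
# period jitter) mirrors the scatter of real multi-stable cultures
multistable_fixture <- function(sync_s = 240, async_s = 60, seed = 3) {
  generate_multistable(list(
    bursting_model(n_channels = 16, period = 1.5, jitter_sd = 0.2,
                   burst_duration = 0.3, burst_rate = 30,
                   background_rate = 1, participation = 0.6,
                   duration = sync_s, seed = 1),
    bursting_model(n_channels = 16, period = 1.5, jitter_sd = 0.2,
                   burst_duration = 0.3, burst_rate = 4,
                   background_rate = 2.5, participation = 0.3,
                   duration = async_s, seed = 2)),
    seed = seed)
}

# null / separated controllability study tables
study_table <- function(sep_sd = 0, n_per = 3, seed = 1) {
  with_seed(seed, {
    mu <- rep(c(0, 1, 2) * sep_sd, each = n_per)
    data.frame(protocol = rep(c("DFC", "aDFC", "Poisson"), each = n_per),
               synchrony = stats::rnorm(3 * n_per, 1 + mu, 1),
               firing_rate = stats::rnorm(3 * n_per, 1 + mu, 1),
               oscillation_db = stats::rnorm(3 * n_per, mu, 1))
  })
}

# phase of stimuli relative to burst peaks of a T-periodic rhythm
stim_phases <- function(stim_times, burst_times, period_at,
                        burst_duration = 0.2) {
  ph <- vapply(stim_times, function(s) {
    prior <- burst_times[burst_times <= s]
    if (!length(prior)) return(NA_real_)
    peak <- max(prior) + burst_duration / 2
    Tt <- period_at(s)
    (2 * pi * (s - peak) / Tt) %% (2 * pi)
  }, numeric(1))
  ph[!is.na(ph)]
}

circular_mean <- function(ph) Arg(mean(exp(1i * ph))) %% (2 * pi)
circular_resultant <- function(ph) Mod(mean(exp(1i * ph)))

# independent spectral bookkeeping on the raw (unaveraged) periodogram:
# same SNR definition as oscillation_intensity(), different estimator and
# different code path
periodogram_snr_oracle <- function(x, fs, n_harmonics = 6) {
  xm <- x - mean(x)
  n <- length(xm)
  P <- abs(stats::fft(xm))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  half <- 2:floor(n / 2)
  lobe <- function(i) {
    lo <- i; while (lo > 2 && P[lo - 1] < P[lo]) lo <- lo - 1
    hi <- i; while (hi < max(half) && P[hi + 1] < P[hi]) hi <- hi + 1
    lo:hi
  }
  ifund <- half[which.max(P[half])]
  sig_idx <- lobe(ifund)
  excl <- c(2:4, sig_idx)
  for (h in 2:(n_harmonics + 1)) {
    ih <- which.min(abs(freq - h * freq[ifund]))
    excl <- c(excl, max(2, ih - 2):min(max(half), ih + 2))
  }
  ni <- setdiff(half, excl)
  10 * log10(sum(P[sig_idx]) / (sum(P[ni]) * length(half) / length(ni)))
}
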
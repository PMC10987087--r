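#' Welch power spectral density
#'
#' Averaged modified periodogram of a uniformly sampled signal: the signal is
#' split into segments of `nperseg` samples with `overlap` fractional
#' overlap, each segment is detrended by its mean, tapered with a Hann
#' window and transformed; the squared magnitudes are averaged and scaled to
#' a one-sided density. Defaults follow common practice when only the
#' estimator, not its parameters, is prescribed: segment length is one
#' eighth of the signal capped at 2048 samples, 50% overlap.
#'
#' @param values numeric signal samples.
#' @param fs sampling frequency, Hz.
#' @param nperseg segment length in samples.
#' @param overlap fractional overlap in \[0, 1).
#' @return list with `freq` (Hz), `psd` (power / Hz), and the parameters.
#' @export
welch_psd <- function(values, fs,
                      nperseg = min(floor(length(values) / 8), 2048L),
                      overlap = 0.5) {
  n <- length(values)
  if (nperseg < 8) stop("signal too short for Welch segmentation")
  if (nperseg > n) stop("signal shorter than one Welch segment")
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  if (length(starts) < 2) stop("signal too short for >= 2 Welch segments")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  scale <- fs * sum(w^2)
  nfreq <- nperseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- values[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / scale
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nperseg)
  dbl <- 2:(nfreq - if (nperseg %% 2 == 0) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_len(nfreq) - 1) * fs / nperseg, psd = psd,
       nperseg = nperseg, overlap = overlap, n_segments = length(starts))
}

#' Oscillation intensity of a firing-rate signal
#'
#' How rhythmic the population is: the signal-to-noise ratio (dB) of the
#' fundamental peak of the firing-rate power spectrum. The PSD is estimated
#' with [welch_psd()] on the mean-removed signal; the fundamental is the
#' frequency of the PSD maximum (DC excluded). SNR is the ratio of power in
#' the fundamental band to the noise power, where the noise excludes DC, the
#' fundamental and its first `n_harmonics` harmonics, each widened by
#' `guard_bins` bins on both sides so that spectral leakage of the excluded
#' lines does not count as noise.
#'
#' @param fr a [firing_rate()] signal, or a numeric vector with `fs` given.
#' @param fs sampling frequency (Hz) when `fr` is a bare vector.
#' @param n_harmonics harmonics (beyond the fundamental) excluded from the
#'   noise estimate; default 6.
#' @param guard_bins half-width, in PSD bins, of each excluded band.
#' @param nperseg,overlap passed to [welch_psd()].
#' @return list with `snr_db`, `fundamental_hz`, and `psd` (the Welch
#'   estimate with its parameters). A flat signal has no fundamental:
#'   `fundamental_hz = NA` and `snr_db = NA`.
#' @export
oscillation_intensity <- function(fr, fs = NULL, n_harmonics = 6,
                                  guard_bins = 1, nperseg = NULL,
                                  overlap = 0.5) {
  if (inherits(fr, "firing_rate")) {
    values <- fr$values
    fs <- 1 / fr$dt
  } else {
    values <- as.numeric(fr)
    if (is.null(fs)) stop("fs required for a bare numeric signal")
  }
  values <- values - mean(values)
  if (all(values == 0))
    return(list(snr_db = NA_real_, fundamental_hz = NA_real_, psd = NULL))
  if (is.null(nperseg)) nperseg <- min(floor(length(values) / 8), 2048L)
  p <- welch_psd(values, fs, nperseg, overlap)
  k <- length(p$psd)
  # a spectral line occupies its whole leakage lobe, not just the peak bin:
  # widen each excluded band from the centre bin out to the local minima of
  # the PSD (never less than guard_bins), so leakage does not count as noise
  band <- function(i) {
    lo <- i
    while (lo > 1 && (i - lo < guard_bins || p$psd[lo - 1] < p$psd[lo]))
      lo <- lo - 1
    hi <- i
    while (hi < k && (hi - i < guard_bins || p$psd[hi + 1] < p$psd[hi]))
      hi <- hi + 1
    lo:hi
  }
  dc_band <- band(1L)
  searchable <- setdiff(seq_len(k), dc_band)
  i_fund <- searchable[which.max(p$psd[searchable])]
  sig_idx <- band(i_fund)
  excl <- c(dc_band, sig_idx)
  f_fund <- p$freq[i_fund]
  for (h in seq_len(n_harmonics) + 1) {
    ih <- which.min(abs(p$freq - h * f_fund))
    if (abs(p$freq[ih] - h * f_fund) < p$freq[2] * (guard_bins + 1))
      excl <- c(excl, band(ih))
  }
  noise_idx <- setdiff(seq_len(k), unique(excl))
  sig_pow <- sum(p$psd[sig_idx])
  # total noise power over the whole band: excluded bins contribute at the
  # mean noise density (the classic SNR bookkeeping)
  noise_pow <- sum(p$psd[noise_idx]) * k / length(noise_idx)
  list(snr_db = 10 * log10(sig_pow / noise_pow),
       fundamental_hz = f_fund, psd = p)
}

#' Morlet wavelet spectrogram of a firing-rate signal
#'
#' Continuous wavelet transform magnitude over time and frequency using an
#' analytic Morlet wavelet (centre frequency `omega0 = 6` rad), evaluated in
#' the Fourier domain. Frequencies are logarithmically spaced over
#' `freq_range`, which by default spans 0.05-5 Hz -- the period range of
#' network bursts in the seconds scale. A periodic firing rate produces a
#' ridge at its fundamental frequency.
#'
#' @param fr a [firing_rate()] signal.
#' @param freq_range two frequencies (Hz) inside (0, Nyquist).
#' @param n_freq number of frequency bins.
#' @param omega0 Morlet centre frequency, rad.
#' @return a `wavelet_spectrogram`: `power` matrix (time x frequency),
#'   `t` (s), `freq` (Hz).
#' @export
wavelet_spectrogram <- function(fr, freq_range = c(0.05, 5), n_freq = 64,
                                omega0 = 6) {
  stopifnot(inherits(fr, "firing_rate"))
  fs <- 1 / fr$dt
  if (length(freq_range) != 2 || any(freq_range <= 0) ||
      any(freq_range >= fs / 2) || freq_range[2] <= freq_range[1])
    stop("freq_range must be increasing and inside (0, Nyquist)")
  x <- fr$values - mean(fr$values)
  n <- length(x)
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_freq))
  scales <- omega0 / (2 * pi * freqs)
  xf <- stats::fft(x)
  wk <- 2 * pi * fs * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  power <- matrix(0, n, n_freq)
  for (j in seq_len(n_freq)) {
    # analytic Morlet: support only on positive frequencies
    psi <- pi^(-0.25) * exp(-(scales[j] * wk - omega0)^2 / 2) * (wk > 0)
    wt <- stats::fft(xf * psi * sqrt(scales[j]), inverse = TRUE) / n
    power[, j] <- Mod(wt)
  }
  structure(list(power = power, t = fr$t, freq = freqs, omega0 = omega0),
            class = "wavelet_spectrogram")
}

#' @export
print.wavelet_spectrogram <- function(x, ...) {
  cat(sprintf("<wavelet_spectrogram> %d times x %d freqs (%.3g-%.3g Hz)\n",
              nrow(x$power), ncol(x$power), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Ridge of a wavelet spectrogram
#'
#' Frequency of maximal wavelet power at each time sample; the simplest
#' instantaneous-frequency readout of an oscillatory firing rate.
#'
#' @param ws a [wavelet_spectrogram()].
#' @return numeric vector of frequencies (Hz), one per time sample.
#' @export
spectrogram_ridge <- function(ws) {
  stopifnot(inherits(ws, "wavelet_spectrogram"))
  ws$freq[apply(ws$power, 1, which.max)]
}

#' All headline activity metrics of a recording
#'
#' Convenience wrapper computing the metric triplet used throughout the
#' analysis layer -- chi synchrony, average firing rate, and oscillation
#' intensity (with its fundamental frequency) -- from one spike train set.
#'
#' @param x a [spike_train_set()].
#' @param fr_window,fr_dt firing-rate estimation parameters (s).
#' @param box_width synchrony occupancy box (s).
#' @return list `synchrony`, `firing_rate_hz`, `oscillation_snr_db`,
#'   `fundamental_hz`.
#' @export
activity_metrics <- function(x, fr_window = 0.1, fr_dt = 0.01,
                             box_width = 0.05) {
  fr <- firing_rate(x, fr_window, fr_dt)
  osc <- tryCatch(oscillation_intensity(fr),
                  error = function(e) list(snr_db = NA_real_,
                                           fundamental_hz = NA_real_))
  list(synchrony = as.numeric(chi_synchrony(x, box_width)),
       firing_rate_hz = average_firing_rate(x),
       oscillation_snr_db = osc$snr_db,
       fundamental_hz = osc$fundamental_hz)
}
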
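#' Metrics of one OFF-ON-OFF stimulation trial
#'
#' The unit experiment: a pre-stimulation baseline (OFF), a stimulation
#' epoch (ON) and a post-stimulation recovery (OFF). Computes the headline
#' metric triplet -- chi synchrony, average firing rate, oscillation
#' intensity -- for each segment of an annotated recording.
#'
#' @param x a [spike_train_set()] covering all three segments.
#' @param segments list of `c(start, end)` (seconds) named `off_pre`, `on`,
#'   `off_post`; all three must lie inside the recording.
#' @param protocol protocol label carried into the result.
#' @param ... passed to [activity_metrics()].
#' @return a `trial_result`: `protocol` and one metrics list per segment.
#' @export
run_protocol_trial <- function(x, segments, protocol = "aDFC", ...) {
  stopifnot(inherits(x, "spike_train_set"))
  need <- c("off_pre", "on", "off_post")
  if (!all(need %in% names(segments)))
    stop("segments must name off_pre, on, off_post")
  for (s in need) {
    b <- segments[[s]]
    if (length(b) != 2 || b[1] < x$t_start - 1e-9 || b[2] > x$t_end + 1e-9)
      stop("segment `", s, "` not covered by the recording")
  }
  out <- list(protocol = protocol,
              metrics = lapply(segments[need], function(b)
                activity_metrics(crop_spikes(x, b[1], b[2]), ...)))
  class(out) <- "trial_result"
  out
}

#' Normalise trial metrics to the pre-stimulation baseline
#'
#' Synchrony and firing rate are expressed as ratios to the OFF-pre value;
#' oscillation intensity, being in dB (a log scale), as the difference.
#' The identity trial maps to (1, 1, 0). Applied to both the ON and the
#' OFF-post segments.
#'
#' @param trial a [run_protocol_trial()] result, or a list with `metrics`
#'   holding `off_pre`, `on`, `off_post` metric lists.
#' @return list with `on` and `off_post`, each holding `synchrony` and
#'   `firing_rate` ratios and `oscillation_db` difference, plus
#'   `fundamental_ratio` (oscillation-frequency fold change) when both
#'   fundamentals exist.
#' @export
fold_change <- function(trial) {
  m <- trial$metrics
  base <- m$off_pre
  if (is.na(base$synchrony) || base$synchrony <= 0 ||
      base$firing_rate_hz <= 0)
    stop("pre-stimulation synchrony and firing rate must be positive")
  rel <- function(seg) list(
    synchrony = seg$synchrony / base$synchrony,
    firing_rate = seg$firing_rate_hz / base$firing_rate_hz,
    oscillation_db = seg$oscillation_snr_db - base$oscillation_snr_db,
    fundamental_ratio =
      if (!is.na(seg$fundamental_hz) && !is.na(base$fundamental_hz) &&
          base$fundamental_hz > 0)
        seg$fundamental_hz / base$fundamental_hz else NA_real_)
  list(on = rel(m$on), off_post = rel(m$off_post))
}

#' Classify a network as controllable or uncontrollable
#'
#' A network is controllable when different stimulation protocols drive it
#' to statistically different regions of the metric space. The test is a
#' one-way MANOVA (Wilks' lambda) of the per-trial normalised ON metrics
#' (synchrony and firing-rate fold changes, oscillation-intensity
#' difference) with protocol as the factor; `p < alpha` labels the network
#' controllable. At least three trials of each protocol are required.
#'
#' @param trials data.frame with columns `protocol`, `synchrony`,
#'   `firing_rate`, `oscillation_db` -- one row per trial, normalised ON
#'   values (see [fold_change()]).
#' @param alpha significance level (default 0.05).
#' @param min_trials minimum trials per protocol (default 3).
#' @return list `p_value`, `label` (`"controllable"` /
#'   `"uncontrollable"`), `statistic` (approximate F), `alpha`.
#' @export
classify_controllability <- function(trials, alpha = 0.05, min_trials = 3) {
  need <- c("protocol", "synchrony", "firing_rate", "oscillation_db")
  if (!all(need %in% names(trials))) stop("missing columns in `trials`")
  counts <- table(trials$protocol)
  if (length(counts) < 2)
    stop("need at least two stimulation protocols")
  if (any(counts < min_trials))
    stop("every protocol needs >= ", min_trials, " trials")
  y <- as.matrix(trials[, c("synchrony", "firing_rate", "oscillation_db")])
  fit <- stats::manova(y ~ factor(trials$protocol))
  sm <- summary(fit, test = "Wilks")$stats
  p <- sm[1, "Pr(>F)"]
  list(p_value = unname(p),
       label = if (p < alpha) "controllable" else "uncontrollable",
       statistic = unname(sm[1, "approx F"]), alpha = alpha)
}

#' Project baseline dynamics on their first principal component
#'
#' Summarises where each experiment's spontaneous activity sits along the
#' dominant axis of baseline dynamics: both features (baseline synchrony
#' and firing rate) are z-scored and projected on the first principal
#' component. The sign is fixed so that PC1 loads positively on firing
#' rate, making scores comparable across datasets.
#'
#' @param baseline data.frame with columns `synchrony` and `firing_rate`,
#'   one row per experiment (>= 2 rows).
#' @return list `scores` (PC1 projection per row), `loadings`,
#'   `var_explained` (fraction of variance on PC1).
#' @export
baseline_pc1_projection <- function(baseline) {
  if (nrow(baseline) < 2) stop("need >= 2 experiments")
  feats <- baseline[, c("synchrony", "firing_rate")]
  if (any(vapply(feats, stats::sd, 1) == 0))
    stop("zero-variance feature: PC1 undefined")
  pc <- stats::prcomp(feats, center = TRUE, scale. = TRUE)
  flip <- if (pc$rotation["firing_rate", 1] < 0) -1 else 1
  list(scores = flip * pc$x[, 1],
       loadings = flip * pc$rotation[, 1],
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Cluster network states from sliding-window metrics
#'
#' Identifies the firing regimes a recording visits by fitting Gaussian
#' mixture models to the (firing rate, synchrony) window table, choosing
#' the number of components (1 to `max_components`) by BIC. Clusters with
#' mean synchrony below `as_synchrony` and mean firing rate below the
#' recording average are flagged as the asynchronous state (AS) -- the
#' desynchronised, low-rate regime that stimulation aims to reach.
#' The fit uses model-based agglomerative initialisation (deterministic
#' given the data), with EM started from `n_init` deterministic
#' random restarts seeded from `seed`; the best log-likelihood wins.
#'
#' @param windows data.frame from [sliding_window_metrics()] (columns `t`,
#'   `firing_rate`, `synchrony`; >= 10 rows).
#' @param max_components largest mixture size tried.
#' @param n_init extra random EM restarts per component count.
#' @param seed RNG seed for the restarts.
#' @param as_synchrony AS synchrony threshold (default 0.5).
#' @return a `state_clustering`: `windows` (input plus `cluster` and
#'   `as` columns), `centroids` (per-cluster mean synchrony / firing rate,
#'   `as` flag), `n_components`, `bic` (per component count), `model`.
#' @importFrom mclust Mclust mclustBIC me map nMclustParams
#' @export
cluster_network_states <- function(windows, max_components = 4, n_init = 10,
                                   seed = 1, as_synchrony = 0.5) {
  windows <- windows[stats::complete.cases(
    windows[, c("firing_rate", "synchrony")]), ]
  if (nrow(windows) < 10) stop("need >= 10 complete windows")
  dat <- windows[, c("firing_rate", "synchrony")]
  fit <- with_seed(seed, {
    best <- mclust::Mclust(dat, G = 1:max_components, modelNames = "VVV",
                           verbose = FALSE)
    # extra random-restart EMs; keep whichever beats the default init by BIC
    for (G in 1:max_components) {
      for (r in seq_len(n_init)) {
        z <- matrix(stats::runif(nrow(dat) * G), ncol = G)
        z <- z / rowSums(z)
        me <- tryCatch(
          mclust::me(data = dat, modelName = "VVV", z = z),
          error = function(e) NULL)
        if (!is.null(me) && !is.na(me$loglik)) {
          df_r <- mclust::nMclustParams("VVV", d = 2, G = G)
          bic_r <- 2 * me$loglik - df_r * log(nrow(dat))
          if (bic_r > best$bic) {
            cl <- mclust::map(me$z)
            best$bic <- bic_r
            best$G <- G
            best$classification <- cl
            best$parameters <- me$parameters
            best$z <- me$z
          }
        }
      }
    }
    best
  })
  cl <- fit$classification
  mean_fr_all <- mean(windows$firing_rate)
  cents <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    data.frame(cluster = k,
               synchrony = mean(windows$synchrony[cl == k]),
               firing_rate = mean(windows$firing_rate[cl == k]))
  }))
  cents$as <- cents$synchrony < as_synchrony & cents$firing_rate < mean_fr_all
  windows$cluster <- cl
  windows$as <- cents$as[match(cl, cents$cluster)]
  structure(list(windows = windows, centroids = cents,
                 n_components = fit$G, bic = fit$BIC, model = fit),
            class = "state_clustering")
}

#' @export
print.state_clustering <- function(x, ...) {
  cat(sprintf("<state_clustering> %d windows, %d components, %d AS cluster(s)\n",
              nrow(x$windows), x$n_components, sum(x$centroids$as)))
  invisible(x)
}

#' Width of the state-clustering window from burst periodicity
#'
#' The conventional clustering window spans five periodic events: five
#' times the median inter-burst interval of the recording. Burst-free
#' recordings fall back to a fixed window.
#'
#' @param x a [spike_train_set()].
#' @param threshold,min_interval burst detection parameters.
#' @param n_events events per window (default 5).
#' @param fallback window for burst-free recordings, s.
#' @return window width in seconds.
#' @export
clustering_window_width <- function(x, threshold = 10, min_interval = 0.1,
                                    n_events = 5, fallback = 10) {
  fr <- firing_rate(x)
  b <- detect_bursts(fr, threshold, min_interval)
  if (length(b$times) < 2) {
    message("no periodic events detected; using the fallback window of ",
            fallback, " s")
    return(fallback)
  }
  n_events * stats::median(diff(b$times))
}

#' Percentage of time spent in the asynchronous state
#'
#' Assigns clustered windows to trial segments by their centre time and
#' reports, per segment, the percentage of window time labelled AS.
#'
#' @param clustering a [cluster_network_states()] result.
#' @param segments named list of `c(start, end)` in seconds.
#' @return named numeric vector of percentages; `NA` for a segment that
#'   contains no window centre.
#' @export
time_in_asynchronous_state <- function(clustering, segments) {
  stopifnot(inherits(clustering, "state_clustering"))
  w <- clustering$windows
  vapply(segments, function(b) {
    inside <- w$t >= b[1] & w$t < b[2]
    if (!any(inside)) return(NA_real_)
    100 * mean(w$as[inside])
  }, numeric(1))
}
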
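test_that("trial metrics are near-identical for statistically identical segments", {
  sts <- bursting_fixture(duration = 90, seed = 21)
  tr <- run_protocol_trial(sts, list(off_pre = c(0, 30), on = c(30, 60),
                                     off_post = c(60, 90)))
  m <- tr$metrics
  expect_equal(m$on$synchrony, m$off_pre$synchrony, tolerance = 0.15)
  expect_equal(m$on$firing_rate_hz, m$off_pre$firing_rate_hz,
               tolerance = 0.15 * m$off_pre$firing_rate_hz)
  expect_error(run_protocol_trial(sts, list(off_pre = c(0, 30),
                                            on = c(30, 60),
                                            off_post = c(60, 120))),
               "not covered")
  expect_error(run_protocol_trial(sts, list(off_pre = c(0, 30),
                                            on = c(30, 90))),
               "off_post")
})

test_that("a desynchronised ON segment shows up in the trial contrast", {
  sync <- bursting_model(n_channels = 16, period = 1, jitter_sd = 0.02,
                         burst_duration = 0.2, burst_rate = 40,
                         background_rate = 0.5, duration = 60, seed = 1)
  async <- bursting_model(n_channels = 16, period = 1, burst_rate = 0.001,
                          background_rate = 4, participation = 0,
                          duration = 60, seed = 2)
  ms <- generate_multistable(list(sync, async, sync), seed = 5)
  tr <- run_protocol_trial(ms$spikes, list(off_pre = c(0, 60),
                                           on = c(60, 120),
                                           off_post = c(120, 180)))
  expect_lt(tr$metrics$on$synchrony, tr$metrics$off_pre$synchrony)
  expect_lt(tr$metrics$on$oscillation_snr_db,
            tr$metrics$off_pre$oscillation_snr_db)
  fc <- fold_change(tr)
  expect_lt(fc$on$synchrony, 0.7)
  expect_lt(fc$on$oscillation_db, 0)
})

test_that("fold change is ratio for synchrony/rate and difference in dB", {
  mk <- function(s, f, o) list(synchrony = s, firing_rate_hz = f,
                               oscillation_snr_db = o,
                               fundamental_hz = 1)
  trial <- list(metrics = list(off_pre = mk(0.6, 2, 12), on = mk(0.3, 1, 5),
                               off_post = mk(0.6, 2, 12)))
  fc <- fold_change(trial)
  expect_equal(fc$on$synchrony, 0.5)
  expect_equal(fc$on$firing_rate, 0.5)
  expect_equal(fc$on$oscillation_db, -7)
  expect_equal(fc$off_post$synchrony, 1)
  expect_equal(fc$off_post$oscillation_db, 0)
  bad <- list(metrics = list(off_pre = mk(0, 2, 12), on = mk(0.3, 1, 5),
                             off_post = mk(0.6, 2, 12)))
  expect_error(fold_change(bad), "positive")
})

test_that("controllability MANOVA keeps its nominal type-I error", {
  p <- vapply(1:400, function(s)
    classify_controllability(study_table(sep_sd = 0, seed = s))$p_value,
    numeric(1))
  rate <- mean(p < 0.05)
  ci <- 0.05 + c(-1, 1) * 2.58 * sqrt(0.05 * 0.95 / 400)
  expect_gt(rate, ci[1])
  expect_lt(rate, ci[2])
})

test_that("well-separated protocols are declared controllable", {
  hits <- vapply(1:50, function(s)
    classify_controllability(study_table(sep_sd = 5, seed = s))$p_value < 0.05,
    logical(1))
  expect_gte(mean(hits), 0.95)
  res <- classify_controllability(study_table(sep_sd = 5, seed = 1))
  expect_equal(res$label, "controllable")
})

test_that("insufficient trials are an explicit error", {
  tab <- study_table(seed = 1)[-1, ]  # one protocol down to 2 trials
  expect_error(classify_controllability(tab), ">= 3")
  expect_error(classify_controllability(study_table(seed = 1)[1:3, ]),
               "two stimulation protocols")
})

test_that("PC1 projection standardises, orients, and errors on degeneracy", {
  set.seed(2)
  base <- data.frame(synchrony = rnorm(20, 0.5, 0.1))
  base$firing_rate <- 3 * base$synchrony + 1  # perfectly correlated
  pr <- baseline_pc1_projection(base)
  expect_equal(pr$var_explained, 1, tolerance = 1e-9)
  expect_gt(pr$loadings["firing_rate"], 0)
  # affine rescaling of raw features leaves scores unchanged
  resc <- data.frame(synchrony = 10 * base$synchrony - 2,
                     firing_rate = 0.1 * base$firing_rate + 7)
  expect_equal(baseline_pc1_projection(resc)$scores, pr$scores,
               tolerance = 1e-9)
  expect_error(baseline_pc1_projection(base[1, , drop = FALSE]), ">= 2")
  base$firing_rate <- 1
  expect_error(baseline_pc1_projection(base), "zero-variance")
})

test_that("a bimodal baseline places the middle group between the extremes", {
  set.seed(3)
  grp <- rep(c("low", "mid", "high"), each = 10)
  centre <- c(low = -3, mid = 0, high = 3)[grp]
  base <- data.frame(synchrony = centre + rnorm(30, 0, 0.5),
                     firing_rate = centre + rnorm(30, 0, 0.5))
  sc <- baseline_pc1_projection(base)$scores
  expect_lt(max(sc[grp == "low"]), min(sc[grp == "mid"]) + 1)
  expect_gt(min(sc[grp == "high"]), max(sc[grp == "mid"]) - 1)
  expect_lt(mean(sc[grp == "low"]), mean(sc[grp == "mid"]))
  expect_gt(mean(sc[grp == "high"]), mean(sc[grp == "mid"]))
})

test_that("planted two-state recordings are recovered by GMM/BIC", {
  ms <- multistable_fixture(sync_s = 240, async_s = 60, seed = 3)
  w <- clustering_window_width(ms$spikes)
  wm <- sliding_window_metrics(ms$spikes, w)
  cl <- cluster_network_states(wm, seed = 4)
  expect_equal(cl$n_components, 2)
  expect_equal(sum(cl$centroids$as), 1)
  # label agreement with the planted timeline
  truth <- ifelse(cl$windows$t < 240, FALSE, TRUE)  # async regime second
  expect_gt(mean(truth == cl$windows$as), 0.95)
  # dwell estimate within one window width of the planted 20%
  est <- time_in_asynchronous_state(cl, list(all = c(0, 300)))
  expect_lt(abs(est[["all"]] - 20), 100 * w / 300)
})

test_that("homogeneous data select one component", {
  set.seed(6)
  wm <- data.frame(t = seq_len(200), firing_rate = rnorm(200, 5, 0.3),
                   synchrony = rnorm(200, 0.6, 0.03))
  cl <- cluster_network_states(wm, seed = 7)
  expect_equal(cl$n_components, 1)
  expect_error(cluster_network_states(wm[1:5, ]), ">= 10")
})

test_that("AS flag needs both low synchrony and below-average rate", {
  set.seed(8)
  mk <- function(n, fr, sy) data.frame(t = seq_len(n),
                                       firing_rate = rnorm(n, fr, 0.1),
                                       synchrony = rnorm(n, sy, 0.02))
  # low-synchrony but HIGH-rate cluster: not AS
  wm <- rbind(mk(60, 1, 0.8), mk(60, 8, 0.3))
  wm$t <- seq_len(nrow(wm))
  cl <- cluster_network_states(wm, seed = 9)
  expect_equal(sum(cl$centroids$as), 0)
  # low-synchrony low-rate cluster: AS
  wm2 <- rbind(mk(60, 8, 0.8), mk(60, 1, 0.3))
  wm2$t <- seq_len(nrow(wm2))
  cl2 <- cluster_network_states(wm2, seed = 10)
  expect_equal(sum(cl2$centroids$as), 1)
  expect_true(cl2$centroids$as[which.min(cl2$centroids$synchrony)])
})

test_that("time in AS is segment-resolved and order-invariant", {
  ms <- multistable_fixture(sync_s = 120, async_s = 120, seed = 11)
  wm <- sliding_window_metrics(ms$spikes, 10, 5)
  cl <- cluster_network_states(wm, seed = 12)
  segs <- list(first = c(0, 120), second = c(120, 240), empty = c(500, 600))
  pct <- time_in_asynchronous_state(cl, segs)
  expect_lt(pct[["first"]], 20)
  expect_gt(pct[["second"]], 80)
  expect_true(is.na(pct[["empty"]]))
  # permuting window order changes nothing
  cl2 <- cluster_network_states(wm[sample(nrow(wm)), ], seed = 12)
  expect_equal(sort(cl2$centroids$synchrony), sort(cl$centroids$synchrony),
               tolerance = 1e-6)
})
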
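#' Spike train sets
#'
#' A `spike_train_set` holds per-channel spike timestamps over a recording
#' window. It is the universal input of the package: multi-electrode array
#' recordings, simulated networks (neurons as channels) and synthetic
#' generators all produce one. Channels whose mean firing rate falls below
#' `activity_threshold` are flagged inactive and excluded from population
#' metrics, mirroring the usual practice of only monitoring electrodes with
#' appreciable activity.
#'
#' @param spikes named list of numeric vectors, one per channel, each a
#'   nondecreasing vector of spike times in seconds.
#' @param t_start,t_end recording window (seconds); spikes must lie inside.
#' @param activity_threshold minimum mean rate (Hz) for a channel to count
#'   as active. Default 0.1 Hz.
#' @return an object of class `spike_train_set` with fields `spikes`,
#'   `channels`, `t_start`, `t_end`, `active` (logical per channel).
#' @examples
#' sts <- spike_train_set(list(e1 = c(0.1, 0.5), e2 = numeric(0)),
#'                        t_start = 0, t_end = 1)
#' n_active(sts)
#' @export
spike_train_set <- function(spikes, t_start, t_end, activity_threshold = 0.1) {
  if (!is.list(spikes)) stop("`spikes` must be a list of numeric vectors")
  if (!is.numeric(t_start) || !is.numeric(t_end) || t_end <= t_start)
    stop("need t_end > t_start")
  if (is.null(names(spikes)) || any(!nzchar(names(spikes))))
    names(spikes) <- paste0("ch", seq_along(spikes))
  spikes <- lapply(spikes, function(s) {
    s <- as.numeric(s)
    if (is.unsorted(s)) stop("per-channel spike times must be nondecreasing")
    if (length(s) && (s[1] < t_start || s[length(s)] > t_end))
      stop("spike times outside [t_start, t_end]")
    s
  })
  duration <- t_end - t_start
  rates <- vapply(spikes, length, 1L) / duration
  structure(
    list(spikes = spikes, channels = names(spikes),
         t_start = t_start, t_end = t_end,
         active = rates > activity_threshold,
         activity_threshold = activity_threshold),
    class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d channels (%d active), %.6g-%.6g s, %d spikes\n",
              length(x$channels), sum(x$active), x$t_start, x$t_end,
              sum(vapply(x$spikes, length, 1L))))
  invisible(x)
}

#' @rdname spike_train_set
#' @param x a `spike_train_set`.
#' @export
n_active <- function(x) sum(x$active)

#' @rdname spike_train_set
#' @export
duration <- function(x) x$t_end - x$t_start

# spikes of active channels only, as a list
active_spikes <- function(x) x$spikes[x$active]

#' Restrict a spike train set to a time window
#'
#' Returns a new `spike_train_set` over `[t0, t1]` containing the spikes that
#' fall in the window. The active-channel flags of the parent recording are
#' kept (activity is a property of the whole recording, not of the window),
#' so windowed metrics stay comparable across windows.
#'
#' @param x a `spike_train_set`.
#' @param t0,t1 window bounds in seconds.
#' @return a `spike_train_set`.
#' @export
crop_spikes <- function(x, t0, t1) {
  if (t1 <= t0) stop("need t1 > t0")
  out <- x
  out$spikes <- lapply(x$spikes, function(s) s[s >= t0 & s <= t1])
  out$t_start <- t0
  out$t_end <- t1
  out
}

#' Read / write spike trains as CSV
#'
#' The on-disk format is one spike per row with a `channel,time_s` header.
#' `read_spikes_csv()` validates per-channel monotonicity; the recording
#' window defaults to `[0, max spike time]` when not given. Channels present
#' in `channels` but absent from the file get empty spike vectors, so silent
#' electrodes survive a round trip.
#'
#' @param path CSV file path.
#' @param t_start,t_end recording window; `t_end = NA` uses the last spike.
#' @param channels optional character vector of channel names fixing the
#'   channel set and order.
#' @param activity_threshold passed to [spike_train_set()].
#' @return `read_spikes_csv()` a `spike_train_set`; `write_spikes_csv()` the
#'   path, invisibly.
#' @export
read_spikes_csv <- function(path, t_start = 0, t_end = NA,
                            channels = NULL, activity_threshold = 0.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "time_s") %in% names(df)))
    stop("spike CSV needs columns `channel,time_s`")
  if (is.na(t_end))
    t_end <- if (nrow(df)) max(df$time_s) else t_start + 1
  sp <- split(df$time_s, factor(df$channel,
                                levels = channels %||% sort(unique(df$channel))))
  sp <- lapply(sp, function(s) sort(as.numeric(s)))
  spike_train_set(sp, t_start, t_end, activity_threshold)
}

#' @rdname read_spikes_csv
#' @param x a `spike_train_set`.
#' @export
write_spikes_csv <- function(x, path) {
  df <- data.frame(
    channel = rep(x$channels, vapply(x$spikes, length, 1L)),
    time_s = unlist(x$spikes, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reproducible RNG scoping: run code under a seed, restore global state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
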
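#' Izhikevich network configuration
#'
#' Parameters of the in silico testbed: an all-to-all network of Izhikevich
#' neurons mixing regular-spiking (RS) excitatory cells
#' (a=0.02, b=0.2, c=-65, d=8) and fast-spiking (FS) inhibitory cells
#' (a=0.1, b=0.2, c=-65, d=2). Base synaptic weights are drawn uniformly
#' (excitatory columns on \[0, 0.5\], inhibitory on \[-1, 0\]) and scaled by
#' `weight_scale`; the excitatory fraction and the weight scale are the two
#' axes along which network synchrony -- and with it controllability --
#' varies. Each neuron receives independent Gaussian noise drive per step
#' (SD `noise_exc` for RS, `noise_inh` for FS, the conventional thalamic
#' input of the reference network). A random pool of `n_stim` neurons
#' receives the stimulation current.
#'
#' @param n_neurons network size (reference condition 1000).
#' @param frac_exc excitatory fraction in \[0, 1\] (reference 0.8).
#' @param weight_scale multiplier on the base weight matrix.
#' @param n_stim stimulated-pool size (reference 100).
#' @param stim_amplitude stimulation current per pulse, model units
#'   (reference 20).
#' @param noise_exc,noise_inh per-step noise SD for RS / FS neurons.
#' @param dt integration step, ms (1 ms, with two half-updates of v).
#' @param self_connections keep the diagonal of the weight matrix? Excluded
#'   by default.
#' @param seed RNG seed for weights and pool selection.
#' @return an `izh_config` list.
#' @export
izh_config <- function(n_neurons = 1000, frac_exc = 0.8, weight_scale = 1,
                       n_stim = 100, stim_amplitude = 20,
                       noise_exc = 5, noise_inh = 2, dt = 1,
                       self_connections = FALSE, seed = 1) {
  if (frac_exc < 0 || frac_exc > 1) stop("frac_exc must be in [0, 1]")
  if (n_stim > n_neurons) stop("n_stim cannot exceed n_neurons")
  if (dt <= 0 || dt > 1) stop("dt must be in (0, 1] ms")
  if (weight_scale < 0) stop("weight_scale must be nonnegative")
  structure(as.list(environment()), class = "izh_config")
}

#' Build an Izhikevich network
#'
#' Assigns `floor(frac_exc * n)` RS neurons and the remainder FS, draws the
#' signed all-to-all weight matrix (rows postsynaptic; excitatory columns
#' nonnegative, inhibitory nonpositive), scales it, zeroes the diagonal
#' unless self connections are requested, samples the stimulated pool
#' without replacement, and initialises the membrane state at
#' `v = c`, `u = b v`.
#'
#' @param config an [izh_config()].
#' @return an `izh_network` with fields `v`, `u`, `a`, `b`, `c`, `d`, `S`,
#'   `exc_mask`, `stim_set`, `fired` (logical: crossed threshold on the
#'   last step), `t_ms`, `config`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "izh_config"))
  n <- config$n_neurons
  ne <- floor(config$frac_exc * n)
  exc <- c(rep(TRUE, ne), rep(FALSE, n - ne))
  with_seed(config$seed, {
    S <- matrix(0, n, n)
    if (ne > 0) S[, seq_len(ne)] <- 0.5 * stats::runif(n * ne)
    if (ne < n) S[, (ne + 1):n] <- -stats::runif(n * (n - ne))
    if (!config$self_connections) diag(S) <- 0
    S <- S * config$weight_scale
    stim_set <- sample.int(n, config$n_stim)
    a <- ifelse(exc, 0.02, 0.1)
    b <- rep(0.2, n)
    cc <- rep(-65, n)
    d <- ifelse(exc, 8, 2)
    structure(list(v = cc, u = b * cc, a = a, b = b, c = cc, d = d,
                   S = S, exc_mask = exc, stim_set = stim_set,
                   fired = rep(FALSE, n), t_ms = 0, config = config),
              class = "izh_network")
  })
}

#' @export
print.izh_network <- function(x, ...) {
  cat(sprintf("<izh_network> %d neurons (%d exc), weight scale %g, %d in stim pool\n",
              length(x$v), sum(x$exc_mask), x$config$weight_scale,
              length(x$stim_set)))
  invisible(x)
}

#' Stimulation current vector for one step
#'
#' Returns the per-neuron external current of a single pulse: `amplitude`
#' on the stimulated pool, zero elsewhere. The input is instantaneous --
#' applied for exactly the step it is passed to -- so consecutive pulses do
#' not accumulate.
#'
#' @param net an [build_network()] result.
#' @param amplitude current amplitude in model units.
#' @return numeric vector of length `n_neurons`.
#' @export
apply_stimulus <- function(net, amplitude) {
  cur <- numeric(length(net$v))
  cur[net$stim_set] <- amplitude
  cur
}

#' Advance an Izhikevich network one step
#'
#' One `dt` of the quadratic integrate-and-reset dynamics: neurons that
#' reached `v >= 30` mV on the previous update emit a spike and reset
#' (`v <- c`, `u <- u + d`); the input current of every neuron is its
#' Gaussian noise drive plus the external current plus the sum of the
#' weight-matrix columns of the neurons that just fired; `v` advances with
#' two half-steps of `v' = 0.04 v^2 + 5 v + 140 - u + I` (numerical
#' stabilisation of the quadratic term), and `u` with `u' = a (b v - u)`.
#' Uses the current RNG stream for the noise.
#'
#' @param net an `izh_network`.
#' @param external_current per-neuron current vector (or 0).
#' @return list with `net` (advanced) and `fired` (integer indices of the
#'   neurons that spiked on this step).
#' @export
step_network <- function(net, external_current = 0) {
  n <- length(net$v)
  fired <- which(net$v >= 30)
  if (length(fired)) {
    net$v[fired] <- net$c[fired]
    net$u[fired] <- net$u[fired] + net$d[fired]
  }
  I <- stats::rnorm(n, 0, ifelse(net$exc_mask, net$config$noise_exc,
                                 net$config$noise_inh)) + external_current
  if (length(fired))
    I <- I + rowSums(net$S[, fired, drop = FALSE])
  dt <- net$config$dt
  v <- net$v
  u <- net$u
  v <- v + 0.5 * dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  v <- v + 0.5 * dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  u <- u + dt * net$a * (net$b * v - u)
  if (any(!is.finite(v)))
    stop("non-finite membrane potential: unstable parameters (weight scale ",
         net$config$weight_scale, ")")
  net$v <- v
  net$u <- u
  net$t_ms <- net$t_ms + dt
  list(net = net, fired = fired)
}

#' Closed-loop simulation: stabilise, spontaneous, stimulated
#'
#' Simulates the network for a stabilisation period (discarded from all
#' metrics), an OFF segment of spontaneous activity, and an ON segment in
#' which an aDFC controller consumes the population firing rate computed
#' online from the simulated spikes and triggers stimulation pulses on the
#' stimulated pool. The controller runs on a timescale-matched parameter
#' set: network bursts in silico recur roughly ten times faster than in
#' cultured networks, so the firing-rate window, burst debounce and
#' stimulation-frequency bounds default to the in vitro values scaled by
#' ten. The burst-detection threshold and the initial period are tuned
#' per-simulation from the OFF segment: the threshold midway between the
#' baseline (median) and peak firing rate, the period from the median
#' inter-burst interval.
#'
#' @param config an [izh_config()].
#' @param gain controller gain K; `gain = 0` disables stimulation entirely
#'   (null intervention, the schedule stays empty).
#' @param t_stabilise,t_off,t_on segment durations, ms.
#' @param fr_window online firing-rate window, ms.
#' @param sf_min,sf_max stimulation-frequency bounds, Hz.
#' @param burst_min_interval online burst debounce, ms.
#' @param sim_seed seed for the noise stream (the weight seed lives in
#'   `config`).
#' @return an `izh_sim_result`: `spikes` (a [spike_train_set()] in seconds,
#'   neurons as channels), `schedule`, `segments` (list of `c(start, end)`
#'   in seconds for `stabilise`, `off`, `on`), `fr` (online firing-rate
#'   trace, Hz), `burst_threshold`, `controller` (trace or NULL), `config`.
#' @export
run_closed_loop <- function(config, gain = 5,
                            t_stabilise = 500, t_off = 2000, t_on = 2000,
                            fr_window = 10, sf_min = 10, sf_max = 200,
                            burst_min_interval = 10, sim_seed = 2) {
  stopifnot(inherits(config, "izh_config"))
  net <- build_network(config)
  dt <- config$dt
  n <- config$n_neurons
  n_steps <- round((t_stabilise + t_off + t_on) / dt)
  i_off0 <- round(t_stabilise / dt) + 1L
  i_on0 <- round((t_stabilise + t_off) / dt) + 1L
  wlen <- max(1L, round(fr_window / dt))

  spike_t <- vector("list", n_steps)
  spike_id <- vector("list", n_steps)
  fr_trace <- numeric(n_steps)
  counts <- integer(n_steps)
  stim_steps <- integer(0)
  ctrl <- NULL
  pulse <- apply_stimulus(net, config$stim_amplitude)

  with_seed(sim_seed, {
    ext <- numeric(n)
    stim_next <- FALSE
    for (i in seq_len(n_steps)) {
      step <- step_network(net, if (stim_next) pulse else 0)
      net <- step$net
      stim_next <- FALSE
      if (length(step$fired)) {
        spike_t[[i]] <- rep((i - 1) * dt, length(step$fired))
        spike_id[[i]] <- step$fired
      }
      counts[i] <- length(step$fired)
      lo <- max(1L, i - wlen + 1L)
      fr_trace[i] <- sum(counts[lo:i]) / (n * wlen * dt / 1000)

      if (i == i_on0 - 1L && gain > 0) {
        # tune the controller from the OFF segment before ON starts
        fr_off <- fr_trace[i_off0:i]
        thr <- (stats::median(fr_off) + max(fr_off)) / 2
        frs <- new_firing_rate(fr_off, dt / 1000, fr_window / 1000,
                               t0 = (i_off0 - 1) * dt / 1000)
        bo <- detect_bursts(frs, thr, burst_min_interval / 1000)
        T0 <- if (length(bo$times) >= 3)
          stats::median(diff(bo$times)) else 0.1
        cc <- controller_config(gain = gain, period = T0, adaptive = TRUE,
                                sf_min = sf_min, sf_max = sf_max,
                                burst_threshold = thr,
                                burst_min_interval = burst_min_interval / 1000,
                                fr_window = fr_window / 1000,
                                positive_only = TRUE,
                                amplitude = config$stim_amplitude)
        ctrl <- controller_init(cc, dt / 1000,
                                t0 = (i_on0 - 1) * dt / 1000,
                                n_hint = n_steps - i_on0 + 2L)
      }
      if (!is.null(ctrl) && i >= i_on0) {
        stim_next <- controller_step(ctrl, fr_trace[i], (i - 1) * dt / 1000)
        if (stim_next) stim_steps <- c(stim_steps, i)
      }
    }
  })

  ids <- unlist(spike_id)
  tt <- unlist(spike_t) / 1000
  sp <- split(tt, factor(ids, levels = seq_len(n)))
  names(sp) <- sprintf("n%04d", seq_len(n))
  total_s <- n_steps * dt / 1000
  res <- list(
    spikes = spike_train_set(lapply(sp, sort), 0, total_s,
                             activity_threshold = 0),
    schedule = if (!is.null(ctrl))
      controller_finalize(ctrl, "aDFC")$schedule
    else stim_schedule(numeric(0), config$stim_amplitude, "aDFC"),
    segments = list(
      stabilise = c(0, t_stabilise) / 1000,
      off = c(t_stabilise, t_stabilise + t_off) / 1000,
      on = c(t_stabilise + t_off, t_stabilise + t_off + t_on) / 1000),
    fr = new_firing_rate(fr_trace, dt / 1000, fr_window / 1000, 0),
    burst_threshold = if (!is.null(ctrl)) ctrl$config$burst_threshold else NA,
    controller = if (!is.null(ctrl)) controller_finalize(ctrl, "aDFC")$trace
                 else NULL,
    config = config)
  class(res) <- "izh_sim_result"
  res
}

#' @export
print.izh_sim_result <- function(x, ...) {
  cat(sprintf("<izh_sim_result> %d neurons, %d stimuli in ON segment\n",
              length(x$spikes$channels), length(x$schedule$times)))
  invisible(x)
}

# synchrony + firing rate of one segment of a simulation
segment_metrics <- function(res, segment, box_width = 0.05) {
  w <- crop_spikes(res$spikes, res$segments[[segment]][1],
                   res$segments[[segment]][2])
  list(synchrony = as.numeric(chi_synchrony(w, box_width)),
       firing_rate = average_firing_rate(w))
}

#' Controllability map over network architecture
#'
#' Sweeps the excitatory fraction and the synaptic weight scale on a grid;
#' each cell runs `n_reps` independent closed-loop simulations (fresh
#' weight and noise seeds per repetition) and records the OFF-segment
#' synchrony and firing rate plus their ON-minus-OFF change under aDFC.
#' Low weight/excitation corners yield asynchronous networks, high corners
#' strongly synchronised ones; the intermediate regime is where delayed
#' feedback stimulation can desynchronise the rhythm.
#'
#' @param frac_exc_grid,weight_scale_grid grid axes.
#' @param n_reps repetitions per cell.
#' @param n_neurons network size for the sweep.
#' @param gain controller gain.
#' @param seed master seed; per-run seeds are derived deterministically.
#' @param ... further arguments to [run_closed_loop()].
#' @return a data.frame (class `controllability_map`) with one row per
#'   (cell, rep): `frac_exc`, `weight_scale`, `rep`, `sync_off`, `fr_off`,
#'   `sync_on`, `fr_on`, `d_sync`, `d_fr`, `n_stimuli`.
#' @export
sweep_parameter_grid <- function(frac_exc_grid, weight_scale_grid,
                                 n_reps = 5, n_neurons = 300, gain = 5,
                                 seed = 1, ...) {
  if (!length(frac_exc_grid) || !length(weight_scale_grid))
    stop("grids must be nonempty")
  rows <- list()
  run_id <- 0L
  for (fe in frac_exc_grid) for (ws in weight_scale_grid)
    for (r in seq_len(n_reps)) {
      run_id <- run_id + 1L
      cfg <- izh_config(n_neurons = n_neurons, frac_exc = fe,
                        weight_scale = ws,
                        n_stim = min(100L, n_neurons),
                        seed = seed * 10000L + run_id)
      res <- run_closed_loop(cfg, gain = gain,
                             sim_seed = seed * 10000L + run_id + 5000L, ...)
      off <- segment_metrics(res, "off")
      on <- segment_metrics(res, "on")
      rows[[run_id]] <- data.frame(
        frac_exc = fe, weight_scale = ws, rep = r,
        sync_off = off$synchrony, fr_off = off$firing_rate,
        sync_on = on$synchrony, fr_on = on$firing_rate,
        d_sync = on$synchrony - off$synchrony,
        d_fr = on$firing_rate - off$firing_rate,
        n_stimuli = length(res$schedule$times))
    }
  out <- do.call(rbind, rows)
  class(out) <- c("controllability_map", class(out))
  out
}

#' Aggregate a controllability map over repetitions
#'
#' @param map output of [sweep_parameter_grid()].
#' @return data.frame with per-cell means of the map columns.
#' @export
summarise_map <- function(map) {
  stats::aggregate(cbind(sync_off, fr_off, sync_on, fr_on, d_sync, d_fr)
                   ~ frac_exc + weight_scale, data = map, FUN = mean)
}
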
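#' Square current-step protocol definitions
#'
#' `firing_protocol()` defaults to the evoked-firing protocol (steps of
#' 500 ms duration, 10 pA increment); `passive_protocol()` to the passive
#' protocol (-120 to +20 pA in 20 pA increments, 200 ms duration).
#'
#' @param step_start_pa first step amplitude, pA.
#' @param step_increment_pa increment per step, pA (> 0).
#' @param step_duration_ms step duration, ms.
#' @param n_steps number of sweeps.
#' @return a named list protocol description.
#' @export
firing_protocol <- function(step_start_pa = 10, step_increment_pa = 10,
                            step_duration_ms = 500, n_steps = 10L) {
  stopifnot_scalar(step_increment_pa, "step_increment_pa", positive = TRUE)
  stopifnot_scalar(step_duration_ms, "step_duration_ms", positive = TRUE)
  stopifnot_scalar(n_steps, "n_steps", positive = TRUE, integerish = TRUE)
  list(step_start_pa = step_start_pa, step_increment_pa = step_increment_pa,
       step_duration_ms = step_duration_ms, n_steps = as.integer(n_steps))
}

#' @rdname firing_protocol
#' @export
passive_protocol <- function(step_start_pa = -120, step_increment_pa = 20,
                             step_duration_ms = 200, n_steps = 8L) {
  firing_protocol(step_start_pa, step_increment_pa, step_duration_ms, n_steps)
}

#' Configuration for a synthetic current-clamp cell
#'
#' Parameters of a leaky-integrator model cell: membrane voltage relaxes
#' exponentially (time constant `tau_ms`) toward `rest_mv + I * rin_mohm /
#' 1000` during a current step of `I` pA. Whenever the voltage reaches
#' `spike_threshold_mv` within the step, a stereotyped action-potential
#' template (half-cosine rise of `ap_amp_mv` over `ap_rise_ms`, half-cosine
#' decay back to rest over `ap_fall_ms`) is pasted and the integrator resets
#' to rest. Optional Gaussian measurement noise is added to the recorded
#' trace only (it does not feed back into the dynamics, so stored ground
#' truth is exact).
#'
#' @param rin_mohm input resistance, MOhm.
#' @param tau_ms membrane time constant, ms.
#' @param rest_mv resting (holding) potential, mV.
#' @param spike_threshold_mv spike threshold, mV.
#' @param protocol a [firing_protocol()] or [passive_protocol()].
#' @param pre_ms,post_ms baseline before and tail after the step, ms.
#' @param sample_interval_ms sampling interval, ms (0.05 ms = 20 kHz).
#' @param noise_sd_mv measurement noise SD, mV.
#' @param ap_amp_mv,ap_rise_ms,ap_fall_ms action-potential template
#'   amplitude above threshold and rise/fall durations.
#' @param seed integer seed.
#' @return an object of class `cell_config`.
#' @export
cell_config <- function(rin_mohm = 600, tau_ms = 50, rest_mv = -60,
                        spike_threshold_mv = -40,
                        protocol = firing_protocol(),
                        pre_ms = 100, post_ms = 100,
                        sample_interval_ms = 0.05, noise_sd_mv = 0,
                        ap_amp_mv = 100, ap_rise_ms = 0.7, ap_fall_ms = 1.3,
                        seed = 1L) {
  stopifnot_scalar(rin_mohm, "rin_mohm", positive = TRUE)
  stopifnot_scalar(tau_ms, "tau_ms", positive = TRUE)
  stopifnot_scalar(rest_mv, "rest_mv")
  stopifnot_scalar(spike_threshold_mv, "spike_threshold_mv")
  if (spike_threshold_mv <= rest_mv) {
    stop("`spike_threshold_mv` must exceed `rest_mv`", call. = FALSE)
  }
  stopifnot_scalar(sample_interval_ms, "sample_interval_ms", positive = TRUE)
  stopifnot_scalar(noise_sd_mv, "noise_sd_mv", nonneg = TRUE)
  stopifnot_scalar(pre_ms, "pre_ms", positive = TRUE)
  stopifnot_scalar(post_ms, "post_ms", positive = TRUE)
  stopifnot_scalar(ap_amp_mv, "ap_amp_mv", positive = TRUE)
  stopifnot_scalar(ap_rise_ms, "ap_rise_ms", positive = TRUE)
  stopifnot_scalar(ap_fall_ms, "ap_fall_ms", positive = TRUE)
  stopifnot_scalar(seed, "seed", integerish = TRUE)
  structure(
    list(rin_mohm = rin_mohm, tau_ms = tau_ms, rest_mv = rest_mv,
         spike_threshold_mv = spike_threshold_mv, protocol = protocol,
         pre_ms = pre_ms, post_ms = post_ms,
         sample_interval_ms = sample_interval_ms, noise_sd_mv = noise_sd_mv,
         ap_amp_mv = ap_amp_mv, ap_rise_ms = ap_rise_ms,
         ap_fall_ms = ap_fall_ms, seed = as.integer(seed)),
    class = "cell_config"
  )
}

#' Construct a current-clamp recording from raw sweep data
#'
#' @param time_ms sample times, ms, uniform spacing.
#' @param sweeps numeric matrix, one column per sweep (mV).
#' @param current_pa per-sweep step amplitudes, pA, strictly increasing.
#' @param step_onset_ms,step_offset_ms step window, ms.
#' @param cell_id identifier.
#' @param ground_truth optional generator ground truth.
#' @return an object of class `current_clamp_recording`.
#' @export
current_clamp_recording <- function(time_ms, sweeps, current_pa,
                                    step_onset_ms, step_offset_ms,
                                    cell_id = "cell",
                                    ground_truth = NULL) {
  sweeps <- as.matrix(sweeps)
  if (length(time_ms) != nrow(sweeps)) {
    stop("`time_ms` must match the sweep length", call. = FALSE)
  }
  dt <- diff(time_ms)
  if (any(abs(dt - dt[1]) > 1e-9)) {
    stop("`time_ms` must be uniformly spaced", call. = FALSE)
  }
  if (length(current_pa) != ncol(sweeps)) {
    stop("need one current amplitude per sweep", call. = FALSE)
  }
  if (any(diff(current_pa) <= 0)) {
    stop("`current_pa` must be strictly increasing", call. = FALSE)
  }
  if (step_onset_ms < time_ms[1] || step_offset_ms > time_ms[length(time_ms)] ||
      step_onset_ms >= step_offset_ms) {
    stop("step window must lie within the trace", call. = FALSE)
  }
  if (anyNA(sweeps) || any(!is.finite(sweeps))) {
    stop("sweep voltages must be finite", call. = FALSE)
  }
  structure(
    list(time_ms = as.numeric(time_ms), sweeps = sweeps,
         current_pa = as.numeric(current_pa),
         step_onset_ms = step_onset_ms, step_offset_ms = step_offset_ms,
         dt_ms = dt[1], cell_id = as.character(cell_id),
         ground_truth = ground_truth),
    class = "current_clamp_recording"
  )
}

#' @export
print.current_clamp_recording <- function(x, ...) {
  cat(sprintf(
    "<current_clamp_recording> %s: %d sweeps (%g..%g pA), dt %g ms, step [%g, %g] ms\n",
    x$cell_id, ncol(x$sweeps), min(x$current_pa), max(x$current_pa),
    x$dt_ms, x$step_onset_ms, x$step_offset_ms
  ))
  invisible(x)
}

# Closed-form rheobase of the leaky integrator: smallest protocol amplitude
# whose deflection at the end of the step, I * R/1000 * (1 - exp(-T/tau)),
# reaches the threshold-to-rest gap. NA if no step crosses.
lif_rheobase <- function(cfg) {
  p <- cfg$protocol
  amps <- p$step_start_pa + (seq_len(p$n_steps) - 1) * p$step_increment_pa
  gap <- cfg$spike_threshold_mv - cfg$rest_mv
  settle <- 1 - exp(-p$step_duration_ms / cfg$tau_ms)
  defl <- amps * cfg$rin_mohm / 1000 * settle
  cross <- which(defl >= gap)
  if (length(cross) == 0L) NA_real_ else amps[cross[1]]
}

#' Generate a synthetic current-clamp sweep family
#'
#' Simulates the leaky-integrator cell of [cell_config()] under its square
#' current-step protocol using the exact exponential update (the discrete
#' solution of the membrane equation), pasting the action-potential template
#' at every threshold crossing within the step. Ground truth (rin, tau,
#' rheobase, per-sweep spike peak times, template upstroke/downstroke
#' velocities) is stored on the recording.
#'
#' @param cfg a [cell_config()].
#' @param cell_id identifier stamped on the recording.
#' @return a [current_clamp_recording()] with `ground_truth`.
#' @export
generate_sweep_family <- function(cfg, cell_id = "cell") {
  stopifnot(inherits(cfg, "cell_config"))
  p <- cfg$protocol
  dt <- cfg$sample_interval_ms
  onset <- cfg$pre_ms
  offset <- cfg$pre_ms + p$step_duration_ms
  total <- offset + cfg$post_ms
  t <- seq(0, total, by = dt)
  n <- length(t)
  amps <- p$step_start_pa + (seq_len(p$n_steps) - 1) * p$step_increment_pa

  n_rise <- max(1L, round(cfg$ap_rise_ms / dt))
  n_fall <- max(1L, round(cfg$ap_fall_ms / dt))
  th <- cfg$spike_threshold_mv
  rise_tmpl <- th + cfg$ap_amp_mv *
    (1 - cos(pi * seq_len(n_rise) / n_rise)) / 2
  peak_v <- th + cfg$ap_amp_mv
  fall_tmpl <- cfg$rest_mv + (peak_v - cfg$rest_mv) *
    (1 + cos(pi * seq_len(n_fall) / n_fall)) / 2
  decay <- exp(-dt / cfg$tau_ms)

  sweeps <- matrix(cfg$rest_mv, nrow = n, ncol = p$n_steps)
  spike_times <- vector("list", p$n_steps)
  for (s in seq_len(p$n_steps)) {
    v <- numeric(n)
    v[1] <- cfg$rest_mv
    spikes <- numeric(0)
    k <- 1L
    while (k < n) {
      in_step <- t[k + 1L] >= onset && t[k + 1L] < offset
      asym <- cfg$rest_mv + (if (in_step) amps[s] * cfg$rin_mohm / 1000 else 0)
      v_new <- asym + (v[k] - asym) * decay
      # Paste only when the template peak still lands inside the step, so
      # stored spike times always lie in the step window.
      if (in_step && v_new >= th && t[k + 1L] + cfg$ap_rise_ms <= offset) {
        # Paste the AP template: clamp the crossing sample to threshold,
        # rise to the peak, decay to rest, then resume integration.
        v[k + 1L] <- th
        idx_peak <- k + 1L + n_rise
        hi <- min(n, idx_peak)
        if (k + 2L <= hi) v[(k + 2L):hi] <- rise_tmpl[seq_len(hi - k - 1L)]
        if (idx_peak <= n) spikes <- c(spikes, t[idx_peak])
        lo <- idx_peak + 1L
        hi <- min(n, idx_peak + n_fall)
        if (lo <= hi) v[lo:hi] <- fall_tmpl[seq_len(hi - lo + 1L)]
        k <- min(n, idx_peak + n_fall)
        v[k] <- cfg$rest_mv # reset
      } else {
        v[k + 1L] <- v_new
        k <- k + 1L
      }
    }
    spike_times[[s]] <- spikes
    sweeps[, s] <- v
  }

  if (cfg$noise_sd_mv > 0) {
    sweeps <- sweeps + with_seed(cfg$seed, {
      matrix(stats::rnorm(n * p$n_steps, 0, cfg$noise_sd_mv), nrow = n)
    })
  }

  rheo <- lif_rheobase(cfg)
  counts <- vapply(spike_times, length, integer(1))
  first_spike <- if (!is.na(rheo)) {
    st <- spike_times[[which(amps == rheo)]]
    if (length(st) > 0) st[1] else NA_real_
  } else NA_real_
  gt <- list(
    rin_mohm = cfg$rin_mohm, tau_ms = cfg$tau_ms, rest_mv = cfg$rest_mv,
    spike_threshold_mv = th, rheobase_pa = rheo,
    spike_times_ms = spike_times, spike_counts = counts,
    max_spike_count = max(counts),
    max_firing_frequency_hz = max(counts) / (p$step_duration_ms / 1000),
    upstroke_mv_per_ms = cfg$ap_amp_mv * pi / (2 * cfg$ap_rise_ms),
    downstroke_mv_per_ms = -(peak_v - cfg$rest_mv) * pi / (2 * cfg$ap_fall_ms),
    latency_ms = if (is.na(first_spike)) NA_real_ else first_spike - onset,
    capacitance_pf = 1000 * cfg$tau_ms / cfg$rin_mohm
  )
  current_clamp_recording(t, sweeps, amps, onset, offset, cell_id, gt)
}
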
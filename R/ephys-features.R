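#' Extract one sweep from a recording
#'
#' @param recording a [current_clamp_recording()].
#' @param i sweep index (ordered by current amplitude).
#' @return a list with `time_ms`, `voltage_mv`, `current_pa`,
#'   `step_onset_ms`, `step_offset_ms`, `dt_ms`.
#' @export
get_sweep <- function(recording, i) {
  stopifnot(inherits(recording, "current_clamp_recording"))
  stopifnot_scalar(i, "i", positive = TRUE, integerish = TRUE)
  if (i > ncol(recording$sweeps)) stop("sweep index out of range", call. = FALSE)
  list(time_ms = recording$time_ms,
       voltage_mv = recording$sweeps[, i],
       current_pa = recording$current_pa[i],
       step_onset_ms = recording$step_onset_ms,
       step_offset_ms = recording$step_offset_ms,
       dt_ms = recording$dt_ms)
}

#' Detect action-potential peaks in a sweep
#'
#' Local voltage maxima above `peak_floor_mv` within the current-step
#' window, separated by at least `refractory_ms`.
#'
#' @param sweep a sweep as returned by [get_sweep()].
#' @param peak_floor_mv minimum peak voltage, mV (default 0).
#' @param refractory_ms minimum peak separation, ms (default 2).
#' @return numeric vector of spike peak times, ms (possibly empty).
#' @export
detect_spikes <- function(sweep, peak_floor_mv = 0, refractory_ms = 2) {
  v <- sweep$voltage_mv
  t <- sweep$time_ms
  n <- length(v)
  if (n < 3L) return(numeric(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] > peak_floor_mv &
                 t[cand] >= sweep$step_onset_ms &
                 t[cand] <= sweep$step_offset_ms]
  if (length(cand) == 0L) return(numeric(0))
  keep <- cand[1]
  last <- t[cand[1]]
  for (i in cand[-1]) {
    if (t[i] - last >= refractory_ms) {
      keep <- c(keep, i)
      last <- t[i]
    }
  }
  t[keep]
}

# Central-difference derivative, mV/ms; endpoints use one-sided differences.
dvdt <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

# Index of the first sustained crossing of the dV/dt criterion before the
# spike peak: scanning backward from the peak, the sample after the last one
# whose derivative is below the criterion. NA if the derivative never falls
# below the criterion in the search window, or never reaches it. The
# derivative is averaged over 3 samples before thresholding: at high
# sampling rates the central difference amplifies measurement noise enough
# to stop the scan inside the upstroke, and the sub-criterion approach to
# threshold is slow, so the averaging costs well under a sample's rise.
threshold_index <- function(sweep, peak_index, dvdt_crit = 10) {
  d <- dvdt(sweep$voltage_mv, sweep$dt_ms)
  d <- as.numeric(zoo::rollapply(d, 3, mean, partial = TRUE,
                                 align = "center"))
  search_start <- max(1L, which.min(abs(sweep$time_ms - sweep$step_onset_ms)))
  if (max(d[search_start:peak_index]) < dvdt_crit) return(NA_integer_)
  i <- peak_index
  while (i > search_start && d[i - 1L] >= dvdt_crit) i <- i - 1L
  if (i == search_start) return(NA_integer_) # never below criterion
  i
}

#' Action-potential voltage threshold
#'
#' The membrane voltage at which the rising-phase dV/dt of the action
#' potential first (sustainedly) exceeds `dvdt_crit`: scanning backward from
#' the spike peak, the returned voltage is at the sample following the last
#' sample whose central-difference derivative is below the criterion.
#' Conventionally measured on the first evoked spike of the rheobase sweep.
#'
#' @param sweep a sweep as returned by [get_sweep()].
#' @param spike_time_ms peak time of the spike to analyze, ms.
#' @param dvdt_crit derivative criterion, mV/ms (default 10).
#' @return the threshold voltage, mV; `NA` (with a warning) when the
#'   derivative never exceeds or never falls below the criterion in the
#'   search window.
#' @export
voltage_threshold <- function(sweep, spike_time_ms, dvdt_crit = 10) {
  peak_index <- which.min(abs(sweep$time_ms - spike_time_ms))
  ti <- threshold_index(sweep, peak_index, dvdt_crit)
  if (is.na(ti)) {
    warning("voltage threshold undefined for this spike", call. = FALSE)
    return(NA_real_)
  }
  sweep$voltage_mv[ti]
}

#' Current threshold (rheobase)
#'
#' Smallest step amplitude whose sweep contains at least one detected spike.
#'
#' @param recording a [current_clamp_recording()].
#' @param ... passed to [detect_spikes()].
#' @return the rheobase in pA, or `NA` (with a warning) when no sweep spikes.
#' @export
current_threshold <- function(recording, ...) {
  for (i in seq_along(recording$current_pa)) {
    if (length(detect_spikes(get_sweep(recording, i), ...)) > 0L) {
      return(recording$current_pa[i])
    }
  }
  warning("no spiking sweep: current threshold undefined", call. = FALSE)
  NA_real_
}

#' Firing curve: spike counts and frequencies per step amplitude
#'
#' @param recording a [current_clamp_recording()].
#' @param ... passed to [detect_spikes()].
#' @return a list with `curve` (data.frame `current_pa`, `n_spikes`,
#'   `frequency_hz`), `max_spike_count`, `max_firing_frequency_hz`
#'   (max count divided by the step duration in seconds) and
#'   `step_duration_ms`.
#' @export
firing_curve <- function(recording, ...) {
  dur_s <- (recording$step_offset_ms - recording$step_onset_ms) / 1000
  counts <- vapply(seq_along(recording$current_pa), function(i) {
    length(detect_spikes(get_sweep(recording, i), ...))
  }, integer(1))
  list(
    curve = data.frame(current_pa = recording$current_pa, n_spikes = counts,
                       frequency_hz = counts / dur_s),
    max_spike_count = max(counts),
    max_firing_frequency_hz = max(counts) / dur_s,
    step_duration_ms = recording$step_offset_ms - recording$step_onset_ms
  )
}

#' Firing frequency at a queried step amplitude
#'
#' @param recording a [current_clamp_recording()].
#' @param amplitude_pa queried amplitude; must be a protocol amplitude.
#' @param ... passed to [detect_spikes()].
#' @return frequency in Hz.
#' @export
frequency_at <- function(recording, amplitude_pa, ...) {
  i <- which(abs(recording$current_pa - amplitude_pa) < 1e-9)
  if (length(i) != 1L) {
    stop(sprintf("%g pA is not a protocol amplitude", amplitude_pa),
         call. = FALSE)
  }
  fc <- firing_curve(recording, ...)
  fc$curve$frequency_hz[i]
}

#' Input resistance from the steady-state voltage-current relationship
#'
#' For each non-spiking sweep, the steady-state voltage is the mean over the
#' last `steady_fraction` of the step window; the input resistance is the
#' ordinary-least-squares slope of steady-state voltage against injected
#' current, converted from mV/pA to MOhm.
#'
#' @param recording a passive-protocol [current_clamp_recording()].
#' @param steady_fraction trailing fraction of the step treated as steady
#'   state (default 0.25).
#' @param ... passed to [detect_spikes()] for spike exclusion.
#' @return input resistance, MOhm.
#' @export
input_resistance <- function(recording, steady_fraction = 0.25, ...) {
  if (!is.numeric(steady_fraction) || steady_fraction <= 0 ||
      steady_fraction > 1) {
    stop("`steady_fraction` must be in (0, 1]", call. = FALSE)
  }
  t <- recording$time_ms
  w0 <- recording$step_offset_ms -
    steady_fraction * (recording$step_offset_ms - recording$step_onset_ms)
  sel <- t >= w0 & t < recording$step_offset_ms
  usable <- vapply(seq_along(recording$current_pa), function(i) {
    length(detect_spikes(get_sweep(recording, i), ...)) == 0L
  }, logical(1))
  if (sum(usable) < 3L) {
    stop("fewer than 3 spike-free sweeps: cannot fit V-I relationship",
         call. = FALSE)
  }
  v_ss <- colMeans(recording$sweeps[sel, usable, drop = FALSE])
  i_pa <- recording$current_pa[usable]
  slope <- unname(stats::coef(stats::lm(v_ss ~ i_pa))[2]) # mV/pA
  rin <- slope * 1000
  if (!is.finite(rin) || rin <= 0) {
    stop("non-physical input resistance (slope <= 0)", call. = FALSE)
  }
  rin
}

#' Passive membrane properties: time constant and capacitance
#'
#' Fits a single exponential `V(t) = a + b * exp(-(t - onset) / tau)` to the
#' onset transient of the smallest-magnitude hyperpolarizing step
#' (Levenberg-Marquardt least squares) and derives the whole-cell
#' capacitance as `1000 * tau / rin` (ms/MOhm to pF).
#'
#' @param recording a passive-protocol [current_clamp_recording()].
#' @param rin_mohm input resistance; computed with [input_resistance()] when
#'   omitted.
#' @param ... passed to [input_resistance()].
#' @return a list with `rin_mohm`, `tau_ms`, `capacitance_pf`.
#' @export
passive_properties <- function(recording, rin_mohm = NULL, ...) {
  if (is.null(rin_mohm)) rin_mohm <- input_resistance(recording, ...)
  hyper <- which(recording$current_pa < 0)
  if (length(hyper) == 0L) {
    stop("no hyperpolarizing sweep: cannot estimate tau", call. = FALSE)
  }
  i <- hyper[which.max(recording$current_pa[hyper])] # smallest magnitude
  sw <- get_sweep(recording, i)
  sel <- sw$time_ms >= sw$step_onset_ms & sw$time_ms < sw$step_offset_ms
  tt <- sw$time_ms[sel] - sw$step_onset_ms
  vv <- sw$voltage_mv[sel]
  a0 <- mean(vv[tt > 0.75 * max(tt)])
  b0 <- vv[1] - a0
  tau0 <- max(max(tt) / 5, sw$dt_ms)
  fit <- tryCatch(
    minpack.lm::nlsLM(vv ~ a + b * exp(-tt / tau),
                      start = list(a = a0, b = b0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    stop("exponential fit of the onset transient failed", call. = FALSE)
  }
  tau <- unname(stats::coef(fit)[["tau"]])
  if (!is.finite(tau) || tau <= 0) {
    stop("exponential fit returned a non-physical time constant",
         call. = FALSE)
  }
  list(rin_mohm = rin_mohm, tau_ms = tau,
       capacitance_pf = 1000 * tau / rin_mohm)
}

#' Action-potential waveform features
#'
#' Upstroke velocity (maximum central-difference dV/dt between the voltage
#' threshold and the spike peak), downstroke velocity (minimum dV/dt between
#' the peak and the after-spike minimum) and latency (first spike peak time
#' minus step onset). Conventionally measured on the first evoked spike of
#' the rheobase sweep.
#'
#' @param sweep a sweep as returned by [get_sweep()].
#' @param spike_time_ms peak time of the spike, ms.
#' @param dvdt_crit threshold derivative criterion, mV/ms.
#' @return a list with `upstroke_mv_per_ms`, `downstroke_mv_per_ms`,
#'   `latency_ms`, `threshold_mv`. Threshold-dependent entries are `NA`
#'   when the voltage threshold is undefined.
#' @export
ap_waveform_features <- function(sweep, spike_time_ms, dvdt_crit = 10) {
  peak_index <- which.min(abs(sweep$time_ms - spike_time_ms))
  d <- dvdt(sweep$voltage_mv, sweep$dt_ms)
  ti <- threshold_index(sweep, peak_index, dvdt_crit)
  n <- length(sweep$voltage_mv)
  # After-spike minimum: first sample after the peak where the voltage stops
  # falling (or the trace end).
  j <- peak_index
  while (j < n && sweep$voltage_mv[j + 1L] < sweep$voltage_mv[j]) j <- j + 1L
  upstroke <- if (is.na(ti)) NA_real_ else max(d[ti:peak_index])
  downstroke <- if (j > peak_index) min(d[peak_index:j]) else NA_real_
  list(
    upstroke_mv_per_ms = upstroke,
    downstroke_mv_per_ms = downstroke,
    latency_ms = spike_time_ms - sweep$step_onset_ms,
    threshold_mv = if (is.na(ti)) NA_real_ else sweep$voltage_mv[ti]
  )
}

#' Full per-cell electrophysiological feature table
#'
#' Combines active features from a firing-protocol recording (rheobase,
#' voltage threshold, upstroke/downstroke, latency, maximum spike count and
#' firing frequency — all spike-waveform features measured on the first
#' evoked spike of the rheobase sweep) with passive features from a
#' passive-protocol recording (input resistance, time constant,
#' capacitance).
#'
#' @param firing a firing-protocol [current_clamp_recording()].
#' @param passive a passive-protocol [current_clamp_recording()], or `NULL`
#'   to skip passive features.
#' @param dvdt_crit voltage-threshold derivative criterion, mV/ms.
#' @return a one-row data.frame with columns `cell_id`,
#'   `voltage_threshold_mv`, `current_threshold_pa`, `rin_mohm`, `tau_ms`,
#'   `capacitance_pf`, `upstroke_mv_per_ms`, `downstroke_mv_per_ms`,
#'   `latency_ms`, `max_spikes`, `max_freq_hz`.
#' @export
extract_ephys_features <- function(firing, passive = NULL, dvdt_crit = 10) {
  rheo <- suppressWarnings(current_threshold(firing))
  fc <- firing_curve(firing)
  vt <- up <- down <- lat <- NA_real_
  if (!is.na(rheo)) {
    i <- which(firing$current_pa == rheo)
    sw <- get_sweep(firing, i)
    st <- detect_spikes(sw)
    wf <- ap_waveform_features(sw, st[1], dvdt_crit)
    vt <- wf$threshold_mv
    up <- wf$upstroke_mv_per_ms
    down <- wf$downstroke_mv_per_ms
    lat <- wf$latency_ms
  }
  rin <- tau <- cap <- NA_real_
  if (!is.null(passive)) {
    pp <- passive_properties(passive)
    rin <- pp$rin_mohm
    tau <- pp$tau_ms
    cap <- pp$capacitance_pf
  }
  data.frame(
    cell_id = firing$cell_id,
    voltage_threshold_mv = vt, current_threshold_pa = rheo,
    rin_mohm = rin, tau_ms = tau, capacitance_pf = cap,
    upstroke_mv_per_ms = up, downstroke_mv_per_ms = down,
    latency_ms = lat, max_spikes = fc$max_spike_count,
    max_freq_hz = fc$max_firing_frequency_hz,
    stringsAsFactors = FALSE
  )
}
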
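test_that("spike detection finds the pasted templates at their times", {
  cfg <- cell_config(rin_mohm = 600, sample_interval_ms = 0.1)
  rec <- generate_sweep_family(cfg)
  for (i in seq_along(rec$current_pa)) {
    st <- detect_spikes(get_sweep(rec, i))
    gt <- rec$ground_truth$spike_times_ms[[i]]
    expect_length(st, length(gt))
    if (length(gt) > 0) expect_lt(max(abs(st - gt)), rec$dt_ms + 1e-9)
  }
})

test_that("spike counts survive measurement noise at realistic SNR", {
  cfg0 <- cell_config(rin_mohm = 600, noise_sd_mv = 0, seed = 5,
                      sample_interval_ms = 0.1)
  cfgn <- cell_config(rin_mohm = 600, noise_sd_mv = 1, seed = 5,
                      sample_interval_ms = 0.1)
  counts0 <- generate_sweep_family(cfg0)$ground_truth$spike_counts
  recn <- generate_sweep_family(cfgn)
  countsn <- vapply(seq_along(recn$current_pa), function(i) {
    length(detect_spikes(get_sweep(recn, i)))
  }, integer(1))
  expect_equal(countsn, counts0)
})

test_that("voltage threshold recovers a piecewise-linear upstroke origin", {
  # 5 mV/ms up to -40 mV, then 50 mV/ms to the peak, then linear decay
  dt <- 0.05
  seg1 <- seq(-60, -40, by = 5 * dt)
  seg2 <- seq(-40 + 50 * dt, 40, by = 50 * dt)
  seg3 <- seq(40 - 80 * dt, -60, by = -80 * dt)
  v <- c(rep(-60, 100), seg1, seg2, seg3, rep(-60, 100))
  t <- (seq_along(v) - 1) * dt
  sweep <- list(time_ms = t, voltage_mv = v, current_pa = 50,
                step_onset_ms = 0, step_offset_ms = max(t), dt_ms = dt)
  st <- detect_spikes(sweep)
  expect_length(st, 1L)
  vt <- voltage_threshold(sweep, st[1])
  expect_lt(abs(vt - (-40)), 50 * dt + 1e-9) # within one sample's rise
  # criterion above the maximum slope -> undefined
  expect_warning(out <- voltage_threshold(sweep, st[1], dvdt_crit = 100),
                 "undefined")
  expect_true(is.na(out))
})

test_that("voltage threshold matches the generator threshold at fine dt", {
  cfg <- cell_config(rin_mohm = 600, sample_interval_ms = 0.05,
                     noise_sd_mv = 0)
  rec <- generate_sweep_family(cfg)
  i <- which(rec$current_pa == rec$ground_truth$rheobase_pa)
  sw <- get_sweep(rec, i)
  st <- detect_spikes(sw)
  expect_lt(abs(voltage_threshold(sw, st[1]) -
                  rec$ground_truth$spike_threshold_mv), 1)
})

test_that("threshold and upstroke estimates converge as dt shrinks", {
  errs <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    cfg <- cell_config(rin_mohm = 600, sample_interval_ms = dt)
    rec <- generate_sweep_family(cfg)
    i <- which(rec$current_pa == rec$ground_truth$rheobase_pa)
    sw <- get_sweep(rec, i)
    st <- detect_spikes(sw)
    wf <- ap_waveform_features(sw, st[1])
    abs(wf$upstroke_mv_per_ms - rec$ground_truth$upstroke_mv_per_ms)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / 224.4, 0.02)
})

test_that("firing curve reports counts, maxima and queried frequencies", {
  cfg <- cell_config(rin_mohm = 600, sample_interval_ms = 0.1)
  rec <- generate_sweep_family(cfg)
  fc <- firing_curve(rec)
  expect_equal(fc$curve$n_spikes, unname(rec$ground_truth$spike_counts))
  expect_true(all(diff(fc$curve$n_spikes) >= 0)) # monotone in amplitude
  expect_equal(fc$max_firing_frequency_hz * 0.5, fc$max_spike_count)
  expect_equal(fc$curve$frequency_hz, fc$curve$n_spikes / 0.5)
  expect_equal(frequency_at(rec, 40), fc$curve$frequency_hz[4])
  expect_error(frequency_at(rec, 45), "not a protocol amplitude")
})

test_that("input resistance recovery and unit conversion are exact", {
  # three orders of magnitude; short tau so steady state is fully settled
  for (rin in c(50, 500, 5000)) {
    cfg <- cell_config(rin_mohm = rin, tau_ms = 10,
                       protocol = passive_protocol(),
                       sample_interval_ms = 0.1)
    rec <- generate_sweep_family(cfg)
    expect_equal(input_resistance(rec), rin, tolerance = 1e-3)
  }
  flat <- current_clamp_recording(
    time_ms = seq(0, 400, by = 0.5),
    sweeps = matrix(-60, 801, 4),
    current_pa = c(-60, -40, -20, 0),
    step_onset_ms = 100, step_offset_ms = 300
  )
  expect_error(input_resistance(flat), "non-physical")
})

test_that("passive properties recover tau and derive capacitance", {
  cfg <- cell_config(rin_mohm = 500, tau_ms = 50,
                     protocol = passive_protocol(),
                     sample_interval_ms = 0.1)
  rec <- generate_sweep_family(cfg)
  pp <- passive_properties(rec, rin_mohm = 500)
  expect_equal(pp$tau_ms, 50, tolerance = 1e-2)
  expect_equal(pp$capacitance_pf, 1000 * pp$tau_ms / 500)
  no_hyper <- current_clamp_recording(
    rec$time_ms, rec$sweeps[, 7:8], rec$current_pa[7:8],
    rec$step_onset_ms, rec$step_offset_ms
  )
  expect_error(passive_properties(no_hyper, rin_mohm = 500),
               "hyperpolarizing")
})

test_that("waveform features match the template ground truth", {
  cfg <- cell_config(rin_mohm = 600, sample_interval_ms = 0.05)
  rec <- generate_sweep_family(cfg)
  gt <- rec$ground_truth
  i <- which(rec$current_pa == gt$rheobase_pa)
  sw <- get_sweep(rec, i)
  st <- detect_spikes(sw)
  wf <- ap_waveform_features(sw, st[1])
  expect_lt(abs(wf$upstroke_mv_per_ms - gt$upstroke_mv_per_ms) /
              gt$upstroke_mv_per_ms, 0.02)
  expect_lt(abs(wf$downstroke_mv_per_ms - gt$downstroke_mv_per_ms) /
              abs(gt$downstroke_mv_per_ms), 0.02)
  expect_equal(wf$latency_ms, gt$latency_ms, tolerance = rec$dt_ms)
  expect_gt(wf$upstroke_mv_per_ms, 0)
  expect_lt(wf$downstroke_mv_per_ms, 0)
})

test_that("the combined feature table carries all Table-style columns", {
  base <- list(rin_mohm = 600, tau_ms = 50, sample_interval_ms = 0.1)
  firing <- generate_sweep_family(do.call(cell_config, base), "c1")
  passive <- generate_sweep_family(
    do.call(cell_config, c(base, list(protocol = passive_protocol()))), "c1"
  )
  tab <- extract_ephys_features(firing, passive)
  expect_equal(nrow(tab), 1L)
  expect_named(tab, c("cell_id", "voltage_threshold_mv",
                      "current_threshold_pa", "rin_mohm", "tau_ms",
                      "capacitance_pf", "upstroke_mv_per_ms",
                      "downstroke_mv_per_ms", "latency_ms", "max_spikes",
                      "max_freq_hz"))
  expect_equal(tab$current_threshold_pa, firing$ground_truth$rheobase_pa)
  expect_equal(tab$max_spikes, firing$ground_truth$max_spike_count)
})
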
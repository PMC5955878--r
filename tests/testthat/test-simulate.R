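test_that("configuration is validated", {
  expect_error(sim_config(duration_s = -5), "duration")
  expect_error(sim_config(swd_spike_freq_hz = 4), "5, 9")
  expect_error(sim_config(class_fractions = c(ictal_low = 0.5,
                                              ictal_high = 0.5,
                                              neutral = 0.2, quiet = 0)),
               "sum to 1")
  expect_error(sim_config(kernel_tau_s = 0), "kernel_tau_s")
  expect_error(sim_config(indicator = "OGB"), "indicator")
  expect_error(sim_config(shared_signal_state = "never"), "shared_signal")
})

test_that("identical seed and config give bit-identical sessions", {
  cfg <- sim_config(duration_s = 120, n_neurons = 6, n_neuropil = 1,
                    seed = 33)
  s1 <- simulate_session(cfg, locomotion = TRUE)
  s2 <- simulate_session(cfg, locomotion = TRUE)
  expect_identical(s1$fluor, s2$fluor)
  expect_identical(s1$eeg$samples, s2$eeg$samples)
  expect_identical(s1$velocity, s2$velocity)
  expect_identical(s1$truth$true_event_counts, s2$truth$true_event_counts)
})

test_that("zero seizure rate gives a pure background EEG", {
  cfg <- sim_config(duration_s = 60, seizure_rate_per_min = 0,
                    n_neurons = 4, n_neuropil = 1, seed = 1)
  ee <- simulate_eeg(cfg)
  expect_identical(nrow(ee$truth), 0L)
  expect_length(detect_seizures(ee$eeg)$onset_s, 0)
})

test_that("planted spike trains run at the configured frequency", {
  cfg <- sim_config(duration_s = 120, seizure_rate_per_min = 0.5,
                    seizure_duration_s = c(3, 3), swd_spike_freq_hz = 6,
                    n_neurons = 4, n_neuropil = 1, seed = 2)
  ee <- simulate_eeg(cfg)
  expect_identical(nrow(ee$truth), 1L)
  isi <- diff(ee$truth$spike_times_s[[1]])
  expect_true(all(abs(isi - 1 / 6) < 1e-9))
})

test_that("planted ictal fraction matches rate x duration at 30 minutes", {
  cfg <- sim_config(duration_s = 1800, n_neurons = 4, n_neuropil = 1,
                    seed = 3)
  ee <- simulate_eeg(cfg)
  frac <- sum(ee$truth$offset_s - ee$truth$onset_s) / 1800
  expected <- cfg$seizure_rate_per_min / 60 * mean(cfg$seizure_duration_s)
  expect_lt(abs(frac - expected) / expected, 0.10)
  ## all bursts separated enough to survive curation
  gaps <- ee$truth$onset_s[-1] - ee$truth$offset_s[-nrow(ee$truth)]
  expect_true(all(gaps >= 6))
})

test_that("calcium traces follow the generative contract", {
  cfg <- sim_config(duration_s = 120, n_neurons = 8, n_neuropil = 2,
                    modulation_depth = c(ictal_low = 0, ictal_high = 0,
                                         neutral = 0, quiet = 0),
                    seed = 4)
  ee <- simulate_eeg(cfg)
  ca <- simulate_calcium(cfg, ee$truth)
  ## zero modulation: every non-quiet class is statistically neutral; the
  ## planted labels still partition the population
  expect_identical(dim(ca$fluor), c(10L, 1200L))
  expect_true(all(ca$truth$true_class_per_roi %in%
                    c("ictal_low", "ictal_high", "neutral", "quiet")))
  expect_error(simulate_calcium(cfg, data.frame(onset_s = 500,
                                                offset_s = 510)),
               "outside")
})

test_that("a single noiseless event decays as the exponential kernel", {
  cfg <- sim_config(duration_s = 60, seizure_rate_per_min = 0,
                    noise_sigma_dff = 0, quiet_event_rate_hz = 0,
                    event_rate_hz = 0.02, n_neurons = 30, n_neuropil = 1,
                    seed = 1)
  ca <- simulate_calcium(cfg, data.frame(onset_s = numeric(0),
                                         offset_s = numeric(0)))
  ## find a neuron with exactly one event; its dF/F signal (relative to the
  ## constant baseline and drift) must be a pure exponential
  counts <- ca$truth$true_event_counts
  one <- which(rowSums(counts) == 1 &
                 ca$truth$true_class_per_roi != "quiet")
  one <- one[vapply(one, function(i) {
    t0 <- which(counts[i, ] == 1)
    t0 > 2 && t0 < 560
  }, TRUE)]
  expect_gt(length(one), 0)
  i <- one[1]
  t0 <- which(counts[i, ] == 1)
  ## pre-event fluorescence gives the (slowly drifting) baseline; the decay
  ## is fast relative to the drift, so delta-F over the tail is exponential
  b <- ca$fluor[i, t0 - 1]
  tail_idx <- t0:min(t0 + 20, ncol(counts))
  sig <- 100 * (ca$fluor[i, tail_idx] / b - 1)
  rel <- sig / sig[1]
  a <- exp(-1 / (cfg$kernel_tau_s * cfg$frame_rate_hz))
  expect_lt(max(abs(rel - a^(seq_along(tail_idx) - 1))), 0.03)
})

test_that("voltage simulation respects mode and plants detectable spikes", {
  cfg <- sim_config(duration_s = 10, n_neurons = 2, n_neuropil = 1,
                    seed = 7)
  expect_error(simulate_voltage(cfg, "loose_patch"), "arg")
  ## zero rate: no spikes detected
  v0 <- simulate_voltage(cfg, "whole_cell", ap_rate_hz = 0)
  expect_length(detect_aps(v0$voltage, v0$rate_hz,
                           ap_params("whole_cell"))$times, 0)
  ## noiseless whole-cell: exact recovery within 0.5 ms
  v1 <- simulate_voltage(cfg, "whole_cell", ap_rate_hz = 3,
                         noise_sd_mv = 0)
  aps <- detect_aps(v1$voltage, v1$rate_hz, ap_params("whole_cell"))
  expect_length(aps$times, length(v1$truth$true_ap_times))
  expect_lt(max(abs(aps$times - v1$truth$true_ap_times)), 5e-4)
  ## cell-attached scaled to 1.0 mV: below the 1.9 mV criterion
  v2 <- simulate_voltage(cfg, "cell_attached", ap_rate_hz = 3,
                         noise_sd_mv = 0, amp_mv = 1.0)
  expect_length(detect_aps(v2$voltage, v2$rate_hz,
                           ap_params("cell_attached"))$times, 0)
})

test_that("locomotion bouts avoid seizures", {
  sess <- cached("loco_session", simulate_session(
    sim_config(duration_s = 600, n_neurons = 4, n_neuropil = 1, seed = 10),
    locomotion = TRUE))
  tru <- sess$truth$true_seizures
  moving <- abs(sess$velocity) > 1
  ict <- rep(FALSE, length(sess$frame_times))
  for (k in seq_len(nrow(tru)))
    ict <- ict | (sess$frame_times >= tru$onset_s[k] &
                    sess$frame_times <= tru$offset_s[k])
  expect_lt(mean(moving[ict]), 0.02)
  expect_gt(mean(moving[!ict]), 0.02)
})
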
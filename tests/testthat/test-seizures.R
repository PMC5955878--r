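test_that("degenerate EEG inputs are handled", {
  expect_error(eeg_recording(c(1, NA), 2000), "finite")
  expect_error(eeg_recording(1:10, -1), "rate_hz")
  flat <- eeg_recording(rep(0, 2000 * 30), 2000)
  expect_identical(nrow(detect_seizures(flat)), 0L)
})

test_that("bursts below the minimum duration are rejected", {
  cfg <- sim_config(duration_s = 120, seizure_rate_per_min = 0.5,
                    seizure_duration_s = c(0.4, 0.4),
                    n_neurons = 4, n_neuropil = 1, seed = 5)
  ee <- simulate_eeg(cfg)
  expect_identical(nrow(ee$truth), 1L)           # planted
  expect_identical(nrow(detect_seizures(ee$eeg)), 0L)  # < 0.5 s: rejected
})

test_that("planted seizures are recovered with accurate boundaries", {
  sess <- small_session()
  det <- detect_seizures(sess$eeg)
  tru <- sess$truth$true_seizures
  expect_identical(nrow(det), nrow(tru))
  expect_lt(max(abs(det$onset_s - tru$onset_s)), 0.25)
  expect_lt(max(abs(det$offset_s - tru$offset_s)), 0.25)
  expect_true(all(det$mean_spike_freq_hz >= 5 & det$mean_spike_freq_hz <= 9))
  expect_true(all(det$offset_s - det$onset_s >= 0.5))
  st <- spike_times(det)
  for (k in seq_len(nrow(det))) {
    expect_true(all(st[[k]] >= det$onset_s[k] - 1e-9 &
                      st[[k]] <= det$offset_s[k] + 1e-9))
  }
})

test_that("seizure curation applies the printed exclusion rules", {
  expect_identical(nrow(filter_seizures(make_seizures(numeric(0),
                                                      numeric(0)))), 0L)
  ## a 1.2-s seizure is removed (duration < 1.5 s)
  expect_identical(nrow(filter_seizures(make_seizures(10, 11.2))), 0L)
  ## two 5-s seizures 4 s apart: both removed (gap < 6 s)
  expect_identical(nrow(filter_seizures(make_seizures(c(10, 19),
                                                      c(15, 24)))), 0L)
  ## survivors keep their spike times
  keep <- filter_seizures(make_seizures(c(10, 30), c(15, 36)))
  expect_identical(nrow(keep), 2L)
  expect_length(spike_times(keep), 2)
  expect_error(filter_seizures(make_seizures(c(10, 12), c(14, 20))),
               "overlap")
})

test_that("curation is idempotent", {
  set.seed(12)
  onsets <- sort(runif(12, 0, 500))
  durs <- runif(12, 0.6, 9)
  offs <- pmin(onsets + durs, c(onsets[-1] - 0.2, Inf))
  s <- make_seizures(onsets, offs)
  f1 <- filter_seizures(s)
  f2 <- filter_seizures(f1)
  expect_identical(f1$onset_s, f2$onset_s)
  expect_identical(f1$offset_s, f2$offset_s)
  ## every survivor satisfies both rules
  if (nrow(f1) > 1) {
    expect_true(all(f1$offset_s - f1$onset_s >= 1.5))
    expect_true(all(f1$onset_s[-1] - f1$offset_s[-nrow(f1)] >= 6))
  }
})

test_that("the ictal mask follows the frame-midpoint rule", {
  ft <- (seq_len(300) - 0.5) / 10
  expect_true(all(!build_ictal_mask(make_seizures(numeric(0),
                                                  numeric(0)), ft)$ictal))
  ## one seizure exactly spanning frames 10-19 at 10 Hz
  m <- build_ictal_mask(make_seizures(0.9, 1.9), ft)
  expect_identical(sum(m$ictal), 10L)
  expect_identical(which(m$ictal), 10:19)
  ## partition: ictal + interictal + excluded = total
  expect_identical(m$n_ictal + m$n_interictal + sum(m$excluded), 300L)
  expect_error(build_ictal_mask(make_seizures(1, 2), rev(ft)), "increasing")
})

test_that("locomotion exclusion drops frames from both states", {
  ft <- (seq_len(300) - 0.5) / 10
  m <- build_ictal_mask(make_seizures(10, 15), ft)
  expect_error(remove_locomotion_frames(m, rep(0, 10)), "match")
  m0 <- remove_locomotion_frames(m, rep(0, 300))
  expect_identical(sum(m0$excluded), 0L)
  ## velocity above threshold only interictally: ictal count unchanged
  v <- rep(0, 300)
  v[1:50] <- 3
  m1 <- remove_locomotion_frames(m, v)
  expect_identical(m1$n_ictal, m$n_ictal)
  expect_identical(m1$n_interictal, m$n_interictal - 50L)
  expect_identical(m1$excluded_frames, 1:50)
})

test_that("classification is unchanged by interictal locomotion removal", {
  an <- small_analysis()
  sess <- cached("loco_session", simulate_session(
    sim_config(duration_s = 600, n_neurons = 4, n_neuropil = 1, seed = 10),
    locomotion = TRUE))
  ## reuse the main analysis session; synthesize interictal-only running
  set.seed(31)
  v <- rep(0, length(an$sess$frame_times))
  interictal <- which(!an$mask$ictal)
  bouts <- sample(interictal, 400)
  v[bouts] <- 4
  m2 <- remove_locomotion_frames(an$mask, v)
  cl1 <- classify_roi(an$dff, an$mask)
  cl2 <- classify_roi(an$dff, m2)
  agree <- mean(cl1$label[!an$dff$quiet] == cl2$label[!an$dff$quiet])
  expect_gte(agree, 0.95)
})
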
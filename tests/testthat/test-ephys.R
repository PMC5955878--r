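test_that("flat and empty traces yield no action potentials", {
  p <- ap_params("whole_cell")
  expect_length(detect_aps(rep(0, 5000), 10000, p)$times, 0)
  expect_error(detect_aps(rep(0, 10), 10000, p), "shorter")
})

test_that("detection criteria hold literally on a hand-built waveform", {
  ## whole-cell: 40 mV rise completed within 0.25 ms, plateau over
  ## [0.25, 0.35] ms, repolarized to baseline well before [2.5, 2.9] ms
  rate <- 10000
  p <- ap_params("whole_cell")
  v <- rep(0, 2000)
  t0 <- 1001                       # sample of the rise start
  ## hand-built: full 40 mV reached by +0.2 ms, plateau to +0.5 ms, then
  ## exponential repolarization (tau 0.35 ms)
  t_ms <- (0:40) * 0.1
  wf <- ifelse(t_ms < 0.2, 40 * t_ms / 0.2,
               ifelse(t_ms <= 0.5, 40,
                      40 * exp(-(t_ms - 0.5) / 0.35)))
  v[t0 + seq_along(wf) - 1] <- wf
  ## hand-evaluate the three criteria at t0
  ms <- rate / 1000
  expect_gt(v[t0 + round(0.25 * ms)], v[t0] + p$x)                 # i
  pre <- mean(v[(t0 - round(p$pre1 * ms)):(t0 - round(p$pre2 * ms))])
  peak <- mean(v[(t0 + round(p$p1 * ms)):(t0 + round(p$p2 * ms))])
  post <- mean(v[(t0 + round(p$post1 * ms)):(t0 + round(p$post2 * ms))])
  expect_lt(pre, peak - p$alpha * p$x)                             # ii
  expect_lt(post, pre + p$beta * p$x)                              # iii
  aps <- detect_aps(v, rate, p)
  expect_length(aps$times, 1)
  expect_lt(abs(aps$times - (t0 - 1) / rate), 5e-4)
})

test_that("a 30 mV rise fails the 38 mV whole-cell threshold", {
  rate <- 10000
  p <- ap_params("whole_cell")
  v <- rep(0, 2000)
  wf <- ictaltrace:::ap_waveform(p, rate, 30)
  v[1001 + seq_along(wf) - 1] <- wf
  expect_length(detect_aps(v, rate, p)$times, 0)
})

test_that("noiseless template trains are recovered exactly for both modes", {
  times <- seq(0.5, 9.0, by = 0.9)
  for (mode in c("whole_cell", "cell_attached")) {
    v <- template_train(times, mode)
    aps <- detect_aps(v, 10000, ap_params(mode))
    expect_length(aps$times, length(times))
    expect_lt(max(abs(aps$times - times)), 5e-4)
    expect_true(all(diff(aps$times) >= 1e-3))   # refractory dedup
  }
})

test_that("1.0 mV cell-attached deflections fall below the 1.9 mV threshold", {
  v <- template_train(seq(1, 9), "cell_attached", amp = 1.0)
  expect_length(detect_aps(v, 10000, ap_params("cell_attached"))$times, 0)
})

test_that("detection is robust at twice-threshold amplitude with noise", {
  set.seed(42)
  times <- sort(runif(40, 0.2, 19.5))
  times <- times[c(TRUE, diff(times) > 0.01)]
  v <- template_train(times, "cell_attached", dur_s = 20, noise_sd = 0.1)
  aps <- detect_aps(v, 10000, ap_params("cell_attached"))
  tp <- sum(vapply(times, function(s) any(abs(aps$times - s) < 1e-3), TRUE))
  prec <- tp / max(1, length(aps$times))
  rec <- tp / length(times)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.95)
})

test_that("state firing rates label a suppressed train ictal-low", {
  set.seed(3)
  seiz <- make_seizures(seq(20, 560, by = 36), seq(20, 560, by = 36) + 6)
  dur <- 600
  ## interictal 10 Hz Poisson, ictal 3 Hz (70% drop)
  t_all <- sort(runif(6000, 0, dur))
  ict <- vapply(t_all, function(s)
    any(s >= seiz$onset_s & s <= seiz$offset_s), TRUE)
  keep <- ifelse(ict, runif(length(t_all)) < 0.3, TRUE)
  train <- structure(list(times = t_all[keep], mode = "cell_attached",
                          rate_hz = 10000), class = "ap_train")
  res <- state_firing_rates(train, seiz, duration_s = dur)
  expect_identical(res$label, "ictal_low")
  expect_lt(res$ictal_rate, res$interictal_rate)

  ## uniform train unaffected by seizures: no significant difference
  uni <- structure(list(times = seq(0.05, dur, by = 0.11),
                        mode = "cell_attached", rate_hz = 10000),
                   class = "ap_train")
  expect_identical(state_firing_rates(uni, seiz, duration_s = dur)$label,
                   "neutral")

  ## empty train: neutral with zero rates
  empty <- structure(list(times = numeric(0), mode = "cell_attached",
                          rate_hz = 10000), class = "ap_train")
  res0 <- state_firing_rates(empty, seiz, duration_s = dur)
  expect_identical(res0$label, "neutral")
  expect_identical(res0$ictal_rate, 0)
})

test_that("peri-spike histogram counts, coincidence and edge cases", {
  es <- seq(1, 60, by = 0.17)
  empty <- structure(list(times = numeric(0), mode = "cell_attached",
                          rate_hz = 10000), class = "ap_train")
  h0 <- peri_eeg_spike_histogram(empty, es)
  expect_true(all(h0$counts == 0))
  expect_identical(h0$coincidence_fraction, 0)
  expect_error(peri_eeg_spike_histogram(empty, numeric(0)), "empty")

  ## every AP exactly +10 ms after an EEG spike: one occupied bin,
  ## coincidence 1
  locked <- structure(list(times = es + 0.010, mode = "cell_attached",
                           rate_hz = 10000), class = "ap_train")
  h1 <- peri_eeg_spike_histogram(locked, es)
  expect_identical(sum(h1$counts > 0), 1L)
  expect_identical(h1$coincidence_fraction, 1)
  expect_identical(sum(h1$counts), length(es))

  ## histogram total equals APs within 100 ms of an EEG spike
  set.seed(7)
  rnd <- structure(list(times = sort(runif(500, 0, 61)),
                        mode = "cell_attached", rate_hz = 10000),
                   class = "ap_train")
  h2 <- peri_eeg_spike_histogram(rnd, es)
  inw <- vapply(rnd$times, function(s) any(abs(es - s) <= 0.1), TRUE)
  expect_identical(sum(h2$counts), sum(inw))
})

test_that("coincidence of an independent Poisson train matches theory", {
  set.seed(5)
  lambda <- 8
  dur <- 400
  aps <- structure(list(times = sort(runif(rpois(1, lambda * dur), 0, dur)),
                        mode = "cell_attached", rate_hz = 10000),
                   class = "ap_train")
  es <- seq(5, dur - 5, by = 1.3)
  h <- peri_eeg_spike_histogram(aps, es)
  p_theory <- 1 - exp(-lambda * 0.04)
  se <- sqrt(p_theory * (1 - p_theory) / length(es))
  expect_lt(abs(h$coincidence_fraction - p_theory), 3 * se)
})

test_that("D'Agostino-Pearson test separates normal from uniform offsets", {
  set.seed(9)
  p_norm <- mean(replicate(20, dagostino_pearson(rnorm(200))) < 0.05)
  p_unif <- dagostino_pearson(runif(500, -1, 1))
  expect_lt(p_norm, 0.2)          # near-nominal false-positive rate
  expect_lt(p_unif, 0.05)         # flat distribution rejected
  expect_true(is.na(dagostino_pearson(rep(1, 50))))
})
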
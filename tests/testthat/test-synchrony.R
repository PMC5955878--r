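## A reusable mask with 20 five-second seizures on a 20-min timeline.
sync_mask <- function(nf = 12000) {
  ictal <- rep(FALSE, nf)
  for (k in seq(100, nf - 200, by = 600)) ictal[k:(k + 49)] <- TRUE
  build_ictal_mask(
    make_seizures((which(diff(c(FALSE, ictal)) == 1) - 0.5) / 10,
                  (which(diff(c(ictal, FALSE)) == -1) - 0.5) / 10),
    (seq_len(nf) - 0.5) / 10)
}

test_that("identical traces correlate perfectly in both states", {
  set.seed(41)
  x <- abs(rnorm(12000)) + as.numeric(
    stats::filter(rpois(12000, 0.03) * 25, 0.85, method = "recursive"))
  dff <- make_dff(rbind(x, x))
  sc <- state_correlations(dff, sync_mask())
  expect_equal(sc$pairs$raw_interictal, 1, tolerance = 1e-9)
  expect_equal(sc$pairs$raw_ictal, 1, tolerance = 1e-9)
})

test_that("independent white-noise pairs are near zero", {
  set.seed(42)
  ## ~3000 usable 200-ms bins per state
  nf <- 24000
  ictal <- rep(rep(c(FALSE, TRUE), each = 600), nf / 1200)
  on <- (which(diff(c(FALSE, ictal)) == 1) - 0.5) / 10
  off <- (which(diff(c(ictal, FALSE)) == -1) - 0.5) / 10
  mask <- build_ictal_mask(make_seizures(on, off), (seq_len(nf) - 0.5) / 10)
  dff <- make_dff(matrix(abs(rnorm(2 * nf)), 2))
  sc <- state_correlations(dff, mask)
  expect_lt(abs(sc$pairs$raw_interictal), 0.05)
  expect_lt(abs(sc$pairs$raw_ictal), 0.05)
})

test_that("insufficient state data raises an error", {
  dff <- make_dff(matrix(abs(rnorm(2 * 2000)), 2))
  short_mask <- build_ictal_mask(make_seizures(10, 12),
                                 (seq_len(2000) - 0.5) / 10)
  expect_error(state_correlations(dff, short_mask), "insufficient")
})

test_that("planted common input is recovered at the target correlation", {
  sess <- cached("shared_session", simulate_session(sim_config(
    duration_s = 1200, n_neurons = 14, n_neuropil = 2,
    shared_signal_fraction = 0.5,
    class_fractions = c(ictal_low = 0, ictal_high = 0, neutral = 1,
                        quiet = 0),
    seed = 5)))
  seiz <- filter_seizures(detect_seizures(sess$eeg))
  mask <- build_ictal_mask(seiz, sess$frame_times)
  dff <- suppressWarnings(flag_quiet(denoise_dff(
    compute_dff(sess$fluor, 10))))
  sc <- state_correlations(dff, mask, kinds = sess$rois$kind)
  nn <- sc$pairs[sc$pairs$type == "neuron-neuron", ]
  expect_lt(abs(mean(nn$raw_interictal) -
                  sess$truth$pairwise_target_corr), 0.1)
})

test_that("shuffle correction matches an explicit-shift oracle", {
  set.seed(43)
  n <- 400
  x <- abs(rnorm(n)); y <- abs(rnorm(n))
  rk <- ictaltrace:::all_shift_cor(x, y)
  for (k in c(1, 17, 211)) {
    shifted <- c(y[(k + 1):n], y[seq_len(k)])   # left shift by k
    expect_equal(rk[k + 1], cor(x, shifted), tolerance = 1e-9)
  }
  expect_equal(rk[1], cor(x, y), tolerance = 1e-9)
})

test_that("corrected coefficients are invariant to trace rescaling", {
  set.seed(44)
  m <- matrix(abs(rnorm(2 * 12000)), 2) +
    rbind(rep(0, 12000), rep(0, 12000))
  dff1 <- make_dff(m)
  m2 <- m; m2[1, ] <- 3.7 * m2[1, ]
  dff2 <- make_dff(m2)
  mask <- sync_mask()
  c1 <- shuffle_correct(state_correlations(dff1, mask), 300, seed = 6)
  c2 <- shuffle_correct(state_correlations(dff2, mask), 300, seed = 6)
  expect_lt(abs(c1$pairs$corrected_interictal -
                  c2$pairs$corrected_interictal), 0.01)
  expect_lt(abs(c1$pairs$corrected_ictal - c2$pairs$corrected_ictal), 0.01)
})

test_that("constant series are skipped with a flag", {
  m <- rbind(abs(rnorm(12000)), rep(1, 12000))
  sc <- suppressWarnings(state_correlations(make_dff(m), sync_mask()))
  sc <- shuffle_correct(sc, 50, seed = 1)
  expect_true(sc$pairs$skipped[1])
})

test_that("rate matching equalizes state means by event removal", {
  an <- small_analysis()
  rm <- rate_match_by_event_removal(an$dff, an$mask, seed = 9)
  lg <- rm$log
  done <- !is.na(lg$matched)
  ## every reachable cell lands inside the tolerance
  expect_true(all(abs(lg$achieved_diff[done & lg$matched]) < 0.1))
  ## removals only happen in the initially higher-rate state
  ict <- which(an$mask$ictal)
  int <- which(!an$mask$ictal)
  for (r in which(done & lg$n_removed > 0)) {
    d0 <- mean(an$dff$dff[r, ict]) - mean(an$dff$dff[r, int])
    expect_identical(lg$removed_from[r],
                     if (d0 > 0) "ictal" else "interictal")
    ## removal can only zero samples, never add
    expect_true(all(rm$dff$dff[r, ] <= an$dff$dff[r, ] + 1e-12))
  }
  ## equal means need no removals
  eq <- make_dff(matrix(rep(c(0, 5), 6000), 1))
  meq <- sync_mask()
  lg2 <- rate_match_by_event_removal(eq, meq, seed = 1)$log
  expect_identical(lg2$n_removed[1], 0L)
})

test_that("neuropil patches are more correlated than neurons", {
  an <- small_analysis()
  sc <- state_correlations(an$dff, an$mask, kinds = an$sess$rois$kind)
  pr <- sc$pairs
  expect_gt(mean(pr$raw_interictal[pr$type == "neuropil-neuropil"]),
            mean(pr$raw_interictal[pr$type == "neuron-neuron"]))
})
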
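## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## A mid-sized session with defaults: 10 min, 24 neurons, 4 neuropil.
small_session <- function() {
  cached("small_session", simulate_session(
    sim_config(duration_s = 600, n_neurons = 24, n_neuropil = 4, seed = 11)))
}

small_analysis <- function() {
  cached("small_analysis", {
    sess <- small_session()
    seiz <- filter_seizures(detect_seizures(sess$eeg))
    mask <- build_ictal_mask(seiz, sess$frame_times)
    dff <- suppressWarnings(
      flag_quiet(denoise_dff(compute_dff(
        sess$fluor, sess$config$frame_rate_hz))))
    list(sess = sess, seiz = seiz, mask = mask, dff = dff)
  })
}

## Hand-built dff_matrix around a given matrix (percent units), marked
## denoised so downstream stages accept it.
make_dff <- function(mat, frame_rate_hz = 10, indicator = "GCaMP6M",
                     denoised = TRUE) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  n <- nrow(mat)
  structure(list(dff = mat, frame_rate_hz = frame_rate_hz,
                 frame_times = (seq_len(ncol(mat)) - 0.5) / frame_rate_hz,
                 indicator = indicator, degenerate = rep(FALSE, n),
                 noise_sigma = rep(0.5, n), quiet = rep(FALSE, n),
                 denoised = denoised),
            class = "dff_matrix")
}

## Seizure set from bare onset/offset vectors (spikes at 6 Hz).
make_seizures <- function(onset, offset) {
  st <- lapply(seq_along(onset), function(k)
    seq(onset[k], offset[k], by = 1 / 6))
  structure(data.frame(onset_s = onset, offset_s = offset,
                       mean_spike_freq_hz = rep(6, length(onset))),
            spike_times_s = st,
            class = c("seizure_set", "data.frame"))
}

## Whole-cell / cell-attached template train on a noiseless baseline.
template_train <- function(times, mode, amp = NULL, dur_s = 10,
                           rate_hz = 10000, noise_sd = 0) {
  p <- ap_params(mode)
  if (is.null(amp)) amp <- 2 * p$x
  v <- rnorm(round(dur_s * rate_hz), sd = noise_sd)
  wf <- ictaltrace:::ap_waveform(p, rate_hz, amp)
  for (s in times) {
    i0 <- round(s * rate_hz) + 1L
    idx <- i0 + seq_along(wf) - 1L
    ok <- idx >= 1 & idx <= length(v)
    v[idx[ok]] <- v[idx[ok]] + wf[ok]
  }
  v
}
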
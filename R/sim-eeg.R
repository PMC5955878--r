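## Synthetic EEG with planted spike-wave discharges.

## 1/f ("pink") background noise via spectral shaping of white noise.
pink_noise <- function(n, rate_hz) {
  nf <- 2^ceiling(log2(n))
  w <- rnorm(nf)
  W <- fft(w)
  f <- c(1, seq_len(nf - 1))            # avoid DC blow-up
  f <- pmin(f, nf - f + 1)              # two-sided frequency index
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x / sd(x)
}

## Biphasic spike-wave unit waveform: sharp positive spike (sigma_ms wide)
## followed by a slower negative wave, peak value 1 at t = 0.
swd_waveform <- function(rate_hz, sigma_ms = 3, wave_ms = 60) {
  t <- seq(-0.02, 0.12, by = 1 / rate_hz)
  spike <- exp(-(t * 1000)^2 / (2 * sigma_ms^2))
  wave <- -0.45 * exp(-((t * 1000 - 45)^2) / (2 * (wave_ms / 2.355)^2))
  list(t = t, v = spike + wave, peak_idx = which.min(abs(t)))
}

#' Simulate an EEG trace with planted spike-wave seizures
#'
#' Generates pink (1/f) background noise plus planted spike-wave bursts.
#' Each burst consists of regular sharp biphasic spikes at the configured
#' 5--9 Hz frequency riding on a slow wave; spike peak amplitude is set to a
#' multiple (default 6x) of the background's robust (MAD-derived) envelope,
#' comfortably above the 1.5x detection criterion. Planted bursts are spaced
#' at least 8 s apart so they survive seizure curation.
#'
#' @param config a [sim_config()].
#' @param amp_factor planted spike amplitude as a multiple of the background
#'   MAD envelope.
#' @return list with \code{eeg} (an [eeg_recording()]) and \code{truth}, a
#'   data frame of planted seizures (onset_s, offset_s, spike_times_s list
#'   column).
#' @export
simulate_eeg <- function(config, amp_factor = 6) {
  validate_sim_config(config)
  rate <- config$eeg_rate_hz
  dur <- config$duration_s
  n <- round(dur * rate)
  with_seed(stage_seed(config$seed, "eeg"), {
    bg <- pink_noise(n, rate)
    env <- 1.4826 * mad(bg, center = median(bg))
    seiz <- plant_seizure_times(config)
    v <- bg
    wf <- swd_waveform(rate)
    amp <- amp_factor * env
    all_spikes <- vector("list", nrow(seiz))
    for (k in seq_len(nrow(seiz))) {
      f <- config$swd_spike_freq_hz
      nspk <- floor((seiz$offset_s[k] - seiz$onset_s[k]) * f) + 1L
      st <- seiz$onset_s[k] + (seq_len(nspk) - 1L) / f
      all_spikes[[k]] <- st
      for (s in st) {
        i0 <- round(s * rate) - (wf$peak_idx - 1L)
        idx <- i0 + seq_along(wf$v) - 1L
        ok <- idx >= 1 & idx <= n
        v[idx[ok]] <- v[idx[ok]] + amp * wf$v[ok]
      }
      seiz$offset_s[k] <- st[length(st)]
    }
    seiz$spike_times_s <- all_spikes
    list(eeg = eeg_recording(v, rate),
         truth = seiz)
  })
}

## Place seizures in equal slots with uniform jitter; guarantees >= 8 s
## separation and >= 5 s margins at the recording edges.
plant_seizure_times <- function(config) {
  dur <- config$duration_s
  n_target <- round(config$seizure_rate_per_min * dur / 60)
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  if (n_target < 1) return(empty)
  dmin <- config$seizure_duration_s[1]
  dmax <- config$seizure_duration_s[2]
  pad <- 5
  gap <- 8
  slot <- (dur - 2 * pad) / n_target
  if (slot < dmax + gap)
    stopf("duration too short for %d seizures of up to %g s", n_target, dmax)
  durs <- runif(n_target, dmin, dmax)
  onset <- pad + (seq_len(n_target) - 1) * slot +
    runif(n_target, 0, slot - durs - gap)
  data.frame(onset_s = onset, offset_s = onset + durs)
}
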
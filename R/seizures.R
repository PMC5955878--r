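## Spike-wave seizure detection and curation on the EEG.

#' EEG recording container
#'
#' @param samples numeric vector of EEG samples (microvolts).
#' @param rate_hz sampling rate in Hz (typically 2000 or 5000).
#' @param t0_s time of the first sample on the shared imaging clock (s).
#' @return an object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(samples, rate_hz, t0_s = 0) {
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stopf("rate_hz must be positive")
  if (any(!is.finite(samples)))
    stopf("EEG samples must be finite")
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 t0_s = t0_s),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz))
  invisible(x)
}

seizure_set <- function(onset_s, offset_s, spike_times_s,
                        mean_spike_freq_hz) {
  structure(data.frame(onset_s = onset_s, offset_s = offset_s,
                       mean_spike_freq_hz = mean_spike_freq_hz),
            spike_times_s = spike_times_s,
            class = c("seizure_set", "data.frame"))
}

#' Per-seizure spike times of a seizure set
#' @param seizures a seizure set from [detect_seizures()].
#' @return list of numeric vectors (seconds), one per seizure.
#' @export
spike_times <- function(seizures) attr(seizures, "spike_times_s")

#' Detect spike-wave seizures on an EEG trace
#'
#' Automates the printed seizure criteria: candidate spikes are peaks
#' exceeding \code{amp_factor} (default 1.5) times a robust rolling baseline
#' envelope, grouped into bursts when inter-spike intervals correspond to
#' 5--9 Hz (with tolerance, bridging at most one missing spike); bursts must
#' be regular (low inter-spike-interval dispersion), last at least
#' \code{min_duration_s}, and have a mean spike frequency inside
#' \code{freq_range_hz}. Onset and offset are the peaks of the first and
#' last spike. The baseline envelope is the 10-s rolling
#' median-absolute-deviation envelope of the band-passed signal, recomputed
#' once with detected bursts excluded (two passes).
#'
#' @param eeg an [eeg_recording()]; band-pass filtered to 1--250 Hz
#'   internally if \code{bandpass = TRUE}.
#' @param amp_factor spike threshold as a multiple of the baseline envelope.
#' @param freq_range_hz accepted mean intra-burst spike frequency (Hz).
#' @param min_duration_s minimum burst duration (s).
#' @param min_spikes minimum number of spikes per burst.
#' @param isi_cv_max maximum coefficient of variation of inter-spike
#'   intervals (regularity criterion).
#' @param bandpass apply the 1--250 Hz band-pass before detection.
#' @return a \code{seizure_set} data frame (onset_s, offset_s,
#'   mean_spike_freq_hz) with per-seizure spike times available via
#'   [spike_times()].
#' @export
detect_seizures <- function(eeg, amp_factor = 1.5, freq_range_hz = c(5, 9),
                            min_duration_s = 0.5, min_spikes = 4,
                            isi_cv_max = 0.25, bandpass = TRUE) {
  stopifnot(inherits(eeg, "eeg_recording"))
  v <- eeg$samples
  rate <- eeg$rate_hz
  if (length(v) < rate) return(empty_seizure_set())
  if (bandpass && rate > 502) {
    bf <- signal::butter(2, c(1, 250) / (rate / 2), type = "pass")
    v <- signal::filtfilt(bf, v)
  }
  ## pass 1: envelope from the whole trace; pass 2: exclude detected bursts
  mask <- rep(FALSE, length(v))
  spikes <- numeric(0)
  for (pass in 1:2) {
    env <- mad_envelope(v, rate, exclude = mask)
    spikes <- pick_spikes(v, rate, amp_factor * env)
    bursts <- group_bursts(spikes$time_s, spikes$amp, freq_range_hz,
                           min_duration_s, min_spikes, isi_cv_max)
    mask <- rep(FALSE, length(v))
    for (b in bursts) {
      i1 <- max(1L, floor((b[1] - 0.5) * rate))
      i2 <- min(length(v), ceiling((b[length(b)] + 0.5) * rate))
      mask[i1:i2] <- TRUE
    }
    if (length(bursts) == 0) break
  }
  if (length(bursts) == 0) return(empty_seizure_set())
  onset <- vapply(bursts, function(b) b[1], 0) + eeg$t0_s
  offset <- vapply(bursts, function(b) b[length(b)], 0) + eeg$t0_s
  freq <- vapply(bursts, function(b) (length(b) - 1) / (max(b) - min(b)), 0)
  seizure_set(onset, offset, lapply(bursts, function(b) b + eeg$t0_s), freq)
}

empty_seizure_set <- function() {
  seizure_set(numeric(0), numeric(0), list(), numeric(0))
}

## Rolling robust background envelope: per-second MAD-derived sigma scaled
## to the ~95% amplitude band (2 sigma), median-smoothed over a 10-s
## neighbourhood, constant within each second. The 2-sigma scaling makes
## "amplitude" mean what an electroencephalographer reads as the background
## band, not the RMS, so the 1.5x spike criterion lands at ~3 sigma.
mad_envelope <- function(v, rate, exclude = NULL) {
  sec <- ceiling(seq_along(v) / rate)
  nsec <- max(sec)
  x <- v
  if (!is.null(exclude)) x[exclude] <- NA
  s <- vapply(split(x, sec), function(ch) {
    ch <- ch[!is.na(ch)]
    if (length(ch) < 10) NA_real_ else 2 * 1.4826 * mad(ch, constant = 1)
  }, 0)
  if (all(is.na(s))) s[] <- 2 * 1.4826 * mad(v, constant = 1)
  if (anyNA(s)) {
    ok <- which(!is.na(s))
    s <- stats::approx(ok, s[ok], xout = seq_len(nsec), rule = 2)$y
  }
  sm <- stats::runmed(s, k = min(11L, nsec - (1 - nsec %% 2)))
  rep(sm, each = rate, length.out = length(v))
}

## Local maxima above threshold with a minimum 80-ms separation.
pick_spikes <- function(v, rate, thr) {
  pk <- local_maxima(v)
  pk <- pk[v[pk] > pmax(thr[pk], 1e-12)]
  if (length(pk) == 0)
    return(data.frame(time_s = numeric(0), amp = numeric(0)))
  min_gap <- round(0.08 * rate)
  keep <- integer(0)
  last <- -Inf
  for (i in pk) {
    if (i - last >= min_gap) {
      keep <- c(keep, i)
      last <- i
    } else if (v[i] > v[keep[length(keep)]]) {
      keep[length(keep)] <- i      # keep the taller of two close peaks
      last <- i
    }
  }
  data.frame(time_s = (keep - 1) / rate, amp = v[keep])
}

group_bursts <- function(spikes, amps, freq_range_hz, min_duration_s,
                         min_spikes, isi_cv_max) {
  if (length(spikes) < min_spikes) return(list())
  isi_min <- 1 / freq_range_hz[2] - 0.03
  isi_max <- 1 / freq_range_hz[1] + 0.06
  bridge_max <- 2 * isi_max                 # one missing spike bridged
  isi <- diff(spikes)
  brk <- which(isi > bridge_max)
  gid <- rep(seq_len(length(brk) + 1), diff(c(0, brk, length(spikes))))
  grp <- split(spikes, gid)
  grp_a <- split(amps, gid)
  keep <- list()
  for (k in seq_along(grp)) {
    g <- grp[[k]]
    a <- grp_a[[k]]
    ## trim edge spikes well below the burst amplitude (chained noise peaks)
    while (length(g) > 1 && a[1] < 0.6 * median(a)) {
      g <- g[-1]; a <- a[-1]
    }
    while (length(g) > 1 && a[length(a)] < 0.6 * median(a)) {
      g <- g[-length(g)]; a <- a[-length(a)]
    }
    if (length(g) < min_spikes) next
    dur <- max(g) - min(g)
    if (dur < min_duration_s) next
    f <- (length(g) - 1) / dur
    if (f < freq_range_hz[1] || f > freq_range_hz[2]) next
    gi <- diff(g)
    core <- gi >= isi_min & gi <= isi_max
    if (mean(core) < 0.7) next
    if (sd(gi[core]) / mean(gi[core]) > isi_cv_max) next
    keep[[length(keep) + 1]] <- g
  }
  keep
}

#' Curate a set of detected seizures
#'
#' Applies the exclusion rules used before any temporal analysis: seizures
#' shorter than 1.5 s are removed, and both members of any pair of seizures
#' less than 6 s apart (offset to next onset) are removed; this also
#' eliminates every inter-seizure interval shorter than 1.5 s. Idempotent.
#'
#' @param seizures a \code{seizure_set}.
#' @param min_duration_s minimum seizure duration (s).
#' @param min_gap_s minimum inter-seizure interval (s).
#' @return the curated \code{seizure_set}.
#' @export
filter_seizures <- function(seizures, min_duration_s = 1.5, min_gap_s = 6) {
  st <- spike_times(seizures)
  o <- order(seizures$onset_s)
  seizures <- seizures[o, , drop = FALSE]
  st <- st[o]
  n <- nrow(seizures)
  if (n == 0) return(empty_seizure_set())
  if (n > 1 &&
      any(seizures$onset_s[-1] < seizures$offset_s[-n]))
    stopf("overlapping seizure intervals")
  dur_ok <- (seizures$offset_s - seizures$onset_s) >= min_duration_s
  seizures <- seizures[dur_ok, , drop = FALSE]
  st <- st[dur_ok]
  n <- nrow(seizures)
  if (n == 0) return(empty_seizure_set())
  drop <- rep(FALSE, n)
  if (n > 1) {
    gap <- seizures$onset_s[-1] - seizures$offset_s[-n]
    close <- which(gap < min_gap_s)
    drop[close] <- TRUE
    drop[close + 1] <- TRUE
  }
  seizure_set(seizures$onset_s[!drop], seizures$offset_s[!drop],
              st[!drop], seizures$mean_spike_freq_hz[!drop])
}

#' Build the per-frame ictal/interictal mask
#'
#' A frame is ictal iff its midpoint time lies inside an accepted seizure
#' interval. Frame times are taken to be frame midpoints.
#'
#' @param seizures a \code{seizure_set} (ideally after [filter_seizures()]).
#' @param frame_times strictly increasing frame midpoint times (s).
#' @return an \code{ictal_mask}: list with logical \code{ictal},
#'   logical \code{excluded} (all FALSE here), \code{frame_times} and
#'   ictal/interictal frame counts.
#' @export
build_ictal_mask <- function(seizures, frame_times) {
  if (is.unsorted(frame_times, strictly = TRUE))
    stopf("frame_times must be strictly increasing")
  ictal <- rep(FALSE, length(frame_times))
  for (k in seq_len(nrow(seizures)))
    ictal <- ictal | (frame_times >= seizures$onset_s[k] &
                        frame_times <= seizures$offset_s[k])
  structure(list(ictal = ictal, excluded = rep(FALSE, length(frame_times)),
                 frame_times = frame_times,
                 n_ictal = sum(ictal), n_interictal = sum(!ictal)),
            class = "ictal_mask")
}

#' @export
print.ictal_mask <- function(x, ...) {
  cat(sprintf("<ictal_mask> %d frames: %d ictal, %d interictal, %d excluded\n",
              length(x$ictal), sum(x$ictal & !x$excluded),
              sum(!x$ictal & !x$excluded), sum(x$excluded)))
  invisible(x)
}

#' Exclude locomotion frames from both states
#'
#' Marks frames whose absolute velocity exceeds \code{threshold} as excluded;
#' downstream statistics ignore excluded frames in both the ictal and the
#' interictal state ("digital subtraction" of locomotion frames).
#'
#' @param mask an \code{ictal_mask}.
#' @param velocity per-frame velocity (cm/s), aligned to the mask.
#' @param threshold exclusion threshold (cm/s).
#' @return the mask with updated \code{excluded}, plus
#'   \code{excluded_frames}, the indices newly excluded.
#' @export
remove_locomotion_frames <- function(mask, velocity, threshold = 1) {
  stopifnot(inherits(mask, "ictal_mask"))
  if (length(velocity) != length(mask$ictal))
    stopf("velocity length (%d) does not match frame count (%d)",
          length(velocity), length(mask$ictal))
  moving <- abs(velocity) > threshold
  mask$excluded <- mask$excluded | moving
  mask$n_ictal <- sum(mask$ictal & !mask$excluded)
  mask$n_interictal <- sum(!mask$ictal & !mask$excluded)
  mask$excluded_frames <- which(moving)
  mask
}
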
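## Event-rate inference: iterative smoothing + exponential inverse filter.

#' Iteratively smooth a delta-F/F trace
#'
#' Removes local low-amplitude peaks representing noise without distorting
#' genuine calcium transients: passes of a 3-point median followed by a
#' 3-point mean filter are applied until no local maximum with prominence
#' below \code{2 * noise_sigma} remains, or \code{max_passes} passes.
#' Samples that rise more than \code{2 * noise_sigma} above their smoothed
#' value -- and whose following sample does too, the signature of a
#' kernel-shaped transient rather than a one-sample noise spike -- are kept
#' unmodified in each pass, so sharp transient peaks (which rise within a
#' single frame at typical frame rates) are not clipped.
#'
#' @param x numeric delta-F/F trace (percent).
#' @param noise_sigma per-trace noise SD (percent), e.g. from
#'   [denoise_dff()].
#' @param max_passes maximum smoothing passes.
#' @return the smoothed trace.
#' @export
iterative_smooth <- function(x, noise_sigma, max_passes = 10) {
  if (length(x) < 3) return(x)
  for (pass in seq_len(max_passes)) {
    pk <- local_maxima(x)
    if (length(pk) == 0) break
    prom <- peak_prominence(x, pk)
    if (all(prom >= 2 * noise_sigma)) break
    s <- runmed(x, 3)
    s <- stats::filter(s, rep(1 / 3, 3), sides = 2)
    s[1] <- s[2]; s[length(s)] <- s[length(s) - 1]
    s <- as.numeric(s)
    dev <- x - s > 2 * noise_sigma
    ## transient signature: the next sample stays elevated above the noise
    keep <- dev & c(x[-1], 0) > 2 * noise_sigma
    s[keep] <- x[keep]
    x <- s
  }
  x
}

## Prominence of each local maximum: height above the higher of the two
## flanking minima (trace ends count as minima).
peak_prominence <- function(x, pk) {
  n <- length(x)
  vapply(pk, function(i) {
    l <- i
    while (l > 1 && x[l - 1] <= x[l]) l <- l - 1
    r <- i
    while (r < n && x[r + 1] <= x[r]) r <- r + 1
    x[i] - max(x[l], x[r])
  }, 0)
}

#' Inverse-filter a smoothed trace with an exponential kernel
#'
#' Deconvolution by the discrete first-order exponential kernel
#' \code{k(t) = exp(-t / tau)}: \code{rate(t) = x(t) - a * x(t - 1)} with
#' \code{a = exp(-dt / tau)}, rectified at zero. For a trace that is exactly
#' an exponential decay this returns a single nonzero sample at the
#' transient onset.
#'
#' @param x smoothed delta-F/F trace (percent).
#' @param tau_s indicator decay constant (s); defaults: 0.6 s for GCaMP6M,
#'   1.0 s for GCaMP6S.
#' @param frame_rate_hz frame rate (Hz).
#' @return non-negative inferred event-rate trace (arbitrary units).
#' @export
inverse_filter <- function(x, tau_s, frame_rate_hz) {
  if (tau_s <= 0) stopf("tau_s must be positive")
  a <- exp(-1 / (tau_s * frame_rate_hz))
  r <- x - a * c(0, x[-length(x)])
  pmax(r, 0)
}

DEFAULT_TAU <- c(GCaMP6M = 0.6, GCaMP6S = 1.0)

#' Deconvolve all traces of a dff_matrix
#'
#' Applies [iterative_smooth()] then [inverse_filter()] per ROI and returns
#' the inferred rate traces alongside the input.
#'
#' @param dff a denoised \code{dff_matrix}.
#' @param tau_s kernel decay constant (s); default chosen by indicator.
#' @return list with \code{rate} (ROI x frame matrix) and \code{tau_s}.
#' @export
deconvolve_dff <- function(dff, tau_s = NULL) {
  stopifnot(inherits(dff, "dff_matrix"))
  if (is.null(tau_s)) tau_s <- DEFAULT_TAU[[dff$indicator]]
  rate <- dff$dff
  for (i in seq_len(nrow(rate))) {
    if (dff$degenerate[i]) next
    s <- iterative_smooth(dff$dff[i, ],
                          if (is.na(dff$noise_sigma[i])) 0
                          else dff$noise_sigma[i])
    rate[i, ] <- inverse_filter(s, tau_s, dff$frame_rate_hz)
  }
  list(rate = rate, tau_s = tau_s)
}

#' Smooth event or spike times into a rate trace
#'
#' Counts in a sliding boxcar window (default 100 ms) divided by the window
#' length, sampled on a regular grid.
#'
#' @param times sorted event times (s).
#' @param duration_s output duration (s).
#' @param window_ms boxcar width (ms).
#' @param rate_hz output sampling rate (Hz).
#' @return numeric rate series (events/s) of length
#'   \code{duration_s * rate_hz}.
#' @export
smooth_rate <- function(times, duration_s, window_ms = 100, rate_hz = 100) {
  n <- round(duration_s * rate_hz)
  tt <- (seq_len(n) - 0.5) / rate_hz
  w <- window_ms / 1000 / 2
  if (length(times) == 0) return(numeric(n))
  counts <- findInterval(tt + w, sort(times)) -
    findInterval(tt - w, sort(times))
  counts / (2 * w)
}

#' Smooth inferred rate traces to the indicator's timescale
#'
#' Deconvolution sharpens activity to near-instantaneous events, while the
#' fluorescence it came from carries information at the kernel's timescale.
#' Analyses that compare the two representations (for example, re-running
#' the ictal classification on inferred rates) should first re-smooth the
#' rate traces with a boxcar of the kernel width, mirroring the practice of
#' choosing the spike-rate smoothing window that best matches deconvolved
#' traces.
#'
#' @param rate ROI x frame matrix of inferred rates.
#' @param width_s boxcar width (s); use the kernel decay constant.
#' @param frame_rate_hz frame rate (Hz).
#' @return the smoothed matrix.
#' @export
smooth_rate_traces <- function(rate, width_s, frame_rate_hz) {
  n <- max(1L, round(width_s * frame_rate_hz))
  if (n == 1) return(rate)
  t(apply(rate, 1, function(x) {
    s <- as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
    s[is.na(s)] <- 0
    s
  }))
}
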
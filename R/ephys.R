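## Action-potential detection in patch-clamp voltage traces and their
## relation to EEG seizure spikes.

#' Action-potential detection parameters
#'
#' Window bounds are in milliseconds, the threshold \code{x} in millivolts.
#' Defaults are the two published parameter sets: whole-cell
#' (x = 38 mV, pre = 1.2/0.3 ms, peak = 0.25/0.35 ms, post = 2.5/2.9 ms,
#' alpha = 0.5, beta = 0.8) and cell-attached (x = 1.9 mV, pre = 0.8/0.25
#' ms, peak = 0.15/0.24 ms, post = 1.8/2.1 ms, alpha = 0.55, beta = 0.45).
#'
#' @param mode \code{"whole_cell"} or \code{"cell_attached"}.
#' @param ... named overrides of any field.
#' @return list of class \code{ap_params}.
#' @export
ap_params <- function(mode = c("whole_cell", "cell_attached"), ...) {
  mode <- match.arg(mode)
  p <- if (mode == "whole_cell") {
    list(x = 38, pre1 = 1.2, pre2 = 0.3, p1 = 0.25, p2 = 0.35,
         post1 = 2.5, post2 = 2.9, alpha = 0.5, beta = 0.8)
  } else {
    list(x = 1.9, pre1 = 0.8, pre2 = 0.25, p1 = 0.15, p2 = 0.24,
         post1 = 1.8, post2 = 2.1, alpha = 0.55, beta = 0.45)
  }
  over <- list(...)
  p[names(over)] <- over
  p$mode <- mode
  if (!(p$pre1 > p$pre2 && p$pre2 > 0)) stopf("need pre1 > pre2 > 0")
  if (!(p$p2 > p$p1 && p$p1 > 0)) stopf("need p2 > p1 > 0")
  if (!(p$post2 > p$post1 && p$post1 > 0)) stopf("need post2 > post1 > 0")
  structure(p, class = "ap_params")
}

#' Detect action potentials in a voltage trace
#'
#' A sample \code{t} is flagged as an AP when all three criteria hold, with
#' \code{V} the membrane (or pipette) voltage and windows in ms:
#' \enumerate{
#'   \item \code{V(t + 0.25 ms) > V(t) + x} (fast depolarization);
#'   \item \code{mean(V(t - pre1 .. t - pre2)) <
#'     mean(V(t + p1 .. t + p2)) - alpha * x} (peak well above the
#'     pre-spike baseline);
#'   \item \code{mean(V(t + post1 .. t + post2)) <
#'     mean(V(t - pre1 .. t - pre2)) + beta * x} (repolarization).
#' }
#' Window means use inclusive sample ranges with bounds rounded to the
#' nearest sample. Runs of flagged samples within 1 ms collapse to the
#' earliest sample.
#'
#' @param v voltage trace (mV).
#' @param rate_hz sampling rate (Hz); 10 kHz recommended.
#' @param params an [ap_params()].
#' @return object of class \code{ap_train}: list with \code{times} (s),
#'   \code{mode} and \code{rate_hz}.
#' @export
detect_aps <- function(v, rate_hz, params) {
  stopifnot(inherits(params, "ap_params"))
  n <- length(v)
  ms <- rate_hz / 1000
  k25 <- round(0.25 * ms)
  pre1 <- round(params$pre1 * ms); pre2 <- round(params$pre2 * ms)
  p1 <- round(params$p1 * ms); p2 <- round(params$p2 * ms)
  post1 <- round(params$post1 * ms); post2 <- round(params$post2 * ms)
  if (n <= post2 + 1) stopf("trace shorter than the widest window")
  cs <- c(0, cumsum(v))
  win_mean <- function(lo_off, hi_off, t) {
    lo <- t + lo_off; hi <- t + hi_off
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  t <- (pre1 + 1L):(n - post2)
  c1 <- v[t + k25] > v[t] + params$x
  pre_m <- win_mean(-pre1, -pre2, t)
  peak_m <- win_mean(p1, p2, t)
  post_m <- win_mean(post1, post2, t)
  c2 <- pre_m < peak_m - params$alpha * params$x
  c3 <- post_m < pre_m + params$beta * params$x
  hit <- t[c1 & c2 & c3]
  if (length(hit) == 0)
    return(structure(list(times = numeric(0), mode = params$mode,
                          rate_hz = rate_hz), class = "ap_train"))
  ## collapse flagged samples within 1 ms to the earliest
  keep <- c(TRUE, diff(hit) >= round(1 * ms))
  times <- (hit[keep] - 1L) / rate_hz
  structure(list(times = times, mode = params$mode, rate_hz = rate_hz),
            class = "ap_train")
}

#' @export
print.ap_train <- function(x, ...) {
  cat(sprintf("<ap_train> %d APs (%s)\n", length(x$times), x$mode))
  invisible(x)
}

#' Ictal versus interictal firing rates of a patched neuron
#'
#' Computes, per seizure, the firing rate inside the seizure and in the
#' flanking interictal interval (previous offset to onset and offset to next
#' onset), then compares the paired per-seizure rates with the Wilcoxon
#' signed-rank test and labels the neuron ictal-low, ictal-high or neutral.
#'
#' @param aps an \code{ap_train}.
#' @param seizures curated \code{seizure_set}.
#' @param duration_s recording length (s); defaults to just past the last
#'   event.
#' @param alpha significance level.
#' @return list with per-seizure rates, overall \code{ictal_rate} /
#'   \code{interictal_rate} (Hz), \code{p_value} and \code{label}.
#' @export
state_firing_rates <- function(aps, seizures, duration_s = NULL,
                               alpha = 0.05) {
  stopifnot(inherits(aps, "ap_train"))
  m <- nrow(seizures)
  if (m < 2) stopf("need at least 2 seizures")
  if (is.null(duration_s))
    duration_s <- max(c(aps$times, seizures$offset_s)) + 1
  times <- aps$times
  if (length(times) == 0) {
    return(list(per_seizure = NULL, ictal_rate = 0, interictal_rate = 0,
                p_value = NA_real_, label = "neutral"))
  }
  rate_in <- function(a, b) {
    if (b <= a) return(NA_real_)
    sum(times >= a & times < b) / (b - a)
  }
  per <- data.frame(ictal = NA_real_, interictal = NA_real_)[0, ]
  for (k in seq_len(m)) {
    ri <- rate_in(seizures$onset_s[k], seizures$offset_s[k])
    a <- if (k == 1) 0 else seizures$offset_s[k - 1]
    b <- if (k == m) duration_s else seizures$onset_s[k + 1]
    ro_pre <- rate_in(a, seizures$onset_s[k])
    ro_post <- rate_in(seizures$offset_s[k], b)
    ro <- mean(c(ro_pre, ro_post), na.rm = TRUE)
    per <- rbind(per, data.frame(ictal = ri, interictal = ro))
  }
  p <- suppressWarnings(
    wilcox.test(per$ictal, per$interictal, paired = TRUE,
                exact = FALSE)$p.value)
  mi <- mean(per$ictal, na.rm = TRUE)
  mo <- mean(per$interictal, na.rm = TRUE)
  label <- if (!is.na(p) && p < alpha) {
    if (mi < mo) "ictal_low" else "ictal_high"
  } else "neutral"
  list(per_seizure = per, ictal_rate = mi, interictal_rate = mo,
       p_value = p, label = label)
}

#' Peri-EEG-spike histogram of action potentials
#'
#' Each AP is referenced to its nearest EEG seizure spike (ties to the
#' earlier spike) and the offsets are histogrammed over -100 to +100 ms in
#' \code{bin_ms} bins. Also reports the coincidence fraction -- the
#' proportion of EEG spikes with at least one AP within +/- 20 ms -- and a
#' D'Agostino--Pearson omnibus normality test of the offsets (a unimodal,
#' spike-locked neuron yields approximately normal offsets).
#'
#' @param aps an \code{ap_train}.
#' @param eeg_spike_times EEG spike times (s), e.g. unlisted
#'   [spike_times()].
#' @param bin_ms histogram bin width (ms).
#' @param window_ms histogram half-width (ms).
#' @param coincidence_ms coincidence half-window (ms).
#' @return list with \code{breaks_ms}, \code{counts},
#'   \code{coincidence_fraction}, \code{offsets_ms} and
#'   \code{normality_p}.
#' @export
peri_eeg_spike_histogram <- function(aps, eeg_spike_times, bin_ms = 20,
                                     window_ms = 100, coincidence_ms = 20) {
  stopifnot(inherits(aps, "ap_train"))
  if (length(eeg_spike_times) == 0) stopf("empty EEG spike list")
  es <- sort(eeg_spike_times)
  breaks <- seq(-window_ms, window_ms, by = bin_ms)
  if (length(aps$times) == 0) {
    return(list(breaks_ms = breaks, counts = integer(length(breaks) - 1),
                coincidence_fraction = 0, offsets_ms = numeric(0),
                normality_p = NA_real_))
  }
  ## nearest EEG spike per AP, ties to the earlier spike
  i <- findInterval(aps$times, es)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(es))
  d_lo <- abs(aps$times - es[lo])
  d_hi <- abs(aps$times - es[hi])
  nearest <- ifelse(i == 0, es[hi], ifelse(d_lo <= d_hi, es[lo], es[hi]))
  off <- (aps$times - nearest) * 1000
  inw <- off >= -window_ms & off <= window_ms
  counts <- graphics::hist(off[inw], breaks = breaks, plot = FALSE)$counts
  w <- coincidence_ms / 1000
  hit <- vapply(es, function(s) any(abs(aps$times - s) <= w), TRUE)
  list(breaks_ms = breaks, counts = counts,
       coincidence_fraction = mean(hit), offsets_ms = off[inw],
       normality_p = dagostino_pearson(off[inw]))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standard normal transforms of sample skewness and kurtosis
#' into K2 = Zs^2 + Zk^2, referred to a chi-squared distribution with 2
#' degrees of freedom.
#'
#' @param x numeric sample (n >= 20 recommended).
#' @return two-sided p-value, or NA when n < 8 or the sample is constant.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8 || sd(x) < 1e-12) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3
  ## skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  d <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  zs <- d * log(y / a + sqrt((y / a)^2 + 1))
  ## kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  stdb2 <- (g2 + 3 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  zk <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + stdb2 * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))
  k2 <- zs^2 + zk^2
  pchisq(k2, df = 2, lower.tail = FALSE)
}
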
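## Synthetic patch-clamp voltage traces with planted action potentials.

## Stereotyped AP waveform sampled at rate_hz, built so that a spike of
## amplitude `amp` (mV above baseline) satisfies the three detection
## criteria of its mode when amp comfortably exceeds the threshold x:
## linear rise over [0, p1] ms, plateau to p2 + 0.1 ms, then fast
## exponential repolarization completed well before the post window.
ap_waveform <- function(params, rate_hz, amp) {
  dt_ms <- 1000 / rate_hz
  t <- seq(0, params$post2 + 1, by = dt_ms)
  rise_end <- params$p1
  plat_end <- params$p2 + 0.1
  tau <- (params$post1 - plat_end) / 6
  v <- ifelse(t < rise_end, amp * t / rise_end,
              ifelse(t <= plat_end, amp,
                     amp * exp(-(t - plat_end) / tau)))
  v
}

#' Simulate a patch-clamp voltage trace with planted APs
#'
#' Baseline plus Gaussian noise plus stereotyped spike waveforms at planted
#' times. Waveform amplitude defaults to twice the detection threshold of
#' the requested mode so planted spikes satisfy detection criteria i--iii.
#' If \code{seizures} is supplied, the planted firing rate is multiplied by
#' \code{1 + ictal_modulation} inside seizure intervals.
#'
#' @param config a [sim_config()] (supplies duration and seed).
#' @param mode \code{"whole_cell"} or \code{"cell_attached"}.
#' @param seizures optional data frame of onset_s/offset_s intervals.
#' @param ap_rate_hz baseline firing rate (events/s).
#' @param ictal_modulation fractional rate change during seizures.
#' @param noise_sd_mv Gaussian noise SD (mV).
#' @param amp_mv spike amplitude above baseline (mV); default 2x threshold.
#' @param rate_hz sampling rate, default 10 kHz.
#' @return list with \code{voltage} (mV), \code{rate_hz}, \code{mode} and
#'   \code{truth} (planted AP times in seconds).
#' @export
simulate_voltage <- function(config, mode = c("whole_cell", "cell_attached"),
                             seizures = NULL, ap_rate_hz = 5,
                             ictal_modulation = 0, noise_sd_mv = NULL,
                             amp_mv = NULL, rate_hz = 10000) {
  mode <- match.arg(mode)
  params <- ap_params(mode)
  if (is.null(amp_mv)) amp_mv <- 2 * params$x
  if (is.null(noise_sd_mv))
    noise_sd_mv <- if (mode == "whole_cell") 1 else 0.1
  dur <- config$duration_s
  n <- round(dur * rate_hz)
  with_seed(stage_seed(config$seed, paste0("voltage_", mode)), {
    ## thinned Poisson train with 5 ms refractory spacing
    lam_max <- ap_rate_hz * max(1, 1 + ictal_modulation)
    cand <- if (lam_max > 0) {
      cumsum(rexp(max(10, ceiling(dur * lam_max * 2)), lam_max))
    } else numeric(0)
    ## keep clear of the trace edges: the detection criteria need the full
    ## pre/post windows around every spike
    cand <- cand[cand > 0.005 & cand < dur - 0.005]
    keep <- logical(length(cand))
    last <- -Inf
    for (i in seq_along(cand)) {
      lam <- ap_rate_hz
      if (!is.null(seizures) && nrow(seizures) > 0 &&
          any(cand[i] >= seizures$onset_s & cand[i] <= seizures$offset_s))
        lam <- ap_rate_hz * (1 + ictal_modulation)
      if (runif(1) < lam / lam_max && cand[i] - last >= 0.005) {
        keep[i] <- TRUE
        last <- cand[i]
      }
    }
    times <- cand[keep]
    v <- rnorm(n, sd = noise_sd_mv)
    wf <- ap_waveform(params, rate_hz, amp_mv)
    for (s in times) {
      i0 <- round(s * rate_hz) + 1L
      idx <- i0 + seq_along(wf) - 1L
      ok <- idx >= 1 & idx <= n
      v[idx[ok]] <- v[idx[ok]] + wf[ok]
    }
    list(voltage = v, rate_hz = rate_hz, mode = mode,
         truth = list(true_ap_times = times))
  })
}
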
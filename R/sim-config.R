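#' Configuration for the synthetic session generator
#'
#' Bundles every knob of the simulator into a validated list. Defaults
#' describe a typical 30-minute awake recording: spike-wave discharges at
#' roughly 0.7 events/min lasting 2--8 s with 6 Hz intra-burst spikes on a
#' 1/f EEG background, and GCaMP6M-like somatic traces at 10 Hz built by
#' convolving inhomogeneous Poisson event trains with an exponential kernel.
#'
#' @param duration_s recording length in seconds.
#' @param frame_rate_hz imaging frame rate (Hz); typical resonant/galvo
#'   acquisitions run at 10--20 Hz.
#' @param eeg_rate_hz EEG sampling rate (Hz).
#' @param seizure_rate_per_min planted seizure rate (events/min).
#' @param seizure_duration_s length-2 numeric, min and max seizure duration
#'   (s); draws are uniform in this range.
#' @param swd_spike_freq_hz intra-burst spike frequency (Hz), must lie in
#'   [5, 9].
#' @param class_fractions named proportions over
#'   \code{c("ictal_low","ictal_high","neutral","quiet")}, summing to 1.
#' @param modulation_depth named fractional change of event rate during the
#'   ictal state per class (negative = suppression).
#' @param event_rate_hz baseline (interictal) event rate of active neurons
#'   (events/s). Rates for individual neurons are jittered around this value.
#' @param quiet_event_rate_hz event rate of planted-quiet neurons (events/s).
#' @param event_amp_dff mean single-event delta-F/F amplitude, percent.
#' @param kernel_tau_s calcium indicator decay constant (s).
#' @param noise_sigma_dff Gaussian noise SD on delta-F/F, percent.
#' @param baseline_f raw-fluorescence baseline offset (arbitrary units).
#' @param n_neurons,n_neuropil numbers of neuron and neuropil ROIs.
#' @param neuropil_mixing number of neuron signals averaged into each
#'   neuropil patch.
#' @param shared_signal_fraction pairwise common-input strength in [0, 1):
#'   this fraction of each active neuron's events is drawn from a shared
#'   latent train, planting event-level pairwise correlation equal to the
#'   fraction.
#' @param shared_signal_state which state carries the shared input:
#'   \code{"both"}, \code{"interictal"} or \code{"ictal"}.
#' @param modulation_lead_s seconds before EEG seizure onset at which the
#'   rate modulation of modulated neurons begins (hypoactivity can precede
#'   the electrographic onset); 0 by default.
#' @param drift_enabled if TRUE, modulated neurons flip class at epoch
#'   boundaries (Markov switching of modulation depth).
#' @param drift_epoch_s epoch length for class drift (s).
#' @param drift_prob per-epoch probability that a modulated neuron flips to
#'   the opposite modulated class.
#' @param indicator \code{"GCaMP6M"} or \code{"GCaMP6S"}.
#' @param seed integer RNG seed controlling all simulator randomness.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(duration_s = 300, n_neurons = 20, seed = 1)
sim_config <- function(duration_s = 1800,
                       frame_rate_hz = 10,
                       eeg_rate_hz = 2000,
                       seizure_rate_per_min = 0.7,
                       seizure_duration_s = c(2, 8),
                       swd_spike_freq_hz = 6,
                       class_fractions = c(ictal_low = 0.72,
                                           ictal_high = 0.05,
                                           neutral = 0.11,
                                           quiet = 0.12),
                       modulation_depth = c(ictal_low = -0.8,
                                            ictal_high = 1.5,
                                            neutral = 0,
                                            quiet = 0),
                       event_rate_hz = 0.3,
                       quiet_event_rate_hz = 0.0005,
                       event_amp_dff = 25,
                       kernel_tau_s = 0.6,
                       noise_sigma_dff = 0.5,
                       baseline_f = 100,
                       n_neurons = 60,
                       n_neuropil = 8,
                       neuropil_mixing = 10,
                       shared_signal_fraction = 0.1,
                       shared_signal_state = "both",
                       modulation_lead_s = 0,
                       drift_enabled = FALSE,
                       drift_epoch_s = 900,
                       drift_prob = 1,
                       indicator = "GCaMP6M",
                       seed = 1L) {
  cfg <- list(duration_s = duration_s, frame_rate_hz = frame_rate_hz,
              eeg_rate_hz = eeg_rate_hz,
              seizure_rate_per_min = seizure_rate_per_min,
              seizure_duration_s = seizure_duration_s,
              swd_spike_freq_hz = swd_spike_freq_hz,
              class_fractions = class_fractions,
              modulation_depth = modulation_depth,
              event_rate_hz = event_rate_hz,
              quiet_event_rate_hz = quiet_event_rate_hz,
              event_amp_dff = event_amp_dff,
              kernel_tau_s = kernel_tau_s,
              noise_sigma_dff = noise_sigma_dff,
              baseline_f = baseline_f,
              n_neurons = n_neurons, n_neuropil = n_neuropil,
              neuropil_mixing = neuropil_mixing,
              shared_signal_fraction = shared_signal_fraction,
              shared_signal_state = shared_signal_state,
              modulation_lead_s = modulation_lead_s,
              drift_enabled = drift_enabled,
              drift_epoch_s = drift_epoch_s,
              drift_prob = drift_prob,
              indicator = indicator,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0)
    stopf("duration_s must be positive")
  if (cfg$frame_rate_hz <= 0 || cfg$eeg_rate_hz <= 0)
    stopf("sampling rates must be positive")
  if (cfg$seizure_rate_per_min < 0)
    stopf("seizure_rate_per_min must be non-negative")
  if (length(cfg$seizure_duration_s) != 2 ||
      diff(cfg$seizure_duration_s) < 0 || cfg$seizure_duration_s[1] <= 0)
    stopf("seizure_duration_s must be an increasing positive pair")
  if (cfg$swd_spike_freq_hz < 5 || cfg$swd_spike_freq_hz > 9)
    stopf("swd_spike_freq_hz must lie in [5, 9]")
  cls <- c("ictal_low", "ictal_high", "neutral", "quiet")
  if (!all(cls %in% names(cfg$class_fractions)))
    stopf("class_fractions must name all four classes")
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9)
    stopf("class_fractions must sum to 1")
  if (!all(cls %in% names(cfg$modulation_depth)))
    stopf("modulation_depth must name all four classes")
  if (cfg$kernel_tau_s <= 0) stopf("kernel_tau_s must be positive")
  if (cfg$shared_signal_fraction < 0 || cfg$shared_signal_fraction >= 1)
    stopf("shared_signal_fraction must lie in [0, 1)")
  if (!cfg$shared_signal_state %in% c("both", "interictal", "ictal"))
    stopf("unknown shared_signal_state")
  if (cfg$modulation_lead_s < 0) stopf("modulation_lead_s must be >= 0")
  if (!cfg$indicator %in% c("GCaMP6M", "GCaMP6S"))
    stopf("indicator must be GCaMP6M or GCaMP6S")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %.0f s, %d neurons + %d neuropil @ %g Hz, %.2g seizures/min, seed %d\n",
    x$duration_s, x$n_neurons, x$n_neuropil, x$frame_rate_hz,
    x$seizure_rate_per_min, x$seed))
  invisible(x)
}
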
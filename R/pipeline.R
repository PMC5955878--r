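## End-to-end orchestration: seizures -> dF/F -> classes -> participation ->
## windows -> synchrony -> deconvolution -> summary.

#' Pipeline configuration
#'
#' All tunable thresholds of the analysis stages, with their defaults. Only
#' the listed keys are accepted; unknown keys are rejected.
#'
#' @param seed master RNG seed; every stochastic stage draws a substream
#'   derived from it.
#' @param amp_factor seizure spike threshold (multiple of the baseline
#'   envelope).
#' @param min_seizure_s,min_gap_s curation thresholds (s).
#' @param locomotion_threshold velocity exclusion threshold (cm/s).
#' @param highpass_hz,baseline_window_s delta-F/F extraction parameters.
#' @param alpha familywise significance level.
#' @param participation_shuffles,synchrony_shuffles shuffle counts.
#' @param corr_bin_s correlation bin width (s).
#' @param window_min sliding-window length (minutes).
#' @param window_bin_s sliding-window bin width (s).
#' @param tau_s deconvolution kernel constant (s); NULL = by indicator.
#' @param run_participation,run_windows,run_synchrony,run_deconvolution
#'   stage switches.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, amp_factor = 1.5,
                            min_seizure_s = 1.5, min_gap_s = 6,
                            locomotion_threshold = 1,
                            highpass_hz = 0.1, baseline_window_s = 20,
                            alpha = 0.05,
                            participation_shuffles = 2000,
                            synchrony_shuffles = 2000,
                            corr_bin_s = 0.2, window_min = 7,
                            window_bin_s = 2, tau_s = NULL,
                            run_participation = TRUE, run_windows = TRUE,
                            run_synchrony = TRUE,
                            run_deconvolution = TRUE) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a session
#'
#' Executes the stage DAG: seizure detection and curation on the EEG,
#' ictal-mask construction (with locomotion-frame exclusion when a velocity
#' trace is present), delta-F/F extraction, denoising and quiet-flagging,
#' ictal classification, onset/offset participation profiles,
#' sliding-window reclassification, shuffle-corrected state correlations,
#' and deconvolved-trace classification. Stages that lack their
#' prerequisites (too few seizures, too little state data) are skipped with
#' a log entry rather than failing the run.
#'
#' @param session a \code{swd_session} (from [simulate_session()] or
#'   [read_session()]).
#' @param config a [pipeline_config()].
#' @return object of class \code{result_bundle}: list with
#'   \code{seizures}, \code{mask}, \code{dff}, \code{classification},
#'   \code{participation} (onset/offset), \code{windows},
#'   \code{synchrony}, \code{rate_classification}, \code{summary},
#'   \code{log} and \code{config}.
#' @export
run_pipeline <- function(session, config = pipeline_config()) {
  stopifnot(inherits(session, "swd_session"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  seiz_raw <- detect_seizures(session$eeg, amp_factor = config$amp_factor)
  seiz <- filter_seizures(seiz_raw, config$min_seizure_s, config$min_gap_s)
  note("seizures: %d detected, %d after curation", nrow(seiz_raw),
       nrow(seiz))
  mask <- build_ictal_mask(seiz, session$frame_times)
  if (!is.null(session$velocity)) {
    mask <- remove_locomotion_frames(mask, session$velocity,
                                     config$locomotion_threshold)
    note("locomotion: %d frames excluded", length(mask$excluded_frames))
  }
  indicator <- if (!is.null(session$config$indicator))
    session$config$indicator else "GCaMP6M"
  dff <- compute_dff(session$fluor, session$config$frame_rate_hz,
                     indicator = indicator,
                     highpass_hz = config$highpass_hz,
                     window_s = config$baseline_window_s,
                     frame_times = session$frame_times)
  dff <- denoise_dff(dff)
  dff <- flag_quiet(dff)
  note("dff: %d ROIs, %d quiet, %d degenerate", nrow(dff$dff),
       sum(dff$quiet), sum(dff$degenerate))

  cls <- NULL
  if (nrow(seiz) >= 2 && mask$n_ictal > 0) {
    cls <- classify_roi(dff, mask, alpha = config$alpha)
  } else note("classification skipped: <2 seizures")

  part <- list(onset = NULL, offset = NULL)
  if (config$run_participation && nrow(seiz) >= 2) {
    for (al in c("onset", "offset")) {
      part[[al]] <- participation_profile(
        dff, seiz, alignment = al,
        n_shuffles = config$participation_shuffles, alpha = config$alpha,
        seed = stage_seed(config$seed, paste0("participation_", al)))
    }
  } else note("participation skipped")

  win <- NULL
  if (config$run_windows && nrow(seiz) >= 2 &&
      length(session$frame_times) / session$config$frame_rate_hz >=
        config$window_min * 60 && !is.null(cls)) {
    win <- sliding_window_classes(dff, seiz, mask,
                                  window_min = config$window_min,
                                  bin_s = config$window_bin_s,
                                  alpha = config$alpha, overall = cls)
  } else note("sliding windows skipped")

  syn <- NULL
  if (config$run_synchrony && nrow(seiz) >= 1) {
    kinds <- if (!is.null(session$rois)) session$rois$kind else NULL
    syn <- tryCatch({
      sc <- state_correlations(dff, mask, bin_s = config$corr_bin_s,
                               kinds = kinds)
      shuffle_correct(sc, n_shuffles = config$synchrony_shuffles,
                      seed = stage_seed(config$seed, "synchrony"))
    }, error = function(e) {
      note("synchrony skipped: %s", conditionMessage(e))
      NULL
    })
  }

  rate_cls <- NULL
  if (config$run_deconvolution && !is.null(cls)) {
    dec <- deconvolve_dff(dff, tau_s = config$tau_s)
    rate_dff <- dff
    rate_dff$dff <- smooth_rate_traces(dec$rate, dec$tau_s,
                                       dff$frame_rate_hz)
    rate_cls <- classify_roi(rate_dff, mask, alpha = config$alpha)
  }

  bundle <- structure(list(
    seizures = seiz, mask = mask, dff = dff, classification = cls,
    participation = part, windows = win, synchrony = syn,
    rate_classification = rate_cls, log = log, config = config,
    summary = NULL), class = "result_bundle")
  bundle$summary <- summarize_results(bundle, session)
  bundle
}

summarize_results <- function(bundle, session) {
  s <- list(seed = bundle$config$seed,
            n_seizures = nrow(bundle$seizures),
            n_frames = length(bundle$mask$ictal),
            n_ictal_frames = bundle$mask$n_ictal,
            n_rois = nrow(bundle$dff$dff),
            n_quiet = sum(bundle$dff$quiet))
  kinds <- if (!is.null(session$rois)) session$rois$kind
           else rep("neuron", nrow(bundle$dff$dff))
  if (!is.null(bundle$classification)) {
    cl <- bundle$classification
    neuron <- kinds == "neuron" & cl$label != "quiet"
    nn <- sum(neuron)
    s$frac_ictal_low <- sum(cl$label[neuron] == "ictal_low") / nn
    s$frac_ictal_high <- sum(cl$label[neuron] == "ictal_high") / nn
    s$frac_neutral <- sum(cl$label[neuron] == "neutral") / nn
    s$mean_ictal_dff <- mean(cl$ictal_mean[neuron])
    s$mean_interictal_dff <- mean(cl$interictal_mean[neuron])
  }
  for (al in c("onset", "offset")) {
    pp <- bundle$participation[[al]]
    if (!is.null(pp)) {
      ok <- !apply(is.na(pp$p), 1, all) & kinds == "neuron"
      s[[paste0("frac_participant_", al)]] <-
        mean(pp$participant[ok])
    }
  }
  if (!is.null(bundle$synchrony)) {
    pr <- bundle$synchrony$pairs
    for (ty in unique(pr$type)) {
      sel <- pr$type == ty & !pr$skipped
      key <- if (startsWith(ty, "neuron")) "neuron" else "neuropil"
      s[[paste0("corr_interictal_", key)]] <-
        mean(pr$corrected_interictal[sel], na.rm = TRUE)
      s[[paste0("corr_ictal_", key)]] <-
        mean(pr$corrected_ictal[sel], na.rm = TRUE)
    }
  }
  if (!is.null(bundle$rate_classification) &&
      !is.null(bundle$classification)) {
    ok <- bundle$classification$label != "quiet"
    s$rate_class_agreement <- mean(
      bundle$rate_classification$label[ok] ==
        bundle$classification$label[ok])
  }
  s
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-26s %s\n", nm,
                format(x$summary[[nm]], digits = 4)))
  invisible(x)
}
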
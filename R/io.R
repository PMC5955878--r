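## Session and result serialization. One canonical on-disk layout:
## traces.csv (ROI x frame), frame_times.csv, rois.csv, eeg.csv,
## velocity.csv (optional), meta.json. All delta-F/F values are serialized
## in percent; the unit is recorded in the metadata.

#' Write a session to a directory
#'
#' @param session a \code{swd_session}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "swd_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(roi = rownames(session$fluor), session$fluor,
                       check.names = FALSE),
            file.path(dir, "traces.csv"), row.names = FALSE)
  write.csv(data.frame(frame_time_s = session$frame_times),
            file.path(dir, "frame_times.csv"), row.names = FALSE)
  write.csv(session$rois, file.path(dir, "rois.csv"), row.names = FALSE)
  write.csv(data.frame(time_s = (seq_along(session$eeg$samples) - 1) /
                         session$eeg$rate_hz + session$eeg$t0_s,
                       uV = session$eeg$samples),
            file.path(dir, "eeg.csv"), row.names = FALSE)
  if (!is.null(session$velocity))
    write.csv(data.frame(velocity = session$velocity),
              file.path(dir, "velocity.csv"), row.names = FALSE)
  meta <- list(frame_rate_hz = session$config$frame_rate_hz,
               eeg_rate_hz = session$eeg$rate_hz,
               indicator = session$config$indicator,
               dff_unit = "percent",
               seed = session$config$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from a directory
#'
#' Validates that every expected file exists and that the EEG and the
#' imaging frames cover a common time interval.
#'
#' @param dir directory written by [write_session()].
#' @return a \code{swd_session}.
#' @export
read_session <- function(dir) {
  need <- c("traces.csv", "frame_times.csv", "rois.csv", "eeg.csv",
            "meta.json")
  for (f in need) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stopf("missing session file: %s", p)
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  tr <- read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  fluor <- as.matrix(tr[, -1, drop = FALSE])
  dimnames(fluor) <- list(tr$roi, NULL)
  ft <- read.csv(file.path(dir, "frame_times.csv"))$frame_time_s
  eegd <- read.csv(file.path(dir, "eeg.csv"))
  eeg <- eeg_recording(eegd$uV, meta$eeg_rate_hz, t0_s = eegd$time_s[1])
  eeg_end <- eegd$time_s[1] + length(eegd$uV) / meta$eeg_rate_hz
  overlap <- min(max(ft), eeg_end) - max(min(ft), eegd$time_s[1])
  if (overlap <= 0)
    stopf("EEG [%g, %g] s and imaging [%g, %g] s do not overlap",
          eegd$time_s[1], eeg_end, min(ft), max(ft))
  vel <- NULL
  vp <- file.path(dir, "velocity.csv")
  if (file.exists(vp)) vel <- read.csv(vp)$velocity
  rois <- read.csv(file.path(dir, "rois.csv"), stringsAsFactors = FALSE)
  cfg <- sim_config(duration_s = length(ft) / meta$frame_rate_hz,
                    frame_rate_hz = meta$frame_rate_hz,
                    eeg_rate_hz = meta$eeg_rate_hz,
                    indicator = meta$indicator,
                    n_neurons = sum(rois$kind == "neuron"),
                    n_neuropil = sum(rois$kind == "neuropil"),
                    seed = if (!is.null(meta$seed)) meta$seed else 1L)
  structure(list(fluor = fluor, frame_times = ft, rois = rois, eeg = eeg,
                 velocity = vel, config = cfg, truth = NULL),
            class = "swd_session")
}

#' Write the tables of a result bundle
#'
#' Emits per-ROI classification, participation profiles (both alignments),
#' window classifications, the pairwise correlation table and a JSON
#' summary, plus the run log and config snapshot.
#'
#' @param bundle a \code{result_bundle} from [run_pipeline()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(onset_s = bundle$seizures$onset_s,
                       offset_s = bundle$seizures$offset_s,
                       mean_spike_freq_hz =
                         bundle$seizures$mean_spike_freq_hz),
            file.path(dir, "seizures.csv"), row.names = FALSE)
  if (!is.null(bundle$classification))
    write.csv(bundle$classification,
              file.path(dir, "classification.csv"), row.names = FALSE)
  for (al in c("onset", "offset")) {
    pp <- bundle$participation[[al]]
    if (is.null(pp)) next
    df <- data.frame(roi = seq_len(nrow(pp$delta)), pp$delta)
    names(df)[-1] <- sprintf("bin_%+.1fs", pp$bin_start_s)
    df$participant <- pp$participant
    write.csv(df, file.path(dir, sprintf("participation_%s.csv", al)),
              row.names = FALSE)
  }
  if (!is.null(bundle$windows))
    write.csv(bundle$windows$summary,
              file.path(dir, "window_summary.csv"), row.names = FALSE)
  if (!is.null(bundle$synchrony))
    write.csv(bundle$synchrony$pairs,
              file.path(dir, "correlations.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- bundle$config
  class(cfg) <- NULL
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
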
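#' Simulate a complete aligned recording session
#'
#' Assembles EEG, ROI fluorescence and an optional locomotion trace into one
#' time-aligned session container with full ground truth. Locomotion bouts
#' are placed almost exclusively in the interictal state, mirroring the
#' behavioral arrest that accompanies absence seizures.
#'
#' @param config a [sim_config()].
#' @param locomotion if TRUE, add a velocity trace (cm/s, one sample per
#'   imaging frame) with interictal running bouts.
#' @return an object of class \code{swd_session}: list with \code{fluor},
#'   \code{frame_times}, \code{rois}, \code{eeg}, \code{velocity} (or NULL),
#'   \code{config} and \code{truth}.
#' @export
#' @examples
#' sess <- simulate_session(sim_config(duration_s = 240, n_neurons = 12,
#'                                     seed = 1))
simulate_session <- function(config, locomotion = FALSE) {
  ee <- simulate_eeg(config)
  ca <- simulate_calcium(config, ee$truth)
  vel <- NULL
  if (locomotion) {
    vel <- with_seed(stage_seed(config$seed, "locomotion"), {
      simulate_locomotion(ca$frame_times, ee$truth)
    })
  }
  truth <- c(ca$truth, list(true_seizures = ee$truth))
  structure(list(fluor = ca$fluor, frame_times = ca$frame_times,
                 rois = ca$rois, eeg = ee$eeg, velocity = vel,
                 config = config, truth = truth),
            class = "swd_session")
}

## Running bouts (2-8 s, ~0.8/min) rejected when they overlap a seizure.
simulate_locomotion <- function(frame_times, seizures) {
  dur <- max(frame_times)
  n_bout <- rpois(1, 0.8 * dur / 60)
  v <- rnorm(length(frame_times), sd = 0.05)
  if (n_bout > 0) {
    starts <- runif(n_bout, 0, dur - 8)
    lens <- runif(n_bout, 2, 8)
    for (b in seq_len(n_bout)) {
      if (nrow(seizures) > 0 &&
          any(starts[b] < seizures$offset_s + 1 &
              starts[b] + lens[b] > seizures$onset_s - 1)) next
      inb <- frame_times >= starts[b] & frame_times <= starts[b] + lens[b]
      v[inb] <- v[inb] + runif(1, 2, 5)
    }
  }
  v
}

#' @export
print.swd_session <- function(x, ...) {
  cat(sprintf(
    "<swd_session> %d ROIs (%d neurons) x %d frames @ %g Hz; EEG %g Hz; %d planted seizures\n",
    nrow(x$fluor), sum(x$rois$kind == "neuron"), ncol(x$fluor),
    x$config$frame_rate_hz, x$eeg$rate_hz, nrow(x$truth$true_seizures)))
  invisible(x)
}
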
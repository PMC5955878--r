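## Sliding-window reclassification: class stability from seizure to seizure.

#' Classify ROIs inside sliding 7-minute windows
#'
#' A 7-minute window slides along the recording, advanced serially by one
#' seizure: the first window starts at the recording start, and each later
#' window starts just before the next seizure so that it drops the earliest
#' seizure of its predecessor. Within each window, ictal frames are
#' concatenated and binned in 2-s intervals, likewise interictal frames, and
#' the two bin samples are compared per ROI with the Wilcoxon rank-sum test.
#' Windows containing fewer than two seizures are skipped. The per-ROI
#' summary reports the fraction of evaluated windows spent in the ROI's
#' overall (predicted) class versus the flipped class.
#'
#' @param dff a denoised, quiet-flagged \code{dff_matrix}.
#' @param seizures curated \code{seizure_set}.
#' @param mask \code{ictal_mask} for the full recording (used both for the
#'   overall classification and to honour excluded frames).
#' @param window_min window length in minutes.
#' @param bin_s bin width for the within-window samples (s).
#' @param alpha per-window significance level.
#' @param overall optional \code{roi_classification} giving the predicted
#'   class; computed from the full recording when omitted.
#' @return object of class \code{window_classification}: list with
#'   \code{windows} (start/end/seizure count), \code{labels} (ROI x window
#'   matrix with levels ictal_low / ictal_high / not_significant),
#'   \code{summary} (per-ROI fractions) and \code{skipped}.
#' @export
sliding_window_classes <- function(dff, seizures, mask, window_min = 7,
                                   bin_s = 2, alpha = 0.05, overall = NULL) {
  stopifnot(inherits(dff, "dff_matrix"), inherits(mask, "ictal_mask"))
  fr <- dff$frame_rate_hz
  nf <- ncol(dff$dff)
  dur <- nf / fr
  wlen <- window_min * 60
  if (dur < wlen) stopf("recording shorter than the window length")
  m <- nrow(seizures)
  if (m == 0) {
    return(structure(list(
      windows = data.frame(start_s = numeric(0), end_s = numeric(0),
                           n_seizures = integer(0)),
      labels = matrix(character(0), nrow(dff$dff), 0),
      summary = NULL, skipped = integer(0)),
      class = "window_classification"))
  }
  if (is.null(overall)) overall <- classify_roi(dff, mask)
  ## window k+1 starts just after seizure k's onset, dropping it
  starts <- c(0, seizures$onset_s[-m] + 1e-6)
  starts <- starts[starts + wlen <= dur + 1e-6]
  ft <- dff$frame_times
  usable <- !mask$excluded
  nroi <- nrow(dff$dff)
  labels <- matrix(NA_character_, nroi, length(starts))
  nseiz_w <- integer(length(starts))
  skipped <- integer(0)
  bin_n <- round(bin_s * fr)
  for (w in seq_along(starts)) {
    a <- starts[w]; b <- a + wlen
    inw <- seizures$onset_s >= a & seizures$onset_s <= b
    nseiz_w[w] <- sum(inw)
    if (nseiz_w[w] < 2) {
      skipped <- c(skipped, w)
      next
    }
    fr_in <- ft >= a & ft < b & usable
    ict <- which(fr_in & mask$ictal)
    int <- which(fr_in & !mask$ictal)
    nb_i <- floor(length(ict) / bin_n)
    nb_o <- floor(length(int) / bin_n)
    if (nb_i < 2 || nb_o < 2) {
      skipped <- c(skipped, w)
      next
    }
    gi <- rep(seq_len(nb_i), each = bin_n)
    go <- rep(seq_len(nb_o), each = bin_n)
    ii <- ict[seq_len(nb_i * bin_n)]
    oo <- int[seq_len(nb_o * bin_n)]
    for (r in seq_len(nroi)) {
      if (dff$quiet[r]) next
      xi <- vapply(split(dff$dff[r, ii], gi), mean, 0)
      xo <- vapply(split(dff$dff[r, oo], go), mean, 0)
      p <- suppressWarnings(wilcox.test(xi, xo, exact = FALSE)$p.value)
      labels[r, w] <- if (!is.na(p) && p < alpha) {
        if (mean(xi) < mean(xo)) "ictal_low" else "ictal_high"
      } else "not_significant"
    }
  }
  flip <- c(ictal_low = "ictal_high", ictal_high = "ictal_low")
  summ <- data.frame(roi = overall$roi, overall = overall$label,
                     frac_predicted = NA_real_, frac_flipped = NA_real_,
                     stringsAsFactors = FALSE)
  for (r in seq_len(nroi)) {
    lab <- labels[r, !is.na(labels[r, ])]
    if (length(lab) == 0 || !overall$label[r] %in% names(flip)) next
    summ$frac_predicted[r] <- mean(lab == overall$label[r])
    summ$frac_flipped[r] <- mean(lab == flip[[overall$label[r]]])
  }
  structure(list(
    windows = data.frame(start_s = starts, end_s = starts + wlen,
                         n_seizures = nseiz_w),
    labels = labels, summary = summ, skipped = skipped),
    class = "window_classification")
}

#' @export
print.window_classification <- function(x, ...) {
  cat(sprintf("<window_classification> %d windows (%d skipped), %d ROIs\n",
              nrow(x$windows), length(x$skipped), nrow(x$labels)))
  invisible(x)
}
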
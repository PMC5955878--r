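## Per-ROI ictal classification by ictal-vs-interictal rank-sum test.

#' Classify ROIs as ictal-low, ictal-high or neutral
#'
#' For each non-quiet ROI, all activity during the ictal state is compared
#' with all activity in the interictal state using the two-sample Wilcoxon
#' rank-sum test, Bonferroni-corrected across the family of non-quiet ROIs
#' in the session. The frames of each state are concatenated and binned in
#' \code{bin_s} intervals (1 s by default) before testing: calcium traces
#' are autocorrelated on the indicator's decay timescale, so binning at or
#' above that scale makes the rank-sum samples approximately exchangeable
#' and keeps the false-positive rate at its nominal level. Significant ROIs
#' are labelled \code{ictal_low} or \code{ictal_high} by the sign of the
#' difference of state means; non-significant ROIs are \code{neutral};
#' quiet ROIs keep the label \code{quiet}. Frames excluded by locomotion
#' removal contribute to neither sample.
#'
#' @param dff a denoised, quiet-flagged \code{dff_matrix}.
#' @param mask an \code{ictal_mask} aligned to the frames.
#' @param family_size Bonferroni family size; defaults to the number of
#'   non-quiet ROIs.
#' @param alpha familywise significance level before correction.
#' @param bin_s width of the within-state bins (s); set to 0 to test raw
#'   per-frame samples.
#' @return data frame of class \code{roi_classification}: one row per ROI
#'   with \code{label}, \code{p_value}, \code{corrected_alpha},
#'   \code{ictal_mean} and \code{interictal_mean} (percent delta-F/F).
#' @export
classify_roi <- function(dff, mask, family_size = NULL, alpha = 0.05,
                         bin_s = 1) {
  stopifnot(inherits(dff, "dff_matrix"), inherits(mask, "ictal_mask"))
  if (anyNA(dff$quiet)) stopf("run flag_quiet() before classification")
  ict <- which(mask$ictal & !mask$excluded)
  int <- which(!mask$ictal & !mask$excluded)
  if (length(ict) == 0) stopf("no ictal data")
  if (is.null(family_size)) family_size <- max(1L, sum(!dff$quiet))
  a_corr <- alpha / family_size
  bin_n <- max(1L, round(bin_s * dff$frame_rate_hz))
  state_bins <- function(x, idx) {
    nb <- floor(length(idx) / bin_n)
    if (nb < 1) return(x[idx])
    ii <- idx[seq_len(nb * bin_n)]
    colMeans(matrix(x[ii], nrow = bin_n))
  }
  n <- nrow(dff$dff)
  label <- character(n)
  p <- rep(NA_real_, n)
  mi <- rep(NA_real_, n)
  mo <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (dff$quiet[i]) {
      label[i] <- "quiet"
      next
    }
    xi <- state_bins(dff$dff[i, ], ict)
    xo <- state_bins(dff$dff[i, ], int)
    mi[i] <- mean(xi)
    mo[i] <- mean(xo)
    p[i] <- suppressWarnings(
      wilcox.test(xi, xo, exact = FALSE)$p.value)
    label[i] <- if (!is.na(p[i]) && p[i] < a_corr) {
      if (mi[i] < mo[i]) "ictal_low" else "ictal_high"
    } else "neutral"
  }
  structure(data.frame(
    roi = if (!is.null(rownames(dff$dff))) rownames(dff$dff)
          else sprintf("roi%03d", seq_len(n)),
    label = label, p_value = p, corrected_alpha = a_corr,
    ictal_mean = mi, interictal_mean = mo,
    stringsAsFactors = FALSE),
    class = c("roi_classification", "data.frame"))
}
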
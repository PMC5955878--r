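## State-resolved pairwise correlation with rate-confound corrections.

#' State-resolved pairwise Pearson correlations
#'
#' Traces are resampled to \code{bin_s} bins (default 200 ms, the effective
#' temporal resolution of the imaging); a bin is used only when all of its
#' frames share one state and none is excluded. Each ROI's ictal activity is
#' normalized by the ROI's mean interictal amplitude, the frames of each
#' state are concatenated, and the Pearson coefficient is computed per pair
#' separately for the interictal and ictal states. Quiet ROIs are excluded.
#'
#' @param dff a denoised, quiet-flagged \code{dff_matrix}.
#' @param mask an \code{ictal_mask}.
#' @param bin_s bin width (s).
#' @param kinds optional per-ROI kind vector (\code{"neuron"} /
#'   \code{"neuropil"}); pairs are formed within kind only.
#' @param min_bins minimum usable bins per state.
#' @return object of class \code{correlation_result}: \code{pairs} data
#'   frame (i, j, type, raw interictal/ictal coefficients) plus the binned
#'   per-state series needed by [shuffle_correct()].
#' @export
state_correlations <- function(dff, mask, bin_s = 0.2, kinds = NULL,
                               min_bins = 100) {
  stopifnot(inherits(dff, "dff_matrix"), inherits(mask, "ictal_mask"))
  if (anyNA(dff$quiet)) stopf("run flag_quiet() before correlation")
  fr <- dff$frame_rate_hz
  bin_n <- max(1L, round(bin_s * fr))
  nf <- ncol(dff$dff)
  nb <- floor(nf / bin_n)
  grp <- rep(seq_len(nb), each = bin_n)
  idx <- seq_len(nb * bin_n)
  state <- ifelse(mask$ictal, 1L, 0L)
  st_sum <- tapply(state[idx], grp, sum)
  ex_sum <- tapply(as.integer(mask$excluded[idx]), grp, sum)
  bin_state <- ifelse(ex_sum > 0, NA_integer_,
                      ifelse(st_sum == bin_n, 1L,
                             ifelse(st_sum == 0, 0L, NA_integer_)))
  keep_rois <- which(!dff$quiet)
  if (length(keep_rois) < 2) stopf("need at least two non-quiet ROIs")
  binned <- t(apply(dff$dff[keep_rois, idx, drop = FALSE], 1,
                    function(x) tapply(x, grp, mean)))
  ict_b <- which(!is.na(bin_state) & bin_state == 1L)
  int_b <- which(!is.na(bin_state) & bin_state == 0L)
  if (length(ict_b) < min_bins || length(int_b) < min_bins)
    stopf("insufficient state data (%d ictal, %d interictal bins; need %d)",
          length(ict_b), length(int_b), min_bins)
  x_int <- binned[, int_b, drop = FALSE]
  x_ict <- binned[, ict_b, drop = FALSE]
  ## amplitude normalization of the ictal state by mean interictal amplitude
  int_amp <- rowMeans(x_int)
  scl <- ifelse(abs(int_amp) > 1e-12, int_amp, 1)
  x_ict_n <- sweep(x_ict, 1, scl, `/`)

  if (is.null(kinds)) kinds <- rep("neuron", nrow(dff$dff))
  kk <- kinds[keep_rois]
  cmb <- utils::combn(seq_along(keep_rois), 2)
  same <- kk[cmb[1, ]] == kk[cmb[2, ]]
  cmb <- cmb[, same, drop = FALSE]
  pairs <- data.frame(
    i = keep_rois[cmb[1, ]], j = keep_rois[cmb[2, ]],
    type = paste0(kk[cmb[1, ]], "-", kk[cmb[2, ]]),
    raw_interictal = NA_real_, raw_ictal = NA_real_,
    stringsAsFactors = FALSE)
  ci <- suppressWarnings(cor(t(x_int)))
  cc <- suppressWarnings(cor(t(x_ict_n)))
  pairs$raw_interictal <- ci[cbind(cmb[1, ], cmb[2, ])]
  pairs$raw_ictal <- cc[cbind(cmb[1, ], cmb[2, ])]
  structure(list(pairs = pairs, bin_s = bin_s,
                 roi_index = keep_rois, pair_index = cmb,
                 x_interictal = x_int, x_ictal = x_ict_n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> %d pairs, %d interictal + %d ictal bins of %g s%s\n",
    nrow(x$pairs), ncol(x$x_interictal), ncol(x$x_ictal), x$bin_s,
    if (!is.null(x$pairs$corrected_interictal)) ", shuffle-corrected" else ""))
  invisible(x)
}

## Pearson coefficients of x against every circular shift of y, via FFT.
## Element k + 1 holds cor(x, y shifted by k), k = 0 .. n-1.
all_shift_cor <- function(x, y) {
  n <- length(x)
  sx <- sd(x) * sqrt((n - 1) / n)
  sy <- sd(y) * sqrt((n - 1) / n)
  if (sx < 1e-12 || sy < 1e-12) return(rep(NA_real_, n))
  cc <- Re(fft(Conj(fft(x)) * fft(y), inverse = TRUE)) / n
  (cc / n - mean(x) * mean(y)) / (sx * sy)
}

#' Correct state correlations with circular-shuffle nulls
#'
#' For each pair and state, one member's binned series is circularly shifted
#' by a uniform random offset \code{n_shuffles} times; the null mean of the
#' resulting coefficients is subtracted from the raw coefficient,
#' independently for the interictal and ictal states. The per-offset
#' coefficients are evaluated exactly (via FFT cross-correlation over all
#' offsets) and the seeded random offsets index into that table, which is
#' numerically identical to shifting the series explicitly. Pairs whose
#' series are shorter than 10 bins or constant are skipped and flagged.
#'
#' @param result a \code{correlation_result} from [state_correlations()].
#' @param n_shuffles number of random circular offsets.
#' @param seed RNG seed.
#' @return the \code{correlation_result} with per-pair
#'   \code{corrected_interictal}, \code{corrected_ictal}, null means/SDs and
#'   a \code{skipped} flag added.
#' @export
shuffle_correct <- function(result, n_shuffles = 2000, seed = 1L) {
  stopifnot(inherits(result, "correlation_result"))
  pr <- result$pairs
  np <- nrow(pr)
  out <- data.frame(null_mean_interictal = rep(NA_real_, np),
                    null_sd_interictal = NA_real_,
                    null_mean_ictal = NA_real_, null_sd_ictal = NA_real_,
                    skipped = FALSE)
  with_seed(seed, {
    for (state in c("interictal", "ictal")) {
      xs <- if (state == "interictal") result$x_interictal else result$x_ictal
      n <- ncol(xs)
      if (n < 10) {
        out$skipped <- TRUE
        next
      }
      offs <- sample.int(n - 1L, n_shuffles, replace = TRUE)  # exclude 0
      fx <- t(apply(xs, 1, fft))
      for (p in seq_len(np)) {
        a <- result$pair_index[1, p]
        b <- result$pair_index[2, p]
        xa <- xs[a, ]; xb <- xs[b, ]
        sx <- sd(xa) * sqrt((n - 1) / n)
        sy <- sd(xb) * sqrt((n - 1) / n)
        if (sx < 1e-12 || sy < 1e-12) {
          out$skipped[p] <- TRUE
          next
        }
        cc <- Re(fft(Conj(fx[a, ]) * fx[b, ], inverse = TRUE)) / n
        rk <- (cc / n - mean(xa) * mean(xb)) / (sx * sy)
        null <- rk[offs + 1L]
        out[[paste0("null_mean_", state)]][p] <- mean(null)
        out[[paste0("null_sd_", state)]][p] <- sd(null)
      }
    }
  })
  pr <- cbind(pr, out)
  pr$corrected_interictal <- pr$raw_interictal - pr$null_mean_interictal
  pr$corrected_ictal <- pr$raw_ictal - pr$null_mean_ictal
  result$pairs <- pr
  result$n_shuffles <- n_shuffles
  result
}

#' Equalize state activity by random event removal
#'
#' The alternative rate-confound correction: per cell, calcium events
#' (maximal runs of consecutive nonzero denoised samples) are randomly
#' deleted from the state with the higher mean delta-F/F -- interictal if
#' interictal activity is higher, ictal otherwise -- until the two state
#' means are less than \code{tol_pct} percentage points apart or no events
#' remain in that state. Correlations recomputed on the matched traces need
#' no further rate correction.
#'
#' @param dff a denoised \code{dff_matrix}.
#' @param mask an \code{ictal_mask}.
#' @param tol_pct tolerance on the state-mean difference (percentage points
#'   of delta-F/F).
#' @param seed RNG seed for the removal order.
#' @return list with \code{dff} (matched \code{dff_matrix}) and
#'   \code{log}, a per-ROI data frame (state events were removed from,
#'   number removed, achieved difference, matched flag).
#' @export
rate_match_by_event_removal <- function(dff, mask, tol_pct = 0.1,
                                        seed = 1L) {
  stopifnot(inherits(dff, "dff_matrix"), inherits(mask, "ictal_mask"))
  if (!isTRUE(dff$denoised)) stopf("rate matching requires denoised traces")
  usable <- !mask$excluded
  ict <- which(mask$ictal & usable)
  int <- which(!mask$ictal & usable)
  m <- dff$dff
  nroi <- nrow(m)
  log <- data.frame(roi = seq_len(nroi), removed_from = NA_character_,
                    n_removed = 0L, achieved_diff = NA_real_,
                    matched = NA, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (r in seq_len(nroi)) {
      if (isTRUE(dff$quiet[r]) || dff$degenerate[r]) next
      x <- m[r, ]
      mi <- mean(x[ict]); mo <- mean(x[int])
      d0 <- mi - mo
      log$achieved_diff[r] <- d0
      log$matched[r] <- abs(d0) < tol_pct
      if (abs(d0) < tol_pct) next
      target <- if (d0 > 0) "ictal" else "interictal"
      t_idx <- if (d0 > 0) ict else int
      log$removed_from[r] <- target
      runs <- rle(x != 0)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      ev <- which(runs$values)
      in_state <- logical(length(x))
      in_state[t_idx] <- TRUE
      ev_keep <- vapply(ev, function(e) {
        mean(in_state[starts[e]:ends[e]]) > 0.5
      }, TRUE)
      ev <- ev[ev_keep]
      if (length(ev) == 0) {
        log$matched[r] <- FALSE
        next
      }
      ord <- sample(ev)
      s_t <- sum(x[t_idx])
      n_t <- length(t_idx)
      other <- if (d0 > 0) mo else mi
      best <- x
      best_d <- abs(d0)
      nrem <- 0L
      for (e in ord) {
        seg <- starts[e]:ends[e]
        seg <- seg[in_state[seg]]
        s_t <- s_t - sum(x[seg])
        x[starts[e]:ends[e]] <- 0
        nrem <- nrem + 1L
        d <- s_t / n_t - other
        if (abs(d) < best_d) {
          best_d <- abs(d)
          best <- x
        }
        if (abs(d) < tol_pct) break
        ## d = target-state mean minus other-state mean: starts at |d0| and
        ## only decreases, so once below -tol further removal cannot improve
        if (d < -tol_pct) break
      }
      m[r, ] <- best
      log$n_removed[r] <- nrem
      log$achieved_diff[r] <- if (d0 > 0) best_d else -best_d
      log$matched[r] <- best_d < tol_pct
    }
  })
  dff$dff <- m
  list(dff = dff, log = log)
}
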
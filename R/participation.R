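## Seizure-aligned participation against circular-shuffle nulls.

## Frame index range covering [t1, t2) for frame midpoints (j - 0.5) / fr.
frame_range <- function(t1, t2, fr) {
  lo <- floor(t1 * fr + 0.5) + 1L
  hi <- as.integer(ceiling(t2 * fr + 0.5)) - 1L
  list(lo = as.integer(lo), hi = hi)
}

#' Seizure-aligned participation profile per ROI
#'
#' Calcium activity is aligned to seizure onset (window -10 to +5 s) or
#' offset (-5 to +10 s) and summarized in 30 bins of 0.5 s. For each ROI and
#' bin, the observed sample holds one value per seizure: the mean delta-F/F
#' in that bin minus the ROI's overall mean (the deviation "delta
#' delta-F/F"). The null distribution is built by circularly shuffling the
#' seizure time points: per shuffle, a single uniform offset displaces all
#' alignment points jointly (modulo the recording length), keeping seizure
#' lengths and the calcium trace unchanged, and the bin values are
#' recomputed. Each bin's observed sample is compared with its pooled null
#' by a two-sample Kolmogorov--Smirnov test at \code{alpha / 30}
#' (0.05 / 30 = 0.0017); an ROI is a participant when at least two adjacent
#' bins are significant.
#'
#' @param dff a denoised \code{dff_matrix}.
#' @param seizures curated \code{seizure_set}.
#' @param alignment \code{"onset"} or \code{"offset"}.
#' @param n_shuffles number of circular shuffles (2000 by default).
#' @param alpha familywise level; per-bin threshold is \code{alpha / 30}.
#' @param seed RNG seed for the shuffle offsets.
#' @param rois optional integer subset of ROI rows to analyse.
#' @return object of class \code{participation_profile}: list with
#'   \code{bin_start_s}, \code{delta} (ROI x 30 mean deviations, percent),
#'   \code{p} (ROI x 30 KS p-values), \code{significant},
#'   \code{participant}, \code{alignment} and \code{low_power}.
#' @export
participation_profile <- function(dff, seizures,
                                  alignment = c("onset", "offset"),
                                  n_shuffles = 2000, alpha = 0.05,
                                  seed = 1L, rois = NULL) {
  stopifnot(inherits(dff, "dff_matrix"))
  alignment <- match.arg(alignment)
  nf <- ncol(dff$dff)
  fr <- dff$frame_rate_hz
  dur <- nf / fr
  if (dur < 120) stopf("recording must be at least 2 minutes long")
  nseiz <- nrow(seizures)
  if (nseiz == 0) stopf("no seizures supplied")
  low_power <- nseiz < 3
  if (low_power)
    warning("fewer than 3 seizures: participation profile is low-power",
            call. = FALSE)
  align_t <- if (alignment == "onset") seizures$onset_s else seizures$offset_s
  starts <- if (alignment == "onset") {
    seq(-10, 4.5, by = 0.5)
  } else {
    seq(-5, 9.5, by = 0.5)
  }
  nb <- length(starts)

  ## observed bin index ranges: (seizure, bin)
  t1 <- outer(align_t, starts, `+`)
  obs_rng <- frame_range(t1, t1 + 0.5, fr)

  ## null ranges: (shuffle x seizure, bin), one joint offset per shuffle
  offs <- with_seed(seed, runif(n_shuffles, 0, dur))
  sh_t <- (rep(align_t, times = n_shuffles) +
             rep(offs, each = nseiz)) %% dur
  nt1 <- outer(sh_t, starts, `+`)
  null_rng <- frame_range(nt1, nt1 + 0.5, fr)

  if (is.null(rois)) rois <- seq_len(nrow(dff$dff))
  nroi_all <- nrow(dff$dff)
  delta <- matrix(NA_real_, nroi_all, nb)
  pmat <- matrix(NA_real_, nroi_all, nb)
  thr <- alpha / nb
  for (i in rois) {
    if (isTRUE(dff$quiet[i]) || dff$degenerate[i]) next
    cs <- c(0, cumsum(dff$dff[i, ]))
    mu <- mean(dff$dff[i, ])
    obs <- matrix(bin_mean_cs(cs, obs_rng$lo, obs_rng$hi) - mu,
                  nrow = nseiz)
    nul <- matrix(bin_mean_cs(cs, null_rng$lo, null_rng$hi) - mu,
                  nrow = nseiz * n_shuffles)
    for (b in seq_len(nb)) {
      ob <- obs[, b]; ob <- ob[!is.na(ob)]
      nu <- nul[, b]; nu <- nu[!is.na(nu)]
      if (length(ob) < 2 || length(nu) < 2) next
      delta[i, b] <- mean(ob)
      pmat[i, b] <- suppressWarnings(ks.test(ob, nu)$p.value)
    }
  }
  sig <- !is.na(pmat) & pmat < thr
  part <- apply(sig, 1, function(s) any(s[-length(s)] & s[-1]))
  structure(list(alignment = alignment, bin_start_s = starts,
                 delta = delta, p = pmat, significant = sig,
                 participant = part, threshold = thr,
                 n_shuffles = n_shuffles, low_power = low_power),
            class = "participation_profile")
}

#' @export
print.participation_profile <- function(x, ...) {
  n <- sum(!is.na(x$p[, 1] + 0) | rowSums(!is.na(x$p)) > 0)
  cat(sprintf(
    "<participation_profile> %s-aligned, %d bins, %d shuffles; %d/%d participants\n",
    x$alignment, length(x$bin_start_s), x$n_shuffles,
    sum(x$participant, na.rm = TRUE), nrow(x$p)))
  invisible(x)
}
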
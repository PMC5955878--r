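## Synthetic ROI fluorescence: inhomogeneous-Poisson event trains convolved
## with an exponential indicator kernel, plus noise, on a positive baseline.

#' Simulate ROI fluorescence traces with known ground truth
#'
#' Per neuron, an inhomogeneous Poisson event train whose rate is multiplied
#' by \code{1 + modulation_depth[class]} during ictal frames is convolved
#' with the exponential kernel \code{exp(-t / kernel_tau_s)}, scaled to
#' delta-F/F (percent), and mounted on a positive raw-fluorescence baseline
#' with Gaussian noise. Planted-quiet neurons receive an event rate low
#' enough to fall below the quiet-activity threshold. Neuropil patches are
#' means of \code{neuropil_mixing} randomly chosen neuron signals plus
#' independent noise. Pairwise common input is injected through a shared
#' latent event train: a fraction \code{shared_signal_fraction} of every
#' active neuron's events is drawn from the same realization, which plants an
#' event-level pairwise correlation equal to that fraction (restricted to
#' \code{shared_signal_state} frames).
#'
#' @param config a [sim_config()].
#' @param seizures data frame with \code{onset_s}/\code{offset_s} columns
#'   (e.g. the truth from [simulate_eeg()]); all intervals must lie inside
#'   the configured duration.
#' @return list with \code{fluor} (ROI x frame raw fluorescence matrix),
#'   \code{frame_times} (frame midpoints, s), \code{rois} (metadata table)
#'   and \code{truth} (planted classes, event-count trains, target pairwise
#'   correlation, ictal frame mask).
#' @export
simulate_calcium <- function(config, seizures) {
  validate_sim_config(config)
  if (nrow(seizures) > 0 &&
      (min(seizures$onset_s) < 0 || max(seizures$offset_s) > config$duration_s))
    stopf("seizure outside the simulated duration")
  fr <- config$frame_rate_hz
  nf <- round(config$duration_s * fr)
  ft <- (seq_len(nf) - 0.5) / fr
  ictal <- rep(FALSE, nf)
  mod_on <- rep(FALSE, nf)   # modulation window, may lead the EEG onset
  for (k in seq_len(nrow(seizures))) {
    ictal <- ictal | (ft >= seizures$onset_s[k] & ft <= seizures$offset_s[k])
    mod_on <- mod_on | (ft >= seizures$onset_s[k] - config$modulation_lead_s &
                          ft <= seizures$offset_s[k])
  }

  with_seed(stage_seed(config$seed, "calcium"), {
    nn <- config$n_neurons
    classes <- assign_classes(config$class_fractions, nn)
    epochs <- class_epochs(config, classes)
    dt <- 1 / fr
    a <- exp(-dt / config$kernel_tau_s)
    amp <- config$event_amp_dff

    ## shared latent train (same realization for every recipient)
    f_sh <- config$shared_signal_fraction
    allow <- switch(config$shared_signal_state,
                    both = rep(TRUE, nf), interictal = !ictal, ictal = ictal)
    common <- if (f_sh > 0) {
      rpois(nf, f_sh * config$event_rate_hz * dt) * allow
    } else rep(0L, nf)

    rates <- runif(nn, 0.8, 1.2) * config$event_rate_hz
    counts <- matrix(0L, nrow = nn, ncol = nf)
    sig <- matrix(0, nrow = nn, ncol = nf)
    epoch_id <- pmin(floor(ft / config$drift_epoch_s) + 1L, ncol(epochs))
    for (i in seq_len(nn)) {
      if (classes[i] == "quiet") {
        lam <- rep(config$quiet_event_rate_hz * dt, nf)
        ci <- rpois(nf, lam)
      } else {
        depth <- config$modulation_depth[epochs[i, epoch_id]]
        mult <- ifelse(mod_on, 1 + depth, 1)
        lam_tot <- rates[i] * mult * dt
        ## the shared train is thinned per neuron along with its modulation,
        ## so suppression also withdraws the neuron from the common input
        p_keep <- pmin(1, mult * rates[i] / config$event_rate_hz) * allow
        shared_i <- rbinom(nf, common, p_keep)
        lam_own <- pmax(lam_tot -
                          f_sh * config$event_rate_hz * dt * p_keep, 0)
        ci <- rpois(nf, lam_own) + shared_i
      }
      counts[i, ] <- ci
      sig[i, ] <- stats::filter(amp * ci, a, method = "recursive")
    }

    ## neuropil patches: means of randomly chosen neuron signals
    np <- config$n_neuropil
    mix <- vector("list", np)
    np_sig <- matrix(0, nrow = np, ncol = nf)
    active <- which(classes != "quiet")
    for (j in seq_len(np)) {
      mix[[j]] <- sample(active, min(config$neuropil_mixing, length(active)))
      np_sig[j, ] <- colMeans(sig[mix[[j]], , drop = FALSE])
    }

    all_sig <- rbind(sig, np_sig)
    nroi <- nn + np
    noise <- matrix(rnorm(nroi * nf, sd = config$noise_sigma_dff),
                    nrow = nroi)
    ## slow multiplicative drift exercises the high-pass / rolling baseline
    drift <- 1 + 0.02 * sin(2 * pi * 0.004 * ft + runif(1, 0, 2 * pi))
    fluor <- config$baseline_f *
      sweep((1 + (all_sig + noise) / 100), 2, drift, `*`)

    rois <- data.frame(
      id = sprintf("roi%03d", seq_len(nroi)),
      kind = rep(c("neuron", "neuropil"), c(nn, np)),
      layer = "L2/3",
      area_um2 = c(runif(nn, 80, 160), runif(np, 500, 900)),
      stringsAsFactors = FALSE)
    rownames(fluor) <- rois$id

    truth <- list(
      true_class_per_roi = classes,
      class_epochs = epochs,
      true_event_counts = counts,
      event_rates_hz = rates,
      neuropil_mix = mix,
      pairwise_target_corr = f_sh,
      ictal_frames = ictal)
    list(fluor = fluor, frame_times = ft, rois = rois, truth = truth)
  })
}

assign_classes <- function(fractions, n) {
  cls <- c("ictal_low", "ictal_high", "neutral", "quiet")
  cnt <- floor(fractions[cls] * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(fractions[cls] * n - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  sample(rep(cls, cnt))
}

## Per-epoch class labels; without drift a single epoch. With drift,
## modulated neurons flip to the opposite modulated class at each epoch
## boundary with probability drift_prob.
class_epochs <- function(config, classes) {
  n_ep <- if (config$drift_enabled)
    max(1L, ceiling(config$duration_s / config$drift_epoch_s)) else 1L
  ep <- matrix(classes, nrow = length(classes), ncol = n_ep)
  if (n_ep > 1) {
    flip <- c(ictal_low = "ictal_high", ictal_high = "ictal_low")
    for (e in 2:n_ep) {
      prev <- ep[, e - 1]
      mod <- prev %in% names(flip)
      do_flip <- mod & runif(length(prev)) < config$drift_prob
      ep[, e] <- ifelse(do_flip, flip[prev], prev)
    }
  }
  ep
}

#' Simulate stationary rate-switching pairs for correction calibration
#'
#' Builds independent neuron traces whose event rate depends only on the
#' state label of each frame (interictal vs ictal), with the calcium kernel
#' applied within each state's concatenated frame sequence separately, so
#' the trace is stationary within each state and carries no shared
#' transition dynamics across state boundaries. This isolates the estimator
#' property that shuffle correction must satisfy: truly independent pairs
#' with arbitrarily different per-state rates have corrected coefficients
#' centred on zero in both states.
#'
#' @param n_neurons number of independent traces.
#' @param ictal logical per-frame state vector.
#' @param frame_rate_hz frame rate (Hz).
#' @param rate_interictal_hz,rate_ictal_hz per-state event rates (events/s).
#' @param event_amp_dff event amplitude (percent).
#' @param kernel_tau_s kernel decay constant (s).
#' @param noise_sigma_dff Gaussian noise SD (percent).
#' @param seed RNG seed.
#' @return a denoise-marked \code{dff_matrix} ready for
#'   [state_correlations()].
#' @export
simulate_stationary_pairs <- function(n_neurons, ictal, frame_rate_hz = 10,
                                      rate_interictal_hz = 0.3,
                                      rate_ictal_hz = 0.06,
                                      event_amp_dff = 25,
                                      kernel_tau_s = 0.6,
                                      noise_sigma_dff = 0.5, seed = 1L) {
  nf <- length(ictal)
  dt <- 1 / frame_rate_hz
  a <- exp(-dt / kernel_tau_s)
  with_seed(stage_seed(seed, "stationary_pairs"), {
    m <- matrix(0, n_neurons, nf)
    for (i in seq_len(n_neurons)) {
      x <- numeric(nf)
      for (st in c(TRUE, FALSE)) {
        idx <- which(ictal == st)
        if (length(idx) == 0) next
        rate <- if (st) rate_ictal_hz else rate_interictal_hz
        ev <- rpois(length(idx), rate * dt) * event_amp_dff
        x[idx] <- stats::filter(ev, a, method = "recursive")
      }
      m[i, ] <- x + rnorm(nf, sd = noise_sigma_dff)
    }
    structure(list(dff = m, frame_rate_hz = frame_rate_hz,
                   frame_times = (seq_len(nf) - 0.5) / frame_rate_hz,
                   indicator = "GCaMP6M",
                   degenerate = rep(FALSE, n_neurons),
                   noise_sigma = rep(noise_sigma_dff, n_neurons),
                   quiet = rep(FALSE, n_neurons), denoised = TRUE),
              class = "dff_matrix")
  })
}
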
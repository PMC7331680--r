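#' Specification of a synthetic condition effect
#'
#' Parameterises the N400-like condition difference injected by the
#' generator: a spatio-temporally separable Gaussian bump added to the
#' incongruent trials. A negative amplitude makes incongruent trials more
#' negative than congruent ones, the classic N400 direction. Per-subject
#' heterogeneity (the "variable times or locations" of real individual
#' effects) enters through random jitter of the peak latency and of the
#' topography centre.
#'
#' @param amplitude_uV peak effect amplitude, microvolts (negative =
#'   incongruent more negative). 0 gives exchangeable conditions.
#' @param peak_latency_ms latency of the temporal Gaussian peak, ms.
#' @param temporal_width_ms temporal Gaussian SD, ms (> 0).
#' @param topography_center scalp channel at the spatial Gaussian centre.
#' @param topography_spread spatial Gaussian SD in unit-sphere chord units.
#' @param latency_jitter_sd_ms SD of the per-subject latency perturbation, ms.
#' @param center_jitter_sd SD of the per-subject topography-centre
#'   displacement, unit-sphere units.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(amplitude_uV = -6, peak_latency_ms = 400,
                        temporal_width_ms = 80, topography_center = "Cz",
                        topography_spread = 0.6, latency_jitter_sd_ms = 0,
                        center_jitter_sd = 0) {
  if (temporal_width_ms <= 0) stop("temporal_width_ms must be > 0")
  if (topography_spread <= 0) stop("topography_spread must be > 0")
  if (latency_jitter_sd_ms < 0 || center_jitter_sd < 0)
    stop("jitter SDs must be >= 0")
  structure(list(amplitude_uV = amplitude_uV,
                 peak_latency_ms = peak_latency_ms,
                 temporal_width_ms = temporal_width_ms,
                 topography_center = topography_center,
                 topography_spread = topography_spread,
                 latency_jitter_sd_ms = latency_jitter_sd_ms,
                 center_jitter_sd = center_jitter_sd),
            class = "effect_spec")
}

#' Specification of the synthetic sensor-noise model
#'
#' Sensor noise is the sum of a 1/f ("pink") component and a white component,
#' mixed across channels so that the spatial correlation decays with
#' inter-electrode distance (Gaussian kernel in chord distance). Both
#' conditions share the identical noise law.
#'
#' @param white_sd_uV white-noise SD per sample, microvolts.
#' @param pink_sd_uV 1/f-noise SD per sample, microvolts.
#' @param spatial_corr_scale spatial correlation length, unit-sphere chord
#'   units (0 = spatially independent noise).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd_uV = 4, pink_sd_uV = 8,
                       spatial_corr_scale = 0.8) {
  if (white_sd_uV < 0 || pink_sd_uV < 0 || spatial_corr_scale < 0)
    stop("noise parameters must be >= 0")
  structure(list(white_sd_uV = white_sd_uV, pink_sd_uV = pink_sd_uV,
                 spatial_corr_scale = spatial_corr_scale),
            class = "noise_spec")
}

#' Restrict a montage to a subset of scalp channels
#'
#' Convenience for reduced-scale simulations.
#'
#' @param montage an `eeg_montage`.
#' @param channels scalp channel labels to keep.
#' @return An `eeg_montage` with only those scalp channels (mastoids kept if
#'   present).
#' @export
subset_montage <- function(montage, channels) {
  stopifnot(inherits(montage, "eeg_montage"))
  miss <- setdiff(channels, montage$scalp)
  if (length(miss)) stop("unknown scalp channel(s): ", paste(miss, collapse = ", "))
  keep <- c(channels, intersect(montage$mastoids, montage$names))
  eeg_montage(keep, montage$positions[keep, , drop = FALSE],
              mastoids = montage$mastoids, eog = character())
}

# unit-variance 1/f-amplitude noise, one column per channel
.pink_noise <- function(n_samp, n_chan) {
  W <- matrix(stats::rnorm(n_samp * n_chan), n_samp, n_chan)
  if (n_samp < 4L) return(W)
  k <- 0:(n_samp - 1)
  f <- pmin(k, n_samp - k)            # symmetric frequency index
  a <- ifelse(f == 0, 0, 1 / sqrt(f)) # amplitude ~ f^{-1/2}, power ~ 1/f
  a <- a / sqrt(mean(a^2))
  Re(stats::mvfft(stats::mvfft(W) * a, inverse = TRUE)) / n_samp
}

# channel-mixing factor R (X %*% R has channel covariance C = R'R)
.spatial_mix <- function(positions, scale) {
  n <- nrow(positions)
  if (scale <= 0) return(diag(n))
  D2 <- as.matrix(stats::dist(positions))^2
  C <- exp(-D2 / (2 * scale^2))
  chol(C + diag(1e-9, n))
}

# one trial's noise: n_samp x n_chan
.trial_noise <- function(n_samp, mix, noise) {
  n_chan <- ncol(mix)
  z <- noise$white_sd_uV * matrix(stats::rnorm(n_samp * n_chan), n_samp, n_chan)
  if (noise$pink_sd_uV > 0)
    z <- z + noise$pink_sd_uV * .pink_noise(n_samp, n_chan)
  z %*% mix
}

#' Simulate one subject's epoched EEG
#'
#' Generates `2 * n_pairs` trials (each target pair once per condition) of
#' spatially correlated pink-plus-white noise on the montage's scalp
#' channels, and adds the condition effect -- a separable spatio-temporal
#' Gaussian bump -- to the incongruent trials. Per-subject jitter of latency
#' and topography centre is drawn once according to the effect spec. The
#' realised effect parameters are returned as ground truth for
#' parameter-recovery studies.
#'
#' @param n_pairs number of target pairs (94 reproduces the full session:
#'   188 trials).
#' @param montage an `eeg_montage`; only scalp channels are simulated.
#' @param effect an [effect_spec()].
#' @param noise a [noise_spec()].
#' @param srate sampling rate, Hz.
#' @param window epoch window in ms, half-open.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param subject_id subject label.
#' @param sequence optional [generate_sequence()] result fixing the trial
#'   order (labels and pair ids); by default pairs are interleaved.
#' @return A list with elements `epochs` ([eeg_epochs]) and `ground_truth`
#'   (realised amplitude, latency, width, centre and per-channel topography
#'   weights).
#' @export
simulate_subject <- function(n_pairs = 94, montage = default_montage(),
                             effect = effect_spec(), noise = noise_spec(),
                             srate = 512, window = c(-100, 1000), seed = 1,
                             subject_id = "sim", sequence = NULL) {
  stopifnot(inherits(effect, "effect_spec"), inherits(noise, "noise_spec"))
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  channels <- scalp_channels(montage)
  if (!effect$topography_center %in% channels)
    stop("unknown topography_center: ", effect$topography_center)
  set.seed(as.integer(seed))

  times <- epoch_times(srate, window)
  n_samp <- length(times)
  n_trial <- 2L * n_pairs

  if (is.null(sequence)) {
    condition <- rep(c("congruent", "incongruent"), n_pairs)
    pair_id <- rep(seq_len(n_pairs), each = 2L)
  } else {
    stopifnot(inherits(sequence, "trial_sequence"))
    if (length(sequence$labels) != n_trial)
      stop("sequence length does not match 2 * n_pairs")
    condition <- sequence$labels
    pair_id <- sequence$pair_id
  }

  # subject-level jitter draws (before the noise stream)
  lat <- effect$peak_latency_ms +
    stats::rnorm(1, 0, effect$latency_jitter_sd_ms)
  cpos <- montage$positions[effect$topography_center, ]
  if (effect$center_jitter_sd > 0)
    cpos <- cpos + stats::rnorm(3, 0, effect$center_jitter_sd)
  cpos <- cpos / sqrt(sum(cpos^2))
  pos <- montage$positions[channels, , drop = FALSE]
  topo <- exp(-0.5 * (.chord_dist(pos, cpos) / effect$topography_spread)^2)
  tcourse <- exp(-0.5 * ((times - lat) / effect$temporal_width_ms)^2)
  bump <- effect$amplitude_uV * outer(tcourse, topo) # n_samp x n_chan

  mix <- .spatial_mix(pos, noise$spatial_corr_scale)
  v <- array(0, dim = c(n_trial, length(channels), n_samp))
  for (t in seq_len(n_trial)) {
    tr <- .trial_noise(n_samp, mix, noise)           # n_samp x n_chan
    if (condition[t] == "incongruent") tr <- tr + bump
    v[t, , ] <- t(tr)
  }

  epochs <- eeg_epochs(v, times, srate, condition, pair_id,
                       channels = channels, subject_id = subject_id)
  gt <- list(amplitude_uV = effect$amplitude_uV, peak_latency_ms = lat,
             temporal_width_ms = effect$temporal_width_ms,
             center_xyz = cpos,
             center_channel = channels[which.max(topo)],
             topography = stats::setNames(topo, channels))
  list(epochs = epochs, ground_truth = gt)
}

#' Simulate a cohort of subjects with between-subject heterogeneity
#'
#' Each subject's effect latency and topography centre are drawn around the
#' base spec using its jitter SDs. A responder fraction sets the proportion
#' of subjects carrying a non-zero effect (the rest get amplitude 0); with
#' the defaults of 20 subjects and fraction 0.65, 13 subjects are responders,
#' mirroring the demo scenario.
#'
#' @inheritParams simulate_subject
#' @param n_subjects cohort size.
#' @param responder_fraction proportion of subjects with non-zero amplitude,
#'   in `[0, 1]`.
#' @param seed root seed; per-subject seeds are derived deterministically.
#' @return List of per-subject lists as from [simulate_subject()].
#' @export
simulate_cohort <- function(n_subjects = 20, n_pairs = 94,
                            montage = default_montage(),
                            effect = effect_spec(), noise = noise_spec(),
                            srate = 512, window = c(-100, 1000),
                            responder_fraction = 0.65, seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("responder_fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  n_resp <- round(responder_fraction * n_subjects)
  responders <- sort(sample.int(n_subjects, n_resp))
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    eff <- effect
    if (!i %in% responders) eff$amplitude_uV <- 0
    sub_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    out[[i]] <- simulate_subject(n_pairs, montage, eff, noise, srate, window,
                                 seed = sub_seed,
                                 subject_id = sprintf("sim%02d", i))
    out[[i]]$ground_truth$responder <- i %in% responders
  }
  out
}

#' Simulate a continuous recording realising a trial schedule
#'
#' Builds a continuous multichannel recording whose event-locked windows
#' reproduce, sample for sample, the output of [simulate_subject()] under the
#' same seed and schedule -- so `epoch_recording()` of the result equals the
#' direct epoched simulation. Samples between epochs are zero.
#'
#' @param sequence a [generate_sequence()] result (trial order and pair ids).
#' @inheritParams simulate_subject
#' @param gap_ms silent gap inserted between consecutive epochs, ms.
#' @return A list with `recording` ([continuous_recording]), `epochs` and
#'   `ground_truth`.
#' @export
simulate_continuous <- function(sequence, montage = default_montage(),
                                effect = effect_spec(), noise = noise_spec(),
                                srate = 512, window = c(-100, 1000),
                                seed = 1, subject_id = "sim",
                                gap_ms = 100) {
  stopifnot(inherits(sequence, "trial_sequence"))
  if (gap_ms < 0) stop("gap_ms must be >= 0")
  n_pairs <- length(unique(sequence$pair_id))
  sim <- simulate_subject(n_pairs, montage, effect, noise, srate, window,
                          seed = seed, subject_id = subject_id,
                          sequence = sequence)
  ep <- sim$epochs
  n_samp <- length(ep$times)
  gap <- round(gap_ms * srate / 1000)
  stride <- n_samp + gap
  n_trial <- n_trials(ep)
  total <- n_trial * stride
  v <- matrix(0, n_channels(ep), total)
  rownames(v) <- channel_names(ep)
  onset <- .onset_index(srate, window)
  ev_samples <- integer(n_trial)
  for (t in seq_len(n_trial)) {
    at <- (t - 1L) * stride
    v[, at + seq_len(n_samp)] <- ep$voltages[t, , ]
    ev_samples[t] <- at + onset
  }
  rec <- continuous_recording(v, srate,
                              data.frame(sample = ev_samples,
                                         condition = ep$condition,
                                         pair_id = ep$pair_id),
                              subject_id = subject_id)
  list(recording = rec, epochs = ep, ground_truth = sim$ground_truth)
}
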
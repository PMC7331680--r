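#' Re-reference to the mastoid average
#'
#' Subtracts the mean of the two mastoid channels from every channel at every
#' sample. Idempotent: after re-referencing, the mastoid average is zero, so
#' applying it twice equals applying it once.
#'
#' @param x an [eeg_epochs] or [continuous_recording].
#' @param mastoids the two mastoid channel names.
#' @return Same type as `x`.
#' @export
rereference <- function(x, mastoids = c("M1", "M2")) {
  if (length(mastoids) != 2L) stop("two mastoid channels required")
  if (inherits(x, "eeg_epochs")) {
    miss <- setdiff(mastoids, channel_names(x))
    if (length(miss)) stop("missing mastoid channel: ", miss[1])
    ref <- (x$voltages[, mastoids[1], ] + x$voltages[, mastoids[2], ]) / 2
    for (ch in seq_len(n_channels(x)))
      x$voltages[, ch, ] <- x$voltages[, ch, ] - ref
    x
  } else if (inherits(x, "continuous_recording")) {
    miss <- setdiff(mastoids, rownames(x$voltages))
    if (length(miss)) stop("missing mastoid channel: ", miss[1])
    ref <- colMeans(x$voltages[mastoids, , drop = FALSE])
    x$voltages <- sweep(x$voltages, 2L, ref)
    x
  } else stop("x must be eeg_epochs or continuous_recording")
}

# zero-phase Butterworth band edges: second-order high-pass cascaded with a
# fourth-order low-pass, each applied forward-backward (signal::filtfilt), so
# effective orders are doubled and the phase response is zero
.bandpass_vec <- function(v, hp, lp) {
  v <- v - mean(v)   # demean first: shrinks the high-pass edge transient
  v <- signal::filtfilt(hp, v)
  signal::filtfilt(lp, v)
}

#' Zero-phase band-pass filter
#'
#' Filters every channel with a zero-phase (forward-backward) Butterworth
#' band-pass realised as a 2nd-order high-pass cascaded with a 4th-order
#' low-pass (effective 4th/8th order after the two passes). Attenuation one
#' octave outside the band exceeds 20 dB on both sides; passband ripple is
#' zero (Butterworth is maximally flat).
#'
#' @param x an [eeg_epochs] or [continuous_recording].
#' @param low high-pass edge, Hz.
#' @param high low-pass edge, Hz. Requires `0 < low < high < srate/2`.
#' @return Same type as `x`.
#' @export
bandpass <- function(x, low = 0.1, high = 40) {
  srate <- x$srate
  if (is.null(srate)) stop("x must be eeg_epochs or continuous_recording")
  if (!(low > 0 && low < high && high < srate / 2))
    stop("need 0 < low < high < srate/2")
  hp <- signal::butter(2, low / (srate / 2), type = "high")
  lp <- signal::butter(4, high / (srate / 2), type = "low")
  if (inherits(x, "eeg_epochs")) {
    for (t in seq_len(n_trials(x)))
      for (ch in seq_len(n_channels(x)))
        x$voltages[t, ch, ] <- .bandpass_vec(x$voltages[t, ch, ], hp, lp)
  } else if (inherits(x, "continuous_recording")) {
    for (ch in seq_len(nrow(x$voltages)))
      x$voltages[ch, ] <- .bandpass_vec(x$voltages[ch, ], hp, lp)
  } else stop("x must be eeg_epochs or continuous_recording")
  x
}

#' Cut epochs from a continuous recording
#'
#' One trial per event, spanning the half-open `window` around the event
#' sample (which becomes time 0).
#'
#' @param recording a [continuous_recording].
#' @param window epoch window in ms.
#' @return An [eeg_epochs].
#' @export
epoch_recording <- function(recording, window = c(-100, 1000)) {
  stopifnot(inherits(recording, "continuous_recording"))
  srate <- recording$srate
  times <- epoch_times(srate, window)
  n_samp <- length(times)
  i0 <- .onset_index(srate, window)
  ev <- recording$events
  n_total <- ncol(recording$voltages)
  v <- array(0, c(nrow(ev), nrow(recording$voltages), n_samp))
  for (k in seq_len(nrow(ev))) {
    from <- ev$sample[k] - i0 + 1L
    to <- from + n_samp - 1L
    if (from < 1L || to > n_total)
      stop("event ", k, " (sample ", ev$sample[k],
           ") does not leave room for a full epoch window")
    v[k, , ] <- recording$voltages[, from:to]
  }
  eeg_epochs(v, times, srate, ev$condition, ev$pair_id,
             channels = rownames(recording$voltages),
             subject_id = recording$subject_id)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the (half-open)
#' baseline window. Idempotent.
#'
#' @param epochs an [eeg_epochs].
#' @param window baseline window in ms (default the full pre-stimulus span).
#' @return An [eeg_epochs].
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sel <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  bl <- apply(epochs$voltages[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$voltages <- epochs$voltages -
    array(bl, dim = dim(epochs$voltages))
  epochs
}

#' Flag artifact trials by an absolute-voltage threshold
#'
#' A trial is rejected when any in-scope channel exceeds `threshold`
#' microvolts in absolute value at any sample. The data are untouched: only
#' the rejection mask is set (the multivariate analyses deliberately use all
#' trials; the univariate analyses respect the mask). The per-channel
#' exceedance matrix is attached for the channel-interpolation rule.
#'
#' @param epochs an [eeg_epochs].
#' @param threshold rejection threshold, microvolts.
#' @param scope channel names to consider (default: all channels). Using the
#'   9-channel ROI preserves trials whose artifacts lie outside the ROI.
#' @return The epochs with `rejected` set and an `exceed` attribute
#'   (trials x channels logical, over all channels).
#' @export
reject_artifacts <- function(epochs, threshold = 200, scope = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.null(scope)) scope <- channel_names(epochs)
  if (!length(scope)) stop("scope must contain at least one channel")
  miss <- setdiff(scope, channel_names(epochs))
  if (length(miss)) stop("unknown channel(s) in scope: ", paste(miss, collapse = ", "))
  exceed <- apply(abs(epochs$voltages) > threshold, c(1, 2), any)
  colnames(exceed) <- channel_names(epochs)
  epochs$rejected <- apply(exceed[, scope, drop = FALSE], 1L, any)
  attr(epochs, "exceed") <- exceed
  attr(epochs, "reject_threshold") <- threshold
  epochs
}

# ---- spherical-spline interpolation (Perrin-style, order m, truncated) ----

# g(x) = (1/4pi) sum_{n=1}^{N} (2n+1) / (n (n+1))^m  P_n(x)
.gfun <- function(x, m = 4, nterms = 50) {
  res <- 0
  pnm2 <- rep(1, length(x)) # P_0
  pnm1 <- x                 # P_1
  for (n in seq_len(nterms)) {
    pn <- if (n == 1) pnm1 else {
      p <- ((2 * n - 1) * x * pnm1 - (n - 1) * pnm2) / n
      pnm2 <- pnm1; pnm1 <- p
      p
    }
    res <- res + (2 * n + 1) / (n * (n + 1))^m * pn
  }
  res / (4 * pi)
}

# affine weights over good electrodes reproducing the spherical spline at
# the bad positions; regularised as (G + lambda I)
.spline_weights <- function(good_pos, bad_pos, m = 4, lambda = 1e-5,
                            nterms = 50) {
  g <- nrow(good_pos)
  cosgg <- pmin(pmax(tcrossprod(good_pos), -1), 1)
  G <- matrix(.gfun(cosgg, m, nterms), g, g)
  A <- rbind(cbind(G + diag(lambda, g), 1), c(rep(1, g), 0))
  cosbg <- pmin(pmax(bad_pos %*% t(good_pos), -1), 1)
  gv <- matrix(.gfun(cosbg, m, nterms), nrow(bad_pos), g)
  W <- cbind(gv, 1) %*% solve(A)
  W[, seq_len(g), drop = FALSE]
}

#' Interpolate channels that drive excessive trial rejection
#'
#' Channels whose threshold exceedances would reject more than `fraction` of
#' the trials are replaced by a spherical-spline (Perrin-style, order
#' `m = 4`, regularisation `1e-5`) interpolation of the remaining scalp
#' channels. The epochs must previously have passed through
#' [reject_artifacts()] so that per-channel attribution is available. After
#' interpolation the preprocessing pipeline re-runs from the filtering stage
#' ([preprocess()] enforces this).
#'
#' @param epochs an [eeg_epochs] carrying the `exceed` attribution.
#' @param montage an `eeg_montage` covering the data channels.
#' @param fraction rejection-fraction threshold above which a channel is
#'   interpolated.
#' @return A list: `epochs` (channels replaced) and `interpolated` (channel
#'   names; empty if nothing to do).
#' @export
interpolate_bad_channels <- function(epochs, montage, fraction = 0.10) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(montage, "eeg_montage"))
  exceed <- attr(epochs, "exceed")
  if (is.null(exceed))
    stop("run reject_artifacts() first (per-channel attribution needed)")
  chans <- channel_names(epochs)
  rate <- colMeans(exceed)
  bad <- chans[rate > fraction]
  if (!length(bad)) return(list(epochs = epochs, interpolated = character()))
  if (length(bad) > length(chans) / 2)
    stop("more than half the channels flagged; interpolation unreliable")
  good <- setdiff(intersect(chans, montage$scalp), bad)
  miss <- setdiff(chans, montage$names)
  if (length(miss)) stop("montage lacks channel(s): ", paste(miss, collapse = ", "))
  W <- .spline_weights(montage$positions[good, , drop = FALSE],
                       montage$positions[bad, , drop = FALSE])
  for (t in seq_len(n_trials(epochs)))
    epochs$voltages[t, bad, ] <- W %*% epochs$voltages[t, good, ]
  list(epochs = epochs, interpolated = bad)
}

#' Full preprocessing pipeline for a continuous recording
#'
#' Fixed order: re-reference to the mastoid average, zero-phase band-pass,
#' epoch, baseline-correct, threshold rejection. If any channel's exceedances
#' would reject more than `interp_fraction` of trials, that channel is
#' spherical-spline interpolated in the re-referenced continuous data and the
#' pipeline re-runs from the filtering stage.
#'
#' @param recording a [continuous_recording] including mastoid channels (the
#'   re-referencing step is skipped, with a message, if they are absent).
#' @param montage an `eeg_montage`.
#' @param band band-pass edges, Hz.
#' @param window epoch window, ms.
#' @param baseline baseline window, ms.
#' @param reject_threshold rejection threshold, microvolts.
#' @param reject_scope channels whose artifacts mark a trial rejected
#'   (default: all scalp channels present in the data).
#' @param interp_fraction rejection fraction above which a channel is
#'   interpolated.
#' @param max_passes safety cap on filter-again passes.
#' @return List: `epochs` (baseline-corrected, mask set), `interpolated`
#'   (channel names), `n_rejected` (trials rejected in scope).
#' @export
preprocess <- function(recording, montage, band = c(0.1, 40),
                       window = c(-100, 1000), baseline = c(-100, 0),
                       reject_threshold = 200, reject_scope = NULL,
                       interp_fraction = 0.10, max_passes = 3) {
  stopifnot(inherits(recording, "continuous_recording"))
  have_mast <- all(montage$mastoids %in% rownames(recording$voltages))
  rec <- if (have_mast) rereference(recording, montage$mastoids) else recording
  interpolated <- character()
  for (pass in seq_len(max_passes)) {
    filt <- bandpass(rec, band[1], band[2])
    ep <- epoch_recording(filt, window)
    ep <- baseline_correct(ep, baseline)
    ep_all <- reject_artifacts(ep, reject_threshold, scope = NULL)
    rate <- colMeans(attr(ep_all, "exceed"))
    bad <- setdiff(names(rate)[rate > interp_fraction], montage$mastoids)
    if (!length(bad) || pass == max_passes) {
      scope <- reject_scope
      if (is.null(scope))
        scope <- intersect(channel_names(ep), montage$scalp)
      ep <- reject_artifacts(ep, reject_threshold, scope = scope)
      return(list(epochs = ep, interpolated = interpolated,
                  n_rejected = sum(ep$rejected)))
    }
    if (length(bad) > nrow(rec$voltages) / 2)
      stop("more than half the channels flagged; interpolation unreliable")
    good <- setdiff(intersect(rownames(rec$voltages), montage$scalp), bad)
    W <- .spline_weights(montage$positions[good, , drop = FALSE],
                         montage$positions[bad, , drop = FALSE])
    rec$voltages[bad, ] <- W %*% rec$voltages[good, , drop = FALSE]
    interpolated <- union(interpolated, bad)
  }
}
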
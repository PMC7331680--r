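#' Time-resolved LOTO decoding
#'
#' For each temporal centre, the classifier uses all requested channels at
#' the centre sample and its `halfwidth` neighbours on each side (11 samples
#' at the default), and the leave-one-target-out accuracy is computed as in
#' [loto_crossval]. Centres whose window would cross the epoch edge are
#' skipped, so the first valid centre is at sample index `halfwidth + 1`.
#' Optionally the pairing-preserving permutation null is computed per centre
#' with the same scheme as [permutation_null].
#'
#' @inheritParams loto_decode
#' @param halfwidth temporal half-window in samples (window = `2*halfwidth+1`).
#' @param n_perm permutations (0 = none).
#' @return An object of class `accuracy_map`: `values` (per-centre
#'   accuracies), `centre_times` (ms), and if requested `null` (an
#'   `n_perm x centres` matrix of permutation accuracies).
#' @export
time_resolved_decode <- function(epochs, halfwidth = 5, n_perm = 0, seed = 1,
                                 channels = NULL, cost = 1) {
  di <- .decode_inputs(epochs, channels)
  n_samp <- dim(di$cube)[3]
  if (n_samp < 2 * halfwidth + 1)
    stop("halfwidth too large for the epoch length")
  flips <- matrix(FALSE, 1, di$n_pairs)
  if (n_perm > 0)
    flips <- rbind(flips, .flip_matrix(n_perm, di$n_pairs, seed))
  acc <- .cpp_time_resolved(as.numeric(di$cube), dim(di$cube),
                            as.integer(halfwidth), di$y, di$pair0, flips,
                            cost, 1e-3)
  centres <- (halfwidth + 1):(n_samp - halfwidth)
  structure(list(values = acc[1, ], centre_times = epochs$times[centres],
                 null = if (n_perm > 0) acc[-1, , drop = FALSE],
                 halfwidth = halfwidth, subject_id = epochs$subject_id),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  if (is.matrix(x$values)) {
    cat(sprintf("<accuracy_map> %s: %d channels x %d centres, accuracy %.3f-%.3f\n",
                x$subject_id, nrow(x$values), ncol(x$values),
                min(x$values), max(x$values)))
  } else {
    cat(sprintf("<accuracy_map> %s: %d centres (%.0f..%.0f ms), peak %.3f at %.0f ms\n",
                x$subject_id, length(x$values), min(x$centre_times),
                max(x$centre_times), max(x$values),
                x$centre_times[which.max(x$values)]))
  }
  invisible(x)
}

#' @export
plot.accuracy_map <- function(x, ...) {
  if (is.matrix(x$values)) {
    graphics::matplot(x$centre_times, t(x$values), type = "l", lty = 1,
                      col = grDevices::grey(0.7), xlab = "time (ms)",
                      ylab = "accuracy", main = x$subject_id)
    graphics::lines(x$centre_times, colMeans(x$values), lwd = 2)
  } else {
    plot(x$centre_times, x$values, type = "l", xlab = "time (ms)",
         ylab = "accuracy", main = x$subject_id)
  }
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Threshold-free cluster enhancement of a 1-D statistic series
#'
#' TFCE integrates, for each position, cluster extent and height over all
#' thresholds: \eqn{TFCE(p) = \sum_{h=dh, 2dh, ..}^{s(p)} e(h)^E h^H dh},
#' where `e(h)` is the length of the contiguous supra-threshold run
#' containing `p`. Input statistics should be chance-centred (accuracy minus
#' 0.5); only positive excursions score (one-sided, above-chance direction).
#'
#' @param stats numeric series (chance maps to 0).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh integration step; default `max(stats)/100`.
#' @return Numeric series of non-negative TFCE scores.
#' @export
tfce_series <- function(stats, E = 0.5, H = 2, dh = NULL) {
  if (!all(is.finite(stats))) stop("stats must be finite")
  n <- length(stats)
  top <- max(stats)
  if (top <= 0) return(numeric(n))
  if (is.null(dh)) dh <- top / 100
  if (dh <= 0) stop("dh must be > 0")
  scores <- numeric(n)
  if (top < dh) return(scores)
  heights <- seq(dh, top, by = dh)
  for (h in heights) {
    supra <- stats >= h
    r <- rle(supra)
    extent <- rep(r$lengths, r$lengths)     # run length at every position
    add <- supra * extent^E * h^H * dh
    scores <- scores + add
  }
  scores
}

#' Max-statistic significance for a TFCE series
#'
#' Family-wise error control: a timepoint is significant when its observed
#' TFCE score is higher than `1 - alpha` of the permutation maxima (each
#' maximum taken over the analysis window of its own permutation's TFCE
#' series).
#'
#' @param observed_tfce observed TFCE series (analysis window only).
#' @param null_maxima per-permutation maxima of the null TFCE series.
#' @param alpha level.
#' @return Logical vector flagging significant positions.
#' @export
maxstat_significance <- function(observed_tfce, null_maxima, alpha = 0.05) {
  if (!length(null_maxima)) stop("null maxima are empty")
  vapply(observed_tfce,
         function(v) mean(null_maxima < v) > 1 - alpha, logical(1))
}

#' Time-resolved decoding with TFCE max-statistic inference
#'
#' Runs [time_resolved_decode] with a permutation null, converts accuracies
#' to chance-centred statistics (accuracy - 0.5), applies [tfce_series] to
#' the observed and to every permutation series over the analysis window
#' (all centres excluding the baseline, i.e. centre time >= 0, unless
#' `baseline_excluded = FALSE`), and flags centres whose observed TFCE
#' exceeds `1 - alpha` of the per-permutation maxima.
#'
#' The TFCE integration step is `max(observed statistic)/100`, shared by the
#' observed and null series so scores are comparable.
#'
#' @inheritParams time_resolved_decode
#' @param alpha family-wise level.
#' @param baseline_excluded drop pre-onset centres from the analysis window.
#' @param E,H TFCE exponents.
#' @return An object of class `tfce_test`: the accuracy map, `tfce` scores,
#'   `null_maxima`, `significant` flags, and significant `clusters`
#'   (start/end ms).
#' @export
time_resolved_test <- function(epochs, halfwidth = 5, n_perm = 1000,
                               seed = 1, alpha = 0.05,
                               baseline_excluded = TRUE, channels = NULL,
                               cost = 1, E = 0.5, H = 2) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  map <- time_resolved_decode(epochs, halfwidth, n_perm, seed, channels,
                              cost)
  win <- if (baseline_excluded) map$centre_times >= 0
         else rep(TRUE, length(map$centre_times))
  if (!any(win)) stop("analysis window is empty")
  obs_stat <- map$values[win] - 0.5
  dh <- if (max(obs_stat) > 0) max(obs_stat) / 100 else 0.01
  obs_tfce <- tfce_series(obs_stat, E, H, dh)
  null_maxima <- apply(map$null[, win, drop = FALSE] - 0.5, 1L,
                       function(s) {
                         sc <- tfce_series(s, E, H, dh)
                         if (length(sc)) max(sc) else 0
                       })
  sig_win <- maxstat_significance(obs_tfce, null_maxima, alpha)
  significant <- rep(FALSE, length(map$values))
  significant[win] <- sig_win
  tms <- map$centre_times
  cl <- .mask_clusters(significant, tms)
  structure(list(map = map, analysis_window = win, tfce = obs_tfce,
                 null_maxima = null_maxima, significant = significant,
                 clusters = cl, alpha = alpha,
                 subject_id = map$subject_id),
            class = "tfce_test")
}

# contiguous TRUE runs of a mask -> data.frame(start_ms, end_ms, length)
.mask_clusters <- function(mask, times) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_ms = times[starts[keep]], end_ms = times[ends[keep]],
             length = r$lengths[keep])
}

#' @export
print.tfce_test <- function(x, ...) {
  cat(sprintf("<tfce_test> %s: %d/%d centres significant at alpha = %.2f\n",
              x$subject_id, sum(x$significant), length(x$significant),
              x$alpha))
  if (nrow(x$clusters))
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  %.0f-%.0f ms (%d samples)\n", x$clusters$start_ms[i],
                  x$clusters$end_ms[i], x$clusters$length[i]))
  invisible(x)
}

#' Time-by-space searchlight decoding
#'
#' For every scalp channel and temporal centre, decodes using that channel's
#' `n_channels`-nearest neighbourhood and the `2*halfwidth + 1` surrounding
#' samples; leave-one-target-out accuracy per cell. The maps are descriptive:
#' no significance testing is performed.
#'
#' @inheritParams time_resolved_decode
#' @param montage an `eeg_montage` covering the data channels.
#' @param n_channels electrodes per neighbourhood (default 5).
#' @return An `accuracy_map` whose `values` is a channels x centres matrix.
#' @export
searchlight_decode <- function(epochs, montage, n_channels = 5,
                               halfwidth = 5, cost = 1) {
  stopifnot(inherits(montage, "eeg_montage"))
  chans <- intersect(channel_names(epochs), montage$scalp)
  if (!length(chans)) stop("no scalp channels present")
  di <- .decode_inputs(epochs, chans)
  n_samp <- dim(di$cube)[3]
  if (n_samp < 2 * halfwidth + 1)
    stop("halfwidth too large for the epoch length")
  sub <- subset_montage(montage, chans)
  k <- min(n_channels, length(chans))
  neigh <- t(vapply(chans, function(ch)
    match(channel_neighbourhood(sub, ch, k), chans), integer(k))) - 1L
  acc <- .cpp_searchlight(as.numeric(di$cube), dim(di$cube),
                          as.integer(halfwidth), neigh, di$y, di$pair0,
                          cost, 1e-3)
  rownames(acc) <- chans
  centres <- (halfwidth + 1):(n_samp - halfwidth)
  structure(list(values = acc, centre_times = epochs$times[centres],
                 halfwidth = halfwidth, n_channels = k,
                 subject_id = epochs$subject_id),
            class = "accuracy_map")
}

#' Windowed topographies of a searchlight map
#'
#' Per-channel mean accuracy in four half-open 200 ms windows from 200 to
#' 1000 ms after target onset (the display convention for decoding
#' topographies).
#'
#' @param map a 2-D `accuracy_map` from [searchlight_decode].
#' @param windows matrix-like of window starts/ends, ms; default the four
#'   windows 200-400, 400-600, 600-800, 800-1000.
#' @return Channels x windows matrix of mean accuracies.
#' @export
window_topographies <- function(map,
                                windows = cbind(seq(200, 800, 200),
                                                seq(400, 1000, 200))) {
  stopifnot(inherits(map, "accuracy_map"), is.matrix(map$values))
  windows <- as.matrix(windows)
  out <- matrix(NA_real_, nrow(map$values), nrow(windows),
                dimnames = list(rownames(map$values),
                                sprintf("%d-%d", windows[, 1], windows[, 2])))
  for (w in seq_len(nrow(windows))) {
    sel <- map$centre_times >= windows[w, 1] & map$centre_times < windows[w, 2]
    if (!any(sel))
      stop("map does not cover window ", windows[w, 1], "-", windows[w, 2],
           " ms")
    out[, w] <- rowMeans(map$values[, sel, drop = FALSE])
  }
  out
}
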
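#' Region-of-interest specification for the N400 analysis
#'
#' The default ROI is the centro-parietal 9-channel set centred on Cz with
#' its eight surrounding electrodes; pointwise testing starts at 150 ms and
#' the N400 area is integrated over 300-800 ms.
#'
#' @param channels ROI channel names.
#' @param analysis_start first tested timepoint, ms.
#' @param n400_window area-integration window, ms.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(channels = c("Cz", "FC1", "FCz", "FC2", "C1", "C2",
                                  "CP1", "CPz", "CP2"),
                     analysis_start = 150, n400_window = c(300, 800)) {
  structure(list(channels = channels, analysis_start = analysis_start,
                 n400_window = n400_window), class = "roi_spec")
}

# per-trial ROI-mean series for one condition: trials x samples, non-rejected
.roi_trials <- function(epochs, channels, condition) {
  miss <- setdiff(channels, channel_names(epochs))
  if (length(miss)) stop("ROI channel(s) absent: ", paste(miss, collapse = ", "))
  keep <- epochs$condition == condition & !epochs$rejected
  if (!any(keep))
    stop("no usable (non-rejected) trials in condition ", condition)
  v <- epochs$voltages[keep, channels, , drop = FALSE]
  t(apply(v, c(1, 3), mean))  # -> samples x trials, transpose below
}

#' ROI event-related potentials
#'
#' Channel-mean (over the ROI) then trial-mean waveform per condition, with
#' the standard error of the mean across trials; rejected trials are
#' excluded.
#'
#' @param epochs an [eeg_epochs].
#' @param roi a [roi_spec()] (or character vector of channels).
#' @return An object of class `erp_waveform`: `times`, per-condition `mean`
#'   and `sem` matrices, trial counts `n`.
#' @export
roi_erp <- function(epochs, roi = roi_spec()) {
  chans <- if (inherits(roi, "roi_spec")) roi$channels else roi
  conds <- c("congruent", "incongruent")
  m <- s <- matrix(NA_real_, length(epochs$times), 2,
                  dimnames = list(NULL, conds))
  n <- integer(2)
  for (i in 1:2) {
    tr <- t(.roi_trials(epochs, chans, conds[i]))  # trials x samples
    n[i] <- nrow(tr)
    m[, i] <- colMeans(tr)
    s[, i] <- apply(tr, 2, stats::sd) / sqrt(nrow(tr))
  }
  structure(list(times = epochs$times, mean = m, sem = s,
                 n = stats::setNames(n, conds), channels = chans,
                 subject_id = epochs$subject_id),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %s: %d/%d usable trials (congruent/incongruent), %d samples\n",
              x$subject_id, x$n[1], x$n[2], length(x$times)))
  invisible(x)
}

#' @export
plot.erp_waveform <- function(x, ...) {
  graphics::matplot(x$times, x$mean, type = "l", lty = c(2, 1),
                    col = c("blue", "red"), xlab = "time (ms)",
                    ylab = expression(paste("amplitude (", mu, "V)")),
                    main = x$subject_id)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::legend("topright", legend = colnames(x$mean), lty = c(2, 1),
                   col = c("blue", "red"), bty = "n")
  invisible(x)
}

#' Pointwise two-sample t-tests between conditions
#'
#' Classic pooled-variance two-sample t at each timepoint from
#' `start` ms onward, two-tailed p-values. Degenerate (zero-variance)
#' timepoints get p = 1 with a warning.
#'
#' @param cong,incong trials x samples matrices of per-trial ROI-mean
#'   series.
#' @param times sample times, ms.
#' @param start first tested time, ms.
#' @param tails `"two"` (default) or `"one"` (congruent > incongruent).
#' @return List: `times` (tested), `t`, `p`.
#' @export
pointwise_t <- function(cong, incong, times, start = 150,
                        tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (nrow(cong) < 2 || nrow(incong) < 2)
    stop("need >= 2 usable trials per condition")
  sel <- which(times >= start)
  if (!length(sel)) stop("no timepoints at or after start")
  n1 <- nrow(cong); n2 <- nrow(incong)
  m1 <- colMeans(cong[, sel, drop = FALSE])
  m2 <- colMeans(incong[, sel, drop = FALSE])
  v1 <- apply(cong[, sel, drop = FALSE], 2, stats::var)
  v2 <- apply(incong[, sel, drop = FALSE], 2, stats::var)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df <- n1 + n2 - 2
  degenerate <- !is.finite(tt)
  if (any(degenerate)) {
    warning(sum(degenerate), " timepoint(s) with zero pooled variance; p set to 1")
    tt[degenerate] <- 0
  }
  p <- if (tails == "two") 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
       else stats::pt(tt, df, lower.tail = FALSE)
  p[degenerate] <- 1
  list(times = times[sel], t = tt, p = p)
}

#' Lag-1 autocorrelation of a series
#'
#' Sample lag-1 autocorrelation, used to match the null ERP simulations of
#' the cluster-threshold calibration to the observed waveform's smoothness.
#'
#' @param x numeric series, length >= 3, non-constant.
#' @return Scalar in (-1, 1).
#' @export
lag1_autocorr <- function(x) {
  n <- length(x)
  if (n < 3) stop("series too short")
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0) stop("constant series: autocorrelation undefined")
  sum(xc[-n] * xc[-1]) / den
}

# longest run of TRUE in a logical vector
.longest_run <- function(b) {
  r <- rle(b)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Autocorrelation-matched minimum cluster length
#'
#' Calibrates the minimum number of consecutive p < alpha timepoints needed
#' for a significant cluster: `n_sim` null datasets of per-trial AR(1)
#' Gaussian series with lag-1 coefficient `phi` and the observed trial
#' counts are simulated; each is run through the pointwise t-tests and the
#' longest sub-alpha run recorded. The threshold is the smallest run length
#' attained or exceeded by at most `alpha` of the simulated longest runs --
#' i.e. an observed cluster is significant when it is longer than
#' `1 - alpha` of the null longest runs.
#'
#' @param phi lag-1 autocorrelation, |phi| < 1.
#' @param n_per_condition length-2 trial counts (congruent, incongruent).
#' @param n_timepoints tested series length, samples.
#' @param alpha pointwise and cluster level.
#' @param n_sim simulated null datasets.
#' @param seed integer seed.
#' @return Integer minimum cluster length, in samples.
#' @export
gb_cluster_threshold <- function(phi, n_per_condition, n_timepoints,
                                 alpha = 0.05, n_sim = 1000, seed = 1) {
  if (abs(phi) >= 1) stop("|phi| must be < 1")
  if (alpha >= 1) return(1L)
  n_per_condition <- rep_len(as.integer(n_per_condition), 2L)
  if (any(n_per_condition < 2L)) stop("need >= 2 trials per condition")
  set.seed(as.integer(seed))
  ntr <- sum(n_per_condition)
  Tn <- as.integer(n_timepoints)
  longest <- integer(n_sim)
  chunk <- max(1L, min(n_sim, floor(2e6 / (ntr * Tn)) * 8L))
  done <- 0L
  innov_sd <- sqrt(1 - phi^2)
  while (done < n_sim) {
    m <- min(chunk, n_sim - done)
    X <- matrix(stats::rnorm(m * ntr), m * ntr, 1)
    M <- matrix(0, m * ntr, Tn)
    M[, 1] <- X
    if (Tn > 1)
      for (tt in 2:Tn)
        M[, tt] <- phi * M[, tt - 1] + innov_sd * stats::rnorm(m * ntr)
    for (s in seq_len(m)) {
      rows <- (s - 1L) * ntr + seq_len(ntr)
      cg <- M[rows[seq_len(n_per_condition[1])], , drop = FALSE]
      ig <- M[rows[n_per_condition[1] + seq_len(n_per_condition[2])], ,
              drop = FALSE]
      pt_res <- pointwise_t(cg, ig, seq_len(Tn), start = 1)
      longest[done + s] <- .longest_run(pt_res$p < alpha)
    }
    done <- done + m
  }
  L <- 1L
  while (mean(longest >= L) > alpha) L <- L + 1L
  L
}

#' Extract significant clusters from a p-value series
#'
#' Maximal runs of p < alpha of at least `min_len` samples.
#'
#' @param p p-value series.
#' @param times matching times, ms.
#' @param min_len minimum cluster length (samples), e.g. from
#'   [gb_cluster_threshold].
#' @param alpha pointwise level.
#' @return An object of class `cluster_result`: `clusters`
#'   (start/end ms, length), `significant`, plus the inputs.
#' @export
find_clusters <- function(p, times, min_len, alpha = 0.05) {
  stopifnot(length(p) == length(times))
  cl <- .mask_clusters(p < alpha, times)
  cl <- cl[cl$length >= min_len, , drop = FALSE]
  rownames(cl) <- NULL
  structure(list(p_series = p, times = times, min_cluster_len = min_len,
                 alpha = alpha, clusters = cl,
                 significant = nrow(cl) > 0),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> min length %d samples: %s\n",
              x$min_cluster_len,
              if (x$significant) "significant" else "no significant cluster"))
  if (nrow(x$clusters))
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  %.0f-%.0f ms (%d samples)\n", x$clusters$start_ms[i],
                  x$clusters$end_ms[i], x$clusters$length[i]))
  invisible(x)
}

#' N400 area under the difference waveform
#'
#' Trapezoidal integral of the congruent-minus-incongruent ROI waveform over
#' the window, in steps of one sample; positive when the incongruent
#' condition is more negative (the N400 direction).
#'
#' @param difference congruent-minus-incongruent waveform, microvolts.
#' @param times sample times, ms.
#' @param window integration window, ms (inclusive bounds on samples).
#' @return Area in microvolt-milliseconds.
#' @export
n400_area <- function(difference, times, window = c(300, 800)) {
  stopifnot(length(difference) == length(times))
  if (window[1] < times[1] || window[2] > times[length(times)])
    stop("integration window outside the waveform")
  sel <- which(times >= window[1] & times <= window[2])
  y <- difference[sel]; x <- times[sel]
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Windowed difference topographies
#'
#' Per channel and 200 ms window, the mean over time and trials of
#' (incongruent - congruent); negative values at centro-parietal sites are
#' the classic N400 picture. Rejected trials are excluded.
#'
#' @param epochs an [eeg_epochs].
#' @param windows window starts/ends, ms (default four windows spanning
#'   200-1000 ms, half-open).
#' @return Channels x windows matrix, microvolts.
#' @export
difference_topomap <- function(epochs,
                               windows = cbind(seq(200, 800, 200),
                                               seq(400, 1000, 200))) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  windows <- as.matrix(windows)
  keep_c <- epochs$condition == "congruent" & !epochs$rejected
  keep_i <- epochs$condition == "incongruent" & !epochs$rejected
  if (!any(keep_c) || !any(keep_i)) stop("a condition has no usable trials")
  chans <- channel_names(epochs)
  out <- matrix(NA_real_, length(chans), nrow(windows),
                dimnames = list(chans,
                                sprintf("%d-%d", windows[, 1], windows[, 2])))
  for (w in seq_len(nrow(windows))) {
    sel <- epochs$times >= windows[w, 1] & epochs$times < windows[w, 2]
    if (!any(sel))
      stop("epochs do not cover window ", windows[w, 1], "-", windows[w, 2])
    mc <- apply(epochs$voltages[keep_c, , sel, drop = FALSE], 2, mean)
    mi <- apply(epochs$voltages[keep_i, , sel, drop = FALSE], 2, mean)
    out[, w] <- mi - mc
  }
  out
}

#' Single-subject univariate N400 cluster test
#'
#' The classic pipeline: ROI trial series (rejected trials excluded),
#' pointwise two-sample t-tests from `analysis_start` onward, lag-1
#' autocorrelation of the ROI difference waveform over the tested window,
#' the autocorrelation-matched minimum cluster length
#' ([gb_cluster_threshold]), and cluster extraction. Also reports the
#' 300-800 ms N400 area.
#'
#' @param epochs an [eeg_epochs] (run [reject_artifacts] with the ROI scope
#'   first to reproduce the data-preserving rejection).
#' @param roi a [roi_spec()].
#' @param alpha pointwise and cluster level.
#' @param n_sim null simulations for the threshold.
#' @param seed integer seed.
#' @param tails tails of the pointwise tests.
#' @return An object of class `n400_test` containing the `cluster_result`,
#'   t/p series, `phi`, `min_cluster_len`, `area_uVms` and the ERP.
#' @export
n400_test <- function(epochs, roi = roi_spec(), alpha = 0.05, n_sim = 1000,
                      seed = 1, tails = "two") {
  stopifnot(inherits(roi, "roi_spec"))
  cong <- t(.roi_trials(epochs, roi$channels, "congruent"))
  incong <- t(.roi_trials(epochs, roi$channels, "incongruent"))
  tt <- pointwise_t(cong, incong, epochs$times, roi$analysis_start, tails)
  diff_wave <- colMeans(cong) - colMeans(incong)
  sel <- epochs$times >= roi$analysis_start
  phi <- lag1_autocorr(diff_wave[sel])
  min_len <- gb_cluster_threshold(phi, c(nrow(cong), nrow(incong)),
                                  length(tt$times), alpha, n_sim, seed)
  cl <- find_clusters(tt$p, tt$times, min_len, alpha)
  area <- n400_area(diff_wave, epochs$times, roi$n400_window)
  erp <- roi_erp(epochs, roi)
  structure(list(clusters = cl, t = tt$t, p = tt$p, times = tt$times,
                 phi = phi, min_cluster_len = min_len,
                 significant = cl$significant, area_uVms = area, erp = erp,
                 roi = roi, subject_id = epochs$subject_id),
            class = "n400_test")
}

#' @export
print.n400_test <- function(x, ...) {
  cat(sprintf("<n400_test> %s: phi = %.3f, min cluster %d samples, area %.1f uV.ms\n",
              x$subject_id, x$phi, x$min_cluster_len, x$area_uVms))
  print(x$clusters)
  invisible(x)
}

#' Group-level N400 cluster test
#'
#' Applies the same machinery at the group level: a paired t-test across
#' subjects at each timepoint, which reduces to the one-sample t on the
#' per-subject difference waveforms, with the autocorrelation-matched
#' cluster threshold calibrated on one-sample nulls of matched size.
#'
#' @param diff_waves subjects x samples matrix of per-subject ROI
#'   congruent-minus-incongruent waveforms.
#' @param times sample times, ms.
#' @param start first tested time, ms.
#' @param alpha level.
#' @param n_sim null simulations.
#' @param seed integer seed.
#' @return An object of class `cluster_result` (with `t` attached).
#' @export
group_n400_test <- function(diff_waves, times, start = 150, alpha = 0.05,
                            n_sim = 1000, seed = 1) {
  diff_waves <- as.matrix(diff_waves)
  ns <- nrow(diff_waves)
  if (ns < 2) stop("need >= 2 subjects")
  sel <- which(times >= start)
  m <- colMeans(diff_waves[, sel, drop = FALSE])
  s <- apply(diff_waves[, sel, drop = FALSE], 2, stats::sd)
  tt <- m / (s / sqrt(ns))
  p <- 2 * stats::pt(abs(tt), ns - 1, lower.tail = FALSE)
  phi <- lag1_autocorr(colMeans(diff_waves)[sel])
  set.seed(as.integer(seed))
  Tn <- length(sel)
  innov_sd <- sqrt(1 - phi^2)
  longest <- integer(n_sim)
  for (i in seq_len(n_sim)) {
    M <- matrix(0, ns, Tn)
    M[, 1] <- stats::rnorm(ns)
    if (Tn > 1)
      for (k in 2:Tn) M[, k] <- phi * M[, k - 1] + innov_sd * stats::rnorm(ns)
    mm <- colMeans(M); ss <- apply(M, 2, stats::sd)
    t0 <- mm / (ss / sqrt(ns))
    p0 <- 2 * stats::pt(abs(t0), ns - 1, lower.tail = FALSE)
    longest[i] <- .longest_run(p0 < alpha)
  }
  L <- 1L
  while (mean(longest >= L) > alpha) L <- L + 1L
  res <- find_clusters(p, times[sel], L, alpha)
  res$t <- tt
  res
}
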
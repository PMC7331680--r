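#' Bootstrap standardised measurement error of the N400 score
#'
#' For one channel: accepted trials are resampled with replacement within
#' each condition at the original counts; each bootstrap forms the
#' congruent-minus-incongruent difference ERP and takes its mean amplitude
#' over the scoring window (relative to the already-applied baseline); the
#' SME is the standard deviation of these means over bootstraps. Because the
#' window score is linear in the data, the bootstrap operates on per-trial
#' window means.
#'
#' @param epochs an [eeg_epochs] (baseline-corrected; rejected trials are
#'   excluded).
#' @param channel channel name.
#' @param window scoring window, ms.
#' @param n_boot bootstrap replicates (10000 for full scale).
#' @param seed integer seed.
#' @return SME in microvolts (non-negative scalar).
#' @export
sme_bootstrap <- function(epochs, channel, window = c(300, 800),
                          n_boot = 10000, seed = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!channel %in% channel_names(epochs))
    stop("unknown channel: ", channel)
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) stop("scoring window contains no samples")
  keep_c <- which(epochs$condition == "congruent" & !epochs$rejected)
  keep_i <- which(epochs$condition == "incongruent" & !epochs$rejected)
  if (length(keep_c) < 2 || length(keep_i) < 2)
    stop("need >= 2 accepted trials per condition")
  wm <- apply(epochs$voltages[, channel, sel, drop = FALSE], 1, mean)
  set.seed(as.integer(seed))
  nc <- length(keep_c); ni <- length(keep_i)
  bc <- matrix(sample(wm[keep_c], nc * n_boot, replace = TRUE), n_boot)
  bi <- matrix(sample(wm[keep_i], ni * n_boot, replace = TRUE), n_boot)
  stats::sd(rowMeans(bc) - rowMeans(bi))
}

#' Per-channel SME and its scalp mean
#'
#' Runs [sme_bootstrap] on every requested channel (default: all channels)
#' and reports the per-channel values and their mean.
#'
#' @inheritParams sme_bootstrap
#' @param channels channels to score.
#' @return An object of class `sme_result`: `per_channel` (named, uV),
#'   `mean_uV`, `n_boot`, `window`.
#' @export
sme <- function(epochs, channels = NULL, window = c(300, 800),
                n_boot = 10000, seed = 1) {
  if (is.null(channels)) channels <- channel_names(epochs)
  vals <- vapply(seq_along(channels), function(i)
    sme_bootstrap(epochs, channels[i], window, n_boot,
                  seed = as.integer(seed) + i - 1L), numeric(1))
  names(vals) <- channels
  structure(list(per_channel = vals, mean_uV = mean(vals),
                 n_boot = n_boot, window = window,
                 subject_id = epochs$subject_id),
            class = "sme_result")
}

#' @export
print.sme_result <- function(x, ...) {
  cat(sprintf("<sme_result> %s: mean SME %.3f uV over %d channels (%d bootstraps, %g-%g ms)\n",
              x$subject_id, x$mean_uV, length(x$per_channel), x$n_boot,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-tailed p-value
#' (asymptotic t approximation, as appropriate with ties).
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return List: `rho`, `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Cross-analysis per-subject summary table
#'
#' Collects, per subject, the Yes/No outcomes of the three analyses
#' (unconstrained decoding, time-resolved decoding, univariate N400) plus
#' the quantitative columns, and a totals row in the `13/20` format.
#'
#' @param results list of per-subject lists, each with elements `decoding`
#'   (a `loto_decoding`), `timecourse` (a `tfce_test`), `univariate` (an
#'   `n400_test`), and optionally `sme` (an `sme_result`).
#' @return An object of class `subject_summary` wrapping a data.frame.
#' @export
summarize_subjects <- function(results) {
  if (!length(results)) stop("no subject results supplied")
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    for (nm in c("decoding", "timecourse", "univariate"))
      if (is.null(r[[nm]]))
        stop("subject ", i, " is missing the ", nm, " analysis")
    data.frame(
      subject_id = r$decoding$subject_id,
      mvpa_yes = isTRUE(r$decoding$significant),
      timecourse_yes = any(r$timecourse$significant),
      n400_yes = isTRUE(r$univariate$significant),
      accuracy = r$decoding$accuracy,
      effect_size = r$decoding$effect_size,
      p_rank = r$decoding$p_rank,
      sme_mean_uV = if (!is.null(r$sme)) r$sme$mean_uV else NA_real_,
      n400_area_uVms = r$univariate$area_uVms)
  })
  df <- do.call(rbind, rows)
  structure(list(table = df,
                 totals = c(mvpa = sum(df$mvpa_yes),
                            timecourse = sum(df$timecourse_yes),
                            n400 = sum(df$n400_yes),
                            n = nrow(df))),
            class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  df <- x$table
  yn <- function(b) ifelse(b, "Yes", "No")
  disp <- data.frame(subject = df$subject_id, MVPA = yn(df$mvpa_yes),
                     `time-resolved` = yn(df$timecourse_yes),
                     N400 = yn(df$n400_yes),
                     accuracy = sprintf("%.3f", df$accuracy),
                     check.names = FALSE)
  print(disp, row.names = FALSE)
  n <- x$totals["n"]
  cat(sprintf("Total  %d/%d  %d/%d  %d/%d\n", x$totals["mvpa"], n,
              x$totals["timecourse"], n, x$totals["n400"], n))
  invisible(x)
}

#' @rdname summarize_subjects
#' @param x a `subject_summary`.
#' @param path CSV output path.
#' @export
write_summary_csv <- function(x, path) {
  stopifnot(inherits(x, "subject_summary"))
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}

#' Run the full per-subject analysis battery over a cohort
#'
#' For each subject: baseline correction and ROI-scoped artifact rejection,
#' unconstrained LOTO decoding with its permutation null, time-resolved
#' decoding with TFCE max-statistic correction, optionally the searchlight
#' map, the univariate N400 cluster test, and the SME -- then the
#' cross-analysis summary. One root seed drives every stochastic step, so
#' re-runs are byte-identical. If `out_dir` is given, the summary CSV and a
#' reproducibility manifest (JSON: configuration, seeds, package version)
#' are written there.
#'
#' @param subjects list of [eeg_epochs], or a directory containing `.eeg`
#'   containers saved by [save_epochs].
#' @param montage an `eeg_montage`.
#' @param n_perm permutations for both decoding nulls.
#' @param n_boot SME bootstrap replicates.
#' @param n_sim null simulations for the univariate cluster threshold.
#' @param seed root seed.
#' @param roi a [roi_spec()].
#' @param reject_threshold artifact threshold, microvolts.
#' @param searchlight also compute the searchlight map per subject.
#' @param halfwidth temporal half-window, samples.
#' @param out_dir optional output directory.
#' @return List: `summary` (a `subject_summary`), `per_subject` results.
#' @export
run_pipeline <- function(subjects, montage = default_montage(),
                         n_perm = 100, n_boot = 1000, n_sim = 1000,
                         seed = 1, roi = roi_spec(),
                         reject_threshold = 200, searchlight = FALSE,
                         halfwidth = 5, out_dir = NULL) {
  if (is.character(subjects)) {
    paths <- sort(list.files(subjects, pattern = "\\.eeg$",
                             full.names = TRUE))
    if (!length(paths)) stop("no .eeg containers found in ", subjects)
    subjects <- lapply(paths, load_epochs)
  }
  seed <- as.integer(seed)
  per_subject <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    ep <- subjects[[i]]
    if (!inherits(ep, "eeg_epochs"))
      stop("subject ", i, ": not an eeg_epochs object")
    sseed <- (seed + 104729L * i) %% .Machine$integer.max
    ep <- baseline_correct(ep)
    roi_chans <- intersect(roi$channels, channel_names(ep))
    ep_uni <- reject_artifacts(ep, reject_threshold,
                               scope = if (length(roi_chans)) roi_chans
                                       else channel_names(ep))
    res <- list(
      decoding = loto_decode(ep, n_perm = n_perm, seed = sseed),
      timecourse = time_resolved_test(ep, halfwidth = halfwidth,
                                      n_perm = n_perm, seed = sseed + 1L),
      univariate = n400_test(ep_uni,
                             roi = if (length(roi_chans) ==
                                       length(roi$channels)) roi
                                   else roi_spec(channels = roi_chans,
                                                 analysis_start = roi$analysis_start,
                                                 n400_window = roi$n400_window),
                             n_sim = n_sim, seed = sseed + 2L),
      sme = sme(ep_uni, n_boot = n_boot, seed = sseed + 3L))
    if (searchlight)
      res$searchlight <- searchlight_decode(ep, montage,
                                            halfwidth = halfwidth)
    per_subject[[i]] <- res
  }
  summary <- summarize_subjects(per_subject)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_summary_csv(summary, file.path(out_dir, "summary.csv"))
    manifest <- list(
      package = "n400mvpa",
      version = as.character(utils::packageVersion("n400mvpa")),
      seed = seed, n_perm = n_perm, n_boot = n_boot, n_sim = n_sim,
      n_subjects = length(subjects),
      reject_threshold = reject_threshold,
      roi = roi$channels, searchlight = searchlight)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(summary = summary, per_subject = per_subject)
}
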
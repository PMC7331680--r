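#' Epoched EEG container
#'
#' `eeg_epochs` stores a trials x channels x samples voltage array (in
#' microvolts) together with its time axis, per-trial condition labels
#' (congruent / incongruent), target-pair identifiers, a rejection mask and a
#' subject identifier.
#'
#' Conventions: time 0 ms is target-word onset; the default epoch window is
#' half-open, \eqn{[-100, 1000)} ms, so the sample count is exactly
#' `floor(1.1 * srate)` (563 samples at 512 Hz) and the first sample sits at
#' -100 ms. Each `pair_id` must occur exactly twice, once per condition.
#'
#' @param voltages numeric array `[trial, channel, sample]`, microvolts.
#'   Channel names are taken from `dimnames(voltages)[[2]]` unless given.
#' @param times numeric vector of sample times in ms (uniformly spaced,
#'   strictly increasing).
#' @param srate sampling rate, Hz.
#' @param condition per-trial labels, each `"congruent"` or `"incongruent"`.
#' @param pair_id per-trial integer target-pair identifiers.
#' @param channels optional channel names.
#' @param rejected optional per-trial logical rejection mask (default all
#'   `FALSE`).
#' @param subject_id subject label.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(voltages, times, srate, condition, pair_id,
                       channels = NULL, rejected = NULL,
                       subject_id = "subject") {
  if (length(dim(voltages)) != 3L)
    stop("voltages must be a trials x channels x samples array")
  n_trial <- dim(voltages)[1]
  n_chan <- dim(voltages)[2]
  n_samp <- dim(voltages)[3]
  if (is.null(channels)) channels <- dimnames(voltages)[[2]]
  if (is.null(channels)) channels <- paste0("ch", seq_len(n_chan))
  if (length(channels) != n_chan) stop("channels length mismatch")
  if (!all(is.finite(voltages))) stop("voltages must be finite")
  if (length(times) != n_samp) stop("times length mismatch")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (diff(range(dt)) > 1e-6) stop("times must be uniformly spaced")
  if (abs(dt[1] - 1000 / srate) > 1e-6)
    stop("times spacing must equal 1000/srate ms")
  condition <- as.character(condition)
  if (length(condition) != n_trial || !all(condition %in% c("congruent", "incongruent")))
    stop("condition must be per-trial 'congruent' or 'incongruent'")
  pair_id <- as.integer(pair_id)
  if (length(pair_id) != n_trial) stop("pair_id length mismatch")
  tab <- table(pair_id)
  if (any(tab != 2L))
    stop("pair_id must occur exactly twice (violated by pair ",
         names(tab)[which(tab != 2L)[1]], ")")
  cross <- table(pair_id, condition)
  if (ncol(cross) != 2L || any(cross != 1L))
    stop("each pair_id must occur once per condition")
  if (is.null(rejected)) rejected <- rep(FALSE, n_trial)
  if (length(rejected) != n_trial) stop("rejected length mismatch")
  dimnames(voltages) <- list(NULL, channels, NULL)
  structure(
    list(voltages = voltages, times = as.numeric(times),
         srate = as.numeric(srate), condition = condition,
         pair_id = pair_id, rejected = as.logical(rejected),
         subject_id = as.character(subject_id)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %s: %d trials (%d pairs) x %d channels x %d samples\n",
              x$subject_id, n_trials(x), length(unique(x$pair_id)),
              n_channels(x), length(x$times)))
  cat(sprintf("  %.1f Hz, window [%.1f, %.1f] ms, %d trial(s) rejected\n",
              x$srate, x$times[1], x$times[length(x$times)],
              sum(x$rejected)))
  invisible(x)
}

#' @rdname eeg_epochs
#' @param x an `eeg_epochs`.
#' @export
n_trials <- function(x) dim(x$voltages)[1]

#' @rdname eeg_epochs
#' @export
n_channels <- function(x) dim(x$voltages)[2]

#' @rdname eeg_epochs
#' @export
channel_names <- function(x) dimnames(x$voltages)[[2]]

#' Time axis for an epoch window
#'
#' Sample times in ms for a half-open window `[from, to)` at a given sampling
#' rate: `floor((to - from) * srate / 1000)` samples, the first exactly at
#' `from`.
#'
#' @param srate sampling rate, Hz.
#' @param window length-2 numeric, ms.
#' @return Numeric vector of sample times, ms.
#' @export
epoch_times <- function(srate, window = c(-100, 1000)) {
  n <- floor(diff(window) * srate / 1000)
  window[1] + (seq_len(n) - 1) * 1000 / srate
}

# index of the sample taken as the time-locking (t = 0) sample
.onset_index <- function(srate, window = c(-100, 1000)) {
  round(-window[1] * srate / 1000) + 1L
}

#' Continuous (unepoched) EEG container
#'
#' A channels x samples voltage matrix plus an event table
#' `(sample, condition, pair_id)` marking target-word onsets.
#'
#' @param voltages numeric matrix `[channel, sample]`, microvolts, with
#'   channel rownames.
#' @param srate sampling rate, Hz.
#' @param events data.frame with columns `sample` (1-based onset sample),
#'   `condition`, `pair_id`; sorted by sample.
#' @param subject_id subject label.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(voltages, srate, events,
                                 subject_id = "subject") {
  voltages <- as.matrix(voltages)
  if (is.null(rownames(voltages))) stop("voltages must have channel rownames")
  need <- c("sample", "condition", "pair_id")
  if (!all(need %in% names(events))) stop("events need sample, condition, pair_id")
  events <- events[order(events$sample), , drop = FALSE]
  if (any(events$sample < 1 | events$sample > ncol(voltages)))
    stop("event sample out of range")
  structure(list(voltages = voltages, srate = as.numeric(srate),
                 events = events, subject_id = as.character(subject_id)),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %s: %d channels x %d samples (%.1f s), %d events\n",
              x$subject_id, nrow(x$voltages), ncol(x$voltages),
              ncol(x$voltages) / x$srate, nrow(x$events)))
  invisible(x)
}

# fetch the trials x channels x samples array restricted to given channels
.epochs_cube <- function(epochs, channels = NULL) {
  if (is.null(channels)) return(epochs$voltages)
  miss <- setdiff(channels, channel_names(epochs))
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  epochs$voltages[, channels, , drop = FALSE]
}
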
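#' Sequential bias of a condition sequence
#'
#' Quantifies how predictable the next condition is from the preceding
#' `order` conditions. For every history of `order` labels that occurs in the
#' sequence, the conditional relative frequency of "congruent" among its
#' successors is computed; the bias is the occurrence-weighted mean of the
#' squared deviations of these conditional frequencies from 0.5. A sequence
#' in which every history is followed by each condition equally often scores
#' 0; strict alternation scores 0.25 at order 1.
#'
#' @param labels character vector over `{"congruent", "incongruent"}` (or any
#'   two values; the first level alphabetically plays the role of
#'   "congruent").
#' @param order history length (1, 2 or 3 in the session optimiser).
#' @return Non-negative scalar.
#' @export
sequence_bias <- function(labels, order) {
  n <- length(labels)
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (n < order + 1L)
    stop("sequence must be longer than order")
  x <- as.integer(factor(labels))
  if (length(unique(x)) > 2L) stop("labels must be binary")
  is_c <- x == min(x)
  # history key for each successor position
  idx <- (order + 1L):n
  key <- integer(length(idx))
  for (j in seq_len(order))
    key <- key * 2L + as.integer(is_c[idx - j])
  succ_c <- as.numeric(is_c[idx])
  counts <- tapply(succ_c, key, length)
  p_c <- tapply(succ_c, key, mean)
  sum(counts * (p_c - 0.5)^2) / sum(counts)
}

# run-length constraints: no run longer than max_run, and runs of length L
# no more frequent than runs of length L-1, for L = 2..max_run
.runs_ok <- function(labels, max_run) {
  r <- rle(labels)$lengths
  if (max(r) > max_run) return(FALSE)
  cnt <- tabulate(r, nbins = max_run)
  all(diff(cnt) <= 0)
}

# one balanced candidate drawn under the max-run constraint: labels chosen
# sequentially with probability proportional to the remaining counts, a run
# at max_run forbidding its own extension; dead ends (a depleted condition
# forcing an over-long run) restart the draw. For long sequences an
# unconstrained shuffle essentially never satisfies max_run = 4, so the
# constraint must be built into the sampler.
.sample_constrained <- function(n_pairs, max_run) {
  n <- 2L * n_pairs
  repeat {
    rem <- c(n_pairs, n_pairs)   # 1 = congruent, 2 = incongruent
    out <- integer(n)
    last <- 0L
    run_len <- 0L
    ok <- TRUE
    for (i in seq_len(n)) {
      blocked <- if (run_len >= max_run) last else 0L
      c1 <- rem[1] > 0L && blocked != 1L
      c2 <- rem[2] > 0L && blocked != 2L
      if (!c1 && !c2) { ok <- FALSE; break }
      pick <- if (c1 && c2) {
        if (stats::runif(1) < rem[1] / (rem[1] + rem[2])) 1L else 2L
      } else if (c1) 1L else 2L
      out[i] <- pick
      if (pick == last) run_len <- run_len + 1L
      else { last <- pick; run_len <- 1L }
      rem[pick] <- rem[pick] - 1L
    }
    if (ok) return(c("congruent", "incongruent")[out])
  }
}

#' Generate a bias-minimised trial sequence
#'
#' Draws `n_candidates` random orderings of `n_pairs` congruent and
#' `n_pairs` incongruent labels, keeps those satisfying the run constraints
#' (no more than `max_run` same-condition trials in a row, and longer
#' same-condition runs no more frequent than shorter ones), and returns the
#' candidate minimising the summed first-, second- and third-order
#' [sequence_bias()]. Pair (sentence-frame) identifiers are then assigned so
#' that each frame occurs once in each half of the session, and compliance
#' question trials are placed approximately every `question_every` trials
#' with a jitter of `question_jitter` trials.
#'
#' @param n_pairs number of target pairs; the sequence has `2 * n_pairs`
#'   trials.
#' @param n_candidates candidate sequences drawn (default 1000).
#' @param max_run maximum allowed same-condition run length.
#' @param seed integer seed.
#' @param question_every nominal spacing of question trials.
#' @param question_jitter uniform jitter (+/- trials) on that spacing.
#' @param return_candidates also return the retained candidates' label
#'   sequences (for auditing the bias minimisation).
#' @return An object of class `trial_sequence`: `labels`, `pair_id`,
#'   `bias_scores` (orders 1-3), `question_trials`, and the number of
#'   candidates that satisfied the run constraints.
#' @export
generate_sequence <- function(n_pairs, n_candidates = 1000, max_run = 4,
                              seed = 1, question_every = 7,
                              question_jitter = 3,
                              return_candidates = FALSE) {
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L)
    stop("n_pairs must be >= 1")
  set.seed(as.integer(seed))
  n <- 2L * n_pairs

  best <- NULL
  best_bias <- Inf
  n_ok <- 0L
  kept <- if (return_candidates) vector("list", n_candidates)
  for (cand in seq_len(n_candidates)) {
    s <- .sample_constrained(n_pairs, max_run)
    if (!.runs_ok(s, max_run)) next
    n_ok <- n_ok + 1L
    if (return_candidates) kept[[n_ok]] <- s
    b <- if (n >= 4L) {
      sum(vapply(1:3, function(o)
        if (n > o) sequence_bias(s, o) else 0, numeric(1)))
    } else sequence_bias(s, 1)
    if (b < best_bias) { best <- s; best_bias <- b }
  }
  if (is.null(best))
    stop("no candidate satisfied the run constraints; ",
         "increase n_candidates or relax max_run")

  # frame balancing: each pair contributes one trial to each half
  half1 <- seq_len(n_pairs)
  half2 <- n_pairs + seq_len(n_pairs)
  c1 <- half1[best[half1] == "congruent"]   # congruent slots, first half
  i1 <- half1[best[half1] == "incongruent"]
  c2 <- half2[best[half2] == "congruent"]
  i2 <- half2[best[half2] == "incongruent"]
  stopifnot(length(c1) == length(i2), length(i1) == length(c2))
  shuf <- function(v) if (length(v) <= 1L) v else sample(v)
  pair_id <- integer(n)
  ids <- if (n_pairs > 1L) sample.int(n_pairs) else 1L
  k <- 0L
  if (length(c1)) {
    grp <- ids[k + seq_along(c1)]; k <- k + length(c1)
    pair_id[shuf(c1)] <- grp
    pair_id[shuf(i2)] <- grp
  }
  if (length(i1)) {
    grp <- ids[k + seq_along(i1)]
    pair_id[shuf(i1)] <- grp
    pair_id[shuf(c2)] <- grp
  }

  # question-trial schedule: gaps of question_every +/- question_jitter
  q <- integer(0)
  pos <- 0
  repeat {
    pos <- pos + question_every +
      sample.int(2L * question_jitter + 1L, 1L) - question_jitter - 1L
    if (pos > n) break
    q <- c(q, pos)
  }

  bias <- vapply(1:3, function(o)
    if (n > o) sequence_bias(best, o) else NA_real_, numeric(1))
  structure(list(labels = best, pair_id = pair_id,
                 bias_scores = stats::setNames(bias, paste0("order", 1:3)),
                 question_trials = q, n_candidates_retained = n_ok,
                 candidates = if (return_candidates) kept[seq_len(n_ok)]),
            class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence> %d trials (%d per condition), %d question trials\n",
              length(x$labels), sum(x$labels == "congruent"),
              length(x$question_trials)))
  cat("  bias:", paste(sprintf("%s=%.4f", names(x$bias_scores),
                               x$bias_scores), collapse = ", "), "\n")
  invisible(x)
}

#' Power of a two-sample t-test
#'
#' Exact noncentral-t power for a two-sample t-test with `n_per_group`
#' observations per group and standardised effect size `d` (noncentrality
#' \eqn{d \sqrt{n/2}}, df \eqn{2n - 2}). With `n_per_group = 94`, `d = 0.5`
#' and one-tailed \eqn{\alpha = 0.05} this gives the 96% session power figure.
#'
#' @param n_per_group observations per group (>= 2).
#' @param d Cohen's d.
#' @param alpha significance level, in (0, 1).
#' @param tails `"one"` or `"two"`.
#' @return Power, in (0, 1).
#' @export
power_two_sample_t <- function(n_per_group, d, alpha = 0.05,
                               tails = c("one", "two")) {
  tails <- match.arg(tails)
  n <- as.integer(n_per_group)
  if (is.na(n) || n < 2L) stop("n_per_group must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (tails == "one") {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  }
}
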
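# ---- feature assembly and Gram computation ----

# signed labels (+1 congruent, -1 incongruent), 0-based pair indices, and
# the trials x trials linear-kernel Gram over the requested channels.
.decode_inputs <- function(epochs, channels = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  tab <- table(epochs$pair_id, epochs$condition)
  bad <- rownames(tab)[rowSums(tab) != 2L | apply(tab, 1, max) > 1L]
  if (length(bad))
    stop("incomplete pair(s): ", paste(bad, collapse = ", "))
  if (length(unique(epochs$pair_id)) < 2L)
    stop("at least 2 pairs required")
  cube <- .epochs_cube(epochs, channels)
  n <- dim(cube)[1]
  X <- matrix(cube, n) # trials x (channels * samples)
  y <- ifelse(epochs$condition == "congruent", 1L, -1L)
  pair0 <- as.integer(factor(epochs$pair_id)) - 1L
  list(X = X, K = tcrossprod(X), y = y, pair0 = pair0,
       n_pairs = length(unique(epochs$pair_id)), cube = cube)
}

# pairing-preserving permutation scheme: each row flips (p = 0.5) the two
# condition labels within every pair; row of FALSE = identity
.flip_matrix <- function(n_perm, n_pairs, seed) {
  set.seed(as.integer(seed))
  matrix(stats::runif(n_perm * n_pairs) < 0.5, n_perm, n_pairs)
}

#' Leave-one-target-out cross-validated decoding accuracy
#'
#' Trains a linear soft-margin SVM (cost `C = 1`, raw voltages from all
#' requested channels and all time points as features) on all pairs but one
#' and tests on the held-out pair's two trials; one fold per pair, fold
#' accuracy in `{0, 0.5, 1}`, overall accuracy the mean over folds. All
#' trials are used regardless of the rejection mask (the LOTO design needs
#' every pair complete).
#'
#' @param epochs an [eeg_epochs]; every pair must have one trial per
#'   condition.
#' @param channels channels to use (default all).
#' @param cost SVM regularisation constant.
#' @return List: `accuracy`, `fold_accuracies` (one per pair, named).
#' @export
loto_crossval <- function(epochs, channels = NULL, cost = 1) {
  di <- .decode_inputs(epochs, channels)
  folds <- .cpp_loto_perm(di$K, di$y, di$pair0,
                          matrix(FALSE, 1, di$n_pairs), cost, 1e-3)[1, ]
  names(folds) <- levels(factor(epochs$pair_id))
  list(accuracy = mean(folds), fold_accuracies = folds)
}

#' Pairing-preserving permutation null for LOTO decoding
#'
#' Each permutation flips, independently with probability 0.5, the two
#' condition labels within every target pair (so the target pairing and the
#' cross-validation scheme are preserved), then re-runs the identical LOTO
#' procedure. The all-no-flip permutation reproduces the observed accuracy
#' exactly.
#'
#' @inheritParams loto_crossval
#' @param n_perm number of permutations.
#' @param seed integer seed for the flip draws.
#' @return Numeric vector of `n_perm` permutation accuracies.
#' @export
permutation_null <- function(epochs, n_perm = 1000, seed = 1,
                             channels = NULL, cost = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  di <- .decode_inputs(epochs, channels)
  flips <- .flip_matrix(n_perm, di$n_pairs, seed)
  rowMeans(.cpp_loto_perm(di$K, di$y, di$pair0, flips, cost, 1e-3))
}

#' Significance of an observed decoding accuracy against its null
#'
#' `p_rank` is the one-tailed rank p-value with the add-one convention,
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`; `p_normal` is the upper-tail
#' probability under a normal fit to the null (the route to p-values below
#' `1/n_perm`). The significance flag applies the selection rule directly:
#' significant iff the observed accuracy is higher than `1 - alpha` of the
#' null accuracies. Flag and `p_rank` can disagree exactly at the boundary;
#' the flag is authoritative for summary tables.
#'
#' @param observed observed accuracy.
#' @param null numeric vector of permutation accuracies.
#' @param alpha level of the selection rule.
#' @return List: `p_rank`, `p_normal`, `significant`.
#' @export
decode_significance <- function(observed, null, alpha = 0.05) {
  if (!length(null)) stop("null distribution is empty")
  n <- length(null)
  p_rank <- (1 + sum(null >= observed)) / (1 + n)
  mu <- mean(null); s <- stats::sd(null)
  p_normal <- if (s > 0) stats::pnorm(observed, mu, s, lower.tail = FALSE)
              else as.numeric(observed <= mu)
  list(p_rank = p_rank, p_normal = p_normal,
       significant = mean(null < observed) > 1 - alpha)
}

#' Null-referenced decoding effect size
#'
#' `(observed - mean(null)) / sd(null)` with the n-1 SD; an illustrative,
#' per-subject effect size in null-SD units.
#'
#' @inheritParams decode_significance
#' @return Dimensionless scalar.
#' @export
decoding_effect_size <- function(observed, null) {
  s <- stats::sd(null)
  if (!is.finite(s) || s == 0)
    stop("degenerate null distribution (zero SD)")
  (observed - mean(null)) / s
}

#' Unconstrained LOTO decoding with permutation inference
#'
#' The package's main fit: spatio-temporally unconstrained leave-one-target-
#' out SVM decoding ([loto_crossval]), a pairing-preserving permutation null
#' ([permutation_null]), rank and normal-fit p-values, the selection-rule
#' significance flag and the null-referenced effect size.
#'
#' @inheritParams permutation_null
#' @param alpha significance level.
#' @return An object of class `loto_decoding` with fields `accuracy`,
#'   `fold_accuracies`, `null_accuracies`, `p_rank`, `p_normal`,
#'   `effect_size`, `significant`, `n_permutations`, `subject_id`.
#' @examples
#' sim <- simulate_subject(n_pairs = 10,
#'                         montage = subset_montage(default_montage(),
#'                                                  c("Cz", "CPz", "FCz")),
#'                         srate = 64, seed = 1)
#' fit <- loto_decode(sim$epochs, n_perm = 50, seed = 2)
#' print(fit)
#' @export
loto_decode <- function(epochs, n_perm = 1000, seed = 1, alpha = 0.05,
                        channels = NULL, cost = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  di <- .decode_inputs(epochs, channels)
  flips <- rbind(rep(FALSE, di$n_pairs),
                 .flip_matrix(n_perm, di$n_pairs, seed))
  fa <- .cpp_loto_perm(di$K, di$y, di$pair0, flips, cost, 1e-3)
  folds <- fa[1, ]
  names(folds) <- levels(factor(epochs$pair_id))
  observed <- mean(folds)
  null <- rowMeans(fa)[-1]
  sig <- decode_significance(observed, null, alpha)
  es <- if (stats::sd(null) > 0) decoding_effect_size(observed, null)
        else NA_real_
  structure(list(accuracy = observed, fold_accuracies = folds,
                 null_accuracies = null, p_rank = sig$p_rank,
                 p_normal = sig$p_normal, effect_size = es,
                 significant = sig$significant, n_permutations = n_perm,
                 alpha = alpha, subject_id = epochs$subject_id),
            class = "loto_decoding")
}

#' @export
print.loto_decoding <- function(x, ...) {
  cat(sprintf("<loto_decoding> %s: accuracy %.1f%% over %d folds\n",
              x$subject_id, 100 * x$accuracy, length(x$fold_accuracies)))
  cat(sprintf("  null (n = %d): mean %.1f%%, sd %.2f%%; p_rank = %.4g, p_normal = %.3g\n",
              x$n_permutations, 100 * mean(x$null_accuracies),
              100 * stats::sd(x$null_accuracies), x$p_rank, x$p_normal))
  cat(sprintf("  effect size = %.2f; %s at alpha = %.2f\n", x$effect_size,
              if (x$significant) "SIGNIFICANT" else "not significant",
              x$alpha))
  invisible(x)
}

#' @export
summary.loto_decoding <- function(object, ...) {
  data.frame(subject_id = object$subject_id, accuracy = object$accuracy,
             null_mean = mean(object$null_accuracies),
             null_sd = stats::sd(object$null_accuracies),
             p_rank = object$p_rank, p_normal = object$p_normal,
             effect_size = object$effect_size,
             significant = object$significant)
}

#' @export
plot.loto_decoding <- function(x, ...) {
  graphics::hist(100 * x$null_accuracies, breaks = 30, col = "khaki",
                 border = NA, main = x$subject_id,
                 xlab = "decoding accuracy (%)",
                 xlim = range(100 * c(x$null_accuracies, x$accuracy, 0.5)))
  graphics::abline(v = 100 * x$accuracy, col = "purple", lwd = 2)
  graphics::abline(v = 50, lty = 2)
  invisible(x)
}

# ---- pseudotrial variant ----

# average groups of k trials within a label class; leftovers dropped;
# returns list(X = pseudotrials x features, lab = +1/-1)
.make_pseudotrials <- function(X, ysgn, k) {
  out_x <- NULL; out_y <- integer()
  for (cls in c(1L, -1L)) {
    idx <- sample(which(ysgn == cls))
    m <- length(idx) %/% k
    if (m < 1L) stop("k exceeds the number of trials in a condition")
    for (g in seq_len(m)) {
      rows <- idx[((g - 1L) * k + 1L):(g * k)]
      out_x <- rbind(out_x, colMeans(X[rows, , drop = FALSE]))
      out_y <- c(out_y, cls)
    }
  }
  list(X = out_x, y = out_y)
}

# LOTO over pseudotrial pairs: pseudotrial i of one class is paired with
# pseudotrial i of the other (pairing by construction order)
.pseudo_loto <- function(ps, cost) {
  m <- sum(ps$y == 1L)
  m2 <- sum(ps$y == -1L)
  mm <- min(m, m2)
  keep <- c(which(ps$y == 1L)[seq_len(mm)], which(ps$y == -1L)[seq_len(mm)])
  X <- ps$X[keep, , drop = FALSE]
  y <- ps$y[keep]
  pair0 <- c(seq_len(mm), seq_len(mm)) - 1L
  if (mm < 2L) stop("need at least two pseudotrial pairs")
  K <- tcrossprod(X)
  mean(.cpp_loto_perm(K, y, pair0, matrix(FALSE, 1, mm), cost, 1e-3)[1, ])
}

#' Pseudotrial decoding
#'
#' Averages `k` randomly chosen same-condition trials into each pseudotrial,
#' builds `n_sets` independent pseudotrial sets, decodes each with
#' leave-one-pseudotrial-pair-out cross-validation and averages the set
#' accuracies into one score. The matching permutation null flips condition
#' labels within real target pairs first and then builds pseudotrial sets
#' the same way. Defaults follow the session parameters (`k = 12`,
#' `n_sets = 100`).
#'
#' @inheritParams loto_decode
#' @param k trials averaged per pseudotrial.
#' @param n_sets pseudotrial sets per accuracy estimate.
#' @return An object of class `loto_decoding` (with `n_sets` and `k` noted).
#' @export
pseudotrial_decode <- function(epochs, k = 12, n_sets = 100, n_perm = 0,
                               seed = 1, alpha = 0.05, channels = NULL,
                               cost = 1) {
  if (k < 1) stop("k must be >= 1")
  if (n_sets < 1) stop("n_sets must be >= 1")
  di <- .decode_inputs(epochs, channels)
  per_cond <- min(table(epochs$condition))
  if (k > per_cond)
    stop("k (", k, ") exceeds the ", per_cond, " trials per condition")
  set.seed(as.integer(seed))
  obs_sets <- vapply(seq_len(n_sets), function(s)
    .pseudo_loto(.make_pseudotrials(di$X, di$y, k), cost), numeric(1))
  observed <- mean(obs_sets)

  null <- NULL
  if (n_perm > 0) {
    flips <- .flip_matrix(n_perm, di$n_pairs, seed + 1L)
    null <- numeric(n_perm)
    pid <- di$pair0 + 1L
    for (p in seq_len(n_perm)) {
      yp <- di$y
      fl <- flips[p, pid]
      yp[fl] <- -yp[fl]
      null[p] <- mean(vapply(seq_len(n_sets), function(s)
        .pseudo_loto(.make_pseudotrials(di$X, yp, k), cost), numeric(1)))
    }
  }
  sig <- if (length(null)) decode_significance(observed, null, alpha)
         else list(p_rank = NA_real_, p_normal = NA_real_, significant = NA)
  es <- if (length(null) && stats::sd(null) > 0)
          decoding_effect_size(observed, null) else NA_real_
  structure(list(accuracy = observed, fold_accuracies = obs_sets,
                 null_accuracies = null, p_rank = sig$p_rank,
                 p_normal = sig$p_normal, effect_size = es,
                 significant = sig$significant,
                 n_permutations = length(null), alpha = alpha, k = k,
                 n_sets = n_sets, subject_id = epochs$subject_id),
            class = "loto_decoding")
}
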
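test_that("LOTO structure: one fold per pair, fold accuracies in {0, .5, 1}", {
  sim <- quick_sim(seed = 1, n_pairs = 10)
  cv <- loto_crossval(sim$epochs)
  expect_length(cv$fold_accuracies, 10)
  expect_true(all(cv$fold_accuracies %in% c(0, 0.5, 1)))
  expect_equal(cv$accuracy, mean(cv$fold_accuracies))
})

test_that("noiseless separable data decode perfectly", {
  sim <- quick_sim(seed = 2, n_pairs = 6,
                   effect = effect_spec(amplitude_uV = -4),
                   noise = noise_spec(0, 0, 0))
  expect_equal(loto_crossval(sim$epochs)$accuracy, 1)
  ps <- pseudotrial_decode(sim$epochs, k = 2, n_sets = 3, seed = 1)
  expect_equal(ps$accuracy, 1)
})

test_that("fold accuracies agree with an independent libsvm (e1071) oracle", {
  skip_if_not_installed("e1071")
  for (seed in 1:5) {
    sim <- quick_sim(seed = 100 + seed, n_pairs = 7, n_ch = 4)
    ep <- sim$epochs
    cv <- loto_crossval(ep)
    X <- matrix(ep$voltages, n_trials(ep))
    y <- factor(ep$condition)
    oracle <- vapply(unique(ep$pair_id), function(q) {
      te <- which(ep$pair_id == q)
      m <- e1071::svm(X[-te, ], y[-te], kernel = "linear", cost = 1,
                      scale = FALSE)
      mean(predict(m, X[te, , drop = FALSE]) == y[te])
    }, numeric(1))
    expect_equal(unname(cv$fold_accuracies), oracle)
  }
})

test_that("the identity permutation reproduces the observed accuracy", {
  sim <- quick_sim(seed = 3, n_pairs = 8)
  fit <- loto_decode(sim$epochs, n_perm = 20, seed = 4)
  # fold row 0 of the internal permutation matrix is all-no-flip
  expect_equal(fit$accuracy, mean(fit$fold_accuracies))
  # flipping every pair inverts all labels: still the same partition
  di <- n400mvpa:::.decode_inputs(sim$epochs)
  allflip <- matrix(TRUE, 1, di$n_pairs)
  noflip <- matrix(FALSE, 1, di$n_pairs)
  a1 <- rowMeans(n400mvpa:::.cpp_loto_perm(di$K, di$y, di$pair0, allflip, 1, 1e-4))
  a0 <- rowMeans(n400mvpa:::.cpp_loto_perm(di$K, di$y, di$pair0, noflip, 1, 1e-4))
  expect_equal(a1, a0)
})

test_that("significance and effect size follow their defining formulas", {
  null <- seq(0.3, 0.7, length.out = 100)
  s <- decode_significance(0.75, null)
  expect_equal(s$p_rank, 1 / 101)
  expect_true(s$significant)
  s2 <- decode_significance(median(null), null)
  expect_gt(s2$p_rank, 0.4)
  expect_false(s2$significant)
  # a normal-fit p-value can go far below 1/n_perm
  null3 <- rnorm(1000, 0.5, 0.025)
  s3 <- decode_significance(mean(null3) + 4 * sd(null3), null3)
  expect_lt(s3$p_normal, 1e-3)
  expect_gte(s3$p_rank, 1 / 1001)

  expect_equal(decoding_effect_size(0.60, c(0.475, 0.525)), 2.828427,
               tolerance = 1e-6)
  expect_equal(decoding_effect_size(0.5, rep(c(0.45, 0.55), 10)), 0)
  x <- rnorm(50, 0.5, 0.02)
  expect_equal(decoding_effect_size(0.55, x),
               (0.55 - mean(x)) / sd(x))
  expect_error(decoding_effect_size(0.6, rep(0.5, 10)), "degenerate")
})

test_that("adding a constant to every voltage leaves fold accuracies unchanged", {
  sim <- quick_sim(seed = 5, n_pairs = 8, n_ch = 4)
  cv1 <- loto_crossval(sim$epochs)
  shifted <- sim$epochs
  shifted$voltages <- shifted$voltages + 37
  cv2 <- loto_crossval(shifted)
  expect_equal(cv1$fold_accuracies, cv2$fold_accuracies)
})

test_that("null decoding is chance-centred", {
  accs <- vapply(1:30, function(i)
    loto_crossval(quick_sim(seed = 200 + i, n_pairs = 10, n_ch = 4,
                            srate = 23)$epochs)$accuracy, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 2.5 * se + 0.01)
})

test_that("pseudotrial bookkeeping: degenerate and invalid parameters", {
  sim <- quick_sim(seed = 6, n_pairs = 24, n_ch = 2, srate = 23)
  expect_error(pseudotrial_decode(sim$epochs, k = 25), "exceeds")
  # defaults k = 12 accepted on a full-size condition count
  expect_no_warning(ps <- pseudotrial_decode(sim$epochs, k = 12, n_sets = 2,
                                             seed = 7))
  expect_true(ps$accuracy >= 0 && ps$accuracy <= 1)
  # k = 1, one set: every real trial becomes its own pseudotrial
  p1 <- pseudotrial_decode(sim$epochs, k = 1, n_sets = 1, seed = 8)
  expect_true(p1$accuracy >= 0 && p1$accuracy <= 1)
  expect_length(p1$fold_accuracies, 1)
})

test_that("permutation null on a real effect sits near chance with a significant observation", {
  sim <- quick_sim(seed = 9, n_pairs = 16, n_ch = 8,
                   effect = effect_spec(amplitude_uV = -8),
                   noise = noise_spec(2, 2, 0.5))
  fit <- loto_decode(sim$epochs, n_perm = 100, seed = 10)
  expect_gt(fit$accuracy, 0.8)
  expect_true(fit$significant)
  expect_lt(abs(mean(fit$null_accuracies) - 0.5), 0.1)
  expect_gt(fit$effect_size, 2)
})
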
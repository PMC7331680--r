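test_that("SME is zero for zero-variance data and scales with the data", {
  v <- array(0, c(8, 1, 110))
  v[c(1, 3, 5, 7), , ] <- 2            # congruent all identical
  v[c(2, 4, 6, 8), , ] <- -1           # incongruent all identical
  ep <- epochs_from_array(v, srate = 100)
  dimnames(ep$voltages)[[2]] <- "Cz"
  expect_equal(sme_bootstrap(ep, "Cz", n_boot = 200, seed = 1), 0)

  sim <- quick_sim(seed = 2, n_pairs = 10, n_ch = 2, srate = 100)
  ep2 <- sim$epochs
  s1 <- sme_bootstrap(ep2, channel_names(ep2)[1], n_boot = 500, seed = 3)
  ep3 <- ep2; ep3$voltages <- 2 * ep3$voltages
  s2 <- sme_bootstrap(ep3, channel_names(ep2)[1], n_boot = 500, seed = 3)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)

  # invariant to a condition-constant shift (difference-ERP based)
  ep4 <- ep2
  ep4$voltages[ep4$condition == "congruent", , ] <-
    ep4$voltages[ep4$condition == "congruent", , ] + 11
  s3 <- sme_bootstrap(ep4, channel_names(ep2)[1], n_boot = 500, seed = 3)
  expect_equal(s3, s1, tolerance = 1e-12)
})

test_that("SME matches the analytic two-sample SE for iid window scores", {
  # trials whose window means are iid N(0, sigma^2); constant over time so
  # each trial's window mean equals its score
  set.seed(4)
  sigma <- 3
  v <- array(0, c(80, 1, 110))
  scores <- rnorm(80, 0, sigma)
  for (t in 1:80) v[t, 1, ] <- scores[t]
  ep <- epochs_from_array(v, srate = 100)
  dimnames(ep$voltages)[[2]] <- "Cz"
  # unbalance the accepted counts via the rejection mask
  ep$rejected[seq(2, 80, by = 2)[1:10]] <- TRUE  # nc = 40, ni = 30
  s <- sme_bootstrap(ep, "Cz", n_boot = 10000, seed = 5)
  cg <- scores[seq(1, 79, 2)]
  ig <- scores[seq(2, 80, 2)][-(1:10)]
  analytic <- sigma * sqrt(1 / 40 + 1 / 30)
  plug_in <- sqrt(var(cg) / 40 + var(ig) / 30)
  expect_lt(abs(s - plug_in) / plug_in, 0.05)
  # and the plug-in itself sits near the population value
  expect_lt(abs(plug_in - analytic) / analytic, 0.3)
  expect_error(sme_bootstrap(ep, "nope"), "unknown")
})

test_that("the per-channel SME summary averages over channels", {
  sim <- quick_sim(seed = 6, n_pairs = 8, n_ch = 4, srate = 100)
  r <- sme(sim$epochs, n_boot = 300, seed = 7)
  expect_length(r$per_channel, 4)
  expect_true(all(r$per_channel >= 0))
  expect_equal(r$mean_uV, mean(r$per_channel))
})

test_that("spearman correlation handles monotone data and ties", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(8)
  a <- sample(c(1, 2, 2, 3, 3, 3, 4, 5, 6, 6))
  b <- rnorm(10)
  r <- spearman_cor(a, b)
  expect_equal(r$rho, unname(cor(rank(a), rank(b))))
  expect_error(spearman_cor(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_cor(1:3, 1:4), "equal length")
})

test_that("the subject summary reproduces module decisions and totals", {
  mk <- function(id, dec, tc, uni) {
    list(decoding = structure(list(subject_id = id, significant = dec,
                                   accuracy = 0.6, effect_size = 1,
                                   p_rank = 0.01),
                              class = "loto_decoding"),
         timecourse = structure(list(significant = rep(tc, 3)),
                                class = "tfce_test"),
         univariate = structure(list(significant = uni, area_uVms = 100),
                                class = "n400_test"))
  }
  res <- c(lapply(1:13, function(i) mk(paste0("s", i), TRUE, FALSE, FALSE)),
           lapply(14:20, function(i) mk(paste0("s", i), FALSE, FALSE, TRUE)))
  sm <- summarize_subjects(res)
  expect_equal(nrow(sm$table), 20)
  expect_equal(unname(sm$totals["mvpa"]), 13)
  expect_equal(unname(sm$totals["n400"]), 7)
  out <- capture.output(print(sm))
  expect_true(any(grepl("13/20", out)))
  expect_error(summarize_subjects(list()), "no subject")
  broken <- res
  broken[[3]]$univariate <- NULL
  expect_error(summarize_subjects(broken), "subject 3 .* univariate")
})

test_that("the cohort pipeline runs end-to-end and is seed-deterministic", {
  mz <- small_montage(6)
  coh <- simulate_cohort(3, n_pairs = 10, montage = mz,
                         effect = effect_spec(amplitude_uV = -6),
                         srate = 46, responder_fraction = 2 / 3, seed = 9)
  dir1 <- tempfile(); dir2 <- tempfile()
  subj <- lapply(coh, `[[`, "epochs")
  r1 <- run_pipeline(subj, mz, n_perm = 30, n_boot = 100, n_sim = 100,
                     seed = 10, roi = roi_spec(channels = c("Cz", "CPz")),
                     out_dir = dir1)
  expect_equal(nrow(r1$summary$table), 3)
  expect_true(file.exists(file.path(dir1, "summary.csv")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))

  r2 <- run_pipeline(subj, mz, n_perm = 30, n_boot = 100, n_sim = 100,
                     seed = 10, roi = roi_spec(channels = c("Cz", "CPz")),
                     out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "summary.csv")),
                   readLines(file.path(dir2, "summary.csv")))

  # a directory cohort with a corrupt container aborts naming the culprit
  dir3 <- tempfile(); dir.create(dir3)
  save_epochs(subj[[1]], file.path(dir3, "s1.eeg"))
  writeBin(as.raw(1:32), file.path(dir3, "s2.eeg"))
  expect_error(run_pipeline(dir3, mz, n_perm = 5), "s2.eeg")
})
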
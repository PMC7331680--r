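test_that("ROI ERPs average channels then trials, with SEM across trials", {
  v <- array(3, c(4, 2, 20))
  ep <- epochs_from_array(v, srate = 100)
  dimnames(ep$voltages)[[2]] <- c("Cz", "CPz")
  erp <- roi_erp(ep, roi_spec(channels = c("Cz", "CPz")))
  expect_true(all(erp$mean == 3))
  expect_true(all(erp$sem == 0))

  # two congruent trials at 0 and 2 uV -> mean 1, SEM 1
  v2 <- array(0, c(4, 1, 20))
  v2[1, , ] <- 0; v2[3, , ] <- 2      # congruent trials (pairs interleaved)
  v2[2, , ] <- 5; v2[4, , ] <- 5
  ep2 <- epochs_from_array(v2, srate = 100)
  dimnames(ep2$voltages)[[2]] <- "Cz"
  erp2 <- roi_erp(ep2, roi_spec(channels = "Cz"))
  expect_true(all(erp2$mean[, "congruent"] == 1))
  expect_true(all(erp2$sem[, "congruent"] == 1))

  # rejected trials are excluded, equivalently to manual filtering
  sim <- quick_sim(seed = 1, n_pairs = 6, n_ch = 2)
  ep3 <- sim$epochs
  dimnames(ep3$voltages)[[2]] <- c("Cz", "CPz")
  ep3$rejected[c(1, 4)] <- TRUE
  erp3 <- roi_erp(ep3, roi_spec(channels = c("Cz", "CPz")))
  keep <- !ep3$rejected
  mc <- colMeans(apply(ep3$voltages[keep & ep3$condition == "congruent", , ,
                                    drop = FALSE], c(1, 3), mean))
  expect_equal(unname(erp3$mean[, "congruent"]), unname(mc))
})

test_that("pointwise t-tests: separation, antisymmetry, calibration", {
  set.seed(2)
  n <- 20; Tn <- 400
  cong <- matrix(rnorm(n * Tn), n)
  incong <- matrix(rnorm(n * Tn), n)
  times <- seq_len(Tn)
  # strong separation at one timepoint
  incong[, 100] <- incong[, 100] - 10
  r <- pointwise_t(cong, incong, times, start = 1)
  expect_lt(r$p[100], 1e-6)
  # antisymmetric under condition swap
  r2 <- pointwise_t(incong, cong, times, start = 1)
  expect_equal(r2$t, -r$t)
  # null calibration across timepoints
  null_p <- r$p[-100]
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.03)
  expect_error(pointwise_t(cong[1, , drop = FALSE], incong, times, 1),
               ">= 2")
})

test_that("lag-1 autocorrelation estimates AR(1) structure", {
  set.seed(3)
  n <- 20000
  x <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
  expect_lt(abs(lag1_autocorr(x) - 0.9), 0.05)
  expect_lt(abs(lag1_autocorr(rnorm(10000))), 0.05)
  alt <- rep(c(1, -1), 50)
  expect_lt(abs(lag1_autocorr(alt) - (-1)), 0.02)
  expect_error(lag1_autocorr(rep(1, 10)), "constant")
})

test_that("the cluster-length threshold is calibrated and monotone in phi", {
  expect_equal(gb_cluster_threshold(0, c(10, 10), 50, alpha = 1), 1L)

  # phi = 0 oracle: p < .05 indicators are iid Bernoulli(.05); compare the
  # longest-run distribution from direct Bernoulli simulation at 10x size
  thr <- gb_cluster_threshold(0, c(15, 15), 80, n_sim = 400, seed = 4)
  set.seed(5)
  longest <- vapply(1:4000, function(i) {
    r <- rle(runif(80) < 0.05)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }, integer(1))
  L <- 1L
  while (mean(longest >= L) > 0.05) L <- L + 1L
  expect_lte(abs(thr - L), 1)

  thrs <- vapply(c(0, 0.5, 0.9), function(phi)
    gb_cluster_threshold(phi, c(15, 15), 80, n_sim = 300, seed = 6),
    integer(1))
  expect_true(all(diff(thrs) >= 0))
  expect_error(gb_cluster_threshold(1.2, c(10, 10), 50), "phi")
})

test_that("cluster extraction respects the minimum length", {
  times <- seq(0, 990, by = 10)
  p <- rep(1, 100)
  r0 <- find_clusters(p, times, 5)
  expect_equal(nrow(r0$clusters), 0)
  expect_false(r0$significant)

  p[20:23] <- 0.01                     # length 4 < min_len 5
  expect_equal(nrow(find_clusters(p, times, 5)$clusters), 0)
  p[40:54] <- 0.01                     # length 15 >= 5
  r <- find_clusters(p, times, 5)
  expect_equal(nrow(r$clusters), 1)
  expect_equal(r$clusters$start_ms, times[40])
  expect_equal(r$clusters$end_ms, times[54])
  expect_true(r$significant)
})

test_that("the N400 area integrates the difference trapezoidally", {
  times <- seq(0, 1000, by = 2)
  d <- ifelse(times >= 300 & times <= 800, 1, 0)
  expect_equal(n400_area(d, times, c(300, 800)), 500)
  expect_equal(n400_area(numeric(length(times)), times), 0)
  # triangular bump, base 500 ms, peak 2 uV -> area 500 uV.ms
  tri <- pmax(0, 2 * (1 - abs(times - 550) / 250))
  expect_equal(n400_area(tri, times, c(300, 800)), 500, tolerance = 0.01)
  expect_error(n400_area(d, times, c(300, 2000)), "window")
  # linearity and additivity over subwindows
  expect_equal(n400_area(3 * tri, times, c(300, 800)),
               3 * n400_area(tri, times, c(300, 800)))
  expect_equal(n400_area(tri, times, c(300, 550)) +
                 n400_area(tri, times, c(550, 800)),
               n400_area(tri, times, c(300, 800)))
})

test_that("difference topographies localise the injected effect", {
  sim <- quick_sim(seed = 7, n_pairs = 20, n_ch = 8, srate = 64,
                   effect = effect_spec(amplitude_uV = -6,
                                        topography_center = "Cz",
                                        topography_spread = 0.4),
                   noise = noise_spec(1, 2, 0.5))
  tp <- difference_topomap(sim$epochs)
  expect_equal(dim(tp), c(8, 4))
  # peak window (400-600 contains the 400 ms peak tail); most negative at Cz
  # or an immediate neighbour
  w <- tp[, "200-400"] + tp[, "400-600"]
  best <- rownames(tp)[which.min(w)]
  expect_true(best %in% channel_neighbourhood(small_montage(8), "Cz", 3))

  null <- quick_sim(seed = 8, n_pairs = 20, n_ch = 4, srate = 64)
  tp0 <- difference_topomap(null$epochs)
  expect_lt(max(abs(tp0)), 4)          # noise-level means around zero
})

test_that("the single-subject N400 test flags a real effect and not a null", {
  eff <- quick_sim(seed = 9, n_pairs = 40, n_ch = 8, srate = 64,
                   effect = effect_spec(amplitude_uV = -6,
                                        temporal_width_ms = 120),
                   noise = noise_spec(2, 4, 0.8))
  ep <- baseline_correct(eff$epochs)
  roi <- roi_spec(channels = intersect(channel_names(ep),
                                       c("Cz", "FCz", "CPz", "C3", "C4")))
  r <- n400_test(ep, roi, n_sim = 300, seed = 10)
  expect_true(r$significant)
  expect_gt(r$area_uVms, 0)            # incongruent more negative

  nul <- quick_sim(seed = 11, n_pairs = 40, n_ch = 8, srate = 64)
  r0 <- n400_test(baseline_correct(nul$epochs), roi, n_sim = 300, seed = 12)
  expect_s3_class(r0$clusters, "cluster_result")
})

test_that("the group test equals a one-sample t on difference waveforms", {
  set.seed(13)
  dw <- matrix(rnorm(12 * 100), 12)
  dw[, 40:60] <- dw[, 40:60] + 1.5
  times <- seq(150, by = 2, length.out = 100)
  g <- group_n400_test(dw, times, start = 150, n_sim = 200, seed = 14)
  tt_manual <- apply(dw, 2, function(col) unname(t.test(col)$statistic))
  expect_equal(g$t, tt_manual, tolerance = 1e-10)
  expect_true(g$significant)
})
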
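test_that("mastoid re-referencing subtracts the mastoid mean", {
  # hand-computed 2 scalp channel, 3 sample case
  v <- matrix(c(1, 2, 3,
                4, 5, 6,
                2, 2, 2,
                0, 4, 2), 4, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "M1", "M2"), NULL))
  rec <- continuous_recording(v, 100, data.frame(
    sample = 2, condition = "congruent", pair_id = 1))
  rr <- rereference(rec, c("M1", "M2"))
  expect_equal(rr$voltages["a", ], c(1, 2, 3) - c(1, 3, 2))
  expect_equal(rr$voltages["b", ], c(4, 5, 6) - c(1, 3, 2))
  # mastoid mean is zero afterwards -> idempotent
  expect_equal(colMeans(rr$voltages[c("M1", "M2"), ]), c(0, 0, 0))
  expect_equal(rereference(rr, c("M1", "M2"))$voltages, rr$voltages)

  # zero mastoids leave the data unchanged
  v0 <- v; v0[c("M1", "M2"), ] <- 0
  rec0 <- continuous_recording(v0, 100, rec$events)
  expect_equal(rereference(rec0, c("M1", "M2"))$voltages, v0)
  expect_error(rereference(rec, c("M1", "nope")), "mastoid")
})

test_that("the band-pass keeps the passband and kills DC and 80 Hz", {
  srate <- 512
  t <- seq(0, 10, by = 1 / srate)[-1]
  mk <- function(x) {
    m <- matrix(x, 1, length(x), dimnames = list("Cz", NULL))
    continuous_recording(m, srate, data.frame(
      sample = 5000, condition = "congruent", pair_id = 1))
  }
  # 10 Hz sine passes within 5% (measured away from the edges)
  s10 <- sin(2 * pi * 10 * t)
  out <- bandpass(mk(s10), 0.1, 40)$voltages[1, ]
  mid <- 1000:4000
  expect_gt(max(abs(out[mid])), 0.95)
  expect_lt(max(abs(out[mid])), 1.05)
  # 50 uV DC offset is removed
  dc <- bandpass(mk(rep(50, length(t))), 0.1, 40)$voltages[1, ]
  expect_lt(abs(mean(dc)), 1)
  # 80 Hz (one octave above the 40 Hz edge) is attenuated >= 90%
  s80 <- sin(2 * pi * 80 * t)
  out80 <- bandpass(mk(s80), 0.1, 40)$voltages[1, ]
  expect_lt(max(abs(out80[mid])), 0.1)
  expect_error(bandpass(mk(s10), 40, 0.1), "low < high")
})

test_that("epoching cuts aligned windows out of a ramp", {
  srate <- 100
  v <- matrix(seq_len(500), 1, 500, dimnames = list("Cz", NULL))
  rec <- continuous_recording(v, srate, data.frame(
    sample = c(100, 300), condition = c("congruent", "incongruent"),
    pair_id = c(1, 1)))
  ep <- epoch_recording(rec, c(-100, 1000))
  expect_equal(n_trials(ep), 2)
  expect_length(ep$times, 110)
  # the ramp segment starts 10 samples (100 ms) before each event
  expect_equal(ep$voltages[1, 1, ], seq(90, length.out = 110))
  expect_equal(ep$voltages[2, 1, ], seq(290, length.out = 110))
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  v <- array(7, c(2, 2, 20))
  ep <- epochs_from_array(v, srate = 100)
  bc <- baseline_correct(ep)
  expect_true(all(bc$voltages == 0))

  set.seed(5)
  v2 <- array(rnorm(2 * 2 * 110), c(2, 2, 110))
  ep2 <- baseline_correct(epochs_from_array(v2, srate = 100))
  sel <- ep2$times >= -100 & ep2$times < 0
  expect_lt(max(abs(apply(ep2$voltages[, , sel], c(1, 2), mean))), 1e-6)
  expect_equal(baseline_correct(ep2)$voltages, ep2$voltages)
  expect_error(baseline_correct(ep2, c(-500, -200)), "no samples")
})

test_that("artifact rejection respects its scope and only sets the mask", {
  set.seed(6)
  v <- array(rnorm(4 * 3 * 20), c(4, 3, 20))
  v[1, 3, 5] <- 250                      # trial 1 exceeds on channel 3
  ep <- epochs_from_array(v, srate = 100)
  dimnames(ep$voltages)[[2]] <- c("Cz", "CPz", "F7")

  all_scope <- reject_artifacts(ep, 200)
  expect_identical(which(all_scope$rejected), 1L)
  expect_identical(all_scope$voltages, ep$voltages) # non-destructive

  roi <- reject_artifacts(ep, 200, scope = c("Cz", "CPz"))
  expect_false(any(roi$rejected))        # offender outside the ROI
  expect_error(reject_artifacts(ep, 200, scope = character()), "scope")
  expect_error(reject_artifacts(ep, -1), "threshold")

  # ROI scope never rejects more than the all-channel scope
  for (seed in 1:10) {
    set.seed(seed)
    w <- array(rnorm(6 * 3 * 20, sd = 120), c(6, 3, 20))
    e <- epochs_from_array(w, srate = 100)
    dimnames(e$voltages)[[2]] <- c("Cz", "CPz", "F7")
    n_all <- sum(reject_artifacts(e, 200)$rejected)
    n_roi <- sum(reject_artifacts(e, 200, scope = c("Cz", "CPz"))$rejected)
    expect_lte(n_roi, n_all)
  }
})

test_that("spherical-spline interpolation replaces only over-threshold channels", {
  # interpolation needs a dense montage; use the full 64-channel layout
  m <- default_montage()
  sim <- simulate_subject(n_pairs = 5, montage = m, srate = 46, seed = 7,
                          effect = effect_spec(amplitude_uV = 0))
  ep <- sim$epochs

  # clean data: identity, nothing interpolated
  clean <- reject_artifacts(ep, 200)
  res <- interpolate_bad_channels(clean, m)
  expect_identical(res$interpolated, character())
  expect_identical(res$epochs$voltages, clean$voltages)

  # rail one channel at +500 uV on 20% of trials
  bad <- ep
  bad$voltages[1:2, "Cz", ] <- 500
  bad <- reject_artifacts(bad, 200)
  res2 <- interpolate_bad_channels(bad, m, fraction = 0.10)
  expect_identical(res2$interpolated, "Cz")
  # interpolated values stay within the spatial range of the good channels
  # (spherical splines can overshoot slightly; allow a small margin)
  good <- setdiff(channel_names(ep), "Cz")
  for (tr in c(1, 4)) {
    lo <- apply(bad$voltages[tr, good, ], 2, min)
    hi <- apply(bad$voltages[tr, good, ], 2, max)
    span <- hi - lo
    vi <- res2$epochs$voltages[tr, "Cz", ]
    expect_true(all(vi >= lo - span / 10 & vi <= hi + span / 10))
  }
  expect_error(interpolate_bad_channels(ep, m), "reject_artifacts")
})

test_that("interpolating a channel that already equals its spline prediction is a no-op", {
  m <- small_montage(8)
  sim <- quick_sim(seed = 8, n_pairs = 6, n_ch = 8)
  ep <- sim$epochs
  good <- setdiff(channel_names(ep), "Cz")
  W <- n400mvpa:::.spline_weights(m$positions[good, ],
                                  m$positions["Cz", , drop = FALSE])
  for (tr in seq_len(n_trials(ep)))
    ep$voltages[tr, "Cz", ] <- W %*% ep$voltages[tr, good, ]
  # force Cz to be flagged via a fake exceedance attribution
  flag <- reject_artifacts(ep, 200)
  ex <- attr(flag, "exceed")
  ex[, "Cz"] <- TRUE
  attr(flag, "exceed") <- ex
  res <- interpolate_bad_channels(flag, m)
  expect_identical(res$interpolated, "Cz")
  expect_lt(max(abs(res$epochs$voltages[, "Cz", ] - ep$voltages[, "Cz", ])),
            1e-6)
})

test_that("the continuous pipeline interpolates railed channels and re-filters", {
  m <- small_montage(8)
  sq <- generate_sequence(6, n_candidates = 100, seed = 9)
  cont <- simulate_continuous(sq, montage = m, srate = 64, seed = 10)
  rec <- cont$recording
  # rail one channel inside a fifth of the epochs
  railed <- which(rownames(rec$voltages) == "Pz")
  for (ev in rec$events$sample[seq(1, 12, by = 4)])
    rec$voltages[railed, ev:(ev + 10)] <- 500
  out <- preprocess(rec, m, band = c(0.5, 25), reject_threshold = 200)
  expect_true("Pz" %in% out$interpolated)
  expect_s3_class(out$epochs, "eeg_epochs")
  expect_equal(n_trials(out$epochs), 12)
  # after interpolation and re-filtering nothing rails any more
  expect_lt(max(abs(out$epochs$voltages)), 200)
})
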
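# Preprocessing pipeline: ambient normalization, truncation, padding,
# humidity standardization and class weighting.

test_that("ambient normalization implements x/median(baseline) - 1", {
  m <- matrix(2, 6, 2)
  m[4, 1] <- 3
  out <- ambientNormalize(m, 1:3)
  expect_equal(out[4, 1], 0.5)                 # 3/2 - 1
  expect_equal(out[1, 2], 0)                   # at baseline median -> 0
  # even window: midpoint-median convention, against a sort-based oracle
  w <- matrix(c(1, 3, 2, 2), 4, 1)
  sorted <- sort(w[1:2, 1])
  oracle_med <- (sorted[1] + sorted[2]) / 2
  expect_equal(oracle_med, 2)
  expect_equal(ambientNormalize(w, 1:2)[3, 1], 0)
  # invariance to per-channel multiplicative rescaling (exact)
  set.seed(1)
  r <- matrix(abs(rnorm(40, 5)), 10, 4)
  scaled <- sweep(r, 2, c(2, 10, 0.5, 7), `*`)
  expect_equal(ambientNormalize(scaled, 1:4), ambientNormalize(r, 1:4))
  expect_error(ambientNormalize(matrix(0, 4, 1), 1:2), "channel")
  expect_error(ambientNormalize(r, integer(0)), "nonempty")
})

test_that("truncation keeps recovery terminus + buffer and is a no-op when short", {
  p <- protocolSpec()
  rec <- simulateDataset(p, noise_free_config(), 2, seed = 1)[[1]]
  expect_identical(nrow(response(truncateRecording(rec, buffer_s = 60))), 170L)
  t0 <- truncateRecording(rec, buffer_s = 0)
  expect_identical(nrow(response(t0)), 110L)   # recovery terminus
  expect_identical(length(humidity(t0)), 110L)
  # already shorter than cutoff: unchanged
  expect_identical(response(truncateRecording(t0, buffer_s = 60)),
                   response(t0))
})

test_that("padding appends zero rows with a prefix-true mask", {
  x <- matrix(1, 170, 4)
  c <- rep(0.5, 170)
  same <- padToLength(x, c, 170)
  expect_true(all(same$mask))
  expect_identical(same$x, x)
  pad <- padToLength(x, c, 180)
  expect_identical(sum(pad$mask), pad$valid_len)
  expect_identical(pad$valid_len, 170L)
  expect_equal(pad$x[171:180, ], matrix(0, 10, 4))
  expect_identical(pad$mask[171:180], rep(FALSE, 10))
  expect_error(padToLength(x, c, 100), "truncate")
})

test_that("humidity standardization is the training-fold z-score", {
  st <- normalizationStats(0.5, 0.1)
  expect_equal(standardizeHumidity(rep(0.5, 5), st), rep(0, 5))
  expect_equal(standardizeHumidity(0.7, st), 2.0)
  mask <- c(TRUE, TRUE, FALSE)
  out <- standardizeHumidity(c(0.7, 0.6, 0.9), st, mask)
  expect_equal(out, c(2, 1, 0))                # padded position zeroed
  expect_error(normalizationStats(0.5, 0), "positive")
  # pooled standardized training humidity has mean ~0, variance ~1
  recs <- simulateDataset(protocolSpec(), simConfig(), 60, seed = 3)
  d <- preprocessDataset(recs)
  pooled <- d@c[d@mask]
  expect_lt(abs(mean(pooled)), 1e-8)
  expect_equal(var(pooled), 1, tolerance = 0.01)
})

test_that("class weights follow n/(K*n_c) and error on empty classes", {
  w <- classWeights(rep(1:2, c(112, 56)))
  expect_equal(unname(w), c(0.75, 1.5))
  expect_equal(sum(w[rep(1:2, c(112, 56))]), 168)  # weighted sum = n
  expect_equal(unname(classWeights(rep(1:3, each = 5))), rep(1, 3))
  expect_error(classWeights(rep(1L, 10), n_classes = 2), "no samples")
})

test_that("the pipeline refuses already-normalized input and orders stages", {
  recs <- simulateDataset(protocolSpec(), simConfig(), 6, seed = 5)
  d <- preprocessDataset(recs)
  expect_s4_class(d, "PreprocessedDataset")
  expect_identical(dim(d@x), c(6L, 170L, 32L))
  flagged <- recs[[1]]
  flagged@meta$normalized <- TRUE
  expect_error(preprocessDataset(list(flagged)), "twice")
})

test_that("held-out preprocessing with training stats leaks nothing", {
  train <- simulateDataset(protocolSpec(), simConfig(), 20, seed = 1)
  test <- simulateDataset(protocolSpec(), simConfig(), 10, shift = "range_shift",
                          seed = 2)
  dtr <- preprocessDataset(train)
  st <- normalizationStats(dtr@stats$humidity_mean, dtr@stats$humidity_sd)
  dte <- preprocessDataset(test, stats = st, L_max = dtr@stats$L_max)
  expect_identical(dte@stats$humidity_mean, dtr@stats$humidity_mean)
  # shifted humidity is systematically below the training mean
  expect_lt(mean(dte@c[, 31:60]), 0)
})

test_that("masked positions contribute to no loss or statistic", {
  d <- tiny_dataset(n = 4, pad_last = 3, seed = 2)
  m <- buildModel(tiny_arch(), "cirl", seed = 1)
  z <- encode(m, d@x)
  xh <- decode(m, z$z_task, z$z_conf)
  ch <- predictConfounder(m, z$z_task)
  l0 <- reconstructionLoss(d@x, xh, d@mask)
  c0 <- confounderLoss(d@c, ch, d@mask)
  # perturb reconstructions/predictions only on padded cells
  xh2 <- xh
  xh2[, 10:12, ] <- xh2[, 10:12, ] + 100
  ch2 <- ch
  ch2[, 10:12] <- ch2[, 10:12] - 50
  expect_identical(reconstructionLoss(d@x, xh2, d@mask), l0)
  expect_identical(confounderLoss(d@c, ch2, d@mask), c0)
})
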
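# Synthetic e-nose generator: protocol geometry, kinetics, confounding
# model and dataset-level sampling properties.

test_that("protocol defaults give 170 timesteps and valid phase indices", {
  p <- protocolSpec()
  expect_identical(nTimesteps(p), 170L)
  expect_error(protocolSpec(ambient_s = 0), "positive")
  rec <- simulateDataset(p, noise_free_config(), n = 2, seed = 1)[[1]]
  expect_identical(phases(rec), c(30L, 60L, 110L))
})

test_that("humidity trace follows first-order kinetics toward the level", {
  p <- protocolSpec()
  cfg <- noise_free_config()
  # no forcing: level at ambient gives a constant trace
  flat <- makeHumidityTrace(p, cfg, level = cfg$humidity_ambient)
  expect_equal(flat, rep(cfg$humidity_ambient, 170))
  # monotone approach toward the level during exposure
  tr <- makeHumidityTrace(p, cfg, level = 0.95)
  expect_length(tr, 170)
  exposure <- tr[31:60]
  expect_true(all(diff(exposure) > 0))
  expect_true(all(exposure <= 0.95))
  expect_gt(exposure[30], 0.9)       # approaches the level by end of exposure
  # decay back toward ambient afterwards
  expect_true(all(diff(tr[61:170]) < 0))
  expect_error(makeHumidityTrace(p, simConfig(tau_adsorb = -1), 0.9),
               "positive")
})

test_that("clean responses are flat at baseline and class-dependent at exposure", {
  p <- protocolSpec()
  cfg <- noise_free_config(sensitivity_matrix = matrix(0, 32, 2))
  expect_equal(makeCleanResponse(p, cfg, label = 1),
               matrix(1, 170, 32))
  cfg2 <- noise_free_config()
  r1 <- makeCleanResponse(p, cfg2, label = 1)
  r2 <- makeCleanResponse(p, cfg2, label = 2)
  expect_equal(r1[1:30, ], matrix(1, 30, 32))  # ambient phase flat
  m1 <- colMeans(r1[31:60, , drop = FALSE])
  m2 <- colMeans(r2[31:60, , drop = FALSE])
  expect_gt(max(abs(m1 - m2)), 0.005)          # distinct exposure means
  # noise-free, nonnegative sensitivities: exposure mean >= ambient mean
  expect_true(all(m1 >= colMeans(r1[1:30, , drop = FALSE]) - 1e-12))
  expect_error(makeCleanResponse(p, cfg2, label = 3), "1..n_classes")
})

test_that("confounding model is the stated affine coupling", {
  cfg <- noise_free_config(n_channels = 3, gamma = c(0, 0, 0.4),
                           beta = c(0, 1, 0))
  clean <- matrix(2, 5, 3)
  h <- rep(cfg$humidity_ambient + 0.5, 5)
  out <- applyConfounding(clean, h, cfg)
  expect_equal(out[, 1], rep(2, 5))            # gamma = beta = 0: identity
  expect_equal(out[, 2], rep(2 + 1 * 0.5, 5))  # additive offset
  expect_equal(out[, 3], rep(2 * (1 + 0.4 * 0.5), 5))  # multiplicative gain
  cfg0 <- noise_free_config(n_channels = 3, gamma = rep(0, 3), beta = rep(0, 3))
  expect_identical(applyConfounding(clean, h, cfg0), clean)
  expect_error(applyConfounding(clean[1:3, ], h, cfg), "same length")
})

test_that("datasets honour class priors, correlation and determinism", {
  p <- protocolSpec()
  cfg <- simConfig()
  # ketosis-style imbalance: expected counts ~ (112, 56) at n = 168
  recs <- simulateDataset(p, cfg, n = 168, class_probs = c(2/3, 1/3),
                          seed = 42)
  counts <- table(attr(recs, "sim_meta")$label)
  expect_gt(counts[1], counts[2])
  expect_lt(abs(counts[1] - 112), 20)          # binomial fluctuation
  # rho = 0: label and peak humidity uncorrelated (Monte-Carlo at n = 2000)
  cfg0 <- simConfig(rho = 0)
  meta <- attr(simulateDataset(p, cfg0, n = 2000, seed = 7), "sim_meta")
  expect_lt(abs(cor(meta$label, meta$level)), 0.1)
  # rho = 0.6 induces a clear positive association
  meta6 <- attr(simulateDataset(p, simConfig(rho = 0.6), n = 2000, seed = 7),
                "sim_meta")
  expect_gt(cor(meta6$label, meta6$level), 0.35)
  # byte-identical under identical (config, seed)
  a <- simulateDataset(p, cfg, n = 5, seed = 9)
  b <- simulateDataset(p, cfg, n = 5, seed = 9)
  expect_identical(lapply(a, response), lapply(b, response))
  expect_identical(lapply(a, humidity), lapply(b, humidity))
  expect_error(simulateDataset(p, cfg, n = 1), "at least")
  expect_error(simulateDataset(p, cfg, n = 8, shift = "bogus"))
})

test_that("range shift yields humidity levels disjoint from the training range", {
  p <- protocolSpec()
  cfg <- simConfig()
  tr <- attr(simulateDataset(p, cfg, 50, shift = "none", seed = 1), "sim_meta")
  sh <- attr(simulateDataset(p, cfg, 50, shift = "range_shift", seed = 2),
             "sim_meta")
  expect_true(max(sh$level) < min(tr$level))
  de <- attr(simulateDataset(p, cfg, 2000, shift = "decorrelated", seed = 3),
             "sim_meta")
  expect_lt(abs(cor(de$label, de$level)), 0.1)
})

test_that("confounding strength rises monotonically with the gamma gains", {
  p <- protocolSpec()
  r2 <- vapply(c(0.1, 0.4, 1.2), function(g_scale) {
    cfg <- simConfig(gamma = rep(g_scale, 32), beta = rep(0, 32))
    recs <- simulateDataset(p, cfg, 60, seed = 11)
    meta <- attr(recs, "sim_meta")
    feat <- t(vapply(recs, function(r) colMeans(response(r)[31:60, ]),
                     numeric(32)))
    summary(lm(meta$level ~ feat))$r.squared
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-6))
})
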
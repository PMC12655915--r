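# Evaluation harness: CV geometry, metric oracles, paired comparison,
# probes, ablation fairness and the hyperparameter search.

test_that("the CV plan partitions stratified 60/20/20", {
  labels <- rep(1:2, c(60, 40))
  plan <- makeCVPlan(labels, k = 5, seed = 1)
  tests <- lapply(plan$folds, `[[`, "test")
  # the 5 test folds partition the dataset
  expect_identical(sort(unlist(tests)), seq_along(labels))
  expect_true(all(vapply(seq_len(4), function(i)
    length(intersect(tests[[i]], unlist(tests[(i + 1):5]))) == 0, logical(1))))
  for (f in plan$folds) {
    expect_identical(length(f$test), 20L)
    expect_identical(length(f$val), 20L)
    expect_identical(length(f$train), 60L)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$train, f$test), 0)
    # stratification within one sample of the 60/40 proportions
    expect_lte(abs(sum(labels[f$test] == 1) - 12), 1)
    expect_lte(abs(sum(labels[f$val] == 1) - 12), 1)
  }
  expect_identical(makeCVPlan(labels, seed = 1), makeCVPlan(labels, seed = 1))
  expect_error(makeCVPlan(rep(1:2, c(3, 60)), k = 5), "at least")
})

test_that("classification metrics match a hand-computed confusion matrix", {
  # fixed 20-sample case: class 2 as positive with TP=4, FP=1, FN=1, TN=4
  # on the first 10; remaining 10 split to keep both classes populated
  y <- c(rep(2L, 5), rep(1L, 5), rep(1L, 5), rep(2L, 5))
  pred <- c(rep(2L, 4), 1L, 2L, rep(1L, 4), rep(1L, 5), rep(2L, 5))
  probs <- cbind(1 - (pred == 2), (pred == 2)) * 0.9 + 0.05
  m <- classificationMetrics(y, probs)
  tp <- sum(pred == 2 & y == 2); fp <- sum(pred == 2 & y != 2)
  fn <- sum(pred != 2 & y == 2)
  expect_equal(m$per_class$precision[2], tp / (tp + fp))
  expect_equal(m$per_class$recall[2], tp / (tp + fn))
  expect_equal(m$per_class$f1[2], 2 * 0.9 * 0.9 / (0.9 + 0.9))
  expect_equal(m$macro_f1, mean(m$per_class$f1))
  perfect <- classificationMetrics(y, cbind(y == 1, y == 2) * 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$auc, 1)
  expect_error(classificationMetrics(rep(1L, 5), matrix(0.5, 5, 2)),
               "single class")
})

test_that("AUC of random scores is about one half", {
  set.seed(123)
  n <- 2000
  y <- sample(1:2, n, replace = TRUE)
  p2 <- runif(n)
  m <- classificationMetrics(y, cbind(1 - p2, p2))
  expect_equal(m$auc, 0.5, tolerance = 0.05)
})

test_that("multiclass AUC is the unweighted one-vs-rest mean", {
  set.seed(5)
  n <- 300
  y <- sample(1:3, n, replace = TRUE)
  probs <- matrix(runif(n * 3), n, 3)
  probs <- probs / rowSums(probs)
  m <- classificationMetrics(y, probs)
  byhand <- mean(vapply(1:3, function(k) {
    r <- pROC::roc(factor(as.integer(y == k), levels = c(0, 1)), probs[, k],
                   quiet = TRUE, direction = "<", levels = c("0", "1"))
    as.numeric(pROC::auc(r))
  }, numeric(1)))
  expect_equal(m$auc, byhand)
})

test_that("the paired fold test matches the closed form and guards degeneracy", {
  a <- c(0.2, 0.1, 0.15, 0.25, 0.3)
  b <- rep(0, 5)
  r <- pairedFoldTest(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(r$t, t_oracle)
  expect_equal(r$p_value, 2 * pt(-abs(t_oracle), df = 4))
  expect_false(r$degenerate)
  same <- pairedFoldTest(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  const <- pairedFoldTest(b + 0.1, b)
  expect_true(const$degenerate)
  expect_equal(const$p_value, 0)
  expect_error(pairedFoldTest(a, a[1:3]), "equal length")
  expect_error(pairedFoldTest(1, 2), "at least 2")
})

test_that("probes recover humidity from informative features but not noise", {
  a <- tiny_arch(input_len = 20)
  set.seed(21)
  n <- 80
  level <- runif(n, -1, 1)
  k <- seq(0, 1, length.out = 20)
  cmat <- outer(level, k) + matrix(rnorm(n * 20, sd = 0.02), n, 20)
  mask <- matrix(TRUE, n, 20)
  tr <- 1:60; te <- 61:80
  oracle_z <- cbind(level, level^2, rnorm(n))     # informative features
  noise_z <- matrix(rnorm(n * 3), n, 3)           # independent features
  p_or <- cirl:::train_probe(a, oracle_z[tr, ], cmat[tr, ], mask[tr, ],
                             seed = 1, max_epochs = 600, patience = 60)
  p_no <- cirl:::train_probe(a, noise_z[tr, ], cmat[tr, ], mask[tr, ],
                             seed = 1, max_epochs = 600, patience = 60)
  mse_or <- cirl:::probe_mse(a, p_or, oracle_z[te, ], cmat[te, ], mask[te, ])
  mse_no <- cirl:::probe_mse(a, p_no, noise_z[te, ], cmat[te, ], mask[te, ])
  # positional-mean predictor is the uninformative optimum
  mse_bias <- mean(sweep(cmat[te, ], 2, colMeans(cmat[tr, ]))^2)
  expect_lt(mse_or, 0.1 * mse_no)        # informative features: near-zero MSE
  expect_lt(abs(mse_no - mse_bias), 0.6 * mse_bias)
  expect_gt(mse_no, 3 * mse_or)
})

test_that("probe disentanglement requires a trained split-latent model", {
  d <- tiny_dataset(n = 10)
  m <- buildModel(tiny_arch(), "cirl", seed = 1)
  expect_error(probeDisentanglement(m, d, 1:6, 7:10), "trained")
  m@trained <- TRUE
  r <- probeDisentanglement(m, d, 1:6, 7:10, max_epochs = 3)
  expect_gte(r$mse_from_z_task, 0)
  expect_gte(r$mse_from_z_conf, 0)
  mb <- buildModel(tiny_arch(), "baseline", seed = 1)
  mb@trained <- TRUE
  expect_error(probeDisentanglement(mb, d, 1:6, 7:10), "split latent")
})

test_that("the ablation ladder is fair across variants and reports 3 rows", {
  d <- tiny_dataset(n = 20, seed = 2)
  dt <- tiny_dataset(n = 10, seed = 3)
  ab <- runAblation(d, dt, tiny_arch(),
                    cfg = trainConfig(max_epochs = 2, patience = 5,
                                      batch_size = 8),
                    seeds = c(1, 2))
  expect_identical(nrow(ab$summary), 3L)
  expect_identical(ab$summary$variant, c("baseline", "recon_only", "cirl"))
  expect_identical(nrow(ab$results), 6L)
  # identical seeds imply identical splits across variants (index hash)
  for (s in c(1, 2)) {
    hashes <- ab$results$split_hash[ab$results$seed == s]
    expect_identical(length(unique(hashes)), 1L)
  }
  expect_error(runAblation(d, dt, tiny_arch(), seeds = integer(0)), "seed")
})

test_that("hyperparameter search is seeded, bounded and returns the maximizer", {
  obj <- function(cfg) -(log10(cfg$lr) + 3)^2 - cfg$lambda_conf
  one <- hyperparameterSearch(obj, budget = 1, seed = 3)
  expect_identical(nrow(one$trials), 1L)
  expect_equal(one$best$score, one$trials$score[1])
  r <- hyperparameterSearch(obj, budget = 12, seed = 3)
  expect_true(all(r$trials$lr >= 1e-4 & r$trials$lr <= 1e-2))
  expect_true(all(r$trials$lambda_rec >= 0.5 & r$trials$lambda_rec <= 2))
  expect_true(all(r$trials$lambda_task >= 0.5 & r$trials$lambda_task <= 2))
  expect_true(all(r$trials$lambda_conf >= 0.1 & r$trials$lambda_conf <= 0.5))
  expect_equal(r$best$score, max(r$trials$score))
  r2 <- hyperparameterSearch(obj, budget = 12, seed = 3)
  expect_identical(r$trials, r2$trials)
  expect_error(hyperparameterSearch(obj, budget = 0), "budget")
})
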
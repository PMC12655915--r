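# Training: backward-pass correctness against finite differences, the
# two-optimizer partition, reversal semantics through the encoder, variant
# trajectory equivalence and determinism.

# composite objective as a pure function of parameters (training-mode batch
# norm, dropout disabled) for finite-difference checks
composite_loss_fn <- function(model, x, mask, cmat, y, w, cw, scale = 1) {
  a <- model@arch
  function(params) {
    enc <- cirl:::enc_fwd(params$enc, model@stats$enc, a, x, training = TRUE)
    dec <- cirl:::dec_fwd(params$dec, model@stats$dec, a,
                          cbind(enc$z_task, enc$z_conf), training = TRUE)
    cls <- cirl:::cls_fwd(params$cls, a, enc$z_task, training = FALSE)
    adv <- cirl:::adv_fwd(params$adv, a, enc$z_task)
    totalLoss(w, reconstructionLoss(x, dec$x_hat, mask),
              taskLoss(y, cls$probs, cw),
              confounderLoss(cmat, adv$c_hat, mask))
  }
}

analytic_grads <- function(model, x, mask, cmat, y, w, cw, scale = 1) {
  a <- model@arch
  params <- model@params
  enc <- cirl:::enc_fwd(params$enc, model@stats$enc, a, x, training = TRUE)
  dec <- cirl:::dec_fwd(params$dec, model@stats$dec, a,
                        cbind(enc$z_task, enc$z_conf), training = TRUE)
  cls <- cirl:::cls_fwd(params$cls, a, enc$z_task, training = FALSE)
  adv <- cirl:::adv_fwd(params$adv, a, enc$z_task)
  db <- cirl:::dec_bwd(params$dec, a, dec$cache,
                       cirl:::reconstruction_loss_grad(x, dec$x_hat, mask) *
                         w$lambda_rec)
  dz_task <- db$dz[, seq_len(a$z_task_dim), drop = FALSE]
  dz_conf <- db$dz[, a$z_task_dim + seq_len(a$z_conf_dim), drop = FALSE]
  cb <- cirl:::cls_bwd(params$cls, cls$cache,
                       cirl:::task_loss_grad_logits(y, cls$probs, cw) *
                         w$lambda_task)
  ab <- cirl:::adv_bwd(params$adv, a, adv$cache,
                       cirl:::confounder_loss_grad(cmat, adv$c_hat, mask))
  dz_task <- dz_task + cb$dz + gradReverseGrad(ab$dz * w$lambda_conf, scale)
  eb <- cirl:::enc_bwd(params$enc, a, enc$cache, dz_task = dz_task,
                       dz_conf = dz_conf)
  # in L_total the adversary's parameters carry weight -lambda_conf
  adv_g <- rapply(ab$grads, function(g) -w$lambda_conf * g, how = "replace")
  list(enc = eb$grads, dec = db$grads, cls = cb$grads, adv = adv_g,
       dz_conf_branch = ab$dz)
}

test_that("backward pass matches finite differences across all modules", {
  set.seed(101)
  a <- tiny_arch(input_len = 8, encoder_filters = c(3, 2, 2),
                 classifier_units = c(3, 2), conf_predictor_units = c(3, 4),
                 adv_channels = 2, input_channels = 2)
  B <- 2
  x <- array(rnorm(B * 8 * 2), c(B, 8, 2))
  mask <- matrix(TRUE, B, 8); mask[2, 7:8] <- FALSE
  x[2, 7:8, ] <- 0
  cmat <- matrix(rnorm(B * 8), B, 8); cmat[2, 7:8] <- 0
  y <- c(1L, 2L)
  w <- lossWeights()
  cw <- c(1, 1)
  model <- buildModel(a, "cirl", seed = 11)
  fn <- composite_loss_fn(model, x, mask, cmat, y, w, cw)
  ag <- analytic_grads(model, x, mask, cmat, y, w, cw)
  eps <- 1e-5
  for (mod in names(model@params)) {
    for (layer in names(model@params[[mod]])) {
      for (pn in names(model@params[[mod]][[layer]])) {
        arr <- model@params[[mod]][[layer]][[pn]]
        ng <- arr
        for (i in seq_along(arr)) {
          pp <- model@params; pp[[mod]][[layer]][[pn]][i] <- arr[i] + eps
          pm <- model@params; pm[[mod]][[layer]][[pn]][i] <- arr[i] - eps
          ng[i] <- (fn(pp) - fn(pm)) / (2 * eps)
        }
        expect_lt(max(abs(ng - ag[[mod]][[layer]][[pn]])),
                  1e-6 + 1e-4 * max(abs(ng)))
      }
    }
  }
})

test_that("reversal through the encoder negates and scales the adversarial gradient", {
  set.seed(101)
  a <- tiny_arch()
  model <- buildModel(a, "cirl", seed = 7)
  x <- array(rnorm(3 * 12 * 3), c(3, 12, 3))
  mask <- matrix(TRUE, 3, 12)
  cmat <- matrix(rnorm(36), 3, 12)
  enc <- cirl:::enc_fwd(model@params$enc, model@stats$enc, a, x, TRUE)
  adv <- cirl:::adv_fwd(model@params$adv, a, enc$z_task)
  ab <- cirl:::adv_bwd(model@params$adv, a, adv$cache,
                       cirl:::confounder_loss_grad(cmat, adv$c_hat, mask))
  enc_grad <- function(dz_task) {
    cirl:::enc_bwd(model@params$enc, a, enc$cache, dz_task = dz_task,
                   dz_conf = matrix(0, 3, a$z_conf_dim))$grads
  }
  plain <- enc_grad(ab$dz)
  reversed <- enc_grad(gradReverseGrad(ab$dz, 1))
  half <- enc_grad(gradReverseGrad(ab$dz, 0.5))
  zero <- enc_grad(gradReverseGrad(ab$dz, 0))
  for (layer in names(plain)) {
    for (pn in names(plain[[layer]])) {
      expect_equal(reversed[[layer]][[pn]], -plain[[layer]][[pn]])
      expect_equal(half[[layer]][[pn]], -0.5 * plain[[layer]][[pn]])
      expect_equal(max(abs(zero[[layer]][[pn]])), 0)
    }
  }
})

test_that("the two optimizers update disjoint parameter partitions", {
  d <- tiny_dataset(n = 12, seed = 3)
  m0 <- buildModel(tiny_arch(), "cirl", seed = 5)
  fit <- trainModel(m0, d, list(train = 1:8, val = 9:12),
                    cfg = trainConfig(max_epochs = 2, patience = 5,
                                      batch_size = 4, seed = 1))
  # all four modules changed overall ...
  expect_false(identical(fit$model@params$adv, m0@params$adv))
  expect_false(identical(fit$model@params$enc, m0@params$enc))
  # ... and with a frozen main player (weights 0) only the adversary moves
  w0 <- lossWeights(0, 0, 0)
  fit0 <- trainModel(buildModel(tiny_arch(), "cirl", seed = 5), d,
                     list(train = 1:8, val = 9:12), weights = w0,
                     cfg = trainConfig(max_epochs = 2, patience = 5,
                                       batch_size = 4, seed = 1))
  expect_false(identical(fit0$model@params$adv, m0@params$adv))
  expect_equal(fit0$model@params$enc, m0@params$enc, tolerance = 1e-12)
  expect_equal(fit0$model@params$dec, m0@params$dec, tolerance = 1e-12)
  expect_equal(fit0$model@params$cls, m0@params$cls, tolerance = 1e-12)
})

test_that("zero reversal scale and zero adversarial weight reproduce recon_only", {
  d <- tiny_dataset(n = 16, seed = 6)
  splits <- list(train = 1:12, val = 13:16)
  cfg0 <- trainConfig(max_epochs = 3, patience = 5, batch_size = 4,
                      reverse_scale = 0, seed = 2)
  w0 <- lossWeights(1, 1.5, 0)
  a <- tiny_arch()
  fit_cirl <- trainModel(buildModel(a, "cirl", seed = 9), d, splits, w0, cfg0)
  fit_rec <- trainModel(buildModel(a, "recon_only", seed = 9), d, splits,
                        lossWeights(1, 1.5, 0.3), cfg0)
  expect_equal(fit_cirl$model@params, fit_rec$model@params, tolerance = 1e-12)
  expect_equal(fit_cirl$history$train_l_total, fit_rec$history$train_l_total,
               tolerance = 1e-12)
})

test_that("training histories are deterministic and satisfy the loss identity", {
  d <- tiny_dataset(n = 16, seed = 8)
  splits <- list(train = 1:12, val = 13:16)
  cfg <- trainConfig(max_epochs = 3, patience = 5, batch_size = 4, seed = 4)
  w <- lossWeights()
  h1 <- trainModel(buildModel(tiny_arch(), "cirl", seed = 1), d, splits, w, cfg)$history
  h2 <- trainModel(buildModel(tiny_arch(), "cirl", seed = 1), d, splits, w, cfg)$history
  expect_identical(h1, h2)
  expect_equal(h1$val_l_total,
               h1$lambda_rec * h1$val_l_rec + h1$lambda_task * h1$val_l_task -
                 h1$lambda_conf * h1$val_l_conf,
               tolerance = 1e-12)
  expect_true(all(is.finite(as.matrix(h1[sapply(h1, is.numeric)]))))
})

test_that("class weighting equals minority duplication in expected loss", {
  # fixed batch: duplicating every minority sample with unit weights gives
  # the same total loss as weighting, up to the batch-mean normalization
  probs <- matrix(c(0.8, 0.2,
                    0.3, 0.7,
                    0.6, 0.4), 3, 2, byrow = TRUE)
  y <- c(1L, 2L, 1L)                      # class 2 is the minority (1 of 3)
  w <- classWeights(y, 2)                 # (0.75, 1.5)
  dup_probs <- probs[c(1, 2, 2, 3), ]
  dup_y <- c(1L, 2L, 2L, 1L)
  # inverse-frequency weighting gives exactly the duplicated-batch mean loss
  expect_equal(taskLoss(y, probs, w), taskLoss(dup_y, dup_probs, NULL))
})

test_that("adaptive-lambda training keeps weights inside the search ranges", {
  d <- tiny_dataset(n = 12, seed = 10)
  cfg <- trainConfig(max_epochs = 2, patience = 5, batch_size = 4,
                     adaptive_lambda = TRUE, seed = 3)
  fit <- trainModel(buildModel(tiny_arch(), "cirl", seed = 2), d,
                    list(train = 1:8, val = 9:12), lossWeights(), cfg)
  h <- fit$history
  expect_true(all(h$lambda_rec >= 0.5 & h$lambda_rec <= 2))
  expect_true(all(h$lambda_task >= 0.5 & h$lambda_task <= 2))
  expect_true(all(h$lambda_conf >= 0.1 & h$lambda_conf <= 0.5))
})
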
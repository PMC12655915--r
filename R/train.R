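# Two-optimizer adversarial training.
#
# Per batch, the main optimizer updates encoder, decoder and classifier on
# the composite objective; the adversarial confounder branch contributes
# its gradient to the encoder through the gradient-reversal connector,
# realizing the minus sign of the objective. A second optimizer then
# updates only the confounder predictor to minimize the (un-reversed)
# confounder loss on the same batch latents. The two parameter sets are
# strictly disjoint: neither optimizer ever touches the other's parameters.

#' Training configuration
#'
#' @param lr_main learning rate of the main optimizer (encoder, decoder,
#'   classifier); the tuned values are 3e-4 for the disentangled model and
#'   1e-3 for the baseline.
#' @param lr_adversary learning rate of the confounder predictor's own
#'   optimizer.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience on validation macro-F1.
#' @param reverse_scale gradient-reversal strength (0 disables the
#'   adversarial signal; no annealing schedule by default).
#' @param adaptive_lambda logical; when TRUE, loss weights are re-derived
#'   once per epoch from the last batch's encoder gradient norms (see
#'   [adaptiveLambda()]).
#' @param seed RNG seed controlling batch shuffling and dropout.
#' @return A \code{TrainConfig} record.
#' @export
trainConfig <- function(lr_main = 3e-4, lr_adversary = 1e-3,
                        batch_size = 32, max_epochs = 200, patience = 20,
                        reverse_scale = 1, adaptive_lambda = FALSE,
                        seed = 1L) {
  if (lr_main < 1e-4 || lr_main > 1e-2)
    stop("lr_main must lie within the search range [1e-4, 1e-2]")
  if (lr_adversary <= 0) stop("lr_adversary must be positive")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (reverse_scale < 0) stop("reverse_scale must be nonnegative")
  structure(list(lr_main = lr_main, lr_adversary = lr_adversary,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, reverse_scale = reverse_scale,
                 adaptive_lambda = adaptive_lambda, seed = as.integer(seed)),
            class = "TrainConfig")
}

macro_f1 <- function(y, pred, n_classes) {
  f1 <- vapply(seq_len(n_classes), function(k) {
    tp <- sum(pred == k & y == k)
    fp <- sum(pred == k & y != k)
    fn <- sum(pred != k & y == k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

check_finite <- function(value, component, epoch) {
  if (!is.finite(value))
    stop(sprintf("training diverged: non-finite %s loss at epoch %d",
                 component, epoch))
  value
}

# losses + val F1 + adversary MSE in inference mode
eval_split <- function(params, stats, a, variant, data, idx, weights,
                       class_weight) {
  x <- data@x[idx, , , drop = FALSE]
  mask <- data@mask[idx, , drop = FALSE]
  y <- data@y[idx]
  enc <- enc_fwd(params$enc, stats$enc, a, x, training = FALSE)
  if (variant == "baseline") {
    probs <- cls_fwd(params$cls, a, enc$z, training = FALSE)$probs
    l_task <- taskLoss(y, probs, class_weight)
    l_rec <- 0; l_conf <- 0; adv_mse <- NA_real_
  } else {
    xh <- dec_fwd(params$dec, stats$dec, a, cbind(enc$z_task, enc$z_conf),
                  training = FALSE)$x_hat
    probs <- cls_fwd(params$cls, a, enc$z_task, training = FALSE)$probs
    ch <- adv_fwd(params$adv, a, enc$z_task)$c_hat
    l_rec <- reconstructionLoss(x, xh, mask)
    l_task <- taskLoss(y, probs, class_weight)
    l_conf <- confounderLoss(data@c[idx, , drop = FALSE], ch, mask)
    adv_mse <- l_conf
  }
  list(l_rec = l_rec, l_task = l_task, l_conf = l_conf,
       l_total = totalLoss(weights, l_rec, l_task, l_conf),
       f1 = macro_f1(y, max.col(probs, ties.method = "first"), a$n_classes),
       adv_mse = adv_mse)
}

#' Train a model
#'
#' Runs the two-player optimization: the encoder, decoder and classifier
#' minimize the composite objective (in which the confounder loss enters
#' negatively through the gradient-reversal connector), while a separate
#' optimizer trains the confounder predictor to minimize its own loss.
#' Early stopping monitors validation macro-F1; the best-validation
#' parameters are returned. Fully deterministic given the seed.
#'
#' Variants: \code{"baseline"} trains encoder + classifier on the weighted
#' task loss only; \code{"recon_only"} trains the full autoencoder and
#' classifier with the adversarial term excluded from the objective
#' (\code{lambda_conf} forced to 0, no reversal signal into the encoder)
#' while the confounder predictor still fits its own head.
#'
#' @param model an untrained [CirlModel-class] from [buildModel()].
#' @param data a [PreprocessedDataset-class].
#' @param splits list with integer index vectors \code{train} and
#'   \code{val}.
#' @param weights a [lossWeights()] record.
#' @param cfg a [trainConfig()] record.
#' @return List with \code{model} (trained [CirlModel-class], best
#'   validation epoch) and \code{history} (one row per epoch: train and
#'   validation loss components, validation macro-F1, validation adversary
#'   MSE from the task latent, and the loss weights in force).
#' @export
trainModel <- function(model, data, splits, weights = lossWeights(),
                       cfg = trainConfig()) {
  a <- model@arch
  variant <- model@variant
  if (variant %in% c("recon_only", "baseline"))
    weights <- lossWeights(weights$lambda_rec, weights$lambda_task, 0)
  params <- model@params
  stats <- model@stats
  class_weight <- classWeights(data@y[splits$train], a$n_classes)
  main_names <- setdiff(names(params), "adv")
  opt_main <- adam_init(params[main_names])
  opt_adv <- if (!is.null(params$adv)) adam_init(params["adv"]) else NULL
  set.seed(cfg$seed)
  history <- list()
  best <- list(f1 = -Inf, params = params, stats = stats, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    order <- sample(splits$train)
    batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
    tr <- c(l_rec = 0, l_task = 0, l_conf = 0)
    n_seen <- 0
    last_enc_cache <- NULL
    for (b in batches) {
      x <- data@x[b, , , drop = FALSE]
      mask <- data@mask[b, , drop = FALSE]
      y <- data@y[b]
      enc <- enc_fwd(params$enc, stats$enc, a, x, training = TRUE)
      stats$enc <- enc$stats
      if (variant == "baseline") {
        cls <- cls_fwd(params$cls, a, enc$z, training = TRUE)
        l_task <- check_finite(taskLoss(y, cls$probs, class_weight),
                               "task", epoch)
        dlogits <- task_loss_grad_logits(y, cls$probs, class_weight) *
          weights$lambda_task
        cb <- cls_bwd(params$cls, cls$cache, dlogits)
        eb <- enc_bwd(params$enc, a, enc$cache, dz = cb$dz)
        grads <- list(enc = eb$grads, cls = cb$grads)
        st <- adam_step(params[main_names], grads, opt_main, cfg$lr_main)
        params[main_names] <- st$params
        opt_main <- st$state
        tr <- tr + length(b) * c(0, l_task, 0)
        n_seen <- n_seen + length(b)
        next
      }
      z <- cbind(enc$z_task, enc$z_conf)
      dec <- dec_fwd(params$dec, stats$dec, a, z, training = TRUE)
      stats$dec <- dec$stats
      cls <- cls_fwd(params$cls, a, enc$z_task, training = TRUE)
      adv <- adv_fwd(params$adv, a, enc$z_task)
      cb_target <- data@c[b, , drop = FALSE]
      l_rec <- check_finite(reconstructionLoss(x, dec$x_hat, mask),
                            "reconstruction", epoch)
      l_task <- check_finite(taskLoss(y, cls$probs, class_weight),
                             "task", epoch)
      l_conf <- check_finite(confounderLoss(cb_target, adv$c_hat, mask),
                             "confounder", epoch)

      # main player: backprop the composite objective
      db <- dec_bwd(params$dec, a, dec$cache,
                    reconstruction_loss_grad(x, dec$x_hat, mask) *
                      weights$lambda_rec)
      dz_task <- db$dz[, seq_len(a$z_task_dim), drop = FALSE]
      dz_conf <- db$dz[, a$z_task_dim + seq_len(a$z_conf_dim), drop = FALSE]
      cb <- cls_bwd(params$cls, cls$cache,
                    task_loss_grad_logits(y, cls$probs, class_weight) *
                      weights$lambda_task)
      dz_task <- dz_task + cb$dz
      ab <- adv_bwd(params$adv, a, adv$cache,
                    confounder_loss_grad(cb_target, adv$c_hat, mask))
      if (variant == "cirl" && weights$lambda_conf > 0 && cfg$reverse_scale > 0)
        dz_task <- dz_task +
          gradReverseGrad(ab$dz * weights$lambda_conf, cfg$reverse_scale)
      eb <- enc_bwd(params$enc, a, enc$cache,
                    dz_task = dz_task, dz_conf = dz_conf)
      grads <- list(enc = eb$grads, dec = db$grads, cls = cb$grads)
      st <- adam_step(params[main_names], grads, opt_main, cfg$lr_main)
      params[main_names] <- st$params
      opt_main <- st$state

      # adversary player: minimize the confounder loss, own parameters only
      st_adv <- adam_step(params["adv"], list(adv = ab$grads), opt_adv,
                          cfg$lr_adversary)
      params["adv"] <- st_adv$params
      opt_adv <- st_adv$state

      tr <- tr + length(b) * c(l_rec, l_task, l_conf)
      n_seen <- n_seen + length(b)
      last_enc_cache <- list(enc = enc, dec = dec, cls = cls, adv = ab,
                             x = x, mask = mask, y = y, c = cb_target)
    }
    tr <- tr / n_seen

    if (cfg$adaptive_lambda && variant == "cirl" &&
        !is.null(last_enc_cache)) {
      weights <- update_lambda_from_batch(params, a, last_enc_cache,
                                          weights, cfg, class_weight)
    }

    val <- eval_split(params, stats, a, variant, data, splits$val, weights,
                      class_weight)
    history[[epoch]] <- data.frame(
      epoch = epoch,
      train_l_rec = tr[1], train_l_task = tr[2], train_l_conf = tr[3],
      train_l_total = totalLoss(weights, tr[1], tr[2], tr[3]),
      val_l_rec = val$l_rec, val_l_task = val$l_task,
      val_l_conf = val$l_conf, val_l_total = val$l_total,
      val_macro_f1 = val$f1, val_adv_mse = val$adv_mse,
      lambda_rec = weights$lambda_rec, lambda_task = weights$lambda_task,
      lambda_conf = weights$lambda_conf)
    # ties keep the most recent parameters: among equal-validation epochs
    # the later one has had more adversarial refinement, and in-distribution
    # validation F1 cannot see invariance (the shortcut still works there)
    if (val$f1 >= best$f1) {
      best <- list(f1 = val$f1, params = params, stats = stats,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  out <- model
  out@params <- best$params
  out@stats <- best$stats
  out@trained <- TRUE
  list(model = out, history = do.call(rbind, history),
       best_epoch = best$epoch)
}

# re-derive loss weights from per-component encoder gradient norms on the
# last batch of the epoch (forward passes recomputed with updated params)
update_lambda_from_batch <- function(params, a, lb, weights, cfg,
                                     class_weight) {
  enc <- lb$enc
  norm_of <- function(dz_task = NULL, dz_conf = NULL) {
    zt <- if (is.null(dz_task)) matrix(0, nrow(lb$x), a$z_task_dim) else dz_task
    zc <- if (is.null(dz_conf)) matrix(0, nrow(lb$x), a$z_conf_dim) else dz_conf
    grads_norm(enc_bwd(params$enc, a, enc$cache,
                       dz_task = zt, dz_conf = zc)$grads)
  }
  db <- dec_bwd(params$dec, a, lb$dec$cache,
                reconstruction_loss_grad(lb$x, lb$dec$x_hat, lb$mask))
  g_rec <- norm_of(db$dz[, seq_len(a$z_task_dim), drop = FALSE],
                   db$dz[, a$z_task_dim + seq_len(a$z_conf_dim), drop = FALSE])
  cb <- cls_bwd(params$cls, lb$cls$cache,
                task_loss_grad_logits(lb$y, lb$cls$probs, class_weight))
  g_task <- norm_of(dz_task = cb$dz)
  g_conf <- norm_of(dz_task = gradReverseGrad(lb$adv$dz, cfg$reverse_scale))
  dz_total_t <- db$dz[, seq_len(a$z_task_dim), drop = FALSE] *
    weights$lambda_rec + cb$dz * weights$lambda_task +
    gradReverseGrad(lb$adv$dz * weights$lambda_conf, cfg$reverse_scale)
  dz_total_c <- db$dz[, a$z_task_dim + seq_len(a$z_conf_dim), drop = FALSE] *
    weights$lambda_rec
  g_total <- norm_of(dz_total_t, dz_total_c)
  adaptiveLambda(list(rec = g_rec, task = g_task, conf = g_conf,
                      total = g_total), weights)
}
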
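# Evaluation protocol: stratified 5-fold cross-validation with nested
# train/validation splits, classification metrics, probe-based
# disentanglement measurement, fold-level paired comparison, the ablation
# ladder and a bounded hyperparameter search.

#' Stratified k-fold cross-validation plan
#'
#' The k test folds are a stratified partition of the data (20% each at
#' k = 5); within each fold the remaining 80% is split, again stratified,
#' 75/25 into train and validation, yielding the 60/20/20 geometry.
#' Per-class proportions are preserved within one sample.
#'
#' @param labels integer class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return A \code{CVPlan}: list with \code{k}, \code{seed} and
#'   \code{folds}, each fold holding disjoint \code{train}, \code{val} and
#'   \code{test} index vectors.
#' @export
makeCVPlan <- function(labels, k = 5, seed = 1L) {
  counts <- table(labels)
  if (any(counts < k))
    stop(sprintf("every class needs at least k=%d samples (smallest has %d)",
                 k, min(counts)))
  set.seed(seed)
  classes <- sort(unique(labels))
  test_folds <- vector("list", k)
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    fold_of <- rep_len(seq_len(k), length(idx))   # round-robin: sizes +/- 1
    for (j in seq_len(k))
      test_folds[[j]] <- c(test_folds[[j]], idx[fold_of == j])
  }
  folds <- lapply(seq_len(k), function(j) {
    test <- sort(test_folds[[j]])
    rest <- setdiff(seq_along(labels), test)
    val <- integer(0)
    for (cl in classes) {
      ridx <- sample(rest[labels[rest] == cl])
      val <- c(val, ridx[seq_len(round(length(ridx) / 4))])
    }
    val <- sort(val)
    list(train = sort(setdiff(rest, val)), val = val, test = test)
  })
  structure(list(k = k, seed = seed, folds = folds), class = "CVPlan")
}

#' Classification metrics report
#'
#' Per-class precision, recall and F1 from argmax predictions, their macro
#' (unweighted) averages, and AUROC: binary AUROC for two classes, the
#' unweighted one-vs-rest mean for more. A class absent from both truth
#' and predictions scores 0 with a warning.
#'
#' @param y_true integer labels in \code{1..n_classes}.
#' @param y_probs n x n_classes probability matrix.
#' @return A \code{MetricsReport}: list with \code{per_class} (data.frame),
#'   \code{macro_f1}, \code{macro_precision}, \code{macro_recall},
#'   \code{auc}.
#' @export
classificationMetrics <- function(y_true, y_probs) {
  n_classes <- ncol(y_probs)
  if (length(unique(y_true)) < 2)
    stop("AUC undefined: y_true contains a single class")
  pred <- max.col(y_probs, ties.method = "first")
  per <- lapply(seq_len(n_classes), function(k) {
    tp <- sum(pred == k & y_true == k)
    fp <- sum(pred == k & y_true != k)
    fn <- sum(pred != k & y_true == k)
    if (tp + fp + fn == 0)
      warning(sprintf("class %d absent from truth and predictions; metrics set to 0", k))
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = k, precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  auc_one <- function(k) {
    resp <- factor(as.integer(y_true == k), levels = c(0, 1))
    as.numeric(pROC::auc(pROC::roc(resp, y_probs[, k], quiet = TRUE,
                                   direction = "<", levels = c("0", "1"))))
  }
  auc <- if (n_classes == 2) auc_one(2)
         else mean(vapply(seq_len(n_classes), auc_one, numeric(1)))
  structure(list(per_class = per,
                 macro_f1 = mean(per$f1),
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 auc = auc),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport: macro F1 %.3f | precision %.3f | recall %.3f | AUC %.3f\n",
              x$macro_f1, x$macro_precision, x$macro_recall, x$auc))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Paired fold-level comparison
#'
#' Two-sided paired t-test on per-fold metric differences. Degenerate
#' zero-variance differences are handled explicitly: p = 1 when the mean
#' difference is 0 (identical vectors), p = 0 when a constant nonzero
#' difference makes the direction certain.
#'
#' @param metric_a,metric_b per-fold metric values, paired by fold.
#' @return List with \code{t}, \code{p_value}, \code{mean_diff},
#'   \code{df}, and \code{degenerate} (TRUE when the zero-variance branch
#'   fired).
#' @export
pairedFoldTest <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stop("fold vectors must have equal length")
  if (length(metric_a) < 2) stop("need at least 2 folds")
  d <- metric_a - metric_b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p_value = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), df = length(d) - 1L,
                degenerate = TRUE))
  }
  tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(d), df = unname(tt$parameter), degenerate = FALSE)
}

## ---- probe-based disentanglement ---------------------------------------

# train a fresh humidity-regression probe (confounder-predictor
# architecture, no gradient reversal) on frozen latents
train_probe <- function(a, z_train, c_train, mask_train, seed,
                        max_epochs = 100, patience = 10, lr = 1e-3,
                        batch_size = 32) {
  set.seed(seed)
  params <- init_adversary(a, ncol(z_train))
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params)
  wait <- 0L
  n <- nrow(z_train)
  for (epoch in seq_len(max_epochs)) {
    order <- sample(n)
    batches <- split(order, ceiling(seq_along(order) / batch_size))
    tot <- 0
    for (b in batches) {
      fw <- adv_fwd(params, a, z_train[b, , drop = FALSE])
      l <- confounderLoss(c_train[b, , drop = FALSE], fw$c_hat,
                          mask_train[b, , drop = FALSE])
      bw <- adv_bwd(params, a, fw$cache,
                    confounder_loss_grad(c_train[b, , drop = FALSE],
                                         fw$c_hat,
                                         mask_train[b, , drop = FALSE]))
      st <- adam_step(params, bw$grads, opt, lr)
      params <- st$params
      opt <- st$state
      tot <- tot + l * length(b)
    }
    tot <- tot / n
    if (tot < best$loss - 1e-6) {
      best <- list(loss = tot, params = params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best$params
}

probe_mse <- function(a, probe_params, z, c_target, mask) {
  confounderLoss(c_target, adv_fwd(probe_params, a, z)$c_hat, mask)
}

#' Probe-based disentanglement measurement
#'
#' Freezes the trained encoder, trains two fresh probe regressors (the
#' confounder-predictor architecture, without gradient reversal) — one from
#' the task latent, one from the confounder latent — to reconstruct the
#' standardized humidity trace on the training split, and reports each
#' probe's masked MSE on the test split. A large task-latent MSE together
#' with a small confounder-latent MSE indicates successful disentanglement.
#'
#' @param model a trained split-latent [CirlModel-class].
#' @param data a [PreprocessedDataset-class] (standardized with
#'   training-fold statistics).
#' @param train_idx,test_idx probe train and evaluation indices.
#' @param probe_seed RNG seed for probe initialization and batching.
#' @param max_epochs,patience probe training budget.
#' @return A \code{DisentanglementReport}: list with
#'   \code{mse_from_z_task}, \code{mse_from_z_conf} and probe details.
#' @export
probeDisentanglement <- function(model, data, train_idx, test_idx,
                                 probe_seed = 1L, max_epochs = 100,
                                 patience = 10) {
  if (!model@trained) stop("model must be trained before probing")
  if (model@variant == "baseline")
    stop("the baseline has no split latent to probe")
  a <- model@arch
  ztr <- encode(model, data@x[train_idx, , , drop = FALSE])
  zte <- encode(model, data@x[test_idx, , , drop = FALSE])
  ctr <- data@c[train_idx, , drop = FALSE]
  cte <- data@c[test_idx, , drop = FALSE]
  mtr <- data@mask[train_idx, , drop = FALSE]
  mte <- data@mask[test_idx, , drop = FALSE]
  p_task <- train_probe(a, ztr$z_task, ctr, mtr, probe_seed,
                        max_epochs, patience)
  p_conf <- train_probe(a, ztr$z_conf, ctr, mtr, probe_seed + 1L,
                        max_epochs, patience)
  structure(list(mse_from_z_task = probe_mse(a, p_task, zte$z_task, cte, mte),
                 mse_from_z_conf = probe_mse(a, p_conf, zte$z_conf, cte, mte),
                 probe = list(seed = probe_seed, max_epochs = max_epochs,
                              patience = patience)),
            class = "DisentanglementReport")
}

#' @export
print.DisentanglementReport <- function(x, ...) {
  cat(sprintf("DisentanglementReport: humidity MSE %.3f from z_task vs %.3f from z_conf\n",
              x$mse_from_z_task, x$mse_from_z_conf))
  invisible(x)
}

## ---- ablation ladder ----------------------------------------------------

# stratified train/val split of a sample pool (75/25 by default)
stratified_split <- function(labels, idx, val_frac = 0.25, seed = 1L) {
  set.seed(seed)
  val <- integer(0)
  for (cl in sort(unique(labels[idx]))) {
    cidx <- sample(idx[labels[idx] == cl])
    val <- c(val, cidx[seq_len(round(length(cidx) * val_frac))])
  }
  list(train = sort(setdiff(idx, val)), val = sort(val))
}

#' Ablation ladder over model variants
#'
#' Trains the three variants — single-latent baseline, disentangled
#' autoencoder without adversary, and the full adversarial model — under
#' identical splits and seeds, and reports test macro-F1 per variant and
#' seed. The fairness contract (identical split per seed across variants)
#' is enforced by construction.
#'
#' @param train_data pool [PreprocessedDataset-class] used for training and
#'   validation.
#' @param test_data held-out [PreprocessedDataset-class] (e.g. the
#'   humidity-range-shifted split).
#' @param arch an [architectureSpec()].
#' @param weights a [lossWeights()] record.
#' @param cfg a [trainConfig()] record; \code{lr_main} applies to the split
#'   variants and \code{lr_baseline} to the baseline.
#' @param seeds integer vector of training seeds (one run per seed and
#'   variant).
#' @param lr_baseline learning rate for the baseline variant.
#' @param variants variants to run.
#' @return List with \code{results} (data.frame: variant, seed, macro F1,
#'   AUC), \code{summary} (per-variant median and IQR) and \code{runs}
#'   (the trained models' histories).
#' @export
runAblation <- function(train_data, test_data, arch,
                        weights = lossWeights(), cfg = trainConfig(),
                        seeds = 1:5, lr_baseline = 1e-3,
                        variants = c("baseline", "recon_only", "cirl")) {
  if (length(seeds) < 1) stop("need at least one seed")
  rows <- list()
  runs <- list()
  for (seed in seeds) {
    split <- stratified_split(train_data@y, seq_len(nSamples(train_data)),
                              seed = seed)
    for (variant in variants) {
      model <- buildModel(arch, variant, seed = seed)
      vcfg <- cfg
      vcfg$seed <- as.integer(seed)
      if (variant == "baseline") vcfg$lr_main <- lr_baseline
      fit <- trainModel(model, train_data, split, weights, vcfg)
      probs <- predictProbs(fit$model, test_data)
      met <- classificationMetrics(test_data@y, probs)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant, seed = seed, macro_f1 = met$macro_f1,
        auc = met$auc, best_epoch = fit$best_epoch,
        split_hash = sum(split$train) + 7919 * sum(split$val))
      runs[[paste(variant, seed, sep = "_")]] <-
        list(history = fit$history, model = fit$model, split = split)
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$variant), function(d)
    data.frame(variant = d$variant[1],
               median_f1 = stats::median(d$macro_f1),
               mean_f1 = mean(d$macro_f1),
               sd_f1 = stats::sd(d$macro_f1))))
  ord <- match(c("baseline", "recon_only", "cirl"), summary$variant)
  summary <- summary[ord[!is.na(ord)], ]
  list(results = results, summary = summary, runs = runs)
}

## ---- hyperparameter search ----------------------------------------------

#' Seeded random search over the tuning ranges
#'
#' Draws \code{budget} configurations — learning rate log-uniform in
#' [1e-4, 1e-2], loss weights uniform in their ranges — evaluates each with
#' the supplied objective (validation macro-F1 by convention) and returns
#' the maximizer. The trial sequence is fully determined by the seed.
#'
#' @param objective function(config list) -> numeric score to maximize;
#'   the config holds \code{lr}, \code{lambda_rec}, \code{lambda_task},
#'   \code{lambda_conf}.
#' @param budget number of trials (>= 1).
#' @param seed RNG seed.
#' @return List with \code{best} (config + score) and \code{trials}
#'   (data.frame of all trials).
#' @export
hyperparameterSearch <- function(objective, budget = 10, seed = 1L) {
  if (budget < 1) stop("budget must be >= 1")
  r <- search_ranges()
  set.seed(seed)
  draws <- data.frame(
    lr = 10^stats::runif(budget, log10(r$lr[1]), log10(r$lr[2])),
    lambda_rec = stats::runif(budget, r$lambda_rec[1], r$lambda_rec[2]),
    lambda_task = stats::runif(budget, r$lambda_task[1], r$lambda_task[2]),
    lambda_conf = stats::runif(budget, r$lambda_conf[1], r$lambda_conf[2]))
  scores <- numeric(budget)
  for (i in seq_len(budget))
    scores[i] <- objective(as.list(draws[i, ]))
  draws$score <- scores
  best <- which.max(scores)
  list(best = c(as.list(draws[best, setdiff(names(draws), "score")]),
                score = scores[best]),
       trials = draws)
}
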
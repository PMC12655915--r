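# The packaged benchmark study: the full synthetic experiment that the
# evaluation harness, the test suite and the reproduction script all share.

#' Run the default confounded-synthetic benchmark study
#'
#' For each seed: simulates a confounded training pool (class-correlated
#' humidity, rho = 0.6) and a humidity-range-shifted test set under the
#' default study conditions, trains the three model variants (single-latent
#' baseline, reconstruction-only, full adversarial model) on an identical
#' stratified train/validation split, and scores test macro-F1. For the
#' first \code{n_probe_seeds} seeds it additionally trains post-hoc
#' humidity probes from each latent subspace — scored both on the
#' range-shifted test set and on an in-distribution (humidity-decorrelated)
#' held-out set — and fits the least-squares trend of the training-time
#' adversary's validation MSE after a fixed burn-in.
#'
#' @param master_seed integer master seed; all per-seed, per-stage RNG
#'   seeds are derived from it deterministically.
#' @param seeds number of replicate seeds (training runs per variant).
#' @param n_probe_seeds number of seeds for which probes and training
#'   dynamics are measured.
#' @param n_train,n_test training-pool and test-set sizes.
#' @param arch an [architectureSpec()]; reduced by default so the full
#'   study runs on one CPU core in minutes.
#' @param weights a [lossWeights()].
#' @param max_epochs,patience training budget per run.
#' @param slope_burn_in epochs discarded before fitting the adversary-MSE
#'   trend (the adversary's own initial fitting transient).
#' @param verbose print one line per run.
#' @return List with \code{ablation} (data.frame: seed, variant, shifted
#'   test macro-F1), \code{medians} (per-variant median F1),
#'   \code{probes} (data.frame per probe seed: shifted and in-distribution
#'   MSE from each latent), \code{slopes} (adversary-MSE trend per probe
#'   seed) and \code{conditions} (the generator and training settings
#'   used).
#' @export
runStudy <- function(master_seed = 1L, seeds = 5L, n_probe_seeds = 3L,
                     n_train = 400L, n_test = 200L,
                     arch = reducedArchitectureSpec(),
                     weights = lossWeights(),
                     max_epochs = 60L, patience = 15L,
                     slope_burn_in = 10L, verbose = TRUE) {
  protocol <- protocolSpec()
  sim <- simConfig()
  rows <- list()
  probes <- list()
  slopes <- numeric(0)
  for (i in seq_len(seeds)) {
    base <- deriveSeed(master_seed, "simulate") + i
    train_recs <- simulateDataset(protocol, sim, n_train, shift = "none",
                                  seed = deriveSeed(base, "simulate"))
    test_recs <- simulateDataset(protocol, sim, n_test,
                                 shift = "range_shift",
                                 seed = deriveSeed(base, "shift"))
    train_data <- preprocessDataset(train_recs)
    st <- normalizationStats(train_data@stats$humidity_mean,
                             train_data@stats$humidity_sd)
    test_data <- preprocessDataset(test_recs, stats = st,
                                   L_max = train_data@stats$L_max)
    split <- stratified_split(train_data@y, seq_len(nSamples(train_data)),
                              seed = deriveSeed(base, "train"))
    for (variant in c("baseline", "recon_only", "cirl")) {
      cfg <- trainConfig(max_epochs = max_epochs, patience = patience,
                         lr_adversary = 3e-3,
                         lr_main = if (variant == "baseline") 1e-3 else 3e-4,
                         seed = deriveSeed(base, "train"))
      fit <- trainModel(buildModel(arch, variant,
                                   seed = deriveSeed(base, "train")),
                        train_data, split, weights, cfg)
      f1 <- classificationMetrics(test_data@y,
                                  predictProbs(fit$model, test_data))$macro_f1
      rows[[length(rows) + 1L]] <- data.frame(seed = i, variant = variant,
                                              macro_f1 = f1)
      if (verbose)
        message(sprintf("seed %d %-10s shifted test macro-F1 %.3f", i,
                        variant, f1))
      if (variant == "cirl" && i <= n_probe_seeds) {
        dec_recs <- simulateDataset(protocol, sim, n_test,
                                    shift = "decorrelated",
                                    seed = deriveSeed(base, "evaluate"))
        dec_data <- preprocessDataset(dec_recs, stats = st,
                                      L_max = train_data@stats$L_max)
        n_tr <- nSamples(train_data)
        pr_shift <- probeDisentanglement(
          fit$model, bindDatasets(train_data, test_data),
          train_idx = seq_len(n_tr), test_idx = n_tr + seq_len(n_test),
          probe_seed = deriveSeed(base, "probe"))
        pr_in <- probeDisentanglement(
          fit$model, bindDatasets(train_data, dec_data),
          train_idx = seq_len(n_tr), test_idx = n_tr + seq_len(n_test),
          probe_seed = deriveSeed(base, "probe"))
        h <- fit$history
        hb <- h[h$epoch > slope_burn_in, ]
        slope <- if (nrow(hb) >= 2)
          unname(stats::coef(stats::lm(val_adv_mse ~ epoch, data = hb))[2])
        else NA_real_
        probes[[length(probes) + 1L]] <- data.frame(
          seed = i,
          mse_z_task_shifted = pr_shift$mse_from_z_task,
          mse_z_conf_shifted = pr_shift$mse_from_z_conf,
          mse_z_task_indist = pr_in$mse_from_z_task,
          mse_z_conf_indist = pr_in$mse_from_z_conf)
        slopes <- c(slopes, slope)
        if (verbose)
          message(sprintf(
            "seed %d probes: shifted z_task %.2f / z_conf %.2f | in-dist z_task %.2f / z_conf %.2f | adv-MSE trend %+.4f",
            i, pr_shift$mse_from_z_task, pr_shift$mse_from_z_conf,
            pr_in$mse_from_z_task, pr_in$mse_from_z_conf, slope))
      }
    }
  }
  ablation <- do.call(rbind, rows)
  medians <- vapply(split(ablation$macro_f1, ablation$variant),
                    stats::median, numeric(1))
  list(ablation = ablation,
       medians = medians[c("baseline", "recon_only", "cirl")],
       probes = do.call(rbind, probes),
       slopes = slopes,
       conditions = list(n_train = n_train, n_test = n_test,
                         rho = sim$rho, max_epochs = max_epochs,
                         patience = patience,
                         slope_burn_in = slope_burn_in,
                         arch = unclass(arch)))
}
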
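# End-to-end experiment pipeline: simulate -> preprocess -> train variants
# -> evaluate, probe and compare, with a manifest tying every output to the
# configuration and seeds that produced it.

#' Default pipeline configuration
#'
#' @param out_dir experiment output directory.
#' @param n training-pool size.
#' @param n_test held-out test-set size.
#' @param n_classes number of classes.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param shift humidity regime of the held-out test split.
#' @param variants model variants to train.
#' @param arch an [architectureSpec()]; the reduced architecture by
#'   default.
#' @param weights a [lossWeights()].
#' @param max_epochs,patience,batch_size training budget.
#' @return A config list for [runPipeline()].
#' @export
pipelineConfig <- function(out_dir = tempfile("cirl_exp_"),
                           n = 200, n_test = 100, n_classes = 2,
                           seed = 1L,
                           shift = c("range_shift", "decorrelated", "none"),
                           variants = c("baseline", "cirl"),
                           arch = reducedArchitectureSpec(n_classes = n_classes),
                           weights = lossWeights(),
                           max_epochs = 25, patience = 10,
                           batch_size = 32) {
  shift <- match.arg(shift)
  bad <- setdiff(variants, c("baseline", "recon_only", "cirl"))
  if (length(bad))
    stop(sprintf("unknown variant(s): %s", paste(bad, collapse = ", ")))
  list(out_dir = out_dir, n = n, n_test = n_test, n_classes = n_classes,
       seed = as.integer(seed), shift = shift, variants = variants,
       arch = arch, weights = weights, max_epochs = max_epochs,
       patience = patience, batch_size = batch_size)
}

#' Run the full experiment pipeline
#'
#' Simulates a confounded training pool and a held-out (by default
#' humidity-range-shifted) test set, writes the recordings, preprocesses
#' both with training-pool statistics, trains the requested variants on a
#' stratified train/validation split, evaluates them on the test set,
#' probes disentanglement for split-latent variants, and writes metric
#' CSVs, training logs and a JSON manifest into \code{out_dir}.
#'
#' @param config a [pipelineConfig()] list.
#' @return Invisibly, a list with the manifest, per-variant metrics and
#'   report paths.
#' @export
runPipeline <- function(config) {
  cfg <- config
  bad <- setdiff(cfg$variants, c("baseline", "recon_only", "cirl"))
  if (length(bad))
    stop(sprintf("unknown variant(s): %s", paste(bad, collapse = ", ")))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  protocol <- protocolSpec()
  sim <- simConfig(n_classes = cfg$n_classes)

  train_recs <- simulateDataset(protocol, sim, cfg$n, shift = "none",
                                seed = deriveSeed(cfg$seed, "simulate"))
  test_recs <- simulateDataset(protocol, sim, cfg$n_test, shift = cfg$shift,
                               seed = deriveSeed(cfg$seed, "shift"))
  rec_dir <- file.path(cfg$out_dir, "recordings")
  writeRecordings(train_recs, file.path(rec_dir, "train"))
  writeRecordings(test_recs, file.path(rec_dir, "test"))

  train_data <- preprocessDataset(train_recs)
  test_data <- preprocessDataset(
    test_recs,
    stats = normalizationStats(train_data@stats$humidity_mean,
                               train_data@stats$humidity_sd),
    L_max = train_data@stats$L_max)
  savePreprocessed(train_data, file.path(cfg$out_dir, "train_data.rds"))
  savePreprocessed(test_data, file.path(cfg$out_dir, "test_data.rds"))

  split <- stratified_split(train_data@y, seq_len(nSamples(train_data)),
                            seed = deriveSeed(cfg$seed, "train"))
  tcfg <- trainConfig(max_epochs = cfg$max_epochs, patience = cfg$patience,
                      batch_size = cfg$batch_size,
                      seed = deriveSeed(cfg$seed, "train"))
  metrics <- list()
  probes <- list()
  for (variant in cfg$variants) {
    vcfg <- tcfg
    if (variant == "baseline") vcfg$lr_main <- 1e-3
    model <- buildModel(cfg$arch, variant,
                        seed = deriveSeed(cfg$seed, "train"))
    fit <- trainModel(model, train_data, split, cfg$weights, vcfg)
    utils::write.csv(fit$history,
                     file.path(cfg$out_dir, sprintf("history_%s.csv", variant)),
                     row.names = FALSE)
    probs <- predictProbs(fit$model, test_data)
    met <- classificationMetrics(test_data@y, probs)
    metrics[[variant]] <- met
    utils::write.csv(met$per_class,
                     file.path(cfg$out_dir, sprintf("metrics_%s.csv", variant)),
                     row.names = FALSE)
    if (variant != "baseline") {
      # probe train/test: training pool latents vs held-out shifted set
      all_data <- bindDatasets(train_data, test_data)
      pr <- probeDisentanglement(fit$model, all_data,
                                 train_idx = seq_len(nSamples(train_data)),
                                 test_idx = nSamples(train_data) +
                                   seq_len(nSamples(test_data)),
                                 probe_seed = deriveSeed(cfg$seed, "probe"))
      probes[[variant]] <- pr
    }
    saveRDS(fit$model, file.path(cfg$out_dir, sprintf("model_%s.rds", variant)))
  }
  summary <- data.frame(
    variant = names(metrics),
    macro_f1 = vapply(metrics, `[[`, numeric(1), "macro_f1"),
    auc = vapply(metrics, `[[`, numeric(1), "auc"))
  utils::write.csv(summary, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE)
  if (length(probes)) {
    ptab <- data.frame(
      variant = names(probes),
      mse_from_z_task = vapply(probes, `[[`, numeric(1), "mse_from_z_task"),
      mse_from_z_conf = vapply(probes, `[[`, numeric(1), "mse_from_z_conf"))
    utils::write.csv(ptab, file.path(cfg$out_dir, "probes.csv"),
                     row.names = FALSE)
  }
  data_files <- c("train_data.rds", "test_data.rds")
  manifest <- list(
    seed = cfg$seed,
    stage_seeds = list(simulate = deriveSeed(cfg$seed, "simulate"),
                       shift = deriveSeed(cfg$seed, "shift"),
                       train = deriveSeed(cfg$seed, "train"),
                       probe = deriveSeed(cfg$seed, "probe")),
    n = cfg$n, n_test = cfg$n_test, n_classes = cfg$n_classes,
    shift = cfg$shift, variants = cfg$variants,
    weights = unclass(cfg$weights),
    max_epochs = cfg$max_epochs, patience = cfg$patience,
    dataset_md5 = as.list(tools::md5sum(file.path(cfg$out_dir, data_files))),
    version = as.character(utils::packageVersion("cirl")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, metrics = metrics, probes = probes,
                 summary = summary, out_dir = cfg$out_dir))
}

#' Concatenate two preprocessed datasets
#'
#' Both must share the padded length, channel count and standardization
#' statistics (i.e. the second was preprocessed with the first's
#' training-fold statistics).
#'
#' @param a,b [PreprocessedDataset-class] objects.
#' @return The row-bound [PreprocessedDataset-class].
#' @export
bindDatasets <- function(a, b) {
  stopifnot(identical(dim(a@x)[2:3], dim(b@x)[2:3]))
  new("PreprocessedDataset",
      x = {
        arr <- array(0, c(dim(a@x)[1] + dim(b@x)[1], dim(a@x)[2], dim(a@x)[3]))
        arr[seq_len(dim(a@x)[1]), , ] <- a@x
        arr[dim(a@x)[1] + seq_len(dim(b@x)[1]), , ] <- b@x
        arr
      },
      mask = rbind(a@mask, b@mask), c = rbind(a@c, b@c),
      y = c(a@y, b@y), stats = a@stats,
      meta = rbind(a@meta, b@meta))
}
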
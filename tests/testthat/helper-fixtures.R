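# Tiny fixtures shared across test files. Everything is generated in code.

tiny_arch <- function(...) {
  args <- list(encoder_filters = c(4, 3, 2), kernel_size = 3, stride = 2,
               z_task_dim = 3, z_conf_dim = 2, baseline_latent_dim = 5,
               classifier_units = c(4, 3), conf_predictor_units = c(4, 5),
               adv_channels = 2, input_len = 12, input_channels = 3,
               n_classes = 2)
  args[names(list(...))] <- list(...)
  do.call(architectureSpec, args)
}

# a synthetic PreprocessedDataset with valid masks, built directly
tiny_dataset <- function(n = 12, L = 12, C = 3, n_classes = 2, seed = 1,
                         pad_last = 0) {
  set.seed(seed)
  x <- array(rnorm(n * L * C, sd = 0.5), c(n, L, C))
  cmat <- matrix(rnorm(n * L), n, L)
  mask <- matrix(TRUE, n, L)
  if (pad_last > 0) {
    for (i in seq_len(n)) {
      v <- L - pad_last
      mask[i, (v + 1):L] <- FALSE
      x[i, (v + 1):L, ] <- 0
      cmat[i, (v + 1):L] <- 0
    }
  }
  y <- rep_len(seq_len(n_classes), n)
  new("PreprocessedDataset", x = x, mask = mask, c = cmat, y = as.integer(y),
      stats = list(humidity_mean = 0.5, humidity_sd = 0.2, L_max = L),
      meta = data.frame(level = rep(NA_real_, n),
                        shift = rep(NA_character_, n)))
}

small_protocol <- function() protocolSpec()

noise_free_config <- function(...) {
  args <- list(noise_sd = 0, drift_sd = 0, amplitude_cv = 0,
               sensitivity_jitter_sd = 0, humidity_ambient_sd = 0,
               humidity_tau_cv = 0)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}
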
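# The disentangled adversarial autoencoder and its matched single-latent
# baseline.
#
# Encoder: three strided temporal-convolution blocks (conv -> batch-norm ->
# leaky rectifier), flattened, then two parallel affine heads producing the
# task latent (32-d) and the confounder latent (20-d); the baseline uses a
# single 52-d head so its capacity matches. Decoder mirrors the encoder
# with transposed convolutions and consumes the concatenated latents.
# Classifier: two rectified affine layers with dropout, softmax output.
# Confounder predictor (adversary): gradient-reversal connector on the task
# latent, two affine layers, then one transposed temporal convolution
# producing the full-length humidity trace.

#' Architecture description
#'
#' The tunable shape of the model family. At the defaults the split latent
#' (32-d task + 20-d confounder) matches the unified 52-d baseline latent,
#' so baseline and disentangled variants have identical encoder capacity.
#'
#' @param encoder_filters conv filter counts of the three encoder blocks.
#' @param kernel_size,stride temporal convolution kernel and stride.
#' @param leaky_slope negative slope of the leaky rectifier.
#' @param z_task_dim,z_conf_dim task and confounder latent dimensions.
#' @param baseline_latent_dim unified latent dimension of the baseline;
#'   must equal \code{z_task_dim + z_conf_dim}.
#' @param classifier_units hidden units of the two classifier layers.
#' @param classifier_dropout classifier dropout rate (training only).
#' @param conf_predictor_units hidden units of the confounder predictor.
#' @param adv_channels channel count of the predictor's transposed-conv
#'   upsampling stage.
#' @param input_len padded input length L.
#' @param input_channels sensor channel count.
#' @param n_classes number of task classes.
#' @return An \code{ArchitectureSpec} record (validated list).
#' @export
architectureSpec <- function(encoder_filters = c(256, 128, 64),
                             kernel_size = 3, stride = 2, leaky_slope = 0.2,
                             z_task_dim = 32, z_conf_dim = 20,
                             baseline_latent_dim = 52,
                             classifier_units = c(256, 128),
                             classifier_dropout = 0.3,
                             conf_predictor_units = c(128, 256),
                             adv_channels = 8,
                             input_len = 170, input_channels = 32,
                             n_classes = 2) {
  dims <- c(encoder_filters, z_task_dim, z_conf_dim, baseline_latent_dim,
            classifier_units, conf_predictor_units, adv_channels,
            input_len, input_channels, n_classes, kernel_size, stride)
  if (any(dims <= 0)) stop("all architecture dimensions must be positive")
  if (z_task_dim + z_conf_dim != baseline_latent_dim)
    stop("z_task_dim + z_conf_dim must equal baseline_latent_dim for a fair comparison")
  if (length(encoder_filters) != 3) stop("the encoder has three conv blocks")
  lens <- input_len
  for (i in 1:3) lens <- c(lens, ceiling(lens[i] / stride))
  structure(list(encoder_filters = encoder_filters,
                 kernel_size = kernel_size, stride = stride,
                 leaky_slope = leaky_slope,
                 z_task_dim = z_task_dim, z_conf_dim = z_conf_dim,
                 baseline_latent_dim = baseline_latent_dim,
                 classifier_units = classifier_units,
                 classifier_dropout = classifier_dropout,
                 conf_predictor_units = conf_predictor_units,
                 adv_channels = adv_channels,
                 input_len = input_len, input_channels = input_channels,
                 n_classes = n_classes,
                 conv_lens = lens[-1]),   # temporal lengths after each block
            class = "ArchitectureSpec")
}

#' A small architecture for desk-scale experiments
#'
#' Same topology, latent split (32 + 20 = 52) and input geometry as the
#' full architecture but with narrow layers, so full adversarial training
#' runs in seconds-to-minutes on one CPU core.
#'
#' @param ... overrides forwarded to [architectureSpec()].
#' @return An \code{ArchitectureSpec}.
#' @export
reducedArchitectureSpec <- function(...) {
  args <- list(encoder_filters = c(32, 16, 8),
               classifier_units = c(64, 32),
               conf_predictor_units = c(32, 64),
               adv_channels = 4)
  args[names(list(...))] <- list(...)
  do.call(architectureSpec, args)
}

#' Gradient reversal connector (forward pass)
#'
#' The identity on the forward pass; on the backward pass incoming
#' gradients are multiplied by \code{-scale} (see [gradReverseGrad()]).
#' Placing this connector between the task latent and the confounder
#' predictor turns the predictor's minimization into an adversarial signal
#' that pushes the encoder to maximize the confounder loss.
#'
#' @param u numeric tensor.
#' @param scale nonnegative reversal strength.
#' @return \code{u}, unchanged.
#' @export
gradReverse <- function(u, scale = 1) {
  if (scale < 0) stop("reversal scale must be nonnegative")
  u
}

#' Gradient reversal connector (backward pass)
#'
#' @param g upstream gradient tensor.
#' @param scale nonnegative reversal strength; 0 disables the adversarial
#'   signal entirely.
#' @return \code{-scale * g}.
#' @export
gradReverseGrad <- function(g, scale = 1) {
  if (scale < 0) stop("reversal scale must be nonnegative")
  -scale * g
}

## ---- parameter initialization ------------------------------------------

init_encoder <- function(a, variant) {
  f <- a$encoder_filters
  p <- list(conv1 = conv1d_init(a$kernel_size, a$input_channels, f[1]),
            bn1 = bn_init(f[1]),
            conv2 = conv1d_init(a$kernel_size, f[1], f[2]),
            bn2 = bn_init(f[2]),
            conv3 = conv1d_init(a$kernel_size, f[2], f[3]),
            bn3 = bn_init(f[3]))
  flat <- a$conv_lens[3] * f[3]
  if (variant == "baseline") {
    p$head <- dense_init(flat, a$baseline_latent_dim)
  } else {
    p$head_task <- dense_init(flat, a$z_task_dim)
    p$head_conf <- dense_init(flat, a$z_conf_dim)
  }
  p
}

init_decoder <- function(a) {
  f <- a$encoder_filters
  flat <- a$conv_lens[3] * f[3]
  list(fc = dense_init(a$z_task_dim + a$z_conf_dim, flat),
       tconv1 = tconv1d_init(a$kernel_size, f[3], f[2]),
       bn1 = bn_init(f[2]),
       tconv2 = tconv1d_init(a$kernel_size, f[2], f[1]),
       bn2 = bn_init(f[1]),
       tconv3 = tconv1d_init(a$kernel_size, f[1], a$input_channels))
}

init_classifier <- function(a, zdim) {
  u <- a$classifier_units
  list(fc1 = dense_init(zdim, u[1]),
       fc2 = dense_init(u[1], u[2]),
       out = dense_init(u[2], a$n_classes))
}

# shared by the adversary and the post-hoc probes (zdim varies)
init_adversary <- function(a, zdim) {
  u <- a$conf_predictor_units
  t0 <- a$conv_lens[3]
  list(fc1 = dense_init(zdim, u[1]),
       fc2 = dense_init(u[1], u[2]),
       proj = dense_init(u[2], t0 * a$adv_channels),
       up = tconv1d_init(ceiling(a$input_len / t0), a$adv_channels, 1))
}

#' Build a model
#'
#' @param arch an [architectureSpec()].
#' @param variant \code{"cirl"} (full disentangled adversarial
#'   autoencoder), \code{"baseline"} (identical encoder, unified latent,
#'   classifier only) or \code{"recon_only"} (disentangled autoencoder and
#'   classifier without the adversarial signal; identical parameter count
#'   to \code{"cirl"}).
#' @param seed RNG seed for parameter initialization.
#' @return A [CirlModel-class].
#' @examples
#' m <- buildModel(reducedArchitectureSpec(), "cirl", seed = 1)
#' m
#' @export
buildModel <- function(arch, variant = c("cirl", "baseline", "recon_only"),
                       seed = 1L) {
  variant <- match.arg(variant)
  set.seed(seed)
  f <- arch$encoder_filters
  params <- list(enc = init_encoder(arch, variant))
  stats <- list(enc = list(bn1 = bn_stats_init(f[1]),
                           bn2 = bn_stats_init(f[2]),
                           bn3 = bn_stats_init(f[3])))
  if (variant == "baseline") {
    params$cls <- init_classifier(arch, arch$baseline_latent_dim)
  } else {
    params$dec <- init_decoder(arch)
    stats$dec <- list(bn1 = bn_stats_init(f[2]), bn2 = bn_stats_init(f[1]))
    params$cls <- init_classifier(arch, arch$z_task_dim)
    params$adv <- init_adversary(arch, arch$z_task_dim)
  }
  new("CirlModel", arch = unclass(arch), variant = variant,
      params = params, stats = stats, trained = FALSE)
}

## ---- forward / backward passes -----------------------------------------

as_batch <- function(x, a) {
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  d <- dim(x)
  if (length(d) != 3 || d[2] != a$input_len || d[3] != a$input_channels)
    stop(sprintf("input must be (batch, %d, %d); got (%s)",
                 a$input_len, a$input_channels, paste(d, collapse = ", ")))
  x
}

enc_fwd <- function(params, stats, a, x, training = FALSE) {
  cache <- list()
  h <- x
  for (i in 1:3) {
    cv <- conv1d_fwd(h, params[[paste0("conv", i)]], a$stride)
    bn <- bn_fwd(cv$y, params[[paste0("bn", i)]], stats[[paste0("bn", i)]],
                 training)
    lk <- leaky_fwd(bn$y, a$leaky_slope)
    h <- lk$y
    cache[[paste0("conv", i)]] <- cv$cache
    cache[[paste0("bn", i)]] <- bn$cache
    cache[[paste0("lk", i)]] <- lk$cache
    stats[[paste0("bn", i)]] <- bn$stats
  }
  d <- dim(h)
  hmat <- matrix(h, d[1], d[2] * d[3])
  cache$hdims <- d
  if (!is.null(params$head)) {
    hd <- dense_fwd(hmat, params$head)
    cache$head <- hd$cache
    list(z = hd$y, cache = cache, stats = stats)
  } else {
    ht <- dense_fwd(hmat, params$head_task)
    hc <- dense_fwd(hmat, params$head_conf)
    cache$head_task <- ht$cache
    cache$head_conf <- hc$cache
    list(z_task = ht$y, z_conf = hc$y, cache = cache, stats = stats)
  }
}

# dz_task/dz_conf (or dz for the baseline head) -> encoder parameter grads
enc_bwd <- function(params, a, cache, dz_task = NULL, dz_conf = NULL,
                    dz = NULL) {
  grads <- list()
  if (!is.null(params$head)) {
    bd <- dense_bwd(dz, params$head, cache$head)
    grads$head <- bd$grads
    dflat <- bd$dx
  } else {
    bt <- dense_bwd(dz_task, params$head_task, cache$head_task)
    bc <- dense_bwd(dz_conf, params$head_conf, cache$head_conf)
    grads$head_task <- bt$grads
    grads$head_conf <- bc$grads
    dflat <- bt$dx + bc$dx
  }
  dh <- array(dflat, cache$hdims)
  for (i in 3:1) {
    dh <- leaky_bwd(dh, cache[[paste0("lk", i)]])
    bn <- bn_bwd(dh, params[[paste0("bn", i)]], cache[[paste0("bn", i)]])
    grads[[paste0("bn", i)]] <- bn$grads
    cv <- conv1d_bwd(bn$dx, params[[paste0("conv", i)]],
                     cache[[paste0("conv", i)]])
    grads[[paste0("conv", i)]] <- cv$grads
    dh <- cv$dx
  }
  list(grads = grads, dx = dh)
}

dec_fwd <- function(params, stats, a, z, training = FALSE) {
  f <- a$encoder_filters
  t3 <- a$conv_lens[3]
  cache <- list()
  fc <- dense_fwd(z, params$fc)
  cache$fc <- fc$cache
  h <- array(fc$y, c(nrow(z), t3, f[3]))
  lens <- c(2L * t3, 4L * t3)
  for (i in 1:2) {
    tc <- tconv1d_fwd(h, params[[paste0("tconv", i)]], a$stride, lens[i])
    bn <- bn_fwd(tc$y, params[[paste0("bn", i)]], stats[[paste0("bn", i)]],
                 training)
    lk <- leaky_fwd(bn$y, a$leaky_slope)
    h <- lk$y
    cache[[paste0("tconv", i)]] <- tc$cache
    cache[[paste0("bn", i)]] <- bn$cache
    cache[[paste0("lk", i)]] <- lk$cache
    stats[[paste0("bn", i)]] <- bn$stats
  }
  tc3 <- tconv1d_fwd(h, params$tconv3, a$stride, a$input_len)
  cache$tconv3 <- tc3$cache
  list(x_hat = tc3$y, cache = cache, stats = stats)
}

dec_bwd <- function(params, a, cache, dx_hat) {
  grads <- list()
  tc3 <- tconv1d_bwd(dx_hat, params$tconv3, cache$tconv3)
  grads$tconv3 <- tc3$grads
  dh <- tc3$dx
  for (i in 2:1) {
    dh <- leaky_bwd(dh, cache[[paste0("lk", i)]])
    bn <- bn_bwd(dh, params[[paste0("bn", i)]], cache[[paste0("bn", i)]])
    grads[[paste0("bn", i)]] <- bn$grads
    tc <- tconv1d_bwd(bn$dx, params[[paste0("tconv", i)]],
                      cache[[paste0("tconv", i)]])
    grads[[paste0("tconv", i)]] <- tc$grads
    dh <- tc$dx
  }
  d <- dim(dh)
  fc <- dense_bwd(matrix(dh, d[1], d[2] * d[3]), params$fc, cache$fc)
  grads$fc <- fc$grads
  list(grads = grads, dz = fc$dx)
}

cls_fwd <- function(params, a, z, training = FALSE) {
  cache <- list()
  f1 <- dense_fwd(z, params$fc1); cache$fc1 <- f1$cache
  r1 <- relu_fwd(f1$y);           cache$r1 <- r1$cache
  d1 <- dropout_fwd(r1$y, a$classifier_dropout, training); cache$d1 <- d1$cache
  f2 <- dense_fwd(d1$y, params$fc2); cache$fc2 <- f2$cache
  r2 <- relu_fwd(f2$y);           cache$r2 <- r2$cache
  d2 <- dropout_fwd(r2$y, a$classifier_dropout, training); cache$d2 <- d2$cache
  o <- dense_fwd(d2$y, params$out); cache$out <- o$cache
  list(probs = softmax_rows(o$y), logits = o$y, cache = cache)
}

# dlogits -> grads + dz
cls_bwd <- function(params, cache, dlogits) {
  grads <- list()
  o <- dense_bwd(dlogits, params$out, cache$out)
  grads$out <- o$grads
  dh <- dropout_bwd(o$dx, cache$d2)
  dh <- relu_bwd(dh, cache$r2)
  f2 <- dense_bwd(dh, params$fc2, cache$fc2)
  grads$fc2 <- f2$grads
  dh <- dropout_bwd(f2$dx, cache$d1)
  dh <- relu_bwd(dh, cache$r1)
  f1 <- dense_bwd(dh, params$fc1, cache$fc1)
  grads$fc1 <- f1$grads
  list(grads = grads, dz = f1$dx)
}

adv_fwd <- function(params, a, z) {
  cache <- list()
  f1 <- dense_fwd(z, params$fc1); cache$fc1 <- f1$cache
  r1 <- leaky_fwd(f1$y, a$leaky_slope); cache$r1 <- r1$cache
  f2 <- dense_fwd(r1$y, params$fc2); cache$fc2 <- f2$cache
  r2 <- leaky_fwd(f2$y, a$leaky_slope); cache$r2 <- r2$cache
  pj <- dense_fwd(r2$y, params$proj); cache$proj <- pj$cache
  t0 <- a$conv_lens[3]
  h <- array(pj$y, c(nrow(z), t0, a$adv_channels))
  up <- tconv1d_fwd(h, params$up, ceiling(a$input_len / t0), a$input_len)
  cache$up <- up$cache
  list(c_hat = matrix(up$y, nrow(z), a$input_len), cache = cache)
}

adv_bwd <- function(params, a, cache, dc_hat) {
  grads <- list()
  d <- c(nrow(dc_hat), a$input_len, 1L)
  up <- tconv1d_bwd(array(dc_hat, d), params$up, cache$up)
  grads$up <- up$grads
  dd <- dim(up$dx)
  pj <- dense_bwd(matrix(up$dx, dd[1], dd[2] * dd[3]), params$proj, cache$proj)
  grads$proj <- pj$grads
  dh <- leaky_bwd(pj$dx, cache$r2)
  f2 <- dense_bwd(dh, params$fc2, cache$fc2)
  grads$fc2 <- f2$grads
  dh <- leaky_bwd(f2$dx, cache$r1)
  f1 <- dense_bwd(dh, params$fc1, cache$fc1)
  grads$fc1 <- f1$grads
  list(grads = grads, dz = f1$dx)
}

## ---- user-facing inference operations ----------------------------------

#' Encode sensor inputs into the latent space(s)
#'
#' @param model a [CirlModel-class].
#' @param x input batch: array (batch, L, C) or a single L x C matrix.
#' @param training logical; TRUE uses batch statistics in the
#'   normalization layers (training mode), FALSE the running statistics
#'   (deterministic inference).
#' @return For split-latent variants, a list with \code{z_task}
#'   (batch x 32) and \code{z_conf} (batch x 20); for the baseline, a list
#'   with the unified \code{z} (batch x 52).
#' @export
encode <- function(model, x, training = FALSE) {
  x <- as_batch(x, model@arch)
  out <- enc_fwd(model@params$enc, model@stats$enc, model@arch, x, training)
  if (!is.null(out$z)) list(z = out$z)
  else list(z_task = out$z_task, z_conf = out$z_conf)
}

#' Decode latents back to the input space
#'
#' @param model a split-latent [CirlModel-class].
#' @param z_task batch x 32 task latents.
#' @param z_conf batch x 20 confounder latents.
#' @param training logical, see [encode()].
#' @return Reconstruction array (batch, L, C).
#' @export
decode <- function(model, z_task, z_conf, training = FALSE) {
  if (model@variant == "baseline")
    stop("the baseline variant has no decoder")
  if (is.null(dim(z_task))) z_task <- matrix(z_task, 1)
  if (is.null(dim(z_conf))) z_conf <- matrix(z_conf, 1)
  dec_fwd(model@params$dec, model@stats$dec, model@arch,
          cbind(z_task, z_conf), training)$x_hat
}

#' Classify from the task latent
#'
#' @param model a [CirlModel-class].
#' @param z latent batch: the task latent for split variants, the unified
#'   latent for the baseline.
#' @param training logical; TRUE applies dropout (stochastic), FALSE is
#'   deterministic inference.
#' @return batch x n_classes matrix of class probabilities (rows sum to 1).
#' @export
classify <- function(model, z, training = FALSE) {
  if (is.null(dim(z))) z <- matrix(z, 1)
  cls_fwd(model@params$cls, model@arch, z, training)$probs
}

#' Predict the humidity trace from the task latent (adversary head)
#'
#' The gradient-reversal connector is the identity on this forward pass;
#' \code{reverse_scale} only affects gradients during training.
#'
#' @param model a split-latent [CirlModel-class].
#' @param z_task batch x 32 task latents.
#' @param reverse_scale nonnegative reversal strength (no forward effect).
#' @return batch x L matrix of predicted standardized humidity traces.
#' @export
predictConfounder <- function(model, z_task, reverse_scale = 1) {
  if (model@variant == "baseline")
    stop("the baseline variant has no confounder predictor")
  if (reverse_scale < 0) stop("reversal scale must be nonnegative")
  if (is.null(dim(z_task))) z_task <- matrix(z_task, 1)
  adv_fwd(model@params$adv, model@arch, gradReverse(z_task, reverse_scale))$c_hat
}

#' Predict class probabilities for a preprocessed dataset
#'
#' Runs the encoder and classifier in inference mode.
#'
#' @param model a trained [CirlModel-class].
#' @param data a [PreprocessedDataset-class].
#' @param idx optional sample indices; defaults to all samples.
#' @return n x n_classes probability matrix.
#' @export
predictProbs <- function(model, data, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nSamples(data))
  z <- encode(model, data@x[idx, , , drop = FALSE])
  classify(model, if (model@variant == "baseline") z$z else z$z_task)
}
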
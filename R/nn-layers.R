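# Internal neural-network primitives.
#
# Plain-R implementations of the layers the disentangled autoencoder needs:
# strided 1D convolution (im2col), transposed 1D convolution, batch
# normalization, dense layers, leaky rectifier, dropout and the Adam
# optimizer. Every layer exposes a *_fwd / *_bwd pair; the backward passes
# are checked against finite-difference oracles in the test suite.
#
# Array convention: batches are arrays of dim (B, L, C) — batch, time,
# channel. Flattening uses R's native column-major order, so
# matrix(x, B, L * C) and array(m, c(B, L, C)) are exact inverses.

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

## ---- padding bookkeeping ("same"-style, ceil-mode length recurrence) ----

same_pad <- function(len, kernel, stride) {
  out <- ceiling(len / stride)
  p <- max(0L, (out - 1L) * stride + kernel - len)
  list(left = p %/% 2L, right = p - p %/% 2L, out = out)
}

## ---- strided 1D convolution -------------------------------------------

conv1d_init <- function(kernel, cin, cout) {
  list(W = array(stats::rnorm(kernel * cin * cout, sd = sqrt(2 / (kernel * cin))),
                 dim = c(kernel, cin, cout)),
       b = numeric(cout))
}

# x: (B, L, Cin) -> (B, Lout, Cout) with ceil-mode same padding
conv1d_fwd <- function(x, p, stride) {
  d <- dim(x); B <- d[1]; L <- d[2]; cin <- d[3]
  k <- dim(p$W)[1]; cout <- dim(p$W)[3]
  pad <- same_pad(L, k, stride)
  Lp <- L + pad$left + pad$right
  xp <- array(0, c(B, Lp, cin))
  xp[, pad$left + seq_len(L), ] <- x
  lout <- pad$out
  cols <- matrix(0, B * lout, k * cin)
  for (tap in seq_len(k)) {
    idx <- seq(tap, by = stride, length.out = lout)
    slice <- xp[, idx, , drop = FALSE]
    dim(slice) <- c(B * lout, cin)
    cols[, (tap - 1L) * cin + seq_len(cin)] <- slice
  }
  # rows of Wmat ordered (cin fastest, tap slowest) to match cols blocks
  Wmat <- matrix(aperm(p$W, c(2, 1, 3)), cin * k, cout)
  out <- cols %*% Wmat
  out <- out + rep(p$b, each = nrow(out))
  dim(out) <- c(B, lout, cout)
  list(y = out,
       cache = list(cols = cols, dims = d, pad = pad, stride = stride,
                    k = k, cin = cin, cout = cout, lout = lout))
}

conv1d_bwd <- function(dy, p, cache) {
  B <- cache$dims[1]; L <- cache$dims[2]; cin <- cache$cin
  k <- cache$k; cout <- cache$cout; lout <- cache$lout
  dmat <- dy
  dim(dmat) <- c(B * lout, cout)
  Wmat <- matrix(aperm(p$W, c(2, 1, 3)), cin * k, cout)
  dW <- array(aperm(array(crossprod(cache$cols, dmat), c(cin, k, cout)),
                    c(2, 1, 3)), dim = dim(p$W))
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, Wmat)   # (B*lout, k*cin)
  pad <- cache$pad
  Lp <- L + pad$left + pad$right
  dxp <- array(0, c(B, Lp, cin))
  for (tap in seq_len(k)) {
    idx <- seq(tap, by = cache$stride, length.out = lout)
    block <- dcols[, (tap - 1L) * cin + seq_len(cin)]
    dim(block) <- c(B, lout, cin)
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + block
  }
  list(dx = dxp[, pad$left + seq_len(L), , drop = FALSE],
       grads = list(W = dW, b = db))
}

## ---- transposed 1D convolution ----------------------------------------

tconv1d_init <- function(kernel, cin, cout) {
  list(W = array(stats::rnorm(kernel * cin * cout, sd = sqrt(2 / (kernel * cin))),
                 dim = c(kernel, cin, cout)),
       b = numeric(cout))
}

# x: (B, Lin, Cin) -> (B, out_len, Cout); full length (Lin-1)*stride + kernel,
# cropped at the tail to out_len
tconv1d_fwd <- function(x, p, stride, out_len) {
  d <- dim(x); B <- d[1]; lin <- d[2]; cin <- d[3]
  k <- dim(p$W)[1]; cout <- dim(p$W)[3]
  lfull <- (lin - 1L) * stride + k
  stopifnot(out_len <= lfull)
  xmat <- x
  dim(xmat) <- c(B * lin, cin)
  y <- array(0, c(B, lfull, cout))
  for (tap in seq_len(k)) {
    contrib <- xmat %*% matrix(p$W[tap, , ], cin, cout)
    dim(contrib) <- c(B, lin, cout)
    pos <- (seq_len(lin) - 1L) * stride + tap
    y[, pos, ] <- y[, pos, , drop = FALSE] + contrib
  }
  y <- y + rep(p$b, each = B * lfull)
  list(y = y[, seq_len(out_len), , drop = FALSE],
       cache = list(xmat = xmat, dims = d, k = k, cin = cin, cout = cout,
                    stride = stride, lfull = lfull, out_len = out_len))
}

tconv1d_bwd <- function(dy, p, cache) {
  B <- cache$dims[1]; lin <- cache$dims[2]; cin <- cache$cin
  k <- cache$k; cout <- cache$cout; stride <- cache$stride
  dyf <- array(0, c(B, cache$lfull, cout))
  dyf[, seq_len(cache$out_len), ] <- dy
  dW <- array(0, dim = dim(p$W))
  dxmat <- matrix(0, B * lin, cin)
  for (tap in seq_len(k)) {
    pos <- (seq_len(lin) - 1L) * stride + tap
    dcontrib <- dyf[, pos, , drop = FALSE]
    dim(dcontrib) <- c(B * lin, cout)
    dW[tap, , ] <- crossprod(cache$xmat, dcontrib)
    dxmat <- dxmat + tcrossprod(dcontrib, matrix(p$W[tap, , ], cin, cout))
  }
  dim(dyf) <- c(B * cache$lfull, cout)
  db <- colSums(dyf)
  dim(dxmat) <- cache$dims
  list(dx = dxmat, grads = list(W = dW, b = db))
}

## ---- batch normalization (per channel over batch x time) ---------------

bn_init <- function(c) list(g = rep(1, c), b = numeric(c))
bn_stats_init <- function(c) list(mean = numeric(c), var = rep(1, c))

bn_fwd <- function(x, p, stats, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  m <- x
  dim(m) <- c(n, d[3])
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2          # biased batch variance
    v <- pmax(v, 0)
    new_stats <- list(mean = momentum * stats$mean + (1 - momentum) * mu,
                      var = momentum * stats$var + (1 - momentum) * v)
  } else {
    mu <- stats$mean; v <- stats$var
    new_stats <- stats
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (m - rep(mu, each = n)) * rep(inv_sd, each = n)
  y <- xhat * rep(p$g, each = n) + rep(p$b, each = n)
  dim(y) <- d
  list(y = y, stats = new_stats,
       cache = list(xhat = xhat, inv_sd = inv_sd, dims = d, training = training))
}

bn_bwd <- function(dy, p, cache) {
  d <- cache$dims
  n <- d[1] * d[2]
  dym <- dy
  dim(dym) <- c(n, d[3])
  xhat <- cache$xhat
  dg <- colSums(dym * xhat)
  db <- colSums(dym)
  dxhat <- dym * rep(p$g, each = n)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
      rep(cache$inv_sd, each = n)
  } else {
    dx <- dxhat * rep(cache$inv_sd, each = n)
  }
  dim(dx) <- d
  list(dx = dx, grads = list(g = dg, b = db))
}

## ---- dense / activations / dropout ------------------------------------

dense_init <- function(nin, nout) {
  list(W = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

dense_fwd <- function(x, p) {
  list(y = sweep(x %*% p$W, 2, p$b, `+`), cache = list(x = x))
}

dense_bwd <- function(dy, p, cache) {
  list(dx = tcrossprod(dy, p$W),
       grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

leaky_fwd <- function(x, slope) {
  fmask <- 1 + (slope - 1) * (x < 0)
  list(y = x * fmask, cache = list(fmask = fmask))
}

leaky_bwd <- function(dy, cache) {
  dy * cache$fmask
}

relu_fwd <- function(x) {
  fmask <- (x >= 0)
  list(y = x * fmask, cache = list(fmask = fmask))
}

relu_bwd <- function(dy, cache) {
  dy * cache$fmask
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  keep <- (stats::runif(length(x)) >= rate) / (1 - rate)
  list(y = x * keep, cache = list(keep = keep))
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) return(dy)
  dy * cache$keep
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(a) a * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

# params and grads share the same nested-list structure
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    newp <- p - lr * mhat / (sqrt(vhat) + eps)
    attributes(newp) <- attributes(p)   # keep exact parameter shape
    attributes(m) <- attributes(p)
    attributes(v) <- attributes(p)
    list(p = newp, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      # grads may be assembled in a different order: align by name
      out <- Map(walk, p, g[names(p)], m[names(p)], v[names(p)])
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

grads_zero_like <- function(params) {
  rapply(params, function(a) {
    z <- a; z[] <- 0; z
  }, how = "replace")
}

grads_norm <- function(g) {
  sqrt(sum(unlist(rapply(g, function(a) sum(a^2), how = "unlist"))))
}
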
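# Preprocessing pipeline: ambient normalization -> temporal truncation ->
# right zero-padding with validity masks, plus humidity-target
# standardization and class weighting.

#' Ambient (baseline) normalization
#'
#' Per-channel transform \code{x' = x / median(x[baseline]) - 1}, where the
#' baseline window is the ambient reference phase. Compensates inter-sensor
#' variability and baseline drift while preserving relative response
#' magnitudes. The median uses the midpoint convention for even windows.
#'
#' @param response T x C raw response matrix.
#' @param baseline_window integer indices of the baseline (ambient) rows.
#' @return T x C normalized matrix.
#' @examples
#' m <- matrix(2, 5, 1)
#' m[3, 1] <- 3
#' ambientNormalize(m, 1:2)   # (3/2 - 1) = 0.5 at row 3
#' @export
ambientNormalize <- function(response, baseline_window) {
  if (length(baseline_window) == 0) stop("baseline window must be nonempty")
  med <- apply(response[baseline_window, , drop = FALSE], 2, stats::median)
  zero <- which(med == 0)
  if (length(zero))
    stop(sprintf("baseline median is zero on channel(s) %s; cannot normalize",
                 paste(zero, collapse = ", ")))
  sweep(response, 2, med, `/`) - 1
}

#' Truncate a recording after the recovery phase plus a buffer
#'
#' Keeps timesteps up to the recovery-phase terminus plus
#' \code{buffer_s} seconds, truncating the response and the humidity and
#' temperature traces identically. Recordings already shorter than the
#' cutoff are returned unchanged.
#'
#' @param rec a [SensorRecording-class] (raw or normalized).
#' @param buffer_s buffer after the recovery terminus, seconds.
#' @return The truncated [SensorRecording-class].
#' @export
truncateRecording <- function(rec, buffer_s = 60) {
  if (length(rec@phases) != 3L || any(is.na(rec@phases)))
    stop("recovery terminus unknown: recording has no valid phase boundaries")
  cutoff <- rec@phases[3] + as.integer(round(buffer_s * rec@rate_hz))
  t_len <- nrow(rec@response)
  if (cutoff >= t_len) return(rec)
  keep <- seq_len(cutoff)
  SensorRecording(response = rec@response[keep, , drop = FALSE],
                  humidity = rec@humidity[keep],
                  temperature = if (length(rec@temperature)) rec@temperature[keep] else numeric(0),
                  label = rec@label, phases = rec@phases,
                  rate_hz = rec@rate_hz, meta = rec@meta)
}

#' Right-pad a sample to a fixed length with a validity mask
#'
#' Appends zero rows to the response and zeros to the humidity target until
#' length \code{L_max}; the mask is TRUE on the first T (real) positions and
#' FALSE on the padded suffix.
#'
#' @param x T x C normalized response matrix.
#' @param c length-T humidity target.
#' @param L_max target length; must satisfy \code{T <= L_max}.
#' @return List with \code{x} (L_max x C), \code{c} (length L_max),
#'   \code{mask} (logical length L_max) and \code{valid_len}.
#' @export
padToLength <- function(x, c, L_max) {
  t_len <- nrow(x)
  if (length(c) != t_len) stop("x and c must have the same length")
  if (t_len > L_max)
    stop("sample longer than L_max: truncate before padding")
  xp <- matrix(0, L_max, ncol(x))
  xp[seq_len(t_len), ] <- x
  cp <- numeric(L_max)
  cp[seq_len(t_len)] <- c
  list(x = xp, c = cp,
       mask = c(rep(TRUE, t_len), rep(FALSE, L_max - t_len)),
       valid_len = t_len)
}

#' Training-fold humidity standardization statistics
#'
#' @param humidity_mean,humidity_sd pooled mean and standard deviation of
#'   the training-fold humidity values over valid timesteps.
#' @return A \code{NormalizationStats} record.
#' @export
normalizationStats <- function(humidity_mean, humidity_sd) {
  if (humidity_sd <= 0) stop("humidity_sd must be positive")
  structure(list(humidity_mean = humidity_mean, humidity_sd = humidity_sd),
            class = "NormalizationStats")
}

#' Standardize a humidity target trace
#'
#' Elementwise z-scoring \code{(c - mean) / sd} with training-fold moments;
#' padded (mask-FALSE) positions are set to zero.
#'
#' @param c humidity trace.
#' @param stats a [normalizationStats()] record fitted on training folds.
#' @param mask optional logical validity mask; defaults to all-valid.
#' @return Standardized trace with zeros on masked-out positions.
#' @export
standardizeHumidity <- function(c, stats, mask = NULL) {
  if (stats$humidity_sd <= 0) stop("humidity_sd must be positive")
  if (is.null(mask)) mask <- rep(TRUE, length(c))
  out <- numeric(length(c))
  out[mask] <- (c[mask] - stats$humidity_mean) / stats$humidity_sd
  out
}

#' Inverse-frequency class weights
#'
#' \code{weight_c = n_total / (n_classes * n_c)}, so the weighted sum of
#' per-sample weights equals \code{n_total}. Used to emphasize minority
#' classes in the task loss.
#'
#' @param labels integer class labels in \code{1..n_classes}.
#' @param n_classes number of classes; defaults to \code{max(labels)}.
#' @return Named numeric weight vector of length \code{n_classes}.
#' @examples
#' classWeights(rep(1:2, c(112, 56)))   # 0.75, 1.5
#' @export
classWeights <- function(labels, n_classes = max(labels)) {
  counts <- tabulate(labels, nbins = n_classes)
  if (any(counts == 0))
    stop(sprintf("class(es) %s have no samples; weights undefined",
                 paste(which(counts == 0), collapse = ", ")))
  w <- length(labels) / (n_classes * counts)
  names(w) <- seq_len(n_classes)
  w
}

#' Run the full preprocessing pipeline on a set of recordings
#'
#' Applies, in order: ambient normalization (baseline window = the ambient
#' phase), truncation at the recovery terminus plus \code{buffer_s}, right
#' zero-padding to \code{L_max}, and standardization of the humidity target
#' with training-fold moments. Recordings flagged as already normalized are
#' rejected — the pipeline is not idempotent.
#'
#' For held-out data, pass the \code{stats} and \code{L_max} recorded from
#' the training folds so no test-fold information leaks into the
#' standardization.
#'
#' @param recordings list of raw [SensorRecording-class] objects.
#' @param buffer_s truncation buffer, seconds.
#' @param stats optional [normalizationStats()] fitted on training folds;
#'   computed from \code{recordings} when \code{NULL}.
#' @param L_max optional fixed padded length; defaults to the maximum
#'   post-truncation length within \code{recordings}.
#' @return A [PreprocessedDataset-class].
#' @export
preprocessDataset <- function(recordings, buffer_s = 60, stats = NULL,
                              L_max = NULL) {
  if (length(recordings) == 0) stop("no recordings to preprocess")
  norm <- lapply(recordings, function(rec) {
    if (isTRUE(rec@meta$normalized))
      stop("recording is already normalized; the pipeline must not be applied twice")
    tr <- truncateRecording(rec, buffer_s = buffer_s)
    xn <- ambientNormalize(tr@response, seq_len(tr@phases[1]))
    list(x = xn, h = tr@humidity, y = tr@label, meta = tr@meta)
  })
  lens <- vapply(norm, function(s) nrow(s$x), integer(1))
  if (is.null(L_max)) L_max <- max(lens)
  if (is.null(stats)) {
    pooled <- unlist(lapply(norm, `[[`, "h"))
    stats <- normalizationStats(mean(pooled), stats::sd(pooled))
  }
  n <- length(norm)
  n_ch <- ncol(norm[[1]]$x)
  x <- array(0, c(n, L_max, n_ch))
  cmat <- matrix(0, n, L_max)
  mask <- matrix(FALSE, n, L_max)
  y <- integer(n)
  for (s in seq_len(n)) {
    cz <- (norm[[s]]$h - stats$humidity_mean) / stats$humidity_sd
    p <- padToLength(norm[[s]]$x, cz, L_max)
    x[s, , ] <- p$x
    cmat[s, ] <- p$c
    mask[s, ] <- p$mask
    y[s] <- norm[[s]]$y
  }
  meta <- data.frame(
    level = vapply(norm, function(s) {
      if (is.null(s$meta$level)) NA_real_ else s$meta$level
    }, numeric(1)),
    shift = vapply(norm, function(s) {
      if (is.null(s$meta$shift)) NA_character_ else s$meta$shift
    }, character(1)))
  new("PreprocessedDataset", x = x, mask = mask, c = cmat, y = y,
      stats = list(humidity_mean = stats$humidity_mean,
                   humidity_sd = stats$humidity_sd, L_max = L_max),
      meta = meta)
}

#' Extract a subset of a preprocessed dataset
#'
#' @param data a [PreprocessedDataset-class].
#' @param idx integer sample indices.
#' @return A [PreprocessedDataset-class] restricted to \code{idx}.
#' @export
subsetDataset <- function(data, idx) {
  new("PreprocessedDataset",
      x = data@x[idx, , , drop = FALSE],
      mask = data@mask[idx, , drop = FALSE],
      c = data@c[idx, , drop = FALSE],
      y = data@y[idx], stats = data@stats,
      meta = data@meta[idx, , drop = FALSE])
}
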
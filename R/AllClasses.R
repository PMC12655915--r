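#' @import methods
NULL

#' SensorRecording: one electronic-nose exposure recording
#'
#' Container for a single aroma digitization run: the multichannel
#' chemiresistive response matrix, the co-recorded relative-humidity trace,
#' an optional temperature trace, the class label and the indices of the
#' three protocol phase boundaries (end of ambient, end of exposure, end of
#' recovery).
#'
#' @slot response numeric T x C matrix of relative resistance responses
#'   (unitless), sampled at \code{rate_hz}.
#' @slot humidity numeric length-T relative-humidity trace (fraction in
#'   [0, 1]).
#' @slot temperature numeric length-T temperature trace in degrees Celsius,
#'   or \code{numeric(0)} when not recorded.
#' @slot label integer class label in \code{1..n_classes}.
#' @slot phases integer vector of length 3: sample indices at which the
#'   ambient, exposure and recovery phases end; strictly increasing and
#'   within \code{[1, T]}.
#' @slot rate_hz numeric sampling rate in Hz.
#' @slot meta list of free-form provenance fields (simulation parameters,
#'   humidity level, preprocessing flags).
#'
#' @seealso [simulateDataset()], [readRecordings()]
#' @export
setClass("SensorRecording",
         representation(response = "matrix", humidity = "numeric",
                        temperature = "numeric", label = "integer",
                        phases = "integer", rate_hz = "numeric",
                        meta = "list"))

setValidity("SensorRecording", function(object) {
  msgs <- character()
  t_len <- nrow(object@response)
  if (length(object@humidity) != t_len)
    msgs <- c(msgs, "humidity trace length must equal response row count")
  if (length(object@temperature) > 0 && length(object@temperature) != t_len)
    msgs <- c(msgs, "temperature trace length must equal response row count")
  if (!all(is.finite(object@response)) || !all(is.finite(object@humidity)))
    msgs <- c(msgs, "response and humidity must be finite")
  if (length(object@phases) != 3L)
    msgs <- c(msgs, "phases must hold exactly three boundary indices")
  else {
    if (any(diff(object@phases) <= 0))
      msgs <- c(msgs, "phase boundaries must be strictly increasing")
    if (object@phases[1] < 1L || object@phases[3] > t_len)
      msgs <- c(msgs, "phase boundaries must lie within [1, T]")
  }
  if (length(object@label) != 1L || object@label < 1L)
    msgs <- c(msgs, "label must be a single positive class index")
  if (length(object@rate_hz) != 1L || object@rate_hz <= 0)
    msgs <- c(msgs, "rate_hz must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SensorRecording
#'
#' @param response T x C response matrix.
#' @param humidity length-T humidity trace (fraction).
#' @param label integer class label in \code{1..n_classes}.
#' @param phases integer vector of the three phase-end indices
#'   (ambient, exposure, recovery).
#' @param temperature optional length-T temperature trace.
#' @param rate_hz sampling rate in Hz.
#' @param meta list of provenance fields.
#' @return A validated [SensorRecording-class] object.
#' @export
SensorRecording <- function(response, humidity, label, phases,
                            temperature = numeric(0), rate_hz = 1,
                            meta = list()) {
  new("SensorRecording", response = as.matrix(response),
      humidity = as.numeric(humidity),
      temperature = as.numeric(temperature),
      label = as.integer(label), phases = as.integer(phases),
      rate_hz = as.numeric(rate_hz), meta = meta)
}

setMethod("show", "SensorRecording", function(object) {
  cat(sprintf("SensorRecording: %d timesteps x %d channels @ %g Hz\n",
              nrow(object@response), ncol(object@response), object@rate_hz))
  cat(sprintf("  label: %d | phases end at %s | humidity %.2f-%.2f\n",
              object@label, paste(object@phases, collapse = "/"),
              min(object@humidity), max(object@humidity)))
})

#' PreprocessedDataset: normalized, padded model-ready samples
#'
#' Output of [preprocessDataset()]: ambient-normalized, truncated and
#' right-zero-padded response tensors with validity masks, the standardized
#' humidity target used by the adversary, and class labels.
#'
#' @slot x numeric array (n, L, C) of normalized responses; zero on padded
#'   positions.
#' @slot mask logical matrix (n, L); TRUE marks real timesteps. Each row is
#'   TRUE on a prefix and FALSE on the suffix (right padding only).
#' @slot c numeric matrix (n, L): standardized humidity target, zero on
#'   padded positions.
#' @slot y integer class labels in \code{1..n_classes}.
#' @slot stats list with \code{humidity_mean} and \code{humidity_sd}, the
#'   training-fold moments used to standardize \code{c}.
#' @slot meta data.frame of per-sample metadata (humidity level, split tag).
#'
#' @export
setClass("PreprocessedDataset",
         representation(x = "array", mask = "matrix", c = "matrix",
                        y = "integer", stats = "list", meta = "data.frame"))

setValidity("PreprocessedDataset", function(object) {
  msgs <- character()
  d <- dim(object@x)
  if (length(d) != 3L) msgs <- c(msgs, "x must be a 3D array (n, L, C)")
  if (!identical(dim(object@mask), d[1:2]))
    msgs <- c(msgs, "mask must be (n, L)")
  if (!identical(dim(object@c), d[1:2]))
    msgs <- c(msgs, "c must be (n, L)")
  if (length(object@y) != d[1]) msgs <- c(msgs, "y must have one label per sample")
  for (i in seq_len(d[1])) {
    m <- object@mask[i, ]
    v <- sum(m)
    if (v < d[2] && any(m[(v + 1):d[2]]))
      msgs <- c(msgs, sprintf("mask row %d is not a prefix mask", i))
    if (v < d[2]) {
      if (any(object@x[i, (v + 1):d[2], ] != 0))
        msgs <- c(msgs, sprintf("x row %d has nonzero padded values", i))
      if (any(object@c[i, (v + 1):d[2]] != 0))
        msgs <- c(msgs, sprintf("c row %d has nonzero padded values", i))
    }
  }
  if (!is.null(object@stats$humidity_sd) && object@stats$humidity_sd <= 0)
    msgs <- c(msgs, "humidity_sd must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PreprocessedDataset", function(object) {
  d <- dim(object@x)
  cat(sprintf("PreprocessedDataset: %d samples x %d timesteps x %d channels\n",
              d[1], d[2], d[3]))
  cat(sprintf("  classes: %s | humidity target: mean %.3f sd %.3f (training-fold)\n",
              paste(sprintf("%d(n=%d)", sort(unique(object@y)),
                            tabulate(object@y)[sort(unique(object@y))]),
                    collapse = " "),
              object@stats$humidity_mean, object@stats$humidity_sd))
})

#' CirlModel: model state of the disentangled autoencoder or its baseline
#'
#' Holds the architecture description, the variant tag, all trainable
#' parameters and the batch-norm running statistics. Created by
#' [buildModel()] and updated by [trainModel()].
#'
#' @slot arch the [architectureSpec()] record the model was built from.
#' @slot variant one of \code{"cirl"}, \code{"baseline"},
#'   \code{"recon_only"}.
#' @slot params nested list of parameter arrays (encoder, decoder,
#'   classifier, adversary).
#' @slot stats nested list of batch-norm running means/variances.
#' @slot trained logical; TRUE once [trainModel()] has run.
#'
#' @export
setClass("CirlModel",
         representation(arch = "list", variant = "character",
                        params = "list", stats = "list", trained = "logical"))

setValidity("CirlModel", function(object) {
  if (!object@variant %in% c("cirl", "baseline", "recon_only"))
    return("variant must be one of cirl, baseline, recon_only")
  TRUE
})

setMethod("show", "CirlModel", function(object) {
  a <- object@arch
  cat(sprintf("CirlModel (variant: %s, %strained)\n", object@variant,
              if (object@trained) "" else "un"))
  cat(sprintf("  encoder: %d conv blocks, filters [%s], kernel %d, stride %d\n",
              length(a$encoder_filters),
              paste(a$encoder_filters, collapse = ", "),
              a$kernel_size, a$stride))
  if (object@variant == "baseline") {
    cat(sprintf("  latent: unified %d-d\n", a$baseline_latent_dim))
  } else {
    cat(sprintf("  latent: %d-d task + %d-d confounder\n",
                a$z_task_dim, a$z_conf_dim))
  }
  cat(sprintf("  input: %d timesteps x %d channels, %d classes | %d parameters\n",
              a$input_len, a$input_channels, a$n_classes,
              nParameters(object)))
})

#' Number of trainable parameters of a model
#'
#' @param model a [CirlModel-class].
#' @return Integer parameter count.
#' @export
nParameters <- function(model) {
  sum(unlist(rapply(model@params, length, how = "unlist")))
}

## ---- accessors ----------------------------------------------------------

#' @describeIn SensorRecording-class response matrix accessor
#' @param x a SensorRecording
#' @export
setGeneric("response", function(x) standardGeneric("response"))
#' @export
setMethod("response", "SensorRecording", function(x) x@response)

#' @describeIn SensorRecording-class humidity trace accessor
#' @export
setGeneric("humidity", function(x) standardGeneric("humidity"))
#' @export
setMethod("humidity", "SensorRecording", function(x) x@humidity)

#' @describeIn SensorRecording-class class-label accessor
#' @export
setGeneric("recordingLabel", function(x) standardGeneric("recordingLabel"))
#' @export
setMethod("recordingLabel", "SensorRecording", function(x) x@label)

#' @describeIn SensorRecording-class phase-boundary accessor
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))
#' @export
setMethod("phases", "SensorRecording", function(x) x@phases)

#' @describeIn PreprocessedDataset-class class labels accessor
#' @param object a PreprocessedDataset
#' @export
datasetLabels <- function(object) object@y

#' @describeIn PreprocessedDataset-class number of samples
#' @export
nSamples <- function(object) dim(object@x)[1]
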
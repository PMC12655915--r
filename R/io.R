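# Recording and dataset readers/writers.
#
# One CSV per recording (time_s, ch00..chNN, humidity[, temperature]) plus
# a JSON sidecar carrying the label, phase indices and provenance. The
# packed preprocessed dataset uses R native serialization plus a JSON
# manifest.

recording_stem <- function(i) sprintf("rec_%05d", i)

#' Write recordings to a directory
#'
#' Each recording becomes \code{rec_NNNNN.csv} (columns \code{time_s},
#' \code{ch00..}, \code{humidity}, optionally \code{temperature}) and a
#' JSON sidecar \code{rec_NNNNN.json} with label, phase indices, sampling
#' rate and metadata. The writer is deterministic: writing, reading and
#' re-writing produces identical bytes.
#'
#' @param recordings list of [SensorRecording-class] objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the file stems written.
#' @export
writeRecordings <- function(recordings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stems <- character(length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    stem <- recording_stem(i)
    n_ch <- ncol(rec@response)
    df <- data.frame(time_s = (seq_len(nrow(rec@response)) - 1) / rec@rate_hz)
    resp <- as.data.frame(rec@response)
    names(resp) <- sprintf("ch%02d", seq_len(n_ch) - 1)
    df <- cbind(df, resp, humidity = rec@humidity)
    if (length(rec@temperature)) df$temperature <- rec@temperature
    utils::write.csv(df, file.path(dir, paste0(stem, ".csv")),
                     row.names = FALSE)
    side <- list(label = rec@label, phases = rec@phases,
                 rate_hz = rec@rate_hz, meta = rec@meta)
    jsonlite::write_json(side, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA)
    stems[i] <- stem
  }
  invisible(stems)
}

#' Read recordings from a directory
#'
#' Reads every \code{rec_*.csv} + sidecar pair, validating each recording;
#' malformed files raise an error naming the file and the reason. An empty
#' directory yields an empty list with a warning.
#'
#' @param dir directory written by [writeRecordings()].
#' @return List of validated [SensorRecording-class] objects.
#' @export
readRecordings <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("directory '%s' does not exist", dir))
  csvs <- sort(list.files(dir, pattern = "^rec_\\d+\\.csv$",
                          full.names = TRUE))
  if (length(csvs) == 0) {
    warning(sprintf("no recordings found in '%s'", dir))
    return(list())
  }
  lapply(csvs, function(f) {
    df <- utils::read.csv(f)
    if (!"humidity" %in% names(df))
      stop(sprintf("%s: missing 'humidity' column", basename(f)))
    if (!"time_s" %in% names(df))
      stop(sprintf("%s: missing 'time_s' column", basename(f)))
    if (is.unsorted(df$time_s, strictly = TRUE))
      stop(sprintf("%s: time_s is not strictly increasing", basename(f)))
    side_path <- sub("\\.csv$", ".json", f)
    if (!file.exists(side_path))
      stop(sprintf("%s: missing JSON sidecar", basename(f)))
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    ch_cols <- grep("^ch\\d+$", names(df), value = TRUE)
    resp <- as.matrix(df[, ch_cols])
    dimnames(resp) <- NULL
    if (any(side$phases < 1) || any(side$phases > nrow(resp)))
      stop(sprintf("%s: phase indices out of range", basename(f)))
    tryCatch(
      SensorRecording(response = resp, humidity = df$humidity,
                      label = side$label, phases = side$phases,
                      temperature = if ("temperature" %in% names(df))
                        df$temperature else numeric(0),
                      rate_hz = side$rate_hz,
                      meta = as.list(side$meta)),
      error = function(e)
        stop(sprintf("%s: %s", basename(f), conditionMessage(e))))
  })
}

#' Save / load a packed preprocessed dataset
#'
#' The arrays go into an \code{.rds}; a JSON manifest alongside records the
#' padded length, the standardization statistics and the pipeline version
#' so every number in downstream reports is reachable from the manifest.
#'
#' @param data a [PreprocessedDataset-class].
#' @param path output \code{.rds} path.
#' @return Invisibly, \code{path}.
#' @export
savePreprocessed <- function(data, path) {
  saveRDS(list(x = data@x, mask = data@mask, c = data@c, y = data@y,
               stats = data@stats, meta = data@meta), path)
  manifest <- list(L_max = data@stats$L_max,
                   humidity_mean = data@stats$humidity_mean,
                   humidity_sd = data@stats$humidity_sd,
                   n_samples = dim(data@x)[1],
                   n_channels = dim(data@x)[3],
                   pipeline = "ambient_normalize>truncate>pad",
                   version = as.character(utils::packageVersion("cirl")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname savePreprocessed
#' @export
loadPreprocessed <- function(path) {
  d <- readRDS(path)
  new("PreprocessedDataset", x = d$x, mask = d$mask, c = d$c, y = d$y,
      stats = d$stats, meta = d$meta)
}

# deterministic per-stage seed derivation from a master seed
deriveSeed <- function(master, stage) {
  stages <- c(simulate = 1L, shift = 2L, preprocess = 3L, train = 4L,
              evaluate = 5L, probe = 6L, search = 7L)
  as.integer((as.numeric(master) * 7919 + stages[[stage]]) %% 2147483647)
}
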
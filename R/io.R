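#' Read / write ROI time series matrices
#'
#' The on-disk format is a comma-separated numeric matrix (rows = ROIs,
#' columns = samples, no header, period decimal) with a sidecar JSON
#' file `<path>.json` holding `roi_labels`, `dt` and `participant_id`.
#' On read, rows are reordered to the canonical ROI ordering
#' ([ROI_LABELS]) when the labels match that set.
#'
#' @param path path of the matrix file.
#' @return [readROISeries()] returns an [ROITimeSeries-class];
#'   `writeROISeries()` returns `path` invisibly.
#' @export
readROISeries <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (!file.exists(side)) stop("sidecar JSON not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("roi_labels", "dt", "participant_id"))
    if (is.null(meta[[f]])) stop("sidecar missing required field '", f, "'")
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  dimnames(m) <- NULL
  labs <- as.character(meta$roi_labels)
  if (nrow(m) != length(labs))
    stop("matrix has ", nrow(m), " rows but sidecar lists ",
         length(labs), " roi_labels")
  if (setequal(labs, ROI_LABELS)) {
    ord <- match(ROI_LABELS, labs)
    m <- m[ord, , drop = FALSE]
    labs <- ROI_LABELS
  }
  ROITimeSeries(m, roiLabels = labs, dt = as.numeric(meta$dt),
                participantId = as.character(meta$participant_id))
}

#' @rdname readROISeries
#' @param ts an [ROITimeSeries-class] to write.
#' @export
writeROISeries <- function(ts, path) {
  stopifnot(methods::is(ts, "ROITimeSeries"))
  utils::write.table(signalValues(ts), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(roi_labels = roiLabels(ts),
                            dt = samplingInterval(ts),
                            participant_id = participantId(ts)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write raw EEG recordings (delimited form)
#'
#' Delimited channels-by-samples matrix with sidecar JSON (`fs`,
#' `participant_id`, `label`). The channel count must be 64 and the
#' sampling rate 250 or 500 Hz.
#'
#' @param path matrix file path.
#' @param n_channels required channel count (default 64).
#' @return [readRawEEG()] returns a [RawRecording-class];
#'   `writeRawEEG()` returns `path` invisibly.
#' @export
readRawEEG <- function(path, n_channels = 64L) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (!file.exists(side)) stop("sidecar JSON not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("fs", "participant_id", "label"))
    if (is.null(meta[[f]])) stop("sidecar missing required field '", f, "'")
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != n_channels)
    stop("expected ", n_channels, " channels, found ", nrow(m))
  fs <- as.numeric(meta$fs)
  if (!fs %in% c(250, 500))
    stop("unsupported sampling rate ", fs, " Hz; allowed: 250, 500")
  RawRecording(m, fs = fs, participantId = as.character(meta$participant_id),
               label = as.character(meta$label))
}

#' @rdname readRawEEG
#' @param rec a [RawRecording-class] to write.
#' @export
writeRawEEG <- function(rec, path) {
  stopifnot(methods::is(rec, "RawRecording"))
  utils::write.table(signalValues(rec), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(fs = samplingRate(rec),
                            participant_id = participantId(rec),
                            label = recordingLabel(rec)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
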
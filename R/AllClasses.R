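#' Canonical region-of-interest ordering
#'
#' The ten cortical parcels used throughout the package, in fixed order:
#' left/right frontal, central, parietal, temporal and occipital. Flow
#' matrices are always indexed transmitter (row) by receiver (column) in
#' this order.
#'
#' @export
ROI_LABELS <- c("LF", "RF", "LC", "RC", "LP", "RP", "LT", "RT", "LO", "RO")

#' ROITimeSeries: one participant's source-space recording
#'
#' Container for the region-of-interest (ROI) source time series of a
#' single participant: an \eqn{R \times N} numeric matrix whose row
#' \eqn{i} holds the summed source magnitude of ROI \eqn{i} at each
#' sample, together with the ROI labels, the sampling interval and a
#' participant identifier.
#'
#' @slot values numeric matrix, rows = ROIs, columns = samples.
#' @slot roiLabels character vector of unique ROI names, one per row.
#' @slot dt sampling interval in seconds per sample.
#' @slot participantId character scalar.
#'
#' @seealso [ROITimeSeries()] for the constructor, [ifrMatrix()].
#' @export
setClass("ROITimeSeries",
  representation(
    values = "matrix",
    roiLabels = "character",
    dt = "numeric",
    participantId = "character"
  )
)

setValidity("ROITimeSeries", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 ROIs (rows)")
  if (ncol(v) < 3L) msg <- c(msg, "need at least 3 samples (columns)")
  if (any(!is.finite(v))) msg <- c(msg, "'values' contains non-finite entries")
  if (length(object@roiLabels) != nrow(v))
    msg <- c(msg, sprintf("%d roiLabels for %d rows", length(object@roiLabels), nrow(v)))
  if (anyDuplicated(object@roiLabels))
    msg <- c(msg, "roiLabels must be unique")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "'dt' must be a single positive number")
  if (length(object@participantId) != 1L)
    msg <- c(msg, "'participantId' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an ROITimeSeries
#'
#' @param values numeric matrix, rows = ROIs, columns = samples.
#' @param roiLabels ROI names, one per row; defaults to [ROI_LABELS] when
#'   the matrix has ten rows, otherwise `"ROI1"..."ROIR"`.
#' @param dt sampling interval in seconds per sample (1/250 by default,
#'   i.e. 250 Hz source sampling).
#' @param participantId participant identifier.
#' @return An [ROITimeSeries-class] object.
#' @examples
#' x <- ROITimeSeries(matrix(rnorm(40), nrow = 4), dt = 0.004)
#' nROI(x)
#' @export
ROITimeSeries <- function(values, roiLabels = NULL, dt = 1 / 250,
                          participantId = "P0") {
  values <- as.matrix(values)
  if (is.null(roiLabels)) {
    roiLabels <- if (nrow(values) == length(ROI_LABELS)) ROI_LABELS
      else paste0("ROI", seq_len(nrow(values)))
  }
  rownames(values) <- roiLabels
  methods::new("ROITimeSeries", values = values, roiLabels = roiLabels,
               dt = dt, participantId = as.character(participantId))
}

#' FlowMatrix: normalized information flow rates for one participant
#'
#' An \eqn{R \times R} matrix of normalized Liang-Kleeman flow rates
#' \eqn{\tau_{i \to j}} (row = transmitter \eqn{i}, column = receiver
#' \eqn{j}). The diagonal is undefined and stored as `NA`; off-diagonal
#' entries may also be `NA` when a pair was degenerate (masked).
#'
#' @slot tau numeric matrix of \eqn{\tau} values with `NA` diagonal.
#' @slot roiLabels character vector of node names.
#' @slot participantId character scalar.
#'
#' @seealso [ifrMatrix()], [absTau()], [weightedDegrees()].
#' @export
setClass("FlowMatrix",
  representation(
    tau = "matrix",
    roiLabels = "character",
    participantId = "character"
  )
)

setValidity("FlowMatrix", function(object) {
  m <- object@tau
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "'tau' must be square")
  if (!all(is.na(diag(m)))) msg <- c(msg, "diagonal of 'tau' must be masked (NA)")
  off <- m[row(m) != col(m)]
  if (any(is.infinite(off))) msg <- c(msg, "off-diagonal tau must be finite or NA")
  if (length(object@roiLabels) != nrow(m))
    msg <- c(msg, "roiLabels length must match matrix dimension")
  if (length(msg)) msg else TRUE
})

#' Construct a FlowMatrix
#'
#' @param tau square numeric matrix; its diagonal is forced to `NA`.
#' @param roiLabels node names (defaults as in [ROITimeSeries()]).
#' @param participantId participant identifier.
#' @return A [FlowMatrix-class] object.
#' @export
FlowMatrix <- function(tau, roiLabels = NULL, participantId = "P0") {
  tau <- as.matrix(tau)
  diag(tau) <- NA_real_
  if (is.null(roiLabels)) {
    roiLabels <- if (nrow(tau) == length(ROI_LABELS)) ROI_LABELS
      else paste0("ROI", seq_len(nrow(tau)))
  }
  dimnames(tau) <- list(roiLabels, roiLabels)
  methods::new("FlowMatrix", tau = tau, roiLabels = roiLabels,
               participantId = as.character(participantId))
}

#' SyntheticCohort: ground-truth-known ROI dynamics for two groups
#'
#' A list of [ROITimeSeries-class] participants with group labels
#' (`"concussed-like"` or `"control-like"`) and, for each participant,
#' the generating coupling specification (drift matrix, noise, dt).
#'
#' @slot participants list of [ROITimeSeries-class].
#' @slot groupLabel character vector, one label per participant.
#' @slot truth list of per-participant generating specifications.
#' @export
setClass("SyntheticCohort",
  representation(
    participants = "list",
    groupLabel = "character",
    truth = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  n <- length(object@participants)
  if (n < 1L) msg <- c(msg, "cohort must contain at least one participant")
  if (length(object@groupLabel) != n)
    msg <- c(msg, "one group label per participant required")
  ok <- vapply(object@participants, methods::is, logical(1), "ROITimeSeries")
  if (!all(ok)) msg <- c(msg, "all participants must be ROITimeSeries")
  if (all(ok) && n > 1L) {
    rr <- vapply(object@participants, nROI, integer(1))
    dts <- vapply(object@participants, samplingInterval, numeric(1))
    if (length(unique(rr)) != 1L) msg <- c(msg, "participants differ in node count")
    if (length(unique(dts)) != 1L) msg <- c(msg, "participants differ in dt")
  }
  if (length(msg)) msg else TRUE
})

#' RawRecording: one multichannel raw EEG recording
#'
#' A 64-channel (by convention) raw EEG recording with its sampling rate,
#' participant id and class label (`"concussed"` or `"non-concussed"`).
#'
#' @slot signal numeric matrix, rows = channels, columns = samples.
#' @slot fs sampling rate in Hz.
#' @slot participantId character scalar.
#' @slot label character scalar class label.
#' @export
setClass("RawRecording",
  representation(
    signal = "matrix",
    fs = "numeric",
    participantId = "character",
    label = "character"
  )
)

setValidity("RawRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@signal)) msg <- c(msg, "'signal' must be numeric")
  if (length(object@fs) != 1L || !(object@fs > 0))
    msg <- c(msg, "'fs' must be a single positive rate in Hz")
  if (length(object@label) != 1L || length(object@participantId) != 1L)
    msg <- c(msg, "'participantId' and 'label' must be single strings")
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#'
#' @param signal channels-by-samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param participantId participant identifier.
#' @param label class label, `"concussed"` or `"non-concussed"`.
#' @return A [RawRecording-class] object.
#' @export
RawRecording <- function(signal, fs, participantId = "P0",
                         label = "non-concussed") {
  methods::new("RawRecording", signal = as.matrix(signal), fs = fs,
               participantId = as.character(participantId),
               label = as.character(label))
}
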
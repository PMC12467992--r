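#' @title Accessors for flowconn containers
#' @description Small generic accessors shared by the package's S4
#'   containers: number of nodes, node labels, sampling interval,
#'   participant identifier and the absolute flow matrix.
#' @param object a flowconn S4 object.
#' @return The corresponding slot value; `absTau()` returns the
#'   elementwise absolute \eqn{|\tau|} matrix (diagonal `NA`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nROI", function(object) standardGeneric("nROI"))

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))

#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(object) standardGeneric("samplingInterval"))

#' @rdname accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))

#' @rdname accessors
#' @export
setGeneric("absTau", function(object) standardGeneric("absTau"))

#' @rdname accessors
#' @export
setGeneric("tauMatrix", function(object) standardGeneric("tauMatrix"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("participants", function(object) standardGeneric("participants"))

#' @rdname accessors
setMethod("nROI", "ROITimeSeries", function(object) nrow(object@values))

#' @rdname accessors
setMethod("nROI", "FlowMatrix", function(object) nrow(object@tau))

#' @rdname accessors
setMethod("roiLabels", "ROITimeSeries", function(object) object@roiLabels)

#' @rdname accessors
setMethod("roiLabels", "FlowMatrix", function(object) object@roiLabels)

#' @rdname accessors
setMethod("samplingInterval", "ROITimeSeries", function(object) object@dt)

#' @rdname accessors
setMethod("participantId", "ROITimeSeries", function(object) object@participantId)

#' @rdname accessors
setMethod("participantId", "FlowMatrix", function(object) object@participantId)

#' @rdname accessors
setMethod("participantId", "RawRecording", function(object) object@participantId)

#' @rdname accessors
setMethod("tauMatrix", "FlowMatrix", function(object) object@tau)

#' @rdname accessors
setMethod("absTau", "FlowMatrix", function(object) abs(object@tau))

#' @rdname accessors
setMethod("groupLabels", "SyntheticCohort", function(object) object@groupLabel)

#' @rdname accessors
setMethod("participants", "SyntheticCohort", function(object) object@participants)

#' Extract the signal values of a recording
#'
#' @param object an [ROITimeSeries-class] or [RawRecording-class].
#' @return numeric matrix, rows = channels/ROIs, columns = samples.
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))

#' @rdname signalValues
setMethod("signalValues", "ROITimeSeries", function(object) object@values)

#' @rdname signalValues
setMethod("signalValues", "RawRecording", function(object) object@signal)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
setMethod("samplingRate", "RawRecording", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("recordingLabel", function(object) standardGeneric("recordingLabel"))

#' @rdname accessors
setMethod("recordingLabel", "RawRecording", function(object) object@label)

setMethod("show", "ROITimeSeries", function(object) {
  cat(sprintf("ROITimeSeries '%s': %d ROIs x %d samples, dt = %g s (%g Hz)\n",
              object@participantId, nrow(object@values), ncol(object@values),
              object@dt, 1 / object@dt))
  cat("  ROIs:", paste(object@roiLabels, collapse = " "), "\n")
})

setMethod("show", "FlowMatrix", function(object) {
  off <- abs(object@tau[row(object@tau) != col(object@tau)])
  cat(sprintf("FlowMatrix '%s': %d nodes, %d directed pairs\n",
              object@participantId, nrow(object@tau),
              sum(!is.na(off))))
  cat(sprintf("  |tau| range: [%.3g, %.3g], masked pairs: %d\n",
              suppressWarnings(min(off, na.rm = TRUE)),
              suppressWarnings(max(off, na.rm = TRUE)),
              sum(is.na(off))))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@groupLabel)
  cat(sprintf("SyntheticCohort: %d participants (%s)\n",
              length(object@participants),
              paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
})

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording '%s' [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@participantId, object@label, nrow(object@signal),
              ncol(object@signal), object@fs, ncol(object@signal) / object@fs))
})
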
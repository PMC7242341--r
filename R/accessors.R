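#' Accessors for EEG containers
#'
#' Small generic accessors shared by [EEGRecording-class] and
#' [EEGSegment-class]: subject id, cohort group, sampling rate, channel
#' labels, the raw signal matrix and its dimensions.
#'
#' @param object an \code{EEGRecording} or \code{EEGSegment}.
#' @return the corresponding slot value.
#' @name eeg-accessors
#' @examples
#' rec <- EEGRecording("s1", "contrast", 128, c("C3", "C4"),
#'                     matrix(0, 2, 128))
#' samplingRate(rec); nSamples(rec)
NULL

#' @rdname eeg-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname eeg-accessors
#' @export
setGeneric("subjectGroup", function(object) standardGeneric("subjectGroup"))
#' @rdname eeg-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname eeg-accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname eeg-accessors
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))
#' @rdname eeg-accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname eeg-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname eeg-accessors
setMethod("subjectId", "EEGRecording", function(object) object@subjectId)
#' @rdname eeg-accessors
setMethod("subjectGroup", "EEGRecording", function(object) object@group)
#' @rdname eeg-accessors
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname eeg-accessors
setMethod("channelLabels", "EEGRecording", function(object) object@channels)
#' @rdname eeg-accessors
setMethod("signalData", "EEGRecording", function(object) object@data)
#' @rdname eeg-accessors
setMethod("nChannels", "EEGRecording", function(object) nrow(object@data))
#' @rdname eeg-accessors
setMethod("nSamples", "EEGRecording", function(object) ncol(object@data))

#' @rdname eeg-accessors
setMethod("subjectId", "EEGSegment", function(object) object@recordingRef)
#' @rdname eeg-accessors
setMethod("subjectGroup", "EEGSegment", function(object) object@group)
#' @rdname eeg-accessors
setMethod("samplingRate", "EEGSegment", function(object) object@fs)
#' @rdname eeg-accessors
setMethod("channelLabels", "EEGSegment", function(object) object@channels)
#' @rdname eeg-accessors
setMethod("signalData", "EEGSegment", function(object) object@data)
#' @rdname eeg-accessors
setMethod("nChannels", "EEGSegment", function(object) nrow(object@data))
#' @rdname eeg-accessors
setMethod("nSamples", "EEGSegment", function(object) ncol(object@data))

#' @describeIn EEGSegment-class 0-based start sample of the excerpt.
#' @param object an \code{EEGSegment}.
#' @export
setGeneric("startSample", function(object) standardGeneric("startSample"))
#' @rdname EEGSegment-class
setMethod("startSample", "EEGSegment", function(object) object@startSample)

#' Band-set accessors
#'
#' @param object a [BandSet-class].
#' @return \code{nBands}: number of bands; \code{bandSignals}: the bands x
#'   samples matrix (low to high frequency); \code{bandRanges}: data.frame
#'   with \code{band_index}, \code{low_hz}, \code{high_hz}.
#' @name bandset-accessors
NULL

#' @rdname bandset-accessors
#' @export
setGeneric("nBands", function(object) standardGeneric("nBands"))
#' @rdname bandset-accessors
#' @export
setGeneric("bandSignals", function(object) standardGeneric("bandSignals"))
#' @rdname bandset-accessors
#' @export
setGeneric("bandRanges", function(object) standardGeneric("bandRanges"))

#' @rdname bandset-accessors
setMethod("nBands", "BandSet", function(object) object@levels + 1L)
#' @rdname bandset-accessors
setMethod("bandSignals", "BandSet", function(object) object@signals)
#' @rdname bandset-accessors
setMethod("bandRanges", "BandSet", function(object)
  data.frame(band_index = seq_len(object@levels + 1L),
             low_hz = object@lowHz, high_hz = object@highHz))

#' Coerce results to data.frame
#'
#' @param x an \code{RQAResult}, \code{MultiscaleCurve} or
#'   \code{RegionSummary}.
#' @param ... unused.
#' @name result-coercion
NULL

#' @rdname result-coercion
#' @export
setMethod("as.data.frame", "RQAResult", function(x, ...)
  data.frame(Lmax = x@lmax, Lmean = x@lmean, TT = x@tt, DET = x@det,
             LAM = x@lam, RR = x@rr, epsilon = x@epsilon))

#' @rdname result-coercion
#' @export
setMethod("as.data.frame", "MultiscaleCurve", function(x, ...)
  data.frame(measure = x@measure, sensor = x@sensor, group = x@group,
             band_index = seq_along(x@bandMeans), mean = x@bandMeans,
             ci_half_width = x@ciHalfWidth, n = x@nPerBand))

#' @rdname result-coercion
#' @export
setMethod("as.data.frame", "RegionSummary", function(x, ...)
  data.frame(measure = x@measure, F = x@fStatistic,
             df_between = x@dfBetween, df_within = x@dfWithin,
             p = x@pValue,
             t(as.matrix(x@cellMeans))))

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz\n",
              object@subjectId, object@group, nrow(object@data),
              ncol(object@data), object@fs))
  cat("  channels:", paste(object@channels, collapse = " "), "\n")
})

setMethod("show", "EEGSegment", function(object) {
  cat(sprintf(
    "EEGSegment of '%s' (%s): %d ch x %d samples @ %g Hz, start %d, seed %d\n",
    object@recordingRef, object@group, nrow(object@data),
    ncol(object@data), object@fs, object@startSample, object@selectionSeed))
})

setMethod("show", "BandSet", function(object) {
  cat(sprintf("BandSet: %d bands (%s, %d levels) of %d samples @ %g Hz\n",
              object@levels + 1L, object@wavelet, object@levels,
              ncol(object@signals), object@fs))
  cat("  nominal edges (Hz):",
      paste(sprintf("(%g,%g]", object@lowHz, object@highHz),
            collapse = " "), "\n")
})

setMethod("show", "RQAResult", function(object) {
  cat(sprintf(
    "RQAResult: Lmax=%g Lmean=%g TT=%g DET=%g LAM=%g RR=%g eps=%g\n",
    object@lmax, object@lmean, object@tt, object@det, object@lam,
    object@rr, object@epsilon))
})

setMethod("show", "MultiscaleCurve", function(object) {
  cat(sprintf("MultiscaleCurve %s @ %s (%s), %d bands\n", object@measure,
              object@sensor, object@group, length(object@bandMeans)))
  print(data.frame(mean = object@bandMeans, ci = object@ciHalfWidth,
                   n = object@nPerBand))
})

setMethod("show", "RegionSummary", function(object) {
  cat(sprintf("RegionSummary %s: F(%d, %d) = %.4g, p = %.3g\n",
              object@measure, object@dfBetween, object@dfWithin,
              object@fStatistic, object@pValue))
  print(object@cellMeans)
})

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage: %d sensors, %d centrotemporal (%s)\n",
              length(object@allSensors), length(object@ctSensors),
              paste(object@ctSensors, collapse = " ")))
})

#' Region-summary accessors
#'
#' @param object a [RegionSummary-class].
#' @name regionsummary-accessors
NULL

#' @rdname regionsummary-accessors
#' @export
setGeneric("fStatistic", function(object) standardGeneric("fStatistic"))
#' @rdname regionsummary-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname regionsummary-accessors
#' @export
setGeneric("cellMeans", function(object) standardGeneric("cellMeans"))
#' @rdname regionsummary-accessors
#' @export
setGeneric("regionCells", function(object) standardGeneric("regionCells"))

#' @rdname regionsummary-accessors
setMethod("fStatistic", "RegionSummary", function(object) object@fStatistic)
#' @rdname regionsummary-accessors
setMethod("pValue", "RegionSummary", function(object) object@pValue)
#' @rdname regionsummary-accessors
setMethod("cellMeans", "RegionSummary", function(object) object@cellMeans)
#' @rdname regionsummary-accessors
setMethod("regionCells", "RegionSummary", function(object) object@cells)
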
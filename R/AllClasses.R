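#' @import methods
NULL

#' Multichannel scalp EEG recording
#'
#' Container for one subject's EEG: a channels-by-samples signal matrix in
#' microvolts, the sampling rate, normalized 10-20 channel labels, and the
#' cohort label (\code{"case"} or \code{"contrast"}).
#'
#' @slot subjectId opaque subject identifier.
#' @slot group cohort label, one of \code{"case"}, \code{"contrast"}.
#' @slot fs sampling rate in Hz (positive scalar).
#' @slot channels ordered character vector of normalized channel labels.
#' @slot data numeric matrix, channels x samples, microvolts. Row order
#'   matches \code{channels}.
#'
#' @seealso [readEDFRecording()], [writeEDF()], [selectAwakeSegment()]
#' @export
setClass("EEGRecording",
  representation(
    subjectId = "character",
    group     = "character",
    fs        = "numeric",
    channels  = "character",
    data      = "matrix"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(object@group) != 1L || !object@group %in% c("case", "contrast"))
    msg <- c(msg, "group must be 'case' or 'contrast'")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar (Hz)")
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "nrow(data) must equal length(channels)")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique after normalization")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param subjectId subject identifier.
#' @param group \code{"case"} or \code{"contrast"}.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel labels (normalized with
#'   [normalizeChannelLabel()] unless \code{normalize = FALSE}).
#' @param data channels x samples numeric matrix (microvolts).
#' @param normalize normalize the channel labels (default \code{TRUE}).
#' @return an [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording("s1", "case", fs = 256,
#'                     channels = c("EEG C3-REF", "cz"),
#'                     data = matrix(rnorm(512), nrow = 2))
#' channelLabels(rec)
#' @export
EEGRecording <- function(subjectId, group, fs, channels, data,
                         normalize = TRUE) {
  if (normalize) channels <- vapply(channels, normalizeChannelLabel, "",
                                    USE.NAMES = FALSE)
  data <- as.matrix(data)
  rownames(data) <- channels
  new("EEGRecording", subjectId = as.character(subjectId),
      group = as.character(group), fs = as.numeric(fs),
      channels = channels, data = data)
}

#' Fixed-duration excerpt of a recording
#'
#' A per-channel excerpt of an [EEGRecording-class] with provenance: source
#' subject, start sample (0-based), duration, and the seed used to select it.
#'
#' @slot recordingRef subject id of the source recording.
#' @slot group cohort label inherited from the source.
#' @slot startSample 0-based start index into the source signal.
#' @slot durationS duration in seconds.
#' @slot selectionSeed integer seed that produced the start sample.
#' @slot fs sampling rate in Hz.
#' @slot channels normalized channel labels.
#' @slot data channels x (durationS * fs) matrix.
#' @export
setClass("EEGSegment",
  representation(
    recordingRef  = "character",
    group         = "character",
    startSample   = "integer",
    durationS     = "numeric",
    selectionSeed = "integer",
    fs            = "numeric",
    channels      = "character",
    data          = "matrix"
  )
)

setValidity("EEGSegment", function(object) {
  msg <- character()
  if (object@startSample < 0L) msg <- c(msg, "startSample must be >= 0")
  n <- object@durationS * object@fs
  if (abs(n - round(n)) > 1e-9)
    msg <- c(msg, "durationS * fs must be an integer sample count")
  if (ncol(object@data) != round(n))
    msg <- c(msg, "data must have durationS * fs columns")
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "nrow(data) must equal length(channels)")
  if (length(msg)) msg else TRUE
})

#' 10-20 scalp montage with a centrotemporal sensor set
#'
#' The 19 sensors of the standard 10-20 montage, the subset regarded as
#' centrotemporal (CT), and the alias map used to normalize raw labels
#' (legacy names T3/T4/T5/T6 map to T7/T8/P7/P8).
#'
#' @slot allSensors ordered character vector of the 19 montage labels.
#' @slot ctSensors subset of \code{allSensors} classified as centrotemporal.
#' @slot aliasMap named character vector, raw label -> normalized label.
#' @seealso [standardMontage()], [classifySensorRegion()]
#' @export
setClass("Montage",
  representation(
    allSensors = "character",
    ctSensors  = "character",
    aliasMap   = "character"
  )
)

setValidity("Montage", function(object) {
  msg <- character()
  if (!all(object@ctSensors %in% object@allSensors))
    msg <- c(msg, "ctSensors must be a subset of allSensors")
  if (anyDuplicated(object@allSensors))
    msg <- c(msg, "allSensors must be unique")
  if (length(msg)) msg else TRUE
})

#' Ordered frequency-band decomposition of one channel
#'
#' Result of [waveletBandDecompose()]: one time-domain signal per dyadic
#' frequency band, ordered low to high frequency, each the same length as
#' the input, summing exactly back to the input.
#'
#' @slot signals numeric matrix, (levels + 1) bands x n samples, row 1 the
#'   lowpass approximation band, last row the finest detail band.
#' @slot lowHz,highHz nominal band edges in Hz (dyadic partition of
#'   (0, fs/2]).
#' @slot fs sampling rate of the decomposed signal.
#' @slot wavelet decomposition filter used (\code{"shannon"} or a
#'   Daubechies family member).
#' @slot levels decomposition depth.
#' @export
setClass("BandSet",
  representation(
    signals = "matrix",
    lowHz   = "numeric",
    highHz  = "numeric",
    fs      = "numeric",
    wavelet = "character",
    levels  = "integer"
  )
)

setValidity("BandSet", function(object) {
  msg <- character()
  nb <- object@levels + 1L
  if (nrow(object@signals) != nb)
    msg <- c(msg, "signals must have levels + 1 rows")
  if (length(object@lowHz) != nb || length(object@highHz) != nb)
    msg <- c(msg, "band edges must have levels + 1 entries")
  if (length(msg)) msg else TRUE
})

#' Recurrence analysis configuration
#'
#' Parameters of the delay embedding, radius calibration and line-structure
#' statistics. Defaults: embedding dimension m = 3, delay tau = 1 sample, a
#' calibrated radius targeting recurrence rate 0.10, Euclidean norm, Theiler
#' exclusion of the line of identity only, and minimum line length 2 for both
#' diagonal and vertical structures.
#'
#' @slot m embedding dimension (>= 1).
#' @slot tau embedding delay in samples (>= 1).
#' @slot rrTarget target off-diagonal recurrence rate in (0, 1).
#' @slot norm distance norm: \code{"euclidean"}, \code{"chebyshev"} or
#'   \code{"manhattan"}.
#' @slot theilerW half-width of the excluded band around the line of
#'   identity. Diagonal offsets with |i - j| < theilerW are excluded from
#'   diagonal statistics; the line of identity itself is always excluded,
#'   so both 0 and 1 exclude exactly the main diagonal.
#' @slot lmin minimum diagonal line length counted (>= 2).
#' @slot vmin minimum vertical line length counted (>= 2).
#' @export
setClass("RecurrenceConfig",
  representation(m = "integer", tau = "integer", rrTarget = "numeric",
                 norm = "character", theilerW = "integer",
                 lmin = "integer", vmin = "integer")
)

setValidity("RecurrenceConfig", function(object) {
  msg <- character()
  if (object@m < 1L) msg <- c(msg, "m must be >= 1")
  if (object@tau < 1L) msg <- c(msg, "tau must be >= 1")
  if (object@rrTarget <= 0 || object@rrTarget >= 1)
    msg <- c(msg, "rrTarget must lie in (0, 1)")
  if (!object@norm %in% c("euclidean", "chebyshev", "manhattan"))
    msg <- c(msg, "norm must be euclidean, chebyshev or manhattan")
  if (object@theilerW < 0L) msg <- c(msg, "theilerW must be >= 0")
  if (object@lmin < 2L) msg <- c(msg, "lmin must be >= 2")
  if (object@vmin < 2L) msg <- c(msg, "vmin must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @rdname RecurrenceConfig-class
#' @param m,tau,rrTarget,norm,theilerW,lmin,vmin see slot documentation.
#' @return a \code{RecurrenceConfig} object.
#' @examples recurrenceConfig(m = 2, rrTarget = 0.05)
#' @export
recurrenceConfig <- function(m = 3, tau = 1, rrTarget = 0.10,
                             norm = "euclidean", theilerW = 1,
                             lmin = 2, vmin = 2) {
  new("RecurrenceConfig", m = as.integer(m), tau = as.integer(tau),
      rrTarget = as.numeric(rrTarget), norm = norm,
      theilerW = as.integer(theilerW), lmin = as.integer(lmin),
      vmin = as.integer(vmin))
}

#' Sample entropy configuration
#'
#' Template length m (default 2) and tolerance expressed as a multiple of
#' the signal standard deviation (default 0.2), with Chebyshev distance --
#' the canonical parameterization in the entropy literature.
#'
#' @slot m template length (>= 1).
#' @slot rFactor tolerance as a multiple of SD(x) (> 0).
#' @export
setClass("SampEnConfig",
  representation(m = "integer", rFactor = "numeric"))

setValidity("SampEnConfig", function(object) {
  msg <- character()
  if (object@m < 1L) msg <- c(msg, "m must be >= 1")
  if (object@rFactor <= 0) msg <- c(msg, "rFactor must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SampEnConfig-class
#' @param m,rFactor see slot documentation.
#' @return a \code{SampEnConfig} object.
#' @examples sampEnConfig(m = 2, rFactor = 0.2)
#' @export
sampEnConfig <- function(m = 2, rFactor = 0.2) {
  new("SampEnConfig", m = as.integer(m), rFactor = as.numeric(rFactor))
}

#' Recurrence quantification result
#'
#' Line-structure statistics of one recurrence matrix. Measures that are
#' undefined on the given matrix (no qualifying line) are \code{NA}, never
#' zero, except \code{lmax} which is 0 when no diagonal reaches the minimum
#' length.
#'
#' @slot lmax maximum diagonal line length (samples; 0 if none >= lmin).
#' @slot lmean mean diagonal line length over lines >= lmin (NA if none).
#' @slot tt trapping time: mean vertical line length over lines >= vmin
#'   (NA if none).
#' @slot det determinism: fraction of counted recurrence points lying on
#'   diagonal lines >= lmin.
#' @slot lam laminarity: fraction of recurrence points on vertical lines
#'   >= vmin.
#' @slot rr realized off-diagonal recurrence rate.
#' @slot epsilon the recurrence radius used (signal units).
#' @export
setClass("RQAResult",
  representation(lmax = "numeric", lmean = "numeric", tt = "numeric",
                 det = "numeric", lam = "numeric", rr = "numeric",
                 epsilon = "numeric"))

#' Per-sensor multiscale curve for one cohort
#'
#' Mean of a nonlinear measure per frequency band across the subjects of
#' one group at one sensor, with 95\% confidence half-widths.
#'
#' @slot measure measure name (e.g. \code{"SampE"}, \code{"TT"}).
#' @slot sensor normalized 10-20 label.
#' @slot group \code{"case"} or \code{"contrast"}.
#' @slot bandMeans per-band mean, ordered low to high frequency.
#' @slot ciHalfWidth per-band 95\% CI half-width (>= 0).
#' @slot nPerBand per-band number of contributing subjects.
#' @export
setClass("MultiscaleCurve",
  representation(measure = "character", sensor = "character",
                 group = "character", bandMeans = "numeric",
                 ciHalfWidth = "numeric", nPerBand = "integer"))

setValidity("MultiscaleCurve", function(object) {
  msg <- character()
  k <- length(object@bandMeans)
  if (length(object@ciHalfWidth) != k || length(object@nPerBand) != k)
    msg <- c(msg, "bandMeans, ciHalfWidth and nPerBand must share length")
  if (any(object@ciHalfWidth < 0, na.rm = TRUE))
    msg <- c(msg, "ciHalfWidth must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Four-cell region summary with one-way ANOVA
#'
#' Area-under-curve observations pooled into the four (group, region)
#' cells -- case/contrast crossed with centrotemporal (CT) / non-CT -- and
#' the classical one-way ANOVA over those cells.
#'
#' @slot measure measure name.
#' @slot cells named list of four numeric vectors of per-(subject, sensor)
#'   AUC observations.
#' @slot cellMeans named numeric vector of cell means.
#' @slot fStatistic ANOVA F statistic (MS_between / MS_within).
#' @slot dfBetween between-cells degrees of freedom (3).
#' @slot dfWithin within-cells degrees of freedom (n - 4).
#' @slot pValue exact p-value from the F distribution.
#' @export
setClass("RegionSummary",
  representation(measure = "character", cells = "list",
                 cellMeans = "numeric", fStatistic = "numeric",
                 dfBetween = "integer", dfWithin = "integer",
                 pValue = "numeric"))

setValidity("RegionSummary", function(object) {
  msg <- character()
  if (length(object@cells) != 4L) msg <- c(msg, "exactly 4 cells required")
  if (object@dfBetween != 3L) msg <- c(msg, "dfBetween must be 3")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Generative parameters of the synthetic 19-channel cohort: per-channel
#' signals are a mixture \code{(1 - w) * colored_noise(beta) + w * sine}
#' with both components standardized to unit variance, where the mixing
#' weight \code{w} controls signal regularity. Case subjects receive
#' \code{oscMix + ctDeficit} on centrotemporal channels and \code{oscMix}
#' elsewhere; contrast subjects receive \code{oscMix} everywhere. A higher
#' weight gives a more regular, lower-complexity signal, emulating the
#' reduced-complexity epileptogenic zone.
#'
#' @slot nCase,nContrast subjects per group (>= 1).
#' @slot fs sampling rate in Hz (default 256).
#' @slot durationS recording duration in seconds (default 60).
#' @slot beta spectral exponent of the 1/f^beta background noise (default 1).
#' @slot oscMix baseline oscillation mixing weight in [0, 1) (default 0.1).
#' @slot ctDeficit extra weight added on CT channels of case subjects
#'   (default 0.5, chosen from the [calibrateComplexityKnob()] sweep as the
#'   smallest deficit whose band-aggregated entropy response is decisively
#'   in the injected low-complexity direction).
#' @slot oscFreqHz oscillation frequency in Hz (default 9).
#' @slot jitterSD SD of the random weight perturbation drawn independently
#'   per subject x channel (default 0.02).
#' @slot phaseJitterSD per-sample SD of the oscillation's random-walk phase
#'   noise in radians (default 0.05), making the oscillation quasi-periodic.
#' @slot seed master seed; every signal is a deterministic function of it.
#' @export
setClass("SyntheticCohortSpec",
  representation(nCase = "integer", nContrast = "integer", fs = "numeric",
                 durationS = "numeric", beta = "numeric", oscMix = "numeric",
                 ctDeficit = "numeric", oscFreqHz = "numeric",
                 jitterSD = "numeric", phaseJitterSD = "numeric",
                 seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
  msg <- character()
  if (object@nCase < 1L || object@nContrast < 1L)
    msg <- c(msg, "nCase and nContrast must be >= 1")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
  if (object@oscMix < 0 || object@oscMix >= 1)
    msg <- c(msg, "oscMix must lie in [0, 1)")
  if (object@ctDeficit < 0) msg <- c(msg, "ctDeficit must be >= 0")
  if (object@oscMix + object@ctDeficit + 5 * object@jitterSD >= 1)
    msg <- c(msg, "oscMix + ctDeficit + jitter bound must stay below 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticCohortSpec-class
#' @param nCase,nContrast,fs,durationS,beta,oscMix,ctDeficit,oscFreqHz
#'   see slot documentation.
#' @param jitterSD,phaseJitterSD,seed see slot documentation.
#' @return a \code{SyntheticCohortSpec}.
#' @examples syntheticCohortSpec(nCase = 2, nContrast = 2, seed = 7)
#' @export
syntheticCohortSpec <- function(nCase = 10, nContrast = 10, fs = 256,
                                durationS = 60, beta = 1, oscMix = 0.1,
                                ctDeficit = 0.5, oscFreqHz = 9,
                                jitterSD = 0.02, phaseJitterSD = 0.05,
                                seed = 1L) {
  new("SyntheticCohortSpec", nCase = as.integer(nCase),
      nContrast = as.integer(nContrast), fs = as.numeric(fs),
      durationS = as.numeric(durationS), beta = as.numeric(beta),
      oscMix = as.numeric(oscMix), ctDeficit = as.numeric(ctDeficit),
      oscFreqHz = as.numeric(oscFreqHz), jitterSD = as.numeric(jitterSD),
      phaseJitterSD = as.numeric(phaseJitterSD), seed = as.integer(seed))
}

#' Pipeline run configuration
#'
#' All knobs of the extract/analyze stages: segment selection, band
#' decomposition, recurrence and entropy settings, the measures to compute,
#' and behaviour flags.
#'
#' @slot durationS segment duration in seconds (default 30).
#' @slot selectionSeed integer seed driving segment selection.
#' @slot wavelet,levels band decomposition settings (default db4, 6 levels).
#' @slot rqa a [RecurrenceConfig-class].
#' @slot sampen a [SampEnConfig-class].
#' @slot measures character vector among \code{"SampE"}, \code{"TT"},
#'   \code{"Lmax"}, \code{"Lmean"}, \code{"DET"}, \code{"LAM"}, \code{"RR"},
#'   \code{"DFA"}.
#' @slot analysisSamples number of leading samples of each band signal fed
#'   to the O(n^2) nonlinear kernels (default 2048; \code{Inf} uses the full
#'   segment).
#' @slot allowMissing tolerate unreadable recordings / absent montage
#'   channels with a warning instead of an error.
#' @slot artifactVeto reject candidate segments containing samples with
#'   |x| > 500 microvolts (default off; mirrors an unfiltered analysis).
#' @slot tCI use t-based rather than normal-approximation confidence
#'   intervals for multiscale curves.
#' @slot bonferroni apply Bonferroni correction across measures in the
#'   ANOVA output table (default off).
#' @export
setClass("RunConfig",
  representation(durationS = "numeric", selectionSeed = "integer",
                 wavelet = "character", levels = "integer",
                 rqa = "RecurrenceConfig", sampen = "SampEnConfig",
                 measures = "character", analysisSamples = "numeric",
                 allowMissing = "logical", artifactVeto = "logical",
                 tCI = "logical", bonferroni = "logical"))

setValidity("RunConfig", function(object) {
  msg <- character()
  bad <- setdiff(object@measures,
                 c("SampE", "TT", "Lmax", "Lmean", "DET", "LAM", "RR", "DFA"))
  if (length(bad))
    msg <- c(msg, paste("unknown measures:", paste(bad, collapse = ", ")))
  if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
  if (object@analysisSamples < 64)
    msg <- c(msg, "analysisSamples must be >= 64")
  if (length(msg)) msg else TRUE
})

#' @rdname RunConfig-class
#' @param durationS,selectionSeed,wavelet,levels,rqa,sampen,measures
#'   see slot documentation.
#' @param analysisSamples,allowMissing,artifactVeto,tCI,bonferroni
#'   see slot documentation.
#' @return a \code{RunConfig}.
#' @examples runConfig(measures = "SampE", analysisSamples = 512)
#' @export
runConfig <- function(durationS = 30, selectionSeed = 1L, wavelet = "shannon",
                      levels = 6, rqa = recurrenceConfig(),
                      sampen = sampEnConfig(),
                      measures = c("SampE", "TT", "Lmax", "Lmean"),
                      analysisSamples = 2048, allowMissing = FALSE,
                      artifactVeto = FALSE, tCI = FALSE,
                      bonferroni = FALSE) {
  new("RunConfig", durationS = as.numeric(durationS),
      selectionSeed = as.integer(selectionSeed), wavelet = wavelet,
      levels = as.integer(levels), rqa = rqa, sampen = sampen,
      measures = measures, analysisSamples = as.numeric(analysisSamples),
      allowMissing = allowMissing, artifactVeto = artifactVeto,
      tCI = tCI, bonferroni = bonferroni)
}
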
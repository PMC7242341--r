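#' Select a random fixed-duration segment from a recording
#'
#' Draws the segment start uniformly from the candidate starts on a
#' one-second grid in \code{[0, T - durationS]} (reproducible for a fixed
#' seed), and slices all channels. No filtering is applied to the signal.
#' With \code{vetoAmplitudeUV} set, candidate windows containing any sample
#' with \code{|x|} above the threshold are excluded before the draw
#' (off by default).
#'
#' @param rec an [EEGRecording-class].
#' @param durationS segment duration in seconds (default 30).
#' @param seed integer selection seed.
#' @param vetoAmplitudeUV optional amplitude veto threshold in microvolts;
#'   \code{NULL} (default) disables the veto.
#' @return an [EEGSegment-class].
#' @examples
#' rec <- EEGRecording("s1", "case", 64, c("C3", "C4"),
#'                     matrix(rnorm(2 * 64 * 60), 2))
#' seg <- selectAwakeSegment(rec, durationS = 30, seed = 7)
#' startSample(seg)
#' @export
selectAwakeSegment <- function(rec, durationS = 30, seed = 1L,
                               vetoAmplitudeUV = NULL) {
  fs <- rec@fs
  n <- ncol(rec@data)
  need <- durationS * fs
  if (abs(need - round(need)) > 1e-9)
    stop("durationS * fs must be an integer sample count", call. = FALSE)
  need <- as.integer(round(need))
  if (n < need)
    stop(sprintf(
      "recording too short: %.3f s available, %.3f s required",
      n / fs, durationS), call. = FALSE)
  lastStart <- n - need                      # in samples
  starts <- seq(0L, lastStart, by = as.integer(round(fs)))
  if (!is.null(vetoAmplitudeUV)) {
    ok <- vapply(starts, function(s0) {
      all(abs(rec@data[, (s0 + 1L):(s0 + need), drop = FALSE]) <=
            vetoAmplitudeUV)
    }, TRUE)
    if (!any(ok))
      stop("no candidate window passes the ", vetoAmplitudeUV,
           " uV amplitude veto", call. = FALSE)
    starts <- starts[ok]
  }
  s0 <- withSeed(seed, starts[sample.int(length(starts), 1L)])
  new("EEGSegment",
      recordingRef = rec@subjectId, group = rec@group,
      startSample = as.integer(s0), durationS = as.numeric(durationS),
      selectionSeed = as.integer(seed), fs = fs, channels = rec@channels,
      data = rec@data[, (s0 + 1L):(s0 + need), drop = FALSE])
}
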
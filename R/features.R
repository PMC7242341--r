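.MEASURE_NAMES <- c("SampE", "TT", "Lmax", "Lmean", "DET", "LAM", "RR",
                    "DFA")
.RQA_MEASURES <- c("TT", "Lmax", "Lmean", "DET", "LAM", "RR")

#' Nonlinear features of one segment, per sensor and frequency band
#'
#' Decomposes every montage channel of the segment into dyadic wavelet
#' bands and computes the requested nonlinear measures on each band signal,
#' returning long-format rows
#' \code{subject_id, group, sensor, region, band_index, band_low_hz,
#' band_high_hz, measure, value} (plus a \code{reason} column populated for
#' missing values). A measure that is undefined on one band yields a row
#' with \code{NA} and a reason, never an aborted extraction.
#'
#' Only the first \code{analysisSamples} samples of each band signal feed
#' the O(n^2) recurrence and entropy kernels; the decomposition itself uses
#' the full segment.
#'
#' @param seg an [EEGSegment-class].
#' @param config a [RunConfig-class] (measures, wavelet, levels, recurrence
#'   and entropy settings, analysis window).
#' @param montage a [Montage-class]; non-montage channels (e.g. ECG) are
#'   dropped with a message, absent montage channels raise an error unless
#'   \code{config@allowMissing}.
#' @param verbose emit progress messages.
#' @return data.frame of \code{n_sensors * n_bands * n_measures} rows.
#' @examples
#' rec <- EEGRecording("s1", "case", 128,
#'                     standardMontage()@allSensors,
#'                     matrix(rnorm(19 * 128 * 8), 19))
#' seg <- selectAwakeSegment(rec, 4, seed = 1)
#' ft <- featuresForSegment(seg, runConfig(measures = "SampE",
#'                                         analysisSamples = 256))
#' @export
featuresForSegment <- function(seg, config = runConfig(),
                               montage = standardMontage(),
                               verbose = FALSE) {
  measures <- config@measures
  stopifnot(all(measures %in% .MEASURE_NAMES))
  chans <- seg@channels
  extra <- setdiff(chans, montage@allSensors)
  if (length(extra))
    .logMsg("dropping non-montage channels: %s",
            paste(extra, collapse = ", "), verbose = verbose)
  absent <- setdiff(montage@allSensors, chans)
  if (length(absent)) {
    if (!config@allowMissing)
      stop("montage channels missing from segment: ",
           paste(absent, collapse = ", "),
           " (set allowMissing to drop them)", call. = FALSE)
    warning("montage channels missing, dropped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  use <- intersect(montage@allSensors, chans)
  nb <- config@levels + 1L
  rng <- bandFrequencyRanges(seg@fs, config@levels)
  needRqa <- any(measures %in% .RQA_MEASURES)
  rows <- vector("list", length(use))

  for (ci in seq_along(use)) {
    sensor <- use[ci]
    region <- classifySensorRegion(sensor, montage)
    bs <- waveletBandDecompose(seg@data[match(sensor, chans), ], seg@fs,
                               config@wavelet, config@levels)
    win <- seq_len(min(config@analysisSamples, ncol(bs@signals)))
    vals <- matrix(NA_real_, nb, length(measures),
                   dimnames = list(NULL, measures))
    reasons <- matrix(NA_character_, nb, length(measures))
    for (b in seq_len(nb)) {
      xb <- bs@signals[b, win]
      rqa <- NULL
      if (needRqa) {
        rqa <- tryCatch(rqaFromSignal(xb, config@rqa), error = identity)
      }
      for (mi in seq_along(measures)) {
        meas <- measures[mi]
        if (meas == "SampE") {
          v <- tryCatch(sampleEntropy(xb, config@sampen), error = identity)
        } else if (meas == "DFA") {
          v <- tryCatch(dfaAlpha(xb), error = identity)
        } else {
          v <- if (inherits(rqa, "error")) rqa else
            switch(meas, TT = rqa@tt, Lmax = rqa@lmax, Lmean = rqa@lmean,
                   DET = rqa@det, LAM = rqa@lam, RR = rqa@rr)
        }
        if (inherits(v, "error")) {
          reasons[b, mi] <- conditionMessage(v)
        } else if (is.na(v)) {
          reasons[b, mi] <- attr(v, "reason") %||% "undefined"
        } else {
          vals[b, mi] <- as.numeric(v)
        }
      }
    }
    rows[[ci]] <- data.frame(
      subject_id = seg@recordingRef, group = seg@group, sensor = sensor,
      region = region,
      band_index = rep(seq_len(nb), times = length(measures)),
      band_low_hz = rep(rng$low_hz, times = length(measures)),
      band_high_hz = rep(rng$high_hz, times = length(measures)),
      measure = rep(measures, each = nb),
      value = as.vector(vals), reason = as.vector(reasons),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  nMissing <- sum(is.na(out$value))
  if (nMissing)
    .logMsg("segment %s: %d of %d feature values missing",
            seg@recordingRef, nMissing, nrow(out), verbose = verbose)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a feature table as CSV
#'
#' Serializes the long-format feature table with columns
#' \code{subject_id,group,sensor,region,band_index,band_low_hz,
#' band_high_hz,measure,value}; missing values become empty fields. A
#' \code{# config_hash:} comment line is prepended when a hash is given.
#'
#' @param table feature-table data.frame.
#' @param path CSV path.
#' @param configHash optional hash string to record.
#' @export
writeFeatureTable <- function(table, path, configHash = NULL) {
  cols <- c("subject_id", "group", "sensor", "region", "band_index",
            "band_low_hz", "band_high_hz", "measure", "value")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(configHash))
    writeLines(paste0("# config_hash: ", configHash), con)
  utils::write.csv(table[cols], con, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
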
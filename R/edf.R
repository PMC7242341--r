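# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores a fixed 256-byte ASCII header, 256 ASCII bytes per signal of
# per-signal metadata, then data records of 16-bit little-endian integers
# that map linearly from the digital to the physical (microvolt) range.
# The writer emits one-second data records; the reader accepts any record
# duration. No R EDF package is available, so both directions are
# implemented here and round-trip plus external-reader checks live in the
# test suite.

.edfPad <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width)
    stop("EDF field too wide: '", s, "' (max ", width, ")", call. = FALSE)
  formatC(s, width = -width)
}

# format a number into <= `width` ASCII chars
.edfNum <- function(x, width = 8) {
  for (digits in 7:1) {
    s <- formatC(signif(x, digits), format = "g", width = -1)
    if (nchar(s) <= width) return(.edfPad(s, width))
  }
  stop("cannot format ", x, " into ", width, " EDF chars", call. = FALSE)
}

#' Write a recording to an EDF file
#'
#' Emits a plain EDF file with one-second data records, 16-bit samples and
#' per-channel symmetric physical calibration spanning the channel's
#' observed amplitude range. The sample count must be a whole number of
#' seconds. Output is byte-deterministic (fixed header dates), so identical
#' recordings produce identical files.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @param rawLabels optional character vector of labels to store verbatim
#'   (defaults to the recording's normalized labels).
#' @param samplesPerRecord optional per-channel samples-per-record override
#'   (defaults to \code{fs} for every channel); used mainly to exercise
#'   mixed-rate error handling.
#' @return \code{path}, invisibly.
#' @seealso [readEDFRecording()]
#' @export
writeEDF <- function(rec, path, rawLabels = NULL, samplesPerRecord = NULL) {
  fs <- rec@fs
  x <- rec@data
  nch <- nrow(x)
  if (is.null(rawLabels)) rawLabels <- rec@channels
  if (is.null(samplesPerRecord)) samplesPerRecord <- rep(fs, nch)
  if (any(abs(samplesPerRecord - round(samplesPerRecord)) > 1e-9))
    stop("samples per one-second record must be integer (fs = ", fs, ")",
         call. = FALSE)
  samplesPerRecord <- as.integer(round(samplesPerRecord))
  ndr <- ncol(x) / fs
  if (abs(ndr - round(ndr)) > 1e-9)
    stop("EDF writer requires a whole number of seconds (",
         ncol(x), " samples at ", fs, " Hz)", call. = FALSE)
  ndr <- as.integer(round(ndr))

  pmax <- apply(x, 1, function(ch) max(abs(ch), 1e-6))
  pmin <- -pmax
  dmax <- 32767; dmin <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(.edfPad("0", 8))                                   # version
  wr(.edfPad(paste0("X X X ", rec@subjectId), 80))      # patient id
  wr(.edfPad(paste0("Startdate 01-JAN-2000 ", rec@subjectId), 80))
  wr(.edfPad("01.01.00", 8))                            # start date
  wr(.edfPad("00.00.00", 8))                            # start time
  wr(.edfPad(256L * (nch + 1L), 8))                     # header bytes
  wr(.edfPad("", 44))                                   # reserved
  wr(.edfPad(ndr, 8))                                   # n data records
  wr(.edfPad(1L, 8))                                    # record duration (s)
  wr(.edfPad(nch, 4))                                   # n signals
  for (lab in rawLabels) wr(.edfPad(lab, 16))
  for (i in seq_len(nch)) wr(.edfPad("", 80))           # transducer
  for (i in seq_len(nch)) wr(.edfPad("uV", 8))          # physical dimension
  for (i in seq_len(nch)) wr(.edfNum(pmin[i]))
  for (i in seq_len(nch)) wr(.edfNum(pmax[i]))
  for (i in seq_len(nch)) wr(.edfPad(dmin, 8))
  for (i in seq_len(nch)) wr(.edfPad(dmax, 8))
  for (i in seq_len(nch)) wr(.edfPad("", 80))           # prefiltering
  for (i in seq_len(nch)) wr(.edfPad(samplesPerRecord[i], 8))
  for (i in seq_len(nch)) wr(.edfPad("", 32))           # reserved

  # digital conversion (rounded, clamped to the 16-bit range)
  dig <- lapply(seq_len(nch), function(i) {
    d <- round((x[i, ] - pmin[i]) / (pmax[i] - pmin[i]) *
                 (dmax - dmin) + dmin)
    as.integer(pmin(pmax(d, dmin), dmax))
  })
  for (r in seq_len(ndr)) {
    for (i in seq_len(nch)) {
      spr <- samplesPerRecord[i]
      idx <- ((r - 1L) * spr + 1L):(r * spr)
      idx <- idx[idx <= length(dig[[i]])]
      smp <- dig[[i]][idx]
      if (length(smp) < spr) smp <- c(smp, rep(0L, spr - length(smp)))
      writeBin(smp, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses an EDF/EDF+ file, converts every signal to physical units using
#' its stored calibration, drops annotation channels, normalizes channel
#' labels to 10-20 form and returns an [EEGRecording-class]. Channels whose
#' sampling rates differ are rejected (no resampling).
#'
#' @param path EDF file path.
#' @param subjectId subject identifier to attach.
#' @param group cohort label, \code{"case"} or \code{"contrast"}.
#' @param montage montage supplying the alias map for label normalization.
#' @return an [EEGRecording-class].
#' @examples
#' rec <- EEGRecording("s1", "case", 128, c("C3", "C4"),
#'                     matrix(sin(seq_len(256) / 5), 2, 128, byrow = TRUE))
#' f <- tempfile(fileext = ".edf")
#' writeEDF(rec, f)
#' rec2 <- readEDFRecording(f, "s1", "case")
#' @export
readEDFRecording <- function(path, subjectId, group,
                             montage = standardMontage()) {
  if (!file.exists(path))
    stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0L || nchar(s, type = "bytes") < n)
      stop("corrupt or truncated EDF file: ", path, call. = FALSE)
    s
  }
  rdNum <- function(n, what) {
    v <- suppressWarnings(as.numeric(trimws(rd(n))))
    if (is.na(v))
      stop("corrupt EDF header (", what, ") in file: ", path, call. = FALSE)
    v
  }
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids, date, time
  rdNum(8, "header bytes")
  rd(44)
  ndr <- rdNum(8, "record count")
  recDur <- rdNum(8, "record duration")
  ns <- as.integer(rdNum(4, "signal count"))
  if (ns < 1L)
    stop("EDF file has no signals: ", path, call. = FALSE)
  labs <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin <- vapply(seq_len(ns), function(i) rdNum(8, "physical min"), 0)
  pmax <- vapply(seq_len(ns), function(i) rdNum(8, "physical max"), 0)
  dmin <- vapply(seq_len(ns), function(i) rdNum(8, "digital min"), 0)
  dmax <- vapply(seq_len(ns), function(i) rdNum(8, "digital max"), 0)
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) rdNum(8, "samples per record"), 0)
  for (i in seq_len(ns)) rd(32)

  isAnn <- grepl("annotation", labs, ignore.case = TRUE)
  keep <- which(!isAnn)
  if (!length(keep))
    stop("EDF file contains only annotation channels: ", path, call. = FALSE)
  fsAll <- spr[keep] / recDur
  if (length(unique(fsAll)) > 1L)
    stop("channels have differing sampling rates (",
         paste(unique(fsAll), collapse = ", "),
         " Hz); resampling is not performed: ", path, call. = FALSE)
  fs <- fsAll[1]

  perRec <- as.integer(sum(spr))
  raw <- readBin(con, integer(), n = perRec * ndr, size = 2L,
                 endian = "little")
  if (length(raw) < perRec * ndr)
    stop("corrupt or truncated EDF data section: ", path, call. = FALSE)
  offs <- c(0, cumsum(spr))
  sig <- matrix(0, nrow = length(keep), ncol = spr[keep[1]] * ndr)
  for (r in seq_len(ndr)) {
    base <- (r - 1L) * perRec
    for (k in seq_along(keep)) {
      i <- keep[k]
      d <- raw[(base + offs[i] + 1L):(base + offs[i + 1L])]
      phys <- (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) +
        pmin[i]
      sig[k, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  EEGRecording(subjectId = subjectId, group = group, fs = fs,
               channels = vapply(labs[keep], normalizeChannelLabel, "",
                                 montage = montage, USE.NAMES = FALSE),
               data = sig, normalize = FALSE)
}

#' Read / write a cohort manifest
#'
#' The manifest is a CSV with header \code{subject_id,group,edf_path} and
#' \code{group} in \{case, contrast\}.
#'
#' @param path CSV path.
#' @return \code{readCohortManifest}: data.frame with those three columns.
#' @export
readCohortManifest <- function(path) {
  if (!file.exists(path))
    stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "edf_path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(m$group), c("case", "contrast"))
  if (length(bad))
    stop("manifest group labels must be case/contrast; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  # EDF paths may be stored relative to the manifest's directory
  rel <- !file.exists(m$edf_path) &
    file.exists(file.path(dirname(path), m$edf_path))
  m$edf_path[rel] <- file.path(dirname(path), m$edf_path[rel])
  m[need]
}

#' @rdname readCohortManifest
#' @param manifest data.frame with columns subject_id, group, edf_path.
#' @export
writeCohortManifest <- function(manifest, path) {
  utils::write.csv(manifest[c("subject_id", "group", "edf_path")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
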
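# 10-20 montage handling: label normalization, centrotemporal
# classification, montage construction.

.MONTAGE_19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                 "T7", "C3", "Cz", "C4", "T8",
                 "P7", "P3", "Pz", "P4", "P8", "O1", "O2")

.CT_SENSORS <- c("C3", "C4", "Cz", "T7", "T8", "P7", "P8")

# legacy 10-20 nomenclature -> modern labels
.LEGACY_ALIASES <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Standard 19-sensor 10-20 montage
#'
#' The 19 sensors of the standard 10-20 system with the centrotemporal set
#' C3, C4, Cz, T7, T8, P7, P8 (covering the epileptogenic zone of
#' centrotemporal-spike epilepsy) and the legacy alias map
#' T3/T4/T5/T6 -> T7/T8/P7/P8.
#'
#' @param ctSensors override of the centrotemporal set.
#' @param aliases extra raw-label -> normalized-label aliases, merged over
#'   the legacy defaults.
#' @return a [Montage-class] object.
#' @examples
#' m <- standardMontage()
#' classifySensorRegion("T3", m)   # legacy label, maps to T7 -> "CT"
#' @export
standardMontage <- function(ctSensors = .CT_SENSORS, aliases = character()) {
  am <- .LEGACY_ALIASES
  if (length(aliases)) am[names(aliases)] <- aliases
  new("Montage", allSensors = .MONTAGE_19, ctSensors = ctSensors,
      aliasMap = am)
}

#' Read a montage override from JSON
#'
#' Accepts a JSON object with optional keys \code{ct_sensors} (array of
#' labels) and \code{aliases} (object raw -> normalized).
#'
#' @param path JSON file path.
#' @return a [Montage-class].
#' @export
montageFromJSON <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  ct <- if (!is.null(spec$ct_sensors)) as.character(spec$ct_sensors)
        else .CT_SENSORS
  al <- if (!is.null(spec$aliases)) unlist(spec$aliases) else character()
  standardMontage(ctSensors = ct, aliases = al)
}

#' Normalize a raw EEG channel label to its 10-20 form
#'
#' Strips the \code{"EEG "} prefix and reference suffixes
#' (\code{-REF}, \code{-LE}, \code{-A1}, \code{-A2}), fixes case
#' (\code{"cz"} -> \code{"Cz"}), and maps legacy names (T3 -> T7, T4 -> T8,
#' T5 -> P7, T6 -> P8). Labels that are not 10-20 sensors (e.g. "ECG")
#' pass through unchanged and are excluded from montage analyses
#' downstream.
#'
#' @param raw raw channel label from an EDF header.
#' @param montage montage providing the alias map.
#' @return normalized label (single string).
#' @examples
#' normalizeChannelLabel("EEG T3-REF")  # "T7"
#' normalizeChannelLabel("cz")          # "Cz"
#' @export
normalizeChannelLabel <- function(raw, montage = standardMontage()) {
  lab <- trimws(raw)
  lab <- sub("^EEG[ _]+", "", lab, ignore.case = TRUE)
  lab <- sub("-(REF|LE|A1|A2)$", "", lab, ignore.case = TRUE)
  lab <- trimws(lab)
  # canonical case via the montage list (plus legacy names)
  known <- c(montage@allSensors, names(montage@aliasMap))
  hit <- match(toupper(lab), toupper(known))
  if (!is.na(hit)) lab <- known[hit]
  if (lab %in% names(montage@aliasMap)) lab <- montage@aliasMap[[lab]]
  lab
}

#' Classify a sensor as centrotemporal or not
#'
#' @param label normalized 10-20 label (normalize first with
#'   [normalizeChannelLabel()]).
#' @param montage a [Montage-class].
#' @return \code{"CT"} if the label belongs to the montage's centrotemporal
#'   set, else \code{"nonCT"}.
#' @examples
#' classifySensorRegion("C3")  # "CT"
#' classifySensorRegion("F3")  # "nonCT"
#' @export
classifySensorRegion <- function(label, montage = standardMontage()) {
  if (!label %in% montage@allSensors)
    stop("sensor '", label, "' is not part of the montage", call. = FALSE)
  if (label %in% montage@ctSensors) "CT" else "nonCT"
}
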
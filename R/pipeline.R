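# Orchestration: simulate -> extract -> analyze, with JSON configs, a
# config fingerprint in every output CSV, and a run-metadata file holding
# seeds and per-subject segment provenance.

.configAsList <- function(config) {
  list(durationS = config@durationS, selectionSeed = config@selectionSeed,
       wavelet = config@wavelet, levels = config@levels,
       rqa = list(m = config@rqa@m, tau = config@rqa@tau,
                  rrTarget = config@rqa@rrTarget, norm = config@rqa@norm,
                  theilerW = config@rqa@theilerW, lmin = config@rqa@lmin,
                  vmin = config@rqa@vmin),
       sampen = list(m = config@sampen@m, rFactor = config@sampen@rFactor),
       measures = config@measures,
       analysisSamples = config@analysisSamples,
       allowMissing = config@allowMissing,
       artifactVeto = config@artifactVeto, tCI = config@tCI,
       bonferroni = config@bonferroni)
}

#' Serialize / deserialize a run configuration
#'
#' @param config a [RunConfig-class].
#' @param path JSON file path.
#' @return \code{readRunConfig} returns a [RunConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(.configAsList(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  runConfig(durationS = j$durationS %||% 30,
            selectionSeed = j$selectionSeed %||% 1L,
            wavelet = j$wavelet %||% "shannon", levels = j$levels %||% 6,
            rqa = do.call(recurrenceConfig, as.list(j$rqa %||% list())),
            sampen = do.call(sampEnConfig, as.list(j$sampen %||% list())),
            measures = j$measures %||% c("SampE", "TT", "Lmax", "Lmean"),
            analysisSamples = j$analysisSamples %||% 2048,
            allowMissing = j$allowMissing %||% FALSE,
            artifactVeto = j$artifactVeto %||% FALSE,
            tCI = j$tCI %||% FALSE, bonferroni = j$bonferroni %||% FALSE)
}

#' Fingerprint of a run configuration
#'
#' FNV-1a hash of the canonical JSON form; recorded as a comment line in
#' every output CSV so outputs name the configuration that produced them.
#'
#' @param config a [RunConfig-class].
#' @return 8-hex-digit hash string.
#' @export
configHash <- function(config) {
  fnv1aHash(jsonlite::toJSON(.configAsList(config), auto_unbox = TRUE,
                             digits = NA))
}

.writeHashedCSV <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Extract features for a whole cohort
#'
#' Reads (or takes) each recording, selects one awake segment per subject
#' with a per-subject seed derived from \code{config@selectionSeed}, and
#' stacks the per-segment feature rows. Unreadable recordings abort unless
#' \code{config@allowMissing}, in which case they are logged and skipped.
#'
#' @param manifest data.frame \code{subject_id, group, edf_path}; ignored
#'   when \code{recordings} is given.
#' @param config a [RunConfig-class].
#' @param recordings optional list of [EEGRecording-class] objects to use
#'   directly (in-memory path, bypassing EDF files).
#' @param montage a [Montage-class].
#' @param verbose emit per-subject progress messages.
#' @return list with \code{features} (data.frame), \code{provenance}
#'   (per-subject start sample and seed), \code{skipped} (subject ids).
#' @export
extractCohortFeatures <- function(manifest = NULL, config = runConfig(),
                                  recordings = NULL,
                                  montage = standardMontage(),
                                  verbose = FALSE) {
  if (is.null(recordings)) {
    if (is.null(manifest)) stop("need a manifest or recordings",
                                call. = FALSE)
    ids <- manifest$subject_id
  } else {
    ids <- vapply(recordings, subjectId, "")
  }
  feats <- list(); prov <- list(); skipped <- character()
  for (i in seq_along(ids)) {
    rec <- if (!is.null(recordings)) recordings[[i]] else
      tryCatch(readEDFRecording(manifest$edf_path[i], manifest$subject_id[i],
                                manifest$group[i], montage),
               error = identity)
    if (inherits(rec, "error")) {
      if (!config@allowMissing)
        stop("failed to read recording for subject ", ids[i], ": ",
             conditionMessage(rec), call. = FALSE)
      warning("skipping subject ", ids[i], ": ", conditionMessage(rec),
              call. = FALSE)
      skipped <- c(skipped, ids[i])
      next
    }
    segSeed <- deriveSeed(config@selectionSeed, i)
    t0 <- proc.time()[3]
    seg <- selectAwakeSegment(
      rec, config@durationS, segSeed,
      vetoAmplitudeUV = if (config@artifactVeto) 500 else NULL)
    feats[[length(feats) + 1L]] <-
      featuresForSegment(seg, config, montage, verbose = FALSE)
    prov[[length(prov) + 1L]] <-
      data.frame(subject_id = ids[i], start_sample = seg@startSample,
                 selection_seed = segSeed, stringsAsFactors = FALSE)
    .logMsg("extracted %s (%.1f s)", ids[i], proc.time()[3] - t0,
            verbose = verbose)
  }
  if (!length(feats))
    stop("no subjects could be extracted", call. = FALSE)
  list(features = do.call(rbind, feats),
       provenance = do.call(rbind, prov), skipped = skipped)
}

#' Analyze a feature table
#'
#' For every measure present: the per-sensor multiscale curves of both
#' groups, the per-observation AUC table, the four-cell region ANOVA and
#' the per-sensor heatmap table, written as
#' \code{curves_<measure>.csv}, \code{auc_<measure>.csv},
#' \code{anova_<measure>.csv}, \code{heatmap_<measure>.csv}.
#'
#' @param features long-format feature table.
#' @param outDir output directory.
#' @param config a [RunConfig-class].
#' @param montage a [Montage-class].
#' @param verbose emit progress messages.
#' @return (invisibly) named list of [RegionSummary-class] per measure.
#' @export
analyzeFeatures <- function(features, outDir, config = runConfig(),
                            montage = standardMontage(), verbose = FALSE) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  hash <- configHash(config)
  measures <- intersect(.MEASURE_NAMES, unique(features$measure))
  summaries <- list()
  pAll <- numeric(0)
  for (meas in measures) {
    curves <- list()
    for (sensor in intersect(montage@allSensors,
                             unique(features$sensor))) {
      for (grp in intersect(c("case", "contrast"),
                            unique(features$group))) {
        cv <- tryCatch(
          multiscaleGroupCurve(features, meas, sensor, grp,
                               ci = if (config@tCI) "t" else "normal"),
          error = identity)
        if (!inherits(cv, "error"))
          curves[[length(curves) + 1L]] <- as.data.frame(cv)
      }
    }
    .writeHashedCSV(do.call(rbind, curves),
                    file.path(outDir, paste0("curves_", meas, ".csv")),
                    hash)
    auc <- suppressWarnings(subjectSensorAUC(features, meas))
    .writeHashedCSV(auc, file.path(outDir, paste0("auc_", meas, ".csv")),
                    hash)
    rs <- tryCatch(regionANOVA(features, meas), error = identity)
    if (!inherits(rs, "error")) {
      summaries[[meas]] <- rs
      pAll[meas] <- rs@pValue
      .writeHashedCSV(as.data.frame(rs),
                      file.path(outDir, paste0("anova_", meas, ".csv")),
                      hash)
    } else {
      .logMsg("ANOVA unavailable for %s: %s", meas, conditionMessage(rs),
              verbose = verbose)
    }
    hm <- tryCatch(
      heatmapTable(features, meas, montage,
                   allowMissing = config@allowMissing),
      error = identity)
    if (!inherits(hm, "error"))
      .writeHashedCSV(hm, file.path(outDir, paste0("heatmap_", meas,
                                                   ".csv")), hash)
    .logMsg("analyzed %s", meas, verbose = verbose)
  }
  if (config@bonferroni && length(pAll)) {
    adj <- data.frame(measure = names(pAll), p = unname(pAll),
                      p_bonferroni = stats::p.adjust(unname(pAll),
                                                     "bonferroni"))
    .writeHashedCSV(adj, file.path(outDir, "anova_adjusted.csv"), hash)
  }
  invisible(summaries)
}

#' Run the pipeline
#'
#' Stages: \code{"simulate"} (synthetic cohort to EDF + manifest),
#' \code{"extract"} (manifest to feature table CSV), \code{"analyze"}
#' (feature table to curve/AUC/ANOVA/heatmap CSVs), or \code{"all"}.
#' Every stage writes \code{run_metadata.json} with the configuration
#' echo, its hash, seeds and per-subject segment provenance; identical
#' configurations and seeds reproduce every output byte for byte.
#'
#' @param stage one of \code{"simulate"}, \code{"extract"},
#'   \code{"analyze"}, \code{"all"}.
#' @param outDir output directory.
#' @param spec a [SyntheticCohortSpec-class] (simulate/all).
#' @param manifest manifest path or data.frame (extract; defaults to the
#'   simulated cohort for \code{"all"}).
#' @param features feature-table path or data.frame (analyze).
#' @param config a [RunConfig-class].
#' @param montage a [Montage-class].
#' @param verbose logging (default TRUE).
#' @return (invisibly) the output directory.
#' @examples
#' \donttest{
#' out <- runPipeline("all", tempfile(),
#'                    spec = syntheticCohortSpec(2, 2, seed = 1),
#'                    config = runConfig(measures = "SampE",
#'                                       analysisSamples = 512))
#' }
#' @export
runPipeline <- function(stage = c("all", "simulate", "extract", "analyze"),
                        outDir, spec = NULL, manifest = NULL,
                        features = NULL, config = runConfig(),
                        montage = standardMontage(), verbose = TRUE) {
  stage <- match.arg(stage)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  hash <- configHash(config)
  meta <- list(package_version = as.character(utils::packageVersion("eegrqa")),
               config = .configAsList(config), config_hash = hash)

  if (stage %in% c("simulate", "all")) {
    if (is.null(spec)) stop("stage '", stage, "' needs a cohort spec",
                            call. = FALSE)
    .logMsg("simulating %d + %d subjects", spec@nCase, spec@nContrast,
            verbose = verbose)
    sim <- generateCohort(spec, dir = file.path(outDir, "edf"),
                          montage = montage, verbose = verbose)
    manifest <- sim$manifest
    meta$cohort_seed <- spec@seed
  }
  if (stage %in% c("extract", "all")) {
    if (is.character(manifest)) manifest <- readCohortManifest(manifest)
    if (is.null(manifest)) stop("stage '", stage, "' needs a manifest",
                                call. = FALSE)
    ex <- extractCohortFeatures(manifest, config, montage = montage,
                                verbose = verbose)
    writeFeatureTable(ex$features, file.path(outDir, "features.csv"),
                      configHash = hash)
    features <- ex$features
    meta$segments <- ex$provenance
    meta$skipped_subjects <- ex$skipped
    meta$n_subjects_extracted <- length(unique(ex$features$subject_id))
    if (length(ex$skipped))
      .logMsg("skipped %d unreadable subject(s)", length(ex$skipped),
              verbose = verbose)
  }
  if (stage %in% c("analyze", "all")) {
    if (is.character(features)) features <- readFeatureTable(features)
    if (is.null(features)) stop("stage '", stage, "' needs features",
                                call. = FALSE)
    analyzeFeatures(features, outDir, config, montage, verbose = verbose)
  }
  jsonlite::write_json(meta, file.path(outDir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
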
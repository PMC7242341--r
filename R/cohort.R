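# Synthetic 19-channel EEG-like cohort generator. Each channel mixes
# 1/f^beta colored noise with a quasi-periodic (phase-jittered) sine; the
# mixing weight is the ground-truth complexity knob: more oscillation means
# a more regular, lower-complexity signal. Case subjects carry an extra
# weight on centrotemporal channels only, giving a region-localized
# complexity deficit with a known direction and location.

# 1/f^beta noise via frequency-domain synthesis: random phases, amplitude
# proportional to f^(-beta/2); standardized to zero mean, unit SD.
.coloredNoise <- function(n, beta) {
  nf <- n %/% 2
  amp <- (seq_len(nf))^(-beta / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = rep(0, n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Mod(spec[nf]))     # Nyquist bin real
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE))
  (x - mean(x)) / stats::sd(x)
}

# quasi-periodic oscillation: sine with random-walk phase noise, unit SD
.jitteredSine <- function(n, fs, freqHz, phaseJitterSD) {
  ph <- 2 * pi * freqHz * (0:(n - 1)) / fs +
    cumsum(stats::rnorm(n, 0, phaseJitterSD))
  x <- sin(ph)
  (x - mean(x)) / stats::sd(x)
}

#' Generate one synthetic EEG-like channel signal
#'
#' \code{x = (1 - w) * coloredNoise(beta) + w * jitteredSine}, both
#' components standardized to unit variance before mixing. Deterministic
#' for a fixed seed.
#'
#' @param fs sampling rate in Hz.
#' @param durationS duration in seconds.
#' @param beta spectral exponent of the noise component.
#' @param mixWeight oscillation weight w in [0, 1).
#' @param oscFreqHz oscillation frequency in Hz.
#' @param phaseJitterSD per-sample phase random-walk SD (radians).
#' @param seed integer seed.
#' @return numeric vector of \code{fs * durationS} samples.
#' @examples
#' x <- generateChannelSignal(256, 4, mixWeight = 0.3, seed = 1)
#' @export
generateChannelSignal <- function(fs, durationS, beta = 1, mixWeight = 0.1,
                                  oscFreqHz = 9, phaseJitterSD = 0.05,
                                  seed = 1L) {
  if (mixWeight < 0 || mixWeight >= 1)
    stop("mixWeight must lie in [0, 1)", call. = FALSE)
  n <- as.integer(round(fs * durationS))
  withSeed(seed, {
    (1 - mixWeight) * .coloredNoise(n, beta) +
      mixWeight * .jitteredSine(n, fs, oscFreqHz, phaseJitterSD)
  })
}

#' Ground-truth mixing weights of a synthetic cohort
#'
#' The per-subject, per-channel oscillation weights the generator will use:
#' baseline \code{oscMix} everywhere, plus \code{ctDeficit} on
#' centrotemporal channels of case subjects, plus an independent
#' N(0, jitterSD) perturbation per subject x channel (clamped to
#' [0, 0.95]). Exposes the injected contrast's location for verification.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param montage a [Montage-class].
#' @return data.frame with \code{subject_id, group, sensor, weight}.
#' @export
cohortWeightPlan <- function(spec, montage = standardMontage()) {
  subs <- data.frame(
    subject_id = c(sprintf("case%02d", seq_len(spec@nCase)),
                   sprintf("contrast%02d", seq_len(spec@nContrast))),
    group = rep(c("case", "contrast"), c(spec@nCase, spec@nContrast)),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(subs)), function(i) {
    isCT <- montage@allSensors %in% montage@ctSensors
    w <- spec@oscMix +
      ifelse(subs$group[i] == "case" & isCT, spec@ctDeficit, 0)
    jit <- withSeed(deriveSeed(spec@seed, 101L, i),
                    stats::rnorm(length(w), 0, spec@jitterSD))
    data.frame(subject_id = subs$subject_id[i], group = subs$group[i],
               sensor = montage@allSensors,
               weight = pmin(pmax(w + jit, 0), 0.95),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic cohort
#'
#' Builds one 19-channel [EEGRecording-class] per subject according to the
#' spec's weight plan. With \code{dir} set, each recording is also written
#' as an EDF file and a cohort manifest CSV
#' (\code{subject_id,group,edf_path}) is emitted; output is
#' byte-deterministic for a fixed spec.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param dir optional output directory for EDF files and the manifest.
#' @param montage a [Montage-class].
#' @param verbose emit progress messages.
#' @return list with \code{recordings} (list of EEGRecording) and
#'   \code{manifest} (data.frame; \code{edf_path} is \code{NA} when no
#'   files are written).
#' @examples
#' coh <- generateCohort(syntheticCohortSpec(nCase = 1, nContrast = 1,
#'                                           durationS = 4, seed = 3))
#' coh$manifest
#' @export
generateCohort <- function(spec, dir = NULL, montage = standardMontage(),
                           verbose = FALSE) {
  validObject(spec)
  plan <- cohortWeightPlan(spec, montage)
  subs <- unique(plan[c("subject_id", "group")])
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  recs <- vector("list", nrow(subs))
  paths <- rep(NA_character_, nrow(subs))
  # microvolt scale for EDF storage; unit-variance signals are ~50 uV RMS
  ampUV <- 50
  for (i in seq_len(nrow(subs))) {
    pw <- plan[plan$subject_id == subs$subject_id[i], ]
    data <- t(vapply(seq_len(nrow(pw)), function(ch) {
      ampUV * generateChannelSignal(
        spec@fs, spec@durationS, spec@beta, pw$weight[ch], spec@oscFreqHz,
        spec@phaseJitterSD, seed = deriveSeed(spec@seed, i, ch))
    }, numeric(as.integer(round(spec@fs * spec@durationS)))))
    recs[[i]] <- EEGRecording(subs$subject_id[i], subs$group[i], spec@fs,
                              pw$sensor, data, normalize = FALSE)
    if (!is.null(dir)) {
      paths[i] <- file.path(dir, paste0(subs$subject_id[i], ".edf"))
      writeEDF(recs[[i]], paths[i])
      .logMsg("wrote %s", paths[i], verbose = verbose)
    }
  }
  manifest <- data.frame(subject_id = subs$subject_id, group = subs$group,
                         edf_path = paths, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    # stored relative to the manifest so the cohort directory is portable
    portable <- manifest
    portable$edf_path <- basename(portable$edf_path)
    writeCohortManifest(portable, file.path(dir, "cohort.csv"))
  }
  list(recordings = recs, manifest = manifest)
}

#' Calibration sweep of the complexity knob
#'
#' Generates single channels over a grid of mixing weights and measures
#' them with the pipeline's own kernels, returning the mean measure value
#' per weight -- the table used to verify each measure's response direction
#' to the injected regularity.
#'
#' @param spec a [SyntheticCohortSpec-class] (supplies fs, beta,
#'   oscillation settings and the seed).
#' @param measure one of \code{"SampE"}, \code{"TT"}, \code{"Lmax"},
#'   \code{"Lmean"}, \code{"DET"}, \code{"LAM"}.
#' @param weights mixing-weight grid.
#' @param nSeeds signals averaged per weight.
#' @param nSamples samples per generated signal.
#' @param rqaCfg,sampenCfg kernel settings.
#' @return data.frame with \code{weight, mean_value, n}.
#' @export
calibrateComplexityKnob <- function(spec, measure = "SampE",
                                    weights = c(0, 0.2, 0.4, 0.6, 0.8),
                                    nSeeds = 20, nSamples = 7680,
                                    rqaCfg = recurrenceConfig(),
                                    sampenCfg = sampEnConfig()) {
  stopifnot(measure %in% c("SampE", .RQA_MEASURES))
  durS <- nSamples / spec@fs
  rows <- lapply(seq_along(weights), function(wi) {
    vals <- vapply(seq_len(nSeeds), function(s) {
      x <- generateChannelSignal(spec@fs, durS, spec@beta, weights[wi],
                                 spec@oscFreqHz, spec@phaseJitterSD,
                                 seed = deriveSeed(spec@seed, 900L, wi, s))
      if (measure == "SampE") {
        as.numeric(sampleEntropy(x, sampenCfg))
      } else {
        r <- rqaFromSignal(x, rqaCfg)
        switch(measure, TT = r@tt, Lmax = r@lmax, Lmean = r@lmean,
               DET = r@det, LAM = r@lam, RR = r@rr)
      }
    }, 0)
    data.frame(weight = weights[wi], mean_value = mean(vals, na.rm = TRUE),
               n = sum(!is.na(vals)))
  })
  do.call(rbind, rows)
}
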
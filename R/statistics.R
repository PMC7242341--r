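# Group-level statistics: per-sensor multiscale curves with confidence
# bands, per-observation area under the multiscale curve, the four-cell
# (group x region) one-way ANOVA, and the per-sensor heatmap table.

#' Multiscale curve of one measure at one sensor for one cohort
#'
#' Per-band mean across the subjects of the group, with 95\% confidence
#' half-widths (normal approximation \code{1.96 * SD / sqrt(n)} by
#' default, or t-based with \code{ci = "t"}). Missing observations are
#' excluded per band; a band with no observation at all is an error. A
#' single-subject band yields a zero half-width with a warning.
#'
#' @param table long-format feature table.
#' @param measure measure name.
#' @param sensor normalized sensor label.
#' @param group \code{"case"} or \code{"contrast"}.
#' @param ci \code{"normal"} (default) or \code{"t"}.
#' @return a [MultiscaleCurve-class].
#' @export
multiscaleGroupCurve <- function(table, measure, sensor, group,
                                 ci = c("normal", "t")) {
  ci <- match.arg(ci)
  sub <- table[table$measure == measure & table$sensor == sensor &
                 table$group == group, ]
  if (!nrow(sub))
    stop("no observations for ", measure, " at ", sensor, " (", group, ")",
         call. = FALSE)
  bands <- sort(unique(table$band_index[table$measure == measure]))
  mu <- hw <- numeric(length(bands))
  nPer <- integer(length(bands))
  for (k in seq_along(bands)) {
    v <- sub$value[sub$band_index == bands[k]]
    v <- v[!is.na(v)]
    if (!length(v))
      stop("band ", bands[k], " has zero non-missing observations for ",
           measure, " at ", sensor, " (", group, ")", call. = FALSE)
    nPer[k] <- length(v)
    mu[k] <- mean(v)
    if (length(v) == 1L) {
      warning("band ", bands[k], " has a single subject (n = 1); ",
              "confidence half-width set to 0", call. = FALSE)
      hw[k] <- 0
    } else {
      crit <- if (ci == "normal") 1.96 else stats::qt(0.975, length(v) - 1L)
      hw[k] <- crit * stats::sd(v) / sqrt(length(v))
    }
  }
  new("MultiscaleCurve", measure = measure, sensor = sensor, group = group,
      bandMeans = mu, ciHalfWidth = hw, nPerBand = nPer)
}

#' Area under a multiscale curve
#'
#' Trapezoidal area over the band index with unit spacing. Interior missing
#' bands are linearly interpolated; missing terminal bands truncate the
#' curve with a warning. Fewer than two non-missing values is an error.
#'
#' @param values numeric vector of per-band values, ordered low to high
#'   frequency.
#' @return scalar area.
#' @examples
#' curveAUC(c(1, 3, 2))   # 4.5
#' @export
curveAUC <- function(values) {
  ok <- which(!is.na(values))
  if (length(ok) < 2L)
    stop("curve AUC needs at least 2 non-missing band values",
         call. = FALSE)
  lo <- min(ok); hi <- max(ok)
  if (lo > 1L || hi < length(values))
    warning("missing terminal band(s); curve truncated to bands ",
            lo, "-", hi, call. = FALSE)
  v <- values[lo:hi]
  if (anyNA(v))    # interior gaps: linear interpolation on the band index
    v <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                       xout = seq_along(v))$y
  sum((v[-1] + v[-length(v)]) / 2)
}

#' Per-(subject, sensor) areas under the multiscale curve
#'
#' Reduces the feature table to one AUC observation per subject and sensor
#' for the given measure -- the observation unit pooled into the four
#' (group, region) cells. Curves that cannot produce an AUC (fewer than
#' two non-missing bands) are dropped with a warning.
#'
#' @param table long-format feature table.
#' @param measure measure name.
#' @return data.frame with \code{subject_id, group, sensor, region, auc}.
#' @export
subjectSensorAUC <- function(table, measure) {
  sub <- table[table$measure == measure, ]
  if (!nrow(sub)) stop("no rows for measure ", measure, call. = FALSE)
  sub <- sub[order(sub$subject_id, sub$sensor, sub$band_index), ]
  key <- interaction(sub$subject_id, sub$sensor, drop = TRUE)
  pieces <- split(sub, key)
  out <- lapply(pieces, function(p) {
    a <- tryCatch(suppressWarnings(curveAUC(p$value)), error = identity)
    if (inherits(a, "error")) return(NULL)
    data.frame(subject_id = p$subject_id[1], group = p$group[1],
               sensor = p$sensor[1], region = p$region[1], auc = a,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, TRUE))
  if (dropped)
    warning(dropped, " subject x sensor curve(s) dropped (fewer than 2 ",
            "non-missing bands)", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way four-cell region ANOVA
#'
#' Pools the per-(subject, sensor) AUC observations of one measure into the
#' four (group, region) cells -- case/contrast crossed with CT/non-CT --
#' and runs the classical one-way ANOVA over the cells:
#' \code{F = MS_between / MS_within} on \code{(3, n - 4)} degrees of
#' freedom with the exact p-value from the F distribution. Sensors within a
#' subject are pooled as independent observations, a deliberate
#' pseudo-replication the region contrast is defined on.
#'
#' @param table long-format feature table.
#' @param measure measure name.
#' @param montage unused placeholder for future montage overrides.
#' @return a [RegionSummary-class].
#' @export
regionANOVA <- function(table, measure, montage = standardMontage()) {
  auc <- subjectSensorAUC(table, measure)
  cellNames <- c("case_CT", "case_nonCT", "contrast_CT", "contrast_nonCT")
  cell <- factor(paste(auc$group, auc$region, sep = "_"),
                 levels = cellNames)
  counts <- table(cell)
  if (any(counts == 0))
    stop("empty (group, region) cell(s): ",
         paste(cellNames[counts == 0], collapse = ", "), call. = FALSE)
  cells <- split(auc$auc, cell)
  if (all(vapply(cells, function(v) stats::var(v) == 0 || length(v) < 2,
                 TRUE)))
    stop("zero within-cell variance everywhere: F undefined",
         call. = FALSE)
  fit <- stats::lm(auc$auc ~ cell)
  an <- stats::anova(fit)
  new("RegionSummary", measure = measure, cells = cells,
      cellMeans = vapply(cells, mean, 0),
      fStatistic = an$`F value`[1],
      dfBetween = as.integer(an$Df[1]), dfWithin = as.integer(an$Df[2]),
      pValue = an$`Pr(>F)`[1])
}

#' Per-sensor, per-group mean AUC heatmap table
#'
#' Mean area under the multiscale curve at each of the 19 sensors for each
#' cohort, with region annotation -- the table behind scalp heatmaps of a
#' nonlinear measure.
#'
#' @param table long-format feature table.
#' @param measure measure name.
#' @param montage a [Montage-class].
#' @param allowMissing tolerate sensors with no observations (dropped with
#'   a warning) instead of raising an error.
#' @return data.frame with \code{sensor, region, group, mean_auc},
#'   one row per sensor per group.
#' @export
heatmapTable <- function(table, measure, montage = standardMontage(),
                         allowMissing = FALSE) {
  auc <- subjectSensorAUC(table, measure)
  combos <- expand.grid(sensor = montage@allSensors,
                        group = c("case", "contrast"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    v <- auc$auc[auc$sensor == combos$sensor[i] &
                   auc$group == combos$group[i]]
    if (!length(v)) {
      if (!allowMissing)
        stop("sensor ", combos$sensor[i], " has no AUC observations for ",
             combos$group[i], call. = FALSE)
      warning("sensor ", combos$sensor[i], " (", combos$group[i],
              ") missing; dropped", call. = FALSE)
      return(NULL)
    }
    data.frame(sensor = combos$sensor[i],
               region = classifySensorRegion(combos$sensor[i], montage),
               group = combos$group[i], mean_auc = mean(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
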
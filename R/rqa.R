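# Recurrence quantification: delay embedding, radius calibration at a
# target recurrence rate, the binary recurrence matrix, and statistics of
# its diagonal (predictability) and vertical (laminarity) line structures.

.NORM_CODES <- c(euclidean = 0L, chebyshev = 1L, manhattan = 2L)

.rowDistFun <- function(norm) {
  switch(norm,
         euclidean = function(a, b) sqrt(sum((a - b)^2)),
         chebyshev = function(a, b) max(abs(a - b)),
         manhattan = function(a, b) sum(abs(a - b)),
         stop("unknown norm '", norm, "'", call. = FALSE))
}

#' Delay embedding of a scalar time series
#'
#' Builds the trajectory matrix whose row i is
#' \code{(x[i], x[i + tau], ..., x[i + (m - 1) tau])}.
#'
#' @param x numeric signal vector.
#' @param m embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @return numeric matrix with \code{length(x) - (m - 1) * tau} rows and
#'   \code{m} columns.
#' @examples
#' embedTimeSeries(1:4, m = 2, tau = 1)
#' @export
embedTimeSeries <- function(x, m, tau = 1) {
  m <- as.integer(m); tau <- as.integer(tau)
  n <- length(x)
  need <- 1L + (m - 1L) * tau
  if (n < need)
    stop(sprintf(
      "signal of length %d too short to embed with m = %d, tau = %d (needs >= %d)",
      n, m, tau, need), call. = FALSE)
  rows <- n - (m - 1L) * tau
  out <- matrix(0, rows, m)
  for (k in seq_len(m))
    out[, k] <- x[(1L + (k - 1L) * tau):(rows + (k - 1L) * tau)]
  out
}

#' Calibrate the recurrence radius to a target recurrence rate
#'
#' Bisection on the radius until the off-diagonal recurrence rate falls
#' within \code{rrTarget +/- 0.01} (it converges well inside that band for
#' continuous distance distributions). When the target is unattainable --
#' e.g. the distance distribution has an atom that jumps across it -- the
#' smallest radius whose rate is at least the target is returned. Fully
#' deterministic.
#'
#' @param traj trajectory matrix from [embedTimeSeries()] (>= 2 rows).
#' @param rrTarget target recurrence rate in (0, 1).
#' @param norm distance norm (\code{"euclidean"}, \code{"chebyshev"},
#'   \code{"manhattan"}).
#' @return the calibrated radius (signal units).
#' @examples
#' traj <- embedTimeSeries(rnorm(200), m = 3)
#' eps <- calibrateRadius(traj, 0.1)
#' @export
calibrateRadius <- function(traj, rrTarget = 0.10, norm = "euclidean") {
  if (nrow(traj) < 2L) stop("trajectory needs >= 2 rows", call. = FALSE)
  nc <- .NORM_CODES[[norm]]
  hi <- .cppMaxPairDist(traj, nc)
  if (hi == 0)
    stop("zero-diameter trajectory: all phase-space points identical",
         call. = FALSE)
  lo <- 0
  best <- hi
  for (it in seq_len(80L)) {
    mid <- (lo + hi) / 2
    rr <- .cppRecurrenceRate(traj, mid, nc)
    if (abs(rr - rrTarget) <= 0.005) return(mid)
    if (rr >= rrTarget) { best <- mid; hi <- mid } else lo <- mid
    if (hi - lo < 1e-12 * max(1, best)) break
  }
  best          # smallest radius found with rate >= target
}

#' Binary recurrence matrix
#'
#' \code{R[i, j] = 1} iff the distance between trajectory rows i and j is
#' at most \code{epsilon}; symmetric with a unit main diagonal (the line of
#' identity).
#'
#' @param traj trajectory matrix.
#' @param epsilon recurrence radius (>= 0).
#' @param norm distance norm.
#' @return integer 0/1 matrix, N x N.
#' @examples
#' recurrenceMatrix(embedTimeSeries(c(0, 1, 0, 1), 1), 0.5)
#' @export
recurrenceMatrix <- function(traj, epsilon, norm = "euclidean") {
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  traj <- as.matrix(traj)
  d <- switch(norm,
    euclidean = as.matrix(stats::dist(traj, method = "euclidean")),
    chebyshev = as.matrix(stats::dist(traj, method = "maximum")),
    manhattan = as.matrix(stats::dist(traj, method = "manhattan")),
    stop("unknown norm '", norm, "'", call. = FALSE))
  R <- (d <= epsilon) * 1L
  storage.mode(R) <- "integer"
  dimnames(R) <- NULL
  R
}

.checkBinarySquare <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop("R must be a square matrix", call. = FALSE)
  if (!all(R %in% c(0L, 1L)))
    stop("R must be binary", call. = FALSE)
}

#' Diagonal line lengths of a recurrence matrix
#'
#' Lengths of all maximal runs of consecutive recurrence points along the
#' diagonals of \code{R}. The line of identity is always excluded, and a
#' Theiler band of offsets \code{|i - j| < theilerW} around it is excluded
#' as well (so \code{theilerW} of 0 or 1 excludes exactly the main
#' diagonal).
#'
#' @param R square binary matrix.
#' @param theilerW Theiler exclusion half-width (>= 0).
#' @return integer vector of line lengths (one entry per maximal run,
#'   both triangles).
#' @examples
#' diagonalLineLengths(diag(5), theilerW = 1)    # none: only the LOI
#' @export
diagonalLineLengths <- function(R, theilerW = 1) {
  .checkBinarySquare(R)
  n <- nrow(R)
  kmin <- max(1L, as.integer(theilerW))
  lens <- integer(0)
  if (kmin >= n) return(lens)
  for (k in kmin:(n - 1L)) {
    i <- 1L:(n - k)
    for (v in list(R[cbind(i, i + k)], R[cbind(i + k, i)])) {
      r <- rle(v)
      lens <- c(lens, r$lengths[r$values == 1L])
    }
  }
  as.integer(lens)
}

#' Vertical line lengths of a recurrence matrix
#'
#' Lengths of all maximal runs of consecutive recurrence points down each
#' column (line-of-identity cells included).
#'
#' @param R square binary matrix.
#' @return integer vector of run lengths.
#' @examples
#' verticalLineLengths(matrix(1L, 4, 4))  # four runs of length 4
#' @export
verticalLineLengths <- function(R) {
  .checkBinarySquare(R)
  lens <- integer(0)
  for (j in seq_len(ncol(R))) {
    r <- rle(R[, j])
    lens <- c(lens, r$lengths[r$values == 1L])
  }
  as.integer(lens)
}

.rqaFromLineSets <- function(dl, vl, rTotal, n, cfg, epsilon = NA_real_) {
  dq <- dl[dl >= cfg@lmin]
  vq <- vl[vl >= cfg@vmin]
  new("RQAResult",
      lmax  = if (length(dq)) max(dq) else 0,
      lmean = if (length(dq)) mean(dq) else NA_real_,
      tt    = if (length(vq)) mean(vq) else NA_real_,
      det   = if (sum(dl) > 0) sum(dq) / sum(dl) else NA_real_,
      lam   = if (sum(vl) > 0) sum(vq) / sum(vl) else NA_real_,
      rr    = (rTotal - n) / (n * (n - 1)),
      epsilon = as.numeric(epsilon))
}

#' Recurrence quantification measures of a recurrence matrix
#'
#' Computes the diagonal- and vertical-line statistics: \code{Lmax} and
#' \code{Lmean} (maximum / mean diagonal line length at least \code{lmin};
#' diagonal offsets inside the Theiler band excluded), trapping time
#' \code{TT} (mean vertical line length at least \code{vmin}, full matrix),
#' determinism \code{DET}, laminarity \code{LAM} and the off-diagonal
#' recurrence rate \code{RR}. Measures with no qualifying line are
#' \code{NA} (\code{Lmax} is 0), never silently zero.
#'
#' @param R square binary recurrence matrix.
#' @param cfg a [RecurrenceConfig-class].
#' @param epsilon optional radius to record in the result.
#' @return an [RQAResult-class].
#' @examples
#' R <- recurrenceMatrix(embedTimeSeries(sin(1:100 / 3), 3), 0.5)
#' rqaMeasures(R)
#' @export
rqaMeasures <- function(R, cfg = recurrenceConfig(), epsilon = NA_real_) {
  .checkBinarySquare(R)
  .rqaFromLineSets(diagonalLineLengths(R, cfg@theilerW),
                   verticalLineLengths(R),
                   sum(R), nrow(R), cfg, epsilon)
}

#' Recurrence quantification of a signal (fast path)
#'
#' Embeds the signal, calibrates the radius to the configured target
#' recurrence rate, and computes the line statistics matrix-free in
#' compiled code -- equivalent to
#' \code{rqaMeasures(recurrenceMatrix(embedTimeSeries(x, m, tau), eps))}
#' without materializing the N x N matrix.
#'
#' @param x numeric signal vector.
#' @param cfg a [RecurrenceConfig-class].
#' @return an [RQAResult-class].
#' @examples
#' rqaFromSignal(sin(1:500 / 5))
#' @export
rqaFromSignal <- function(x, cfg = recurrenceConfig()) {
  traj <- embedTimeSeries(x, cfg@m, cfg@tau)
  eps <- calibrateRadius(traj, cfg@rrTarget, cfg@norm)
  s <- .cppRqaStats(traj, eps, .NORM_CODES[[cfg@norm]], cfg@theilerW,
                    cfg@lmin, cfg@vmin)
  new("RQAResult", lmax = s$lmax, lmean = s$lmean, tt = s$tt,
      det = s$det, lam = s$lam, rr = s$rr, epsilon = eps)
}
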
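#' Sample entropy of a signal
#'
#' The negative natural logarithm of the conditional probability that two
#' subsequences matching for \code{m} points (Chebyshev distance at most
#' \code{r = rFactor * SD(x)}) also match at the next point, counting only
#' distinct pairs (no self-matches). Lower values indicate a more
#' self-similar, more regular signal.
#'
#' @param x numeric signal vector, length > m + 1, non-constant.
#' @param cfg a [SampEnConfig-class] (defaults m = 2, rFactor = 0.2).
#' @return sample entropy in nats, or \code{NA} with attribute
#'   \code{"reason"} when no template pair matches at length m (or none
#'   continues to m + 1), in which case the conditional probability is
#'   undefined.
#' @examples
#' sampleEntropy(rep(c(1, 2), 25))   # perfectly self-similar: 0
#' @export
sampleEntropy <- function(x, cfg = sampEnConfig()) {
  m <- cfg@m
  if (length(x) <= m + 1L)
    stop("signal too short for sample entropy with m = ", m, call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("constant signal: sample entropy undefined (zero SD)",
         call. = FALSE)
  cnt <- .cppSampEnCounts(as.numeric(x), m, cfg@rFactor * s)
  A <- cnt[1]; B <- cnt[2]
  if (B == 0)
    return(structure(NA_real_, reason = "no template matches at length m"))
  if (A == 0)
    return(structure(NA_real_, reason = "no template matches at length m+1"))
  -log(A / B)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Standard first-order DFA: integrate the mean-removed signal, split into
#' non-overlapping windows of each size, remove a per-window linear trend,
#' and regress log RMS fluctuation on log window size. The slope alpha is
#' about 0.5 for white noise, 1.5 for its cumulative sum, and 1.0 at the
#' 1/f boundary.
#'
#' @param x numeric signal vector.
#' @param windowSizes integer vector of window sizes (>= 4 sizes). Default:
#'   15 log-spaced sizes from 10 to \code{length(x) / 10}.
#' @return the scaling exponent alpha.
#' @examples
#' dfaAlpha(rnorm(2048))   # about 0.5
#' @export
dfaAlpha <- function(x, windowSizes = NULL) {
  n <- length(x)
  if (is.null(windowSizes)) {
    if (n < 100) stop("signal too short for default DFA windows",
                      call. = FALSE)
    windowSizes <- unique(round(exp(seq(log(10), log(n / 10),
                                        length.out = 15))))
  }
  windowSizes <- sort(unique(as.integer(windowSizes)))
  if (length(windowSizes) < 4L)
    stop("DFA needs at least 4 distinct window sizes", call. = FALSE)
  if (n < 4L * max(windowSizes))
    stop(sprintf(
      "signal of length %d too short: needs >= 4 * max window (%d)",
      n, 4L * max(windowSizes)), call. = FALSE)
  y <- cumsum(x - mean(x))
  Fn <- vapply(windowSizes, function(w) {
    k <- n %/% w
    Y <- matrix(y[seq_len(k * w)], nrow = w)       # one window per column
    t <- seq_len(w)
    res <- stats::lm.fit(cbind(1, t), Y)$residuals
    sqrt(mean(res^2))
  }, 0)
  unname(stats::coef(stats::lm(log(Fn) ~ log(windowSizes)))[2])
}
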
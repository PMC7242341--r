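# Independent brute-force oracles: every one is a direct transcription of
# the defining formula, deliberately sharing no code with the package
# internals it checks.

# diagonal line lengths by explicit per-diagonal scan
oracleDiagLengths <- function(R, theilerW = 1) {
  n <- nrow(R)
  kmin <- max(1L, theilerW)
  lens <- integer(0)
  for (off in c(-(n - 1):-kmin, kmin:(n - 1))) {
    run <- 0L
    for (i in seq_len(n)) {
      j <- i + off
      v <- if (j >= 1 && j <= n) R[i, j] else 0L
      if (v == 1L) run <- run + 1L
      if ((v == 0L || i == n) && run > 0L) {
        lens <- c(lens, run)
        run <- 0L
      }
    }
  }
  lens
}

# vertical line lengths by explicit per-column scan
oracleVertLengths <- function(R) {
  n <- nrow(R)
  lens <- integer(0)
  for (j in seq_len(n)) {
    run <- 0L
    for (i in seq_len(n)) {
      if (R[i, j] == 1L) run <- run + 1L
      if ((R[i, j] == 0L || i == n) && run > 0L) {
        lens <- c(lens, run)
        run <- 0L
      }
    }
  }
  lens
}

# RQA summary by exhaustive enumeration from the two oracle multisets
oracleRqa <- function(R, theilerW = 1, lmin = 2, vmin = 2) {
  dl <- oracleDiagLengths(R, theilerW)
  vl <- oracleVertLengths(R)
  dq <- dl[dl >= lmin]
  vq <- vl[vl >= vmin]
  n <- nrow(R)
  list(lmax = if (length(dq)) max(dq) else 0,
       lmean = if (length(dq)) mean(dq) else NA_real_,
       tt = if (length(vq)) mean(vq) else NA_real_,
       det = if (sum(dl) > 0) sum(dq) / sum(dl) else NA_real_,
       lam = if (sum(vl) > 0) sum(vq) / sum(vl) else NA_real_,
       rr = (sum(R) - n) / (n * (n - 1)))
}

# sample-entropy template counts: definition transcribed, inner loop
# vectorized over the second template index only
oracleSampEnCounts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    js <- (i + 1):nt
    dmax <- rep(0, length(js))
    for (k in 0:(m - 1))
      dmax <- pmax(dmax, abs(x[i + k] - x[js + k]))
    okm <- dmax <= r
    B <- B + sum(okm)
    A <- A + sum(okm & abs(x[i + m] - x[js + m]) <= r)
  }
  c(A = A, B = B)
}

# pairwise recurrence matrix by double loop
oracleRecurrenceMatrix <- function(traj, eps, norm = "euclidean") {
  n <- nrow(traj)
  R <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- switch(norm,
                euclidean = sqrt(sum((traj[i, ] - traj[j, ])^2)),
                chebyshev = max(abs(traj[i, ] - traj[j, ])),
                manhattan = sum(abs(traj[i, ] - traj[j, ])))
    R[i, j] <- as.integer(d <= eps)
  }
  R
}

# random symmetric binary matrix with unit diagonal (a valid recurrence
# matrix shape)
randomRecurrenceLike <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  R <- matrix(0L, n, n)
  up <- upper.tri(R)
  R[up] <- as.integer(runif(sum(up)) < p)
  R <- R + t(R)
  diag(R) <- 1L
  storage.mode(R) <- "integer"
  R
}

# small feature table with two bands per (subject, sensor) whose AUC is a
# prescribed value (constant curve over 2 bands has AUC equal to it)
featureTableFromAUC <- function(cellValues, measure = "SampE") {
  ct <- c("C3", "C4", "Cz", "T7", "T8", "P7", "P8")
  nonct <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "P3", "Pz", "P4",
             "O1", "O2")
  rows <- list()
  for (cell in names(cellValues)) {
    parts <- strsplit(cell, "_")[[1]]
    grp <- parts[1]; reg <- parts[2]
    sensors <- if (reg == "CT") ct else nonct
    vals <- cellValues[[cell]]
    for (k in seq_along(vals)) {
      sid <- sprintf("%s%02d", grp, (k - 1) %/% length(sensors) + 1)
      sen <- sensors[(k - 1) %% length(sensors) + 1]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = grp, sensor = sen, region = reg,
        band_index = 1:2, band_low_hz = c(0, 64), band_high_hz = c(64, 128),
        measure = measure, value = rep(vals[k], 2),
        reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# 19-channel recording on the standard montage with iid noise
noiseRecording <- function(subjectId = "s1", group = "case", fs = 128,
                           durationS = 8, seed = 1) {
  set.seed(seed)
  labs <- standardMontage()@allSensors
  EEGRecording(subjectId, group, fs, labs,
               matrix(rnorm(19 * fs * durationS), 19), normalize = FALSE)
}
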
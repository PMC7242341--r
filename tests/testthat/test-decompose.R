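test_that("nominal dyadic band edges follow fs and levels", {
  r <- bandFrequencyRanges(256, 6)
  expect_equal(r$low_hz, c(0, 2, 4, 8, 16, 32, 64))
  expect_equal(r$high_hz, c(2, 4, 8, 16, 32, 64, 128))
  r2 <- bandFrequencyRanges(200, 2)
  expect_equal(r2$low_hz, c(0, 25, 50))
  expect_equal(r2$high_hz, c(25, 50, 100))
  expect_error(bandFrequencyRanges(256, 0), "levels")
})

test_that("band signals sum exactly back to the input for assorted lengths", {
  set.seed(11)
  for (wavelet in c("shannon", "haar", "db2", "db4", "db8")) {
    for (n in c(64, 100, 777, 1024, 2048)) {
      for (levels in c(1L, 3L, 6L)) {
        if (n < 2^levels) next
        x <- rnorm(n)
        bs <- waveletBandDecompose(x, 256, wavelet, levels)
        expect_identical(nBands(bs), levels + 1L)
        relErr <- sqrt(sum((colSums(bandSignals(bs)) - x)^2)) /
          sqrt(sum(x^2))
        expect_lt(relErr, 1e-8)
      }
    }
  }
})

test_that("a constant signal lands entirely in the approximation band", {
  bs <- waveletBandDecompose(rep(5, 512), 256)
  e <- rowSums(bandSignals(bs)^2)
  expect_gt(e[1] / sum(e), 0.9999)
})

test_that("a 10 Hz tone concentrates in the 8-16 Hz band (FFT oracle)", {
  n <- 2048; fs <- 256
  x <- sin(2 * pi * 10 * (0:(n - 1)) / fs)
  inBandFrac <- function(bs) {
    # FFT oracle: spectral mass of the reconstructed band inside 8-16 Hz
    spec <- Mod(fft(bandSignals(bs)[4, ]))^2
    freqs <- (0:(n - 1)) * fs / n
    inBand <- freqs >= 8 & freqs <= 16 | freqs >= fs - 16 & freqs <= fs - 8
    sum(spec[inBand]) / sum(spec)
  }
  for (wavelet in c("shannon", "db4")) {
    bs <- waveletBandDecompose(x, fs, wavelet, 6)
    e <- rowSums(bandSignals(bs)^2)
    expect_gt(e[4] / sum(e), 0.80)
    expect_gt(inBandFrac(bs), 0.80)
  }
  # the ideal filterbank localizes exactly
  bs <- waveletBandDecompose(x, fs, "shannon", 6)
  expect_gt(inBandFrac(bs), 0.999)
})

test_that("band energies partition white-noise energy within 1%", {
  set.seed(12)
  x <- rnorm(4096)
  for (wavelet in c("shannon", "db4")) {
    bs <- waveletBandDecompose(x, 256, wavelet)
    expect_lt(abs(sum(rowSums(bandSignals(bs)^2)) - sum(x^2)) / sum(x^2),
              0.01)
  }
})

test_that("infeasible depth errors with the maximum feasible level", {
  expect_error(waveletBandDecompose(rnorm(50), 256, levels = 6),
               "maximum feasible level: 5")
  expect_error(waveletBandDecompose(rnorm(100), 256, wavelet = "sym9"),
               "unknown wavelet")
})
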
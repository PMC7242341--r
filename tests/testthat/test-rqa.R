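test_that("delay embedding unrolls the definition and checks its bounds", {
  expect_equal(embedTimeSeries(1:4, 1, 1), matrix(1:4, ncol = 1))
  expect_equal(embedTimeSeries(1:4, 2, 1),
               matrix(c(1, 2, 3, 2, 3, 4), ncol = 2))
  # length 10, m = 3, tau = 4: exactly two rows survive
  tr <- embedTimeSeries(0:9, 3, 4)
  expect_equal(tr, matrix(c(0, 1, 4, 5, 8, 9), ncol = 3))
  expect_error(embedTimeSeries(1:8, 3, 4), "needs >= 9")
})

test_that("recurrence matrix matches threshold geometry and a brute-force oracle", {
  tr <- embedTimeSeries(c(0, 1, 0, 1), 1, 1)
  expect_equal(recurrenceMatrix(tr, 0.5),
               matrix(c(1, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 1),
                      4, 4))
  for (s in 1:5) {
    set.seed(s)
    tr <- matrix(rnorm(24), 8, 3)
    for (norm in c("euclidean", "chebyshev", "manhattan")) {
      eps <- 0.8
      expect_identical(recurrenceMatrix(tr, eps, norm),
                       oracleRecurrenceMatrix(tr, eps, norm))
    }
  }
  expect_true(all(diag(recurrenceMatrix(matrix(rnorm(30), 10), 0.1)) == 1L))
})

test_that("radius calibration hits the target rate and handles atoms", {
  # two distinct points: rate jumps 0 -> 1 at their distance
  tr <- matrix(c(0, 3), 2, 1)
  eps <- calibrateRadius(tr, 0.5)
  expect_equal(eps, 3)     # smallest radius whose rate reaches the target
  set.seed(21)
  tr <- matrix(rnorm(100), ncol = 1)
  eps <- calibrateRadius(tr, 0.10)
  d <- as.matrix(dist(tr))
  rr <- (sum(d <= eps) - 100) / (100 * 99)     # exhaustive oracle count
  expect_gte(rr, 0.09)
  expect_lte(rr, 0.11)
  expect_error(calibrateRadius(matrix(2, 5, 1), 0.1), "zero-diameter")
})

test_that("recurrence rate is nondecreasing in the radius", {
  set.seed(22)
  tr <- embedTimeSeries(rnorm(150), 3, 1)
  rates <- vapply(seq(0, 3, by = 0.25), function(e) {
    R <- recurrenceMatrix(tr, e)
    (sum(R) - nrow(R)) / (nrow(R) * (nrow(R) - 1))
  }, 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("permuting trajectory rows conjugates the recurrence matrix", {
  set.seed(23)
  tr <- matrix(rnorm(36), 12, 3)
  R <- recurrenceMatrix(tr, 1)
  p <- sample(12)
  expect_identical(recurrenceMatrix(tr[p, ], 1), R[p, p])
})

test_that("diagonal line multisets match hand enumeration", {
  expect_length(diagonalLineLengths(diag(10L), theilerW = 1), 0)
  checker <- recurrenceMatrix(embedTimeSeries(c(0, 1, 0, 1), 1, 1), 0.5)
  expect_identical(sort(diagonalLineLengths(checker, 1)), c(2L, 2L))
  ones10 <- matrix(1L, 10, 10)
  expect_identical(sort(diagonalLineLengths(ones10, 1)),
                   sort(rep(1:9, each = 2)))
})

test_that("vertical line multisets match a per-column run-length oracle", {
  expect_identical(verticalLineLengths(matrix(1L, 10, 10)), rep(10L, 10))
  expect_identical(verticalLineLengths(diag(10L)), rep(1L, 10))
  for (s in 1:5) {
    R <- randomRecurrenceLike(12, 0.4, seed = s)
    expect_identical(sort(verticalLineLengths(R)),
                     sort(oracleVertLengths(R)))
    expect_identical(sort(diagonalLineLengths(R, 1)),
                     sort(oracleDiagLengths(R, 1)))
  }
})

test_that("summary measures follow the line structure of canonical matrices", {
  cfg <- recurrenceConfig()
  ones16 <- matrix(1L, 16, 16)
  r <- rqaMeasures(ones16, cfg)
  expect_equal(r@lmax, 15)       # longest off-LOI diagonal
  expect_equal(r@tt, 16)         # full columns
  expect_equal(r@rr, 1)
  checker <- recurrenceMatrix(embedTimeSeries(c(0, 1, 0, 1), 1, 1), 0.5)
  rc <- rqaMeasures(checker, cfg)
  expect_equal(rc@lmax, 2)
  expect_equal(rc@lmean, 2)
  rid <- rqaMeasures(diag(10L), cfg)
  expect_equal(rid@lmax, 0)
  expect_true(is.na(rid@tt))     # no vertical line reaches vmin
  expect_true(is.na(rid@lmean))
})

test_that("theiler width widens the excluded diagonal band", {
  ones8 <- matrix(1L, 8, 8)
  expect_equal(max(diagonalLineLengths(ones8, theilerW = 1)), 7)
  expect_equal(max(diagonalLineLengths(ones8, theilerW = 3)), 5)
})

test_that("the compiled signal path equals the matrix route exactly", {
  cfg <- recurrenceConfig()
  for (s in 1:5) {
    set.seed(s + 30)
    x <- sin((1:250) / (2 + s)) + rnorm(250, 0, 0.3)
    fast <- rqaFromSignal(x, cfg)
    traj <- embedTimeSeries(x, cfg@m, cfg@tau)
    R <- recurrenceMatrix(traj, fast@epsilon, cfg@norm)
    slow <- rqaMeasures(R, cfg, fast@epsilon)
    for (sl in c("lmax", "lmean", "tt", "det", "lam", "rr"))
      expect_equal(slot(fast, sl), slot(slow, sl), tolerance = 1e-12)
  }
})
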
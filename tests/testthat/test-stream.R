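# Brute-force oracle: re-derive the whole clustering from scratch.
bruteStream <- function(w, keepFraction = 0.2, divisor = "N-1") {
  n <- length(w)
  if (n == 1) return(w)
  dbar <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i) s <- s + abs(w[i] - w[j])
    dbar[i] <- s / if (divisor == "N-1") (n - 1) else n
  }
  ord <- order(dbar, seq_len(n))
  keep <- ord[seq_len(max(1, floor(keepFraction * n + 0.5)))]
  mean(w[keep])
}

test_that("mean pairwise distance matches hand-computed values", {
  w <- c(70, 71, 72, 100, 101)
  expect_equal(meanPairwiseDistance(w, "N-1"),
               c(16, 15.25, 15, 22, 22.75))
  expect_equal(meanPairwiseDistance(w, "N"),
               c(16, 15.25, 15, 22, 22.75) * 4 / 5)
  expect_equal(meanPairwiseDistance(rep(80, 4)), rep(0, 4))
  expect_error(meanPairwiseDistance(70), "at least 2")
})

test_that("core selection keeps the densest fraction with stable ties", {
  w <- c(70, 71, 72, 100, 101)
  dbar <- meanPairwiseDistance(w)
  expect_equal(selectCore(w, dbar, 0.2), 3L)
  expect_equal(sort(selectCore(w, dbar, 1.0)), 1:5)
  # ties broken toward earlier frames
  expect_equal(selectCore(rep(5, 4), rep(0, 4), 0.5), c(1L, 2L))
})

test_that("stream estimate composes distance, sort, keep, centroid", {
  expect_equal(streamEstimate(c(70, 71, 72, 100, 101), 0.2), 72)
  expect_equal(streamEstimate(83), 83)
})

test_that("stream estimate agrees with the brute-force re-derivation on
           1000 random series under both divisor conventions", {
  set.seed(42)
  for (k in 1:1000) {
    n <- sample(1:10, 1)
    # continuous weights: exact ties in the mean distances have measure
    # zero, so the frame-order tie-break never has to fire
    w <- runif(n, 40, 140)
    frac <- sample(c(0.2, 0.35, 0.5, 1), 1)
    expect_identical(streamEstimate(w, frac, "N-1"),
                     bruteStream(w, frac, "N-1"))
    expect_identical(streamEstimate(w, frac, "N"),
                     bruteStream(w, frac, "N"))
  }
  # exact ties (identical values) resolve to the earliest frames
  expect_identical(streamEstimate(rep(90, 6), 0.5), 90)
})

test_that("stream estimate stays inside the estimate range and resists
           outliers below the keep fraction", {
  set.seed(7)
  for (k in 1:200) {
    w <- runif(sample(2:15, 1), 40, 140)
    s <- streamEstimate(w)
    expect_gte(s, min(w))
    expect_lte(s, max(w))
  }
  # inliers at w* +- 1, outliers at +30: estimate within 1 kg of w*
  for (k in 1:50) {
    wStar <- runif(1, 60, 100)
    nIn <- sample(10:20, 1)
    nOut <- sample(0:floor(nIn * 0.2 - 1e-9), 1)
    w <- c(wStar + runif(nIn, -1, 1), rep(wStar + 30, nOut))
    expect_lt(abs(streamEstimate(w) - wStar), 1 + 1e-9)
  }
})

test_that("permutation changes nothing when distances are distinct", {
  set.seed(9)
  w <- runif(9, 50, 120)
  p <- sample(9)
  expect_equal(streamEstimate(w), streamEstimate(w[p]))
})
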
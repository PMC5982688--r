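test_that("subject-level split has the right sizes and no leakage", {
  ids <- rep(1:10, each = 3)
  sp <- splitBySubject(ids, 0.7, seed = 2)
  expect_equal(length(sp$trainSubjects), 7)
  expect_equal(length(sp$testSubjects), 3)
  expect_equal(sum(sp$train) + sum(sp$test), length(ids))
  # all frames of one subject land on the same side
  for (s in 1:10) {
    sides <- unique(sp$train[ids == s])
    expect_length(sides, 1)
  }
  sp2 <- splitBySubject(ids, 0.7, seed = 2)
  expect_identical(sp$trainSubjects, sp2$trainSubjects)
  expect_error(splitBySubject(rep(1, 5)), "at least 2")
})

test_that("network fits a constant and is deterministic given the seed", {
  set.seed(1)
  x <- matrix(rnorm(200), 50, 4)
  y <- rep(80, 50)
  cfg <- networkConfig(nHidden = 8, maxEpochs = 300, seed = 3)
  m <- trainWeightNet(x, y, cfg = cfg)
  expect_lt(max(abs(predictWeight(m, x) - 80)), 0.5)
  m2 <- trainWeightNet(x, y, cfg = cfg)
  expect_identical(m@w1, m2@w1)
  expect_identical(m@w2, m2@w2)
})

test_that("network recovers a linear rule from noisy data", {
  set.seed(9)
  n <- 300
  vol <- runif(n, 0.04, 0.12)
  extra <- matrix(rnorm(n * 3), n, 3)
  y <- 400 * vol + rnorm(n, 0, 1) + 40
  x <- cbind(vol, extra)
  sp <- splitBySubject(seq_len(n), 0.7, seed = 1)
  m <- trainWeightNet(x[sp$train, ], y[sp$train],
                      personIds = which(sp$train),
                      cfg = networkConfig(seed = 5))
  pred <- predictWeight(m, x[sp$test, ])
  expect_lt(mean(abs(pred - y[sp$test])), 2)
})

test_that("training loss converges essentially monotonically on a
           noiseless linear problem without weight decay", {
  # iRPROP- adapts one step size per weight from gradient signs; single
  # epochs can overshoot transiently, but the loss must collapse and the
  # overshoots must be rare and small
  set.seed(12)
  x <- matrix(rnorm(120), 40, 3)
  y <- drop(x %*% c(3, -2, 1)) + 70
  cfg <- networkConfig(nHidden = 6, weightDecay = 0, maxEpochs = 150,
                       patience = 150, valFraction = 0.1, seed = 2)
  m <- trainWeightNet(x, y, cfg = cfg)
  tr <- m@history$train
  expect_lt(min(tr), tr[1] / 100)
  expect_lt(mean(diff(tr) > 1e-8), 0.10)
  expect_true(all(diff(cummin(tr)) <= 0))
})

test_that("early stopping returns the best-validation weights", {
  set.seed(30)
  x <- matrix(rnorm(400), 100, 4)
  y <- drop(x %*% c(5, 1, -2, 0.5)) + 75 + rnorm(100, 0, 3)
  m <- trainWeightNet(x, y, cfg = networkConfig(seed = 8,
                                                maxEpochs = 500))
  val <- m@history$validation
  expect_lte(val[m@history$bestEpoch], val[length(val)] + 1e-12)
  expect_equal(min(val), val[m@history$bestEpoch])
})

test_that("prediction checks inputs and batch equals per-row", {
  set.seed(2)
  x <- matrix(rnorm(90), 30, 3)
  y <- rowSums(x) + 60
  m <- trainWeightNet(x, y, cfg = networkConfig(nHidden = 4, seed = 1,
                                                maxEpochs = 200))
  batch <- predictWeight(m, x)
  rows <- vapply(seq_len(30), function(i) predictWeight(m, x[i, ]),
                 numeric(1))
  expect_equal(batch, rows)
  expect_error(predictWeight(m, x[, 1:2]), "feature width")
  xb <- x; xb[1, 1] <- NA
  expect_error(predictWeight(m, xb), "non-finite")
  expect_error(trainWeightNet(xb, y), "non-finite")
})

test_that("models serialize to JSON and back without changing output", {
  set.seed(6)
  x <- matrix(rnorm(60), 20, 3)
  m <- trainWeightNet(x, rowSums(x) + 70,
                      cfg = networkConfig(nHidden = 5, seed = 4,
                                          maxEpochs = 100))
  f <- withr::local_tempfile(fileext = ".json")
  saveWeightNet(m, f)
  m2 <- readWeightNet(f)
  expect_equal(predictWeight(m2, x), predictWeight(m, x),
               tolerance = 1e-12)
})

test_that("evaluation metrics reproduce the defining formulas", {
  m <- evaluateEstimates(90, 100)
  expect_equal(m$relErr, 0.1)
  e <- c(1, -2, 3)
  m2 <- evaluateEstimates(c(100, 100, 100) - e, c(100, 100, 100))
  expect_equal(m2$mae, 2)
  expect_equal(m2$mse, 14 / 3)
  perfect <- evaluateEstimates(c(70, 80), c(70, 80))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$pctWithin5, 100)
  expect_error(evaluateEstimates(1, 0), "zero")
  # sign convention: overestimate gives negative relative error
  expect_lt(evaluateEstimates(110, 100)$relErr, 0)
})

test_that("in-range percentages are monotone in the band radius", {
  set.seed(77)
  for (k in 1:20) {
    truth <- runif(30, 50, 120)
    pred <- truth * (1 + rnorm(30, 0, 0.1))
    m <- evaluateEstimates(pred, truth)
    expect_lte(m$pctWithin5, m$pctWithin10)
    expect_lte(m$pctWithin10, m$pctWithin20)
    expect_lte(m$pctWithin20, 100)
  }
})
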
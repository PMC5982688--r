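test_that("pinhole projection follows u = cx + fx x/z", {
  intr <- intrinsics(fx = 500, fy = 500, cx = 320, cy = 240)
  expect_equal(drop(projectPoints(c(0, 0, 1),
                                  intrinsics(1, 1, 0, 0))),
               c(u = 0, v = 0))
  expect_equal(drop(projectPoints(c(1, 2, 2), intr)),
               c(u = 570, v = 740))
  expect_error(projectPoints(c(0, 0, -1), intr), "depth")
})

test_that("distortion polynomial is identity at zero coefficients and at
           the principal point", {
  intr0 <- intrinsics(500, 500, 320, 240)
  q <- cbind(c(10, 350, 600), c(400, 240, 20))
  expect_equal(rectifyPixel(q, intr0), cbind(u = q[, 1], v = q[, 2]))
  intrK <- intrinsics(500, 500, 320, 240, dist = c(0.1, 0, 0, 0, 0))
  expect_equal(drop(rectifyPixel(c(320, 240), intrK)),
               c(u = 320, v = 240))
  # radial displacement fx * k1 * r^2 * x_n at q = (330, 240)
  out <- rectifyPixel(c(330, 240), intrK)
  expect_equal(out[["u"]], 330 + 500 * 0.1 * (10 / 500)^2 * (10 / 500))
  expect_equal(out[["v"]], 240)
})

test_that("depth images back-project to organized clouds and round-trip", {
  intr <- testIntr()
  pc <- planeCloud(intr, 1)
  expect_true(isOrganized(pc))
  expect_equal(unique(coords(pc)[, 3]), 1)
  # single pixel at the principal point
  d <- matrix(NA_real_, intr@height, intr@width)
  d[24, 32] <- 2  # 0-based (31.5, 23.5) rounds into this pixel
  pc1 <- depthToCloud(d, intr)
  v <- validCoordsOf(pc1)
  expect_equal(nrow(v), 1)
  expect_equal(unname(v[1, 3]), 2)
  expect_lt(max(abs(v[1, 1:2])), 2 * 0.5 / 100 + 1e-9)
  # projection of the cloud reproduces the pixel grid within 0.5 px
  set.seed(2)
  dep <- matrix(runif(intr@height * intr@width, 0.5, 3),
                intr@height, intr@width)
  pc2 <- depthToCloud(dep, intr)
  uv <- projectPoints(coords(pc2), intr)
  uu <- rep(0:(intr@width - 1), times = intr@height)
  vv <- rep(0:(intr@height - 1), each = intr@width)
  expect_lt(max(abs(uv[, 1] - uu)), 0.5)
  expect_lt(max(abs(uv[, 2] - vv)), 0.5)
})

test_that("thermal fusion samples the right pixels and never moves points", {
  intr <- testIntr()
  pc <- planeCloud(intr, 2)
  img36 <- matrix(36, intr@height, intr@width)
  fused <- fuseThermal(pc, img36, intr)
  expect_identical(coords(fused), coords(pc))
  expect_true(all(temperature(fused) == 36))
  # two-temperature image split at u = cx
  img <- matrix(20, intr@height, intr@width)
  img[, (floor(intr@cx) + 2):intr@width] <- 40   # u > cx -> warm
  fused2 <- fuseThermal(pc, img, intr)
  xs <- coords(fused2)[, 1]
  tt <- temperature(fused2)
  expect_true(all(tt[xs > 0.02] == 40))
  expect_true(all(tt[xs < -0.02] == 20))
  # a point projecting outside the image keeps no temperature
  far <- pointCloud(matrix(c(100, 0, 1), 1, 3))
  expect_true(is.na(temperature(fuseThermal(far, img36, intr))))
})

test_that("calibration configs parse intrinsics and extrinsics", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(sensors = list(
    depth = list(fx = 365, fy = 365, cx = 255.5, cy = 211.5,
                 width = 512, height = 424),
    thermal = list(fx = 330, fy = 330, cx = 191, cy = 143.5,
                   dist = c(-0.2, 0.05, 0, 0, 0),
                   rotation = diag(3), translation = c(0.05, 0, 0)))),
    auto_unbox = TRUE), f)
  cal <- readCalibrationConfig(f)
  expect_equal(cal$depth$intr@fx, 365)
  expect_null(cal$depth$extr)
  expect_equal(cal$thermal$intr@dist[1], -0.2)
  expect_equal(cal$thermal$extr@translation, c(0.05, 0, 0))
})
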
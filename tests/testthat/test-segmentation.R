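test_that("ROI cropping keeps exactly the in-box points", {
  roi <- list(min = c(0, 0, 0), max = c(1, 1, 1))
  inside <- matrix(runif(30, 0.1, 0.9), 10, 3)
  expect_equal(nValidPoints(cropROI(pointCloud(inside), roi)), 10)
  outside <- matrix(runif(30, 2, 3), 10, 3)
  expect_equal(nValidPoints(cropROI(pointCloud(outside), roi)), 0)
  set.seed(5)
  mixed <- rbind(matrix(runif(12, 0.2, 0.8), 4, 3),
                 matrix(runif(18, 1.5, 4), 6, 3))
  expect_equal(nValidPoints(cropROI(pointCloud(mixed), roi)), 4)
})

test_that("RANSAC finds a plane among clutter, reproducibly", {
  set.seed(8)
  gx <- runif(1000, -1, 1); gy <- runif(1000, -1, 1)
  n0 <- c(0.1, -0.2, 0.97); n0 <- n0 / sqrt(sum(n0^2))
  # plane through origin with normal n0: span by two orthogonal vectors
  b1 <- c(n0[3], 0, -n0[1]); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(n0[2] * b1[3] - n0[3] * b1[2],
          n0[3] * b1[1] - n0[1] * b1[3],
          n0[1] * b1[2] - n0[2] * b1[1])
  planePts <- outer(gx, b1) + outer(gy, b2)
  planePts <- sweep(planePts, 2, c(0, 0, 2), "+")
  boxPts <- cbind(runif(100, -0.2, 0.2), runif(100, -0.2, 0.2),
                  runif(100, 1.2, 1.6))
  cloud <- pointCloud(rbind(planePts, boxPts))
  out <- removePlaneRANSAC(cloud, tol = 0.01, iters = 300, seed = 4)
  expect_equal(nValidPoints(out$remainder), 100)
  # recovered normal within 0.5 degrees
  ang <- acos(min(abs(sum(out$plane@normal * n0)), 1)) * 180 / pi
  expect_lt(ang, 0.5)
  # all points coplanar -> empty remainder
  out2 <- removePlaneRANSAC(pointCloud(planePts), tol = 0.01,
                            iters = 100, seed = 1)
  expect_equal(nValidPoints(out2$remainder), 0)
  # bit-exact reproducibility given the seed
  outA <- removePlaneRANSAC(cloud, tol = 0.01, iters = 300, seed = 9)
  outB <- removePlaneRANSAC(cloud, tol = 0.01, iters = 300, seed = 9)
  expect_identical(coords(outA$remainder), coords(outB$remainder))
  expect_identical(outA$plane@normal, outB$plane@normal)
  expect_error(removePlaneRANSAC(pointCloud(matrix(1, 2, 3))),
               "3 valid points")
})

test_that("thermal thresholding keeps warm points only", {
  co <- matrix(rnorm(60), 20, 3)
  warm <- pointCloud(co, temperature = rep(36, 20))
  expect_equal(nValidPoints(thermalSegment(warm, 30)), 20)
  mixed <- pointCloud(co, temperature = rep(c(36, 22), 10))
  expect_equal(nValidPoints(thermalSegment(mixed, 30)), 10)
  expect_equal(nValidPoints(thermalSegment(mixed, 50)), 0)
  expect_error(thermalSegment(pointCloud(co), 30), "temperature")
})

test_that("background subtraction keeps only changed geometry", {
  intr <- testIntr()
  ref <- planeCloud(intr, 3)
  expect_equal(nValidPoints(subtractBackground(ref, ref, 0.05)), 0)
  # person surface at z = 1.5 in the central window
  d <- matrix(3, intr@height, intr@width)
  d[10:40, 20:45] <- 1.5
  scene <- depthToCloud(d, intr)
  out <- subtractBackground(scene, ref, 0.1)
  expect_equal(nValidPoints(out), 31 * 26)
  expect_true(all(validCoordsOf(out)[, 3] == 1.5))
  expect_equal(nValidPoints(subtractBackground(scene, ref, 10)), 0)
  refSmall <- planeCloud(intrinsics(100, 100, 15.5, 11.5,
                                    width = 32L, height = 24L), 3)
  expect_error(subtractBackground(scene, refSmall), "grids differ")
  expect_error(subtractBackground(scene, randomCloud(10)), "organized")
})

test_that("largest component survives with deterministic tie-breaks", {
  set.seed(14)
  blobA <- matrix(rnorm(1500, sd = 0.02), 500, 3)
  blobB <- sweep(matrix(rnorm(150, sd = 0.02), 50, 3), 2,
                 c(1, 0, 0), "+")
  out <- largestComponent(pointCloud(rbind(blobA, blobB)), 0.05)
  expect_equal(nValidPoints(out), 500)
  expect_lt(max(abs(colMeans(validCoordsOf(out)))), 0.1)
  single <- pointCloud(blobA)
  expect_equal(nValidPoints(largestComponent(single, 0.05)), 500)
  # tie: two equal blobs, the nearer one wins
  near <- matrix(c(0, 0, 1, 0.01, 0, 1), 2, 3, byrow = TRUE)
  far <- matrix(c(0, 0, 3, 0.01, 0, 3), 2, 3, byrow = TRUE)
  tied <- largestComponent(pointCloud(rbind(far, near)), 0.05)
  expect_equal(unname(validCoordsOf(tied)[1, 3]), 1)
  empty <- pointCloud(matrix(numeric(0), 0, 3))
  expect_equal(nValidPoints(largestComponent(empty, 0.05)), 0)
})

test_that("morphological opening removes speckles, keeps large regions", {
  m <- matrix(0L, 60, 60)
  m[6:55, 6:55] <- 1L
  opened <- morphologicalClean(m, 2)
  # opening never adds pixels and at most rounds the square's corners
  expect_true(all(opened <= m))
  expect_gt(sum(opened), 0.99 * sum(m))
  expect_equal(opened[20:40, 20:40], m[20:40, 20:40])
  dot <- matrix(0L, 20, 20); dot[10, 10] <- 1L
  expect_equal(sum(morphologicalClean(dot, 1)), 0)
  both <- m
  both[2, 2] <- both[58, 3] <- both[3, 58] <- 1L
  cleaned <- morphologicalClean(both, 1)
  expect_equal(cleaned[2, 2] + cleaned[58, 3] + cleaned[3, 58], 0L)
  expect_equal(cleaned, morphologicalClean(m, 1))
})

test_that("statistical outlier filter removes displaced points only", {
  g <- as.matrix(expand.grid(x = seq(0, 1, 0.05), y = seq(0, 1, 0.05),
                             z = 0))
  # a uniform grid survives (edge points have slightly sparser
  # neighborhoods, so the band must cover that tail)
  expect_equal(nValidPoints(statisticalOutlierFilter(pointCloud(g),
                                                     8, 5)), nrow(g))
  out <- rbind(g, c(0.5, 0.5, 1))
  filtered <- statisticalOutlierFilter(pointCloud(out), 8, 2)
  expect_true(all(validCoordsOf(filtered)[, 3] == 0))
  expect_gt(nValidPoints(filtered), 0.95 * nrow(g))
  # sigma -> infinity keeps everything
  expect_equal(nValidPoints(statisticalOutlierFilter(pointCloud(out),
                                                     8, 1e9)),
               nrow(out))
  expect_error(statisticalOutlierFilter(pointCloud(g[1:5, ]), 8),
               "more points than k")
})

test_that("lying segmentation recovers the person and the stretcher", {
  subj <- samplePopulation(2, seed = 31)[[1]]
  spec <- sceneSpec("lying", clutter = list(bystander = TRUE))
  sc <- renderScene(subj, spec, seed = 6)
  seg <- segmentLying(sc$cloud)
  tp <- sc$labels == "person" & validMask(sc$cloud)
  vm <- validMask(personCloud(seg))
  expect_gt(sum(vm & tp) / sum(tp), 0.99)
  expect_lt(sum(vm & !tp) / sum(!tp & validMask(sc$cloud)), 0.01)
  # partition: person + environment = valid scene points
  expect_equal(nValidPoints(personCloud(seg)) +
                 nValidPoints(environmentCloud(seg)),
               nValidPoints(sc$cloud))
  # stretcher plane recovered at its true pose
  expect_lt(abs(supportPlane(seg)@offset - 2), 0.01)
  expect_gt(abs(supportPlane(seg)@normal[3]), 0.999)
  # scene without a person raises an empty-segmentation error
  ref <- renderScene(NULL, sceneSpec("lying"), seed = 6)
  expect_error(segmentLying(ref$cloud), "empty segmentation")
})

test_that("standing segmentation via background subtraction recovers the
           person", {
  subj <- samplePopulation(2, seed = 31)[[2]]
  spec <- sceneSpec("standing")
  spec@pitchRad <- atan((1.5 - 0.87) / 2.6)
  ref <- renderScene(NULL, spec, seed = 61)
  sc <- renderScene(subj, spec, seed = 62)
  seg <- segmentStanding(sc$cloud, ref$cloud)
  tp <- sc$labels == "person" & validMask(sc$cloud)
  vm <- validMask(personCloud(seg))
  expect_gt(sum(vm & tp) / sum(tp), 0.99)
  expect_lt(sum(vm & !tp) / sum(!tp & validMask(sc$cloud)), 0.01)
  expect_equal(nValidPoints(personCloud(seg)) +
                 nValidPoints(environmentCloud(seg)),
               nValidPoints(sc$cloud))
  # the floor plane is the support plane (height ~ 1.5 m)
  expect_lt(abs(supportPlane(seg)@offset - 1.5), 0.02)
  expect_error(segmentStanding(ref$cloud, ref$cloud),
               "empty segmentation")
})
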
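test_that("subjects are deterministic with exact analytic weight", {
  a <- samplePopulation(1, seed = 10)[[1]]
  b <- samplePopulation(1, seed = 10)[[1]]
  expect_identical(groundTruthKg(a), groundTruthKg(b))
  expect_equal(groundTruthKg(a), a@density * analyticVolume(a))
  # volume equals the sum of ellipsoid volumes (disjoint segments)
  vsum <- sum(vapply(a@segments,
                     function(s) 4 / 3 * pi * prod(s$semi), numeric(1)))
  expect_equal(analyticVolume(a), vsum)
})

test_that("population weights land in the calibrated band", {
  pop <- samplePopulation(300, seed = 1)
  w <- vapply(pop, groundTruthKg, numeric(1))
  expect_gt(mean(w), 77); expect_lt(mean(w), 85)
  expect_gt(sd(w), 12); expect_lt(sd(w), 18)
  expect_true(all(w >= 45 & w <= 140))
})

test_that("posture flags change the geometry as intended", {
  plain <- syntheticSubject(posture = list())
  crossed <- syntheticSubject(posture = list(armsCrossed = TRUE))
  fore <- function(s) Filter(function(g) grepl("forearm", g$name),
                             s@segments)
  zs <- vapply(fore(crossed), function(g) g$center[3], numeric(1))
  expect_true(all(zs > 0.1))          # forearms in front of the chest
  zp <- vapply(fore(plain), function(g) g$center[3], numeric(1))
  expect_true(all(zp == 0))
  # abduction moves arm centers outward symmetrically
  ab <- syntheticSubject(posture = list(armAbduction = 0.3))
  xa <- sort(vapply(fore(ab), function(g) g$center[1], numeric(1)))
  xp <- sort(vapply(fore(plain), function(g) g$center[1], numeric(1)))
  expect_gt(xa[2], xp[2])
  expect_lt(xa[1], xp[1])
})

test_that("noiseless lying renders put plane points exactly on the plane", {
  subj <- samplePopulation(1, seed = 4)[[1]]
  spec <- sceneSpec("lying", noiseSigma = 0)
  sc <- renderScene(subj, spec, seed = 1)
  env <- coords(sc$cloud)[sc$labels == "environment", ]
  stretcher <- env[abs(env[, 3] - 2) < 0.2, ]
  expect_gt(nrow(stretcher), 100)
  expect_lt(max(abs(stretcher[, 3] - 2)), 1e-9)
  # person points present and roughly matching the projected area
  nP <- sum(sc$labels == "person")
  expect_gt(nP, 0)
  intr <- spec@intr
  # projected-area prediction: frontal silhouette  ~ sum of segment
  # cross-sections seen at ~2 m
  areaPred <- sum(vapply(subj@segments, function(s)
    pi * s$semi[1] * s$semi[2], numeric(1)))
  pxPred <- areaPred * intr@fx * intr@fy / 2^2
  expect_gt(nP, pxPred * 0.8)
  expect_lt(nP, pxPred * 1.25)
})

test_that("rendering is deterministic and the thermal contrast is clean", {
  subj <- samplePopulation(1, seed = 5)[[1]]
  spec <- sceneSpec("lying")
  a <- renderScene(subj, spec, seed = 3)
  b <- renderScene(subj, spec, seed = 3)
  expect_identical(coords(a$cloud), coords(b$cloud))
  expect_identical(a$labels, b$labels)
  tt <- temperature(a$cloud)
  expect_true(all(tt[a$labels == "person"] == 36.5, na.rm = TRUE))
  expect_true(all(tt[a$labels == "environment"] == 21, na.rm = TRUE))
})

test_that("volume feature of a noiseless lying render tracks the frontal
           analytic volume", {
  # single-ellipsoid 'subject': frontal volume over the tangent back
  # plane is analytic: pi*a*b*c + 2/3*pi*a*b*c (dome plus skirt)
  subj <- samplePopulation(1, seed = 8)[[1]]
  spec <- sceneSpec("lying", noiseSigma = 0)
  sc <- renderScene(subj, spec, seed = 1)
  seg <- segmentLying(sc$cloud)
  mesh <- computeFrontalMesh(personCloud(seg))
  vol <- computeVolume(mesh, supportPlane(seg))
  # frontal volume of the whole body: between 1x and 2x the body volume
  expect_gt(vol, analyticVolume(subj))
  expect_lt(vol, 2 * analyticVolume(subj))
})

test_that("walking sequences approach the camera deterministically", {
  subj <- samplePopulation(1, seed = 6)[[1]]
  spec <- sceneSpec("walking", subjectDistanceM = 3.3)
  frames <- renderWalk(subj, spec, nFrames = 8, seed = 2,
                       endDistance = 2.0)
  depths <- vapply(frames, function(f) {
    p <- coords(f$cloud)[f$labels == "person", ]
    mean(p[, 3])
  }, numeric(1))
  expect_true(all(diff(depths) < 0))
  counts <- vapply(frames, function(f) sum(f$labels == "person"),
                   numeric(1))
  expect_gt(counts[8], counts[1])
  again <- renderWalk(subj, spec, nFrames = 8, seed = 2,
                      endDistance = 2.0)
  expect_identical(coords(frames[[3]]$cloud), coords(again[[3]]$cloud))
})

test_that("fixture sets follow the naming convention and manifest", {
  dir <- withr::local_tempdir()
  pop <- samplePopulation(2, seed = 12)
  spec <- sceneSpec("lying")
  man <- writeFixtureSet(pop, spec, dir, framesPerSubject = 3, seed = 1)
  pcds <- list.files(dir, pattern = "\\.pcd$")
  expect_length(pcds, 6)
  for (f in pcds) {
    meta <- parseDatasetFilename(f)
    subj <- pop[[meta$person_id]]
    expect_equal(meta$ground_truth_kg, round(groundTruthKg(subj), 1))
    expect_equal(meta$gender, subj@gender)
  }
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(man$ground_truth_kg,
               rep(vapply(pop, groundTruthKg, numeric(1)), each = 3))
  # round-trip: read one fixture back and segment it
  pc <- readPCD(file.path(dir, pcds[1]))
  expect_true(isOrganized(pc))
  expect_true(hasTemperature(pc))
  seg <- segmentLying(pc)
  labs <- readLines(file.path(dir, sub("\\.pcd$", ".labels.txt",
                                       pcds[1])))
  tp <- labs == "person" & validMask(pc)
  vm <- validMask(personCloud(seg))
  expect_gt(sum(vm & tp) / sum(tp), 0.99)
})
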
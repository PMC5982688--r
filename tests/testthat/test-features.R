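test_that("scatter eigenvalues match hand computation and a brute-force
           characteristic-polynomial oracle", {
  expect_equal(scatterEigenvalues(rbind(c(0, 0, 0), c(1, 0, 0),
                                        c(2, 0, 0))),
               c(2, 0, 0))
  expect_error(scatterEigenvalues(rbind(c(0, 0, 0), c(1, 1, 1))),
               "at least 3")
  # oracle: roots of det(S - lambda I) via polyroot
  set.seed(3)
  pts <- matrix(rnorm(600), 200, 3)
  s <- crossprod(sweep(pts, 2, colMeans(pts)))
  cf <- c(-det(s),
          s[1, 1] * s[2, 2] - s[1, 2]^2 + s[1, 1] * s[3, 3] -
            s[1, 3]^2 + s[2, 2] * s[3, 3] - s[2, 3]^2,
          -(s[1, 1] + s[2, 2] + s[3, 3]), 1)
  roots <- sort(Re(polyroot(cf)), decreasing = TRUE)
  expect_equal(scatterEigenvalues(pts), roots, tolerance = 1e-9)
})

test_that("eigen shape ratios reproduce the known poses", {
  f <- eigenShapeFeatures(4.7e3, 3.9e2, 7.1e1)
  expect_equal(round(f[["flatness"]], 4), 0.1236)
  expect_equal(round(f[["linearity"]], 4), 0.8351)
  expect_equal(eigenShapeFeatures(c(1, 1, 1)),
               c(sphericity = 1 / 3, flatness = 0, linearity = 0))
  expect_equal(eigenShapeFeatures(c(2, 0, 0)),
               c(sphericity = 0, flatness = 0, linearity = 1))
  expect_error(eigenShapeFeatures(c(0, 0, 0)), "positive")
})

test_that("eigen identities hold for random clouds", {
  set.seed(11)
  for (k in 1:25) {
    ev <- scatterEigenvalues(matrix(rnorm(90) * runif(1, 0.1, 10),
                                    30, 3))
    f <- eigenShapeFeatures(ev)
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(sum(f), (ev[1] + ev[2] - ev[3]) / sum(ev))
    expect_lte(sum(f), 1 + 1e-12)
  }
})

test_that("frontal mesh triangulates valid quads below the jump threshold", {
  intr <- intrinsics(fx = 10, fy = 10, cx = 1, cy = 1,
                     width = 3L, height = 3L)
  pc <- planeCloud(intr, 1)
  mesh <- computeFrontalMesh(pc)
  expect_equal(nrow(mesh@triangles), 8)
  # invalidate the center pixel: no triangle may touch it
  co <- coords(pc); co[5, ] <- NaN
  pc2 <- pointCloud(co, width = 3L, height = 3L)
  expect_equal(nrow(computeFrontalMesh(pc2)@triangles), 0)
  expect_error(computeFrontalMesh(randomCloud(9)), "organized")
  # depth jumps are not bridged
  co3 <- coords(pc); co3[1:3, 3] <- 2
  expect_lt(nrow(computeFrontalMesh(pointCloud(co3, width = 3L,
                                               height = 3L))@triangles),
            8)
})

test_that("mesh surface area is exact for planar grids and agrees with a
           per-triangle Heron oracle", {
  expect_equal(computeSurface(new("FrontalMesh",
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    triangles = matrix(1:3, 1))), 0.5)
  expect_equal(computeSurface(new("FrontalMesh",
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    triangles = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))), 1.0)
  intr <- testIntr()
  pc <- planeCloud(intr, 2)
  mesh <- computeFrontalMesh(pc)
  ext <- apply(validCoordsOf(pc)[, 1:2], 2, function(x) diff(range(x)))
  expect_equal(computeSurface(mesh), prod(ext), tolerance = 1e-6)
  # Heron oracle on a random mesh
  set.seed(4)
  v <- matrix(rnorm(30), 10, 3)
  tri <- matrix(sample(10, 9, TRUE), 3, 3)
  tri <- tri[apply(tri, 1, function(r) length(unique(r)) == 3), ,
             drop = FALSE]
  mesh2 <- new("FrontalMesh", vertices = v, triangles = tri)
  heron <- sum(apply(tri, 1, function(r) {
    a <- sqrt(sum((v[r[1], ] - v[r[2], ])^2))
    b <- sqrt(sum((v[r[2], ] - v[r[3], ])^2))
    c_ <- sqrt(sum((v[r[3], ] - v[r[1], ])^2))
    s <- (a + b + c_) / 2
    sqrt(max(s * (s - a) * (s - b) * (s - c_), 0))
  }))
  expect_equal(computeSurface(mesh2), heron, tolerance = 1e-9)
})

test_that("prism volume recovers analytic solids within 2% at 5 mm grid", {
  plane <- new("PlaneModel", normal = c(0, 0, -1), offset = 2)
  grid5 <- function(xr, yr) {
    xs <- seq(xr[1], xr[2], by = 0.005)
    ys <- seq(yr[1], yr[2], by = 0.005)
    list(x = rep(xs, times = length(ys)),
         y = rep(ys, each = length(xs)),
         w = length(xs), h = length(ys))
  }
  # flat 1 m x 0.5 m patch 0.2 m above the plane -> 0.1 m^3
  g <- grid5(c(0, 1), c(0, 0.5))
  patch <- pointCloud(cbind(g$x, g$y, 1.8), width = g$w, height = g$h)
  vol <- computeVolume(computeFrontalMesh(patch), plane)
  expect_lt(abs(vol - 0.1) / 0.1, 0.02)
  # mesh exactly on the plane -> 0
  onplane <- pointCloud(cbind(g$x, g$y, 2), width = g$w, height = g$h)
  expect_equal(computeVolume(computeFrontalMesh(onplane), plane), 0)
  # half-cylinder r = 0.15, L = 1 -> pi r^2 L / 2
  g2 <- grid5(c(-0.15, 0.15), c(0, 1))
  z <- 2 - sqrt(pmax(0.15^2 - g2$x^2, 0))
  half <- pointCloud(cbind(g2$x, g2$y, z), width = g2$w, height = g2$h)
  vol2 <- computeVolume(computeFrontalMesh(half), plane)
  truth <- pi * 0.15^2 * 1 / 2
  expect_lt(abs(vol2 - truth) / truth, 0.02)
})

test_that("statistical moments match hand computations", {
  two <- rbind(c(-1, 0, 0), c(1, 0, 0))
  f <- statisticalFeatures(two)
  expect_equal(f[["compactness"]], 1)
  expect_equal(f[["kurtosis"]], 2)
  expect_true(is.na(f[["alt_compactness"]]))
  same <- matrix(1, 4, 3)
  f2 <- statisticalFeatures(same, flatness = 0)
  expect_equal(f2[["compactness"]], 0)
  expect_equal(f2[["kurtosis"]], 0)
  expect_true(is.na(f2[["alt_compactness"]]))
  f3 <- statisticalFeatures(two, flatness = 0.5)
  expect_equal(f3[["alt_compactness"]], 1 / 0.5)
  expect_error(statisticalFeatures(matrix(0, 1, 3)), "at least 2")
})

test_that("distance to person uses the centroid (or nearest point)", {
  expect_equal(distanceToPerson(pointCloud(matrix(c(0, 0, 2), 1))), 2)
  pair <- pointCloud(rbind(c(-1, 0, 2), c(1, 0, 2)))
  expect_equal(distanceToPerson(pair), 2)
  expect_equal(distanceToPerson(pair, "nearest"), sqrt(5))
  expect_error(distanceToPerson(pointCloud(matrix(NaN, 1, 3))), "empty")
})

test_that("silhouette features follow the border-polygon convention", {
  intr <- intrinsics(fx = 50, fy = 50, cx = 15.5, cy = 15.5,
                     width = 32L, height = 32L)
  # filled 10x10 square of pixels at depth 1
  uu <- rep(8:17, times = 10); vv <- rep(8:17, each = 10)
  pc <- pointCloud(cbind((uu - intr@cx) / 50, (vv - intr@cy) / 50, 1))
  f <- silhouetteFeatures(pc, intr)
  expect_equal(f[["contour_area"]], 100)
  expect_equal(f[["contour_length"]], 36)
  expect_equal(f[["hull_length"]], 36)
  expect_equal(f[["hull_area"]], 100)
  # square with a deep notch: contour longer than hull, area smaller
  keep <- !(uu %in% 12:13 & vv >= 8 & vv <= 14)
  pc2 <- pointCloud(cbind((uu[keep] - intr@cx) / 50,
                          (vv[keep] - intr@cy) / 50, 1))
  f2 <- silhouetteFeatures(pc2, intr)
  expect_gt(f2[["contour_length"]], f2[["hull_length"]])
  expect_lt(f2[["contour_area"]], f2[["hull_area"]])
  expect_error(silhouetteFeatures(pointCloud(matrix(c(500, 0, 0.5), 1)),
                                  intr), "silhouette|empty")
})

test_that("f5-f13 are invariant under rigid transforms within 1e-9", {
  set.seed(21)
  base <- matrix(rnorm(300, sd = 0.4), 100, 3)
  ev0 <- scatterEigenvalues(base)
  st0 <- statisticalFeatures(base, flatness = 0.3)
  for (k in 1:20) {
    rt <- randomRigid(k)
    pts <- applyRigid(base, rt)
    expect_equal(scatterEigenvalues(pts), ev0, tolerance = 1e-9)
    expect_equal(statisticalFeatures(pts, flatness = 0.3), st0,
                 tolerance = 1e-9)
  }
})

test_that("extractFeatures fills availability flags correctly", {
  subj <- samplePopulation(1, seed = 2)[[1]]
  sc <- renderScene(subj, sceneSpec("lying"), seed = 1)
  seg <- segmentLying(sc$cloud)
  fv <- extractFeatures(personCloud(seg), scene = sc$cloud,
                        plane = supportPlane(seg), gender = "f")
  expect_true(all(featureAvailable(fv)))
  expect_equal(featureValues(fv)[["gender"]], 0)
  # no plane: volume unavailable, the rest present
  fv2 <- extractFeatures(personCloud(seg), scene = sc$cloud,
                         plane = NULL, gender = NULL)
  expect_false(featureAvailable(fv2)[["volume"]])
  expect_false(featureAvailable(fv2)[["gender"]])
  expect_true(featureAvailable(fv2)[["surface"]])
  # density is a simple ratio
  expect_equal(featureValues(fv)[["density"]],
               nValidPoints(personCloud(seg)) / nValidPoints(sc$cloud))
})
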
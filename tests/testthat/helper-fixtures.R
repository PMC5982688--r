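# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# cross-test scratch space (used to compare experiment modes)
.acceptanceCache <- new.env(parent = emptyenv())

# A small random unorganized cloud with optional color/temperature.
randomCloud <- function(n = 50, seed = 1, color = FALSE, temp = FALSE) {
  set.seed(seed)
  pointCloud(matrix(rnorm(n * 3), n, 3),
             color = if (color) matrix(sample(0:255, n * 3, TRUE), n, 3),
             temperature = if (temp) runif(n, 20, 40))
}

# Organized cloud of a flat plane at depth z0 seen by intr.
planeCloud <- function(intr, z0 = 1) {
  depthToCloud(matrix(z0, intr@height, intr@width), intr)
}

validCoordsOf <- function(cloud) coords(cloud)[validMask(cloud), ,
                                               drop = FALSE]

testIntr <- function() {
  intrinsics(fx = 100, fy = 100, cx = 31.5, cy = 23.5,
             width = 64L, height = 48L)
}

# Random rigid transform (rotation via QR, det +1).
randomRigid <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(r = q, t = rnorm(3, 0, 2))
}

applyRigid <- function(pts, rt) {
  sweep(pts %*% t(rt$r), 2, rt$t, "+")
}
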
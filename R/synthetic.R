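# Synthetic RGB-D(-T) scene generator: parametric humanoids with analytic
# ground-truth weight, rendered through the pinhole model into organized
# point clouds with depth noise, thermal contrast and per-point labels.
# This makes the whole pipeline (segmentation -> features -> estimator ->
# stream) testable without any recorded data.
#
# Body frame: origin at the feet contact point, x lateral, y up, z frontal
# (the direction the subject faces). Segments are ellipsoids, pairwise
# disjoint by construction, so the body volume is the exact sum of
# 4/3 pi abc terms and the label weight = density * volume carries no
# hidden noise.

ellipsoidVolume <- function(semi) 4 / 3 * pi * prod(semi)

# Base humanoid, 1.81 m tall: head, neck, chest, pelvis, 2 upper arms,
# 2 forearms, 2 thighs, 2 shins. Units meters. Adjacent segments are
# tangent (never overlapping), so the body volume is an exact sum, while
# every junction keeps the two surfaces within the Euclidean-clustering
# linkage radius of the segmentation stage, as a connected body should.
baseSegments <- function() {
  seg <- function(name, center, semi)
    list(name = name, center = center, semi = semi, rot = diag(3))
  list(
    seg("chest", c(0, 1.30, 0), c(0.19, 0.20, 0.13)),
    seg("pelvis", c(0, 1.00, 0), c(0.17, 0.10, 0.12)),
    seg("neck", c(0, 1.53, 0), c(0.06, 0.03, 0.06)),
    seg("head", c(0, 1.675, 0.02), c(0.09, 0.11, 0.095)),
    seg("shoulder_r", c(0.24, 1.425, 0), c(0.075, 0.055, 0.06)),
    seg("shoulder_l", c(-0.24, 1.425, 0), c(0.075, 0.055, 0.06)),
    seg("upper_arm_r", c(0.24, 1.22, 0), c(0.05, 0.15, 0.05)),
    seg("upper_arm_l", c(-0.24, 1.22, 0), c(0.05, 0.15, 0.05)),
    seg("forearm_r", c(0.24, 0.93, 0), c(0.042, 0.14, 0.042)),
    seg("forearm_l", c(-0.24, 0.93, 0), c(0.042, 0.14, 0.042)),
    seg("thigh_r", c(0.09, 0.67, 0.02), c(0.085, 0.23, 0.085)),
    seg("thigh_l", c(-0.09, 0.67, 0.02), c(0.085, 0.23, 0.085)),
    seg("shin_r", c(0.09, 0.22, 0.03), c(0.06, 0.22, 0.06)),
    seg("shin_l", c(-0.09, 0.22, 0.03), c(0.06, 0.22, 0.06))
  )
}

baseHeight <- 1.785

rotateSegmentAbout <- function(seg, pivot, rot) {
  seg$center <- drop(rot %*% (seg$center - pivot)) + pivot
  seg$rot <- rot %*% seg$rot
  seg
}

# Apply anthropometric scaling and posture to the base body. Beyond the
# global height/girth factors, torso depth (front-back) and limb girth
# vary independently: frontal-view features cannot see body depth, which
# is what makes the back-plane volume feature uniquely informative.
buildBody <- function(scaleH, scaleW, gender, posture,
                      depthFactor = 1, limbFactor = 1) {
  segs <- baseSegments()
  widen <- if (gender == "female") c(torso = 0.94, thigh = 1.04)
           else c(torso = 1.0, thigh = 1.0)
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    s$center <- s$center * c(scaleW, scaleH, scaleW)
    s$semi <- s$semi * c(scaleW, scaleH, scaleW)
    if (grepl("chest|pelvis|head", s$name)) {
      s$semi[c(1, 3)] <- s$semi[c(1, 3)] * widen[["torso"]]
      if (!grepl("head", s$name)) s$semi[3] <- s$semi[3] * depthFactor
    }
    if (grepl("thigh|shin", s$name)) {
      s$semi[c(1, 3)] <- s$semi[c(1, 3)] * widen[["thigh"]] * limbFactor
      s$center[1] <- s$center[1] * limbFactor  # keep the legs apart
      # keep the leg fronts nearly flush with the belly front whatever
      # the torso depth, so the hip and knee surfaces stay visibly
      # contiguous from every viewpoint
      wl <- widen[["thigh"]] * limbFactor
      pelvisFront <- 0.12 * widen[["torso"]] * depthFactor
      s$center[3] <- if (grepl("thigh", s$name))
        max(0, pelvisFront - 0.085 * wl - 0.005) * scaleW
      else
        max(0, pelvisFront - 0.060 * wl - 0.010) * scaleW
    }
    if (grepl("arm", s$name))
      s$semi[c(1, 3)] <- s$semi[c(1, 3)] * limbFactor
    segs[[i]] <- s
  }
  byName <- function(n) which(vapply(segs, `[[`, "", "name") == n)
  topOf <- function(s) s$center + c(0, s$semi[2], 0)
  ab <- posture$armAbduction %||% 0
  sw <- posture$armSwing %||% 0
  st <- posture$legStance %||% 0
  crossed <- isTRUE(posture$armsCrossed)
  for (side in c("r", "l")) {
    sgn <- if (side == "r") 1 else -1
    ua <- byName(paste0("upper_arm_", side))
    fa <- byName(paste0("forearm_", side))
    shoulder <- topOf(segs[[ua]])
    rot <- rotZ(sgn * ab) %*% rotX(sw * sgn)   # abduction swings outward
    segs[[ua]] <- rotateSegmentAbout(segs[[ua]], shoulder, rot)
    if (crossed) {
      # stacked horizontally across the belly, one above the other so the
      # segments stay disjoint and the analytic volume stays exact
      torso <- segs[[byName("chest")]]
      yc <- if (side == "r") 1.17 else 1.06
      segs[[fa]]$center <- c(sgn * 0.05 * scaleW, yc * scaleH,
                             torso$semi[3] + segs[[fa]]$semi[1] + 0.01)
      segs[[fa]]$rot <- rotZ(pi / 2)
    } else {
      segs[[fa]] <- rotateSegmentAbout(segs[[fa]], shoulder, rot)
    }
    th <- byName(paste0("thigh_", side))
    sh <- byName(paste0("shin_", side))
    hip <- topOf(segs[[th]])
    ls <- posture$legSwing %||% 0          # stride: legs alternate
    lrot <- rotZ(sgn * st) %*% rotX(sgn * ls)  # stance opens outward
    segs[[th]] <- rotateSegmentAbout(segs[[th]], hip, lrot)
    segs[[sh]] <- rotateSegmentAbout(segs[[sh]], hip, lrot)
  }
  segs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a synthetic subject
#'
#' @param scaleH,scaleW height and girth scale factors applied to the
#'   1.785 m base body.
#' @param gender "female" or "male".
#' @param posture list: \code{armAbduction} (rad), \code{armSwing} (rad),
#'   \code{legSwing} (rad), \code{legStance} (rad), \code{armsCrossed},
#'   \code{backpack} flags.
#' @param density tissue density, kg/m^3 (default 985, near water).
#' @param id integer subject id.
#' @param depthFactor torso front-back depth factor (belly build).
#' @param limbFactor limb girth factor.
#' @return a [SyntheticSubject-class] with exact analytic volume and
#'   ground-truth weight density * volume.
#' @export
syntheticSubject <- function(scaleH = 1, scaleW = 1, gender = "male",
                             posture = list(), density = 985,
                             id = 1L, depthFactor = 1, limbFactor = 1) {
  segs <- buildBody(scaleH, scaleW, gender, posture, depthFactor,
                    limbFactor)
  vol <- sum(vapply(segs, function(s) ellipsoidVolume(s$semi),
                    numeric(1)))
  posture$.depthFactor <- NULL
  posture$.limbFactor <- NULL
  new("SyntheticSubject", segments = segs, density = density,
      gender = gender,
      posture = c(posture, list(.depthFactor = depthFactor,
                                .limbFactor = limbFactor)),
      heightM = baseHeight * scaleH,
      analyticVolume = vol, groundTruthKg = density * vol,
      id = as.integer(id))
}

#' @rdname SyntheticSubject-class
#' @export
setMethod("groundTruthKg", "SyntheticSubject",
          function(x) x@groundTruthKg)

#' @rdname SyntheticSubject-class
#' @export
setMethod("analyticVolume", "SyntheticSubject",
          function(x) x@analyticVolume)

setMethod("show", "SyntheticSubject", function(object) {
  cat(sprintf(
    "SyntheticSubject #%d: %s, %.2f m, %.1f kg (V = %.4f m^3)\n",
    object@id, object@gender, object@heightM, object@groundTruthKg,
    object@analyticVolume))
})

#' Sample a population of synthetic subjects
#'
#' Height and girth scale factors are drawn log-normally, calibrated so the
#' resulting weight distribution matches a mixed adult cohort (mean about
#' 78 kg, sd about 15 kg); weights outside the configurable band are
#' re-drawn. Posture varies per subject (arm abduction, leg stance, a
#' minority with crossed arms). Deterministic given the seed.
#'
#' @param n number of subjects.
#' @param seed RNG seed.
#' @param density tissue density, kg/m^3.
#' @param meanKg target population mean weight.
#' @param band admissible weight range, kg.
#' @param sdLogH,sdLogW log-sd of the height and girth factors.
#' @param sdLogDepth,sdLogLimb log-sd of the independent torso-depth and
#'   limb-girth factors; body depth is invisible to frontal-view features
#'   and is what the back-plane volume feature captures.
#' @param crossedArmRate share of subjects with crossed arms. Default 0:
#'   most subjects hold their arms aside, and the disjoint-ellipsoid body
#'   renders crossed forearms as floating surfaces with depth cliffs a
#'   real connected body does not have (see the methods vignette); the
#'   posture remains available for descriptor-variation studies.
#' @return list of [SyntheticSubject-class] objects (ids 1..n).
#' @export
samplePopulation <- function(n, seed = 1L, density = 985,
                             meanKg = 78.3, band = c(45, 140),
                             sdLogH = 0.05, sdLogW = 0.09,
                             sdLogDepth = 0.10, sdLogLimb = 0.05,
                             crossedArmRate = 0) {
  stopifnot(n >= 1)
  # gender-averaged base weight so the population mean is on target
  w0 <- density * mean(c(
    sum(vapply(buildBody(1, 1, "male", list()),
               function(s) ellipsoidVolume(s$semi), numeric(1))),
    sum(vapply(buildBody(1, 1, "female", list()),
               function(s) ellipsoidVolume(s$semi), numeric(1)))))
  vTot <- sdLogH^2 + 4 * sdLogW^2
  muW <- (log(meanKg) - vTot / 2 - log(w0)) / 2
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        sh <- exp(stats::rnorm(1, 0, sdLogH))
        sw <- exp(stats::rnorm(1, muW, sdLogW))
        df <- exp(stats::rnorm(1, 0, sdLogDepth))
        lf <- exp(stats::rnorm(1, 0, sdLogLimb))
        gender <- if (stats::runif(1) < 0.5) "female" else "male"
        posture <- list(
          armAbduction = stats::runif(1, 0.05, 0.25),
          legStance = stats::runif(1, 0.02, 0.15),
          armsCrossed = stats::runif(1) < crossedArmRate,
          armSwing = 0)
        subj <- syntheticSubject(sh, sw, gender, posture, density, i,
                                 depthFactor = df, limbFactor = lf)
        if (subj@groundTruthKg >= band[1] &&
            subj@groundTruthKg <= band[2]) return(subj)
      }
    })
  })
}

#' Default synthetic depth sensor
#'
#' A wide-FOV time-of-flight-style sensor (70 x 60 degree field of view,
#' the Kinect One class) at 224 x 186 resolution: a 0.44 down-scaling that
#' keeps render and segmentation costs low while sampling the body densely
#' enough (1.3-1.6 cm pixel spacing at 2-2.6 m) that thin joints stay
#' connected at the segmentation linkage radius.
#' @export
syntheticIntrinsics <- function() {
  intrinsics(fx = 160.0, fy = 160.7, cx = 111.5, cy = 92.5,
             width = 224L, height = 186L)
}

#' Construct a scene specification
#'
#' @param mode "lying", "standing" or "walking".
#' @param intr sensor [Intrinsics-class].
#' @param cameraHeightM camera height above the floor (standing/walking);
#'   for lying scenes, the distance from the overhead camera down to the
#'   stretcher surface.
#' @param pitchRad downward pitch of the optical axis (standing/walking);
#'   NA picks a pitch centering the subject automatically.
#' @param subjectDistanceM camera-to-subject ground distance (start
#'   distance for walking).
#' @param noiseSigma along-ray Gaussian depth noise sd, meters (default
#'   3 mm, a mid-range depth-camera figure at 2 m).
#' @param bodyTempC,backgroundTempC thermal contrast.
#' @param withThermal attach a temperature channel.
#' @param clutter list; \code{bystander = TRUE} adds a cool blob beside
#'   the stretcher, \code{backpack = TRUE} a box behind the torso.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(mode = c("standing", "lying", "walking"),
                      intr = syntheticIntrinsics(),
                      cameraHeightM = if (match.arg(mode) == "lying") 2.0
                                      else 1.5,
                      pitchRad = NA_real_,
                      subjectDistanceM = if (match.arg(mode) == "lying")
                        2.0 else 2.6,
                      noiseSigma = 0.003,
                      bodyTempC = 36.5, backgroundTempC = 21,
                      withThermal = TRUE, clutter = list()) {
  mode <- match.arg(mode)
  new("SceneSpec", mode = mode, intr = intr,
      cameraHeightM = cameraHeightM, pitchRad = pitchRad,
      subjectDistanceM = subjectDistanceM, noiseSigma = noiseSigma,
      bodyTempC = bodyTempC, backgroundTempC = backgroundTempC,
      withThermal = withThermal, clutter = clutter)
}

# --- ray casting ---------------------------------------------------------

# Quadratic ray-ellipsoid intersection for all rays at once. dirs: n x 3
# unit directions, origin at 0. Returns distance along ray (Inf = miss).
rayEllipsoid <- function(dirs, center, semi, rot) {
  a3 <- sweep(dirs %*% rot, 2, semi, "/")        # rot = world orientation
  b3 <- -drop(crossprod(rot, center)) / semi
  aa <- rowSums(a3^2)
  ab <- drop(a3 %*% b3)
  bb <- sum(b3^2)
  disc <- ab^2 - aa * (bb - 1)
  t <- rep(Inf, nrow(dirs))
  hit <- disc >= 0
  th <- (-ab[hit] - sqrt(disc[hit])) / aa[hit]
  th[th <= 0] <- Inf
  t[hit] <- th
  t
}

# Axis-aligned box in a local frame given by rot/origin (slab method).
rayBox <- function(dirs, rot, origin, bmin, bmax) {
  d <- dirs %*% rot
  o <- -drop(crossprod(rot, origin))
  tmin <- rep(-Inf, nrow(dirs)); tmax <- rep(Inf, nrow(dirs))
  for (k in 1:3) {
    dk <- d[, k]
    para <- abs(dk) < 1e-12
    t1 <- (bmin[k] - o[k]) / dk
    t2 <- (bmax[k] - o[k]) / dk
    lo <- pmin(t1, t2); hi <- pmax(t1, t2)
    lo[para] <- ifelse(o[k] >= bmin[k] & o[k] <= bmax[k], -Inf, Inf)[para]
    hi[para] <- ifelse(o[k] >= bmin[k] & o[k] <= bmax[k], Inf, -Inf)[para]
    tmin <- pmax(tmin, lo); tmax <- pmin(tmax, hi)
  }
  t <- ifelse(tmax >= tmin & tmax > 0, ifelse(tmin > 0, tmin, Inf), Inf)
  t
}

# World-frame placement of the subject's segments.
placeSegments <- function(subject, rBody, tBody) {
  lapply(subject@segments, function(s) {
    list(center = drop(rBody %*% s$center) + tBody,
         semi = s$semi, rot = rBody %*% s$rot, name = s$name)
  })
}

segmentFrustumCheck <- function(segsW, toCam, intr) {
  for (s in segsW) {
    ax <- t(s$rot %*% diag(s$semi))          # rows: semi-axis vectors
    pts <- rbind(sweep(ax, 2, s$center, "+"),
                 sweep(-ax, 2, s$center, "+"))
    ptsC <- pts %*% t(toCam)
    if (any(ptsC[, 3] <= 0.05)) return(FALSE)
    uv <- cbind(intr@cx + intr@fx * ptsC[, 1] / ptsC[, 3],
                intr@cy + intr@fy * ptsC[, 2] / ptsC[, 3])
    if (any(uv[, 1] < 0 | uv[, 1] > intr@width - 1 |
            uv[, 2] < 0 | uv[, 2] > intr@height - 1)) return(FALSE)
  }
  TRUE
}

#' Render a synthetic scene into a labeled organized point cloud
#'
#' Depth-buffer sampling of the ellipsoid-union body plus supporting plane
#' and background through the pinhole model at sensor resolution. Gaussian
#' depth noise is added along each ray; body points carry the body
#' temperature and environment points the background temperature. Labels
#' ("person" / "environment" / "clutter") are returned out-of-band for
#' tests. Deterministic given (subject, spec, seed).
#'
#' @param subject a [SyntheticSubject-class].
#' @param spec a [SceneSpec-class].
#' @param seed RNG seed for the depth noise.
#' @param distance override of the camera-to-subject distance (used by
#'   [renderWalk()]).
#' @param lateralOffset subject offset across the walking line, meters.
#' @param postureOverride list overriding posture fields for this frame.
#' @return list with \code{cloud} (organized [PointCloud-class]),
#'   \code{labels} (character vector, one per point) and \code{plane}
#'   (the true support [PlaneModel-class], camera frame).
#' @export
renderScene <- function(subject, spec, seed = 1L, distance = NULL,
                        lateralOffset = 0, postureOverride = NULL) {
  intr <- spec@intr
  w <- intr@width; h <- intr@height
  stopifnot(w > 0, h > 0)
  if (!is.null(subject) && !is.null(postureOverride)) {
    posture <- utils::modifyList(subject@posture, postureOverride)
    subject <- syntheticSubject(subject@heightM / baseHeight,
                                scaleWOf(subject), subject@gender,
                                posture, subject@density, subject@id,
                                depthFactor =
                                  posture$.depthFactor %||% 1,
                                limbFactor =
                                  posture$.limbFactor %||% 1)
  }
  uu <- rep(0:(w - 1L), times = h)
  vv <- rep(0:(h - 1L), each = w)
  dcam <- cbind((uu - intr@cx) / intr@fx, (vv - intr@cy) / intr@fy, 1)
  dcam <- dcam / sqrt(rowSums(dcam^2))
  n <- nrow(dcam)
  D <- distance %||% spec@subjectDistanceM

  tBuf <- rep(Inf, n)
  lab <- rep("environment", n)
  hitUpdate <- function(t, what) {
    closer <- t < tBuf
    tBuf[closer] <<- t[closer]
    lab[closer] <<- what
  }

  if (spec@mode == "lying") {
    toCam <- diag(3)
    dG <- dcam
    zs <- spec@cameraHeightM              # stretcher depth below camera
    # floor (well below the stretcher)
    tFloor <- (zs + 1.4) / dG[, 3]
    hitUpdate(tFloor, "environment")
    # stretcher rectangle
    tS <- zs / dG[, 3]
    px <- tS * dG[, 1]; py <- tS * dG[, 2]
    tS[abs(px) > 1.08 | abs(py) > 0.40] <- Inf
    hitUpdate(tS, "environment")
    rBody <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3)
    tBody <- c(0, lateralOffset, zs)
    if (!is.null(subject)) {
      # rest the deepest body segment on the stretcher surface
      backExtent <- vapply(subject@segments, function(s)
        sqrt(sum((s$rot[3, ] * s$semi)^2)) - s$center[3], numeric(1))
      tBody <- c(-subject@heightM / 2, lateralOffset,
                 zs - max(backExtent))
    }
    truePlane <- new("PlaneModel", normal = c(0, 0, -1), offset = zs,
                     tolerance = 0.015)
    if (isTRUE(spec@clutter$bystander)) {
      tC <- rayEllipsoid(dG, c(0.15, 0.55, 1.82),
                         c(0.17, 0.17, 0.17), diag(3))
      hitUpdate(tC, "clutter")
    }
  } else {
    pitch <- spec@pitchRad
    if (is.na(pitch)) {
      midH <- if (is.null(subject)) 0.87 else subject@heightM / 2
      pitch <- atan((spec@cameraHeightM - midH) / D)
    }
    toCam <- rotX(pitch)
    dG <- dcam %*% toCam                  # rays in the gravity frame
    hC <- spec@cameraHeightM
    # the room is fixed: the wall sits behind the scene's nominal subject
    # position, not behind wherever the subject currently stands
    zw <- spec@subjectDistanceM + 2.0
    tF <- ifelse(dG[, 2] > 1e-9, hC / dG[, 2], Inf)
    fx_ <- tF * dG[, 1]; fz <- tF * dG[, 3]
    tF[abs(fx_) > 3.5 | fz < 0 | fz > zw] <- Inf
    hitUpdate(tF, "environment")
    tW <- ifelse(dG[, 3] > 1e-9, zw / dG[, 3], Inf)
    hitUpdate(tW, "environment")
    rBody <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3)
    clearance <- 0.025                    # shoe sole: keeps feet clear of
    tBody <- c(lateralOffset, hC - clearance, D)   # the floor tolerance
    nG <- c(0, -1, 0)                     # floor normal (toward camera)
    nC <- drop(toCam %*% nG)              # same plane in the camera frame
    truePlane <- new("PlaneModel", normal = nC, offset = hC,
                     tolerance = 0.015)
    if (!is.null(subject) && isTRUE(spec@clutter$backpack)) {
      tB <- rayBox(dG, rBody, drop(rBody %*% c(0, 1.2, -0.30)) + tBody,
                   c(-0.18, -0.25, -0.07), c(0.18, 0.25, 0.07))
      hitUpdate(tB, "clutter")
    }
  }

  if (!is.null(subject)) {
    segsW <- placeSegments(subject, rBody, tBody)
    if (!segmentFrustumCheck(segsW, toCam, intr))
      stop("subject does not fit inside the sensor frustum",
           call. = FALSE)
    for (s in segsW) {
      tS <- rayEllipsoid(dG, s$center, s$semi, s$rot)
      hitUpdate(tS, "person")
    }
  }

  tNoisy <- withSeed(seed, tBuf + stats::rnorm(n, 0, spec@noiseSigma))
  tNoisy[!is.finite(tBuf)] <- NaN
  co <- dcam * tNoisy
  temp <- NULL
  if (spec@withThermal) {
    temp <- ifelse(lab == "person", spec@bodyTempC, spec@backgroundTempC)
    temp[!is.finite(tNoisy)] <- NA_real_
  }
  meta <- if (is.null(subject)) list() else
    list(gender = subject@gender,
         ground_truth_kg = subject@groundTruthKg,
         person_id = subject@id)
  cloud <- pointCloud(co, temperature = temp, width = w, height = h,
                      meta = meta)
  list(cloud = cloud, labels = lab, plane = truePlane)
}

# Girth scale factor recovered from a built subject (torso x semi-axis
# relative to the base body, undoing the gender widening).
scaleWOf <- function(subject) {
  chest <- Filter(function(s) s$name == "chest", subject@segments)[[1]]
  widen <- if (subject@gender == "female") 0.94 else 1.0
  chest$semi[1] / (0.19 * widen)
}

#' Render a walking sequence
#'
#' The subject translates from the start marker toward the camera down to
#' \code{endDistance}, with per-frame arm swing and small posture
#' perturbations. Each frame is a [renderScene()] render; deterministic
#' given the seed.
#'
#' @param subject a [SyntheticSubject-class].
#' @param spec a [SceneSpec-class] (mode "walking" or "standing"); the
#'   camera pitch is fixed at mid-path so the sensor does not move.
#' @param nFrames number of frames (>= 1).
#' @param seed RNG seed.
#' @param endDistance distance at the near marker, meters.
#' @param swingAmplitude arm-swing amplitude, radians.
#' @param strideAmplitude leg-stride amplitude, radians (legs alternate,
#'   in antiphase with the arms, over an 8-frame gait cycle).
#' @return list of per-frame [renderScene()] results.
#' @export
renderWalk <- function(subject, spec, nFrames = 20L, seed = 1L,
                       endDistance = 2.0, swingAmplitude = 0.25,
                       strideAmplitude = 0.3) {
  stopifnot(nFrames >= 1)
  startD <- spec@subjectDistanceM
  if (is.na(spec@pitchRad)) {
    midD <- (startD + endDistance) / 2
    spec@pitchRad <- atan((spec@cameraHeightM - subject@heightM / 2) /
                            midD)
  }
  dists <- if (nFrames == 1) startD else
    seq(startD, endDistance, length.out = nFrames)
  lat <- withSeed(seed, stats::rnorm(nFrames, 0, 0.02))
  lapply(seq_len(nFrames), function(i) {
    ph <- 2 * pi * (i - 1) / 8
    renderScene(subject, spec, seed = seed + i,
                distance = dists[i], lateralOffset = lat[i],
                postureOverride = list(
                  armSwing = swingAmplitude * sin(ph),
                  legSwing = -strideAmplitude * sin(ph)))
  })
}

#' Write a fixture set of PCD frames plus a manifest
#'
#' Files follow the open dataset's naming convention
#' GENDER_GROUNDTRUTH_PERSONID_FRAMEID.pcd; per-frame ground-truth labels
#' go to parallel <stem>.labels.txt files and a manifest.csv records the
#' analytic ground truth.
#'
#' @param population list of [SyntheticSubject-class] objects.
#' @param spec a [SceneSpec-class].
#' @param outDir writable output directory (created if missing).
#' @param framesPerSubject frames rendered per subject.
#' @param seed RNG seed.
#' @param dialect PCD dialect passed to [writePCD()].
#' @return invisibly, the manifest data.frame.
#' @export
writeFixtureSet <- function(population, spec, outDir,
                            framesPerSubject = 1L, seed = 1L,
                            dialect = "binary") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (subj in population) {
    frames <- if (spec@mode == "walking")
      renderWalk(subj, spec, nFrames = framesPerSubject,
                 seed = seed + subj@id * 1000L)
    else lapply(seq_len(framesPerSubject), function(f)
      renderScene(subj, spec, seed = seed + subj@id * 1000L + f))
    for (f in seq_along(frames)) {
      stem <- sprintf("%s_%s_%03d_%04d",
                      substr(subj@gender, 1, 1),
                      formatC(round(subj@groundTruthKg, 1), format = "fg"),
                      subj@id, f)
      writePCD(frames[[f]]$cloud, file.path(outDir,
                                            paste0(stem, ".pcd")),
               dialect = dialect)
      writeLines(frames[[f]]$labels,
                 file.path(outDir, paste0(stem, ".labels.txt")))
      rows[[length(rows) + 1L]] <- data.frame(
        file = paste0(stem, ".pcd"), gender = subj@gender,
        ground_truth_kg = subj@groundTruthKg,
        analytic_volume_m3 = subj@analyticVolume,
        person_id = subj@id, frame_id = f)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
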
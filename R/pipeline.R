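# End-to-end experiment driver tying the stages together:
# simulate -> segment -> extract -> split -> train -> predict -> evaluate,
# with the stream aggregation added for walking sequences. Reports mirror
# the standard result-table layout (relative-error min/max/mean/sd, share
# within 5/10/20 percent, MAE, MSE) and are reproducible given the seed.

# Render one subject's scene plus (standing) a person-free reference with
# the identical camera pose, segment it and extract the descriptor.
frameFeatures <- function(subject, spec, segCfg, seed,
                          distance = NULL, useVolume = TRUE,
                          postureOverride = NULL) {
  if (spec@mode == "lying") {
    sc <- renderScene(subject, spec, seed = seed, distance = distance,
                      postureOverride = postureOverride)
    seg <- segmentLying(sc$cloud, segCfg)
    fv <- extractFeatures(seg@person, scene = sc$cloud,
                          plane = if (useVolume) seg@supportPlane,
                          gender = subject@gender)
  } else {
    D <- distance %||% spec@subjectDistanceM
    if (is.na(spec@pitchRad))
      spec@pitchRad <- atan((spec@cameraHeightM - 0.87) / D)
    ref <- renderScene(NULL, spec, seed = seed + 1L, distance = D)
    sc <- renderScene(subject, spec, seed = seed, distance = D,
                      postureOverride = postureOverride)
    seg <- segmentStanding(sc$cloud, ref$cloud, segCfg)
    fv <- extractFeatures(seg@person, scene = sc$cloud, plane = NULL,
                          gender = subject@gender)
  }
  fv
}

# Feature table for a population, one frame per subject.
populationFeatures <- function(pop, spec, segCfg, seed,
                               distances = NULL, useVolume = TRUE,
                               armSwing = NULL, legSwing = NULL) {
  fvs <- vector("list", length(pop))
  for (i in seq_along(pop)) {
    po <- c(if (!is.null(armSwing)) list(armSwing = armSwing[i]),
            if (!is.null(legSwing)) list(legSwing = legSwing[i]))
    fvs[[i]] <- frameFeatures(pop[[i]], spec, segCfg,
                              seed = seed + i * 17L,
                              distance = distances[i],
                              useVolume = useVolume,
                              postureOverride = if (length(po)) po)
  }
  tab <- featureTable(fvs)
  tab$ground_truth_kg <- vapply(pop, groundTruthKg, numeric(1))
  tab$person_id <- vapply(pop, function(s) s@id, integer(1))
  tab
}

# Columns of the descriptor usable as network inputs: available in every
# frame of the table (plus an explicit exclusion list).
usableFeatureMask <- function(tab, exclude = character(0)) {
  nm <- weightFeatureNames()
  ok <- vapply(nm, function(cn) all(is.finite(tab[[cn]])), logical(1))
  ok[nm %in% exclude] <- FALSE
  ok
}

#' Run a full synthetic body-weight estimation experiment
#'
#' Generates a population of synthetic subjects, renders their scenes,
#' segments each, extracts the f1..f19 descriptor, splits 70/30 at subject
#' level, trains the network on the training share and evaluates on the
#' held-out subjects. In walking mode the network is trained on
#' standing-mode renders spanning the walking path's distance range (the
#' descriptor has no volume there) and evaluated per frame on walking
#' sequences, with the stream-clustering aggregate compared against the
#' per-frame estimates.
#'
#' @param mode "lying", "standing" or "walking".
#' @param nSubjects population size (for walking: training population;
#'   \code{nWalkSubjects} controls the evaluated sequences).
#' @param seed master seed; every random stage derives from it.
#' @param spec optional [sceneSpec()] override.
#' @param segCfg a [segmentationConfig()] list.
#' @param netCfg a [networkConfig()] list.
#' @param keepFraction stream-clustering keep fraction (walking).
#' @param nWalkSubjects,nFramesPerWalk walking-sequence counts.
#' @param noiseSigma depth-noise override, meters.
#' @param trials number of independently initialized networks; the
#'   reported prediction is their median, damping the run-to-run
#'   variability of randomly initialized training.
#' @return list with \code{metrics} (test-set [evaluateEstimates()]
#'   result), \code{table} (result-table row), \code{model}, plus
#'   per-frame and per-stream detail in walking mode.
#' @export
runExperiment <- function(mode = c("lying", "standing", "walking"),
                          nSubjects = 300L, seed = 1L,
                          spec = NULL,
                          segCfg = segmentationConfig(),
                          netCfg = networkConfig(seed = seed),
                          keepFraction = 0.2,
                          nWalkSubjects = 14L, nFramesPerWalk = 20L,
                          noiseSigma = NULL, trials = 3L) {
  mode <- match.arg(mode)
  trainTrials <- function(x, y, ids, mask) {
    lapply(seq_len(trials), function(t) {
      cfg <- netCfg
      cfg$seed <- netCfg$seed + (t - 1L) * 1009L
      trainWeightNet(x, y, personIds = ids, cfg = cfg,
                     featureMask = mask)
    })
  }
  predictTrials <- function(models, x) {
    apply(vapply(models, function(m) predictWeight(m, x),
                 numeric(nrow(x))), 1L, stats::median)
  }
  if (mode %in% c("lying", "standing")) {
    if (is.null(spec)) spec <- sceneSpec(mode)
    if (!is.null(noiseSigma)) spec@noiseSigma <- noiseSigma
    pop <- samplePopulation(nSubjects, seed = seed)
    distances <- withSeed(seed + 5L, {
      if (mode == "lying") rep(spec@subjectDistanceM, nSubjects)
      else stats::runif(nSubjects, spec@subjectDistanceM - 0.2,
                        spec@subjectDistanceM + 0.2)
    })
    tab <- populationFeatures(pop, spec, segCfg, seed = seed * 101L,
                              distances = distances,
                              useVolume = mode == "lying")
    mask <- usableFeatureMask(tab)
    sp <- splitBySubject(tab$person_id, netCfg$trainFraction, seed)
    x <- as.matrix(tab[, weightFeatureNames()[mask], drop = FALSE])
    models <- trainTrials(x[sp$train, , drop = FALSE],
                          tab$ground_truth_kg[sp$train],
                          tab$person_id[sp$train], mask)
    pred <- predictTrials(models, x[sp$test, , drop = FALSE])
    metrics <- evaluateEstimates(pred, tab$ground_truth_kg[sp$test])
    return(list(mode = mode, seed = seed, metrics = metrics,
                table = metricsRow(mode, sum(sp$test), metrics),
                model = models[[1]], models = models, features = tab,
                split = sp))
  }

  # walking: train on standing renders across the path's distance range
  if (is.null(spec)) spec <- sceneSpec("walking",
                                       subjectDistanceM = 3.3)
  if (!is.null(noiseSigma)) spec@noiseSigma <- noiseSigma
  endD <- 2.0
  trainSpec <- sceneSpec("standing", intr = spec@intr,
                         cameraHeightM = spec@cameraHeightM,
                         noiseSigma = spec@noiseSigma)
  trainSpec@pitchRad <- atan((spec@cameraHeightM - 0.87) /
                               ((spec@subjectDistanceM + endD) / 2))
  pop <- samplePopulation(nSubjects, seed = seed)
  # two independent distance/pose draws per training subject so the
  # model can separate body shape from where along the path (and in
  # which gait phase) a frame was taken
  tabs <- lapply(1:2, function(rep) {
    distances <- withSeed(seed + 5L + rep,
                          stats::runif(nSubjects, endD - 0.1,
                                       spec@subjectDistanceM))
    swings <- withSeed(seed + 60L + rep, list(
      arm = stats::runif(nSubjects, -0.25, 0.25),
      leg = stats::runif(nSubjects, -0.3, 0.3)))
    populationFeatures(pop, trainSpec, segCfg,
                       seed = seed * 101L + rep * 31L,
                       distances = distances, useVolume = FALSE,
                       armSwing = swings$arm, legSwing = swings$leg)
  })
  tab <- rbind(tabs[[1]], tabs[[2]])
  mask <- usableFeatureMask(tab, exclude = "volume")
  x <- as.matrix(tab[, weightFeatureNames()[mask], drop = FALSE])
  models <- trainTrials(x, tab$ground_truth_kg, tab$person_id, mask)

  walkPop <- samplePopulation(nWalkSubjects, seed = seed + 999L)
  spec@pitchRad <- trainSpec@pitchRad
  perFrame <- list()
  streamPred <- truths <- numeric(length(walkPop))
  ref <- renderScene(NULL, spec, seed = seed + 7L,
                     distance = spec@subjectDistanceM)
  for (i in seq_along(walkPop)) {
    frames <- renderWalk(walkPop[[i]], spec, nFrames = nFramesPerWalk,
                         seed = seed + i * 1000L, endDistance = endD)
    fvs <- lapply(frames, function(fr) {
      seg <- segmentStanding(fr$cloud, ref$cloud, segCfg)
      extractFeatures(seg@person, scene = fr$cloud, plane = NULL,
                      gender = walkPop[[i]]@gender)
    })
    fx <- as.matrix(featureTable(fvs))[, mask, drop = FALSE]
    est <- predictTrials(models, fx)
    streamPred[i] <- streamEstimate(est, keepFraction)
    truths[i] <- groundTruthKg(walkPop[[i]])
    perFrame[[i]] <- est
  }
  metrics <- evaluateEstimates(streamPred, truths)
  list(mode = mode, seed = seed, metrics = metrics,
       table = metricsRow(mode, length(walkPop), metrics),
       model = models[[1]], models = models,
       perFrameEstimates = perFrame,
       streamEstimates = streamPred, truths = truths)
}

metricsRow <- function(mode, n, m) {
  data.frame(mode = mode, n = n,
             rel_min = m$minRel, rel_max = m$maxRel,
             rel_mean = m$meanRel, rel_sd = m$sdRel,
             within5 = m$pctWithin5, within10 = m$pctWithin10,
             within20 = m$pctWithin20, mae = m$mae, mse = m$mse)
}

#' Cumulative relative-error curve
#'
#' For thresholds 0..30 percent (step 1), the share of subjects whose
#' absolute relative error is at most the threshold. The curve is a
#' nondecreasing step function.
#'
#' @param metrics an [evaluateEstimates()] result (or a numeric vector of
#'   relative errors as fractions).
#' @return data.frame with \code{threshold_pct} and \code{cumulative_pct}.
#' @export
cumulativeErrorCurve <- function(metrics) {
  eps <- if (is.list(metrics)) metrics$relErr else metrics
  thr <- 0:30
  data.frame(threshold_pct = thr,
             cumulative_pct = vapply(thr, function(tp)
               100 * mean(abs(eps) <= tp / 100 + 1e-12), numeric(1)))
}

#' Write an experiment report to JSON (and its table to CSV)
#'
#' @param result a [runExperiment()] result.
#' @param path output JSON path; a sibling .csv is written next to it.
#' @export
writeReport <- function(result, path) {
  jsonlite::write_json(list(
    mode = result$mode, seed = result$seed,
    table = result$table,
    relative_errors = result$metrics$relErr,
    cumulative = cumulativeErrorCurve(result$metrics)),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$table, sub("\\.json$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}
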
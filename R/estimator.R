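# Three-layer feed-forward regression of body weight from the feature
# descriptor, trained full-batch by resilient propagation (iRPROP- variant)
# on squared error with L2 weight decay, with a subject-level validation
# split driving early stopping. The output neuron is linear and emits
# kilograms directly.

#' Network and training configuration
#'
#' @param nHidden hidden-layer size (tanh units).
#' @param weightDecay L2 penalty coefficient on all weights.
#' @param etaPlus,etaMinus,delta0,deltaMin,deltaMax resilient-propagation
#'   step control (published standard defaults).
#' @param maxEpochs upper bound on training epochs.
#' @param patience early-stopping patience: epochs without a new best
#'   validation error before training aborts.
#' @param valFraction fraction of training subjects held out as the
#'   validation set for early stopping.
#' @param trainFraction share of subjects that [splitBySubject()] assigns
#'   to the training side.
#' @param seed RNG seed for weight initialization and internal splits.
#' @return named list of parameters.
#' @export
networkConfig <- function(nHidden = 16L, weightDecay = 1e-4,
                          etaPlus = 1.2, etaMinus = 0.5, delta0 = 0.1,
                          deltaMin = 1e-6, deltaMax = 50,
                          maxEpochs = 2000L, patience = 50L,
                          valFraction = 0.15, trainFraction = 0.70,
                          seed = 1L) {
  stopifnot(etaMinus < 1, etaPlus > 1,
            trainFraction > 0, trainFraction < 1)
  list(nHidden = as.integer(nHidden), weightDecay = weightDecay,
       etaPlus = etaPlus, etaMinus = etaMinus, delta0 = delta0,
       deltaMin = deltaMin, deltaMax = deltaMax,
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       valFraction = valFraction, trainFraction = trainFraction,
       seed = as.integer(seed))
}

#' Split frames into train and test sets at subject granularity
#'
#' No subject contributes frames to both sides (avoids leakage across the
#' frames of one walking sequence). The training side receives
#' round(fraction * nSubjects) subjects, drawn deterministically given the
#' seed.
#'
#' @param personIds vector of subject identifiers, one per frame.
#' @param fraction training share of subjects, default 0.70.
#' @param seed RNG seed.
#' @return list with logical \code{train} and \code{test} frame masks and
#'   the \code{trainSubjects} / \code{testSubjects} id vectors.
#' @export
splitBySubject <- function(personIds, fraction = 0.70, seed = 1L) {
  subj <- unique(personIds)
  if (length(subj) < 2)
    stopDegenerate("subject-level split needs at least 2 subjects")
  nTrain <- roundHalfUp(fraction * length(subj))
  nTrain <- max(1L, min(length(subj) - 1L, nTrain))
  trainSubj <- withSeed(seed, sample(subj, nTrain))
  trainMask <- personIds %in% trainSubj
  list(train = trainMask, test = !trainMask,
       trainSubjects = trainSubj,
       testSubjects = setdiff(subj, trainSubj))
}

forwardNet <- function(w1, b1, w2, b2, xs) {
  hidden <- tanh(sweep(xs %*% t(w1), 2, b1, "+"))
  drop(hidden %*% w2) + b2
}

netGradients <- function(w1, b1, w2, b2, xs, y, wd) {
  n <- nrow(xs)
  a <- sweep(xs %*% t(w1), 2, b1, "+")
  hidden <- tanh(a)
  pred <- drop(hidden %*% w2) + b2
  r <- pred - y                                  # dE/dpred, E = mean(r^2)/2
  gw2 <- drop(crossprod(hidden, r)) / n + wd * w2
  gb2 <- mean(r)
  dh <- outer(r, w2) * (1 - hidden^2)            # n x h
  gw1 <- crossprod(dh, xs) / n + wd * w1
  gb1 <- colMeans(dh)
  list(gw1 = gw1, gb1 = gb1, gw2 = gw2, gb2 = gb2,
       loss = mean(r^2) / 2 + wd / 2 * (sum(w1^2) + sum(w2^2)))
}

#' Train the weight-estimation network
#'
#' Features are standardized on the training rows (constant columns get
#' unit scale). A subject-level validation split drives early stopping:
#' training aborts once the validation error has not improved for
#' \code{patience} epochs, and the weights of the best validation epoch are
#' returned. Resilient propagation (iRPROP-) adapts one step size per
#' weight from the gradient sign alone, so learning is invariant to the
#' scale of the error. Deterministic given the config seed.
#'
#' @param features numeric matrix (frames x features) or data.frame; NA
#'   entries are not allowed in used columns (mask features out instead).
#' @param weightsKg numeric vector of ground-truth weights.
#' @param personIds subject id per frame (used for the validation split);
#'   defaults to one subject per frame.
#' @param cfg a [networkConfig()] list.
#' @param featureMask logical 19-vector recording which descriptor
#'   components the columns of \code{features} correspond to (stored in
#'   the model for provenance; defaults to the first p components).
#' @return a [WeightNet-class].
#' @export
trainWeightNet <- function(features, weightsKg,
                           personIds = seq_along(weightsKg),
                           cfg = networkConfig(), featureMask = NULL) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stopDegenerate("training needs at least 2 rows")
  if (any(!is.finite(x)))
    stop("non-finite feature values; mask unavailable features out",
         call. = FALSE)
  if (is.null(featureMask)) {
    featureMask <- rep(FALSE, 19)
    featureMask[seq_len(min(p, 19))] <- TRUE
    if (p > 19) featureMask <- c(featureMask, rep(TRUE, p - 19))
  }
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  y <- as.numeric(weightsKg)

  # subject-level validation split for early stopping
  subj <- unique(personIds)
  nVal <- max(1L, roundHalfUp(cfg$valFraction * length(subj)))
  nVal <- min(nVal, length(subj) - 1L)
  valSubj <- if (length(subj) >= 2)
    withSeed(cfg$seed + 1L, sample(subj, nVal)) else character(0)
  valMask <- personIds %in% valSubj
  if (all(valMask) || !any(valMask)) valMask <- rep(FALSE, n)
  xtr <- xs[!valMask, , drop = FALSE]; ytr <- y[!valMask]
  xval <- xs[valMask, , drop = FALSE]; yval <- y[valMask]

  h <- cfg$nHidden
  init <- withSeed(cfg$seed, list(
    w1 = matrix(stats::runif(h * p, -0.5, 0.5) / sqrt(p), h, p),
    b1 = stats::runif(h, -0.1, 0.1)))
  w1 <- init$w1; b1 <- init$b1
  w2 <- rep(0, h); b2 <- mean(ytr)

  dW1 <- matrix(cfg$delta0, h, p); dB1 <- rep(cfg$delta0, h)
  dW2 <- rep(cfg$delta0, h); dB2 <- cfg$delta0
  pW1 <- matrix(0, h, p); pB1 <- rep(0, h); pW2 <- rep(0, h); pB2 <- 0

  rpropStep <- function(g, gPrev, delta) {
    s <- g * gPrev
    delta <- ifelse(s > 0, pmin(delta * cfg$etaPlus, cfg$deltaMax),
                    ifelse(s < 0, pmax(delta * cfg$etaMinus, cfg$deltaMin),
                           delta))
    g[s < 0] <- 0                    # iRPROP-: forget the sign flip
    list(step = -sign(g) * delta, g = g, delta = delta)
  }

  best <- list(err = Inf, w1 = w1, b1 = b1, w2 = w2, b2 = b2,
               epoch = 0L)
  trainTrace <- valTrace <- numeric(0)
  sinceBest <- 0L
  for (epoch in seq_len(cfg$maxEpochs)) {
    gr <- netGradients(w1, b1, w2, b2, xtr, ytr, cfg$weightDecay)
    s1 <- rpropStep(gr$gw1, pW1, dW1); w1 <- w1 + s1$step
    pW1 <- s1$g; dW1 <- s1$delta
    s2 <- rpropStep(gr$gb1, pB1, dB1); b1 <- b1 + s2$step
    pB1 <- s2$g; dB1 <- s2$delta
    s3 <- rpropStep(gr$gw2, pW2, dW2); w2 <- w2 + s3$step
    pW2 <- s3$g; dW2 <- s3$delta
    s4 <- rpropStep(gr$gb2, pB2, dB2); b2 <- b2 + s4$step
    pB2 <- s4$g; dB2 <- s4$delta

    trainTrace[epoch] <- gr$loss
    vErr <- if (length(yval))
      mean((forwardNet(w1, b1, w2, b2, xval) - yval)^2)
    else mean((forwardNet(w1, b1, w2, b2, xtr) - ytr)^2)
    valTrace[epoch] <- vErr
    if (vErr < best$err - 1e-12) {
      best <- list(err = vErr, w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                   epoch = epoch)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest > cfg$patience) break
    }
  }
  new("WeightNet", w1 = best$w1, b1 = best$b1, w2 = best$w2,
      b2 = best$b2, center = center, scale = scl,
      featureMask = as.logical(featureMask), config = cfg,
      history = list(train = trainTrace, validation = valTrace,
                     bestEpoch = best$epoch))
}

#' Predict body weight from features
#'
#' Forward pass through the trained network on standardized inputs. The
#' output is finite and unclamped (kilograms).
#'
#' @param model a [WeightNet-class].
#' @param features numeric vector (one frame), matrix/data.frame (frames x
#'   features, matching the model's input width), or a
#'   [FeatureVector-class] / list of them (the model's feature mask selects
#'   the components).
#' @return numeric vector of predicted weights in kg.
#' @export
predictWeight <- function(model, features) {
  if (is(features, "FeatureVector")) features <- list(features)
  if (is.list(features) && length(features) &&
      is(features[[1]], "FeatureVector")) {
    tab <- as.matrix(featureTable(features))
    features <- tab[, model@featureMask, drop = FALSE]
  }
  x <- if (is.null(dim(features))) matrix(features, 1) else
    as.matrix(features)
  if (ncol(x) != ncol(model@w1))
    stop("feature width does not match the model (need ",
         ncol(model@w1), " columns)", call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite feature values passed to predict", call. = FALSE)
  xs <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  forwardNet(model@w1, model@b1, model@w2, model@b2, xs)
}

#' @describeIn WeightNet-class predict method delegating to
#'   [predictWeight()].
#' @param object a WeightNet
#' @param features see [predictWeight()]
#' @export
setMethod("predict", "WeightNet", function(object, features, ...) {
  predictWeight(object, features)
})

setMethod("show", "WeightNet", function(object) {
  cat("WeightNet:", ncol(object@w1), "inputs ->", nrow(object@w1),
      "tanh units -> 1 linear output (kg)\n")
  cat("  features:", paste(weightFeatureNames()[object@featureMask],
                           collapse = ", "), "\n")
  cat("  best validation epoch:", object@history$bestEpoch, "\n")
})

#' Serialize a trained model to JSON
#' @param model a [WeightNet-class].
#' @param path output path.
#' @export
saveWeightNet <- function(model, path) {
  jsonlite::write_json(list(
    topology = list(nInput = ncol(model@w1), nHidden = nrow(model@w1)),
    w1 = model@w1, b1 = model@b1, w2 = model@w2, b2 = model@b2,
    center = model@center, scale = model@scale,
    featureMask = model@featureMask, config = model@config),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model serialized by [saveWeightNet()]
#' @param path path to the JSON file.
#' @return a [WeightNet-class].
#' @export
readWeightNet <- function(path) {
  j <- jsonlite::fromJSON(path)
  new("WeightNet", w1 = matrix(unlist(j$w1), j$topology$nHidden,
                               j$topology$nInput),
      b1 = as.numeric(j$b1), w2 = as.numeric(j$w2),
      b2 = as.numeric(j$b2), center = as.numeric(j$center),
      scale = as.numeric(j$scale), featureMask = as.logical(j$featureMask),
      config = as.list(j$config), history = list())
}

#' Evaluation metrics for weight estimates
#'
#' Relative error per subject \eqn{\epsilon_i = (\hat x_i - \tilde x_i) /
#' \hat x_i} (ground truth \eqn{\hat x}, estimate \eqn{\tilde x}; positive
#' means underestimate), mean absolute error \eqn{(1/N) \sum |e_i|} and
#' mean square error \eqn{(1/N) \sum e_i^2} of the absolute errors
#' \eqn{e_i = \hat x_i - \tilde x_i}, and the share of subjects within the
#' \eqn{\pm}5/10/20 percent relative-error bands.
#'
#' @param predictions estimated weights, kg.
#' @param truths ground-truth weights, kg (all positive).
#' @return list of class \code{weightMetrics}: \code{relErr} (vector),
#'   \code{meanRel}, \code{sdRel}, \code{minRel}, \code{maxRel} (percent),
#'   \code{mae} (kg), \code{mse} (kg^2), \code{pctWithin5},
#'   \code{pctWithin10}, \code{pctWithin20} (percent).
#' @export
evaluateEstimates <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths),
            length(truths) >= 1)
  if (any(truths == 0))
    stop("relative error undefined for zero ground truth", call. = FALSE)
  e <- truths - predictions
  eps <- e / truths
  structure(list(
    relErr = eps,
    meanRel = mean(eps) * 100, sdRel = stats::sd(eps) * 100,
    minRel = min(eps) * 100, maxRel = max(eps) * 100,
    mae = mean(abs(e)), mse = mean(e^2),
    pctWithin5 = 100 * mean(abs(eps) <= 0.05),
    pctWithin10 = 100 * mean(abs(eps) <= 0.10),
    pctWithin20 = 100 * mean(abs(eps) <= 0.20)),
    class = "weightMetrics")
}

#' @export
print.weightMetrics <- function(x, ...) {
  cat(sprintf(
    "Relative error %%: min %.2f  max %.2f  mean %.2f  sd %.2f\n",
    x$minRel, x$maxRel, x$meanRel, x$sdRel))
  cat(sprintf("In range %%:  |eps|<=5: %.1f  <=10: %.1f  <=20: %.1f\n",
              x$pctWithin5, x$pctWithin10, x$pctWithin20))
  cat(sprintf("MAE %.2f kg   MSE %.2f kg^2   (N = %d)\n", x$mae, x$mse,
              length(x$relErr)))
  invisible(x)
}
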
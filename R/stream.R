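# Aggregation of per-frame weight estimates over a walking sequence into a
# single robust value. Single-frame estimates of a walking subject scatter
# widely (outliers beyond 30 percent occur); the densest fifth of the
# estimates, found by ranking frames by their mean absolute distance to all
# other estimates, averages to a far more reliable value.

#' Mean pairwise distance of each estimate to all others
#'
#' \eqn{\bar d_i = \frac{1}{D} \sum_{j \ne i} |w_i - w_j|} over the N
#' frames of one sequence. The divisor D is N-1 (the true mean over the
#' summed terms, the default) or N; the ranking of frames — all that
#' downstream selection uses — is identical under both conventions.
#'
#' @param w numeric vector of per-frame weight estimates, kg (N >= 2).
#' @param divisor "N-1" or "N".
#' @return numeric vector of mean distances.
#' @export
meanPairwiseDistance <- function(w, divisor = c("N-1", "N")) {
  divisor <- match.arg(divisor)
  n <- length(w)
  if (n < 2)
    stopDegenerate("mean pairwise distance needs at least 2 estimates")
  tot <- colSums(abs(outer(w, w, "-")))
  tot / if (divisor == "N-1") (n - 1) else n
}

#' Select the core (densest) estimates of a sequence
#'
#' Sorts the mean pairwise distances ascending and keeps the
#' \code{max(1, roundHalfUp(keepFraction * N))} frames with the smallest
#' distances. Ties are broken toward the earlier frame index; the
#' selection is deterministic.
#'
#' @param w per-frame estimates (used only for its length).
#' @param dbar mean pairwise distances from [meanPairwiseDistance()].
#' @param keepFraction fraction of frames to keep, in (0, 1]; default 0.2.
#' @return integer vector of kept frame indices.
#' @export
selectCore <- function(w, dbar, keepFraction = 0.2) {
  stopifnot(keepFraction > 0, keepFraction <= 1,
            length(dbar) == length(w))
  nKeep <- max(1L, roundHalfUp(keepFraction * length(w)))
  nKeep <- min(nKeep, length(w))
  order(dbar, seq_along(dbar))[seq_len(nKeep)]
}

#' Aggregate a stream of per-frame estimates into one weight
#'
#' The centroid (mean) of the core estimates selected by
#' [selectCore()]. A single-frame sequence returns its only estimate.
#' The result always lies within [min(w), max(w)].
#'
#' @param w numeric vector of per-frame weight estimates, kg (N >= 1).
#' @param keepFraction fraction of frames kept, default 0.2.
#' @param divisor Eq.-style divisor convention, see
#'   [meanPairwiseDistance()].
#' @return aggregated weight estimate, kg.
#' @examples
#' streamEstimate(c(70, 71, 72, 100, 101))   # 72
#' @export
streamEstimate <- function(w, keepFraction = 0.2,
                           divisor = c("N-1", "N")) {
  stopifnot(length(w) >= 1, all(is.finite(w)))
  if (length(w) == 1L) return(w[[1]])
  dbar <- meanPairwiseDistance(w, divisor = match.arg(divisor))
  mean(w[selectCore(w, dbar, keepFraction)])
}
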
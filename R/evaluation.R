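# Cross-validation protocols and threshold-sweep metrics. Per-fold masking
# recomputes every similarity matrix from the masked adjacency matrix, so no
# test label can leak into the kernels.

.checkLabels <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
}

# threshold sweep shared by ROC and PR: cumulative TP/FP at the last index of
# each tie group of descending scores
.sweep <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  n <- length(s)
  boundary <- c(s[-1] != s[-n], TRUE)
  list(tp = cumsum(l)[boundary], fp = cumsum(1 - l)[boundary],
       npos = sum(l), nneg = n - sum(l), cut = (1:n)[boundary])
}

#' ROC curve from pooled scores
#'
#' Sweeps every distinct score threshold and returns the (FPR, TPR) points,
#' prepending (0, 0); with both classes present the curve ends at (1, 1).
#' TPR = TP / (TP + FN), FPR = FP / (FP + TN).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 ground-truth labels (both classes must be present).
#' @return data.frame with columns `fpr`, `tpr`.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
#' @export
rocCurve <- function(scores, labels) {
  .checkLabels(scores, labels)
  if (sum(labels) == 0 || sum(labels) == length(labels))
    stop("AUC undefined: one class absent")
  sw <- .sweep(scores, labels)
  data.frame(fpr = c(0, sw$fp / sw$nneg), tpr = c(0, sw$tp / sw$npos))
}

#' Area under the ROC curve
#'
#' Trapezoidal area of [rocCurve()]. Equivalent to the Mann-Whitney rank
#' statistic P(score+ > score-) + 0.5 P(tie).
#'
#' @inheritParams rocCurve
#' @return AUC in \[0, 1\].
#' @export
aucScore <- function(scores, labels) {
  roc <- rocCurve(scores, labels)
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

# Mann-Whitney form; midranks give the half-credit tie correction for free.
# Kept as a second route: tests assert it agrees with the trapezoid exactly,
# and the CV drivers use it where only the scalar AUC is needed.
.rankAuc <- function(scores, labels) {
  .checkLabels(scores, labels)
  npos <- sum(labels); nneg <- length(labels) - npos
  if (npos == 0 || nneg == 0) stop("AUC undefined: one class absent")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Precision-recall curve from pooled scores
#'
#' Precision and recall at every distinct score threshold (descending).
#'
#' @inheritParams rocCurve
#' @return data.frame with columns `recall`, `precision`.
#' @export
prCurve <- function(scores, labels) {
  .checkLabels(scores, labels)
  if (sum(labels) == 0) stop("AUPR undefined: no positives")
  sw <- .sweep(scores, labels)
  data.frame(recall = sw$tp / sw$npos, precision = sw$tp / sw$cut)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step estimator over distinct thresholds:
#' `sum_t (recall_t - recall_\{t-1\}) * precision_t`.
#'
#' @inheritParams rocCurve
#' @return AUPR in \[0, 1\].
#' @export
auprScore <- function(scores, labels) {
  pr <- prCurve(scores, labels)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' Partition the known positives into cross-validation folds
#'
#' Uniformly random, seed-reproducible partition of the known-positive cells
#' of Y into k disjoint folds whose sizes differ by at most one.
#'
#' @param ds an [AssociationSet-class].
#' @param k number of folds (>= 2, <= number of positives).
#' @param seed integer RNG seed.
#' @return a [FoldSplit-class].
#' @examples
#' ds <- simulateAssociations(r = 12, n = 10, nBlocks = 2, seed = 3)
#' makeFolds(ds, k = 5, seed = 42)
#' @export
makeFolds <- function(ds, k, seed = 1L) {
  stopifnot(is(ds, "AssociationSet"))
  if (k < 2) stop("k must be at least 2")
  pos <- which(ds@Y == 1)
  if (k > length(pos)) stop("k exceeds the number of known positives")
  perm <- withr::with_seed(as.integer(seed), sample(pos))
  sizes <- rep(length(pos) %/% k, k)
  extra <- length(pos) %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- split(perm, rep(seq_len(k), times = sizes))
  new("FoldSplit", k = as.integer(k), folds = unname(folds),
      seed = as.integer(seed), dim = dim(ds@Y))
}

.evalResult <- function(scores, labels, perFold, seed, protocol) {
  sw <- .sweep(scores, labels)  # one sort shared by ROC, PR, AUC and AUPR
  roc <- data.frame(fpr = c(0, sw$fp / sw$nneg), tpr = c(0, sw$tp / sw$npos))
  pr <- data.frame(recall = sw$tp / sw$npos, precision = sw$tp / sw$cut)
  n <- nrow(roc)
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
  aupr <- sum(diff(c(0, pr$recall)) * pr$precision)
  new("EvaluationResult", auc = auc, aupr = aupr, roc = roc, pr = pr,
      perFoldAuc = perFold, seed = as.integer(seed), protocol = protocol,
      nPos = as.integer(sw$npos), nNeg = as.numeric(sw$nneg))
}

#' k-fold cross-validation of the prediction pipeline
#'
#' Splits the known positives into k folds ([makeFolds()]). For each fold its
#' positives are zeroed in a copy of Y, the entire pipeline (all similarity
#' kernels, fusion, both projections) is recomputed from the masked matrix,
#' and the held-out positives are scored together with every cell that is 0
#' in the original Y (the unknown pairs, serving as negatives). Scores are
#' pooled across folds for the headline ROC/AUC and AUPR; per-fold AUCs are
#' reported for dispersion. The input dataset is never modified.
#'
#' @param ds an [AssociationSet-class].
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold split.
#' @param K,weight,deltaFill,mode,kernels pipeline configuration, see
#'   [predictScores()].
#' @return an [EvaluationResult-class] with protocol `"kfold"`.
#' @examples
#' ds <- simulateAssociations(r = 30, n = 20, nBlocks = 3, seed = 2)
#' kfoldCV(ds, k = 5, seed = 42)
#' @export
kfoldCV <- function(ds, k = 5, seed = 1L, K = 5, weight = 0.5,
                    deltaFill = 1e-30, mode = "full",
                    kernels = c("cosine", "jaccard", "spectral")) {
  fs <- makeFolds(ds, k, seed)
  neg <- which(ds@Y == 0)
  scores <- vector("list", k); labels <- vector("list", k)
  perFold <- numeric(k)
  for (f in seq_len(k)) {
    Ytrain <- ds@Y
    Ytrain[fs@folds[[f]]] <- 0
    P <- .predictMatrix(Ytrain, K, weight, deltaFill, mode, kernels,
                        ds@lncIds, ds@miIds)
    sc <- c(P[fs@folds[[f]]], P[neg])
    lb <- c(rep(1, length(fs@folds[[f]])), rep(0, length(neg)))
    perFold[f] <- .rankAuc(sc, lb)
    scores[[f]] <- sc; labels[[f]] <- lb
  }
  .evalResult(unlist(scores), unlist(labels), perFold, seed, "kfold")
}

#' Leave-one-out cross-validation of the prediction pipeline
#'
#' Each known positive is masked in turn, the pipeline is recomputed from the
#' masked matrix, and the held-out positive is scored against all cells that
#' are 0 in the original Y. Scores are pooled over all held-out cases for the
#' headline ROC/AUC; `perFoldAuc` holds each case's individual rank AUC.
#' `maxCases` subsamples the held-out positives (seeded) for desk-scale runs;
#' the result is then an approximation of full LOOCV over a random subset of
#' cases.
#'
#' @inheritParams kfoldCV
#' @param maxCases optional cap on the number of held-out positives.
#' @return an [EvaluationResult-class] with protocol `"loocv"`.
#' @export
loocv <- function(ds, seed = 1L, maxCases = NULL, K = 5, weight = 0.5,
                  deltaFill = 1e-30, mode = "full",
                  kernels = c("cosine", "jaccard", "spectral")) {
  stopifnot(is(ds, "AssociationSet"))
  pos <- which(ds@Y == 1)
  if (length(pos) < 2)
    stop("LOOCV needs at least 2 known positives")
  if (!is.null(maxCases) && maxCases < length(pos))
    pos <- withr::with_seed(as.integer(seed), sample(pos, maxCases))
  neg <- which(ds@Y == 0)
  nc <- length(pos); nn <- length(neg)
  scores <- numeric(nc * (nn + 1))
  labels <- rep.int(c(1, rep.int(0, nn)), nc)
  perCase <- numeric(nc)
  for (ci in seq_len(nc)) {
    Ytrain <- ds@Y
    Ytrain[pos[ci]] <- 0
    P <- .predictMatrix(Ytrain, K, weight, deltaFill, mode, kernels,
                        ds@lncIds, ds@miIds)
    s <- P[pos[ci]]; nv <- P[neg]
    # rank AUC of a single positive against this run's negatives
    perCase[ci] <- (sum(nv < s) + 0.5 * sum(nv == s)) / nn
    scores[((ci - 1) * (nn + 1) + 1):(ci * (nn + 1))] <- c(s, nv)
  }
  .evalResult(scores, labels, perCase, seed, "loocv")
}

#' Fraction of top-k novel predictions confirmed by held-out truth
#'
#' Scores all pairs on the training associations, drops the training
#' positives, takes the top k remaining candidates (lexicographic
#' tie-breaking) and returns the fraction present in `truth`, a table of
#' held-out true pairs disjoint from the training positives.
#'
#' @param dsTrain training [AssociationSet-class].
#' @param truth data.frame with columns `lncId`, `miId` of held-out true
#'   pairs.
#' @param k number of top candidates to examine (default 100).
#' @inheritParams kfoldCV
#' @return hit fraction in \[0, 1\].
#' @export
topkHitFraction <- function(dsTrain, truth, k = 100, K = 5, weight = 0.5,
                            deltaFill = 1e-30, mode = "full",
                            kernels = c("cosine", "jaccard", "spectral")) {
  if (k <= 0) stop("k must be positive")
  keyTruth <- paste(truth$lncId, truth$miId, sep = "\r")
  posIdx <- which(dsTrain@Y == 1, arr.ind = TRUE)
  keyTrain <- paste(dsTrain@lncIds[posIdx[, 1]], dsTrain@miIds[posIdx[, 2]],
                    sep = "\r")
  if (any(keyTruth %in% keyTrain))
    stop("truth pairs must be disjoint from the training positives")
  sc <- predictScores(dsTrain, K = K, weight = weight, deltaFill = deltaFill,
                      mode = mode, kernels = kernels)
  top <- rankPredictions(sc, dsTrain, topK = k, excludeKnown = TRUE)
  if (!nrow(top)) return(0)
  mean(paste(top$lncId, top$miId, sep = "\r") %in% keyTruth)
}

#' Serialize an EvaluationResult to JSON
#'
#' Writes all result fields (protocol, seed, AUC, AUPR, per-fold AUCs, ROC
#' and PR points, class counts) as JSON. Numbers are written at full
#' precision, so identical (dataset, configuration, seed) runs produce
#' byte-identical files.
#'
#' @param result an [EvaluationResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvaluation <- function(result, path) {
  obj <- list(
    protocol = result@protocol,
    seed = result@seed,
    auc = result@auc,
    aupr = result@aupr,
    n_pos = result@nPos,
    n_neg = result@nNeg,
    per_fold_auc = result@perFoldAuc,
    roc = list(fpr = result@roc$fpr, tpr = result@roc$tpr),
    pr = list(recall = result@pr$recall, precision = result@pr$precision))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
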
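#' @import methods
NULL

.SIM_KINDS <- c("cosine", "jaccard", "spectral", "jaccard_spectral", "integrated")

#' AssociationSet: a binary lncRNA-miRNA association matrix
#'
#' Container for an experimentally verified lncRNA-miRNA association network:
#' ordered identifier lists for the two sides of the bipartite graph and the
#' r x n binary adjacency matrix Y, with Y\[i, j\] = 1 iff lncRNA i has a
#' verified association with miRNA j. Rows of Y are lncRNA interaction
#' profiles, columns are miRNA interaction profiles; these profiles are the
#' only feature vectors the prediction method uses.
#'
#' @slot lncIds character vector of unique lncRNA identifiers (length r).
#' @slot miIds character vector of unique miRNA identifiers (length n).
#' @slot Y r x n numeric matrix with entries in \{0, 1\}.
#'
#' @seealso [AssociationSet()], [readAssociations()], [predictScores()]
#' @aliases AssociationSet-class
#' @exportClass AssociationSet
setClass("AssociationSet",
  slots = c(lncIds = "character", miIds = "character", Y = "matrix"))

setValidity("AssociationSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@lncIds)) msg <- c(msg, "duplicate lncRNA identifiers")
  if (anyDuplicated(object@miIds)) msg <- c(msg, "duplicate miRNA identifiers")
  if (nrow(object@Y) != length(object@lncIds) ||
      ncol(object@Y) != length(object@miIds))
    msg <- c(msg, "matrix dimensions must equal identifier-list lengths")
  if (!is.numeric(object@Y) || !all(object@Y %in% c(0, 1)))
    msg <- c(msg, "every entry of Y must be exactly 0 or 1")
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: a square similarity kernel over one entity side
#'
#' A symmetric p x p matrix of pairwise similarities between the entities of
#' one side of the bipartite network (all lncRNAs, or all miRNAs), tagged with
#' the kernel that produced it. Entries lie in \[0, 1\]. The spectral kernel
#' has a zero diagonal by definition; cosine and Jaccard kernels have a unit
#' diagonal for any entity with at least one association.
#'
#' @slot ids character vector of entity identifiers (length p).
#' @slot S p x p numeric matrix of similarities.
#' @slot kind one of `"cosine"`, `"jaccard"`, `"spectral"`,
#'   `"jaccard_spectral"`, `"integrated"`.
#'
#' @seealso [cosineSimilarity()], [jaccardSimilarity()], [spectralSimilarity()],
#'   [fuseSimilarities()]
#' @aliases SimilarityMatrix-class
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  slots = c(ids = "character", S = "matrix", kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  p <- length(object@ids)
  if (nrow(object@S) != p || ncol(object@S) != p)
    msg <- c(msg, "S must be square with dimension matching ids")
  if (length(object@kind) != 1L || !object@kind %in% .SIM_KINDS)
    msg <- c(msg, paste0("kind must be one of: ", paste(.SIM_KINDS, collapse = ", ")))
  if (p > 0) {
    if (max(abs(object@S - t(object@S))) > 1e-12)
      msg <- c(msg, "S must be symmetric within 1e-12")
    if (min(object@S) < -1e-12 || max(object@S) > 1 + 1e-12)
      msg <- c(msg, "all similarities must lie in [0, 1]")
    if (identical(object@kind, "spectral") && any(diag(object@S) != 0))
      msg <- c(msg, "spectral similarity must have a zero diagonal")
  }
  if (length(msg)) msg else TRUE
})

#' ScoreMatrix: final association prediction scores
#'
#' The r x n matrix of network-consistency-projection prediction scores for
#' every lncRNA-miRNA pair. Scores are bounded in \[0, 1\] (a Cauchy-Schwarz
#' consequence of the projection normalization); higher scores indicate
#' stronger predicted association.
#'
#' @slot lncIds,miIds identifier vectors matching the source dataset.
#' @slot P r x n numeric matrix of prediction scores.
#'
#' @seealso [predictScores()], [rankPredictions()]
#' @aliases ScoreMatrix-class
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
  slots = c(lncIds = "character", miIds = "character", P = "matrix"))

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  if (nrow(object@P) != length(object@lncIds) ||
      ncol(object@P) != length(object@miIds))
    msg <- c(msg, "score matrix dimensions must match identifier lists")
  if (length(object@P) &&
      (min(object@P) < -1e-12 || max(object@P) > 1 + 1e-12))
    msg <- c(msg, "scores must lie in [0, 1] (within 1e-12)")
  if (length(msg)) msg else TRUE
})

#' FoldSplit: a seeded partition of known positives
#'
#' A reproducible random partition of the linear indices of the known-positive
#' cells of Y into k disjoint folds whose sizes differ by at most one, used by
#' the cross-validation protocols.
#'
#' @slot k number of folds.
#' @slot folds list of k integer vectors of linear (column-major) cell indices.
#' @slot seed the RNG seed that produced the partition.
#' @slot dim dimensions of the source matrix, for index interpretation.
#'
#' @seealso [makeFolds()], [kfoldCV()]
#' @aliases FoldSplit-class
#' @exportClass FoldSplit
setClass("FoldSplit",
  slots = c(k = "integer", folds = "list", seed = "integer", dim = "integer"))

setValidity("FoldSplit", function(object) {
  msg <- character()
  if (length(object@folds) != object@k)
    msg <- c(msg, "number of folds must equal k")
  sizes <- lengths(object@folds)
  if (length(sizes) && max(sizes) - min(sizes) > 1L)
    msg <- c(msg, "fold sizes must differ by at most 1")
  all_idx <- unlist(object@folds, use.names = FALSE)
  if (anyDuplicated(all_idx)) msg <- c(msg, "folds must be disjoint")
  if (length(msg)) msg else TRUE
})

#' EvaluationResult: cross-validated performance summary
#'
#' Pooled ROC and precision-recall curves, their areas, per-fold (or
#' per-held-out-case) AUCs, and the protocol and seed that produced them.
#' The ROC starts at (0, 0), ends at (1, 1) and is non-decreasing in both
#' coordinates; `auc` is its trapezoidal area.
#'
#' @slot auc area under the pooled ROC curve, in \[0, 1\].
#' @slot aupr area under the pooled precision-recall curve (non-interpolated
#'   step estimator), in \[0, 1\].
#' @slot roc data.frame with columns `fpr`, `tpr`.
#' @slot pr data.frame with columns `recall`, `precision`.
#' @slot perFoldAuc AUC of each fold (k-fold) or held-out case (LOOCV).
#' @slot seed integer seed of the fold split.
#' @slot protocol `"kfold"` or `"loocv"`.
#' @slot nPos,nNeg pooled positive / negative counts behind the curves.
#'
#' @seealso [kfoldCV()], [loocv()], [writeEvaluation()]
#' @aliases EvaluationResult-class
#' @exportClass EvaluationResult
setClass("EvaluationResult",
  slots = c(auc = "numeric", aupr = "numeric", roc = "data.frame",
            pr = "data.frame", perFoldAuc = "numeric", seed = "integer",
            protocol = "character", nPos = "integer", nNeg = "numeric"))

setValidity("EvaluationResult", function(object) {
  msg <- character()
  if (!object@protocol %in% c("kfold", "loocv"))
    msg <- c(msg, "protocol must be 'kfold' or 'loocv'")
  roc <- object@roc
  if (nrow(roc)) {
    if (roc$fpr[1] != 0 || roc$tpr[1] != 0)
      msg <- c(msg, "ROC must start at (0, 0)")
    if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
      msg <- c(msg, "ROC must end at (1, 1)")
    if (is.unsorted(roc$fpr) || is.unsorted(roc$tpr))
      msg <- c(msg, "ROC coordinates must be non-decreasing")
    area <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
    if (abs(area - object@auc) > 1e-12)
      msg <- c(msg, "auc must equal the trapezoidal area of roc within 1e-12")
  }
  if (length(msg)) msg else TRUE
})
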
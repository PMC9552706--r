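# Network consistency projection: score a pair (i, j) by projecting lncRNA
# i's integrated similarity vector onto miRNA j's association vector (lncRNA
# space) and vice versa (miRNA space), then combine and normalize.

.rowNorms <- function(M) sqrt(rowSums(M * M))
.colNorms <- function(M) sqrt(colSums(M * M))

#' Replace unknown associations by a tiny positive constant
#'
#' Returns the adjacency matrix with every 0 replaced by `deltaFill`. Unknown
#' pairs are uncertain rather than confirmed negatives, and an all-zero
#' association vector would put a zero denominator in the projection; the
#' tiny constant keeps every vector norm strictly positive without
#' measurably affecting any score.
#'
#' @param Y binary matrix (or [AssociationSet-class]).
#' @param deltaFill small positive constant, default `1e-30`.
#' @return numeric matrix with entries in \{`deltaFill`, 1\}.
#' @export
fillUnknowns <- function(Y, deltaFill = 1e-30) {
  if (is(Y, "AssociationSet")) Y <- Y@Y
  if (!is.numeric(deltaFill) || length(deltaFill) != 1 || deltaFill <= 0)
    stop("deltaFill must be a single positive number")
  Yd <- Y
  Yd[Yd == 0] <- deltaFill
  Yd
}

#' lncRNA-space consistency projection
#'
#' `out[i, j] = (SL_i . Yd_j) / ||Yd_j||` where `SL_i` is row i of the
#' integrated lncRNA similarity matrix and `Yd_j` is column j of the
#' delta-filled adjacency matrix: the scalar projection of lncRNA i's
#' similarity vector onto miRNA j's association vector.
#'
#' @param lncSim integrated lncRNA [SimilarityMatrix-class] (or r x r matrix).
#' @param Yd delta-filled r x n adjacency matrix from [fillUnknowns()].
#' @return r x n numeric matrix of projection scores.
#' @export
lncSpaceProjection <- function(lncSim, Yd) {
  S <- if (is(lncSim, "SimilarityMatrix")) lncSim@S else as.matrix(lncSim)
  if (ncol(S) != nrow(Yd))
    stop("lncRNA similarity dimension does not match the adjacency matrix")
  sweep(S %*% Yd, 2, .colNorms(Yd), "/")
}

#' miRNA-space consistency projection
#'
#' `out[i, j] = (SM_j . Yd_i) / ||Yd_i||` where `SM_j` is column j of the
#' integrated miRNA similarity matrix and `Yd_i` is row i of the delta-filled
#' adjacency matrix.
#'
#' @param miSim integrated miRNA [SimilarityMatrix-class] (or n x n matrix).
#' @param Yd delta-filled r x n adjacency matrix from [fillUnknowns()].
#' @return r x n numeric matrix of projection scores.
#' @export
miSpaceProjection <- function(miSim, Yd) {
  S <- if (is(miSim, "SimilarityMatrix")) miSim@S else as.matrix(miSim)
  if (nrow(S) != ncol(Yd))
    stop("miRNA similarity dimension does not match the adjacency matrix")
  sweep(Yd %*% S, 1, .rowNorms(Yd), "/")
}

#' Combine the two space projections into normalized scores
#'
#' `P[i, j] = (lncProj[i, j] + miProj[i, j]) / (||SL_i|| + ||SM_j||)`.
#' Each projection is bounded by the norm of its similarity vector
#' (Cauchy-Schwarz), so every combined score lies in \[0, 1\]; the bound is
#' attained exactly when each association vector is proportional to the
#' corresponding similarity vector.
#'
#' @param lncProj,miProj r x n projection matrices.
#' @param lncSim,miSim the integrated similarity matrices used to build them.
#' @param lncIds,miIds identifier vectors for the result.
#' @return a [ScoreMatrix-class].
#' @export
combineProjections <- function(lncProj, miProj, lncSim, miSim,
                               lncIds = NULL, miIds = NULL) {
  SL <- if (is(lncSim, "SimilarityMatrix")) lncSim@S else as.matrix(lncSim)
  SM <- if (is(miSim, "SimilarityMatrix")) miSim@S else as.matrix(miSim)
  if (is.null(lncIds))
    lncIds <- if (is(lncSim, "SimilarityMatrix")) lncSim@ids else paste0("L", seq_len(nrow(SL)))
  if (is.null(miIds))
    miIds <- if (is(miSim, "SimilarityMatrix")) miSim@ids else paste0("M", seq_len(nrow(SM)))
  rn <- .rowNorms(SL)
  cn <- .colNorms(SM)
  denom <- outer(rn, cn, "+")
  if (any(denom == 0)) {
    bad <- which(denom == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("zero normalization denominator for pair (%s, %s): both similarity vectors are identically zero",
                 lncIds[bad[1]], miIds[bad[2]]))
  }
  P <- (lncProj + miProj) / denom
  P <- pmin(pmax(P, 0), 1)  # clip floating-point spill beyond the exact bound
  dimnames(P) <- list(lncIds, miIds)
  new("ScoreMatrix", lncIds = as.character(lncIds), miIds = as.character(miIds), P = P)
}

# plain-matrix pipeline used by the S4 methods and (directly) by the CV
# loops, which rerun it once per masked matrix
.predictMatrix <- function(Y, K, weight, deltaFill, mode, kernels,
                           lncIds = NULL, miIds = NULL) {
  mode <- match.arg(mode, c("full", "lnc", "mi"))
  if (sum(Y) < 1) stop("the prediction pipeline needs at least one known association")
  if (nrow(Y) < 2 || ncol(Y) < 2) stop("need at least two entities per side")
  SL <- .integratedKernel(Y, K, weight, kernels)
  SM <- .integratedKernel(t(Y), K, weight, kernels)
  Yd <- fillUnknowns(Y, deltaFill)
  if (mode == "full") {
    L <- sweep(SL %*% Yd, 2, .colNorms(Yd), "/")
    M <- sweep(Yd %*% SM, 1, .rowNorms(Yd), "/")
    rn <- .rowNorms(SL); cn <- .colNorms(SM)
    denom <- outer(rn, cn, "+")
    if (any(denom == 0)) {
      bad <- which(denom == 0, arr.ind = TRUE)[1, ]
      stop(sprintf("zero normalization denominator for pair (%s, %s): both similarity vectors are identically zero",
                   if (is.null(lncIds)) bad[1] else lncIds[bad[1]],
                   if (is.null(miIds)) bad[2] else miIds[bad[2]]))
    }
    P <- (L + M) / denom
  } else if (mode == "lnc") {
    rn <- .rowNorms(SL)
    if (any(rn == 0))
      stop("zero lncRNA similarity vector at row ", which(rn == 0)[1])
    P <- sweep(sweep(SL %*% Yd, 2, .colNorms(Yd), "/"), 1, rn, "/")
  } else {
    cn <- .colNorms(SM)
    if (any(cn == 0))
      stop("zero miRNA similarity vector at column ", which(cn == 0)[1])
    P <- sweep(sweep(Yd %*% SM, 1, .rowNorms(Yd), "/"), 2, cn, "/")
  }
  pmin(pmax(P, 0), 1)  # clip floating-point spill beyond the exact [0,1] bound
}

.predictCore <- function(ds, K, weight, deltaFill, mode, kernels) {
  P <- .predictMatrix(ds@Y, K, weight, deltaFill, mode, kernels,
                      ds@lncIds, ds@miIds)
  dimnames(P) <- list(ds@lncIds, ds@miIds)
  new("ScoreMatrix", lncIds = ds@lncIds, miIds = ds@miIds, P = P)
}

#' Score all lncRNA-miRNA pairs by network consistency projection
#'
#' Runs the complete closed-form prediction pipeline: build the integrated
#' similarity matrices on both sides ([integratedSimilarities()]), replace
#' unknown associations by `deltaFill` ([fillUnknowns()]), project each
#' entity's similarity vector onto the other side's association vectors, and
#' combine the two space projections into a normalized score in \[0, 1\]
#' ([combineProjections()]). `mode = "lnc"` and `mode = "mi"` are the
#' single-space ablations, each normalized by its own similarity-vector norm
#' so the \[0, 1\] bound is preserved.
#'
#' @param x an [AssociationSet-class] or binary adjacency matrix.
#' @param K spectral-bandwidth neighbour index (default 5).
#' @param weight similarity fusion weight (default 0.5).
#' @param deltaFill zero-replacement constant for the projection (default
#'   `1e-30`).
#' @param mode `"full"` (both spaces), `"lnc"` or `"mi"` (single-space
#'   ablations).
#' @param kernels similarity kernels to include in the fusion chain.
#' @return a [ScoreMatrix-class]; higher scores mean stronger predicted
#'   association.
#' @examples
#' ds <- simulateAssociations(r = 20, n = 15, nBlocks = 3, seed = 7)
#' predictScores(ds)
#' @rdname predictScores
#' @export
setMethod("predictScores", "AssociationSet",
  function(x, K = 5, weight = 0.5, deltaFill = 1e-30,
           mode = c("full", "lnc", "mi"),
           kernels = c("cosine", "jaccard", "spectral")) {
    .predictCore(x, K, weight, deltaFill, mode, kernels)
  })

#' @rdname predictScores
#' @export
setMethod("predictScores", "matrix",
  function(x, K = 5, weight = 0.5, deltaFill = 1e-30,
           mode = c("full", "lnc", "mi"),
           kernels = c("cosine", "jaccard", "spectral")) {
    lids <- rownames(x); if (is.null(lids)) lids <- paste0("L", seq_len(nrow(x)))
    mids <- colnames(x); if (is.null(mids)) mids <- paste0("M", seq_len(ncol(x)))
    .predictCore(AssociationSet(lids, mids, x), K, weight, deltaFill, mode, kernels)
  })
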
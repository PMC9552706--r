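# Interaction-profile similarity kernels. All three operate on the rows of a
# profile matrix V: for side = "lnc" the rows of Y, for side = "mi" the
# columns of Y (i.e. t(Y)).

.profiles <- function(x, side) {
  side <- match.arg(side, c("lnc", "mi"))
  if (is(x, "AssociationSet")) {
    if (side == "lnc") list(V = x@Y, ids = x@lncIds)
    else list(V = t(x@Y), ids = x@miIds)
  } else {
    Y <- as.matrix(x)
    if (!all(Y %in% c(0, 1))) stop("profile matrix must be binary")
    if (side == "lnc") {
      ids <- rownames(Y); if (is.null(ids)) ids <- paste0("L", seq_len(nrow(Y)))
      list(V = Y, ids = ids)
    } else {
      ids <- colnames(Y); if (is.null(ids)) ids <- paste0("M", seq_len(ncol(Y)))
      list(V = t(Y), ids = ids)
    }
  }
}

.cosineKernel <- function(V) {
  G <- tcrossprod(V)
  nrm <- sqrt(diag(G))
  S <- G / outer(nrm, nrm)
  zero <- nrm == 0
  S[zero, ] <- 0
  S[, zero] <- 0
  S
}

.jaccardKernel <- function(V) {
  inter <- tcrossprod(V)
  sz <- rowSums(V)
  un <- outer(sz, sz, "+") - inter
  S <- inter / un
  S[un == 0] <- 0
  S
}

.spectralKernel <- function(V, K) {
  p <- nrow(V)
  if (p < 2) stop("need at least two profiles")
  if (K < 1) stop("K must be >= 1")
  sz <- rowSums(V * V)
  d2 <- outer(sz, sz, "+") - 2 * tcrossprod(V)
  d2[d2 < 0] <- 0
  d2 <- (d2 + t(d2)) / 2  # enforce exact symmetry
  d <- sqrt(d2)
  Kc <- min(K, p - 1)
  delta <- vapply(seq_len(p), function(i) {
    di <- d[i, -i]
    sort(di, partial = Kc)[Kc]
  }, numeric(1))
  if (all(delta == 0)) {
    # every profile has >= K exact duplicates: identical pairs are maximally
    # similar, everything else (there is nothing else at this point, but keep
    # the rule total) dissimilar
    S <- (d2 == 0) * 1
  } else {
    if (any(delta == 0)) delta[delta == 0] <- min(delta[delta > 0])
    S <- exp(-d2 / outer(delta, delta))
  }
  diag(S) <- 0
  S
}

.simObject <- function(S, ids, kind) {
  dimnames(S) <- list(ids, ids)
  new("SimilarityMatrix", ids = ids, S = S, kind = kind)
}

#' Cosine similarity of interaction profiles
#'
#' For each pair of entities on one side of the bipartite network, the cosine
#' of the angle between their binary interaction profiles (rows of Y for
#' lncRNAs, columns for miRNAs). An entity with no associations has an
#' all-zero profile and, by convention, similarity 0 to everything (including
#' itself): an empty profile carries no evidence of similarity and the 0/0
#' case must be resolved.
#'
#' @param x an [AssociationSet-class] or a binary matrix Y.
#' @param side `"lnc"` (rows of Y) or `"mi"` (columns of Y).
#' @return a [SimilarityMatrix-class] of kind `"cosine"`.
#' @examples
#' ds <- simulateAssociations(r = 10, n = 8, nBlocks = 2, seed = 1)
#' cosineSimilarity(ds, "lnc")
#' @rdname cosineSimilarity
#' @export
setMethod("cosineSimilarity", "ANY", function(x, side = c("lnc", "mi")) {
  pr <- .profiles(x, match.arg(side))
  .simObject(.cosineKernel(pr$V), pr$ids, "cosine")
})

#' Jaccard similarity of interaction profiles
#'
#' Jaccard index |A intersect B| / |A union B| of the association supports of
#' two entities on one side of the bipartite network. Pairs with an empty
#' union (both entities unassociated) get similarity 0 by the same convention
#' as [cosineSimilarity()].
#'
#' @inheritParams cosineSimilarity
#' @return a [SimilarityMatrix-class] of kind `"jaccard"`.
#' @rdname jaccardSimilarity
#' @export
setMethod("jaccardSimilarity", "ANY", function(x, side = c("lnc", "mi")) {
  pr <- .profiles(x, match.arg(side))
  .simObject(.jaccardKernel(pr$V), pr$ids, "jaccard")
})

#' Self-tuning spectral-clustering similarity
#'
#' The locally scaled Gaussian affinity of self-tuning spectral clustering:
#' `S[i,j] = exp(-||v_i - v_j||^2 / (delta_i * delta_j))` for `i != j` and 0
#' on the diagonal, where the per-entity bandwidth `delta_i` is the Euclidean
#' distance from profile `v_i` to its K-th nearest neighbouring profile (self
#' excluded). Because each bandwidth adapts to the local point density, the
#' affinity stays informative on sparse binary profiles and is used to
#' densify the sparse Jaccard similarity matrix.
#'
#' Degenerate bandwidths are handled explicitly: K is clamped to p - 1 when
#' fewer than K neighbours exist; a zero bandwidth (the K-th neighbour is an
#' identical profile) is replaced by the smallest strictly positive bandwidth
#' over all entities; if every bandwidth is zero, identical profiles get
#' similarity 1 and all other pairs 0.
#'
#' @inheritParams cosineSimilarity
#' @param K which nearest neighbour sets the local bandwidth (default 5).
#' @return a [SimilarityMatrix-class] of kind `"spectral"` (zero diagonal).
#' @rdname spectralSimilarity
#' @export
setMethod("spectralSimilarity", "ANY", function(x, side = c("lnc", "mi"), K = 5) {
  pr <- .profiles(x, match.arg(side))
  .simObject(.spectralKernel(pr$V, K), pr$ids, "spectral")
})
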
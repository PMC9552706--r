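#' Accessors for the core classes
#'
#' `lncIds()` and `miIds()` return the ordered identifier lists of an
#' [AssociationSet-class] or [ScoreMatrix-class]; `assocMatrix()` returns the
#' binary adjacency matrix with identifiers as dimnames; `ids()` and
#' `simKind()` return the identifiers and kernel tag of a
#' [SimilarityMatrix-class]. `as.matrix()` methods return the underlying
#' numeric matrix of any of the three matrix-backed classes.
#'
#' @param x,object an object of the documented class.
#' @param ... ignored.
#' @return character vectors for the identifier accessors, a numeric matrix
#'   for the matrix accessors.
#' @name accessors
#' @aliases lncIds miIds assocMatrix ids simKind
#' @examples
#' ds <- simulateAssociations(r = 12, n = 8, nBlocks = 2, seed = 1)
#' lncIds(ds)
#' dim(assocMatrix(ds))
NULL

#' @rdname accessors
#' @export
setGeneric("lncIds", function(x) standardGeneric("lncIds"))

#' @rdname accessors
#' @export
setGeneric("miIds", function(x) standardGeneric("miIds"))

#' @rdname accessors
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))

#' @rdname accessors
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' @rdname accessors
#' @export
setGeneric("simKind", function(x) standardGeneric("simKind"))

#' @rdname cosineSimilarity
#' @export
setGeneric("cosineSimilarity",
  function(x, side = c("lnc", "mi")) standardGeneric("cosineSimilarity"))

#' @rdname jaccardSimilarity
#' @export
setGeneric("jaccardSimilarity",
  function(x, side = c("lnc", "mi")) standardGeneric("jaccardSimilarity"))

#' @rdname spectralSimilarity
#' @export
setGeneric("spectralSimilarity",
  function(x, side = c("lnc", "mi"), K = 5) standardGeneric("spectralSimilarity"))

#' @rdname predictScores
#' @export
setGeneric("predictScores",
  function(x, K = 5, weight = 0.5, deltaFill = 1e-30,
           mode = c("full", "lnc", "mi"),
           kernels = c("cosine", "jaccard", "spectral"))
    standardGeneric("predictScores"))
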
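#' Construct an AssociationSet
#'
#' Builds the binary bipartite association container from identifier lists and
#' an adjacency matrix, attaching identifiers as dimnames.
#'
#' @param lncIds character vector of unique lncRNA identifiers (length r).
#' @param miIds character vector of unique miRNA identifiers (length n).
#' @param Y r x n matrix (numeric or logical) with entries in \{0, 1\}.
#' @return an [AssociationSet-class] object.
#' @examples
#' AssociationSet(c("L1", "L2"), c("M1", "M2"),
#'                matrix(c(1, 0, 1, 1), 2, 2))
#' @export
AssociationSet <- function(lncIds, miIds, Y) {
  Y <- matrix(as.numeric(Y), nrow = length(lncIds), ncol = length(miIds),
              dimnames = list(lncIds, miIds))
  new("AssociationSet", lncIds = as.character(lncIds),
      miIds = as.character(miIds), Y = Y)
}

#' @rdname accessors
setMethod("lncIds", "AssociationSet", function(x) x@lncIds)
#' @rdname accessors
setMethod("miIds", "AssociationSet", function(x) x@miIds)
#' @rdname accessors
setMethod("assocMatrix", "AssociationSet", function(x) x@Y)
#' @rdname accessors
setMethod("lncIds", "ScoreMatrix", function(x) x@lncIds)
#' @rdname accessors
setMethod("miIds", "ScoreMatrix", function(x) x@miIds)
#' @rdname accessors
setMethod("ids", "SimilarityMatrix", function(x) x@ids)
#' @rdname accessors
setMethod("simKind", "SimilarityMatrix", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("as.matrix", "AssociationSet", function(x, ...) x@Y)
#' @rdname accessors
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@S)
#' @rdname accessors
#' @export
setMethod("as.matrix", "ScoreMatrix", function(x, ...) x@P)

setMethod("show", "AssociationSet", function(object) {
  cat(sprintf("AssociationSet: %d lncRNAs x %d miRNAs, %d known associations (density %.4f)\n",
              length(object@lncIds), length(object@miIds), sum(object@Y),
              mean(object@Y)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d x %d, range [%.4f, %.4f]\n",
              object@kind, length(object@ids), length(object@ids),
              min(object@S), max(object@S)))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d lncRNAs x %d miRNAs, score range [%.4f, %.4f]\n",
              length(object@lncIds), length(object@miIds),
              min(object@P), max(object@P)))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult (%s, seed %d): AUC %.4f, AUPR %.4f over %d positives / %d negatives\n",
              object@protocol, object@seed, object@auc, object@aupr,
              object@nPos, object@nNeg))
  if (length(object@perFoldAuc) && length(object@perFoldAuc) <= 25)
    cat("  per-fold AUC:", paste(sprintf("%.4f", object@perFoldAuc), collapse = " "), "\n")
})

.detectDelimiter <- function(lines) {
  if (sum(grepl("\t", lines)) >= sum(grepl(",", lines))) "\t" else ","
}

#' Read a lncRNA-miRNA association edge list
#'
#' Reads a delimited text file whose rows are (lncRNA id, miRNA id) pairs of
#' experimentally verified associations and builds the binary adjacency
#' matrix. Identifier order is first appearance in the file; duplicate rows
#' collapse to a single association (with a message reporting how many were
#' removed). The delimiter is auto-detected between tab and comma unless
#' given; a header row is assumed present when the file has a third column
#' whose first value is non-numeric (edge lists with extra annotation columns
#' typically carry headers, bare two-column lists typically do not), and can
#' be forced either way.
#'
#' @param path path to the edge-list file.
#' @param delimiter `"auto"` (default), `"\t"` or `","`.
#' @param header `"auto"` (default), `TRUE` or `FALSE`.
#' @return an [AssociationSet-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("L1\tM1", "L1\tM2", "L2\tM2"), f)
#' readAssociations(f)
#' @export
readAssociations <- function(path, delimiter = "auto", header = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no associations in ", path)
  if (identical(delimiter, "auto")) delimiter <- .detectDelimiter(lines)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("malformed row at line ", bad[1], ": fewer than 2 fields")
  if (identical(header, "auto")) {
    first <- fields[[1]]
    header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3])))
  }
  if (isTRUE(header)) fields <- fields[-1]
  if (!length(fields)) stop("no associations in ", path)
  lnc <- trimws(vapply(fields, `[`, character(1), 1L))
  mi <- trimws(vapply(fields, `[`, character(1), 2L))
  dup <- duplicated(paste(lnc, mi, sep = "\r"))
  if (any(dup))
    message("removed ", sum(dup), " duplicated association(s)")
  lnc_u <- lnc[!dup]; mi_u <- mi[!dup]
  lids <- unique(lnc); mids <- unique(mi)
  Y <- matrix(0, length(lids), length(mids), dimnames = list(lids, mids))
  Y[cbind(match(lnc_u, lids), match(mi_u, mids))] <- 1
  AssociationSet(lids, mids, Y)
}

#' Write an AssociationSet as an edge list
#'
#' Writes the known-positive pairs of `ds` as a two-column delimited file in
#' row-major (lncRNA first-appearance) order, the format [readAssociations()]
#' reads back.
#'
#' @param ds an [AssociationSet-class].
#' @param path output path.
#' @param delimiter field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
writeAssociations <- function(ds, path, delimiter = "\t") {
  idx <- which(ds@Y == 1, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  lines <- paste(ds@lncIds[idx[ord, 1]], ds@miIds[idx[ord, 2]], sep = delimiter)
  writeLines(lines, path)
  invisible(path)
}

#' Rank lncRNA-miRNA predictions
#'
#' Flattens a score matrix into a ranked table of candidate pairs. Ties in
#' score are broken by (lncRNA id, miRNA id) lexicographic order (C locale)
#' so repeated runs produce byte-identical rankings.
#'
#' @param scores a [ScoreMatrix-class].
#' @param ds the source [AssociationSet-class] (supplies the `known` flag).
#' @param topK number of top pairs to keep (default all).
#' @param excludeKnown drop pairs already known (Y = 1) before ranking, so the
#'   table lists novel candidates only.
#' @return data.frame with columns `rank`, `lncId`, `miId`, `score`, `known`.
#' @examples
#' ds <- simulateAssociations(r = 10, n = 8, nBlocks = 2, seed = 1)
#' sc <- predictScores(ds)
#' head(rankPredictions(sc, ds, topK = 5, excludeKnown = TRUE))
#' @export
rankPredictions <- function(scores, ds, topK = Inf, excludeKnown = FALSE) {
  stopifnot(is(scores, "ScoreMatrix"), is(ds, "AssociationSet"))
  if (!identical(scores@lncIds, ds@lncIds) || !identical(scores@miIds, ds@miIds))
    stop("score matrix identifiers do not match the dataset")
  if (topK <= 0) stop("topK must be positive")
  r <- length(ds@lncIds)
  df <- data.frame(
    lncId = rep(ds@lncIds, times = length(ds@miIds)),
    miId = rep(ds@miIds, each = r),
    score = as.vector(scores@P),
    known = as.vector(ds@Y == 1),
    stringsAsFactors = FALSE)
  if (excludeKnown) df <- df[!df$known, , drop = FALSE]
  ord <- order(-df$score, df$lncId, df$miId, method = "radix")
  df <- df[ord, , drop = FALSE]
  if (is.finite(topK)) df <- utils::head(df, topK)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", "lncId", "miId", "score", "known")]
}

#' Write ranked predictions to a TSV file
#'
#' @inheritParams rankPredictions
#' @param path output path.
#' @return the ranked data.frame, invisibly.
#' @export
writeRankings <- function(scores, ds, path, topK = Inf, excludeKnown = FALSE) {
  df <- rankPredictions(scores, ds, topK = topK, excludeKnown = excludeKnown)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export a similarity or score matrix as dense CSV
#'
#' Writes the underlying matrix with identifier row/column headers, for
#' inspection and regression comparisons.
#'
#' @param x a [SimilarityMatrix-class] or [ScoreMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMatrixCSV <- function(x, path) {
  M <- as.matrix(x)
  if (is(x, "SimilarityMatrix")) dimnames(M) <- list(x@ids, x@ids)
  if (is(x, "ScoreMatrix")) dimnames(M) <- list(x@lncIds, x@miIds)
  utils::write.csv(M, path, row.names = TRUE)
  invisible(path)
}
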
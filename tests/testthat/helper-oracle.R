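# Independent scalar (loop-based) reimplementation of every pipeline stage,
# used as the oracle the vectorized implementation must match elementwise.
# Deliberately written with explicit loops and no shared code with R/.

oracle_cosine <- function(V) {
  p <- nrow(V)
  S <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ni <- sqrt(sum(V[i, ]^2)); nj <- sqrt(sum(V[j, ]^2))
    S[i, j] <- if (ni == 0 || nj == 0) 0 else sum(V[i, ] * V[j, ]) / (ni * nj)
  }
  S
}

oracle_jaccard <- function(V) {
  p <- nrow(V)
  S <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    inter <- sum(V[i, ] == 1 & V[j, ] == 1)
    un <- sum(V[i, ] == 1 | V[j, ] == 1)
    S[i, j] <- if (un == 0) 0 else inter / un
  }
  S
}

oracle_spectral <- function(V, K = 5) {
  p <- nrow(V)
  stopifnot(p >= 2)
  d <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    d[i, j] <- sqrt(sum((V[i, ] - V[j, ])^2))
  Kc <- min(K, p - 1)
  delta <- numeric(p)
  for (i in seq_len(p)) delta[i] <- sort(d[i, -i])[Kc]
  S <- matrix(0, p, p)
  if (all(delta == 0)) {
    for (i in seq_len(p)) for (j in seq_len(p))
      if (i != j && d[i, j] == 0) S[i, j] <- 1
    return(S)
  }
  delta[delta == 0] <- min(delta[delta > 0])
  for (i in seq_len(p)) for (j in seq_len(p))
    if (i != j) S[i, j] <- exp(-d[i, j]^2 / (delta[i] * delta[j]))
  S
}

oracle_fuse <- function(primary, filler, weight = 0.5) {
  p <- nrow(primary)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    out[i, j] <- if (primary[i, j] != 0)
      weight * primary[i, j] + (1 - weight) * filler[i, j]
    else filler[i, j]
  out
}

oracle_integrated <- function(V, K = 5, weight = 0.5,
                              kernels = c("cosine", "jaccard", "spectral")) {
  acc <- NULL
  for (kn in c("spectral", "jaccard", "cosine")) {
    if (!kn %in% kernels) next
    M <- switch(kn,
                spectral = oracle_spectral(V, K),
                jaccard = oracle_jaccard(V),
                cosine = oracle_cosine(V))
    acc <- if (is.null(acc)) M else oracle_fuse(M, acc, weight)
  }
  acc
}

# full scalar pipeline: similarity -> fusion -> fill -> projections -> combine
oracle_predict <- function(Y, K = 5, weight = 0.5, deltaFill = 1e-30,
                           mode = "full",
                           kernels = c("cosine", "jaccard", "spectral")) {
  r <- nrow(Y); n <- ncol(Y)
  JSCL <- oracle_integrated(Y, K, weight, kernels)
  JSCM <- oracle_integrated(t(Y), K, weight, kernels)
  Yd <- Y
  for (i in seq_len(r)) for (j in seq_len(n))
    if (Yd[i, j] == 0) Yd[i, j] <- deltaFill
  P <- matrix(0, r, n)
  for (i in seq_len(r)) for (j in seq_len(n)) {
    lp <- sum(JSCL[i, ] * Yd[, j]) / sqrt(sum(Yd[, j]^2))
    mp <- sum(JSCM[, j] * Yd[i, ]) / sqrt(sum(Yd[i, ]^2))
    if (mode == "full") {
      P[i, j] <- (lp + mp) / (sqrt(sum(JSCL[i, ]^2)) + sqrt(sum(JSCM[, j]^2)))
    } else if (mode == "lnc") {
      P[i, j] <- lp / sqrt(sum(JSCL[i, ]^2))
    } else {
      P[i, j] <- mp / sqrt(sum(JSCM[, j]^2))
    }
  }
  P
}

# AUC by explicit enumeration of positive-negative pairs (half credit to ties)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# stepwise AUPR by explicit threshold enumeration
oracle_aupr <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels)
  area <- 0; prevRecall <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    recall <- tp / npos
    precision <- tp / sum(sel)
    area <- area + (recall - prevRecall) * precision
    prevRecall <- recall
  }
  area
}

# random binary association matrix with at least one positive
random_Y <- function(r, n, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    Y <- (matrix(stats::runif(r * n), r, n) < density) * 1
    if (sum(Y) == 0) Y[sample(r, 1), sample(n, 1)] <- 1
    Y
  })
}

random_dataset <- function(r, n, density = 0.3, seed = 1) {
  AssociationSet(paste0("L", seq_len(r)), paste0("M", seq_len(n)),
                 random_Y(r, n, density, seed))
}
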
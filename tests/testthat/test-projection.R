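test_that("fillUnknowns substitutes the tiny constant only where Y is 0", {
  expect_equal(fillUnknowns(matrix(c(1, 0), 1, 2)), matrix(c(1, 1e-30), 1, 2))
  ones <- matrix(1, 3, 2)
  expect_equal(fillUnknowns(ones), ones)
  zc <- fillUnknowns(matrix(0, 4, 1), deltaFill = 1e-30)
  expect_equal(sqrt(sum(zc^2)), 1e-30 * 2)  # all-zero column keeps norm > 0
  expect_error(fillUnknowns(matrix(1, 2, 2), deltaFill = 0), "positive")
  expect_error(fillUnknowns(matrix(1, 2, 2), deltaFill = -1), "positive")
})

test_that("space projections compute scalar projections onto association vectors", {
  SLint <- rbind(c(1, 0.5), c(0.5, 1))
  Yd <- cbind(c(1, 1e-30), c(1e-30, 1))
  L <- lncSpaceProjection(SLint, Yd)
  expect_equal(L[1, 1], 1, tolerance = 1e-12)     # dot ~1, norm ~1
  zeros <- lncSpaceProjection(matrix(0, 2, 2), Yd)
  expect_equal(zeros, matrix(0, 2, 2))            # zero similarity vector
  # column proportional to the similarity row attains the Cauchy-Schwarz bound
  v <- c(0.8, 0.4)
  Lp <- lncSpaceProjection(rbind(v, c(0.1, 0.2)), cbind(2 * v))
  expect_equal(unname(Lp[1, 1]), sqrt(sum(v^2)))
  # miRNA space mirrors the construction on rows
  SMint <- rbind(c(1, 0.5), c(0.5, 1))
  M <- miSpaceProjection(SMint, rbind(c(1, 1e-30), c(1e-30, 1)))
  expect_equal(M[1, 1], 1, tolerance = 1e-12)
  Mp <- miSpaceProjection(cbind(v, c(0.1, 0.2)), rbind(3 * v))
  expect_equal(unname(Mp[1, 1]), sqrt(sum(v^2)))
  expect_error(lncSpaceProjection(matrix(0, 3, 3), Yd), "dimension")
  expect_error(miSpaceProjection(matrix(0, 3, 3), Yd), "dimension")
})

test_that("combined scores normalize by the similarity-vector norms", {
  SLint <- rbind(c(1, 0.5), c(0.5, 1))   # ||row 1|| = 1.118034
  SMint <- diag(2)                       # ||col 1|| = 1
  L <- matrix(c(1.0, 0, 0, 0), 2, 2)
  M <- matrix(c(0.8, 0, 0, 0), 2, 2)
  P <- as.matrix(combineProjections(L, M, SLint, SMint))
  expect_equal(P[1, 1], 1.8 / (sqrt(1.25) + 1), tolerance = 1e-12)
  expect_equal(P[2, 2], 0)              # zero numerator
  # projections at their Cauchy-Schwarz maxima give exactly 1
  Pm <- as.matrix(combineProjections(matrix(sqrt(1.25), 2, 2), matrix(1, 2, 2),
                                     SLint, SMint))
  expect_equal(Pm[1, 1], 1, tolerance = 1e-12)
  expect_error(
    combineProjections(L, M, matrix(0, 2, 2), matrix(0, 2, 2),
                       c("L1", "L2"), c("M1", "M2")),
    "zero normalization.*L1.*M1")
})

test_that("the full pipeline matches the scalar oracle elementwise", {
  Y <- random_Y(10, 8, density = 0.35, seed = 42)
  for (mode in c("full", "lnc", "mi")) {
    P <- as.matrix(predictScores(Y, mode = mode))
    expect_lt(max(abs(P - oracle_predict(Y, mode = mode))), 1e-10)
  }
})

test_that("predictions respect the symmetry of a symmetric input", {
  P <- as.matrix(predictScores(diag(2)))
  expect_equal(P[1, 1], P[2, 2], tolerance = 1e-14)
  expect_equal(P[1, 2], P[2, 1], tolerance = 1e-14)
})

test_that("scores are permutation-equivariant and bounded", {
  Y <- random_Y(9, 7, density = 0.3, seed = 8)
  P <- as.matrix(predictScores(Y))
  permR <- sample(9); permC <- sample(7)
  Pp <- as.matrix(predictScores(Y[permR, permC]))
  expect_equal(Pp, P[permR, permC], tolerance = 1e-12, ignore_attr = TRUE)
  for (mode in c("full", "lnc", "mi")) {
    Pm <- as.matrix(predictScores(Y, mode = mode))
    expect_true(min(Pm) >= 0 && max(Pm) <= 1 + 1e-12)
  }
})

test_that("a held-out within-block positive scores above the background median", {
  ds <- simulateAssociations(r = 24, n = 16, nBlocks = 2, pIn = 0.8,
                             pOut = 0.02, seed = 5)
  Y <- assocMatrix(ds)
  blockL <- (seq_len(24) - 1) %% 2 + 1
  blockM <- (seq_len(16) - 1) %% 2 + 1
  within <- which(outer(blockL, blockM, "==") & Y == 1)
  held <- within[1]
  Y[held] <- 0
  P <- as.matrix(predictScores(Y))
  cross <- P[outer(blockL, blockM, "!=") & Y == 0]
  expect_gt(P[held], median(cross))
})

test_that("scores are insensitive to the zero-fill constant", {
  Y <- random_Y(8, 6, density = 0.3, seed = 21)
  P1 <- as.matrix(predictScores(Y, deltaFill = 1e-40))
  P2 <- as.matrix(predictScores(Y, deltaFill = 1e-20))
  expect_lt(max(abs(P1 - P2)), 1e-6)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(predictScores(matrix(0, 3, 3)), "at least one known association")
  expect_error(predictScores(matrix(c(1, 0, 1, 0), 1, 4)), "two entities")
})
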
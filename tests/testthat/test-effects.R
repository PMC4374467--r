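fxShape <- function() {
  if (is.null(.fx$shape)) {
    base <- makeSymmetricBaseConfig()
    ph <- simulateShapes(fxSim(), base, qtl = NULL, seed = 77)
    .fx$shapeBase <- base
    .fx$shape <- gpaObjectSymmetry(ph$coords, base$sym)
  }
  .fx$shape
}

# four-region map over the 53-landmark base: pairs split across three
# regions, midline in a fourth, landmark 1 and its partner on a boundary
fxRegions <- function() {
  base <- makeSymmetricBaseConfig()
  p <- nrow(base$sym@pairs)
  regs <- vector("list", base$sym@k)
  for (j in seq_len(p)) {
    r <- c("neurocranium", "lateral_face", "palate")[1 + (j %% 3)]
    regs[[base$sym@pairs[j, 1]]] <- r
    regs[[base$sym@pairs[j, 2]]] <- r
  }
  for (i in base$sym@midline) regs[[i]] <- "dorsal_face"
  regs[[base$sym@pairs[1, 1]]] <- c("neurocranium", "lateral_face")
  regs[[base$sym@pairs[1, 2]]] <- c("neurocranium", "lateral_face")
  RegionMap(regs)
}

test_that("effect magnitude is a norm, invariant to the orthonormal basis", {
  expect_identical(effectMagnitude(rep(0, 5)), 0)
  expect_identical(effectMagnitude(c(0, 1, 0)), 1)
  ss <- fxShape()
  set.seed(31)
  b <- rnorm(nPCs(ss))
  d <- backTransform(ss, b)
  expect_equal(effectMagnitude(b), sqrt(sum(d^2)), tolerance = 1e-10)
  expect_error(effectMagnitude(c(1, NA)), "finite")
})

test_that("variance accounting attributes a single dominating term correctly", {
  pr <- fxProbs()
  n <- nIndividuals(pr)
  loci <- data.frame(chr = "2", pos = 20, stringsAsFactors = FALSE)
  idx <- morphoqtl:::.lociIndices(pr@grid, loci)
  g <- pr@pHet[, idx]
  set.seed(41)
  beta <- rnorm(4)
  Y <- g %o% beta + matrix(rnorm(n * 4, 0, 1e-4), n)
  va <- varianceAccounting(pr, Y, covars = NULL, loci)
  expect_gt(va$pctTotal[va$term != "(Intercept)"][1], 99)
  expect_error(varianceAccounting(pr, matrix(1, n, 2), NULL, loci), "zero")
})

test_that("drop-one sums of squares of orthogonal regressors partition the total", {
  pr <- fxProbs()
  n <- nIndividuals(pr)
  set.seed(43)
  x1 <- rnorm(n); x1 <- x1 - mean(x1)
  x2 <- rnorm(n); x2 <- residuals(lm(x2 ~ x1))
  Y <- x1 %o% c(1, 0, 2) + x2 %o% c(0, 1, 1) + matrix(rnorm(3 * n, 0, 0.3), n)
  cv <- data.frame(a = x1, b = x2)
  # no QTL: terms are the two orthogonal covariates
  va <- varianceAccounting(pr, Y, cv, NULL)
  X <- cbind(1, x1, x2)
  rss <- sum(qr.resid(qr(X), Y)^2)
  tot <- sum(scale(Y, scale = FALSE)^2)
  expect_equal(sum(va$SS) + rss, tot, tolerance = 1e-8)
})

test_that("projection scores isolate the effect direction", {
  pr <- fxProbs()
  n <- nIndividuals(pr)
  set.seed(47)
  g <- rnorm(n)
  beta <- c(1, 2, -1, 0.5)
  Y <- g %o% beta
  ps <- projectionScores(Y, beta)
  expect_equal(ps$scores, g * effectMagnitude(beta), tolerance = 1e-12)
  Yorth <- matrix(rnorm(n * 4), n)
  Yorth <- Yorth - tcrossprod(as.vector(Yorth %*% beta), beta) / sum(beta^2)
  expect_equal(projectionScores(Yorth + 1e-14, beta)$scores, rep(0, n), tolerance = 1e-10)
  expect_error(projectionScores(Y, rep(0, 4)), "non-zero")
  # directional variance: a QTL explaining all variance in its direction
  loci <- data.frame(chr = "3", pos = 5, stringsAsFactors = FALSE)
  idx <- morphoqtl:::.lociIndices(pr@grid, loci)
  Yq <- pr@pHet[, idx] %o% beta
  psq <- projectionScores(Yq, beta, probs = pr, covars = NULL, loci = loci,
                          term = sprintf("QTL_%s@%.6g", "3", 5))
  expect_equal(psq$pctDirection, 100, tolerance = 1e-6)
})

test_that("region decomposition splits boundary landmarks and conserves magnitude", {
  rm2 <- RegionMap(list("A", c("A", "B"), "B"))
  d <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 0, 0)) + 1e-300
  d[2, ] <- c(2, 0, 0)
  rd <- regionDecomposition(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 0, 0)), rm2)
  expect_equal(rd$raw[rd$region == "A"], 0.5)
  expect_equal(rd$raw[rd$region == "B"], 0.5)
  # single-region displacement
  rd2 <- regionDecomposition(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0)), rm2)
  expect_equal(rd2$raw[rd2$region == "A"], 1)
  expect_equal(sum(rd2$raw), 1, tolerance = 1e-12)
  # equal magnitudes: raw = landmark-count shares, normalized uniform
  rm3 <- RegionMap(list("A", "A", "B", "C"))
  dEq <- matrix(rep(c(1, 0, 0), 4), 4, 3, byrow = TRUE)
  rd3 <- regionDecomposition(dEq, rm3)
  expect_equal(rd3$raw, c(0.5, 0.25, 0.25))
  expect_equal(rd3$normalized, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(rd3$normalized), 1, tolerance = 1e-12)
  expect_error(regionDecomposition(matrix(0, 4, 3), rm3), "zero")
})

test_that("random-vector intervals are seed-stable and flag targeted effects", {
  ss <- fxShape()
  rmap <- fxRegions()
  rv1 <- randomVectorIntervals(ss, rmap, nDraws = 200, seed = 5)
  rv2 <- randomVectorIntervals(ss, rmap, nDraws = 200, seed = 5)
  expect_identical(rv1$raw, rv2$raw)
  # a vector confined to neurocranium landmarks exceeds that region's null
  neuro <- which(vapply(rmap@regions, function(r) identical(r, "neurocranium"), TRUE))
  base <- .fx$shapeBase
  basis <- symmetricTangentBasis(base$config, base$sym)
  ef <- makeEffectVector(basis, magnitude = 1, landmarks = neuro, seed = 3)
  # express in the ShapeSpace PC basis via the landmark displacements
  dpc <- as.vector(ss@basis %*% ef$tangent)
  rd <- regionDecomposition(backTransform(ss, dpc), rmap)
  hi <- rv1$raw$upper[rv1$raw$region == "neurocranium"]
  expect_gt(rd$raw[rd$region == "neurocranium"], hi)
})

test_that("PC angles behave analytically at the extremes and under the isotropic null", {
  ss <- fxShape()
  q <- nPCs(ss)
  e1 <- c(1, rep(0, q - 1))
  a1 <- pcAngleAnalysis(e1, ss, mode = "pc1", nNull = 200, seed = 2)
  expect_equal(a1$angles, 0, tolerance = 1e-10)
  # orthogonal to the leading subspace: 90 degrees
  ak <- pcAngleAnalysis(c(rep(0, q - 1), 1), ss, mode = "subspace",
                        varFraction = 0.5, nNull = 200, seed = 2)
  expect_equal(ak$angles, 90, tolerance = 1e-10)
  expect_lt(ak$kSubspace, q - 1)
  # isotropic null, pc1 mode: E[cos^2 theta] = 1/q
  set.seed(11)
  Z <- matrix(rnorm(500 * q), 500)
  az <- pcAngleAnalysis(Z, ss, mode = "pc1", nNull = 100, nPermCor = 100, seed = 4)
  c2 <- cos(az$angles * pi / 180)^2
  se <- sd(c2) / sqrt(length(c2))
  expect_lt(abs(mean(c2) - 1 / q), 3 * se + 1e-4)
  expect_error(pcAngleAnalysis(e1, ss, mode = "nope"), "arg")
})
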
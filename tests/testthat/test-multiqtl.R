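# score-space phenotype with planted QTL, built on the shared fixture cross
plantScores <- function(pr, hidden, map, loci, betas, sigma = 1, seed = 1) {
  set.seed(seed)
  n <- nrow(hidden)
  q <- ncol(betas)
  Y <- matrix(rnorm(n * q, 0, sigma), n)
  for (j in seq_len(nrow(loci))) {
    mi <- which(map@markers$chr == loci$chr[j] &
                  abs(map@markers$pos - loci$pos[j]) < 1e-6)
    Y <- Y + hidden[, mi] %o% betas[j, ]
  }
  Y
}

test_that("null and single-QTL model logP are consistent with the scan", {
  set.seed(2)
  pr <- fxProbs()
  n <- nIndividuals(pr)
  Y <- matrix(rnorm(n * 5), n)
  cv <- fxSim()$cross@covariates
  expect_identical(modelLogP(pr, Y, cv, NULL)$logP, 0)
  loc <- data.frame(chr = "3", pos = 11)
  m1 <- modelLogP(pr, Y, cv, loc)
  sc <- scanShape(pr, Y, cv)
  i <- which(sc@table$chr == "3" & sc@table$pos == 11)
  expect_equal(m1$logP, sc@table$score[i], tolerance = 1e-9)
})

test_that("two orthogonal planted QTL give a larger joint logP than either alone", {
  pr <- fxProbs()
  map <- fxMap5()
  hid <- fxSim()$hidden
  loci <- data.frame(chr = c("1", "4"), pos = c(10, 30), stringsAsFactors = FALSE)
  betas <- rbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0)) * 0.8
  Y <- plantScores(pr, hid, map, loci, betas, seed = 5)
  cv <- fxSim()$cross@covariates
  joint <- modelLogP(pr, Y, cv, loci)$logP
  expect_gt(joint, modelLogP(pr, Y, cv, loci[1, ])$logP)
  expect_gt(joint, modelLogP(pr, Y, cv, loci[2, ])$logP)
})

test_that("refinement is a fixed point at profile maxima and never decreases logP", {
  pr <- fxProbs()
  map <- fxMap5()
  hid <- fxSim()$hidden
  loci <- data.frame(chr = c("1", "4"), pos = c(10, 30), stringsAsFactors = FALSE)
  betas <- rbind(c(1.2, 0, 0, 0, 0), c(0, 1.2, 0, 0, 0))
  Y <- plantScores(pr, hid, map, loci, betas, seed = 6)
  cv <- fxSim()$cross@covariates
  # start 15 cM off the truth on each chromosome
  start <- data.frame(chr = c("1", "4"), pos = c(25, 45), stringsAsFactors = FALSE)
  ref <- refinePositions(pr, Y, cv, start)
  expect_true(all(diff(ref$logPTrace) > 0))
  for (j in 1:2) {
    tr <- loci[loci$chr == ref$loci$chr[j], ]
    expect_lt(abs(ref$loci$pos[j] - tr$pos), 3)
  }
  # refining from the refined positions changes nothing
  again <- refinePositions(pr, Y, cv, ref$loci)
  expect_identical(again$loci, ref$loci)
  expect_equal(again$logP, ref$logP, tolerance = 1e-12)
})

test_that("forward/backward search recovers a strong planted QTL and prefers the null on noise", {
  pr <- fxProbs()
  map <- fxMap5()
  hid <- fxSim()$hidden
  cv <- fxSim()$cross@covariates
  loci <- data.frame(chr = "2", pos = 20, stringsAsFactors = FALSE)
  Y <- plantScores(pr, hid, map, loci, matrix(c(1, 1, 0, 0, 0), 1) * 0.9, seed = 8)
  fb <- forwardBackwardSearch(pr, Y, cv, threshold = 3, maxQTL = 3)
  expect_gte(nrow(fb$model@loci), 1L)
  best <- fb$model@loci
  expect_true(any(best$chr == "2" & abs(best$pos - 20) <= 10))
  # trace bookkeeping: forward adds one QTL per step, backward returns to null
  expect_identical(fb$trace$nQTL[1], 0L)
  expect_identical(tail(fb$trace$nQTL, 1), 0L)
  expect_equal(fb$trace$penalized, fb$trace$logP - 3 * fb$trace$nQTL)
  expect_equal(max(fb$trace$penalized), fb$model@penalized, tolerance = 1e-9)
  # pure noise: the null model wins
  set.seed(99)
  Ynull <- matrix(rnorm(nrow(hid) * 5), nrow(hid))
  fb0 <- forwardBackwardSearch(pr, Ynull, cv, threshold = 3.2, maxQTL = 2)
  expect_identical(nrow(fb0$model@loci), 0L)
  expect_identical(fb0$model@penalized, 0)
})

test_that("stepwise significance search agrees on well-separated strong effects", {
  pr <- fxProbs()
  map <- fxMap5()
  hid <- fxSim()$hidden
  cv <- fxSim()$cross@covariates
  loci <- data.frame(chr = c("1", "4"), pos = c(10, 30), stringsAsFactors = FALSE)
  betas <- rbind(c(1.1, 0, 0, 0, 0), c(0, 1.1, 0, 0, 0))
  Y <- plantScores(pr, hid, map, loci, betas, seed = 12)
  sw <- stepwiseSignificanceSearch(pr, Y, cv, threshold = 3)
  fb <- forwardBackwardSearch(pr, Y, cv, threshold = 3, maxQTL = 4)
  expect_identical(nrow(sw$loci), 2L)
  o <- order(sw$loci$chr)
  expect_equal(sw$loci[o, ], fb$model@loci[order(fb$model@loci$chr), ],
               ignore_attr = TRUE)
  for (j in 1:2) expect_lt(abs(sw$loci$pos[o][j] - loci$pos[j]), 6)
  # null phenotype: empty model
  set.seed(100)
  Ynull <- matrix(rnorm(nrow(hid) * 5), nrow(hid))
  sw0 <- stepwiseSignificanceSearch(pr, Ynull, cv, threshold = 3.2)
  expect_identical(nrow(sw0$loci), 0L)
})

test_that("fitQTLModel interpolates noiseless data and matches drop-one identities", {
  pr <- fxProbs()
  n <- nIndividuals(pr)
  cv <- fxSim()$cross@covariates
  loci <- data.frame(chr = c("2", "5"), pos = c(7, 18), stringsAsFactors = FALSE)
  idx <- morphoqtl:::.lociIndices(pr@grid, loci)
  X <- cbind(1, as.matrix(cv), pr@pHet[, idx])
  set.seed(14)
  Btrue <- matrix(rnorm(ncol(X) * 4), ncol(X))
  Y <- X %*% Btrue
  fit <- fitQTLModel(pr, Y, cv, loci)
  expect_equal(unname(fit@effects), unname(Btrue), tolerance = 1e-9)
  # conditional logP of a term equals the nested-design Pillai computation
  Yn <- Y + matrix(rnorm(length(Y), 0, 0.5), n)
  fit2 <- fitQTLModel(pr, Yn, cv, loci)
  lastTerm <- nrow(fit2@termTests)
  pt <- pillaiTest(Yn, X, X[, -ncol(X)])
  expect_equal(fit2@termTests$logP[lastTerm], pt$logP, tolerance = 1e-9)
  # collinearity error names the duplicated term
  cv2 <- cv; cv2$dup <- pr@pHet[, idx[1]]
  expect_error(fitQTLModel(pr, Yn, cv2, loci), "collinear")
})

test_that("Bayes credible intervals follow the rescaled 1/p accumulation rule", {
  pos <- 0:100
  lp <- rep(0, 101); lp[41] <- 30
  ci <- bayesCredibleInterval(pos, lp, 0.95)
  expect_equal(c(ci$lower, ci$upper), c(40, 40))
  # flat non-zero profile: ceil(0.95 * 101) = 96 grid points
  ciFlat <- bayesCredibleInterval(pos, rep(5, 101), 0.95)
  expect_equal(ciFlat$upper - ciFlat$lower + 1, 96)
  expect_warning(ciZero <- bayesCredibleInterval(pos, rep(0, 101)), "flat")
  expect_equal(c(ciZero$lower, ciZero$upper), c(0, 100))
  expect_error(bayesCredibleInterval(pos, lp, 1.2), "coverage")
})

test_that("interval estimates cover a strong planted locus and convert to bp", {
  pr <- fxProbs()
  map <- fxMap5()
  hid <- fxSim()$hidden
  cv <- fxSim()$cross@covariates
  loci <- data.frame(chr = "2", pos = 20, stringsAsFactors = FALSE)
  Y <- plantScores(pr, hid, map, loci, matrix(c(1, 1, 0, 0, 0), 1), seed = 21)
  sc <- scanShape(pr, Y, cv)
  pk <- which.max(sc@table$score)
  ivs <- qtlIntervals(pr, Y, cv,
                      data.frame(chr = sc@table$chr[pk], pos = sc@table$pos[pk]),
                      anchors = simAnchors(map))
  expect_true(ivs$lower <= 20 && ivs$upper >= 20)
  expect_true(ivs$lower <= ivs$pos && ivs$pos <= ivs$upper)
  expect_equal(ivs$lower_bp, 3e6 + ivs$lower * 2e6)
})
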
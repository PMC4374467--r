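# covariate design matrix: intercept + all covariate columns
.covariateDesign <- function(covars, n) {
  if (is.null(covars)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  covars <- as.data.frame(covars)
  if (anyNA(covars)) stop("covariates contain missing values; drop those individuals first")
  X <- cbind(`(Intercept)` = 1, as.matrix(covars))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qrx$pivot[seq_len(qrx$rank)])
    stop(sprintf("collinear covariate column(s): %s",
                 paste(colnames(X)[bad], collapse = ", ")))
  }
  X
}

# Fast single-QTL Haley-Knott scan core via Frisch-Waugh-Lovell.
# For a single added column x (h = 1), H has rank one and
# V = c' A^-1 c / (x~' x~) with c = Y~' x~ and A = Y~' Y~, where ~ denotes
# residualization on the null design X0.  Identical to pillaiTest per
# position, but one matrix product for the whole grid.
.hkScanShape <- function(pHet, X0, Y) {
  n <- nrow(Y); q <- ncol(Y)
  qr0 <- qr(X0)
  if (qr0$rank < ncol(X0)) {
    bad <- setdiff(seq_len(ncol(X0)), qr0$pivot[seq_len(qr0$rank)])
    stop(sprintf("collinear design column(s): %s",
                 paste(colnames(X0)[bad], collapse = ", ")))
  }
  dfe <- n - qr0$rank - 1L
  if (dfe < q + 2L) stop(sprintf(
    "error df (%d) must be at least q + 2 (%d); truncate the response PCs", dfe, q + 2L))
  Q <- qr.Q(qr0)
  Yt <- Y - Q %*% crossprod(Q, Y)
  Xt <- pHet - Q %*% crossprod(Q, pHet)
  A <- crossprod(Yt)
  C <- crossprod(Yt, Xt)              # q x P
  xx <- colSums(Xt^2)
  V <- colSums(C * solve(A, C)) / xx
  mono <- !is.finite(V) | xx < 1e-10
  if (any(mono)) {
    warning(sprintf("%d monomorphic grid position(s); score set to 0", sum(mono)))
    V[mono] <- 0
  }
  V <- pmin(pmax(V, 0), 1 - 1e-15)
  df1 <- q
  df2 <- dfe - q + 1L
  Fstat <- (df2 / df1) * V / (1 - V)
  logP <- -pf(Fstat, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(V = V, F = Fstat, df1 = df1, df2 = df2, logP = logP)
}

.hkScanScalar <- function(pHet, X0, y) {
  n <- length(y)
  qr0 <- qr(X0)
  Q <- qr.Q(qr0)
  yt <- as.vector(y - Q %*% crossprod(Q, y))
  Xt <- pHet - Q %*% crossprod(Q, pHet)
  rss0 <- sum(yt^2)
  xx <- colSums(Xt^2)
  b <- colSums(Xt * yt)
  rss1 <- rss0 - ifelse(xx < 1e-10, 0, b^2 / pmax(xx, 1e-300))
  lod <- (n / 2) * log10(rss0 / rss1)
  pmax(lod, 0)
}

#' Multivariate Haley-Knott genome scan for shape
#'
#' At each grid position the additive QTL regressor is P(HET) (backcross
#' parameterization, a single column) and the position is tested against
#' the covariate-only model with Pillai's trace; scores are reported as
#' logP = -log10 p of the approximate F statistic, which is exact here
#' because the hypothesis has a single degree of freedom.
#'
#' @param probs a [GenotypeProbs-class].
#' @param shape a [ShapeSpace-class], or directly an n x q score matrix.
#' @param covars data.frame of covariates (e.g. sex, cross_direction,
#'   log centroid size); an intercept is always included.
#' @return a [ScanResult-class] with per-position `V`, `F`, `df1`, `df2`
#'   and `score` = logP.
#' @export
scanShape <- function(probs, shape, covars = NULL) {
  Y <- if (is(shape, "ShapeSpace")) scores(shape) else as.matrix(shape)
  if (nrow(Y) != nrow(probs@pHet)) stop("individuals in shape and probabilities differ")
  X0 <- .covariateDesign(covars, nrow(Y))
  r <- .hkScanShape(probs@pHet, X0, Y)
  tab <- data.frame(chr = probs@grid$chr, pos = probs@grid$pos,
                    score = r$logP, V = r$V, F = r$F,
                    df1 = r$df1, df2 = r$df2, stringsAsFactors = FALSE)
  new("ScanResult", table = tab, type = "shape")
}

#' Haley-Knott genome scan for a scalar trait (LOD)
#'
#' LOD = (n/2) log10(RSS_reduced / RSS_full) at each grid position, for a
#' single trait such as log centroid size.
#'
#' @param probs a [GenotypeProbs-class].
#' @param trait per-individual numeric trait.
#' @param covars data.frame of covariates; an intercept is always included.
#' @return a [ScanResult-class] with `score` = LOD.
#' @export
scanScalar <- function(probs, trait, covars = NULL) {
  if (length(trait) != nrow(probs@pHet)) stop("trait length and probabilities differ")
  X0 <- .covariateDesign(covars, length(trait))
  lod <- .hkScanScalar(probs@pHet, X0, trait)
  tab <- data.frame(chr = probs@grid$chr, pos = probs@grid$pos,
                    score = lod, stringsAsFactors = FALSE)
  new("ScanResult", table = tab, type = "scalar")
}

#' Permutation genome-wide significance threshold
#'
#' Phenotype rows and covariate rows are reshuffled among individuals by
#' one joint permutation per iteration while genotype probabilities stay
#' fixed, the genome scan is repeated, and the genome-wide maximum score
#' is recorded; the threshold is the empirical (1 - alpha) quantile
#' (linear interpolation of order statistics) of the stored maxima.
#'
#' @param probs a [GenotypeProbs-class].
#' @param pheno n x q score matrix, [ShapeSpace-class], or numeric trait.
#' @param covars data.frame of covariates or NULL.
#' @param nPerm number of permutations (>= 2).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return a [PermutationResult-class].
#' @export
genomeWideThreshold <- function(probs, pheno, covars = NULL, nPerm = 1000,
                                alpha = 0.05, seed = 1) {
  if (nPerm < 2) stop("nPerm must be >= 2")
  if (is(pheno, "ShapeSpace")) pheno <- scores(pheno)
  scalar <- is.null(dim(pheno))
  n <- if (scalar) length(pheno) else nrow(pheno)
  X0 <- .covariateDesign(covars, n)
  pH <- probs@pHet
  # Permuting phenotype and covariate rows jointly while genotypes stay
  # fixed leaves Q'Ytilde = 0, so only two thin cross-products change per
  # permutation: c = Ytilde[perm,]' X and Q[perm,]' X.
  Q <- qr.Q(qr(X0))
  r0 <- ncol(Q)
  xsq <- colSums(pH^2)
  maxima <- numeric(nPerm)
  set.seed(seed)
  if (scalar) {
    yt <- as.vector(pheno - Q %*% crossprod(Q, pheno))
    rss0 <- sum(yt^2)
    for (b in seq_len(nPerm)) {
      idx <- sample.int(n)
      cc <- as.vector(crossprod(pH, yt[idx]))
      xx <- xsq - colSums(crossprod(Q[idx, , drop = FALSE], pH)^2)
      rss1 <- rss0 - ifelse(xx < 1e-10, 0, cc^2 / pmax(xx, 1e-300))
      maxima[b] <- max((n / 2) * log10(rss0 / rss1), 0)
    }
  } else {
    q <- ncol(pheno)
    dfe <- n - r0 - 1L
    if (dfe < q + 2L) stop(sprintf(
      "error df (%d) must be at least q + 2 (%d); truncate the response PCs",
      dfe, q + 2L))
    Yt <- pheno - Q %*% crossprod(Q, pheno)
    A <- crossprod(Yt)
    Ainv <- chol2inv(chol(A))
    df1 <- q
    df2 <- dfe - q + 1L
    for (b in seq_len(nPerm)) {
      idx <- sample.int(n)
      C <- crossprod(Yt[idx, , drop = FALSE], pH)
      xx <- xsq - colSums(crossprod(Q[idx, , drop = FALSE], pH)^2)
      V <- colSums(C * (Ainv %*% C)) / xx
      V[!is.finite(V) | xx < 1e-10] <- 0
      V <- pmin(pmax(V, 0), 1 - 1e-15)
      Fs <- (df2 / df1) * V / (1 - V)
      maxima[b] <- max(-pf(Fs, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10))
    }
  }
  thr <- unname(quantile(maxima, 1 - alpha, type = 7))
  new("PermutationResult", maxima = maxima, alpha = alpha,
      threshold = thr, seed = as.integer(seed))
}
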
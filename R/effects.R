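#' Magnitude of a shape effect vector (Procrustes distance)
#'
#' The Euclidean norm of the effect vector; because the PC basis is
#' orthonormal, the norm is the same in PC-score space and after
#' back-transformation to tangent coordinates.
#'
#' @param beta numeric effect vector.
#' @return non-negative scalar.
#' @export
effectMagnitude <- function(beta) {
  if (any(!is.finite(beta))) stop("effect vector must be finite")
  sqrt(sum(beta^2))
}

#' Per-term variance accounting for a fitted QTL model
#'
#' The conditional (drop-one) sum of squares of each model term, summed
#' over all response dimensions, as a percentage of the total Procrustes
#' sum of squares of the symmetric shapes (the total centered SS of the
#' scores, since the PC rotation preserves it).
#'
#' @inheritParams modelLogP
#' @return data.frame: `term`, `SS`, `pctTotal`.
#' @export
varianceAccounting <- function(probs, pheno, covars = NULL, loci = NULL) {
  Y <- .phenoScores(pheno)
  X0 <- .covariateDesign(covars, nrow(Y))
  idx <- .lociIndices(probs@grid, loci)
  lociNames <- if (length(idx)) sprintf("QTL_%s@%.6g", probs@grid$chr[idx],
                                        probs@grid$pos[idx]) else character(0)
  X <- if (length(idx)) cbind(X0, structure(probs@pHet[, idx, drop = FALSE],
                                            dimnames = list(NULL, lociNames))) else X0
  tot <- sum(scale(Y, scale = FALSE)^2)
  if (tot <= 0) stop("total Procrustes variance is zero")
  rssFull <- sum(qr.resid(qr(X), Y)^2)
  terms <- colnames(X)[-1]
  ss <- vapply(terms, function(tm) {
    keep <- setdiff(colnames(X), tm)
    sum(qr.resid(qr(X[, keep, drop = FALSE]), Y)^2) - rssFull
  }, numeric(1))
  data.frame(term = terms, SS = unname(ss), pctTotal = unname(100 * ss / tot),
             stringsAsFactors = FALSE)
}

#' Projection scores onto an effect direction
#'
#' s = Y beta' / ||beta|| is the univariate shape variable associated with
#' the shape change defined by beta; the directional variance percentage
#' is the conditional (drop-one) R^2 of the chosen term in a regression of
#' s on all model terms.
#'
#' @param Y n x q score matrix or [ShapeSpace-class].
#' @param beta effect vector (length q).
#' @param probs,covars,loci optional model context for the directional
#'   variance percentage; `term` names which model term to attribute.
#' @param term term name as in the fitted model (e.g. `"QTL_3@44"`).
#' @return list: `scores` (length n), and `pctDirection` when a model
#'   context is supplied.
#' @export
projectionScores <- function(Y, beta, probs = NULL, covars = NULL, loci = NULL,
                             term = NULL) {
  Y <- .phenoScores(Y)
  nb <- effectMagnitude(beta)
  if (nb <= 0) stop("effect vector must be non-zero")
  s <- as.vector(Y %*% beta) / nb
  out <- list(scores = s)
  if (!is.null(probs) && !is.null(term)) {
    X0 <- .covariateDesign(covars, length(s))
    idx <- .lociIndices(probs@grid, loci)
    lociNames <- if (length(idx)) sprintf("QTL_%s@%.6g", probs@grid$chr[idx],
                                          probs@grid$pos[idx]) else character(0)
    X <- if (length(idx)) cbind(X0, structure(probs@pHet[, idx, drop = FALSE],
                                              dimnames = list(NULL, lociNames))) else X0
    if (!term %in% colnames(X)) stop(sprintf("term '%s' is not in the model", term))
    keep <- setdiff(colnames(X), term)
    rssFull <- sum(qr.resid(qr(X), s)^2)
    rssRed <- sum(qr.resid(qr(X[, keep, drop = FALSE]), s)^2)
    out$pctDirection <- 100 * (rssRed - rssFull) / sum((s - mean(s))^2)
  }
  out
}

# fractional landmark count and per-region magnitude sums
.regionSums <- function(mag, regions, regionNames) {
  sums <- setNames(numeric(length(regionNames)), regionNames)
  counts <- setNames(numeric(length(regionNames)), regionNames)
  for (i in seq_along(regions)) {
    rs <- regions[[i]]
    share <- 1 / length(rs)
    for (r in rs) {
      sums[r] <- sums[r] + mag[i] * share
      counts[r] <- counts[r] + share
    }
  }
  list(sums = sums, counts = counts)
}

#' Anatomical-region decomposition of a shape-change vector
#'
#' Per-landmark displacement magnitudes are summed by region; a landmark
#' assigned to several regions contributes its magnitude in equal shares.
#' Raw proportions divide by the grand total; normalized proportions first
#' divide each region sum by its (fractional) landmark count, then
#' renormalize to sum 1.
#'
#' @param displacement k x 3 per-landmark effect (from [backTransform()]).
#' @param regionMap a [RegionMap-class].
#' @return data.frame per region: `region`, `raw`, `normalized`,
#'   `landmarkShare` (fractional landmark count / k).
#' @export
regionDecomposition <- function(displacement, regionMap) {
  regions <- regionMap@regions
  if (nrow(displacement) != length(regions)) {
    stop("displacement rows must match the region map")
  }
  regionNames <- sort(unique(unlist(regions)))
  mag <- sqrt(rowSums(displacement^2))
  gs <- sum(mag)
  if (gs <= 0) stop("zero total displacement magnitude")
  rs <- .regionSums(mag, regions, regionNames)
  raw <- rs$sums / gs
  dens <- rs$sums / rs$counts
  data.frame(region = regionNames, raw = unname(raw),
             normalized = unname(dens / sum(dens)),
             landmarkShare = unname(rs$counts / length(regions)),
             stringsAsFactors = FALSE)
}

#' Random-vector null intervals for region proportions
#'
#' Draws isotropic standard-normal vectors in the q-dimensional symmetric
#' tangent subspace, back-transforms them to landmark displacements,
#' applies the region decomposition, and returns empirical central
#' intervals per region; observed QTL proportions can be flagged against
#' them.
#'
#' @param shape a [ShapeSpace-class].
#' @param regionMap a [RegionMap-class].
#' @param nDraws number of random vectors (>= 100).
#' @param alpha interval level (default 0.05, i.e. a central 95 percent
#'   interval).
#' @param seed RNG seed.
#' @param observed optional named list/data.frame of observed
#'   decompositions to flag (as returned by [regionDecomposition()]).
#' @return list: `raw` and `normalized` data.frames per region with
#'   `lower`, `upper`, `mean`; `draws` (nDraws x regions raw proportions).
#' @export
randomVectorIntervals <- function(shape, regionMap, nDraws = 1000,
                                  alpha = 0.05, seed = 1) {
  if (nDraws < 100) stop("nDraws must be >= 100")
  q <- nPCs(shape)
  regionNames <- sort(unique(unlist(regionMap@regions)))
  set.seed(seed)
  Z <- matrix(rnorm(nDraws * q), nDraws, q)
  rawD <- matrix(NA_real_, nDraws, length(regionNames),
                 dimnames = list(NULL, regionNames))
  normD <- rawD
  for (b in seq_len(nDraws)) {
    d <- backTransform(shape, Z[b, ])
    rd <- regionDecomposition(d, regionMap)
    rawD[b, rd$region] <- rd$raw
    normD[b, rd$region] <- rd$normalized
  }
  mkTab <- function(M) data.frame(
    region = regionNames,
    lower = apply(M, 2, quantile, alpha / 2, names = FALSE),
    upper = apply(M, 2, quantile, 1 - alpha / 2, names = FALSE),
    mean = colMeans(M), stringsAsFactors = FALSE)
  list(raw = mkTab(rawD), normalized = mkTab(normD), draws = rawD)
}

#' Angles between QTL effect vectors and the phenotypic PC structure
#'
#' For each effect vector, the angle (degrees, in \[0, 90\]) to either the
#' first phenotypic PC (`mode = "pc1"`) or to its projection onto the span
#' of the leading PCs covering `varFraction` of the variance
#' (`mode = "subspace"`).  A Monte-Carlo null of isotropic random vectors
#' under the same mode tests whether the observed mean angle is smaller
#' than random, and the Pearson correlation between per-QTL angle and
#' effect magnitude gets a permutation p-value.
#'
#' @param effects matrix of effect vectors (one per row, q columns) or a
#'   single vector.
#' @param shape a [ShapeSpace-class] (defines the PC variances).
#' @param mode "subspace" (default) or "pc1".
#' @param varFraction variance fraction spanned by the leading-PC subspace
#'   in "subspace" mode (default 0.9).
#' @param nNull Monte-Carlo draws for the angle null (default 10000).
#' @param nPermCor permutations for the angle-magnitude correlation
#'   (default 10000).
#' @param seed RNG seed.
#' @return list: `angles` (degrees per effect), `magnitudes`, `meanAngle`,
#'   `nullMeanAngles`, `pSmallerThanRandom`, `corAngleMagnitude`,
#'   `pCor`, `kSubspace`.
#' @export
pcAngleAnalysis <- function(effects, shape, mode = c("subspace", "pc1"),
                            varFraction = 0.9, nNull = 10000,
                            nPermCor = 10000, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(dim(effects))) effects <- matrix(effects, nrow = 1)
  q <- nPCs(shape)
  if (ncol(effects) != q) stop("effect vectors must have q = nPCs(shape) columns")
  k <- if (mode == "pc1") 1L else {
    ev <- shape@eigenvalues
    max(1L, which(cumsum(ev) / sum(ev) >= varFraction)[1])
  }
  angleOf <- function(v) {
    nv <- sqrt(sum(v^2))
    cosang <- sqrt(sum(v[seq_len(k)]^2)) / nv
    acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
  }
  ang <- apply(effects, 1, angleOf)
  mag <- apply(effects, 1, effectMagnitude)
  set.seed(seed)
  nEff <- nrow(effects)
  nullMeans <- vapply(seq_len(nNull), function(b) {
    mean(apply(matrix(rnorm(nEff * q), nEff, q), 1, angleOf))
  }, numeric(1))
  pSmall <- (1 + sum(nullMeans <= mean(ang))) / (nNull + 1)
  r <- pCor <- NA_real_
  if (nEff >= 3) {
    r <- cor(ang, mag)
    perm <- vapply(seq_len(nPermCor), function(b) cor(ang, sample(mag)), numeric(1))
    pCor <- (1 + sum(abs(perm) >= abs(r))) / (nPermCor + 1)
  }
  list(angles = ang, magnitudes = mag, meanAngle = mean(ang),
       nullMeanAngles = nullMeans, pSmallerThanRandom = pSmall,
       corAngleMagnitude = r, pCor = pCor, kSubspace = k)
}
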
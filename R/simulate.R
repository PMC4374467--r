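#' Synthetic genetic map for an N2 backcross panel
#'
#' Builds a map emulating a dense SNP linkage panel on mouse autosomes:
#' by default 19 chromosomes with lengths declining from ~98 to ~42 cM and
#' ~882 evenly spaced informative markers allocated proportionally to
#' chromosome length.  Optional bp positions place 1 cM ~ 2 Mb from a
#' 3 Mb offset, giving a built-in anchor scale.
#'
#' @param nChrom number of autosomes (default 19).
#' @param nMarkers total marker count (default 882).
#' @param lengths optional per-chromosome lengths in cM.
#' @param bp logical: attach physical positions (default TRUE).
#' @return a [GeneticMap-class].
#' @export
simMap <- function(nChrom = 19, nMarkers = 882, lengths = NULL, bp = TRUE) {
  if (is.null(lengths)) lengths <- seq(98, 42, length.out = nChrom)
  per <- pmax(2L, round(nMarkers * lengths / sum(lengths)))
  marker <- chr <- character(0); pos <- numeric(0)
  for (c in seq_len(nChrom)) {
    p <- seq(0, lengths[c], length.out = per[c])
    marker <- c(marker, sprintf("m%d_%d", c, seq_len(per[c])))
    chr <- c(chr, rep(as.character(c), per[c]))
    pos <- c(pos, p)
  }
  GeneticMap(marker, chr, pos, bp = if (bp) 3e6 + pos * 2e6 else NULL)
}

#' Anchor table matching the bp scale of [simMap()]
#' @param map a [GeneticMap-class] with bp positions.
#' @return data.frame `chr`, `cM`, `bp` (terminal markers per chromosome).
#' @export
simAnchors <- function(map) {
  m <- map@markers
  do.call(rbind, lapply(unique(m$chr), function(ch) {
    mc <- m[m$chr == ch, ]
    data.frame(chr = ch, cM = mc$pos, bp = mc$bp, stringsAsFactors = FALSE)
  }))
}

#' Simulate backcross genotypes along a genetic map
#'
#' Hidden genotypes follow the two-state Markov chain per chromosome with
#' inter-marker transition probability r = `mfCarterFalconer(d)`; observed
#' genotypes flip with the genotyping error rate and drop to missing with
#' the missingness rate.  Covariates copy the mapping panel's design:
#' two directions of cross with a fixed sex ratio within each.
#'
#' @param map a [GeneticMap-class].
#' @param n individuals (default 433).
#' @param errorRate genotyping error probability (default 1e-4).
#' @param missingRate missing-genotype probability (default 0.02).
#' @param seed RNG seed.
#' @return list: `cross` (a [Backcross-class]), `hidden` (error-free
#'   genotype matrix).
#' @export
simulateBackcross <- function(map, n = 433, errorRate = 1e-4,
                              missingRate = 0.02, seed = 1) {
  set.seed(seed)
  m <- map@markers
  hidden <- matrix(NA_integer_, n, nrow(m),
                   dimnames = list(sprintf("ind%03d", seq_len(n)), m$marker))
  for (ch in unique(m$chr)) {
    ci <- which(m$chr == ch)
    r <- mfCarterFalconer(diff(m$pos[ci]))
    g <- matrix(NA_integer_, n, length(ci))
    g[, 1] <- rbinom(n, 1, 0.5)
    for (t in seq_along(r)) {
      flip <- rbinom(n, 1, r[t])
      g[, t + 1] <- (g[, t] + flip) %% 2L
    }
    hidden[, ci] <- g
  }
  obs <- hidden
  err <- matrix(runif(length(obs)) < errorRate, nrow(obs))
  obs[err] <- 1L - obs[err]
  obs[matrix(runif(length(obs)) < missingRate, nrow(obs))] <- NA_integer_
  # strata emulating the mapping panel: direction 0 (n~163; 84 F, 79 M),
  # direction 1 (n~270; 128 F, 142 M)
  n0 <- round(n * 163 / 433)
  dir <- c(rep(0L, n0), rep(1L, n - n0))
  sex <- c(rep(0L, round(n0 * 84 / 163)), rep(1L, n0 - round(n0 * 84 / 163)),
           rep(0L, round((n - n0) * 128 / 270)),
           rep(1L, (n - n0) - round((n - n0) * 128 / 270)))
  covars <- data.frame(sex = sex, cross_direction = dir)
  rownames(covars) <- rownames(obs)
  list(cross = Backcross(map, obs, covars), hidden = hidden)
}

#' Symmetric base configuration for a bilateral landmark set
#'
#' Deterministic (given seed) set of 2p + l landmarks in mm: p bilateral
#' pairs mirrored across the x = 0 plane and l midline landmarks on it,
#' spread over a skull-sized (~25 mm) volume.
#'
#' @param p bilateral pairs (default 22).
#' @param l midline landmarks (default 9).
#' @param seed RNG seed.
#' @return list: `config` (k x 3 matrix), `sym` (a [SymmetryMap-class]).
#' @export
makeSymmetricBaseConfig <- function(p = 22, l = 9, seed = 99) {
  set.seed(seed)
  left <- cbind(runif(p, 2, 8), runif(p, -12, 12), runif(p, -6, 6))
  right <- left; right[, 1] <- -right[, 1]
  mid <- cbind(rep(0, l), runif(l, -12, 12), runif(l, -6, 6))
  config <- rbind(left, right, mid)
  rownames(config) <- c(sprintf("L%02d_l", seq_len(p)), sprintf("L%02d_r", seq_len(p)),
                        sprintf("M%02d", seq_len(l)))
  sym <- SymmetryMap(cbind(seq_len(p), p + seq_len(p)), midline = 2 * p + seq_len(l))
  list(config = config, sym = sym)
}

#' Orthonormal basis of the symmetric tangent subspace at a base shape
#'
#' Structural basis of reflection-invariant displacement fields (3 per
#' bilateral pair, 2 per midline landmark), with the similarity directions
#' at the base shape (in-plane translations, rotation about the bilateral
#' axis, scaling) projected out: 3p + 2l - 4 orthonormal rows.
#'
#' @param config k x 3 base configuration (any position/scale).
#' @param sym a [SymmetryMap-class].
#' @return matrix (3p + 2l - 4) x 3k; rows orthonormal, coordinates
#'   landmark-major (x1, y1, z1, x2, ...).
#' @export
symmetricTangentBasis <- function(config, sym) {
  k <- sym@k
  base <- .centerScale(config)
  p <- nrow(sym@pairs); l <- length(sym@midline)
  vecs <- matrix(0, 3 * p + 2 * l, 3 * k)
  at <- function(i, d) 3 * (i - 1) + d
  row <- 0
  for (j in seq_len(p)) {
    i1 <- sym@pairs[j, 1]; i2 <- sym@pairs[j, 2]
    row <- row + 1; vecs[row, at(i1, 1)] <- 1; vecs[row, at(i2, 1)] <- -1
    row <- row + 1; vecs[row, at(i1, 2)] <- 1; vecs[row, at(i2, 2)] <- 1
    row <- row + 1; vecs[row, at(i1, 3)] <- 1; vecs[row, at(i2, 3)] <- 1
  }
  for (i in sym@midline) {
    row <- row + 1; vecs[row, at(i, 2)] <- 1
    row <- row + 1; vecs[row, at(i, 3)] <- 1
  }
  # similarity directions at the base shape (all symmetric): translations
  # along y and z, rotation about x, scaling
  ty <- rep(c(0, 1, 0), k); tz <- rep(c(0, 0, 1), k)
  sc <- as.vector(t(base))
  rx <- as.vector(t(cbind(0, -base[, 3], base[, 2])))
  G <- rbind(ty, tz, sc, rx)
  Gq <- qr.Q(qr(t(G)))
  vecs <- vecs - (vecs %*% Gq) %*% t(Gq)
  sv <- svd(vecs)
  keep <- sv$d > 1e-8 * sv$d[1]
  t(sv$v[, keep, drop = FALSE])
}

#' Construct an effect vector in the symmetric tangent subspace
#'
#' Draws a random direction in the subspace, or targets a set of
#' landmarks (e.g. one anatomical region) by projecting a displacement
#' confined to those landmarks into the subspace; the result is scaled to
#' the requested Procrustes magnitude.
#'
#' @param basis subspace basis from [symmetricTangentBasis()].
#' @param magnitude Procrustes magnitude of the effect.
#' @param landmarks optional integer vector of target landmark indices.
#' @param seed RNG seed.
#' @return list: `coef` (coordinates in the subspace basis), `tangent`
#'   (3k displacement vector).
#' @export
makeEffectVector <- function(basis, magnitude, landmarks = NULL, seed = 1) {
  set.seed(seed)
  q0 <- nrow(basis); k3 <- ncol(basis)
  if (is.null(landmarks)) {
    co <- rnorm(q0)
  } else {
    d <- numeric(k3)
    idx <- as.vector(vapply(landmarks, function(i) 3 * (i - 1) + 1:3, numeric(3)))
    d[idx] <- rnorm(length(idx))
    co <- as.vector(basis %*% d)
  }
  co <- co / sqrt(sum(co^2)) * magnitude
  list(coef = co, tangent = as.vector(co %*% basis))
}

#' Simulate landmark phenotypes with planted QTL
#'
#' The symmetric shape of individual i is the base shape plus planted QTL
#' effects (indicator of the heterozygote class at the nearest marker times
#' the effect vector), covariate effects (sex, direction of cross,
#' allometry on centered log centroid size) and correlated noise with a
#' low-rank-plus-diagonal covariance in the symmetric tangent subspace.
#' Raw configurations add isotropic asymmetric landmark noise and a random
#' rotation, translation and scale per specimen; centroid size carries sex
#' and direction contributions on the log scale.
#'
#' QTL effect magnitudes can be given directly (`magnitude`, Procrustes
#' units) or as a target fraction of the phenotypic trace (`pctTrace`,
#' converted with var(genotype) = 1/4).
#'
#' @param sim output of [simulateBackcross()].
#' @param base output of [makeSymmetricBaseConfig()].
#' @param qtl data.frame with columns `chr`, `pos` and `magnitude` or
#'   `pctTrace` (optional column `region` is a semicolon-joined landmark
#'   index list for targeted effects); NULL for a null phenotype.
#' @param covarMagnitudes Procrustes magnitudes of the sex, direction and
#'   allometry shape effects (defaults put each near the few-percent
#'   variance regime of a mouse skull cross).
#' @param nFactors,factorSD,diagSD residual covariance: nFactors unit
#'   directions with per-factor sd `factorSD` plus isotropic `diagSD`.
#' @param asymSD sd of the asymmetric (pre-alignment) landmark noise, mm.
#' @param csBase,csSexEffect,csDirEffect,csNoise log-centroid-size model.
#' @param seed RNG seed.
#' @return list: `coords` (k x 3 x n raw landmarks, mm), `covariates`
#'   (sex, cross_direction, logCS), `truth` (planted effects, hidden
#'   genotype column per QTL, noise trace, subspace basis).
#' @export
simulateShapes <- function(sim, base, qtl = NULL,
                           covarMagnitudes = c(sex = 0.005, direction = 0.005,
                                               allometry = 0.13),
                           nFactors = 10, factorSD = 0.004, diagSD = 0.0015,
                           asymSD = 0.002, csBase = log(25),
                           csSexEffect = 0.02, csDirEffect = 0.01,
                           csNoise = 0.02, seed = 1) {
  cross <- sim$cross
  n <- nrow(cross@geno)
  sym <- base$sym
  k <- sym@k
  basis <- symmetricTangentBasis(base$config, sym)
  q0 <- nrow(basis)
  noiseTrace <- nFactors * factorSD^2 + q0 * diagSD^2
  set.seed(seed)

  covars <- cross@covariates
  logCS <- csBase + csSexEffect * covars$sex + csDirEffect * covars$cross_direction +
    rnorm(n, 0, csNoise)
  xAll <- logCS - mean(logCS)

  mkdir <- function(s) { v <- rnorm(q0); v / sqrt(sum(v^2)) }
  bSex <- mkdir() * covarMagnitudes[["sex"]]
  bDir <- mkdir() * covarMagnitudes[["direction"]]
  bAll <- mkdir() * covarMagnitudes[["allometry"]]

  truthQtl <- NULL
  W <- covars$sex %o% bSex + covars$cross_direction %o% bDir + xAll %o% bAll
  if (!is.null(qtl) && nrow(qtl)) {
    m <- cross@map@markers
    truthQtl <- lapply(seq_len(nrow(qtl)), function(j) {
      mc <- which(m$chr == as.character(qtl$chr[j]))
      mi <- mc[which.min(abs(m$pos[mc] - qtl$pos[j]))]
      mag <- if (!is.null(qtl$magnitude) && !is.na(qtl$magnitude[j])) {
        qtl$magnitude[j]
      } else {
        f <- qtl$pctTrace[j] / 100
        sqrt(f / (1 - f) * noiseTrace / 0.25)
      }
      lmk <- NULL
      if (!is.null(qtl$region) && !is.na(qtl$region[j]) && nzchar(qtl$region[j])) {
        lmk <- as.integer(strsplit(as.character(qtl$region[j]), ";")[[1]])
      }
      ef <- makeEffectVector(basis, mag, landmarks = lmk,
                             seed = seed + 1000L + j)
      list(chr = m$chr[mi], pos = m$pos[mi], marker = m$marker[mi],
           magnitude = mag, coef = ef$coef, tangent = ef$tangent,
           genotype = sim$hidden[, mi])
    })
    for (tq in truthQtl) W <- W + tq$genotype %o% tq$coef
  }
  # correlated residuals: low-rank factors plus diagonal
  Ldir <- t(replicate(nFactors, mkdir()))
  W <- W + (matrix(rnorm(n * nFactors, 0, factorSD), n) %*% Ldir) +
    matrix(rnorm(n * q0, 0, diagSD), n)

  baseUnit <- .centerScale(base$config)
  coords <- array(NA_real_, c(k, 3, n),
                  dimnames = list(rownames(base$config), c("x", "y", "z"),
                                  rownames(cross@geno)))
  tang <- W %*% basis                       # n x 3k displacements
  for (i in seq_len(n)) {
    shp <- baseUnit + matrix(tang[i, ], k, 3, byrow = TRUE)
    shp <- shp + matrix(rnorm(3 * k, 0, asymSD), k, 3)
    # random rotation (det +1), scale to CS, random translation
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shp <- (shp / centroidSize(shp)) * exp(logCS[i])
    coords[, , i] <- sweep(shp %*% Q, 2, rnorm(3, 0, 5), `+`)
  }
  covarOut <- data.frame(sex = covars$sex, cross_direction = covars$cross_direction,
                         logCS = logCS, row.names = rownames(cross@geno))
  list(coords = coords, covariates = covarOut,
       truth = list(qtl = truthQtl, bSex = bSex, bDir = bDir, bAll = bAll,
                    noiseTrace = noiseTrace, basis = basis, logCS = logCS))
}
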
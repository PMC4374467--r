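#' @import methods
#' @importFrom stats pf phyper quantile rnorm runif rbinom sd var cor coef
#'   lm.fit qf optimize uniroot approx setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' GeneticMap: ordered markers on chromosomes
#'
#' Holds marker names, chromosome assignment and sex-averaged genetic
#' positions (cM), plus optional physical positions (bp).  Chromosomes keep
#' the order of first appearance; within a chromosome markers are strictly
#' increasing in cM.
#'
#' @slot markers data.frame with columns `marker`, `chr`, `pos` (cM) and
#'   `bp` (NA when no physical positions are attached).
#' @export
setClass("GeneticMap", representation(markers = "data.frame"))

setValidity("GeneticMap", function(object) {
  m <- object@markers
  need <- c("marker", "chr", "pos", "bp")
  if (!all(need %in% names(m))) {
    return(sprintf("markers must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(m$marker)) return("duplicate marker names")
  if (!all(is.finite(m$pos)) || any(m$pos < 0)) return("cM positions must be finite and non-negative")
  for (ch in unique(m$chr)) {
    p <- m$pos[m$chr == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      return(sprintf("cM positions on chromosome %s are not strictly increasing", ch))
    }
    b <- m$bp[m$chr == ch]
    if (any(is.na(b)) && !all(is.na(b))) {
      return(sprintf("bp positions on chromosome %s must be present for all or no markers", ch))
    }
    if (!any(is.na(b)) && is.unsorted(b, strictly = TRUE)) {
      return(sprintf("bp positions on chromosome %s are not strictly increasing", ch))
    }
  }
  TRUE
})

#' Backcross: genetic map, genotypes and covariates for an N2 panel
#'
#' Genotypes are coded 0 = homozygote (recurrent parent), 1 = heterozygote,
#' NA = missing.  Covariates carry at least `sex` and `cross_direction`
#' (both 0/1).
#'
#' @slot map a [GeneticMap-class].
#' @slot geno integer matrix, individuals x markers, values 0/1/NA.
#' @slot covariates data.frame aligned with rows of `geno`.
#' @export
setClass("Backcross", representation(
  map = "GeneticMap", geno = "matrix", covariates = "data.frame"
))

setValidity("Backcross", function(object) {
  g <- object@geno
  if (!identical(colnames(g), object@map@markers$marker)) {
    return("genotype columns must match the map's markers (same order)")
  }
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0L, 1L))) return("genotype codes must be 0, 1 or NA")
  if (nrow(object@covariates) != nrow(g)) return("covariate rows must match individuals")
  TRUE
})

#' GenotypeProbs: HMM posterior genotype probabilities on a cM grid
#'
#' The grid contains every marker plus pseudomarkers so that consecutive
#' positions are at most `step` cM apart.  Because the backcross has two
#' genotype classes, only P(HET) is stored; P(HOM) = 1 - P(HET).
#'
#' @slot grid data.frame with columns `chr`, `pos` (cM), `marker`
#'   (NA at pseudomarkers).
#' @slot pHet numeric matrix, individuals x grid positions.
#' @slot errorRate assumed genotyping error rate.
#' @slot step grid step in cM.
#' @export
setClass("GenotypeProbs", representation(
  grid = "data.frame", pHet = "matrix", errorRate = "numeric", step = "numeric"
))

setValidity("GenotypeProbs", function(object) {
  if (ncol(object@pHet) != nrow(object@grid)) return("pHet columns must match grid rows")
  if (any(object@pHet < -1e-12 | object@pHet > 1 + 1e-12)) return("probabilities outside [0, 1]")
  TRUE
})

#' SymmetryMap: bilateral landmark pairing
#'
#' @slot pairs integer matrix (p x 2) of (left, right) landmark indices.
#' @slot midline integer vector of midline landmark indices.
#' @slot k total number of landmarks.
#' @export
setClass("SymmetryMap", representation(
  pairs = "matrix", midline = "integer", k = "integer"
))

setValidity("SymmetryMap", function(object) {
  idx <- c(as.vector(object@pairs), object@midline)
  if (anyDuplicated(idx)) return("a landmark appears more than once across pairs and midline")
  if (!setequal(idx, seq_len(object@k))) return("pairs and midline must partition 1..k")
  TRUE
})

#' RegionMap: anatomical region membership per landmark
#'
#' A landmark on a boundary may belong to several regions; displacement
#' magnitude is then split equally among them.
#'
#' @slot regions list (length k) of character vectors of region names.
#' @export
setClass("RegionMap", representation(regions = "list"))

setValidity("RegionMap", function(object) {
  if (!all(vapply(object@regions, length, 1L) >= 1L)) {
    return("every landmark must belong to at least one region")
  }
  TRUE
})

#' ShapeSpace: consensus, tangent-space PC basis and specimen scores
#'
#' Result of generalized Procrustes analysis with object symmetry followed
#' by tangent projection and PCA of the symmetric component.  The basis is
#' restricted to principal components with non-zero eigenvalue; scores and
#' basis reproduce the centered tangent coordinates exactly.
#'
#' @slot consensus k x 3 consensus configuration (unit centroid size).
#' @slot basis q x 3k orthonormal PC basis (rows are PCs, coordinates
#'   vectorized landmark-major: x1,y1,z1,x2,...).
#' @slot eigenvalues PC variances, descending.
#' @slot scores n x q specimen PC scores.
#' @slot center 3k vector: mean of the projected tangent coordinates.
#' @slot centroidSize per-specimen centroid sizes of the raw configurations.
#' @slot asymmetric n x 3k asymmetric components (original - reflected)/2.
#' @slot landmarks landmark labels.
#' @slot symmetry the [SymmetryMap-class] used.
#' @export
setClass("ShapeSpace", representation(
  consensus = "matrix", basis = "matrix", eigenvalues = "numeric",
  scores = "matrix", center = "numeric", centroidSize = "numeric",
  asymmetric = "matrix", landmarks = "character", symmetry = "SymmetryMap"
))

setValidity("ShapeSpace", function(object) {
  q <- length(object@eigenvalues)
  if (nrow(object@basis) != q || ncol(object@scores) != q) {
    return("basis rows, score columns and eigenvalues must agree")
  }
  if (q > 1 && is.unsorted(rev(object@eigenvalues))) return("eigenvalues must be sorted descending")
  if (any(object@eigenvalues < 0)) return("eigenvalues must be non-negative")
  G <- tcrossprod(object@basis)
  if (max(abs(G - diag(q))) > 1e-8) return("basis rows must be orthonormal")
  TRUE
})

#' ScanResult: per-position genome scan scores
#'
#' @slot table data.frame: `chr`, `pos`, `score` (logP for shape, LOD for
#'   scalar traits) and, for shape scans, `V`, `F`, `df1`, `df2`.
#' @slot type "shape" or "scalar".
#' @export
setClass("ScanResult", representation(table = "data.frame", type = "character"))

#' PermutationResult: null distribution of genome-wide maxima
#'
#' @slot maxima genome-wide maximum score per permutation.
#' @slot alpha significance level.
#' @slot threshold empirical (1 - alpha) quantile of `maxima`.
#' @slot seed RNG seed used.
#' @export
setClass("PermutationResult", representation(
  maxima = "numeric", alpha = "numeric", threshold = "numeric", seed = "integer"
))

setValidity("PermutationResult", function(object) {
  thr <- unname(quantile(object@maxima, 1 - object@alpha, type = 7))
  if (abs(thr - object@threshold) > 1e-8) return("threshold must be the (1-alpha) quantile of maxima")
  TRUE
})

#' QTLModel: a fitted additive multiple-QTL model
#'
#' @slot loci data.frame: `chr`, `pos` (cM) per QTL, on the scan grid.
#' @slot effects coefficient matrix B (rows: intercept, covariates, loci;
#'   columns: response dimensions).
#' @slot termTests data.frame of drop-one conditional tests per term.
#' @slot logP joint logP of all QTL against the covariate-only model.
#' @slot penalized penalized score logP - T * n_qtl.
#' @slot threshold the genome-wide threshold T used in the penalty.
#' @export
setClass("QTLModel", representation(
  loci = "data.frame", effects = "matrix", termTests = "data.frame",
  logP = "numeric", penalized = "numeric", threshold = "numeric"
))

setValidity("QTLModel", function(object) {
  if (nrow(object@loci) && anyDuplicated(object@loci[c("chr", "pos")])) {
    return("duplicate (chr, pos) loci")
  }
  TRUE
})
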
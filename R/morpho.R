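#' Construct a SymmetryMap
#'
#' @param pairs p x 2 matrix (or list) of (left, right) landmark indices.
#' @param midline integer vector of midline landmark indices.
#' @return a [SymmetryMap-class].
#' @export
SymmetryMap <- function(pairs, midline) {
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2)
  midline <- as.integer(midline)
  new("SymmetryMap", pairs = pairs, midline = midline,
      k = as.integer(2L * nrow(pairs) + length(midline)))
}

#' Construct a RegionMap
#'
#' @param regions list (length = number of landmarks) of character vectors
#'   of region names; a boundary landmark may carry several regions.
#' @return a [RegionMap-class].
#' @export
RegionMap <- function(regions) {
  new("RegionMap", regions = lapply(regions, as.character))
}

#' Centroid size of a landmark configuration
#'
#' The square root of the sum of squared Euclidean distances from each
#' landmark to the landmark centroid.  Invariant to rotation and
#' translation; scales linearly under uniform scaling.
#'
#' @param config k x 3 coordinate matrix (or k x 3 x n array for a batch).
#' @return numeric size(s).
#' @export
centroidSize <- function(config) {
  if (is.matrix(config)) {
    if (any(!is.finite(config))) stop("non-finite coordinates")
    cen <- colMeans(config)
    return(sqrt(sum(sweep(config, 2, cen)^2)))
  }
  apply(config, 3, centroidSize)
}

#' Reflect and relabel a configuration across the bilateral plane
#'
#' Negates the x coordinate (the mirror plane is x = 0 by convention) and
#' swaps each (left, right) landmark pair; midline landmarks keep their
#' label.  Applying it twice returns the input exactly.
#'
#' @param config k x 3 coordinate matrix.
#' @param sym a [SymmetryMap-class].
#' @return the reflected, relabeled k x 3 matrix.
#' @export
reflectRelabel <- function(config, sym) {
  if (nrow(config) != sym@k) stop("configuration size does not match the symmetry map")
  out <- config
  out[, 1] <- -out[, 1]
  perm <- seq_len(sym@k)
  perm[sym@pairs[, 1]] <- sym@pairs[, 2]
  perm[sym@pairs[, 2]] <- sym@pairs[, 1]
  out <- out[perm, , drop = FALSE]
  rownames(out) <- rownames(config)
  out
}

# optimal rotation (no reflection) of X onto target M, both centered
.optRotate <- function(X, M) {
  s <- svd(crossprod(M, X))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  X %*% R
}

.centerScale <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  cs <- sqrt(sum(X^2))
  if (cs < 1e-12) stop("degenerate (all-coincident) configuration")
  X / cs
}

#' Generalized Procrustes analysis with object symmetry
#'
#' Doubles the sample with reflected-relabeled copies, performs iterative
#' full Procrustes superimposition (centering, unit-centroid-size scaling,
#' optimal rotations, consensus re-estimation) of the doubled sample, and
#' extracts per-specimen symmetric components (average of the aligned
#' original and its aligned reflected copy) and asymmetric components
#' (half their difference).  The consensus is symmetrized at every
#' iteration, so the bilateral plane of the common frame is x = 0.
#'
#' The symmetric components are then projected orthogonally onto the
#' tangent space at the consensus and decomposed by PCA; principal
#' components with eigenvalue above `tol` times the largest are retained.
#' For generic data with p bilateral pairs and l midline landmarks this
#' yields exactly 3p + 2l - 4 non-zero PCs.
#'
#' @param coords k x 3 x n array of raw landmark coordinates.
#' @param sym a [SymmetryMap-class].
#' @param tol relative eigenvalue tolerance for retaining PCs (default 1e-9).
#' @param maxIter maximum GPA iterations (default 200).
#' @return a [ShapeSpace-class].
#' @export
gpaObjectSymmetry <- function(coords, sym, tol = 1e-9, maxIter = 200) {
  if (tol <= 0) stop("tol must be > 0")
  n <- dim(coords)[3]
  if (is.null(n) || n < 2) stop("need at least 2 specimens")
  k <- dim(coords)[1]
  if (k != sym@k) stop("landmark count does not match the symmetry map")
  cs <- apply(coords, 3, centroidSize)

  # doubled sample: originals then reflected-relabeled copies
  X <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    X[[i]] <- .centerScale(coords[, , i])
    X[[n + i]] <- .centerScale(reflectRelabel(coords[, , i], sym))
  }
  symmetrize <- function(M) (M + reflectRelabel(M, sym)) / 2
  consensus <- .centerScale(symmetrize(X[[1]]))
  for (iter in seq_len(maxIter)) {
    X <- lapply(X, .optRotate, M = consensus)
    newC <- .centerScale(symmetrize(Reduce(`+`, X) / (2 * n)))
    newC <- .optRotate(newC, consensus)  # remove arbitrary spin about x
    delta <- sqrt(sum((newC - consensus)^2))
    consensus <- newC
    if (delta < 1e-10) break
  }
  X <- lapply(X, .optRotate, M = consensus)  # final pass against fixed consensus

  symc <- matrix(NA_real_, n, 3 * k)
  asym <- matrix(NA_real_, n, 3 * k)
  for (i in seq_len(n)) {
    s <- (X[[i]] + X[[n + i]]) / 2
    a <- (X[[i]] - X[[n + i]]) / 2
    symc[i, ] <- as.vector(t(s))  # landmark-major: x1,y1,z1,x2,...
    asym[i, ] <- as.vector(t(a))
  }

  # orthogonal projection onto the tangent space at the consensus
  mu <- as.vector(t(consensus))           # unit norm: centered, unit CS
  tang <- symc - (symc %*% mu) %*% t(mu)
  ctr <- colMeans(tang)
  tc <- sweep(tang, 2, ctr)
  sv <- svd(tc)
  ev <- sv$d^2 / (n - 1)
  q <- sum(ev > tol * ev[1])
  basis <- t(sv$v[, seq_len(q), drop = FALSE])
  sc <- tc %*% t(basis)
  dn <- dimnames(coords)
  lm <- if (!is.null(dn) && !is.null(dn[[1]])) dn[[1]] else paste0("L", seq_len(k))
  ids <- if (!is.null(dn) && !is.null(dn[[3]])) dn[[3]] else NULL
  rownames(sc) <- ids
  colnames(sc) <- paste0("PC", seq_len(q))
  new("ShapeSpace", consensus = consensus, basis = basis,
      eigenvalues = ev[seq_len(q)], scores = sc, center = ctr,
      centroidSize = cs, asymmetric = asym, landmarks = lm, symmetry = sym)
}

#' Back-transform PC-space vectors to landmark displacements
#'
#' Maps score-space vectors (e.g. QTL effect vectors) through the
#' orthonormal PC basis back to per-landmark 3D displacements in the
#' tangent space.
#'
#' @param shape a [ShapeSpace-class].
#' @param v numeric vector of length `nPCs(shape)` (or a matrix with that
#'   many columns, one vector per row).
#' @return k x 3 displacement matrix (or a list of them for matrix input).
#' @export
backTransform <- function(shape, v) {
  if (is.matrix(v)) return(lapply(seq_len(nrow(v)), function(i) backTransform(shape, v[i, ])))
  if (length(v) != nPCs(shape)) stop("vector length must equal the number of PCs")
  d <- as.vector(v %*% shape@basis)
  matrix(d, ncol = 3, byrow = TRUE,
         dimnames = list(shape@landmarks, c("x", "y", "z")))
}

#' Reconstruct symmetric tangent coordinates from scores
#'
#' @param shape a [ShapeSpace-class].
#' @return n x 3k matrix of tangent coordinates (center re-added).
#' @export
tangentCoordinates <- function(shape) {
  sweep(shape@scores %*% shape@basis, 2, shape@center, `+`)
}

#' Landmark repeatability screen from replicate digitizations
#'
#' Computes, per landmark, the distribution of Euclidean distances between
#' replicate placements and flags landmarks whose error quantile
#' (default: the median, reading "consistently exceeds" as a typical
#' error above the cut) exceeds `cutoff`.
#'
#' @param repA,repB k x 3 x n arrays of replicate digitizations of the
#'   same specimens, same landmark order.
#' @param cutoff error cutoff in the coordinate units (e.g. 0.125 mm).
#' @param quantileLevel which quantile of the per-specimen error must
#'   exceed `cutoff` to flag a landmark (default 0.5).
#' @return data.frame per landmark: `landmark`, `median`, `mean`, `max`,
#'   `flagged`.
#' @export
landmarkRepeatability <- function(repA, repB, cutoff = 0.125, quantileLevel = 0.5) {
  if (!all(dim(repA) == dim(repB))) stop("replicates must have identical dimensions")
  k <- dim(repA)[1]
  d <- sqrt(apply((repA - repB)^2, c(1, 3), sum))  # k x n distances
  med <- apply(d, 1, quantile, probs = quantileLevel, names = FALSE)
  lm <- dimnames(repA)[[1]]
  if (is.null(lm)) lm <- paste0("L", seq_len(k))
  data.frame(landmark = lm, median = med, mean = rowMeans(d),
             max = apply(d, 1, max), flagged = med > cutoff,
             stringsAsFactors = FALSE)
}

#' Rotation aligning a ShapeSpace consensus to a reference configuration
#'
#' The Procrustes frame of an analysis is arbitrary up to rotation; this
#' returns the 3 x 3 rotation matrix R such that `consensus %*% R` best
#' matches the (centered, unit-size) reference, e.g. a simulation's base
#' configuration, so effects can be compared with planted truth.
#'
#' @param shape a [ShapeSpace-class].
#' @param reference k x 3 reference configuration.
#' @return 3 x 3 rotation matrix.
#' @export
alignmentRotation <- function(shape, reference) {
  ref <- .centerScale(reference)
  s <- svd(crossprod(ref, shape@consensus))
  d <- sign(det(s$u %*% t(s$v)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}
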
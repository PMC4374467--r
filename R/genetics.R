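#' Construct a GeneticMap
#'
#' @param marker character vector of marker names.
#' @param chr chromosome of each marker.
#' @param pos sex-averaged position in cM.
#' @param bp optional physical position in bp.
#' @return a [GeneticMap-class].
#' @export
GeneticMap <- function(marker, chr, pos, bp = NULL) {
  df <- data.frame(marker = as.character(marker), chr = as.character(chr),
                   pos = as.numeric(pos),
                   bp = if (is.null(bp)) NA_real_ else as.numeric(bp),
                   stringsAsFactors = FALSE)
  ord <- order(match(df$chr, unique(df$chr)), df$pos)
  new("GeneticMap", markers = df[ord, , drop = FALSE])
}

#' Construct a Backcross object
#'
#' @param map a [GeneticMap-class].
#' @param geno individuals x markers matrix coded 0 (homozygote),
#'   1 (heterozygote), NA (missing); columns must match the map.
#' @param covariates data.frame with one row per individual (typically
#'   `sex` and `cross_direction`, both 0/1).
#' @return a [Backcross-class].
#' @export
Backcross <- function(map, geno, covariates) {
  storage.mode(geno) <- "integer"
  if (is.null(colnames(geno))) colnames(geno) <- map@markers$marker
  new("Backcross", map = map, geno = geno, covariates = covariates)
}

#' Build the scan grid of markers and pseudomarkers
#'
#' Each inter-marker interval is subdivided uniformly into the fewest
#' segments whose spacing does not exceed `step`, so the grid contains every
#' marker position exactly plus evenly spaced pseudomarkers.
#'
#' @param map a [GeneticMap-class].
#' @param step maximum spacing between grid positions (cM).
#' @return data.frame with columns `chr`, `pos`, `marker` (NA at
#'   pseudomarkers).
#' @export
buildPositionGrid <- function(map, step = 1) {
  if (step <= 0) stop("step must be > 0")
  m <- map@markers
  out <- lapply(unique(m$chr), function(ch) {
    mc <- m[m$chr == ch, , drop = FALSE]
    if (nrow(mc) == 0L) stop(sprintf("chromosome %s has no markers", ch))
    if (nrow(mc) == 1L) {
      return(data.frame(chr = ch, pos = mc$pos, marker = mc$marker,
                        stringsAsFactors = FALSE))
    }
    pos <- mc$pos[1]
    lab <- mc$marker[1]
    for (i in seq_len(nrow(mc) - 1L)) {
      a <- mc$pos[i]; b <- mc$pos[i + 1L]
      nseg <- max(1L, ceiling((b - a) / step - 1e-9))
      mid <- a + (b - a) * seq_len(nseg - 1L) / nseg
      pos <- c(pos, mid, b)
      lab <- c(lab, rep(NA_character_, length(mid)), mc$marker[i + 1L])
    }
    # de-duplicate (tolerance 1e-9), keeping marker labels over pseudomarkers
    keep <- c(TRUE, diff(pos) > 1e-9)
    data.frame(chr = ch, pos = pos[keep], marker = lab[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# emission probabilities for one observed genotype column
# states: 1 = HOM, 2 = HET; obs: 0, 1 or NA
.emission <- function(obs, eps) {
  e <- matrix(1, length(obs), 2)
  hom <- !is.na(obs) & obs == 0L
  het <- !is.na(obs) & obs == 1L
  e[hom, 1] <- 1 - eps; e[hom, 2] <- eps
  e[het, 1] <- eps;     e[het, 2] <- 1 - eps
  e
}

#' HMM genotype probabilities for an N2 backcross
#'
#' Runs the forward-backward algorithm on the two-state chain
#' {homozygote, heterozygote} along each chromosome, at every grid position
#' (markers plus pseudomarkers).  The initial distribution is (1/2, 1/2);
#' the transition probability between positions d cM apart is the
#' recombination fraction r = `mfCarterFalconer(d)` (off-diagonal).
#' Observed genotypes are emitted with error: P(observed = true) = 1 - eps;
#' missing genotypes are uninformative.
#'
#' @param cross a [Backcross-class].
#' @param step grid step in cM (default 1, i.e. "every centimorgan").
#' @param errorRate assumed genotyping error rate (default 1e-4).
#' @return a [GenotypeProbs-class].
#' @export
calcGenotypeProbs <- function(cross, step = 1, errorRate = 1e-4) {
  if (errorRate < 0 || errorRate >= 0.5) stop("errorRate must lie in [0, 0.5)")
  map <- cross@map
  grid <- buildPositionGrid(map, step)
  n <- nrow(cross@geno)
  pHet <- matrix(NA_real_, n, nrow(grid))
  for (ch in unique(grid$chr)) {
    gi <- which(grid$chr == ch)
    g <- grid[gi, , drop = FALSE]
    P <- nrow(g)
    # observed genotype per grid position (NA at pseudomarkers)
    obs <- matrix(NA_integer_, n, P)
    mk <- which(!is.na(g$marker))
    obs[, mk] <- cross@geno[, g$marker[mk], drop = FALSE]
    r <- if (P > 1) mfCarterFalconer(diff(g$pos)) else numeric(0)
    # forward
    alpha <- array(NA_real_, c(n, P, 2))
    e <- .emission(obs[, 1], errorRate)
    a1 <- 0.5 * e[, 1]; a2 <- 0.5 * e[, 2]
    s <- a1 + a2
    alpha[, 1, 1] <- a1 / s; alpha[, 1, 2] <- a2 / s
    if (P > 1) for (t in 2:P) {
      a1 <- alpha[, t - 1, 1]; a2 <- alpha[, t - 1, 2]
      p1 <- a1 * (1 - r[t - 1]) + a2 * r[t - 1]
      p2 <- a1 * r[t - 1] + a2 * (1 - r[t - 1])
      e <- .emission(obs[, t], errorRate)
      b1 <- p1 * e[, 1]; b2 <- p2 * e[, 2]
      s <- b1 + b2
      alpha[, t, 1] <- b1 / s; alpha[, t, 2] <- b2 / s
    }
    # backward
    beta <- array(1, c(n, P, 2))
    if (P > 1) for (t in (P - 1):1) {
      e <- .emission(obs[, t + 1], errorRate)
      c1 <- beta[, t + 1, 1] * e[, 1]; c2 <- beta[, t + 1, 2] * e[, 2]
      b1 <- c1 * (1 - r[t]) + c2 * r[t]
      b2 <- c1 * r[t] + c2 * (1 - r[t])
      s <- b1 + b2
      beta[, t, 1] <- b1 / s; beta[, t, 2] <- b2 / s
    }
    num1 <- matrix(alpha[, , 1], n, P) * matrix(beta[, , 1], n, P)
    num2 <- matrix(alpha[, , 2], n, P) * matrix(beta[, , 2], n, P)
    pHet[, gi] <- num2 / (num1 + num2)
  }
  rownames(pHet) <- rownames(cross@geno)
  new("GenotypeProbs", grid = grid, pHet = pHet,
      errorRate = errorRate, step = step)
}

#' Interpolate genetic (cM) to physical (bp) coordinates
#'
#' Piecewise-linear interpolation through per-chromosome anchor points.
#' Queries outside the anchor range are extrapolated linearly from the
#' terminal segment and flagged.
#'
#' @param anchors data.frame with columns `chr`, `cM`, `bp`; >= 2 anchors
#'   per queried chromosome, both scales strictly increasing.
#' @param chr chromosome of each query.
#' @param cM query positions in cM.
#' @return data.frame with columns `chr`, `cM`, `bp`, `extrapolated`.
#' @export
cmToBp <- function(anchors, chr, cM) {
  stopifnot(length(chr) == length(cM))
  out <- data.frame(chr = as.character(chr), cM = cM, bp = NA_real_,
                    extrapolated = FALSE, stringsAsFactors = FALSE)
  for (ch in unique(out$chr)) {
    a <- anchors[anchors$chr == ch, , drop = FALSE]
    if (nrow(a) < 2) stop(sprintf("need >= 2 anchors on chromosome %s", ch))
    a <- a[order(a$cM), , drop = FALSE]
    if (is.unsorted(a$cM, strictly = TRUE) || is.unsorted(a$bp, strictly = TRUE)) {
      stop(sprintf("anchors on chromosome %s are not strictly monotone", ch))
    }
    qi <- which(out$chr == ch)
    q <- out$cM[qi]
    # linear interpolation with terminal-segment extrapolation
    bp <- approx(a$cM, a$bp, xout = pmin(pmax(q, a$cM[1]), a$cM[nrow(a)]))$y
    lo <- q < a$cM[1]; hi <- q > a$cM[nrow(a)]
    if (any(lo)) {
      s <- (a$bp[2] - a$bp[1]) / (a$cM[2] - a$cM[1])
      bp[lo] <- a$bp[1] + s * (q[lo] - a$cM[1])
    }
    if (any(hi)) {
      m <- nrow(a)
      s <- (a$bp[m] - a$bp[m - 1]) / (a$cM[m] - a$cM[m - 1])
      bp[hi] <- a$bp[m] + s * (q[hi] - a$cM[m])
    }
    out$bp[qi] <- bp
    out$extrapolated[qi] <- lo | hi
  }
  out
}
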
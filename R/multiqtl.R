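# map a loci data.frame (chr, pos) to grid column indices
.lociIndices <- function(grid, loci) {
  if (is.null(loci) || NROW(loci) == 0) return(integer(0))
  vapply(seq_len(nrow(loci)), function(j) {
    i <- which(grid$chr == as.character(loci$chr[j]) &
                 abs(grid$pos - loci$pos[j]) < 1e-6)
    if (length(i) != 1L) stop(sprintf("locus (%s, %g cM) is not on the scan grid",
                                      loci$chr[j], loci$pos[j]))
    i
  }, integer(1))
}

.lociFrame <- function(grid, idx) {
  data.frame(chr = grid$chr[idx], pos = grid$pos[idx], stringsAsFactors = FALSE)
}

.phenoScores <- function(pheno) {
  if (is(pheno, "ShapeSpace")) scores(pheno) else as.matrix(pheno)
}

# joint Pillai logP of all loci (by grid index) against covariates only
.modelLogP <- function(pH, X0, Y, idx) {
  if (length(idx) == 0) {
    return(list(V = 0, F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                p = 1, logP = 0, h = 0, q = ncol(Y), dfe = nrow(Y) - ncol(X0)))
  }
  pillaiTest(Y, cbind(X0, pH[, idx, drop = FALSE]), X0)
}

# conditional logP profile for one added QTL given loci at `keepIdx`
.condProfile <- function(pH, X0, Y, keepIdx) {
  Xbase <- if (length(keepIdx)) cbind(X0, pH[, keepIdx, drop = FALSE]) else X0
  suppressWarnings(.hkScanShape(pH, Xbase, Y)$logP)
}

#' Joint logP of a multiple-QTL model
#'
#' Pillai-trace test of all QTL columns jointly (hypothesis df = number of
#' loci) against the covariate-only design.  The null model has logP 0.
#'
#' @param probs a [GenotypeProbs-class].
#' @param pheno n x q score matrix or [ShapeSpace-class].
#' @param covars covariate data.frame or NULL.
#' @param loci data.frame with columns `chr`, `pos` (cM, on the scan grid).
#' @return list as from [pillaiTest()] (`logP = 0` for the null model).
#' @export
modelLogP <- function(probs, pheno, covars = NULL, loci = NULL) {
  Y <- .phenoScores(pheno)
  X0 <- .covariateDesign(covars, nrow(Y))
  .modelLogP(probs@pHet, X0, Y, .lociIndices(probs@grid, loci))
}

# one refinement pass machinery shared by the search functions;
# moves are accepted only if the joint model logP increases.
.refineIdx <- function(pH, X0, Y, idx, grid, maxCycles = 20) {
  if (length(idx) == 0) return(list(idx = idx, logP = 0, trace = numeric(0)))
  cur <- .modelLogP(pH, X0, Y, idx)$logP
  traceLogP <- cur
  for (cycle in seq_len(maxCycles)) {
    changed <- FALSE
    for (j in seq_along(idx)) {
      prof <- .condProfile(pH, X0, Y, idx[-j])
      prof[idx[-j]] <- -Inf               # cannot collide with another QTL
      cand <- which.max(prof)
      if (cand != idx[j]) {
        newIdx <- idx; newIdx[j] <- cand
        newLogP <- .modelLogP(pH, X0, Y, newIdx)$logP
        if (newLogP > cur + 1e-9) {
          idx <- newIdx; cur <- newLogP; changed <- TRUE
          traceLogP <- c(traceLogP, cur)
        }
      }
    }
    if (!changed) break
  }
  list(idx = idx, logP = cur, trace = traceLogP)
}

#' Refine QTL positions by iterative conditional profiling
#'
#' Cyclically re-profiles each QTL over the entire grid holding all other
#' QTL and covariates fixed, moving it to the conditional-logP argmax when
#' that move increases the joint model logP; iterates until no position
#' changes (at most `maxCycles` cycles).  The joint model logP is monotone
#' non-decreasing across accepted moves.
#'
#' @inheritParams modelLogP
#' @param maxCycles maximum refinement cycles (default 20).
#' @return list: `loci` (refined data.frame), `logP`, `logPTrace`.
#' @export
refinePositions <- function(probs, pheno, covars = NULL, loci, maxCycles = 20) {
  Y <- .phenoScores(pheno)
  X0 <- .covariateDesign(covars, nrow(Y))
  r <- .refineIdx(probs@pHet, X0, Y, .lociIndices(probs@grid, loci), probs@grid, maxCycles)
  list(loci = .lociFrame(probs@grid, r$idx), logP = r$logP, logPTrace = r$trace)
}

#' Penalized forward/backward multiple-QTL search
#'
#' Forward: starting from the null model, scan the whole grid for one
#' additional additive QTL conditional on the current model and covariates,
#' add the argmax candidate, refine all positions, and repeat up to
#' `maxQTL` QTL (capped if the error df would drop below q + 2).  Backward:
#' from the forward endpoint, repeatedly drop the QTL whose removal leaves
#' the largest joint logP, refining after each drop, down to the null
#' model.  Every visited model is scored by the penalized criterion
#' logP - T * n_qtl and the best-scoring model is returned.
#'
#' @inheritParams modelLogP
#' @param threshold genome-wide shape threshold T from
#'   [genomeWideThreshold()] (the per-QTL penalty).
#' @param maxQTL largest model size visited by the forward search.
#' @param refine logical: refine positions after each step (default TRUE).
#' @return list: `model` (a [QTLModel-class] for the best model), `trace`
#'   (data.frame of every visited model: step, nQTL, logP, penalized, loci
#'   as a semicolon-joined string).
#' @export
forwardBackwardSearch <- function(probs, pheno, covars = NULL, threshold,
                                  maxQTL = 50, refine = TRUE) {
  Y <- .phenoScores(pheno)
  n <- nrow(Y); q <- ncol(Y)
  X0 <- .covariateDesign(covars, n)
  pH <- probs@pHet
  grid <- probs@grid
  cap <- n - ncol(X0) - (q + 2L)   # largest n_qtl keeping dfe >= q + 2
  if (maxQTL > cap) {
    warning(sprintf("maxQTL capped at %d to keep error df >= q + 2", cap))
    maxQTL <- cap
  }
  visited <- list(list(idx = integer(0), logP = 0))
  idx <- integer(0)
  # forward
  while (length(idx) < maxQTL) {
    prof <- .condProfile(pH, X0, Y, idx)
    prof[idx] <- -Inf
    cand <- which.max(prof)
    idx <- c(idx, cand)
    if (refine) {
      r <- .refineIdx(pH, X0, Y, idx, grid)
      idx <- r$idx; lp <- r$logP
    } else lp <- .modelLogP(pH, X0, Y, idx)$logP
    visited[[length(visited) + 1L]] <- list(idx = idx, logP = lp)
  }
  # backward
  while (length(idx) > 0) {
    if (length(idx) == 1L) {
      idx <- integer(0); lp <- 0
    } else {
      drops <- vapply(seq_along(idx), function(j)
        .modelLogP(pH, X0, Y, idx[-j])$logP, numeric(1))
      idx <- idx[-which.max(drops)]
      if (refine) {
        r <- .refineIdx(pH, X0, Y, idx, grid)
        idx <- r$idx; lp <- r$logP
      } else lp <- .modelLogP(pH, X0, Y, idx)$logP
    }
    visited[[length(visited) + 1L]] <- list(idx = idx, logP = lp)
  }
  tr <- data.frame(
    step = seq_along(visited) - 1L,
    nQTL = vapply(visited, function(v) length(v$idx), integer(1)),
    logP = vapply(visited, function(v) v$logP, numeric(1)),
    stringsAsFactors = FALSE)
  tr$penalized <- tr$logP - threshold * tr$nQTL
  tr$loci <- vapply(visited, function(v)
    paste(sprintf("%s@%.6g", grid$chr[v$idx], grid$pos[v$idx]), collapse = ";"),
    character(1))
  best <- visited[[which.max(tr$penalized)]]
  model <- fitQTLModel(probs, pheno, covars, .lociFrame(grid, best$idx),
                       threshold = threshold)
  list(model = model, trace = tr)
}

#' Stepwise search by conditional genome-wide significance
#'
#' Forward addition while the best candidate's conditional logP reaches the
#' genome-wide threshold; after each addition any QTL whose drop-one
#' conditional logP falls below the threshold is eliminated; positions are
#' refined after each change.
#'
#' @inheritParams forwardBackwardSearch
#' @return list: `model` (a [QTLModel-class]), `loci` data.frame.
#' @export
stepwiseSignificanceSearch <- function(probs, pheno, covars = NULL, threshold,
                                       maxQTL = 50) {
  Y <- .phenoScores(pheno)
  X0 <- .covariateDesign(covars, nrow(Y))
  pH <- probs@pHet
  grid <- probs@grid
  q <- ncol(Y)
  cap <- nrow(Y) - ncol(X0) - (q + 2L)
  maxQTL <- min(maxQTL, cap)
  idx <- integer(0)
  repeat {
    if (length(idx) >= maxQTL) break
    prof <- .condProfile(pH, X0, Y, idx)
    prof[idx] <- -Inf
    cand <- which.max(prof)
    if (prof[cand] < threshold) break
    idx <- c(idx, cand)
    idx <- .refineIdx(pH, X0, Y, idx, grid)$idx
    # backward pruning on conditional significance
    repeat {
      if (length(idx) == 0) break
      cond <- vapply(seq_along(idx), function(j) {
        pillaiTest(Y, cbind(X0, pH[, idx, drop = FALSE]),
                   cbind(X0, pH[, idx[-j], drop = FALSE]))$logP
      }, numeric(1))
      if (all(cond >= threshold)) break
      idx <- idx[-which.min(cond)]
      if (length(idx)) idx <- .refineIdx(pH, X0, Y, idx, grid)$idx
    }
  }
  model <- fitQTLModel(probs, pheno, covars, .lociFrame(grid, idx),
                       threshold = threshold)
  list(model = model, loci = .lociFrame(grid, idx))
}

#' Fit a fixed multiple-QTL model by multivariate Haley-Knott regression
#'
#' Least squares of the response scores on intercept, covariates and
#' P(HET) per locus; per-dimension coefficients are stacked into
#' q-dimensional effect vectors and each term gets a drop-one conditional
#' Pillai test.
#'
#' @inheritParams modelLogP
#' @param threshold genome-wide threshold used in the penalized score
#'   (default 0: the penalized slot then equals the joint logP).
#' @return a [QTLModel-class].
#' @export
fitQTLModel <- function(probs, pheno, covars = NULL, loci = NULL, threshold = 0) {
  Y <- .phenoScores(pheno)
  X0 <- .covariateDesign(covars, nrow(Y))
  idx <- .lociIndices(probs@grid, loci)
  lociNames <- if (length(idx)) sprintf("QTL_%s@%.6g", probs@grid$chr[idx],
                                        probs@grid$pos[idx]) else character(0)
  X <- if (length(idx)) cbind(X0, structure(probs@pHet[, idx, drop = FALSE],
                                            dimnames = list(NULL, lociNames))) else X0
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qrx$pivot[seq_len(qrx$rank)])
    stop(sprintf("collinear model term(s): %s", paste(colnames(X)[bad], collapse = ", ")))
  }
  B <- qr.coef(qrx, Y)
  rownames(B) <- colnames(X)
  terms <- colnames(X)[-1]             # all but the intercept
  tests <- lapply(terms, function(tm) {
    keep <- setdiff(colnames(X), tm)
    pt <- pillaiTest(Y, X, X[, keep, drop = FALSE])
    data.frame(term = tm, V = pt$V, F = pt$F, df1 = pt$df1, df2 = pt$df2,
               p = pt$p, logP = pt$logP, stringsAsFactors = FALSE)
  })
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(term = character(0), V = numeric(0), F = numeric(0),
               df1 = numeric(0), df2 = numeric(0), p = numeric(0),
               logP = numeric(0))
  jp <- .modelLogP(probs@pHet, X0, Y, idx)$logP
  new("QTLModel", loci = .lociFrame(probs@grid, idx), effects = B,
      termTests = tests, logP = jp,
      penalized = jp - threshold * length(idx), threshold = threshold)
}

#' Bayes credible interval from a logP profile
#'
#' Weights w ~ 10^logP are normalized to unit mass over one chromosome's
#' grid; positions sorted by descending weight are accumulated until the
#' requested coverage is reached and the interval is the position range of
#' the accumulated set.
#'
#' @param pos grid positions (cM) on one chromosome.
#' @param logP conditional logP profile at those positions.
#' @param coverage coverage level in (0, 1), default 0.95.
#' @return list: `lower`, `upper`, `peak`, `coverage`.
#' @export
bayesCredibleInterval <- function(pos, logP, coverage = 0.95) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must lie in (0, 1)")
  stopifnot(length(pos) == length(logP))
  if (all(logP <= 0)) {
    warning("flat (all-zero) profile; returning the whole chromosome")
    return(list(lower = min(pos), upper = max(pos),
                peak = pos[which.max(logP)], coverage = coverage))
  }
  w <- 10^(logP - max(logP))
  w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)
  m <- which(cumsum(w[ord]) >= coverage - 1e-12)[1]
  sel <- pos[ord[seq_len(m)]]
  list(lower = min(sel), upper = max(sel),
       peak = pos[which.max(logP)], coverage = coverage)
}

#' Per-QTL conditional profiles and credible intervals
#'
#' For each QTL in a model, profiles its own chromosome conditional on all
#' other (refined) QTL and covariates, and converts the profile into a
#' Bayes credible interval; optionally converts the endpoints to bp via
#' anchor interpolation.
#'
#' @inheritParams modelLogP
#' @param coverage coverage level (default 0.95).
#' @param anchors optional anchor table for [cmToBp()].
#' @return data.frame per QTL: `chr`, `pos`, `lower`, `upper`, `coverage`,
#'   and `lower_bp`/`upper_bp` when anchors are given.
#' @export
qtlIntervals <- function(probs, pheno, covars = NULL, loci, coverage = 0.95,
                         anchors = NULL) {
  Y <- .phenoScores(pheno)
  X0 <- .covariateDesign(covars, nrow(Y))
  idx <- .lociIndices(probs@grid, loci)
  grid <- probs@grid
  out <- lapply(seq_along(idx), function(j) {
    prof <- .condProfile(probs@pHet, X0, Y, idx[-j])
    onChr <- which(grid$chr == grid$chr[idx[j]])
    ci <- bayesCredibleInterval(grid$pos[onChr], prof[onChr], coverage)
    data.frame(chr = grid$chr[idx[j]], pos = grid$pos[idx[j]],
               lower = ci$lower, upper = ci$upper, coverage = coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(anchors) && NROW(out)) {
    out$lower_bp <- cmToBp(anchors, out$chr, out$lower)$bp
    out$upper_bp <- cmToBp(anchors, out$chr, out$upper)$bp
  }
  out
}
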
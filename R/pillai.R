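#' Pillai-trace test of nested multivariate linear models
#'
#' Fits the reduced and full models by least squares, forms the hypothesis
#' and error cross-product matrices H = E_reduced - E_full and E = E_full,
#' and evaluates Pillai's trace V = tr[H (H + E)^-1].  With s = min(q, h),
#' m = (|q - h| - 1)/2 and n' = (df_e - q - 1)/2, the approximate F
#' statistic is F = ((2n' + s + 1)/(2m + s + 1)) * (V/s)/(1 - V/s) with
#' df1 = s(2m + s + 1) and df2 = s(2n' + s + 1); for single-degree
#' hypotheses (s = 1) the approximation is exact.  The p-value is computed
#' on the log scale so that logP = -log10(p) does not saturate.
#'
#' @param Y n x q response matrix.
#' @param Xfull full design matrix (must have full column rank).
#' @param Xreduced nested reduced design matrix.
#' @return list with `V`, `F`, `df1`, `df2`, `p`, `logP`, `h`, `q`, `dfe`.
#' @export
pillaiTest <- function(Y, Xfull, Xreduced) {
  Y <- as.matrix(Y)
  n <- nrow(Y); q <- ncol(Y)
  qrf <- qr(Xfull)
  if (qrf$rank < ncol(Xfull)) {
    piv <- qrf$pivot[seq_len(qrf$rank)]
    bad <- setdiff(seq_len(ncol(Xfull)), piv)
    nm <- colnames(Xfull)
    lab <- if (is.null(nm)) paste(bad, collapse = ", ") else paste(nm[bad], collapse = ", ")
    stop(sprintf("full design is rank deficient; collinear column(s): %s", lab))
  }
  qrr <- qr(Xreduced)
  h <- qrf$rank - qrr$rank
  if (h < 1) stop("full model must add at least one degree of freedom")
  dfe <- n - qrf$rank
  if (dfe < q) stop(sprintf(
    "error df (%d) < response dimension (%d); truncate the response PCs first", dfe, q))
  Rf <- qr.resid(qrf, Y)
  Rr <- qr.resid(qrr, Y)
  E <- crossprod(Rf)
  H <- crossprod(Rr) - E
  V <- tryCatch(sum(diag(solve(H + E, H))), error = function(e) {
    # degenerate error matrix (e.g. noiseless interpolation): pseudo-inverse
    eg <- eigen(H + E, symmetric = TRUE)
    pos <- eg$values > max(abs(eg$values)) * 1e-12
    U <- eg$vectors[, pos, drop = FALSE]
    sum(diag(U %*% (crossprod(U, H) / eg$values[pos])))
  })
  s <- min(q, h)
  m <- (abs(q - h) - 1) / 2
  np <- (dfe - q - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * np + s + 1)
  V <- min(max(V, 0), s)
  Fstat <- (df2 / df1) * (V / (s - V))
  logp <- pf(Fstat, df1, df2, lower.tail = FALSE, log.p = TRUE)
  list(V = V, F = Fstat, df1 = df1, df2 = df2,
       p = exp(logp), logP = -logp / log(10), h = h, q = q, dfe = dfe)
}
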
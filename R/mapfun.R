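#' Carter-Falconer map function pair
#'
#' The Carter-Falconer map function models the strong crossover
#' interference observed in the mouse.  `imfCarterFalconer` converts a
#' recombination fraction r into a genetic distance,
#' d = 12.5 log((1+2r)/(1-2r)) + 25 arctan(2r) cM.  There is no closed
#' forward form; `mfCarterFalconer` inverts it numerically (Brent root
#' search, absolute tolerance 1e-10 on r).
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @param d genetic distance(s) in cM, >= 0.
#' @return `imfCarterFalconer`: distance in cM; `mfCarterFalconer`:
#'   recombination fraction in [0, 0.5).
#' @examples
#' imfCarterFalconer(0.1)        # 10.0032 cM
#' mfCarterFalconer(10.0032)     # ~0.1
#' @export
imfCarterFalconer <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  12.5 * log((1 + 2 * r) / (1 - 2 * r)) + 25 * atan(2 * r)
}

#' @rdname imfCarterFalconer
#' @export
mfCarterFalconer <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("genetic distance must be finite and >= 0")
  vapply(d, function(di) {
    if (di == 0) return(0)
    # imf is strictly increasing; bracket r in [0, 0.5)
    hi <- 0.5 - 1e-14
    if (imfCarterFalconer(hi) <= di) return(hi)
    uniroot(function(r) imfCarterFalconer(r) - di,
            lower = 0, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}
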
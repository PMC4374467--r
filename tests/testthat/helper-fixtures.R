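# shared fixtures, built once per test run
.fx <- new.env()

fxMap5 <- function() {
  if (is.null(.fx$map5)) .fx$map5 <- simMap(nChrom = 5, nMarkers = 50, lengths = rep(45, 5))
  .fx$map5
}

fxSim <- function() {
  if (is.null(.fx$sim)) .fx$sim <- simulateBackcross(fxMap5(), n = 150, seed = 11)
  .fx$sim
}

fxProbs <- function() {
  if (is.null(.fx$probs)) .fx$probs <- calcGenotypeProbs(fxSim()$cross)
  .fx$probs
}

fxTinyBase <- function() {
  if (is.null(.fx$tiny)) .fx$tiny <- makeSymmetricBaseConfig(p = 3, l = 2, seed = 7)
  .fx$tiny
}

# exhaustive-path forward-backward oracle for one individual on one
# chromosome: enumerates all 2^P hidden paths over the grid positions
bruteForceHMM <- function(obs, pos, eps) {
  P <- length(pos)
  r <- mfCarterFalconer(diff(pos))
  paths <- as.matrix(expand.grid(rep(list(0:1), P)))
  w <- apply(paths, 1, function(g) {
    pr <- 0.5
    if (P > 1) for (t in 2:P) {
      pr <- pr * if (g[t] == g[t - 1]) 1 - r[t - 1] else r[t - 1]
    }
    for (t in seq_len(P)) {
      if (!is.na(obs[t])) pr <- pr * if (obs[t] == g[t]) 1 - eps else eps
    }
    pr
  })
  vapply(seq_len(P), function(t) sum(w[paths[, t] == 1]) / sum(w), numeric(1))
}

# random rigid motion + scale applied to a configuration
randomMotion <- function(X, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(X %*% Q * runif(1, 0.5, 2), 2, rnorm(3, 0, 10), `+`)
}

# exhaustive hypergeometric upper tail by enumerating all draws of n from N
bruteHyperUpper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K are the "training" items
  mean(hits >= k)
}
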
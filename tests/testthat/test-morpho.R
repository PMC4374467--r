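test_that("centroid size matches its definition and invariances", {
  X <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  expect_equal(centroidSize(X), sqrt(6))
  expect_equal(centroidSize(sweep(X, 2, c(10, -3, 7), `+`)), sqrt(6))
  expect_equal(centroidSize(X * 2.5), 2.5 * sqrt(6))
  expect_error(centroidSize(rbind(c(NA, 0, 0))), "finite")
  # invariant under rigid motions applied per specimen
  base <- fxTinyBase()
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  expect_equal(centroidSize(sweep(base$config %*% Q, 2, c(4, 5, 6), `+`)),
               centroidSize(base$config), tolerance = 1e-12)
})

test_that("reflect-relabel is an involution fixing symmetric configurations", {
  base <- fxTinyBase()
  expect_equal(reflectRelabel(base$config, base$sym), base$config)
  set.seed(1)
  arb <- base$config + matrix(rnorm(length(base$config)), nrow(base$config))
  expect_identical(reflectRelabel(reflectRelabel(arb, base$sym), base$sym), arb)
  sym1 <- SymmetryMap(cbind(1, 2), integer(0))
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(reflectRelabel(pts, sym1), pts)
  expect_error(reflectRelabel(pts[1, , drop = FALSE], sym1), "match")
})

test_that("GPA aligns rigid motions of one shape to zero Procrustes variance", {
  base <- fxTinyBase()
  k <- nrow(base$config)
  coords <- array(NA_real_, c(k, 3, 4))
  for (i in 1:4) coords[, , i] <- randomMotion(base$config, seed = i)
  ss <- gpaObjectSymmetry(coords, base$sym)
  expect_lt(sum(ss@eigenvalues) * 3, 1e-12)
  # symmetric input: asymmetric residuals vanish
  expect_lt(max(abs(ss@asymmetric)), 1e-10)
})

test_that("GPA recovers shapes known up to rotation, translation and scale", {
  base <- fxTinyBase()
  k <- nrow(base$config)
  set.seed(9)
  n <- 12
  basis <- symmetricTangentBasis(base$config, base$sym)
  baseUnit <- morphoqtl:::.centerScale(base$config)
  devs <- matrix(rnorm(n * nrow(basis), 0, 0.01), n) %*% basis   # n x 3k
  coords <- array(NA_real_, c(k, 3, n))
  for (i in seq_len(n)) {
    shp <- baseUnit + matrix(devs[i, ], k, 3, byrow = TRUE)
    coords[, , i] <- randomMotion(shp, seed = 100 + i)
  }
  ss <- gpaObjectSymmetry(coords, base$sym)
  R <- alignmentRotation(ss, base$config)
  tc <- scale(tangentCoordinates(ss), scale = FALSE)
  devC <- scale(devs, scale = FALSE)
  for (i in seq_len(n)) {
    rec <- matrix(tc[i, ], k, 3, byrow = TRUE) %*% R
    truth <- matrix(devC[i, ], k, 3, byrow = TRUE)
    # recovered deviations match the planted ones up to tangent curvature
    expect_lt(max(abs(rec - truth)), 5e-4)
  }
})

test_that("consensus is symmetric and basis/scores are consistent", {
  base <- fxTinyBase()
  set.seed(21)
  k <- nrow(base$config)
  n <- 20
  coords <- array(NA_real_, c(k, 3, n))
  for (i in seq_len(n)) {
    coords[, , i] <- randomMotion(base$config + matrix(rnorm(3 * k, 0, 0.1), k), seed = 300 + i)
  }
  ss <- gpaObjectSymmetry(coords, base$sym)
  expect_lt(max(abs(ss@consensus - reflectRelabel(ss@consensus, base$sym))), 1e-8)
  B <- ss@basis
  expect_lt(max(abs(tcrossprod(B) - diag(nrow(B)))), 1e-10)
  expect_true(all(diff(ss@eigenvalues) <= 1e-15))
})

test_that("retained PC count obeys the 3p + 2l - 4 dimension law", {
  base <- fxTinyBase()   # p = 3, l = 2 -> 9
  set.seed(31)
  k <- nrow(base$config)
  n <- 30
  coords <- array(NA_real_, c(k, 3, n))
  for (i in seq_len(n)) {
    coords[, , i] <- randomMotion(base$config + matrix(rnorm(3 * k, 0, 0.05), k), seed = 400 + i)
  }
  ss <- gpaObjectSymmetry(coords, base$sym)
  expect_identical(nPCs(ss), 3L * 3L + 2L * 2L - 4L)
  # numerical-rank oracle on the centered symmetric tangent coordinates
  tc <- scale(tangentCoordinates(ss), scale = FALSE)
  sv <- svd(tc)$d
  expect_identical(sum(sv > 1e-6 * sv[1]), 9L)
  # rank bound: n = 3 specimens give at most 2 PCs
  ss3 <- gpaObjectSymmetry(coords[, , 1:3], base$sym)
  expect_lte(nPCs(ss3), 2L)
})

test_that("symmetric and asymmetric components are exactly orthogonal", {
  base <- fxTinyBase()
  set.seed(41)
  k <- nrow(base$config)
  n <- 15
  coords <- array(NA_real_, c(k, 3, n))
  for (i in seq_len(n)) {
    coords[, , i] <- randomMotion(base$config + matrix(rnorm(3 * k, 0, 0.08), k), seed = 500 + i)
  }
  ss <- gpaObjectSymmetry(coords, base$sym)
  tc <- tangentCoordinates(ss)
  # symmetric vectors live in the reflection-invariant subspace and
  # asymmetric ones in its orthogonal complement: all inner products vanish
  cross <- tcrossprod(tc, ss@asymmetric)
  expect_lt(sqrt(sum(cross^2)), 1e-9)
})

test_that("a planted asymmetric perturbation lands in the asymmetric component", {
  base <- makeSymmetricBaseConfig()       # 22 pairs + 9 midline
  k <- nrow(base$config)
  n <- 10
  coords <- array(rep(base$config, n), c(k, 3, n))
  delta <- c(0, 0.2, 0.1)
  coords[1, , ] <- coords[1, , ] + delta   # landmark 1 is the left of a pair
  ss <- gpaObjectSymmetry(coords, base$sym)
  A <- matrix(ss@asymmetric[1, ], k, 3, byrow = TRUE)
  mags <- sqrt(rowSums(A^2))
  # the perturbed pair carries nearly all asymmetric signal (superimposition
  # diffuses a small share across the other landmarks)
  pair1 <- c(1, base$sym@pairs[1, 2])
  expect_gt(sum(mags[pair1]^2), 0.9 * sum(mags^2))
  expect_equal(sort(order(mags, decreasing = TRUE)[1:2]), sort(pair1))
  # and the recovered direction at the perturbed landmark matches delta/2
  expect_gt(abs(cor(A[1, ], delta / 2)), 0.99)
})

test_that("landmark repeatability flags offsets exceeding the cutoff", {
  base <- fxTinyBase()
  k <- nrow(base$config)
  n <- 8
  A <- array(rep(base$config, n), c(k, 3, n))
  expect_true(all(landmarkRepeatability(A, A)$median == 0))
  expect_false(any(landmarkRepeatability(A, A)$flagged))
  B <- A; B[3, 1, ] <- B[3, 1, ] + 0.2
  tab <- landmarkRepeatability(A, B, cutoff = 0.125)
  expect_identical(which(tab$flagged), 3L)
  C <- A + 0.05 / sqrt(3)
  expect_false(any(landmarkRepeatability(A, C, cutoff = 0.125)$flagged))
  expect_error(landmarkRepeatability(A, A[, , 1:3]), "identical")
})
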
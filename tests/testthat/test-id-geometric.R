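test_that("correlation-integral estimate equals a brute-force pair-count oracle", {
  X <- ballPoints(3, 100, seed = 2)
  est <- corrInt(X, k1 = 5, k2 = 15)
  ## oracle: full pairwise enumeration, same two scales
  nt <- buildNeighborTable(X, 15)
  r1 <- mean(neighborDistances(nt)[, 5])
  r2 <- mean(neighborDistances(nt)[, 15])
  dm <- as.matrix(dist(X))
  pairs <- dm[upper.tri(dm)]
  m <- nrow(X)
  c1 <- 2 * sum(pairs <= r1) / (m * (m - 1))
  c2 <- 2 * sum(pairs <= r2) / (m * (m - 1))
  expect_equal(idValue(est), (log(c2) - log(c1)) / (log(r2) - log(r1)),
               tolerance = 1e-12)
  expect_equal(est@params$r1, r1, tolerance = 1e-12)
})

test_that("correlation dimension of a segment is near 1 and scale invariant", {
  seg <- samplePoints(generateManifold("hypercube", 1000, list(d = 1),
                                       seed = 0))
  est <- corrInt(seg)
  expect_gte(idValue(est), 0.8)
  expect_lte(idValue(est), 1.2)
  expect_equal(idValue(corrInt(seg * 3.7)), idValue(est),
               tolerance = 1e-12)
})

test_that("MLE reproduces its single-point closed form for both aggregations", {
  nt <- syntheticNT(matrix(c(0.25, 0.5, 0.75, 1.0), 1))
  want <- 3 / (log(4) + log(2) + log(4 / 3))
  expect_equal(idValue(mleID(nt, k = 4, "mean_of_locals")), want,
               tolerance = 1e-12)
  expect_equal(idValue(mleID(nt, k = 4, "global_mackay")), want,
               tolerance = 1e-12)
})

test_that("global MLE equals the one-pass log-ratio oracle", {
  X <- ballPoints(3, 200, seed = 6)
  k <- 12
  est <- mleID(X, k = k)
  nt <- buildNeighborTable(X, k)
  D <- neighborDistances(nt)
  allTerms <- as.vector(log(D[, k] / D[, 1:(k - 1)]))
  expect_equal(idValue(est), 1 / mean(allTerms), tolerance = 1e-12)
})

test_that("tied neighbor distances make MLE degenerate", {
  nt <- syntheticNT(matrix(0.5, 3, 4))
  expect_equal(idStatus(mleID(nt, k = 4)), "degenerate_input")
  ## duplicate points (zero distances) likewise
  X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20), 10)[1:3, ] * 0)
  X <- rbind(X, X[1, ], X[2, ])
  expect_equal(idStatus(mleID(X, k = 3)), "degenerate_input")
})

test_that("TwoNN solves exact ratio constructions", {
  ## all mu = e -> d = 1; all mu = sqrt(e) -> d = 2 under the MLE fit
  nt1 <- syntheticNT(cbind(rep(1, 50), rep(exp(1), 50)))
  expect_equal(idValue(twoNN(nt1, discardFraction = 0, fit = "mle")), 1,
               tolerance = 1e-12)
  nt2 <- syntheticNT(cbind(rep(1, 50), rep(exp(0.5), 50)))
  expect_equal(idValue(twoNN(nt2, discardFraction = 0, fit = "mle")), 2,
               tolerance = 1e-12)
})

test_that("TwoNN linear fit recovers the shape of exact Pareto quantiles", {
  M <- 1000
  mu <- (1 - (1:M) / (M + 1))^(-1 / 3)  # Pareto(shape 3) quantiles
  nt <- syntheticNT(cbind(rep(1, M), mu))
  d <- idValue(twoNN(nt, discardFraction = 0.1, fit = "linear"))
  expect_equal(d, 3, tolerance = 0.05 * 3)
})

test_that("TwoNN flags degenerate ratio configurations", {
  expect_equal(idStatus(twoNN(syntheticNT(cbind(rep(0, 9), rep(1, 9))))),
               "degenerate_input")
  expect_equal(idStatus(twoNN(syntheticNT(cbind(rep(1, 9), rep(1, 9))))),
               "degenerate_input")
})

test_that("MADA matches its doubling closed form and accounts invalid points", {
  expect_equal(idValue(mada(syntheticNT(cbind(0.25, 0.5)), k = 2)), 1,
               tolerance = 1e-12)
  expect_equal(idValue(mada(syntheticNT(cbind(0.5 / sqrt(2), 0.5)),
                            k = 2)), 2, tolerance = 1e-12)
  ## one tied point among valid ones: estimate ok, fraction reported
  D <- rbind(c(0.25, 0.5), c(0.25, 0.5), c(0.5, 0.5))
  est <- mada(syntheticNT(D), k = 2)
  expect_equal(idStatus(est), "ok")
  expect_equal(est@params$invalidFraction, 1 / 3)
})

test_that("MOM matches direct arithmetic and flags all-equal distances", {
  est <- momID(syntheticNT(matrix(c(0.25, 0.5, 0.75, 1.0), 1)), k = 4)
  expect_equal(idValue(est), 0.625 / 0.375, tolerance = 1e-12)

  ## linear distance growth r_j = w * j / k -> d = (k+1)/(k-1)
  k <- 8; w <- 2
  D <- matrix(w * (1:k) / k, 1)
  m1 <- mean(D)
  expect_equal(idValue(momID(syntheticNT(D), k = k)), m1 / (w - m1),
               tolerance = 1e-12)

  est2 <- momID(syntheticNT(matrix(0.3, 1, 4)), k = 4)
  expect_equal(idStatus(est2), "degenerate_input")
})

test_that("TLE recovers a uniform 2-disk and is scale invariant", {
  X <- ballPoints(2, 2000, seed = 0)
  est <- tleID(X, k = 20)
  expect_gte(idValue(est), 1.6)
  expect_lte(idValue(est), 2.4)
  expect_equal(idValue(tleID(X * 5.1, k = 20)), idValue(est),
               tolerance = 1e-9)
})

test_that("TLE surfaces duplicated points in its status accounting", {
  base <- ballPoints(2, 5, seed = 1)
  X <- base[rep(1:5, each = 8), ]  # every neighborhood is pure duplicates
  est <- tleID(X, k = 5)
  expect_equal(idStatus(est), "degenerate_input")
  expect_equal(est@params$invalidFraction, 1)
})

test_that("MiND likelihood recovers dimension from exact inverse-CDF samples", {
  ## rho ~ F(rho) = 1 - (1 - rho^d)^k with d = 3, k = 10
  k <- 10; d <- 3; n <- 1000
  set.seed(0)
  u <- runif(n)
  rho <- (1 - (1 - u)^(1 / k))^(1 / d)
  D <- cbind(rho, matrix(1, n, k - 1))
  nt <- syntheticNT(D)
  expect_equal(idValue(mindML(nt, k = k, "MLi", DMax = 10)), 3)
  expect_equal(idValue(mindML(nt, k = k, "MLk", DMax = 10)), 3,
               tolerance = 0.3 / 3)
})

test_that("MiND integer output respects its candidate bound", {
  for (s in 1:5) {
    X <- ballPoints(3, 150, seed = s)
    v <- idValue(mindML(X, k = 8, "MLi", DMax = 4))
    expect_true(v %in% 1:4)
  }
})

test_that("kNN-graph scaling identifies flat and curved supports", {
  g <- cbind(seq(0, 1, length.out = 400))
  expect_equal(idValue(knnGraphID(g, sizes = c(100, 200, 400), seed = 0)),
               1)
  disk <- ballPoints(2, 2000, seed = 0)
  expect_equal(idValue(knnGraphID(disk, sizes = c(250, 500, 1000),
                                  seed = 0)), 2)
})

test_that("kNN-graph estimate is bootstrap deterministic and validates sizes", {
  X <- ballPoints(2, 300, seed = 4)
  e1 <- knnGraphID(X, sizes = c(100, 200, 300), seed = 7)
  e2 <- knnGraphID(X, sizes = c(100, 200, 300), seed = 7)
  expect_identical(idValue(e1), idValue(e2))
  expect_identical(e1@params$slope, e2@params$slope)
  expect_error(knnGraphID(X, sizes = c(300)), "at least 2")
  expect_error(knnGraphID(X, sizes = c(200, 100, 300)), "increasing")
})
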
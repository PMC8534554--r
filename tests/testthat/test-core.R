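test_that("neighbor table is exact on a regular grid and complete at k = M-1", {
  nt <- buildNeighborTable(cbind(c(0, 1, 2)), k = 1)
  expect_equal(as.vector(neighborDistances(nt)), c(1, 1, 1))
  expect_equal(as.vector(neighborIndices(nt)), c(2L, 1L, 2L))

  X <- ballPoints(3, 40, seed = 7)
  nt <- buildNeighborTable(X, k = 39)
  for (i in c(1, 17, 40))
    expect_setequal(neighborIndices(nt)[i, ], setdiff(1:40, i))
})

test_that("neighbor table matches a brute-force sort oracle", {
  for (cfg in list(c(m = 60, d = 2, k = 5), c(m = 150, d = 3, k = 10),
                   c(m = 200, d = 5, k = 25))) {
    X <- ballPoints(cfg[["d"]], cfg[["m"]], seed = cfg[["m"]])
    k <- cfg[["k"]]
    nt <- buildNeighborTable(X, k)
    dm <- as.matrix(dist(X))
    for (i in seq_len(nrow(X))) {
      cand <- setdiff(seq_len(nrow(X)), i)
      ord <- cand[order(dm[i, cand], cand)][seq_len(k)]  # ties: lower index
      expect_identical(neighborIndices(nt)[i, ], ord)
      expect_equal(neighborDistances(nt)[i, ], unname(dm[i, ord]),
                   tolerance = 1e-12)
    }
  }
})

test_that("neighbor table rejects k >= M and keeps zero distances for duplicates", {
  X <- matrix(rnorm(20), 10)
  expect_error(buildNeighborTable(X, 10), "at most")
  Xd <- rbind(X, X[1, ])
  nt <- buildNeighborTable(Xd, 2)
  expect_true(any(neighborDistances(nt) == 0))
})

test_that("covariance spectrum has the right rank, symmetry and oracle values", {
  t <- seq(0, 1, length.out = 50)
  l <- eigenvalues(covarianceSpectrum(cbind(t, 2 * t, -t)))
  expect_equal(sum(l > 0), 1L)

  sq <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  l2 <- eigenvalues(covarianceSpectrum(sq))
  expect_equal(l2[1], l2[2])

  set.seed(42)
  X <- matrix(rnorm(250), 50, 5)
  lx <- eigenvalues(covarianceSpectrum(X))
  oracle <- sort(eigen(cov(X), symmetric = TRUE)$values,
                 decreasing = TRUE)
  expect_equal(lx, oracle, tolerance = 1e-9)
  expect_equal(sum(lx), sum(apply(X, 2, var)), tolerance = 1e-9)
})

test_that("constant matrices give an all-zero spectrum", {
  l <- eigenvalues(covarianceSpectrum(matrix(3, 10, 4)))
  expect_true(all(l == 0))
})

test_that("preprocessing scales, deduplicates and subsamples deterministically", {
  expect_equal(as.vector(preprocessMatrix(cbind(c(2, 4, 6)))),
               c(0, 0.5, 1))

  X <- matrix(rnorm(40), 10, 4)
  Xd <- rbind(X, X[3, ])
  expect_equal(nrow(preprocessMatrix(Xd, dedupTol = 0)), 10L)

  ## constant feature maps to 0
  Xc <- cbind(rnorm(10), 5)
  expect_true(all(preprocessMatrix(Xc)[, 2] == 0))

  ## near-duplicate columns removed on the scaled matrix
  Xcol <- cbind(a = rnorm(20), b = rnorm(20))
  Xcol <- cbind(Xcol, Xcol[, 1] + 1e-12)
  expect_equal(ncol(preprocessMatrix(Xcol)), 2L)

  X150 <- matrix(rnorm(450), 150, 3)
  s1 <- preprocessMatrix(X150, maxRows = 100, seed = 11)
  s2 <- preprocessMatrix(X150, maxRows = 100, seed = 11)
  expect_equal(nrow(s1), 100L)
  expect_identical(s1, s2)
  expect_false(identical(
    preprocessMatrix(X150, maxRows = 100, seed = 12), s1))

  expect_error(preprocessMatrix(matrix(1, 5, 2)), "degenerate")
})

test_that("global estimates are invariant to row permutation", {
  X <- ballPoints(3, 300, seed = 5)
  set.seed(1); perm <- sample(nrow(X))
  for (m in setdiff(listMethods(), "KNN")) {  # KNN subsamples row indices
    v1 <- idValue(estimateGlobal(X, m, seed = 0))
    v2 <- idValue(estimateGlobal(X[perm, ], m, seed = 0))
    expect_equal(v1, v2, tolerance = 1e-9, label = m)
  }
})

test_that("estimates are invariant to rotation and translation", {
  X <- ballPoints(3, 300, seed = 5)
  Q <- randomRotation(3, seed = 2)
  Xr <- sweep(X %*% Q, 2, c(5, -2, 11), "+")
  for (m in listMethods()) {
    v1 <- idValue(estimateGlobal(X, m, seed = 0))
    v2 <- idValue(estimateGlobal(Xr, m, seed = 0))
    expect_equal(v1, v2, tolerance = 1e-6, label = m)
  }
})

test_that("NN-ratio estimators are scale invariant", {
  X <- ballPoints(3, 300, seed = 5)
  for (m in c("MLE", "TwoNN", "MADA", "MOM", "TLE", "MiND_MLi",
              "MiND_MLk", "CorrInt")) {
    v1 <- idValue(estimateGlobal(X, m, seed = 0))
    v2 <- idValue(estimateGlobal(X * 7.3, m, seed = 0))
    expect_equal(v1, v2, tolerance = 1e-9, label = m)
  }
})

test_that("local estimation with k = M-1 reproduces the global estimate", {
  X <- ballPoints(2, 30, seed = 3)
  fld <- estimateLocal(X, "lPCA_FO", k = 29)
  expect_equal(idValue(fld),
               rep(idValue(estimateGlobal(X, "lPCA_FO")), 30))

  fld2 <- estimateLocal(X, "MLE", k = 29, params = list(k = 10))
  glb <- estimateGlobal(X, "MLE", params = list(k = 10))
  expect_equal(idValue(fld2), rep(idValue(glb), 30))
})

test_that("local estimation separates segments of different dimension", {
  ldb <- lineDiskBall(c(300, 300, 300), seed = 0)
  fld <- estimateLocal(samplePoints(ldb), "lPCA_FO", k = 40)
  means <- tapply(round(idValue(fld)), segmentLabels(ldb), mean)
  expect_equal(as.numeric(means[c("line", "disk", "ball")]), c(1, 2, 3))
})

test_that("local MLE concentrates near 2 on a 2-sphere surface", {
  s2 <- samplePoints(generateManifold("hypersphere", 2000, list(d = 2),
                                      seed = 0))
  fld <- estimateLocal(s2, "MLE", k = 20)
  inBand <- mean(idValue(fld) >= 1.5 & idValue(fld) <= 2.5, na.rm = TRUE)
  expect_gte(inBand, 0.9)
})

test_that("delimited text round-trips through readDataMatrix", {
  X <- matrix(rnorm(30), 10, 3,
              dimnames = list(paste0("r", 1:10), c("a", "b", "c")))
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = rownames(X), X), tf, row.names = FALSE)
  Y <- readDataMatrix(tf, rowIds = TRUE)
  expect_equal(unname(Y), unname(X), tolerance = 1e-12)
  expect_equal(rownames(Y), rownames(X))
  expect_equal(colnames(Y), colnames(X))
})
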
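smallCollection <- function() {
  list(ball2 = generateManifold("hyperball", 250, list(d = 2), seed = 1),
       ball4 = generateManifold("hyperball", 250, list(d = 4), seed = 2),
       cube3 = generateManifold("hypercube", 250, list(d = 3), seed = 3),
       gauss5 = generateManifold("gaussian", 250, list(d = 5), seed = 4))
}

test_that("profiling a collection is structured, seeded and deterministic", {
  methods <- c("MLE", "TwoNN", "MOM", "lPCA_FO", "lPCA_PR")
  pm1 <- runProfile(smallCollection(), methods, seed = 0)
  pm2 <- runProfile(smallCollection(), methods, seed = 0)
  expect_identical(profileValues(pm1), profileValues(pm2))
  expect_identical(profileStatuses(pm1), profileStatuses(pm2))
  expect_equal(dim(profileValues(pm1)), c(4L, 5L))
  expect_true(all(profileStatuses(pm1) %in%
                    c("ok", "invalid_nan", "invalid_negative",
                      "invalid_infinite", "degenerate_input")))
  ## missingness mirrors statuses
  expect_identical(is.na(profileValues(pm1)),
                   profileStatuses(pm1) != "ok")
  ## a failing cell does not poison the batch: constant dataset
  coll <- c(smallCollection()[1:2], list(flat = matrix(1, 50, 3)))
  pm3 <- runProfile(coll, c("MLE", "lPCA_FO"))
  expect_true(all(profileStatuses(pm3)["flat", ] != "ok"))
  expect_true(all(profileStatuses(pm3)["ball2", ] == "ok"))
})

test_that("per-method caps bound the rows and features an estimator sees", {
  big <- matrix(rnorm(25000 * 3), 25000, 3)
  pm <- runProfile(list(big = big), "MADA", seed = 0)
  expect_lte(profileNUsed(pm)["big", "MADA"], 20000L)
  expect_equal(profileStatuses(pm)["big", "MADA"], "ok")

  wide <- matrix(rnorm(2500 * 40), 2500, 40)
  pm2 <- runProfile(list(wide = wide), "ESS", seed = 0)
  ## ESS refuses anything above 2000 x 20, so an ok status proves the
  ## profiling layer reduced the input below its cap
  expect_equal(profileStatuses(pm2)["wide", "ESS"], "ok")
  expect_lte(profileNUsed(pm2)["wide", "ESS"], 2000L)

  capped <- applyMethodCaps(wide, 2000, 20, seed = 0)
  expect_equal(dim(capped), c(2000L, 20L))
})

test_that("imputation is the identity on complete data and exact on rank-1 profiles", {
  v <- cbind(a = c(1, 2, 3, 4), b = c(3, 1, 4, 2))
  pm <- new("ProfileMatrix", values = v,
            statuses = matrix("ok", 4, 2, dimnames = dimnames(v)))
  expect_identical(profileValues(imputeProfile(pm)), v)

  ## columns exactly proportional (y = 2x): the missing cell must land
  ## on the proportional prediction
  x <- c(1, 2, 3, 4, 5)
  v2 <- cbind(x = x, y = 2 * x)
  v2[3, "y"] <- NA
  st <- ifelse(is.na(v2), "invalid_nan", "ok")
  pm2 <- new("ProfileMatrix", values = v2, statuses = st)
  out <- imputeProfile(pm2)
  expect_equal(unname(profileValues(out)[3, "y"]), 6, tolerance = 1e-6)
  expect_true(all(is.finite(profileValues(out))))
  expect_equal(unname(profileStatuses(out)[3, "y"]), "ok")
})

test_that("imputation refuses unusable columns by name", {
  v <- cbind(good = c(1, 2, 3), dead = c(NA, NA, NA))
  st <- ifelse(is.na(v), "invalid_nan", "ok")
  pm <- new("ProfileMatrix", values = v, statuses = st)
  expect_error(imputeProfile(pm), "dead")
})

test_that("consensus z-scores are standardized and order/scale invariant", {
  set.seed(13)
  v <- matrix(rnorm(60, 10, 3), 10, 6,
              dimnames = list(paste0("d", 1:10), paste0("m", 1:6)))
  pm <- new("ProfileMatrix", values = v,
            statuses = matrix("ok", 10, 6, dimnames = dimnames(v)))
  cr <- consensusID(pm)
  Z <- cr@zscores
  expect_lte(max(abs(colMeans(Z))), 1e-9)
  expect_lte(max(abs(apply(Z, 2, var) - 1)), 1e-9)
  expect_equal(sum(explainedVariance(cr)), 1, tolerance = 1e-9)
  expect_true(all(diff(explainedVariance(cr)) <= 1e-12))

  ## shuffling methods leaves the consensus untouched
  perm <- c(4, 1, 6, 3, 2, 5)
  pmP <- new("ProfileMatrix", values = v[, perm],
             statuses = matrix("ok", 10, 6,
                               dimnames = dimnames(v[, perm])))
  expect_equal(meanZ(consensusID(pmP)), meanZ(cr), tolerance = 1e-12)

  ## affine rescaling of one method's raw values is absorbed by z-scoring
  v2 <- v; v2[, 3] <- 100 * v2[, 3] - 7
  pm2 <- new("ProfileMatrix", values = v2,
             statuses = matrix("ok", 10, 6, dimnames = dimnames(v2)))
  expect_equal(meanZ(consensusID(pm2)), meanZ(cr), tolerance = 1e-9)
})

test_that("two datasets give opposite equal-magnitude consensus scores", {
  v <- rbind(low = c(1, 2, 1.5), high = c(4, 7, 9))
  colnames(v) <- c("m1", "m2", "m3")
  pm <- new("ProfileMatrix", values = v,
            statuses = matrix("ok", 2, 3, dimnames = dimnames(v)))
  mz <- meanZ(consensusID(pm))
  expect_equal(unname(mz[1]), -unname(mz[2]), tolerance = 1e-12)
})

test_that("a shared signal drives same-sign first-component loadings", {
  set.seed(21)
  base <- rnorm(40, 8, 4)
  v <- sapply(1:6, function(j) base + rnorm(40, sd = 0.5))
  dimnames(v) <- list(paste0("d", 1:40), paste0("m", 1:6))
  pm <- new("ProfileMatrix", values = v,
            statuses = matrix("ok", 40, 6, dimnames = dimnames(v)))
  cr <- consensusID(pm)
  l1 <- consensusLoadings(cr)[, 1]
  expect_true(all(l1 > 0))
  expect_gte(explainedVariance(cr)[1], 0.8)
})

test_that("method correlation is symmetric with unit diagonal and exact poles", {
  x <- c(1, 3, 2, 5, 4)
  v <- cbind(a = x, same = x, anti = -2 * x + 1)
  pm <- new("ProfileMatrix", values = v,
            statuses = matrix("ok", 5, 3, dimnames = dimnames(v)))
  cm <- methodCorrelation(pm)
  expect_equal(cm, t(cm), tolerance = 1e-12)
  expect_equal(unname(diag(cm)), rep(1, 3), tolerance = 1e-12)
  expect_equal(cm["a", "same"], 1, tolerance = 1e-12)
  expect_equal(cm["a", "anti"], -1, tolerance = 1e-12)
  v0 <- cbind(a = x, flat = rep(2, 5))
  pm0 <- new("ProfileMatrix", values = v0,
             statuses = matrix("ok", 5, 2, dimnames = dimnames(v0)))
  expect_error(methodCorrelation(pm0), "flat")
})

test_that("redundancy sensitivity reports ratios per contract", {
  set.seed(30)
  X <- matrix(rnorm(200 * 8), 200, 8)
  ## relative-eigenvalue criterion: exactly 1
  expect_identical(redundancySensitivity(X, "lPCA_FO")@ratio, 1)
  ## distance-ratio methods: sqrt(2) rescaling cancels
  for (s in 1:2) {
    set.seed(s)
    Y <- matrix(rnorm(150 * 6), 150, 6)
    r <- redundancySensitivity(Y, "MLE")@ratio
    expect_gte(r, 0.95); expect_lte(r, 1.05)
  }
  ## count-based criteria may move; only the reporting contract holds
  sr <- redundancySensitivity(X, "lPCA_maxgap")
  expect_s4_class(sr, "SensitivityResult")
  expect_true(is.finite(sr@ratio) || is.na(sr@ratio))
  ## invalid runs propagate status instead of producing a ratio
  srBad <- redundancySensitivity(matrix(1, 20, 3) + 0, "MLE")
  expect_true(is.na(srBad@ratio))
  expect_false(srBad@statusOriginal == "ok")
})

test_that("the multiplicative time model is recovered from synthetic records", {
  rec <- expand.grid(Nobj = c(100, 500, 2000), Nvar = c(5, 20, 80))
  rec$seconds <- 0.01 * rec$Nobj^1.5 * rec$Nvar^0.5
  fit <- fitTimeModel(rec)
  expect_equal(fit@c, 0.01, tolerance = 1e-9)
  expect_equal(fit@alpha, 1.5, tolerance = 1e-9)
  expect_equal(fit@beta, 0.5, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
  expect_equal(predictTime(fit, 1000, 10),
               0.01 * 1000^1.5 * sqrt(10), tolerance = 1e-6)

  ## scaling all times by 10 shifts only the constant
  rec10 <- rec; rec10$seconds <- rec10$seconds * 10
  fit10 <- fitTimeModel(rec10)
  expect_equal(fit10@c, 0.1, tolerance = 1e-9)
  expect_equal(fit10@alpha, fit@alpha, tolerance = 1e-9)
  expect_equal(fit10@beta, fit@beta, tolerance = 1e-9)

  ## lognormal noise: exponent still recovered within 0.1
  set.seed(0)
  recN <- data.frame(Nobj = sample(c(100, 300, 1000, 3000), 30, TRUE),
                     Nvar = sample(c(5, 15, 50), 30, TRUE))
  recN$seconds <- 0.02 * recN$Nobj^1.2 * recN$Nvar^0.7 *
    exp(rnorm(30, sd = 0.1))
  fitN <- fitTimeModel(recN)
  expect_lte(abs(fitN@alpha - 1.2), 0.1)

  expect_error(fitTimeModel(data.frame(Nobj = c(1, 2, 3),
                                       Nvar = c(4, 4, 4),
                                       seconds = 1:3)), "Nvar")
})

test_that("profile matrices round-trip through CSV", {
  pm <- runProfile(smallCollection()[1:3], c("MLE", "lPCA_FO"), seed = 0)
  tf <- tempfile(fileext = ".csv")
  writeProfileMatrix(pm, tf)
  back <- readProfileMatrix(tf)
  expect_equal(profileValues(back), profileValues(pm), tolerance = 1e-12)
  expect_identical(profileStatuses(back), profileStatuses(pm))
})

test_that("coefficient of variation helper behaves", {
  expect_equal(coefVariation(c(2, 2, 2)), 0)
  expect_equal(coefVariation(c(1, 3)), sd(c(1, 3)) / 2)
})
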
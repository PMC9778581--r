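test_that("Hadamard G-by-E covariance combines environment and kernel structure", {
  ph <- data.frame(line = c("a", "b", "a", "b"), env = c("E1", "E1", "E2", "E2"))
  des <- makeDesignMatrices(ph)

  # identity kernel: only same-line, same-environment cells survive
  KI <- diag(2); dimnames(KI) <- list(c("a", "b"), c("a", "b"))
  expect_equal(buildGxECovariance(des$ZE, des$Zg, KI), diag(4),
               ignore_attr = TRUE)

  # records in different environments always decorrelate
  Km <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  Om <- buildGxECovariance(des$ZE, des$Zg, Km)
  expect_equal(Om[1:2, 3:4], matrix(0, 2, 2), ignore_attr = TRUE)
  # one environment: Omega is the kernel itself
  ph1 <- ph[1:2, ]
  des1 <- makeDesignMatrices(ph1)
  expect_equal(buildGxECovariance(des1$ZE, des1$Zg, Km),
               matrix(c(1, 0.5, 0.5, 1), 2), ignore_attr = TRUE)

  expect_error(buildGxECovariance(des$ZE, des$Zg[, 1, drop = FALSE], Km),
               "dimension mismatch")
})

test_that("conditional-mean oracle reproduces explicit linear algebra", {
  # zero genetic covariance: prediction is the fixed-effect surface
  C0 <- matrix(0, 3, 3)
  m <- c(1, 2, 3)
  expect_equal(conditionalMeanOracle(c(5, 7), C0, 1, m, testIdx = 3), 3)

  # 2 train + 1 test with scalar covariances, against the written-out solve
  C <- matrix(c(1.0, 0.3, 0.5,
                0.3, 1.0, 0.2,
                0.5, 0.2, 1.0), 3, byrow = TRUE)
  varE <- 0.5
  y <- c(2.0, -1.0)
  m <- c(0.2, 0.2, 0.2)
  A <- C[1:2, 1:2] + varE * diag(2)
  expected <- m[3] + C[3, 1:2] %*% solve(A, y - m[1:2])
  expect_equal(conditionalMeanOracle(y, C, varE, m, 3), drop(expected),
               tolerance = 1e-12)

  # noiseless limit with a duplicated record interpolates the observation
  Cdup <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(conditionalMeanOracle(0.7, Cdup, 1e-10, c(0, 0), 2), 0.7,
               tolerance = 1e-3)
})

test_that("Gibbs chains are deterministic given the seed and exchangeable in line order", {
  ds <- toyDataset(J = 16, seed = 5)
  dist <- squaredDistanceMatrix(ds@markers)
  K <- gaussianKernel(dist, 0.3)
  ph <- ds@phenotypes
  ph$value[1:4] <- NA
  f1 <- fitGibbs(ph, K, quickSpec(seed = 42))
  f2 <- fitGibbs(ph, K, quickSpec(seed = 42))
  expect_identical(f1@fitted, f2@fitted)
  expect_identical(f1@samples, f2@samples)
  f3 <- fitGibbs(ph, K, quickSpec(seed = 43))
  expect_false(identical(f1@fitted, f3@fitted))

  # jointly permuting kernel and phenotype order leaves predictions unchanged
  set.seed(1)
  perm <- sample(nrow(ph))
  idx <- sample(16)
  Kp <- new("KernelMatrix", K = as.matrix(K)[idx, idx], rho = bandwidth(K))
  f4 <- fitGibbs(ph[perm, ], Kp, quickSpec(seed = 42))
  expect_equal(f4@fitted, f1@fitted, tolerance = 1e-12)
})

test_that("constant phenotypes collapse onto the intercept with shrunken genetic variances", {
  mk <- toyMarkers(J = 16, seed = 6)
  K <- gaussianKernel(squaredDistanceMatrix(mk), 0.3)
  ph <- data.frame(line = lineIds(mk), env = "E1", value = 3)
  fit <- fitGibbs(ph, K, quickSpec(seed = 7))
  expect_lt(abs(fit@muHat - 3), 0.2)
  expect_lt(max(abs(fit@yhatTrain - 3)), 0.2)
  # all retained variance draws remain positive
  expect_true(all(fit@samples > 0))
})

test_that("predictions agree with the closed-form oracle at posterior-mean variances", {
  ds <- toyDataset(J = 20, rhoTrue = 0.2, seed = 8)
  ph <- ds@phenotypes
  set.seed(18)
  maskIdx <- sample(nrow(ph), 8)
  phm <- ph
  phm$value[maskIdx] <- NA
  K <- gaussianKernel(squaredDistanceMatrix(ds@markers), 0.2)
  fit <- fitGibbs(phm, K, modelSpec(nIter = 4000, burnIn = 1000, seed = 9))
  pred <- predict(fit, ph[maskIdx, c("line", "env")])

  des <- makeDesignMatrices(ph, lineIds = lineIds(K),
                            envIds = sort(unique(ph$env)))
  Omega <- buildGxECovariance(des$ZE, des$Zg, K)
  Kn <- des$Zg %*% as.matrix(K) %*% t(des$Zg)
  C <- fit@varG * Kn + fit@varGE * Omega
  m <- fit@muHat + fit@envEffects[as.character(ph$env)]
  orc <- conditionalMeanOracle(ph$value[-maskIdx], C, fit@varE, m, maskIdx)
  expect_gt(cor(pred$yhat, orc), 0.95)
  expect_lt(sqrt(mean((pred$yhat - orc)^2)), 0.05)

  # a test record duplicating a training cell returns that cell's fitted value
  predTrain <- predict(fit, phm[1, c("line", "env")])
  expect_equal(predTrain$yhat, fit@yhatTrain[1])
  expect_error(predict(fit, data.frame(line = "ghost", env = "E1")), "absent")
})

test_that("posterior means recover generating variance components", {
  # moderate-size replicates: each variance within 50% relative error of its
  # generating value in at least 80% of seeds
  hits <- c(varG = 0, varGE = 0, varE = 0)
  nRep <- 10
  for (s in seq_len(nRep)) {
    ds <- simulateDataset(simConfig(J = 120, p = 300, rhoTrue = 0.2,
                                    varG = 1, varGE = 0.5, varE = 0.5,
                                    seed = 100 + s))
    K <- gaussianKernel(squaredDistanceMatrix(ds@markers), 0.2)
    fit <- fitGibbs(ds@phenotypes, K,
                    modelSpec(nIter = 3000, burnIn = 1000, seed = s))
    est <- varComponents(fit)
    truth <- c(varG = 1, varGE = 0.5, varE = 0.5)
    hits <- hits + (abs(est - truth) / truth < 0.5)
  }
  expect_true(all(hits >= 0.8 * nRep))
})
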
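test_that("MSE and NRMSE match hand arithmetic and scaling laws", {
  expect_equal(mse(c(0, 2), c(1, 1)), 1.0)
  expect_equal(mse(1:5, 1:5), 0)
  # homogeneity: scaling both vectors by c multiplies MSE by c^2
  y <- c(1.2, -0.4, 2.2)
  yh <- c(1.0, 0.1, 2.0)
  expect_equal(mse(3 * y, 3 * yh), 9 * mse(y, yh))

  expect_equal(nrmse(c(1, 3), c(2, 2)), 0.5)
  expect_equal(nrmse(c(1, 3), c(1, 3)), 0)
  # NRMSE is invariant to joint positive scaling; MSE is not
  expect_equal(nrmse(3 * c(1, 3), 3 * c(2, 2)), nrmse(c(1, 3), c(2, 2)))

  expect_error(mse(numeric(0), numeric(0)), "empty")
  expect_error(mse(1:3, 1:2), "lengths")
  expect_error(nrmse(c(-1, 1), c(0, 0)), "zero")
})

test_that("relative efficiencies behave as ratios with exact identities", {
  expect_equal(relativeEfficiency(0.2, 0.1), 2.0)
  expect_equal(relativeEfficiency(0.7, 0.7), 1.0)
  expect_error(relativeEfficiency(1, 0), "zero")

  # a printed-table-style pair: 3-decimal MSEs reproduce the published ratio
  # within the rounding slack of unrounded fold-level values
  expect_equal(relativeEfficiency(0.138, 0.128), 1.078125, tolerance = 1e-9)
  expect_lt(abs(relativeEfficiency(0.138, 0.128) - 1.077), 0.005)

  # reciprocal and chain identities to numerical precision
  for (s in 1:5) {
    set.seed(s)
    m <- runif(3, 0.05, 0.5)  # NT, GrS, BO metric values
    expect_equal(relativeEfficiency(m[1], m[2]) * relativeEfficiency(m[2], m[1]),
                 1, tolerance = 1e-12)
    expect_equal(relativeEfficiency(m[1], m[2]),
                 relativeEfficiency(m[1], m[3]) * relativeEfficiency(m[3], m[2]),
                 tolerance = 1e-12)
  }
})

test_that("fold aggregation reproduces a spreadsheet-style hand computation", {
  # two folds, two environments, residuals chosen for easy arithmetic
  f1 <- list(predictions = data.frame(
    line = c("a", "b", "c", "d"), env = c("E1", "E1", "E2", "E2"),
    yObs = c(2, 4, 10, 12), yhat = c(3, 3, 11, 11)))
  f2 <- list(predictions = data.frame(
    line = c("e", "f", "g", "h"), env = c("E1", "E1", "E2", "E2"),
    yObs = c(2, 6, 10, 14), yhat = c(4, 4, 12, 12)))
  rep1 <- summarizeFolds(list(NT = list(f1, f2), GrS = list(f1, f2)))
  m <- metricsTable(rep1)

  # E1, fold 1: residuals (-1, 1) -> MSE 1, ybar 3, NRMSE 1/3
  # E1, fold 2: residuals (-2, 2) -> MSE 4, ybar 4, NRMSE 1/2
  e1 <- m[m$scope == "E1" & m$strategy == "NT", ]
  expect_equal(e1$mse, (1 + 4) / 2)
  expect_equal(e1$seMse, sd(c(1, 4)) / sqrt(2))
  expect_equal(e1$nrmse, (1/3 + 1/2) / 2)

  # Global, fold 1: residuals (-1,1,-1,1) -> MSE 1, ybar 7, NRMSE 1/7
  # Global, fold 2: residuals (-2,2,-2,2) -> MSE 4, ybar 8, NRMSE 1/4
  gl <- m[m$scope == "Global" & m$strategy == "NT", ]
  expect_equal(gl$mse, 2.5)
  expect_equal(gl$nrmse, (1/7 + 1/4) / 2)

  # identical strategies: identical rows and RE exactly 1
  re <- relativeEfficiencies(rep1)
  expect_equal(re$reMse, rep(1, nrow(re)))
  expect_equal(re$reNrmse, rep(1, nrow(re)))
  expect_equal(sort(unique(m$scope)), c("E1", "E2", "Global"))

  # identical per-fold metrics give zero SE
  rep2 <- summarizeFolds(list(NT = list(f1, f1)))
  m2 <- metricsTable(rep2)
  expect_equal(m2$seMse, rep(0, nrow(m2)))
})

test_that("report invariants hold on assembled fold results", {
  set.seed(31)
  mkFold <- function() list(predictions = data.frame(
    line = sprintf("l%d", 1:6), env = rep(c("E1", "E2"), 3),
    yObs = rnorm(6, 10), yhat = rnorm(6, 10)))
  folds <- list(NT = list(mkFold(), mkFold(), mkFold()),
                GrS = list(mkFold(), mkFold(), mkFold()),
                BO = list(mkFold(), mkFold(), mkFold()))
  rep <- summarizeFolds(folds)
  re <- relativeEfficiencies(rep)
  expect_equal(nrow(metricsTable(rep)), 3 * 3)  # 3 strategies x (2 envs + Global)
  expect_equal(nrow(re), 3 * 3)                 # 3 comparisons x 3 scopes
  # ratio-chain identity: RE(NT/GrS) = RE(NT/BO) / RE(GrS/BO)
  for (sc in unique(re$scope)) {
    ntgrs <- re$reMse[re$comparison == "NT/GrS" & re$scope == sc]
    ntbo <- re$reMse[re$comparison == "NT/BO" & re$scope == sc]
    grsbo <- re$reMse[re$comparison == "GrS/BO" & re$scope == sc]
    expect_equal(ntgrs, ntbo / grsbo, tolerance = 1e-12)
  }
})
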
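#' Bandwidth grid for grid search
#'
#' 26 bandwidth values: 0.01 to 0.97 in steps of 0.04, plus the upper
#' endpoint 0.999.
#'
#' @return sorted numeric vector of 26 bandwidths in (0, 1).
#' @export
makeGrid <- function() {
  sort(c(seq(0.01, by = 0.04, length.out = 25), 0.999))
}

## Internal: derive a deterministic per-(outer, inner) chain seed so that
## every candidate rho and every strategy sees identical chains (paired
## comparisons). Kept below 2^31.
chainSeed <- function(base, outerFold = 0L, innerFold = 0L) {
  (as.numeric(base) * 1000 + outerFold * 101 + innerFold * 13) %% 2147483647
}

#' Inner cross-validation objective for a candidate bandwidth
#'
#' Fits the kernel GBLUP once per inner fold at the given bandwidth (inner
#' validation lines masked), computes the NRMSE of the masked records on
#' each fold, and returns the mean over folds. Chain seeds depend only on
#' the fold indices, never on rho, so objective values are paired across
#' candidates.
#'
#' @param phenotypes outer-training records (line, env, value).
#' @param dist \linkS4class{DistanceMatrix} over (at least) the
#'   outer-training lines.
#' @param rho candidate bandwidth in (0, 1).
#' @param innerFolds named integer vector: outer-training line -> inner fold.
#' @param spec a \linkS4class{ModelSpec}; its seed is the base of the
#'   per-fold chain seeds.
#' @param outerFold index used in chain-seed derivation (default 0).
#' @return mean NRMSE over the inner validation folds.
#' @export
innerCVObjective <- function(phenotypes, dist, rho, innerFolds, spec,
                             outerFold = 0L) {
  lines <- sort(unique(names(innerFolds)))
  D2 <- dist@D2[lines, lines]
  K <- new("KernelMatrix", K = {
    Km <- exp(log(rho) * D2); diag(Km) <- 1; Km
  }, rho = rho)
  eig <- kernelEigen(K@K)
  folds <- sort(unique(innerFolds))
  for (f in folds) {
    nVal <- sum(as.character(phenotypes$line) %in%
                  names(innerFolds)[innerFolds == f])
    if (nVal < 2L)
      stop("inner fold ", f, " has fewer than 2 validation records")
  }
  vals <- vapply(folds, function(f) {
    valLines <- names(innerFolds)[innerFolds == f]
    isVal <- as.character(phenotypes$line) %in% valLines
    ph <- phenotypes
    ph$value[isVal] <- NA_real_
    fit <- fitGibbs(ph, K, spec = new("ModelSpec",
                                      nIter = spec@nIter, burnIn = spec@burnIn,
                                      thin = spec@thin, priorDf = spec@priorDf,
                                      priorR2 = spec@priorR2,
                                      seed = chainSeed(spec@seed, outerFold, f)),
                    eig = eig)
    pred <- predict(fit, phenotypes[isVal, c("line", "env")])
    nrmse(phenotypes$value[isVal], pred$yhat)
  }, numeric(1))
  mean(vals)
}

#' No-tuning strategy: fixed default bandwidth
#'
#' The manual-tuning baseline fixes gamma = 1, i.e. rho = exp(-1), with no
#' inner-CV evaluations.
#'
#' @return a \linkS4class{TuningResult} with strategy "NT".
#' @export
noTuning <- function() {
  new("TuningResult", strategy = "NT",
      evaluations = data.frame(rho = numeric(0), nrmse = numeric(0)),
      selectedRho = exp(-1), nModelFits = 0)
}

#' Grid-search bandwidth tuning
#'
#' Evaluates the inner-CV NRMSE objective at every grid bandwidth and
#' selects the minimizer (ties broken toward the largest rho, the smoother
#' kernel).
#'
#' @inheritParams innerCVObjective
#' @param grid candidate bandwidths (default \code{\link{makeGrid}()}).
#' @return a \linkS4class{TuningResult} with strategy "GrS".
#' @export
gridSearch <- function(phenotypes, dist, innerFolds, spec,
                       grid = makeGrid(), outerFold = 0L) {
  obj <- vapply(grid, function(r)
    innerCVObjective(phenotypes, dist, r, innerFolds, spec, outerFold),
    numeric(1))
  best <- max(which(obj == min(obj)))  # largest rho among ties
  nFolds <- length(unique(innerFolds))
  new("TuningResult", strategy = "GrS",
      evaluations = data.frame(rho = grid, nrmse = obj),
      selectedRho = grid[best], nModelFits = length(grid) * nFolds)
}

## ---- Bayesian optimization -------------------------------------------------

## Internal: Gaussian-process regression pieces for the 1-D surrogate.
## Squared-exponential covariance; signal variance fixed at the sample
## variance of the standardized observations, lengthscale and noise chosen
## by marginal likelihood over a small grid.
gpLogMarginal <- function(x, y, ell, noise) {
  n <- length(x)
  Kc <- exp(-0.5 * outer(x, x, "-")^2 / ell^2) + diag(noise, n)
  ch <- tryCatch(chol(Kc), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  -0.5 * sum(y * alpha) - sum(log(diag(ch))) - 0.5 * n * log(2 * pi)
}

gpPosterior <- function(x, y, ell, noise, xstar) {
  n <- length(x)
  Kc <- exp(-0.5 * outer(x, x, "-")^2 / ell^2) + diag(noise, n)
  Ks <- exp(-0.5 * outer(xstar, x, "-")^2 / ell^2)
  ch <- chol(Kc)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  mu <- drop(Ks %*% alpha)
  Vhalf <- forwardsolve(t(ch), t(Ks))
  s2 <- pmax(1 - colSums(Vhalf^2), 1e-12)
  list(mean = mu, sd = sqrt(s2))
}

#' Minimize a 1-D objective by Bayesian optimization
#'
#' Gaussian-process surrogate (squared-exponential covariance, observation
#' noise selected by marginal likelihood) with expected-improvement
#' acquisition maximized over a fine mesh. Initialized with 5 evenly spaced
#' design points; fully deterministic for a deterministic objective.
#'
#' @param objective function of one numeric argument to minimize.
#' @param budget total number of objective evaluations (>= 6).
#' @param lower,upper search interval (defaults: the bandwidth box).
#' @param meshSize acquisition mesh resolution.
#' @return list with \code{x} (best query), \code{y} (its objective value)
#'   and \code{evaluations}, a data.frame of all queries in order.
#' @export
boMinimize <- function(objective, budget = 22, lower = 0.01, upper = 0.999,
                       meshSize = 1000) {
  if (budget < 6) stop("budget must be at least 6 (5 design points + 1 acquisition)")
  xs <- seq(lower, upper, length.out = 5)
  ys <- vapply(xs, objective, numeric(1))
  mesh <- seq(lower, upper, length.out = meshSize)
  ellGrid <- c(0.05, 0.1, 0.2, 0.4)
  noiseGrid <- c(1e-6, 1e-4, 1e-2, 1e-1)
  for (t in seq_len(budget - 5)) {
    mu0 <- mean(ys)
    s0 <- stats::sd(ys)
    if (!is.finite(s0) || s0 <= 0) s0 <- 1
    z <- (ys - mu0) / s0
    hp <- expand.grid(ell = ellGrid, noise = noiseGrid)
    lml <- mapply(function(e, nz) gpLogMarginal(xs, z, e, nz),
                  hp$ell, hp$noise)
    bestHp <- hp[which.max(lml), ]
    post <- gpPosterior(xs, z, bestHp$ell, bestHp$noise, mesh)
    fbest <- min(z)
    imp <- fbest - post$mean
    zz <- imp / post$sd
    ei <- imp * pnorm(zz) + post$sd * dnorm(zz)
    # never re-query an already evaluated mesh point
    ei[vapply(mesh, function(m) any(abs(m - xs) < 1e-9), logical(1))] <- -Inf
    xnew <- mesh[which.max(ei)]
    xs <- c(xs, xnew)
    ys <- c(ys, objective(xnew))
  }
  best <- max(which(ys == min(ys)))
  list(x = xs[best], y = ys[best],
       evaluations = data.frame(rho = xs, value = ys))
}

#' Bayesian-optimization bandwidth tuning
#'
#' Runs \code{\link{boMinimize}} on the inner-CV NRMSE objective and selects
#' the best evaluated bandwidth.
#'
#' @inheritParams innerCVObjective
#' @param budget total objective evaluations (default 22, slightly below the
#'   26-point grid).
#' @return a \linkS4class{TuningResult} with strategy "BO".
#' @export
bayesOpt <- function(phenotypes, dist, innerFolds, spec, budget = 22,
                     outerFold = 0L) {
  res <- boMinimize(function(r)
    innerCVObjective(phenotypes, dist, r, innerFolds, spec, outerFold),
    budget = budget)
  nFolds <- length(unique(innerFolds))
  new("TuningResult", strategy = "BO",
      evaluations = data.frame(rho = res$evaluations$rho,
                               nrmse = res$evaluations$value),
      selectedRho = res$x, nModelFits = budget * nFolds)
}
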
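#' Incidence matrices for a phenotype table
#'
#' Builds the 0/1 incidence of records onto environments (Z_E) and onto
#' lines (Z_g) for the long-format phenotype table.
#'
#' @param phenotypes data.frame with columns line, env (value optional).
#' @param lineIds line ordering to use for Z_g columns (default: sorted
#'   unique lines of the table).
#' @param envIds environment ordering for Z_E columns.
#' @return list with matrices ZE (n x I) and Zg (n x J) plus the id vectors.
#' @export
makeDesignMatrices <- function(phenotypes, lineIds = NULL, envIds = NULL) {
  line <- as.character(phenotypes$line)
  env <- as.character(phenotypes$env)
  if (is.null(lineIds)) lineIds <- sort(unique(line))
  if (is.null(envIds)) envIds <- sort(unique(env))
  if (!all(line %in% lineIds))
    stop("phenotype table contains lines not in lineIds: ",
         paste(setdiff(line, lineIds), collapse = ", "))
  if (!all(env %in% envIds))
    stop("phenotype table contains environments not in envIds: ",
         paste(setdiff(env, envIds), collapse = ", "))
  n <- nrow(phenotypes)
  ZE <- matrix(0, n, length(envIds), dimnames = list(NULL, envIds))
  ZE[cbind(seq_len(n), match(env, envIds))] <- 1
  Zg <- matrix(0, n, length(lineIds), dimnames = list(NULL, lineIds))
  Zg[cbind(seq_len(n), match(line, lineIds))] <- 1
  list(ZE = ZE, Zg = Zg, lineIds = lineIds, envIds = envIds)
}

#' Hadamard genotype-by-environment covariance structure
#'
#' Omega = (Z_E Z_E') o (Z_g K Z_g'): the record-level covariance structure
#' of the G-by-E random effect. Records in different environments are
#' uncorrelated; records in the same environment share the kernel similarity
#' of their lines.
#'
#' @param ZE n x I environment incidence.
#' @param Zg n x J line incidence.
#' @param K a \linkS4class{KernelMatrix} (or plain J x J matrix in Zg column
#'   order).
#' @return n x n covariance structure matrix.
#' @export
buildGxECovariance <- function(ZE, Zg, K) {
  Km <- if (is(K, "KernelMatrix")) K@K else as.matrix(K)
  if (ncol(Zg) != nrow(Km))
    stop("dimension mismatch: Zg has ", ncol(Zg), " columns but K is ",
         nrow(Km), " x ", ncol(Km))
  if (!is.null(colnames(Zg)) && !is.null(rownames(Km)))
    Km <- Km[colnames(Zg), colnames(Zg), drop = FALSE]
  (tcrossprod(ZE)) * (Zg %*% Km %*% t(Zg))
}

#' MCMC settings constructor
#'
#' @param nIter,burnIn,thin chain length, burn-in and thinning.
#' @param priorDf,priorR2 scaled-inverse-chi-square prior degrees of freedom
#'   and the prior share of phenotypic variance assigned (in equal halves)
#'   to the two genetic variance components.
#' @param seed sampler seed.
#' @return a \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(nIter = 6000, burnIn = 1000, thin = 5,
                      priorDf = 5, priorR2 = 0.5, seed = 1) {
  new("ModelSpec", nIter = nIter, burnIn = burnIn, thin = thin,
      priorDf = priorDf, priorR2 = priorR2, seed = seed)
}

## Internal: eigen-decomposition of a kernel with PSD check.
## Returns list(V, d) with negative round-off eigenvalues clipped to zero.
kernelEigen <- function(Km) {
  e <- eigen(Km, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("kernel matrix is not positive semi-definite (min eigenvalue ",
         format(min(e$values)), ")")
  e$values[e$values < 0] <- 0
  list(V = e$vectors, d = e$values)
}

## Internal: complete phenotype records to the lines x envs grid.
## Returns y (J x I, NA where unobserved) and mask.
phenotypeGrid <- function(phenotypes, lineIds, envIds) {
  line <- as.character(phenotypes$line)
  env <- as.character(phenotypes$env)
  bad <- setdiff(line, lineIds)
  if (length(bad))
    stop("phenotype table contains lines absent from the kernel: ",
         paste(bad, collapse = ", "))
  key <- paste(line, env, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, environment) records: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  y <- matrix(NA_real_, length(lineIds), length(envIds),
              dimnames = list(lineIds, envIds))
  y[cbind(match(line, lineIds), match(env, envIds))] <- phenotypes$value
  y
}

#' Fit the Bayesian kernel GBLUP by Gibbs sampling
#'
#' Fits y_ij = mu + E_i + g_j + gE_ij + eps_ij with g ~ N(0, varG K),
#' gE ~ N(0, varGE (Z_E Z_E' o Z_g K Z_g')) and Gaussian noise, using a
#' Gibbs sampler that works in the eigenbasis of K. Phenotype values given
#' as NA (and grid cells with no record) are treated as unobserved and
#' imputed by data augmentation; their posterior-mean conditional surfaces
#' are available through \code{\link[=predict]{predict()}}, which is how
#' held-out records are predicted.
#'
#' Priors follow common Bayesian-GBLUP practice: flat on the intercept and
#' environment effects, scaled-inverse-chi-square on each variance with
#' \code{priorDf} degrees of freedom and scales that place the prior mode at
#' \code{priorR2}/2 (each genetic term) and 1 - \code{priorR2} (noise) of
#' the observed phenotypic variance.
#'
#' @param phenotypes data.frame with columns line, env, value (NA = masked).
#' @param K a \linkS4class{KernelMatrix} covering every phenotyped line
#'   (extra genotyped-only lines are allowed and predicted).
#' @param spec a \linkS4class{ModelSpec}.
#' @param eig optional precomputed \code{list(V, d)} eigendecomposition of
#'   the kernel (in sorted-line order), e.g. cached across inner-CV folds.
#' @return a \linkS4class{ModelFit}.
#' @export
fitGibbs <- function(phenotypes, K, spec = modelSpec(), eig = NULL) {
  if (!is(K, "KernelMatrix")) stop("K must be a KernelMatrix")
  validObject(spec)
  # canonical ordering: sorted lines/envs, so jointly permuted inputs give
  # bit-identical chains
  lineIds <- sort(lineIds(K))
  envIds <- sort(unique(as.character(phenotypes$env)))
  Km <- K@K[lineIds, lineIds]
  y <- phenotypeGrid(phenotypes, lineIds, envIds)
  obs <- !is.na(y)
  if (!any(obs)) stop("no observed phenotype records")
  if (is.null(eig)) eig <- kernelEigen(Km)
  vy <- stats::var(y[obs])
  if (vy <= 0) vy <- 1e-6
  df <- spec@priorDf
  Sg <- vy * (spec@priorR2 / 2) * (df + 2) / df
  Se <- vy * (1 - spec@priorR2) * (df + 2) / df
  y0 <- y
  y0[!obs] <- 0
  res <- .gibbs_kernel_gblup(y0, 1L * !obs, eig$V, eig$d,
                             as.integer(spec@nIter), as.integer(spec@burnIn),
                             as.integer(spec@thin), df, Sg, Sg, Se,
                             as.numeric(spec@seed))
  aMean <- colMeans(res$aSamples)
  mu <- mean(aMean)
  envEff <- setNames(aMean - mu, envIds)
  fitted <- res$fitted
  dimnames(fitted) <- list(lineIds, envIds)
  recIdx <- cbind(match(as.character(phenotypes$line), lineIds),
                  match(as.character(phenotypes$env), envIds))
  yhatTrain <- fitted[recIdx]
  vs <- res$varSamples
  colnames(vs) <- c("varG", "varGE", "varE")
  new("ModelFit", muHat = mu, envEffects = envEff,
      varG = mean(vs[, 1]), varGE = mean(vs[, 2]), varE = mean(vs[, 3]),
      fitted = fitted, yhatTrain = yhatTrain, samples = vs,
      lineIds = lineIds, envIds = envIds, spec = spec)
}

#' Predict phenotypes for (line, environment) records
#'
#' Returns the model's posterior-mean conditional expectation (the average
#' over retained draws of the per-draw fitted surface) for the requested
#' records. Any line present in the kernel the model was fitted with can be
#' predicted in any modeled environment.
#'
#' @param object a \linkS4class{ModelFit}.
#' @param newdata data.frame with columns line, env.
#' @param ... unused.
#' @return data.frame with columns line, env, yhat.
#' @export
setMethod("predict", "ModelFit", function(object, newdata, ...) {
  line <- as.character(newdata$line)
  env <- as.character(newdata$env)
  badL <- setdiff(line, object@lineIds)
  if (length(badL))
    stop("cannot predict lines absent from the fitted kernel: ",
         paste(unique(badL), collapse = ", "))
  badE <- setdiff(env, object@envIds)
  if (length(badE))
    stop("cannot predict in environments absent from the training data: ",
         paste(unique(badE), collapse = ", "))
  yhat <- object@fitted[cbind(match(line, object@lineIds),
                              match(env, object@envIds))]
  data.frame(line = line, env = env, yhat = yhat, stringsAsFactors = FALSE)
})

#' Closed-form conditional-mean predictor at fixed variance components
#'
#' The exact Gaussian conditional mean
#' \eqn{\hat y_{test} = m_{test} + C_{t,r} (C_{r,r} + \sigma^2_e I)^{-1}
#' (y_{train} - m_{train})}
#' for a total genetic covariance C supplied by the caller (typically
#' varG * Z_g K Z_g' + varGE * Omega). Serves as an independent oracle for
#' the Gibbs sampler's posterior predictive means.
#'
#' @param yTrain observed training values (length = training records).
#' @param Cfull covariance of the genetic signal over all records
#'   (training then ordered with test via \code{testIdx}).
#' @param varE residual variance.
#' @param fixedEffects fixed-effect surface m for all records.
#' @param testIdx indices of test records within the full record set.
#' @return numeric vector of predictions for the test records.
#' @export
conditionalMeanOracle <- function(yTrain, Cfull, varE, fixedEffects, testIdx) {
  nAll <- nrow(Cfull)
  trainIdx <- setdiff(seq_len(nAll), testIdx)
  if (length(yTrain) != length(trainIdx))
    stop("yTrain length does not match the number of training records")
  Ctt <- Cfull[trainIdx, trainIdx, drop = FALSE] + varE * diag(length(trainIdx))
  ok <- tryCatch({
    ch <- chol(Ctt)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("training covariance plus noise is singular")
  alpha <- backsolve(ch, forwardsolve(t(ch), yTrain - fixedEffects[trainIdx]))
  drop(fixedEffects[testIdx] +
         Cfull[testIdx, trainIdx, drop = FALSE] %*% alpha)
}
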
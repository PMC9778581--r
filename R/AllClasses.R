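#' @import methods
#' @importFrom stats var sd rnorm rbinom runif predict setNames dnorm pnorm
#' @importFrom utils read.csv write.csv packageVersion
#' @useDynLib KernelGBLUP, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Marker genotype matrix
#'
#' Lines-by-markers genotype codes (0/1/2 or -1/0/1 per marker), the raw
#' input to kernel construction. Row names are the line identifiers.
#'
#' @slot genotypes numeric matrix, lines in rows (named), markers in columns.
#' @export
setClass("MarkerMatrix", representation(genotypes = "matrix"))

setValidity("MarkerMatrix", function(object) {
  G <- object@genotypes
  if (!is.numeric(G)) return("genotypes must be numeric")
  if (anyNA(G)) return("genotypes contain missing values; impute before use")
  if (nrow(G) < 2L) return("need at least 2 lines")
  if (ncol(G) < 1L) return("need at least 1 marker")
  ids <- rownames(G)
  if (is.null(ids) || anyDuplicated(ids) > 0L)
    return("line identifiers (rownames) must be present and unique")
  TRUE
})

#' Normalized squared-distance matrix
#'
#' Pairwise squared Euclidean distances between the (column-centered) marker
#' vectors of all lines, divided by their mean off-diagonal value so the
#' off-diagonal average is exactly 1. This normalization keeps the Gaussian
#' kernel exponent O(1) regardless of marker count.
#'
#' @slot D2 symmetric matrix of normalized squared distances, zero diagonal.
#' @slot normalizer positive scalar: the mean off-diagonal raw squared distance.
#' @export
setClass("DistanceMatrix",
         representation(D2 = "matrix", normalizer = "numeric"))

setValidity("DistanceMatrix", function(object) {
  D2 <- object@D2
  if (nrow(D2) != ncol(D2)) return("D2 must be square")
  if (any(D2 < 0)) return("D2 entries must be non-negative")
  if (max(abs(diag(D2))) > 1e-12) return("D2 diagonal must be zero")
  if (max(abs(D2 - t(D2))) > 1e-9) return("D2 must be symmetric")
  if (length(object@normalizer) != 1L || object@normalizer <= 0)
    return("normalizer must be a positive scalar")
  n <- nrow(D2)
  if (n >= 2L) {
    off <- mean(D2[upper.tri(D2) | lower.tri(D2)])
    if (abs(off - 1) > 1e-9)
      return("mean off-diagonal normalized distance must equal 1")
  }
  TRUE
})

#' Kernel similarity matrix
#'
#' Line-by-line similarity used as the covariance structure of genetic
#' effects. For the Gaussian kernel, entries are rho^D2 with unit diagonal
#' and the generating bandwidth rho is stored; the linear genomic
#' relationship matrix stores rho = NA.
#'
#' @slot K symmetric similarity matrix with line identifiers as dimnames.
#' @slot rho Gaussian-kernel bandwidth in (0, 1), or NA for a linear kernel.
#' @export
setClass("KernelMatrix", representation(K = "matrix", rho = "numeric"))

setValidity("KernelMatrix", function(object) {
  K <- object@K
  if (nrow(K) != ncol(K)) return("K must be square")
  if (max(abs(K - t(K))) > 1e-9) return("K must be symmetric")
  ids <- rownames(K)
  if (is.null(ids) || anyDuplicated(ids) > 0L)
    return("line identifiers (dimnames) must be present and unique")
  if (!identical(ids, colnames(K))) return("row and column names must agree")
  if (!is.na(object@rho)) {
    if (object@rho <= 0 || object@rho >= 1)
      return("rho must lie in (0, 1)")
    if (any(K <= 0) || any(K > 1 + 1e-12))
      return("Gaussian-kernel entries must lie in (0, 1]")
    if (max(abs(diag(K) - 1)) > 1e-12)
      return("Gaussian kernel must have unit diagonal")
  }
  TRUE
})

#' MCMC settings for the Gibbs sampler
#'
#' @slot nIter total Gibbs iterations.
#' @slot burnIn discarded iterations.
#' @slot thin thinning interval for retained draws.
#' @slot priorDf degrees of freedom of the scaled-inverse-chi-square priors
#'   placed on each variance component.
#' @slot priorR2 prior proportion of phenotypic variance attributed to the
#'   random genetic terms (split equally between them) when setting prior
#'   scales.
#' @slot seed integer seed for the sampler's own RNG.
#' @export
setClass("ModelSpec",
         representation(nIter = "numeric", burnIn = "numeric", thin = "numeric",
                        priorDf = "numeric", priorR2 = "numeric",
                        seed = "numeric"))

setValidity("ModelSpec", function(object) {
  if (object@nIter <= object@burnIn) return("nIter must exceed burnIn")
  if (object@burnIn < 0) return("burnIn must be >= 0")
  if (object@thin < 1) return("thin must be >= 1")
  if (object@priorDf <= 0) return("priorDf must be positive")
  if (object@priorR2 <= 0 || object@priorR2 >= 1)
    return("priorR2 must lie in (0, 1)")
  TRUE
})

#' Fitted kernel GBLUP model
#'
#' Posterior summaries of the Gibbs chain: intercept, environment effects
#' (sum-to-zero deviations), posterior-mean variance components, the
#' posterior-mean fitted surface over the whole line-by-environment grid,
#' and retained variance draws for diagnostics.
#'
#' @slot muHat posterior-mean intercept.
#' @slot envEffects named posterior-mean environment deviations (sum to zero).
#' @slot varG,varGE,varE posterior-mean variance components.
#' @slot fitted J x I posterior-mean surface (lines x environments), the
#'   Rao-Blackwellized conditional mean of every grid cell.
#' @slot yhatTrain fitted values for the observed training records, in input
#'   record order.
#' @slot samples retained draws of (varG, varGE, varE), one row per draw.
#' @slot lineIds,envIds grid labels.
#' @slot spec the \linkS4class{ModelSpec} used.
#' @export
setClass("ModelFit",
         representation(muHat = "numeric", envEffects = "numeric",
                        varG = "numeric", varGE = "numeric", varE = "numeric",
                        fitted = "matrix", yhatTrain = "numeric",
                        samples = "matrix", lineIds = "character",
                        envIds = "character", spec = "ModelSpec"))

setValidity("ModelFit", function(object) {
  if (any(c(object@varG, object@varGE, object@varE) < 0))
    return("posterior-mean variances must be non-negative")
  TRUE
})

#' Result of one bandwidth-tuning run
#'
#' @slot strategy one of "NT" (no tuning), "GrS" (grid search), "BO"
#'   (Bayesian optimization).
#' @slot evaluations data.frame with columns rho, nrmse in evaluation order.
#' @slot selectedRho chosen bandwidth in (0, 1).
#' @slot nModelFits number of inner-CV model fits performed.
#' @export
setClass("TuningResult",
         representation(strategy = "character", evaluations = "data.frame",
                        selectedRho = "numeric", nModelFits = "numeric"))

setValidity("TuningResult", function(object) {
  if (!object@strategy %in% c("NT", "GrS", "BO"))
    return("strategy must be one of NT, GrS, BO")
  if (object@selectedRho <= 0 || object@selectedRho >= 1)
    return("selectedRho must lie in (0, 1)")
  if (object@strategy == "NT" && nrow(object@evaluations) != 0L)
    return("NT performs no evaluations")
  TRUE
})

#' Nested cross-validation fold plan
#'
#' Line-level fold assignments: an outer partition of all lines and, within
#' each outer training set, an inner partition used for bandwidth tuning.
#'
#' @slot outer named integer vector, line -> outer fold index.
#' @slot inner list (one element per outer fold) of named integer vectors,
#'   outer-training line -> inner fold index.
#' @slot seed the seed the plan was drawn with.
#' @export
setClass("FoldPlan",
         representation(outer = "integer", inner = "list", seed = "numeric"))

setValidity("FoldPlan", function(object) {
  k <- max(object@outer)
  sizes <- tabulate(object@outer, nbins = k)
  if (max(sizes) - min(sizes) > 1L)
    return("outer fold sizes must differ by at most 1")
  if (length(object@inner) != k)
    return("one inner partition per outer fold is required")
  for (f in seq_len(k)) {
    trainLines <- names(object@outer)[object@outer != f]
    inn <- object@inner[[f]]
    if (!setequal(names(inn), trainLines))
      return("inner folds must partition exactly the outer-training lines")
  }
  TRUE
})

#' Cross-validation evaluation report
#'
#' @slot metrics data.frame with columns scope, strategy, mse, seMse, nrmse,
#'   seNrmse (one row per scope x strategy; scope is an environment label or
#'   "Global").
#' @slot relEff data.frame with columns comparison, scope, reMse, reNrmse.
#' @export
setClass("EvaluationReport",
         representation(metrics = "data.frame", relEff = "data.frame"))

setValidity("EvaluationReport", function(object) {
  m <- object@metrics
  need <- c("scope", "strategy", "mse", "seMse", "nrmse", "seNrmse")
  if (!all(need %in% names(m))) return("metrics table is missing columns")
  if (any(m$mse < 0) || any(m$nrmse < 0)) return("metrics must be >= 0")
  if (nrow(object@relEff) > 0 &&
      any(object@relEff$reMse <= 0 | object@relEff$reNrmse <= 0))
    return("relative efficiencies must be positive")
  TRUE
})

#' Configuration of the synthetic-data generator
#'
#' Defines a population of J lines genotyped at p biallelic markers, with
#' genetic values drawn from a Gaussian-process prior under a Gaussian
#' kernel of known bandwidth rhoTrue, environment fixed effects,
#' Hadamard-structured genotype-by-environment effects and Gaussian noise.
#'
#' @slot J,p,I lines, markers, environments.
#' @slot rhoTrue generating bandwidth in (0, 1).
#' @slot varG,varGE,varE generating variance components.
#' @slot envEffects I environment fixed effects.
#' @slot mu intercept.
#' @slot design "all_lines_in_all_envs" or "lines_nested_in_envs".
#' @slot geneticModel "gp" (kernel Gaussian process) or "additive"
#'   (purely linear marker effects, a minimal-nonlinearity control).
#' @slot seed generator seed.
#' @export
setClass("SimulationConfig",
         representation(J = "numeric", p = "numeric", I = "numeric",
                        rhoTrue = "numeric", varG = "numeric",
                        varGE = "numeric", varE = "numeric",
                        envEffects = "numeric", mu = "numeric",
                        design = "character", geneticModel = "character",
                        seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@J < 14) return("need J >= 14 lines")
  if (object@rhoTrue <= 0 || object@rhoTrue >= 1)
    return("rhoTrue must lie in (0, 1)")
  v <- c(object@varG, object@varGE, object@varE)
  if (any(v < 0) || sum(v) <= 0)
    return("variances must be >= 0 with positive total")
  if (length(object@envEffects) != object@I)
    return("envEffects must have length I")
  if (!object@design %in% c("all_lines_in_all_envs", "lines_nested_in_envs"))
    return("unknown design")
  if (!object@geneticModel %in% c("gp", "additive"))
    return("geneticModel must be 'gp' or 'additive'")
  TRUE
})

#' Synthetic dataset with known generating truth
#'
#' @slot markers the simulated \linkS4class{MarkerMatrix}.
#' @slot phenotypes data.frame with columns line, env, value.
#' @slot truth list with the drawn g and gE vectors and the generating
#'   configuration.
#' @slot config the \linkS4class{SimulationConfig}.
#' @export
setClass("SyntheticDataset",
         representation(markers = "MarkerMatrix", phenotypes = "data.frame",
                        truth = "list", config = "SimulationConfig"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "MarkerMatrix", function(object) {
  G <- object@genotypes
  cat(sprintf("MarkerMatrix: %d lines x %d markers\n", nrow(G), ncol(G)))
})

setMethod("show", "KernelMatrix", function(object) {
  cat(sprintf("KernelMatrix: %d lines, %s\n", nrow(object@K),
              if (is.na(object@rho)) "linear GRM"
              else sprintf("Gaussian, rho = %.4g", object@rho)))
})

setMethod("show", "ModelFit", function(object) {
  cat("Kernel GBLUP fit (Gibbs)\n")
  cat(sprintf("  lines: %d  environments: %d  retained draws: %d\n",
              length(object@lineIds), length(object@envIds),
              nrow(object@samples)))
  cat(sprintf("  mu: %.4g  varG: %.4g  varGE: %.4g  varE: %.4g\n",
              object@muHat, object@varG, object@varGE, object@varE))
})

setMethod("show", "TuningResult", function(object) {
  cat(sprintf("TuningResult [%s]: selected rho = %.4g (%d evaluations, %d model fits)\n",
              object@strategy, object@selectedRho, nrow(object@evaluations),
              object@nModelFits))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  print(object@metrics, row.names = FALSE)
  if (nrow(object@relEff)) {
    cat("Relative efficiencies:\n")
    print(object@relEff, row.names = FALSE)
  }
})
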
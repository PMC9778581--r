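#' Draw a nested cross-validation fold plan
#'
#' Assigns lines (not records) to outer folds, so no genotype appears in
#' both training and testing, and draws one frozen inner partition of each
#' outer-training line set. When lines are nested in environments the
#' assignment is stratified by environment so every training set covers
#' every environment.
#'
#' @param phenotypes data.frame with columns line, env.
#' @param seed RNG seed for the plan.
#' @param nOuter,nInner numbers of outer and inner folds.
#' @return a \linkS4class{FoldPlan}.
#' @export
makeFoldPlan <- function(phenotypes, seed = 1, nOuter = 7, nInner = 5) {
  lines <- sort(unique(as.character(phenotypes$line)))
  if (length(lines) < 14)
    stop("need at least 14 distinct lines for a nested fold plan")
  lineEnv <- tapply(as.character(phenotypes$env), as.character(phenotypes$line),
                    function(e) paste(sort(unique(e)), collapse = ","))

  # stratified balanced assignment: within each stratum lines are shuffled,
  # then folds are dealt round-robin with a counter carried across strata,
  # so sizes differ by <= 1 both per stratum and globally
  assignStratified <- function(ids, k) {
    strata <- split(ids, lineEnv[ids])
    ordered <- unlist(lapply(strata, sample), use.names = FALSE)
    labels <- sample(seq_len(k))  # random fold rotation
    fold <- labels[(seq_along(ordered) - 1L) %% k + 1L]
    setNames(fold, ordered)[sort(ordered)]
  }

  withSeed <- function(s, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(s)
    expr
  }

  plan <- withSeed(seed, {
    outer <- assignStratified(lines, nOuter)
    inner <- lapply(seq_len(nOuter), function(f) {
      trainLines <- lines[outer[lines] != f]
      assignStratified(trainLines, nInner)
    })
    list(outer = outer, inner = inner)
  })
  new("FoldPlan", outer = plan$outer, inner = plan$inner, seed = seed)
}

## Internal: run one tuning strategy on one outer-training set.
tuneOuterFold <- function(strategy, trainPhenos, dist, innerFolds, spec,
                          grid, boBudget, outerFold) {
  switch(strategy,
         NT = noTuning(),
         GrS = gridSearch(trainPhenos, dist, innerFolds, spec, grid = grid,
                          outerFold = outerFold),
         BO = bayesOpt(trainPhenos, dist, innerFolds, spec, budget = boBudget,
                       outerFold = outerFold),
         stop("unknown strategy: ", strategy))
}

#' Run one tuning strategy through the nested cross-validation
#'
#' For each outer fold: tune the bandwidth on the outer-training set by
#' 5-fold inner CV (strategies "GrS" and "BO"; "NT" uses the fixed default),
#' refit the GBLUP on the full outer-training set at the selected
#' bandwidth with the outer-test records masked, and record the test-set
#' predictions. Every phenotype record is predicted exactly once across
#' folds.
#'
#' @param markers a \linkS4class{MarkerMatrix} covering all phenotyped lines.
#' @param phenotypes data.frame with columns line, env, value.
#' @param strategy "NT", "GrS" or "BO".
#' @param foldPlan a \linkS4class{FoldPlan}.
#' @param spec a \linkS4class{ModelSpec}; chain seeds for each fold are
#'   derived from its seed identically for every strategy.
#' @param grid grid-search candidates (default \code{\link{makeGrid}()}).
#' @param boBudget Bayesian-optimization evaluation budget.
#' @param dist optional precomputed \linkS4class{DistanceMatrix} over all
#'   lines.
#' @return list of per-fold results: each a list with \code{fold},
#'   \code{strategy}, \code{selectedRho}, \code{tuning} (the
#'   \linkS4class{TuningResult}) and \code{predictions} (line, env, yObs,
#'   yhat for the outer-test records).
#' @export
runStrategy <- function(markers, phenotypes, strategy, foldPlan,
                        spec = modelSpec(), grid = makeGrid(), boBudget = 22,
                        dist = NULL) {
  if (is.null(dist)) dist <- squaredDistanceMatrix(markers)
  phLines <- as.character(phenotypes$line)
  if (!all(phLines %in% lineIds(markers)))
    stop("markers are missing phenotyped lines: ",
         paste(setdiff(phLines, lineIds(markers)), collapse = ", "))
  nOuter <- max(foldPlan@outer)
  lapply(seq_len(nOuter), function(f) {
    testLines <- names(foldPlan@outer)[foldPlan@outer == f]
    isTest <- phLines %in% testLines
    trainPhenos <- phenotypes[!isTest, , drop = FALSE]
    testPhenos <- phenotypes[isTest, , drop = FALSE]
    missingEnv <- setdiff(unique(as.character(testPhenos$env)),
                          unique(as.character(trainPhenos$env)))
    if (length(missingEnv))
      stop("outer-training set of fold ", f,
           " lacks environment(s) present in its test set: ",
           paste(missingEnv, collapse = ", "))
    tuning <- tuneOuterFold(strategy, trainPhenos, dist, foldPlan@inner[[f]],
                            spec, grid, boBudget, f)
    rho <- tuning@selectedRho
    # refit on the full outer-training set, test records masked
    maskPhenos <- phenotypes
    maskPhenos$value[isTest] <- NA_real_
    K <- gaussianKernel(dist, rho)
    refitSpec <- new("ModelSpec", nIter = spec@nIter, burnIn = spec@burnIn,
                     thin = spec@thin, priorDf = spec@priorDf,
                     priorR2 = spec@priorR2,
                     seed = chainSeed(spec@seed, f, 99L))
    fit <- fitGibbs(maskPhenos, K, refitSpec)
    pred <- predict(fit, testPhenos[, c("line", "env")])
    pred$yObs <- testPhenos$value
    list(fold = f, strategy = strategy, selectedRho = rho, tuning = tuning,
         predictions = pred[, c("line", "env", "yObs", "yhat")])
  })
}

#' Run the full three-strategy comparison experiment
#'
#' Runs NT, GrS and BO through the same fold plan with identical chain
#' seeds (a paired design: differences between strategies reflect only the
#' selected bandwidth), then aggregates per-environment and Global metrics
#' and all pairwise relative efficiencies.
#'
#' @inheritParams runStrategy
#' @param strategies subset of c("NT", "GrS", "BO") to run.
#' @return list with \code{report} (an \linkS4class{EvaluationReport}),
#'   \code{folds} (per-strategy fold results) and \code{foldPlan}.
#' @export
runExperiment <- function(markers, phenotypes, foldPlan = NULL,
                          spec = modelSpec(), grid = makeGrid(),
                          boBudget = 22, seed = 1,
                          strategies = c("NT", "GrS", "BO")) {
  if (is.null(foldPlan)) foldPlan <- makeFoldPlan(phenotypes, seed = seed)
  dist <- squaredDistanceMatrix(markers)
  folds <- lapply(setNames(strategies, strategies), function(st)
    runStrategy(markers, phenotypes, st, foldPlan, spec = spec, grid = grid,
                boBudget = boBudget, dist = dist))
  list(report = summarizeFolds(folds), folds = folds, foldPlan = foldPlan)
}
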
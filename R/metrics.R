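#' Mean squared error
#' @param yObs,yHat equal-length numeric vectors of observed and predicted
#'   values.
#' @return mean of squared residuals.
#' @export
mse <- function(yObs, yHat) {
  if (length(yObs) == 0L) stop("empty input: MSE is undefined")
  if (length(yObs) != length(yHat))
    stop("observed and predicted vectors have different lengths")
  mean((yObs - yHat)^2)
}

#' Normalized root mean squared error
#'
#' RMSE divided by the mean of the observed values of the evaluation scope
#' (in absolute value, so the metric is non-negative).
#'
#' @inheritParams mse
#' @return sqrt(MSE) / |mean(yObs)|.
#' @export
nrmse <- function(yObs, yHat) {
  ybar <- mean(yObs)
  if (abs(ybar) < 1e-12)
    stop("NRMSE normalization failed: mean of observed values is zero")
  sqrt(mse(yObs, yHat)) / abs(ybar)
}

#' Relative efficiency of two error metrics
#'
#' Plain ratio numerator/denominator. Values above 1 mean the denominator
#' strategy predicts better (its error is smaller).
#'
#' @param metricNumerator,metricDenominator positive error metrics.
#' @return the ratio.
#' @export
relativeEfficiency <- function(metricNumerator, metricDenominator) {
  if (any(metricDenominator == 0)) stop("zero denominator in relative efficiency")
  metricNumerator / metricDenominator
}

## Internal: per-fold metric within one scope.
## predictions: data.frame(line, env, yObs, yhat)
scopeMetrics <- function(predictions, scope) {
  rows <- if (scope == "Global") predictions else
    predictions[predictions$env == scope, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  c(mse = mse(rows$yObs, rows$yhat), nrmse = nrmse(rows$yObs, rows$yhat))
}

#' Aggregate per-fold results into an evaluation report
#'
#' For every scope (each environment, plus "Global" which pools a fold's
#' predictions across environments) and every strategy, the metric is
#' computed per outer fold and then averaged; SE is the fold-to-fold
#' standard deviation divided by sqrt(number of folds). Relative
#' efficiencies (NT/BO, NT/GrS, GrS/BO, where present) are ratios of the
#' scope-level mean metrics.
#'
#' @param foldResults named list (strategy -> list of per-fold results).
#'   Each per-fold result is a list with element \code{predictions}, a
#'   data.frame with columns line, env, yObs, yhat.
#' @return an \linkS4class{EvaluationReport}.
#' @export
summarizeFolds <- function(foldResults) {
  strategies <- names(foldResults)
  nFolds <- unique(vapply(foldResults, length, integer(1)))
  if (length(nFolds) != 1L)
    stop("all strategies must carry the same number of folds")
  if (nFolds < 2L) stop("need at least 2 folds to aggregate")
  envs <- sort(unique(unlist(lapply(foldResults[[1]], function(fr)
    unique(as.character(fr$predictions$env))))))
  scopes <- c(envs, "Global")
  rows <- list()
  meanMetric <- list()
  for (sc in scopes) {
    for (st in strategies) {
      perFold <- lapply(foldResults[[st]], function(fr)
        scopeMetrics(fr$predictions, sc))
      perFold <- perFold[!vapply(perFold, is.null, logical(1))]
      if (length(perFold) == 0L)
        stop("scope ", sc, " has no predictions for strategy ", st)
      m <- do.call(rbind, perFold)
      nf <- nrow(m)
      rows[[length(rows) + 1L]] <- data.frame(
        scope = sc, strategy = st,
        mse = mean(m[, "mse"]), seMse = sd(m[, "mse"]) / sqrt(nf),
        nrmse = mean(m[, "nrmse"]), seNrmse = sd(m[, "nrmse"]) / sqrt(nf),
        stringsAsFactors = FALSE)
      meanMetric[[paste(sc, st, sep = "\r")]] <-
        c(mse = mean(m[, "mse"]), nrmse = mean(m[, "nrmse"]))
    }
  }
  comparisons <- list(c("NT", "BO"), c("NT", "GrS"), c("GrS", "BO"))
  re <- list()
  for (cmp in comparisons) {
    if (!all(cmp %in% strategies)) next
    for (sc in scopes) {
      a <- meanMetric[[paste(sc, cmp[1], sep = "\r")]]
      b <- meanMetric[[paste(sc, cmp[2], sep = "\r")]]
      re[[length(re) + 1L]] <- data.frame(
        comparison = paste(cmp, collapse = "/"), scope = sc,
        reMse = relativeEfficiency(a["mse"], b["mse"]),
        reNrmse = relativeEfficiency(a["nrmse"], b["nrmse"]),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  new("EvaluationReport",
      metrics = do.call(rbind, rows),
      relEff = if (length(re)) do.call(rbind, re) else
        data.frame(comparison = character(0), scope = character(0),
                   reMse = numeric(0), reNrmse = numeric(0)))
}
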
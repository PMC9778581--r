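#' Simulate biallelic marker genotypes
#'
#' Per-marker allele frequencies are drawn Uniform(0.05, 0.5) and genotypes
#' Binomial(2, freq) per line; monomorphic columns (zero sample variance)
#' are redrawn so every marker is informative.
#'
#' @param J number of lines (>= 2).
#' @param p number of markers (>= 10).
#' @param seed RNG seed.
#' @return a \linkS4class{MarkerMatrix} with lines named L001, L002, ...
#' @export
simulateMarkers <- function(J, p, seed = 1) {
  if (J < 2) stop("need J >= 2 lines")
  if (p < 10) stop("need p >= 10 markers")
  set.seed(seed)
  G <- matrix(0, J, p)
  for (j in seq_len(p)) {
    repeat {
      f <- runif(1, 0.05, 0.5)
      g <- rbinom(J, 2, f)
      if (var(g) > 0) break
    }
    G[, j] <- g
  }
  rownames(G) <- sprintf("L%03d", seq_len(J))
  colnames(G) <- sprintf("M%04d", seq_len(p))
  markerMatrix(G)
}

#' Synthetic-data generator configuration
#'
#' Defaults describe a grain-yield-like trial: an intercept of 5 (t/ha
#' scale), two environments with effects +-0.5, a dominant kernel line
#' variance and heritability 0.7.
#'
#' @param J,p,I lines, markers, environments.
#' @param rhoTrue generating Gaussian-kernel bandwidth.
#' @param varG,varGE,varE generating variance components.
#' @param envEffects environment fixed effects (length I).
#' @param mu intercept.
#' @param design "all_lines_in_all_envs" (every line phenotyped in every
#'   environment) or "lines_nested_in_envs" (each line in one environment,
#'   mimicking successive yield-trial cohorts).
#' @param geneticModel "gp" draws line effects from the Gaussian-process
#'   prior N(0, varG K(rhoTrue)); "additive" builds them as a linear
#'   combination of centered marker codes scaled to variance varG, a
#'   minimal-nonlinearity control.
#' @param seed generator seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simConfig <- function(J = 210, p = 100, I = 2, rhoTrue = 0.05,
                      varG = 1, varGE = 0.4, varE = 0.6,
                      envEffects = NULL, mu = 5,
                      design = "all_lines_in_all_envs",
                      geneticModel = "gp", seed = 1) {
  if (is.null(envEffects)) {
    envEffects <- if (I == 1) 0 else seq(-0.5, 0.5, length.out = I)
  }
  new("SimulationConfig", J = J, p = p, I = I, rhoTrue = rhoTrue,
      varG = varG, varGE = varGE, varE = varE, envEffects = envEffects,
      mu = mu, design = design, geneticModel = geneticModel, seed = seed)
}

#' Heritability implied by a generator configuration
#'
#' Broad-sense proportion (varG + varGE) / (varG + varGE + varE).
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return proportion in [0, 1].
#' @export
heritability <- function(cfg) {
  tot <- cfg@varG + cfg@varGE + cfg@varE
  if (tot <= 0) stop("total variance must be positive")
  (cfg@varG + cfg@varGE) / tot
}

#' Simulate phenotypes with kernel-structured genetics
#'
#' Builds the Gaussian kernel K at the generating bandwidth, draws line
#' effects g ~ N(0, varG K), genotype-by-environment effects
#' gE ~ N(0, varGE (Z_E Z_E' o Z_g K Z_g')) and Gaussian noise, and
#' assembles y = mu + E_i + g_j + gE_ij + eps_ij under the chosen trial
#' design.
#'
#' @param markers a \linkS4class{MarkerMatrix} with cfg@J lines.
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
simulatePhenotypes <- function(markers, cfg) {
  if (!is(markers, "MarkerMatrix")) stop("markers must be a MarkerMatrix")
  J <- nrow(markers@genotypes)
  if (J != cfg@J) stop("markers have ", J, " lines but cfg@J = ", cfg@J)
  set.seed(cfg@seed + 1)
  ids <- lineIds(markers)
  dist <- squaredDistanceMatrix(markers)
  K <- gaussianKernel(dist, cfg@rhoTrue)
  eig <- kernelEigen(K@K)
  sqd <- sqrt(eig$d)

  drawGP <- function(v) drop(eig$V %*% (sqd * rnorm(J, sd = sqrt(v))))

  g <- if (cfg@geneticModel == "gp") {
    drawGP(cfg@varG)
  } else {
    Gc <- scale(markers@genotypes, center = TRUE, scale = FALSE)
    beta <- rnorm(ncol(Gc))
    raw <- drop(Gc %*% beta)
    if (sd(raw) > 0) raw * sqrt(cfg@varG) / sd(raw) else raw
  }
  names(g) <- ids

  envIds <- sprintf("E%d", seq_len(cfg@I))
  envEff <- setNames(cfg@envEffects, envIds)

  if (cfg@design == "all_lines_in_all_envs") {
    lineOfRec <- rep(ids, cfg@I)
    envOfRec <- rep(envIds, each = J)
  } else {
    # each line appears in exactly one environment (cohort layout)
    envAssign <- sample(rep_len(envIds, J))
    lineOfRec <- ids
    envOfRec <- envAssign
  }
  n <- length(lineOfRec)

  # GxE: independent kernel draws per environment, restricted to the lines
  # present there (equivalent to one draw from varGE * Omega)
  gE <- numeric(n)
  for (e in envIds) {
    inEnv <- which(envOfRec == e)
    if (!length(inEnv)) next
    linesHere <- lineOfRec[inEnv]
    if (length(linesHere) == J) {
      u <- drawGP(cfg@varGE)
      gE[inEnv] <- u[match(linesHere, ids)]
    } else {
      Ksub <- K@K[linesHere, linesHere]
      es <- eigen(Ksub, symmetric = TRUE)
      dv <- pmax(es$values, 0)
      gE[inEnv] <- drop(es$vectors %*% (sqrt(dv) *
                                          rnorm(length(linesHere),
                                                sd = sqrt(cfg@varGE))))
    }
  }

  eps <- rnorm(n, sd = sqrt(cfg@varE))
  y <- cfg@mu + envEff[envOfRec] + g[lineOfRec] + gE + eps
  phenotypes <- data.frame(line = lineOfRec, env = envOfRec, value = unname(y),
                           stringsAsFactors = FALSE)
  new("SyntheticDataset", markers = markers, phenotypes = phenotypes,
      truth = list(g = g, gE = setNames(gE, paste(lineOfRec, envOfRec)),
                   rhoTrue = cfg@rhoTrue, varG = cfg@varG, varGE = cfg@varGE,
                   varE = cfg@varE, mu = cfg@mu, envEffects = envEff),
      config = cfg)
}

#' Simulate a complete dataset from a configuration
#'
#' Convenience wrapper: markers then phenotypes, both from cfg@seed.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
simulateDataset <- function(cfg) {
  markers <- simulateMarkers(cfg@J, cfg@p, seed = cfg@seed)
  simulatePhenotypes(markers, cfg)
}
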
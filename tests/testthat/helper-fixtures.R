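# Shared fixtures: small synthetic populations built in code.

# quick marker matrix with controllable seed
toyMarkers <- function(J = 20, p = 50, seed = 1) {
  simulateMarkers(J, p, seed = seed)
}

# small synthetic dataset for model-level tests
toyDataset <- function(J = 20, I = 2, rhoTrue = 0.2, varG = 1, varGE = 0.4,
                       varE = 0.6, seed = 1, ...) {
  simulateDataset(simConfig(J = J, p = 120, I = I, rhoTrue = rhoTrue,
                            varG = varG, varGE = varGE, varE = varE,
                            seed = seed, ...))
}

# short chains for unit tests
quickSpec <- function(seed = 1, nIter = 1500, burnIn = 500, thin = 2) {
  modelSpec(nIter = nIter, burnIn = burnIn, thin = thin, seed = seed)
}

# brute-force normalized squared distances (independent of the package path)
bruteDistances <- function(G) {
  Gc <- scale(G, center = TRUE, scale = FALSE)
  J <- nrow(G)
  D <- matrix(0, J, J)
  for (i in seq_len(J))
    for (j in seq_len(J))
      D[i, j] <- sum((Gc[i, ] - Gc[j, ])^2)
  off <- D[row(D) != col(D)]
  D / mean(off)
}
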
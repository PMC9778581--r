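# KernelGBLUP

Bandwidth tuning for Gaussian-kernel GBLUP genomic prediction with
genotype-by-environment interaction.

## What this package is for

Breeders and quantitative geneticists use genomic best linear unbiased
prediction (GBLUP) to predict the phenotypes of genotyped-but-unphenotyped
lines. Replacing the linear genomic relationship matrix with a Gaussian
kernel lets the model capture non-additive genetic signal, but introduces a
bandwidth hyperparameter that must be chosen well. This package implements
the full comparison of three bandwidth-selection strategies inside a
Bayesian GBLUP with G×E interaction:

* **NT** (no tuning): fix ρ = e⁻¹;
* **GrS** (grid search): evaluate 26 bandwidths on [0.01, 0.999];
* **BO** (Bayesian optimization): Gaussian-process surrogate with expected
  improvement, 22-evaluation budget;

each judged by 5-fold inner cross-validated NRMSE inside a 7-fold outer
cross-validation, with MSE/NRMSE and pairwise relative efficiencies
reported per environment and globally.

The model, for line *j* in environment *i*:

    Y_ij = mu + E_i + g_j + gE_ij + eps_ij,
    g  ~ N(0, sigma2_g * K),
    gE ~ N(0, sigma2_gE * (Z_E Z_E' ∘ Z_g K Z_g')),
    K(x_i, x_j) = rho^(||x_i - x_j||^2),   rho in (0, 1),

with marker distances normalized to mean 1 off-diagonal. Fitting is by a
Gibbs sampler that runs in the eigenbasis of K (one eigendecomposition per
kernel, shared across folds), with held-out records handled by data
augmentation. A synthetic-data generator draws marker panels and phenotypes
with this exact covariance structure at a *known* bandwidth, so the whole
pipeline is testable end to end without external data.

## Worked example

```r
library(KernelGBLUP)

# a small synthetic trial: 30 lines, 2 environments, true bandwidth 0.2
ds <- simulateDataset(simConfig(J = 30, p = 100, rhoTrue = 0.2, seed = 3))

# mask ten records, fit at the generating bandwidth, predict them
ph <- ds@phenotypes
set.seed(9); mask <- sample(nrow(ph), 10)
phTrain <- ph; phTrain$value[mask] <- NA

K <- gaussianKernel(squaredDistanceMatrix(ds@markers), rho = 0.2)
fit <- fitGibbs(phTrain, K, modelSpec(nIter = 6000, burnIn = 1000, seed = 11))
fit
#> Kernel GBLUP fit (Gibbs)
#>   lines: 30  environments: 2  retained draws: 1000
#>   mu: 5.3  varG: 0.6235  varGE: 0.4181  varE: 0.6428

pred <- predict(fit, ph[mask, c("line", "env")])
cor(pred$yhat, ph$value[mask])
#> [1] 0.6049764
```

The fit recovers an intercept near the generating value (5), posterior-mean
variance components of the right order (generating values 1, 0.4, 0.6), and
its masked-record predictions correlate 0.60 with the held-out phenotypes —
around what heritability 0.7 supports at this population size. On the same
fit, the posterior predictive means agree with the closed-form Gaussian
conditional mean (`conditionalMeanOracle`) to correlation 0.9999.

A full strategy comparison on one dataset:

```r
out <- runExperiment(ds@markers, ds@phenotypes, seed = 11,
                     spec = modelSpec(nIter = 3000, seed = 7))
out$report   # per-environment + Global MSE/NRMSE with SEs, and RE table
```

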
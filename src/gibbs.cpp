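#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Gibbs sampler for the kernel GBLUP
//
//   y_ij = mu + E_i + g_j + gE_ij + eps_ij
//   g  ~ N(0, varG * K),  gE ~ N(0, varGE * (Z_E Z_E' o Z_g K Z_g')),
//   eps ~ N(0, varE * I)
//
// The chain runs on the completed J x I line-by-environment grid: missing
// cells (prediction targets or absent records) are imputed each sweep
// (Bayesian data augmentation), so the complete-data likelihood is balanced
// and the whole model rotates into the eigenbasis of K. In rotated
// coordinates (ytil_i = V' y_i per environment) every full conditional is
// diagonal, so one sweep costs O(J * I) vector work plus the sparse
// re-rotation of imputed cells.
//
// Reproducibility: a self-contained xoshiro256++ generator seeded from the
// caller, so chains are bit-identical for a given seed regardless of R's
// global RNG state.

namespace {

struct Rng {
  uint64_t s[4];
  bool have_norm = false;
  double cached = 0.0;

  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // Marsaglia polar method
  inline double norm() {
    if (have_norm) {
      have_norm = false;
      return cached;
    }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cached = v * f;
    have_norm = true;
    return u * f;
  }

  // Marsaglia-Tsang
  double gamma(double a) {
    if (a < 1.0) {
      const double u = unif();
      return gamma(a + 1.0) * std::pow(u, 1.0 / a);
    }
    const double d = a - 1.0 / 3.0;
    const double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do {
        x = norm();
        v = 1.0 + c * x;
      } while (v <= 0.0);
      v = v * v * v;
      const double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }

  inline double chisq(double df) { return 2.0 * gamma(0.5 * df); }
};

}  // namespace

// [[Rcpp::export(name = ".gibbs_kernel_gblup")]]
Rcpp::List gibbs_kernel_gblup(const arma::mat& y,     // J x I grid, NA where masked
                              const arma::umat& mask, // J x I, 1 = masked cell
                              const arma::mat& V,     // eigenvectors of K (J x J)
                              const arma::vec& d,     // eigenvalues of K, >= 0
                              int nIter, int burnIn, int thin,
                              double priorDf, double Sg, double Sge, double Se,
                              double seed) {
  const arma::uword J = y.n_rows;
  const arma::uword I = y.n_cols;
  Rng rng(static_cast<uint64_t>(seed));

  // working rank: eigenpairs carrying genetic signal
  const double dmax = d.max();
  const double tol = dmax * 1e-10;
  arma::uword r = 0;
  for (arma::uword k = 0; k < J; ++k)
    if (d(k) > tol) ++r;
  const arma::vec dr = d.head(r);
  const arma::vec sqd = arma::sqrt(dr);

  // masked index sets per environment, with cached eigenvector rows
  std::vector<arma::uvec> miss(I);
  std::vector<arma::mat> Vm(I), VmT(I);
  for (arma::uword i = 0; i < I; ++i) {
    miss[i] = arma::find(mask.col(i) == 1);
    if (miss[i].n_elem > 0) {
      Vm[i] = V.rows(miss[i]);
      VmT[i] = Vm[i].t();
    }
  }

  // initial imputation: per-environment observed mean
  arma::mat ycur = y;
  for (arma::uword i = 0; i < I; ++i) {
    arma::uvec obs = arma::find(mask.col(i) == 0);
    double m0 = obs.n_elem > 0 ? arma::mean(ycur.elem(obs + i * J)) : 0.0;
    for (arma::uword t = 0; t < miss[i].n_elem; ++t) ycur(miss[i](t), i) = m0;
  }

  arma::mat ytil = V.t() * ycur;          // rotated grid
  const arma::vec v1 = V.t() * arma::ones<arma::vec>(J);

  // state
  arma::vec a(I);                         // per-environment intercept mu + E_i
  for (arma::uword i = 0; i < I; ++i) a(i) = arma::mean(ycur.col(i));
  arma::vec b(r, arma::fill::zeros);      // line-effect coordinates, Var = varG
  arma::mat U(r, I, arma::fill::zeros);   // GxE coordinates, Var = varGE * d_k
  double varG = Sg, varGE = Sge, varE = Se;

  const int nSave = (nIter - burnIn) / thin;
  arma::mat varSamp(nSave > 0 ? nSave : 0, 3);
  arma::mat aSamp(nSave > 0 ? nSave : 0, I);
  arma::mat fAcc(J, I, arma::fill::zeros); // accumulated rotated fitted surface
  int saved = 0;

  arma::vec gtil(J, arma::fill::zeros);   // rotated g (zero beyond rank r)
  arma::mat ftil(J, I);

  for (int it = 1; it <= nIter; ++it) {
    gtil.head(r) = sqd % b;

    // --- per-environment intercepts a_i = mu + E_i (flat prior) ---
    for (arma::uword i = 0; i < I; ++i) {
      double dotv = 0.0;
      for (arma::uword k = 0; k < J; ++k) {
        double e = ytil(k, i) - gtil(k);
        if (k < r) e -= U(k, i);
        dotv += v1(k) * e;
      }
      a(i) = dotv / static_cast<double>(J) +
             rng.norm() * std::sqrt(varE / static_cast<double>(J));
    }

    // --- line-effect coordinates b_k ---
    for (arma::uword k = 0; k < r; ++k) {
      double num = 0.0;
      for (arma::uword i = 0; i < I; ++i)
        num += ytil(k, i) - v1(k) * a(i) - U(k, i);
      const double prec = static_cast<double>(I) * dr(k) / varE + 1.0 / varG;
      const double mean = sqd(k) * num / varE / prec;
      b(k) = mean + rng.norm() / std::sqrt(prec);
    }
    gtil.head(r) = sqd % b;

    // --- GxE coordinates U_ki, prior Var = varGE * d_k ---
    for (arma::uword i = 0; i < I; ++i) {
      for (arma::uword k = 0; k < r; ++k) {
        const double resid = ytil(k, i) - v1(k) * a(i) - gtil(k);
        const double prec = 1.0 / varE + 1.0 / (varGE * dr(k));
        const double mean = resid / varE / prec;
        U(k, i) = mean + rng.norm() / std::sqrt(prec);
      }
    }

    // --- variance components: scaled-inverse-chi-square full conditionals ---
    const double SSg = arma::dot(b, b);
    varG = (priorDf * Sg + SSg) / rng.chisq(priorDf + static_cast<double>(r));

    double SSge = 0.0;
    for (arma::uword i = 0; i < I; ++i)
      for (arma::uword k = 0; k < r; ++k) SSge += U(k, i) * U(k, i) / dr(k);
    varGE = (priorDf * Sge + SSge) /
            rng.chisq(priorDf + static_cast<double>(r * I));

    double SSe = 0.0;
    for (arma::uword i = 0; i < I; ++i) {
      for (arma::uword k = 0; k < J; ++k) {
        double e = ytil(k, i) - v1(k) * a(i) - gtil(k);
        if (k < r) e -= U(k, i);
        SSe += e * e;
      }
    }
    varE = (priorDf * Se + SSe) / rng.chisq(priorDf + static_cast<double>(J * I));

    // --- rotated fitted surface and imputation of masked cells ---
    for (arma::uword i = 0; i < I; ++i) {
      for (arma::uword k = 0; k < J; ++k) {
        double f = v1(k) * a(i) + gtil(k);
        if (k < r) f += U(k, i);
        ftil(k, i) = f;
      }
      const arma::uvec& m = miss[i];
      if (m.n_elem > 0) {
        arma::vec fm = Vm[i] * ftil.col(i);
        arma::vec delta(m.n_elem);
        const double sde = std::sqrt(varE);
        for (arma::uword t = 0; t < m.n_elem; ++t) {
          const double ynew = fm(t) + rng.norm() * sde;
          delta(t) = ynew - ycur(m(t), i);
          ycur(m(t), i) = ynew;
        }
        ytil.col(i) += VmT[i] * delta;
      }
    }

    if (it > burnIn && (it - burnIn) % thin == 0 && saved < nSave) {
      varSamp(saved, 0) = varG;
      varSamp(saved, 1) = varGE;
      varSamp(saved, 2) = varE;
      aSamp.row(saved) = a.t();
      fAcc += ftil;
      ++saved;
    }
  }

  arma::mat fitted = V * (fAcc / std::max(saved, 1)); // posterior-mean surface

  return Rcpp::List::create(
      Rcpp::Named("fitted") = fitted,
      Rcpp::Named("varSamples") = varSamp,
      Rcpp::Named("aSamples") = aSamp,
      Rcpp::Named("nSaved") = saved);
}
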
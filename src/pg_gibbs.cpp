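// Polya-Gamma augmented Gibbs sampler for the multinomial logistic
// transition model. PG(1, z) draws use the exact alternating-series
// rejection sampler (Devroye-type), valid for all real z; draws consume
// R's RNG stream so set.seed() governs the whole fit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PG_TRUNC = 0.64;

// piecewise coefficients of the alternating series bounding the J*(1,.) density
static inline double a_coef(int n, double x) {
  double np = n + 0.5;
  if (x > PG_TRUNC)
    return M_PI * np * std::exp(-np * np * M_PI * M_PI * 0.5 * x);
  return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np * np / x);
}

// log P(InverseGaussian(mu = 1/z, lambda = 1) <= t), safe for large z
static inline double log_pigauss(double t, double z) {
  double rt = std::sqrt(1.0 / t);
  double lb = R::pnorm(rt * (t * z - 1.0), 0.0, 1.0, 1, 1);
  double la = 2.0 * z + R::pnorm(-rt * (t * z + 1.0), 0.0, 1.0, 1, 1);
  // log(exp(lb) + exp(la))
  double m = std::max(lb, la);
  return m + std::log(std::exp(lb - m) + std::exp(la - m));
}

// inverse-Gaussian(1/z, 1) truncated to (0, t); z >= 0
static inline double rtigauss(double z, double t) {
  double x;
  if (z == 0.0 || 1.0 / z > t) {
    // mu > t: one-sided sampler via inverted-chi-square proposal
    while (true) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  } else {
    double mu = 1.0 / z;
    while (true) {
      double y = R::norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
      if (x <= t) return x;
    }
  }
}

// one exact PG(1, z) draw
static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double K = M_PI * M_PI * 0.125 + 0.5 * z * z;
  // mixture weights of the two proposal pieces, in logs for large |z|
  double logp = std::log(M_PI_2 / K) - K * PG_TRUNC;
  double logq = M_LN2 - z + log_pigauss(PG_TRUNC, z);
  double ratio = 1.0 / (1.0 + std::exp(logq - logp));
  while (true) {
    double x;
    if (R::unif_rand() < ratio)
      x = PG_TRUNC + R::exp_rand() / K;
    else
      x = rtigauss(z, PG_TRUNC);
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    bool accept = false, reject = false;
    while (!accept && !reject) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) accept = true;
      } else {
        s += a_coef(n, x);
        if (y > s) reject = true;
      }
    }
    if (accept) return 0.25 * x;
  }
}

//' @name rpolyagamma
//' @keywords internal
// [[Rcpp::export(rpolyagamma)]]
NumericVector rpolyagamma(int n, NumericVector z) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i % z.size()]);
  return out;
}

struct DestBlock {
  int j;               // destination habitat, 0-based
  int offset;          // into the slope/intercept parameter vector
  int size;            // block dimension
  arma::ivec intPos;   // per region, position in block or -1
  arma::ivec timePos;  // positions of cos/sin slopes (may be empty)
  arma::ivec timeCov;  // covariate columns for those (0 = cos, 1 = sin)
  arma::ivec slopePos; // per from-habitat, base position or -1
  arma::ivec slopeCov; // covariate columns (2..5) per parameterized pair
  std::vector<int> elig; // eligible record indices
  int nInt;
};

// [[Rcpp::export]]
List pgGibbsCpp(const IntegerVector& from, const IntegerVector& to,
                const IntegerVector& region, const NumericMatrix& X,
                const LogicalVector& maskArr, int H, int R, int jb,
                const List& layout, NumericVector thetaInit,
                NumericVector hyperInit, double vInt, double vHyper,
                double vSlope, int nIter, int burnIn,
                const CharacterVector& destNames) {
  const int N = from.size();
  const int nDest = layout.size();
  auto maskAt = [&](int r, int i, int j) -> bool {
    return maskArr[r + R * i + (R * H) * j] != 0;
  };

  std::vector<DestBlock> blocks(nDest);
  int P = 0;
  for (int d = 0; d < nDest; ++d) {
    List L = layout[d];
    DestBlock& b = blocks[d];
    b.j = as<int>(L["j"]);
    b.offset = as<int>(L["offset"]);
    b.size = as<int>(L["size"]);
    b.intPos = as<arma::ivec>(L["intPos"]);
    b.timePos = as<arma::ivec>(L["timePos"]);
    b.timeCov = as<arma::ivec>(L["timeCov"]);
    b.slopePos = as<arma::ivec>(L["slopePos"]);
    b.slopeCov = as<arma::ivec>(L["slopeCov"]);
    b.nInt = 0;
    for (int r = 0; r < R; ++r) if (b.intPos[r] >= 0) ++b.nInt;
    for (int n = 0; n < N; ++n)
      if (maskAt(region[n], from[n], b.j)) b.elig.push_back(n);
    P = std::max(P, b.offset + b.size);
  }

  // allowed destination list per record
  std::vector<std::vector<int> > allowed(N);
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < H; ++j)
      if (maskAt(region[n], from[n], j)) allowed[n].push_back(j);
    if (allowed[n].empty()) stop("record with no allowed destination");
  }

  arma::vec theta(thetaInit.begin(), P);
  arma::vec hyper(hyperInit.begin(), H);

  // sparse per-record design row for a destination block
  const int MAXNZ = 8;
  int idx[MAXNZ];
  double val[MAXNZ];

  // linear predictor cache; baseline column stays 0
  arma::mat eta(N, H, arma::fill::zeros);
  auto etaRecompute = [&](const DestBlock& b) {
    for (size_t q = 0; q < b.elig.size(); ++q) {
      int n = b.elig[q];
      double e = 0.0;
      int ip = b.intPos[region[n]];
      if (ip >= 0) e += theta[b.offset + ip];
      for (arma::uword k = 0; k < b.timePos.n_elem; ++k)
        e += theta[b.offset + b.timePos[k]] * X(n, b.timeCov[k]);
      int sp = b.slopePos[from[n]];
      if (sp >= 0)
        for (arma::uword k = 0; k < b.slopeCov.n_elem; ++k)
          e += theta[b.offset + sp + k] * X(n, b.slopeCov[k]);
      eta(n, b.j) = e;
    }
  };
  for (int d = 0; d < nDest; ++d) etaRecompute(blocks[d]);

  const int nKeep = nIter - burnIn;
  arma::mat thetaDraws(nKeep, P);
  arma::mat hyperDraws(nKeep, nDest);
  arma::vec llTrace(nKeep);

  for (int iter = 0; iter < nIter; ++iter) {
    for (int d = 0; d < nDest; ++d) {
      const DestBlock& b = blocks[d];
      const int Pj = b.size;
      arma::mat A(Pj, Pj, arma::fill::zeros);
      arma::vec bb(Pj, arma::fill::zeros);
      for (size_t q = 0; q < b.elig.size(); ++q) {
        int n = b.elig[q];
        // offset c = log-sum-exp of competing destinations' predictors
        double m = -std::numeric_limits<double>::infinity();
        const std::vector<int>& al = allowed[n];
        for (size_t a = 0; a < al.size(); ++a)
          if (al[a] != b.j && eta(n, al[a]) > m) m = eta(n, al[a]);
        double sum = 0.0;
        for (size_t a = 0; a < al.size(); ++a)
          if (al[a] != b.j) sum += std::exp(eta(n, al[a]) - m);
        double c = m + std::log(sum);
        double psi = eta(n, b.j) - c;
        double om = rpg1(psi);
        double kappa = ((to[n] == b.j) ? 0.5 : -0.5) + om * c;
        // sparse design row
        int cnt = 0;
        int ip = b.intPos[region[n]];
        if (ip >= 0) { idx[cnt] = ip; val[cnt] = 1.0; ++cnt; }
        for (arma::uword k = 0; k < b.timePos.n_elem; ++k) {
          idx[cnt] = b.timePos[k]; val[cnt] = X(n, b.timeCov[k]); ++cnt;
        }
        int sp = b.slopePos[from[n]];
        if (sp >= 0)
          for (arma::uword k = 0; k < b.slopeCov.n_elem; ++k) {
            idx[cnt] = sp + (int)k; val[cnt] = X(n, b.slopeCov[k]); ++cnt;
          }
        for (int a = 0; a < cnt; ++a) {
          bb[idx[a]] += val[a] * kappa;
          for (int a2 = a; a2 < cnt; ++a2) {
            double inc = om * val[a] * val[a2];
            A(idx[a], idx[a2]) += inc;
          }
        }
      }
      // symmetrize and add priors
      for (int a = 0; a < Pj; ++a)
        for (int a2 = a + 1; a2 < Pj; ++a2) A(a2, a) = A(a, a2);
      for (int r = 0; r < R; ++r) {
        int ip = b.intPos[r];
        if (ip >= 0) { A(ip, ip) += 1.0 / vInt; bb[ip] += hyper[b.j] / vInt; }
      }
      for (arma::uword k = 0; k < b.timePos.n_elem; ++k)
        A(b.timePos[k], b.timePos[k]) += 1.0 / vSlope;
      for (int i = 0; i < H; ++i) {
        int sp = b.slopePos[i];
        if (sp >= 0)
          for (arma::uword k = 0; k < b.slopeCov.n_elem; ++k)
            A(sp + k, sp + k) += 1.0 / vSlope;
      }
      arma::mat Lc;
      if (!arma::chol(Lc, A, "lower"))
        stop("singular conditional precision in coefficient block for "
             "destination '%s'", std::string(destNames[d]));
      arma::vec mu = arma::solve(arma::trimatu(Lc.t()),
                                 arma::solve(arma::trimatl(Lc), bb));
      arma::vec zv(Pj);
      for (int a = 0; a < Pj; ++a) zv[a] = R::norm_rand();
      arma::vec beta = mu + arma::solve(arma::trimatu(Lc.t()), zv);
      for (int a = 0; a < Pj; ++a) theta[b.offset + a] = beta[a];
      etaRecompute(b);
      // conjugate Normal update of the intercept hyper-mean
      double s = 0.0;
      for (int r = 0; r < R; ++r)
        if (b.intPos[r] >= 0) s += theta[b.offset + b.intPos[r]];
      double prec = b.nInt / vInt + 1.0 / vHyper;
      hyper[b.j] = s / vInt / prec + R::norm_rand() / std::sqrt(prec);
    }
    if (iter >= burnIn) {
      int kr = iter - burnIn;
      thetaDraws.row(kr) = theta.t();
      for (int d = 0; d < nDest; ++d) hyperDraws(kr, d) = hyper[blocks[d].j];
      double ll = 0.0;
      for (int n = 0; n < N; ++n) {
        const std::vector<int>& al = allowed[n];
        double m = 0.0;
        for (size_t a = 0; a < al.size(); ++a)
          if (eta(n, al[a]) > m) m = eta(n, al[a]);
        double sum = 0.0;
        for (size_t a = 0; a < al.size(); ++a)
          sum += std::exp(eta(n, al[a]) - m);
        ll += eta(n, to[n]) - m - std::log(sum);
      }
      llTrace[kr] = ll;
    }
  }

  return List::create(_["theta"] = wrap(thetaDraws),
                      _["hyper"] = wrap(hyperDraws),
                      _["logLik"] = wrap(llTrace));
}
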
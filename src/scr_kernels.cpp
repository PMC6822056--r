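// Hot kernels for the bilateral partial-identity SCR sampler:
// per-individual likelihood factors, the Metropolis-within-Gibbs sweep
// (scalars -> activity centers -> z -> u -> identity permutation), draw scans
// used by the MAP search, and posterior-predictive replicate accumulation.
//
// All randomness goes through R's RNG (unif_rand / norm_rand), so chains are
// reproducible from set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// 0*log(0) = 0; positive count against zero probability is a structural zero
static inline double xlogy(double x, double y) {
  if (x == 0.0) return 0.0;
  if (y <= 0.0) return NEG_INF;
  return x * std::log(std::max(y, 1e-300));
}

static inline double logistic(double t) { return 1.0 / (1.0 + std::exp(-t)); }

struct Pars {
  double psi, theta, phi, omega0, p0, sigM, sigF;
};

// Shared data and model constants for one fit
struct ScrCtx {
  int M, J, K, model;
  bool twoStage, sexed;
  double R;
  arma::mat C1, C2;          // M x J per-row per-trap counts
  arma::vec rt1, rt2;        // per-row totals
  arma::ivec obsIdx1, obsIdx2; // row -> index into overlap cube, or -1
  arma::cube ov;             // overlap counts, observed det1 x det2 x trap
  arma::mat traps;           // J x 2
  double x0, x1, y0, y1;     // state-space bounds
  arma::ivec sex1, sex2;     // recorded sex per row, -1 = unknown

  int nPar() const {
    switch (model) {
      case 1: return 6; case 2: return 5; case 3: return 4; default: return 3;
    }
  }

  Pars decode(const arma::vec& tp) const {
    Pars P; int k = 0;
    P.psi = logistic(tp[k++]);
    P.theta = 0.5; P.phi = 0.5; P.omega0 = 0.5; P.p0 = 0.5;
    if (sexed) P.theta = logistic(tp[k++]);
    if (twoStage) { P.phi = logistic(tp[k++]); P.omega0 = logistic(tp[k++]); }
    else P.p0 = logistic(tp[k++]);
    if (sexed) { P.sigM = R * logistic(tp[k++]); P.sigF = R * logistic(tp[k++]); }
    else { P.sigM = P.sigF = R * logistic(tp[k++]); }
    return P;
  }

  arma::vec natural(const arma::vec& tp) const {
    Pars P = decode(tp);
    arma::vec out(nPar()); int k = 0;
    out[k++] = P.psi;
    if (sexed) out[k++] = P.theta;
    if (twoStage) { out[k++] = P.phi; out[k++] = P.omega0; }
    else out[k++] = P.p0;
    out[k++] = P.sigM;
    if (sexed) out[k++] = P.sigF;
    return out;
  }

  double overlap(int i, int r, int j) const {
    int a = obsIdx1[i], b = obsIdx2[r];
    if (a < 0 || b < 0) return 0.0;
    return ov(a, b, j);
  }

  bool hasData(int i, int r) const { return rt1[i] > 0 || rt2[r] > 0; }

  // detection factor for slot i holding detector-2 row r, given z = 1
  double detLL(int i, int r, int ui, const Pars& P, const double* d2) const {
    double sig = sexed ? (ui ? P.sigM : P.sigF) : P.sigM;
    double inv2s2 = 1.0 / (2.0 * sig * sig);
    double ll = 0.0;
    if (twoStage) {
      double omf = 1.0 - P.phi, omf2 = (1.0 - P.phi) * (1.0 - P.phi);
      double ydd = rt1[i] + rt2[r], ndot = 0.0;
      for (int j = 0; j < J; ++j) {
        double eta = P.omega0 * std::exp(-d2[j] * inv2s2);
        double nij = C1(i, j) + C2(r, j) - overlap(i, r, j);
        ndot += nij;
        ll += xlogy(nij, eta) + xlogy(K - nij, (1.0 - eta) + eta * omf2);
      }
      ll += xlogy(ydd, P.phi) + xlogy(2.0 * ndot - ydd, omf);
    } else {
      for (int j = 0; j < J; ++j) {
        double p = P.p0 * std::exp(-d2[j] * inv2s2);
        double yij = C1(i, j) + C2(r, j);
        ll += xlogy(yij, p) + xlogy(2.0 * K - yij, 1.0 - p);
      }
    }
    return ll;
  }

  double sexPart(int i, int r, int ui, const Pars& P) const {
    if (!sexed) return 0.0;
    if (sex1[i] >= 0 && sex1[i] != ui) return NEG_INF;
    if (sex2[r] >= 0 && sex2[r] != ui) return NEG_INF;
    return ui ? std::log(P.theta) : std::log(1.0 - P.theta);
  }

  // full per-slot log factor
  double indivLL(int i, int r, int zi, int ui, const Pars& P,
                 const double* d2) const {
    double sp = sexPart(i, r, ui, P);
    if (!std::isfinite(sp)) return sp;
    if (zi == 0) return hasData(i, r) ? NEG_INF : sp;
    return sp + detLL(i, r, ui, P, d2);
  }
};

static ScrCtx buildCtx(const List& d) {
  ScrCtx c;
  c.M = as<int>(d["M"]); c.J = as<int>(d["J"]); c.K = as<int>(d["K"]);
  c.model = as<int>(d["model"]);
  c.twoStage = (c.model == 1 || c.model == 3);
  c.sexed = (c.model == 1 || c.model == 2);
  c.R = as<double>(d["R"]);
  c.C1 = as<arma::mat>(d["C1"]); c.C2 = as<arma::mat>(d["C2"]);
  c.rt1 = arma::sum(c.C1, 1); c.rt2 = arma::sum(c.C2, 1);
  c.obsIdx1 = as<arma::ivec>(d["obsIdx1"]);
  c.obsIdx2 = as<arma::ivec>(d["obsIdx2"]);
  c.ov = as<arma::cube>(d["ov"]);
  c.traps = as<arma::mat>(d["traps"]);
  NumericVector b = d["bounds"];
  c.x0 = b[0]; c.x1 = b[1]; c.y0 = b[2]; c.y1 = b[3];
  c.sex1 = as<arma::ivec>(d["sex1"]); c.sex2 = as<arma::ivec>(d["sex2"]);
  return c;
}

static arma::mat sqDistances(const arma::mat& S, const arma::mat& traps) {
  int M = S.n_rows, J = traps.n_rows;
  arma::mat D2(M, J);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < J; ++j) {
      double dx = S(i, 0) - traps(j, 0), dy = S(i, 1) - traps(j, 1);
      D2(i, j) = dx * dx + dy * dy;
    }
  return D2;
}

static inline double reflect(double v, double lo, double hi) {
  double range = hi - lo, period = 2.0 * range;
  double t = v - lo;
  t -= period * std::floor(t / period); // t in [0, period)
  return lo + (t <= range ? t : period - t);
}

// log prior of the transformed scalars (uniforms + logit Jacobians)
static double tPrior(const arma::vec& tp) {
  double s = 0.0;
  for (arma::uword k = 0; k < tp.n_elem; ++k) {
    double l = logistic(tp[k]);
    s += std::log(l) + std::log(1.0 - l);
  }
  return s;
}

static double zPrior(double psi, int Nz, int M) {
  return Nz * std::log(psi) + (M - Nz) * std::log(1.0 - psi);
}

// one sweep of identity-permutation proposals; returns acceptances
static int permSweep(const ScrCtx& c, const Pars& P, const arma::mat& D2,
                     const arma::ivec& z, const arma::ivec& u,
                     arma::ivec& arow, arma::ivec& slotOf, arma::vec& llInd,
                     double& llTot, const arma::ivec& freeRows,
                     const arma::ivec& freeSlots, int nProp) {
  int nr = freeRows.n_elem, ns = freeSlots.n_elem, acc = 0;
  if (nr == 0 || ns < 2) return 0;
  for (int t = 0; t < nProp; ++t) {
    int r = freeRows[(int)(unif_rand() * nr)];
    int i2 = freeSlots[(int)(unif_rand() * ns)];
    int i1 = slotOf[r];
    if (i1 == i2) { ++acc; continue; }
    int r2 = arow[i2];
    arma::rowvec d1 = D2.row(i1), d2v = D2.row(i2);
    double ll1n = c.indivLL(i1, r2, z[i1], u[i1], P, d1.memptr());
    double ll2n = c.indivLL(i2, r, z[i2], u[i2], P, d2v.memptr());
    double logA = ll1n + ll2n - llInd[i1] - llInd[i2];
    if (std::log(unif_rand()) < logA) {
      arow[i1] = r2; arow[i2] = r;
      slotOf[r2] = i1; slotOf[r] = i2;
      llTot += (ll1n - llInd[i1]) + (ll2n - llInd[i2]);
      llInd[i1] = ll1n; llInd[i2] = ll2n;
      ++acc;
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_indiv_loglik(List dataList, NumericVector tp,
                               IntegerVector z, IntegerVector u,
                               NumericMatrix S, IntegerVector arow) {
  ScrCtx c = buildCtx(dataList);
  Pars P = c.decode(as<arma::vec>(tp));
  arma::mat Sm = as<arma::mat>(S);
  arma::mat D2 = sqDistances(Sm, c.traps);
  NumericVector out(c.M);
  for (int i = 0; i < c.M; ++i) {
    arma::rowvec d = D2.row(i);
    out[i] = c.indivLL(i, arow[i], z[i], u[i], P, d.memptr());
  }
  return out;
}

// total log f(Y | mu_p^(d), fixed latents) across scalar draws
// [[Rcpp::export]]
NumericVector cpp_scalar_scan(List dataList, NumericMatrix tDraws,
                              IntegerVector z, IntegerVector u,
                              NumericMatrix S, IntegerVector arow) {
  ScrCtx c = buildCtx(dataList);
  arma::mat Sm = as<arma::mat>(S);
  arma::mat D2 = sqDistances(Sm, c.traps);
  int n = tDraws.nrow();
  NumericVector out(n);
  for (int d = 0; d < n; ++d) {
    arma::vec tp(tDraws.ncol());
    for (int k = 0; k < tDraws.ncol(); ++k) tp[k] = tDraws(d, k);
    Pars P = c.decode(tp);
    double tot = 0.0;
    for (int i = 0; i < c.M; ++i) {
      arma::rowvec dr = D2.row(i);
      tot += c.indivLL(i, arow[i], z[i], u[i], P, dr.memptr());
      if (!std::isfinite(tot)) break;
    }
    out[d] = tot;
  }
  return out;
}

// total log f(Y | fixed mu_p, mu_s^(d)) across latent draws
// [[Rcpp::export]]
NumericVector cpp_latent_scan(List dataList, NumericVector tp,
                              IntegerMatrix zDraws, IntegerMatrix uDraws,
                              IntegerMatrix arowDraws, NumericVector sDraws) {
  ScrCtx c = buildCtx(dataList);
  Pars P = c.decode(as<arma::vec>(tp));
  IntegerVector dims = sDraws.attr("dim"); // n x M x 2
  int n = dims[0], M = dims[1];
  NumericVector out(n);
  arma::mat S(M, 2);
  for (int d = 0; d < n; ++d) {
    for (int i = 0; i < M; ++i) {
      S(i, 0) = sDraws[d + n * i];
      S(i, 1) = sDraws[d + n * i + (long)n * M];
    }
    arma::mat D2 = sqDistances(S, c.traps);
    double tot = 0.0;
    for (int i = 0; i < M; ++i) {
      arma::rowvec dr = D2.row(i);
      tot += c.indivLL(i, arowDraws(d, i), zDraws(d, i), uDraws(d, i), P,
                       dr.memptr());
      if (!std::isfinite(tot)) break;
    }
    out[d] = tot;
  }
  return out;
}

// standalone identity-permutation sweep (same kernel the chain uses)
// [[Rcpp::export]]
List cpp_perm_sweep(List dataList, NumericVector tp, IntegerVector z,
                    IntegerVector u, NumericMatrix S, IntegerVector arow,
                    IntegerVector freeRows, IntegerVector freeSlots,
                    int nProposals) {
  ScrCtx c = buildCtx(dataList);
  Pars P = c.decode(as<arma::vec>(tp));
  arma::mat Sm = as<arma::mat>(S);
  arma::mat D2 = sqDistances(Sm, c.traps);
  arma::ivec ar = as<arma::ivec>(arow);
  arma::ivec slotOf(c.M);
  for (int i = 0; i < c.M; ++i) slotOf[ar[i]] = i;
  arma::vec llInd(c.M);
  double llTot = 0.0;
  for (int i = 0; i < c.M; ++i) {
    arma::rowvec d = D2.row(i);
    llInd[i] = c.indivLL(i, ar[i], z[i], u[i], P, d.memptr());
    llTot += llInd[i];
  }
  int acc = permSweep(c, P, D2, as<arma::ivec>(z), as<arma::ivec>(u), ar,
                      slotOf, llInd, llTot,
                      as<arma::ivec>(freeRows), as<arma::ivec>(freeSlots),
                      nProposals);
  return List::create(_["arow"] = wrap(ar), _["llInd"] = wrap(llInd),
                      _["accepted"] = acc);
}

// [[Rcpp::export]]
List cpp_run_chain(List dataList, List init, List conf) {
  ScrCtx c = buildCtx(dataList);
  const int M = c.M;

  arma::vec tp = as<arma::vec>(init["tp"]);
  arma::ivec z = as<arma::ivec>(init["z"]);
  arma::ivec u = as<arma::ivec>(init["u"]);
  arma::mat S = as<arma::mat>(init["S"]);
  arma::ivec arow = as<arma::ivec>(init["arow"]);

  const int nIter = as<int>(conf["nIter"]);
  const int burnIn = as<int>(conf["burnIn"]);
  const int thin = as<int>(conf["thin"]);
  arma::vec scales = as<arma::vec>(conf["scales"]);
  double sScale = as<double>(conf["sScale"]);
  arma::ivec fixedPar = as<arma::ivec>(conf["fixed"]);
  const bool adapt = as<bool>(conf["adapt"]);
  const bool storeLatents = as<bool>(conf["storeLatents"]);
  const bool updateS = as<bool>(conf["updateS"]);
  const bool updateZ = as<bool>(conf["updateZ"]);
  const bool updateU = as<bool>(conf["updateU"]);
  const bool updateL = as<bool>(conf["updateL"]);
  const int nPerm = as<int>(conf["nPerm"]);
  arma::ivec freeRows = as<arma::ivec>(conf["freeRows"]);
  arma::ivec freeSlots = as<arma::ivec>(conf["freeSlots"]);

  const int p = c.nPar();
  arma::ivec slotOf(M);
  for (int i = 0; i < M; ++i) slotOf[arow[i]] = i;
  arma::mat D2 = sqDistances(S, c.traps);

  Pars P = c.decode(tp);
  arma::vec llInd(M);
  double llTot = 0.0;
  for (int i = 0; i < M; ++i) {
    arma::rowvec d = D2.row(i);
    llInd[i] = c.indivLL(i, arow[i], z[i], u[i], P, d.memptr());
    llTot += llInd[i];
  }
  if (!std::isfinite(llTot))
    stop("non-finite log-likelihood at initialization");
  int Nz = arma::accu(z);

  const int nRet = (nIter - burnIn + thin - 1) / thin;
  arma::mat tDraws(nRet, p), npDraws(nRet, p);
  arma::vec llDraws(nRet), NDraws(nRet);
  arma::mat indivDraws(nRet, M);
  IntegerMatrix zDraws(storeLatents ? nRet : 0, storeLatents ? M : 0);
  IntegerMatrix uDraws(storeLatents ? nRet : 0, storeLatents ? M : 0);
  IntegerMatrix LDraws(storeLatents ? nRet : 0, storeLatents ? M : 0);
  NumericVector sDraws(storeLatents ? (R_xlen_t)nRet * M * 2 : 0);

  arma::vec accScalar(p, arma::fill::zeros), tryScalar(p, arma::fill::zeros);
  arma::vec accWin(p, arma::fill::zeros), tryWin(p, arma::fill::zeros);
  double accS = 0, tryS = 0; long accL = 0, tryL = 0;
  double accSWin = 0, trySWin = 0;
  int stored = 0;

  for (int iter = 0; iter < nIter; ++iter) {
    // --- scalar random-walk updates on the transformed scale ---
    for (int k = 0; k < p; ++k) {
      if (fixedPar[k]) continue;
      tryScalar[k] += 1; tryWin[k] += 1;
      arma::vec tc = tp;
      tc[k] += scales[k] * norm_rand();
      Pars Pc = c.decode(tc);
      double llTotC; arma::vec llC;
      bool psiOnly = (k == 0); // psi enters the z prior only
      if (psiOnly) { llTotC = llTot; }
      else {
        llC.set_size(M); llTotC = 0.0;
        for (int i = 0; i < M; ++i) {
          arma::rowvec d = D2.row(i);
          llC[i] = c.indivLL(i, arow[i], z[i], u[i], Pc, d.memptr());
          llTotC += llC[i];
        }
      }
      double logA = (llTotC + zPrior(Pc.psi, Nz, M) + tPrior(tc)) -
                    (llTot + zPrior(P.psi, Nz, M) + tPrior(tp));
      if (std::log(unif_rand()) < logA) {
        tp = tc; P = Pc;
        if (!psiOnly) { llInd = llC; llTot = llTotC; }
        accScalar[k] += 1; accWin[k] += 1;
      }
    }
    if (adapt && iter < burnIn && (iter + 1) % 50 == 0) {
      for (int k = 0; k < p; ++k) {
        if (fixedPar[k] || tryWin[k] == 0) continue;
        double rate = accWin[k] / tryWin[k];
        scales[k] *= std::exp(0.5 * (rate - 0.35));
        accWin[k] = tryWin[k] = 0;
      }
      if (trySWin > 0) {
        sScale *= std::exp(0.5 * (accSWin / trySWin - 0.35));
        accSWin = trySWin = 0;
      }
    }

    // --- activity centers ---
    if (updateS) {
      for (int i = 0; i < M; ++i) {
        if (z[i] == 0 && !c.hasData(i, arow[i])) {
          // likelihood flat: refresh from the uniform prior
          S(i, 0) = c.x0 + unif_rand() * (c.x1 - c.x0);
          S(i, 1) = c.y0 + unif_rand() * (c.y1 - c.y0);
          for (int j = 0; j < c.J; ++j) {
            double dx = S(i, 0) - c.traps(j, 0), dy = S(i, 1) - c.traps(j, 1);
            D2(i, j) = dx * dx + dy * dy;
          }
          continue;
        }
        tryS += 1; trySWin += 1;
        double sx = reflect(S(i, 0) + sScale * norm_rand(), c.x0, c.x1);
        double sy = reflect(S(i, 1) + sScale * norm_rand(), c.y0, c.y1);
        arma::rowvec d2c(c.J);
        for (int j = 0; j < c.J; ++j) {
          double dx = sx - c.traps(j, 0), dy = sy - c.traps(j, 1);
          d2c[j] = dx * dx + dy * dy;
        }
        double llc = c.indivLL(i, arow[i], z[i], u[i], P, d2c.memptr());
        if (std::log(unif_rand()) < llc - llInd[i]) {
          S(i, 0) = sx; S(i, 1) = sy;
          D2.row(i) = d2c;
          llTot += llc - llInd[i];
          llInd[i] = llc;
          accS += 1; accSWin += 1;
        }
      }
    }

    // --- inclusion indicators (all-zero slots only) ---
    if (updateZ) {
      for (int i = 0; i < M; ++i) {
        if (c.hasData(i, arow[i])) continue;
        arma::rowvec d = D2.row(i);
        double f1 = c.detLL(i, arow[i], u[i], P, d.memptr());
        double lp1 = std::log(P.psi) + f1;
        double lp0 = std::log(1.0 - P.psi);
        double pz1 = 1.0 / (1.0 + std::exp(lp0 - lp1));
        int znew = (unif_rand() < pz1) ? 1 : 0;
        if (znew != z[i]) { Nz += znew - z[i]; z[i] = znew; }
        double lli = c.indivLL(i, arow[i], z[i], u[i], P, d.memptr());
        llTot += lli - llInd[i]; llInd[i] = lli;
      }
    }

    // --- missing sexes (two-point full conditional) ---
    if (updateU && c.sexed) {
      for (int i = 0; i < M; ++i) {
        int r = arow[i];
        if (c.sex1[i] >= 0) { if (u[i] != c.sex1[i]) stop("sex state corrupt"); continue; }
        if (c.sex2[r] >= 0) { // constrained by the assigned row's label
          if (u[i] != c.sex2[r]) {
            u[i] = c.sex2[r];
            arma::rowvec d = D2.row(i);
            double lli = c.indivLL(i, r, z[i], u[i], P, d.memptr());
            llTot += lli - llInd[i]; llInd[i] = lli;
          }
          continue;
        }
        arma::rowvec d = D2.row(i);
        double lm, lf;
        if (z[i] == 1) {
          lm = std::log(P.theta) + c.detLL(i, r, 1, P, d.memptr());
          lf = std::log(1.0 - P.theta) + c.detLL(i, r, 0, P, d.memptr());
        } else {
          lm = std::log(P.theta); lf = std::log(1.0 - P.theta);
        }
        double pm = 1.0 / (1.0 + std::exp(lf - lm));
        u[i] = (unif_rand() < pm) ? 1 : 0;
        double lli = c.indivLL(i, r, z[i], u[i], P, d.memptr());
        llTot += lli - llInd[i]; llInd[i] = lli;
      }
    }

    // --- identity permutation ---
    if (updateL) {
      tryL += nPerm;
      accL += permSweep(c, P, D2, z, u, arow, slotOf, llInd, llTot,
                        freeRows, freeSlots, nPerm);
    }

    // --- record ---
    if (iter >= burnIn && (iter - burnIn) % thin == 0) {
      tDraws.row(stored) = tp.t();
      npDraws.row(stored) = c.natural(tp).t();
      llDraws[stored] = llTot;
      NDraws[stored] = Nz;
      indivDraws.row(stored) = llInd.t();
      if (storeLatents) {
        for (int i = 0; i < M; ++i) {
          zDraws(stored, i) = z[i];
          uDraws(stored, i) = u[i];
          LDraws(stored, i) = slotOf[i] + 1; // L[r] = slot of row r, 1-based
          sDraws[stored + (R_xlen_t)nRet * i] = S(i, 0);
          sDraws[stored + (R_xlen_t)nRet * i + (R_xlen_t)nRet * M] = S(i, 1);
        }
      }
      ++stored;
    }
  }

  NumericVector accOut(p + 2);
  for (int k = 0; k < p; ++k)
    accOut[k] = tryScalar[k] > 0 ? accScalar[k] / tryScalar[k] : NA_REAL;
  accOut[p] = tryS > 0 ? accS / tryS : NA_REAL;
  accOut[p + 1] = tryL > 0 ? (double)accL / tryL : NA_REAL;
  if (storeLatents) sDraws.attr("dim") = IntegerVector::create(nRet, M, 2);

  return List::create(
    _["tDraws"] = wrap(tDraws), _["npDraws"] = wrap(npDraws),
    _["loglik"] = wrap(llDraws), _["NDraws"] = wrap(NDraws),
    _["indivLoglik"] = wrap(indivDraws), _["zDraws"] = zDraws,
    _["uDraws"] = uDraws, _["LDraws"] = LDraws, _["sDraws"] = sDraws,
    _["acceptance"] = accOut, _["finalScales"] = wrap(scales));
}

// Posterior-predictive replicate accumulation for the D-infinity criterion:
// one replicate per used draw; running per-cell mean and sum of squares over
// the 2*M*J*K vectorized binary cells, compared against the observed arrays.
// [[Rcpp::export]]
List cpp_ppl(List dataList, NumericMatrix tDraws, IntegerMatrix zDraws,
             IntegerMatrix uDraws, IntegerMatrix LDraws, NumericVector sDraws,
             NumericVector y1obs, NumericVector y2obs, IntegerVector useDraws) {
  ScrCtx c = buildCtx(dataList);
  const int M = c.M, J = c.J, K = c.K;
  IntegerVector dims = sDraws.attr("dim");
  const int nAll = dims[0];
  const R_xlen_t nCells = (R_xlen_t)M * J * K;
  std::vector<double> sum1(nCells, 0.0), sq1(nCells, 0.0);
  std::vector<double> sum2(nCells, 0.0), sq2(nCells, 0.0);
  std::vector<double> rep1(nCells), rep2(nCells);
  arma::mat S(M, 2);
  arma::ivec slotOf(M);
  const int nUse = useDraws.size();

  for (int t = 0; t < nUse; ++t) {
    int d = useDraws[t] - 1; // 1-based from R
    arma::vec tp(tDraws.ncol());
    for (int k = 0; k < tDraws.ncol(); ++k) tp[k] = tDraws(d, k);
    Pars P = c.decode(tp);
    for (int i = 0; i < M; ++i) {
      S(i, 0) = sDraws[d + (R_xlen_t)nAll * i];
      S(i, 1) = sDraws[d + (R_xlen_t)nAll * i + (R_xlen_t)nAll * M];
      slotOf[i] = LDraws(d, i) - 1; // row i sits in this slot
    }
    std::fill(rep1.begin(), rep1.end(), 0.0);
    std::fill(rep2.begin(), rep2.end(), 0.0);
    // simulate in slot space (activity centers live on slots)
    for (int i = 0; i < M; ++i) {
      if (zDraws(d, i) == 0) continue;
      double sig = c.sexed ? (uDraws(d, i) ? P.sigM : P.sigF) : P.sigM;
      double inv2s2 = 1.0 / (2.0 * sig * sig);
      for (int j = 0; j < J; ++j) {
        double dx = S(i, 0) - c.traps(j, 0), dy = S(i, 1) - c.traps(j, 1);
        double d2 = dx * dx + dy * dy;
        if (c.twoStage) {
          double eta = P.omega0 * std::exp(-d2 * inv2s2);
          for (int k = 0; k < K; ++k) {
            R_xlen_t cell = i + (R_xlen_t)M * j + (R_xlen_t)M * J * k;
            if (unif_rand() < eta) {
              if (unif_rand() < P.phi) rep1[cell] = 1.0;
              if (unif_rand() < P.phi) rep2[cell] = 1.0;
            }
          }
        } else {
          double pj = P.p0 * std::exp(-d2 * inv2s2);
          for (int k = 0; k < K; ++k) {
            R_xlen_t cell = i + (R_xlen_t)M * j + (R_xlen_t)M * J * k;
            if (unif_rand() < pj) rep1[cell] = 1.0;
            if (unif_rand() < pj) rep2[cell] = 1.0;
          }
        }
      }
    }
    // detector-1 replicate rows are in slot order already; detector-2
    // replicate row r takes the slot the draw assigns it to
    for (int r = 0; r < M; ++r) {
      int slot = slotOf[r];
      for (int j = 0; j < J; ++j)
        for (int k = 0; k < K; ++k) {
          R_xlen_t from = slot + (R_xlen_t)M * j + (R_xlen_t)M * J * k;
          R_xlen_t to = r + (R_xlen_t)M * j + (R_xlen_t)M * J * k;
          sum2[to] += rep2[from]; sq2[to] += rep2[from];
        }
    }
    for (R_xlen_t cell = 0; cell < nCells; ++cell) {
      sum1[cell] += rep1[cell]; sq1[cell] += rep1[cell]; // binary: x^2 = x
    }
  }

  double gof = 0.0, pen = 0.0;
  for (R_xlen_t cell = 0; cell < nCells; ++cell) {
    double m1 = sum1[cell] / nUse, m2 = sum2[cell] / nUse;
    gof += (y1obs[cell] - m1) * (y1obs[cell] - m1) +
           (y2obs[cell] - m2) * (y2obs[cell] - m2);
    pen += (sq1[cell] / nUse - m1 * m1) + (sq2[cell] / nUse - m2 * m2);
  }
  return List::create(_["gof"] = gof, _["penalty"] = pen,
                      _["value"] = gof + pen, _["nDraws"] = nUse);
}
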
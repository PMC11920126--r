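// Adaptive Metropolis-within-Gibbs sampler for the hierarchical log-M-ratio
// model with a two-way mixed (instruction x difficulty) effect structure.
//
// Per participant s and difficulty cell c the observed rating counts follow
// the response-conditional type-2 multinomial likelihood with
//   meta-d'[s,c] = exp(lambda[s,c]) * dprime[s,c],
//   lambda[s,c]  = mu + bI*xI[s] + bD*xD[c] + bID*xI[s]*xD[c]
//                  + sigma_u * zu[s] + sigma_e * ze[s,c]   (non-centered),
// per-cell ordered type-2 criteria parameterized as log-scale outward
// increments from the scaled criterion c' = crit * exp(lambda). Type-1
// (d', c) per cell are sampled around their (stabilized) estimates when
// prior SDs are supplied (cell-level independent part plus a shared
// instruction x difficulty group offset for the coherent group-mean
// estimation error), or held fixed when the SDs are zero.
//
// Priors: mu, bI, bD, bID ~ N(0,1); sigma_u, sigma_e ~ Half-Normal(1);
// criterion increments delta ~ Half-Normal(1); zu, ze ~ N(0,1).
//
// Randomness comes from R's RNG, so results are reproducible from
// set.seed() on the R side. Proposal scales adapt toward a 0.44 acceptance
// rate during burn-in only; retained draws use fixed kernels.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct ModelData {
  int S, K;
  // counts[cell][stim][j], j < K: nonmatch response rating j+1,
  // j >= K: match response rating j-K+1
  std::vector<double> counts;    // length S*2*2*2K
  std::vector<double> dprime0;   // prior centers, length S*2
  std::vector<double> crit0;     // prior centers, length S*2
  std::vector<double> dprime_sd; // prior SDs (0 = fixed), length S*2
  std::vector<double> crit_sd;   // prior SDs (0 = fixed), length S*2
  std::vector<double> xI;        // length S
  double xD[2];
  std::vector<int> grp;          // instruction x difficulty group, 0..3
  double gd_sd[4], gc_sd[4];     // group-level type-1 offset SDs
};

inline double phi(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// log-likelihood of one (participant, cell) given lambda, the cell's
// type-1 parameters, and its criterion increments (dlow/dhigh, K-1 each)
double cell_loglik_raw(const ModelData& d, int s, int c, double lambda,
                       double dprime, double crit,
                       const double* dlow, const double* dhigh) {
  const int K = d.K;
  if (lambda > 20.0) lambda = 20.0;
  if (lambda < -20.0) lambda = -20.0;
  const int sc = s * 2 + c;
  const double metad = std::exp(lambda) * dprime;
  const double cpr = crit * std::exp(lambda);
  // ordered criteria around cpr
  std::vector<double> tlow(K - 1), thigh(K - 1);
  double acc = cpr;
  for (int j = 0; j < K - 1; ++j) { acc -= dlow[j]; tlow[j] = acc; }
  acc = cpr;
  for (int j = 0; j < K - 1; ++j) { acc += dhigh[j]; thigh[j] = acc; }

  double ll = 0.0;
  for (int i = 0; i < 2; ++i) {
    const double mu2 = (i == 0 ? -0.5 : 0.5) * metad;
    const double p_cpr = phi(cpr - mu2);
    const double denom_nm = std::max(p_cpr, 1e-300);
    const double denom_m = std::max(1.0 - p_cpr, 1e-300);
    const double* cnt = &d.counts[(size_t)(sc * 2 + i) * 2 * K];
    // nonmatch response: segments from cpr outward to -Inf
    double upper = p_cpr;
    for (int k = 0; k < K; ++k) {
      double lowerp = (k < K - 1) ? phi(tlow[k] - mu2) : 0.0;
      double p = (upper - lowerp) / denom_nm;
      if (p < 1e-12) p = 1e-12;
      if (cnt[k] != 0.0) ll += cnt[k] * std::log(p);
      upper = lowerp;
    }
    // match response: segments from cpr outward to +Inf
    double lowerp = p_cpr;
    for (int k = 0; k < K; ++k) {
      double upperp = (k < K - 1) ? phi(thigh[k] - mu2) : 1.0;
      double p = (upperp - lowerp) / denom_m;
      if (p < 1e-12) p = 1e-12;
      if (cnt[K + k] != 0.0) ll += cnt[K + k] * std::log(p);
      lowerp = upperp;
    }
  }
  return ll;
}

struct State {
  double mu, b1, b2, b3, lsu, lse;
  double gd[4], gc[4];          // shared group-level type-1 offsets
  std::vector<double> zu;       // S
  std::vector<double> ze;       // S*2
  std::vector<double> ld;       // S*2 cells * 2 sides * (K-1), log incs
  std::vector<double> dp;       // S*2 per-cell type-1 d'
  std::vector<double> cc;       // S*2 per-cell type-1 criterion
  std::vector<double> lambda;   // S*2 cached
  std::vector<double> cll;      // S*2 cached cell log-liks
  std::vector<double> delta;    // exp(ld) cached
};

inline double lin_pred(const ModelData& d, const State& st, int s, int c) {
  return st.mu + st.b1 * d.xI[s] + st.b2 * d.xD[c] +
         st.b3 * d.xI[s] * d.xD[c] +
         std::exp(st.lsu) * st.zu[s] + std::exp(st.lse) * st.ze[s * 2 + c];
}

// criteria increments are per participant x cell x side
inline const double* dlow_ptr(const ModelData& d, const State& st, int s,
                              int c) {
  return &st.delta[(size_t)(s * 2 + c) * 2 * (d.K - 1)];
}
inline const double* dhigh_ptr(const ModelData& d, const State& st, int s,
                               int c) {
  return &st.delta[(size_t)(s * 2 + c) * 2 * (d.K - 1) + (d.K - 1)];
}

// cell log-likelihood at the current state (cell + group type-1 terms)
double cell_ll(const ModelData& d, const State& st, int s, int c,
               double lambda) {
  const int sc = s * 2 + c;
  const int g = d.grp[sc];
  return cell_loglik_raw(d, s, c, lambda, st.dp[sc] + st.gd[g],
                         st.cc[sc] + st.gc[g], dlow_ptr(d, st, s, c),
                         dhigh_ptr(d, st, s, c));
}

void refresh_all(const ModelData& d, State& st) {
  for (int s = 0; s < d.S; ++s) {
    for (int c = 0; c < 2; ++c) {
      const int sc = s * 2 + c;
      st.lambda[sc] = lin_pred(d, st, s, c);
      st.cll[sc] = cell_ll(d, st, s, c, st.lambda[sc]);
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".mratio_sampler_cpp")]]
List mratio_sampler_cpp(NumericVector counts, NumericVector dprime,
                        NumericVector crit, NumericVector dprime_sd,
                        NumericVector crit_sd, IntegerVector grp,
                        NumericVector gd_sd, NumericVector gc_sd,
                        NumericVector xI, NumericVector xD, int S, int K,
                        int n_iter, int n_burnin, List init) {
  ModelData d;
  d.S = S;
  d.K = K;
  d.counts.assign(counts.begin(), counts.end());
  d.dprime0.assign(dprime.begin(), dprime.end());
  d.crit0.assign(crit.begin(), crit.end());
  d.dprime_sd.assign(dprime_sd.begin(), dprime_sd.end());
  d.crit_sd.assign(crit_sd.begin(), crit_sd.end());
  d.grp.assign(grp.begin(), grp.end());
  for (int g = 0; g < 4; ++g) {
    d.gd_sd[g] = gd_sd[g];
    d.gc_sd[g] = gc_sd[g];
  }
  d.xI.assign(xI.begin(), xI.end());
  d.xD[0] = xD[0];
  d.xD[1] = xD[1];

  const int n_ld = S * 2 * 2 * (K - 1);
  State st;
  st.mu = as<double>(init["mu"]);
  st.b1 = as<double>(init["b1"]);
  st.b2 = as<double>(init["b2"]);
  st.b3 = as<double>(init["b3"]);
  st.lsu = as<double>(init["lsu"]);
  st.lse = as<double>(init["lse"]);
  st.zu.assign(S, 0.0);
  st.ze.assign(S * 2, 0.0);
  st.ld.assign(n_ld, as<double>(init["ld0"]));
  st.dp.assign(d.dprime0.begin(), d.dprime0.end());
  st.cc.assign(d.crit0.begin(), d.crit0.end());
  for (int g = 0; g < 4; ++g) { st.gd[g] = 0.0; st.gc[g] = 0.0; }
  st.delta.resize(n_ld);
  for (int i = 0; i < n_ld; ++i) st.delta[i] = std::exp(st.ld[i]);
  st.lambda.assign(S * 2, 0.0);
  st.cll.assign(S * 2, 0.0);
  refresh_all(d, st);

  // parameter layout for proposal scales: 6 globals, zu, ze, ld,
  // per-cell type-1 (d', c), 8 group type-1 offsets, plus 6
  // interweaving moves
  const int n_par = 6 + S + 2 * S + n_ld + 2 * 2 * S + 8 + 6;
  std::vector<double> step(n_par, 0.25);
  std::vector<int> acc_n(n_par, 0), try_n(n_par, 0);

  const int n_keep = n_iter - n_burnin;
  NumericMatrix draws(n_keep, 6);
  NumericVector lambda_mean(S * 2);
  NumericVector accept_rate(n_par);

  RNGScope scope;

  auto total_ll = [&]() {
    double t = 0.0;
    for (int i = 0; i < 2 * S; ++i) t += st.cll[i];
    return t;
  };

  for (int it = 0; it < n_iter; ++it) {
    int pidx = 0;

    // ---- global parameters: full-likelihood Metropolis updates ----
    for (int g = 0; g < 6; ++g, ++pidx) {
      double* tgt = (g == 0) ? &st.mu : (g == 1) ? &st.b1 : (g == 2) ? &st.b2
                    : (g == 3) ? &st.b3 : (g == 4) ? &st.lsu : &st.lse;
      const double old = *tgt;
      const double prop = old + step[pidx] * norm_rand();
      double lp_old, lp_new;
      if (g < 4) {  // N(0,1) prior
        lp_old = -0.5 * old * old;
        lp_new = -0.5 * prop * prop;
      } else {      // half-normal(1) on sigma, log-scale with Jacobian
        const double so = std::exp(old), sp = std::exp(prop);
        lp_old = -0.5 * so * so + old;
        lp_new = -0.5 * sp * sp + prop;
      }
      const double ll_old = total_ll();
      *tgt = prop;
      std::vector<double> lam_old = st.lambda, cll_old = st.cll;
      refresh_all(d, st);
      const double ll_new = total_ll();
      ++try_n[pidx];
      if (std::log(unif_rand()) < ll_new + lp_new - ll_old - lp_old) {
        ++acc_n[pidx];
      } else {
        *tgt = old;
        st.lambda = lam_old;
        st.cll = cll_old;
      }
    }

    // ---- participant intercepts zu[s] ----
    for (int s = 0; s < S; ++s, ++pidx) {
      const double old = st.zu[s];
      const double prop = old + step[pidx] * norm_rand();
      st.zu[s] = prop;
      double lam_new[2], cll_new[2], dll = 0.0;
      for (int c = 0; c < 2; ++c) {
        lam_new[c] = lin_pred(d, st, s, c);
        cll_new[c] = cell_ll(d, st, s, c, lam_new[c]);
        dll += cll_new[c] - st.cll[s * 2 + c];
      }
      dll += -0.5 * prop * prop + 0.5 * old * old;
      ++try_n[pidx];
      if (std::log(unif_rand()) < dll) {
        ++acc_n[pidx];
        for (int c = 0; c < 2; ++c) {
          st.lambda[s * 2 + c] = lam_new[c];
          st.cll[s * 2 + c] = cll_new[c];
        }
      } else {
        st.zu[s] = old;
      }
    }

    // ---- cell residuals ze[s,c] ----
    for (int s = 0; s < S; ++s) {
      for (int c = 0; c < 2; ++c, ++pidx) {
        const int sc = s * 2 + c;
        const double old = st.ze[sc];
        const double prop = old + step[pidx] * norm_rand();
        st.ze[sc] = prop;
        const double lam_new = lin_pred(d, st, s, c);
        const double cll_new = cell_ll(d, st, s, c, lam_new);
        double dll = cll_new - st.cll[sc] - 0.5 * prop * prop +
                     0.5 * old * old;
        ++try_n[pidx];
        if (std::log(unif_rand()) < dll) {
          ++acc_n[pidx];
          st.lambda[sc] = lam_new;
          st.cll[sc] = cll_new;
        } else {
          st.ze[sc] = old;
        }
      }
    }

    // ---- criterion increments ld[s, c, side, j] ----
    for (int s = 0; s < S; ++s) {
      for (int c = 0; c < 2; ++c) {
        for (int q = 0; q < 2 * (K - 1); ++q, ++pidx) {
          const size_t li = (size_t)(s * 2 + c) * 2 * (K - 1) + q;
          const double old = st.ld[li];
          const double prop = old + step[pidx] * norm_rand();
          const double d_old = st.delta[li], d_new = std::exp(prop);
          st.ld[li] = prop;
          st.delta[li] = d_new;
          const int sc = s * 2 + c;
          const double cll_new = cell_ll(d, st, s, c, st.lambda[sc]);
          // half-normal(1) prior on delta with log-scale Jacobian
          double dll = cll_new - st.cll[sc] +
                       (-0.5 * d_new * d_new + prop) -
                       (-0.5 * d_old * d_old + old);
          ++try_n[pidx];
          if (std::log(unif_rand()) < dll) {
            ++acc_n[pidx];
            st.cll[sc] = cll_new;
          } else {
            st.ld[li] = old;
            st.delta[li] = d_old;
          }
        }
      }
    }

    // ---- per-cell type-1 parameters (d', c) around their empirical
    // priors; cells with zero prior SD stay fixed ----
    for (int s = 0; s < S; ++s) {
      for (int c = 0; c < 2; ++c) {
        const int sc = s * 2 + c;
        for (int g = 0; g < 2; ++g, ++pidx) {
          const double psd = (g == 0) ? d.dprime_sd[sc] : d.crit_sd[sc];
          if (psd <= 0.0) continue;
          double* tgt = (g == 0) ? &st.dp[sc] : &st.cc[sc];
          const double ctr = (g == 0) ? d.dprime0[sc] : d.crit0[sc];
          const double old = *tgt;
          const double prop = old + step[pidx] * norm_rand();
          *tgt = prop;
          const double cll_new = cell_ll(d, st, s, c, st.lambda[sc]);
          const double dll = cll_new - st.cll[sc] -
            0.5 * ((prop - ctr) * (prop - ctr) -
                   (old - ctr) * (old - ctr)) / (psd * psd);
          ++try_n[pidx];
          if (std::log(unif_rand()) < dll) {
            ++acc_n[pidx];
            st.cll[sc] = cll_new;
          } else {
            *tgt = old;
          }
        }
      }
    }

    // ---- shared group-level type-1 offsets (coherent estimation error
    // of the stabilization group means) ----
    for (int g4 = 0; g4 < 4; ++g4) {
      for (int w = 0; w < 2; ++w, ++pidx) {
        const double psd = (w == 0) ? d.gd_sd[g4] : d.gc_sd[g4];
        if (psd <= 0.0) continue;
        double* tgt = (w == 0) ? &st.gd[g4] : &st.gc[g4];
        const double old = *tgt;
        const double prop = old + step[pidx] * norm_rand();
        *tgt = prop;
        double dll = -0.5 * (prop * prop - old * old) / (psd * psd);
        std::vector<double> cll_new(2 * S);
        for (int s = 0; s < S; ++s) {
          for (int c = 0; c < 2; ++c) {
            const int sc = s * 2 + c;
            if (d.grp[sc] != g4) continue;
            cll_new[sc] = cell_ll(d, st, s, c, st.lambda[sc]);
            dll += cll_new[sc] - st.cll[sc];
          }
        }
        ++try_n[pidx];
        if (std::log(unif_rand()) < dll) {
          ++acc_n[pidx];
          for (int sc = 0; sc < 2 * S; ++sc) {
            if (d.grp[sc] == g4) st.cll[sc] = cll_new[sc];
          }
        } else {
          *tgt = old;
        }
      }
    }

    // ---- interweaving moves (likelihood-invariant reparameterization
    // steps: location effects traded against the standardized random
    // effects, and log-scale moves that rescale them; these decorrelate
    // the funnel directions of the hierarchy) ----
    {
      const double su = std::exp(st.lsu), se = std::exp(st.lse);
      // mu and b1 compensated through zu (participant-constant terms)
      for (int g = 0; g < 2; ++g, ++pidx) {
        double* tgt = (g == 0) ? &st.mu : &st.b1;
        const double delta = step[pidx] * norm_rand();
        const double prop = *tgt + delta;
        double lr = -0.5 * prop * prop + 0.5 * (*tgt) * (*tgt);
        std::vector<double> zu_new(S);
        for (int s = 0; s < S; ++s) {
          const double w = (g == 0) ? 1.0 : d.xI[s];
          zu_new[s] = st.zu[s] - delta * w / su;
          lr += -0.5 * zu_new[s] * zu_new[s] + 0.5 * st.zu[s] * st.zu[s];
        }
        ++try_n[pidx];
        if (std::log(unif_rand()) < lr) {
          ++acc_n[pidx];
          *tgt = prop;
          st.zu = zu_new;
        }
      }
      // b2 and b3 compensated through ze (cell-varying terms)
      for (int g = 0; g < 2; ++g, ++pidx) {
        double* tgt = (g == 0) ? &st.b2 : &st.b3;
        const double delta = step[pidx] * norm_rand();
        const double prop = *tgt + delta;
        double lr = -0.5 * prop * prop + 0.5 * (*tgt) * (*tgt);
        std::vector<double> ze_new(2 * S);
        for (int s = 0; s < S; ++s) {
          for (int c = 0; c < 2; ++c) {
            const double w = (g == 0) ? d.xD[c] : d.xI[s] * d.xD[c];
            const int sc = s * 2 + c;
            ze_new[sc] = st.ze[sc] - delta * w / se;
            lr += -0.5 * ze_new[sc] * ze_new[sc] +
                  0.5 * st.ze[sc] * st.ze[sc];
          }
        }
        ++try_n[pidx];
        if (std::log(unif_rand()) < lr) {
          ++acc_n[pidx];
          *tgt = prop;
          st.ze = ze_new;
        }
      }
      // rescale moves: lsu' = lsu + delta with zu scaled to keep su*zu
      // fixed (Jacobian -S*delta), and likewise for lse / ze
      for (int g = 0; g < 2; ++g, ++pidx) {
        const double delta = step[pidx] * norm_rand();
        double* tgt = (g == 0) ? &st.lsu : &st.lse;
        const int nz = (g == 0) ? S : 2 * S;
        std::vector<double>& z = (g == 0) ? st.zu : st.ze;
        const double old = *tgt, prop = old + delta;
        const double so = std::exp(old), sp = std::exp(prop);
        double lr = (-0.5 * sp * sp + prop) - (-0.5 * so * so + old) -
                    nz * delta;
        const double f = std::exp(-delta);
        for (int i = 0; i < nz; ++i) {
          const double zn = z[i] * f;
          lr += -0.5 * zn * zn + 0.5 * z[i] * z[i];
        }
        ++try_n[pidx];
        if (std::log(unif_rand()) < lr) {
          ++acc_n[pidx];
          *tgt = prop;
          for (int i = 0; i < nz; ++i) z[i] *= f;
        }
      }
    }

    // ---- adapt proposal scales during burn-in ----
    if (it < n_burnin && (it + 1) % 50 == 0) {
      const double g = std::min(0.25, 5.0 / std::sqrt((double)(it + 1)));
      for (int p = 0; p < n_par; ++p) {
        if (try_n[p] > 0) {
          const double r = (double)acc_n[p] / try_n[p];
          step[p] *= std::exp(g * (r - 0.44));
          if (step[p] < 1e-4) step[p] = 1e-4;
          if (step[p] > 10.0) step[p] = 10.0;
        }
        acc_n[p] = 0;
        try_n[p] = 0;
      }
    }

    // ---- record ----
    if (it >= n_burnin) {
      const int row = it - n_burnin;
      draws(row, 0) = st.mu;
      draws(row, 1) = st.b1;
      draws(row, 2) = st.b2;
      draws(row, 3) = st.b3;
      draws(row, 4) = std::exp(st.lsu);
      draws(row, 5) = std::exp(st.lse);
      for (int i = 0; i < 2 * S; ++i) {
        lambda_mean[i] += st.lambda[i] / n_keep;
      }
    }
  }

  for (int p = 0; p < n_par; ++p) {
    accept_rate[p] = try_n[p] > 0 ? (double)acc_n[p] / try_n[p] : NA_REAL;
  }
  colnames(draws) = CharacterVector::create("mu", "b_instruction",
                                            "b_difficulty", "b_interaction",
                                            "sigma_u", "sigma_e");
  return List::create(_["draws"] = draws, _["lambda_mean"] = lambda_mean,
                      _["accept_rate"] = accept_rate);
}
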
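#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Marginal (gamma-approximation) log-likelihood of trajectory summary
// (S, L) at phi = log[4(D dt + sigma_loc^2)].
static inline double loglik_phi(double S, double L, double phi) {
  return -S * std::exp(-phi) - L * phi;
}

// Dirichlet-process mixture Gibbs sampler on the 1D parameter phi,
// a modified auxiliary-candidate sampler (Neal's Algorithm 8) with
// truncated-Gaussian Metropolis-Hastings nudges of the state
// parameters between sweeps.
//
// S, L: per-trajectory sum of squared 2D jumps and jump count.
// Existing states are weighted by the number of jumps already assigned
// to them; the existing-vs-new split uses trajectory counts.
// All randomness comes from R's RNG, so traces are reproducible under
// set.seed().
// [[Rcpp::export]]
List dpmm_gibbs_core(NumericVector S, NumericVector L, double alpha,
                     int m0, double nu, double phi_min, double phi_max,
                     int n_iter) {
  const int N = S.size();
  std::vector<double> phi, njump, Ssum;   // per-state parameter + sufficient stats
  std::vector<int> ntraj;
  std::vector<int> z(N);

  // initialization: m0 uniform candidates, soft assignment by likelihood
  for (int k = 0; k < m0; ++k) {
    phi.push_back(R::runif(phi_min, phi_max));
    njump.push_back(0.0);
    Ssum.push_back(0.0);
    ntraj.push_back(0);
  }
  {
    std::vector<double> lp(m0);
    for (int i = 0; i < N; ++i) {
      double mx = -INFINITY;
      for (int k = 0; k < m0; ++k) {
        lp[k] = loglik_phi(S[i], L[i], phi[k]);
        if (lp[k] > mx) mx = lp[k];
      }
      if (!std::isfinite(mx))
        stop("trajectory %d has zero likelihood for all initial candidates", i + 1);
      double tot = 0.0;
      for (int k = 0; k < m0; ++k) { lp[k] = std::exp(lp[k] - mx); tot += lp[k]; }
      double u = R::unif_rand() * tot, c = 0.0;
      int pick = m0 - 1;
      for (int k = 0; k < m0; ++k) { c += lp[k]; if (u <= c) { pick = k; break; } }
      z[i] = pick;
      njump[pick] += L[i];
      Ssum[pick] += S[i];
      ntraj[pick] += 1;
    }
  }

  const double p_existing = (N - 1.0) / (alpha + N - 1.0);
  std::vector<int> trace_iter;
  std::vector<double> trace_phi, trace_n;
  long mh_prop = 0, mh_acc = 0;
  std::vector<double> lw, cand(m0), clp(m0);

  for (int t = 1; t <= n_iter; ++t) {
    // --- per-trajectory reassignment (Chinese restaurant process) ---
    for (int i = 0; i < N; ++i) {
      const int kold = z[i];
      njump[kold] -= L[i];
      Ssum[kold] -= S[i];
      ntraj[kold] -= 1;

      bool assigned = false;
      if (R::unif_rand() < p_existing) {
        // choose among currently occupied states, weighted by jumps
        const int Ks = (int)phi.size();
        lw.assign(Ks, -INFINITY);
        double mx = -INFINITY;
        for (int k = 0; k < Ks; ++k) {
          if (ntraj[k] <= 0 || njump[k] <= 0) continue;
          lw[k] = std::log(njump[k]) + loglik_phi(S[i], L[i], phi[k]);
          if (lw[k] > mx) mx = lw[k];
        }
        if (std::isfinite(mx)) {
          double tot = 0.0;
          for (int k = 0; k < Ks; ++k) {
            lw[k] = std::isfinite(lw[k]) ? std::exp(lw[k] - mx) : 0.0;
            tot += lw[k];
          }
          double u = R::unif_rand() * tot, c = 0.0;
          int pick = -1;
          for (int k = 0; k < Ks; ++k) { c += lw[k]; if (u <= c) { pick = k; break; } }
          if (pick < 0) { for (int k = Ks - 1; k >= 0; --k) if (lw[k] > 0) { pick = k; break; } }
          z[i] = pick;
          njump[pick] += L[i];
          Ssum[pick] += S[i];
          ntraj[pick] += 1;
          assigned = true;
        }
      }
      if (!assigned) {
        // new state: m0 uniform candidates, accept by likelihood softmax
        double mx = -INFINITY;
        for (int k = 0; k < m0; ++k) {
          cand[k] = R::runif(phi_min, phi_max);
          clp[k] = loglik_phi(S[i], L[i], cand[k]);
          if (clp[k] > mx) mx = clp[k];
        }
        if (!std::isfinite(mx))
          stop("trajectory %d has zero likelihood for all new-state candidates", i + 1);
        double tot = 0.0;
        for (int k = 0; k < m0; ++k) { clp[k] = std::exp(clp[k] - mx); tot += clp[k]; }
        double u = R::unif_rand() * tot, c = 0.0;
        int pick = m0 - 1;
        for (int k = 0; k < m0; ++k) { c += clp[k]; if (u <= c) { pick = k; break; } }
        phi.push_back(cand[pick]);
        njump.push_back(L[i]);
        Ssum.push_back(S[i]);
        ntraj.push_back(1);
        z[i] = (int)phi.size() - 1;
      }
    }

    // --- drop empty states, remap assignments ---
    {
      const int Ks = (int)phi.size();
      std::vector<int> remap(Ks, -1);
      int kk = 0;
      for (int k = 0; k < Ks; ++k) {
        if (ntraj[k] > 0) {
          remap[k] = kk;
          phi[kk] = phi[k];
          njump[kk] = njump[k];
          Ssum[kk] = Ssum[k];
          ntraj[kk] = ntraj[k];
          ++kk;
        }
      }
      phi.resize(kk); njump.resize(kk); Ssum.resize(kk); ntraj.resize(kk);
      for (int i = 0; i < N; ++i) z[i] = remap[z[i]];
    }

    // --- Metropolis-Hastings nudge of each state parameter ---
    const int Ks = (int)phi.size();
    for (int k = 0; k < Ks; ++k) {
      double prop;
      do {
        prop = phi[k] + nu * R::norm_rand();
      } while (prop < phi_min || prop > phi_max);
      // log likelihood ratio via the per-state sufficient statistics,
      // plus the truncation-volume correction of the proposal
      double lr = (-Ssum[k] * std::exp(-prop) - njump[k] * prop) -
                  (-Ssum[k] * std::exp(-phi[k]) - njump[k] * phi[k]);
      double zc = R::pnorm(phi_max, phi[k], nu, 1, 0) -
                  R::pnorm(phi_min, phi[k], nu, 1, 0);
      double zp = R::pnorm(phi_max, prop, nu, 1, 0) -
                  R::pnorm(phi_min, prop, nu, 1, 0);
      lr += std::log(zc) - std::log(zp);
      ++mh_prop;
      if (std::log(R::unif_rand()) < lr) { phi[k] = prop; ++mh_acc; }
    }

    for (int k = 0; k < Ks; ++k) {
      trace_iter.push_back(t);
      trace_phi.push_back(phi[k]);
      trace_n.push_back(njump[k]);
    }
  }

  return List::create(
    _["iteration"] = IntegerVector(trace_iter.begin(), trace_iter.end()),
    _["phi"] = NumericVector(trace_phi.begin(), trace_phi.end()),
    _["n_jumps"] = NumericVector(trace_n.begin(), trace_n.end()),
    _["accept_rate"] = mh_prop > 0 ? (double)mh_acc / (double)mh_prop : NA_REAL,
    _["z_final"] = IntegerVector(z.begin(), z.end()));
}
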
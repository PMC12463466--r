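#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Marginal log-likelihood contribution of one block after integrating the
// Poisson mean under a Gamma(alpha, beta) prior. N is the block count total,
// S the block exposure total (sum over cells of s_i * g_j). The per-cell
// constant sum_[y*log(s g) - log y!] is partition-invariant and excluded.
static inline double lm_block(double N, double S, double alpha, double beta) {
  if (N <= 0.0 && S <= 0.0) return 0.0;
  return alpha * std::log(beta) - R::lgammafn(alpha) + R::lgammafn(alpha + N) -
         (alpha + N) * std::log(beta + S);
}

// Draw an index from unnormalised log-weights (max-subtracted), using R's RNG.
static inline int sample_logweights(const std::vector<double> &lw) {
  const int m = (int)lw.size();
  double mx = lw[0];
  for (int k = 1; k < m; ++k)
    if (lw[k] > mx) mx = lw[k];
  double tot = 0.0;
  for (int k = 0; k < m; ++k) tot += std::exp(lw[k] - mx);
  double u = unif_rand() * tot, c = 0.0;
  for (int k = 0; k < m; ++k) {
    c += std::exp(lw[k] - mx);
    if (u <= c) return k;
  }
  return m - 1;
}

// In-place Fisher-Yates shuffle driven by R's RNG (reproducible via set.seed).
static inline void shuffle_idx(std::vector<int> &idx) {
  for (int i = (int)idx.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// Collapsed Gibbs sampler for the latent block model with gene selection.
//
// Y:    p x n integer count matrix.
// adj:  length-n list of 0-based neighbour index vectors.
// s, g: spot size factors (sum to 1) and gene effects.
// z0:   0-based initial spot labels (length n, values 0..K-1).
// rho0: initial gene labels (length p, values 0..R; 0 = null).
//
// Sweep order per iteration: all spots in a fresh random permutation, all
// genes in a fresh random permutation, then a Beta draw for pi0. The log
// joint (block means and pi0 integrated out, MRF term unnormalised,
// including the partition-invariant per-cell constant) is recorded every
// iteration.
// [[Rcpp::export(name = ".lbm_gibbs")]]
List lbm_gibbs(IntegerMatrix Y, List adj, NumericVector s, NumericVector g,
               int K, int R, double amu, double bmu, double a0, double b0,
               double api, double bpi, double gam, NumericVector bk, double h,
               IntegerVector z0, IntegerVector rho0, double pi0_init,
               int iters, int burnin, int thin, bool debug_check) {
  const int p = Y.nrow(), n = Y.ncol();
  std::vector<int> z(z0.begin(), z0.end());
  std::vector<int> rho(rho0.begin(), rho0.end());
  double pi0 = pi0_init;

  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i].assign(v.begin(), v.end());
  }

  // sufficient statistics
  std::vector<double> Sk(K, 0.0), Gr(R, 0.0);
  double G0 = 0.0, N0 = 0.0;
  std::vector<double> Nrk((size_t)R * K, 0.0);   // column-major R x K
  std::vector<double> nspot((size_t)R * n, 0.0); // R x n
  std::vector<double> ngene((size_t)p * K, 0.0); // p x K
  std::vector<double> tj(p, 0.0);
  std::vector<int> nk(K, 0), pr(R, 0);
  int p0 = 0;
  double sumS = 0.0;
  for (int i = 0; i < n; ++i) sumS += s[i];

  double cell_const = 0.0;
  for (int i = 0; i < n; ++i) {
    const double lsi = std::log(s[i]);
    for (int j = 0; j < p; ++j) {
      const double y = (double)Y(j, i);
      if (y > 0)
        cell_const += y * (lsi + std::log(g[j])) - R::lgammafn(y + 1.0);
    }
  }

  auto recompute = [&](std::vector<double> &Sk_, std::vector<double> &Gr_,
                       double &G0_, double &N0_, std::vector<double> &Nrk_,
                       std::vector<double> &nspot_, std::vector<double> &ngene_,
                       std::vector<int> &nk_, std::vector<int> &pr_, int &p0_) {
    std::fill(Sk_.begin(), Sk_.end(), 0.0);
    std::fill(Gr_.begin(), Gr_.end(), 0.0);
    G0_ = N0_ = 0.0;
    std::fill(Nrk_.begin(), Nrk_.end(), 0.0);
    std::fill(nspot_.begin(), nspot_.end(), 0.0);
    std::fill(ngene_.begin(), ngene_.end(), 0.0);
    std::fill(nk_.begin(), nk_.end(), 0);
    std::fill(pr_.begin(), pr_.end(), 0);
    p0_ = 0;
    for (int i = 0; i < n; ++i) {
      Sk_[z[i]] += s[i];
      nk_[z[i]]++;
    }
    for (int j = 0; j < p; ++j) {
      if (rho[j] == 0) {
        p0_++;
        G0_ += g[j];
      } else {
        pr_[rho[j] - 1]++;
        Gr_[rho[j] - 1] += g[j];
      }
    }
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < p; ++j) {
        const double y = (double)Y(j, i);
        if (y == 0.0) continue;
        ngene_[(size_t)j + (size_t)p * z[i]] += y;
        if (rho[j] == 0)
          N0_ += y;
        else {
          const int r = rho[j] - 1;
          nspot_[(size_t)r + (size_t)R * i] += y;
          Nrk_[(size_t)r + (size_t)R * z[i]] += y;
        }
      }
  };
  recompute(Sk, Gr, G0, N0, Nrk, nspot, ngene, nk, pr, p0);
  for (int j = 0; j < p; ++j) {
    double t = 0.0;
    for (int i = 0; i < n; ++i) t += (double)Y(j, i);
    tj[j] = t;
  }

  auto log_joint = [&]() {
    double lp = cell_const;
    for (int r = 0; r < R; ++r)
      for (int k = 0; k < K; ++k)
        lp += lm_block(Nrk[(size_t)r + (size_t)R * k], Gr[r] * Sk[k], amu, bmu);
    lp += lm_block(N0, G0 * sumS, a0, b0);
    // zero-inflated Polya urn prior with pi0 integrated under Beta(api, bpi)
    lp += R::lbeta(api + p0, bpi + (p - p0)) - R::lbeta(api, bpi);
    for (int r = 0; r < R; ++r)
      if (pr[r] > 0) lp += std::log(gam) + R::lgammafn((double)pr[r]);
    for (int j = 1; j <= p - p0; ++j) lp -= std::log(gam + j - 1.0);
    // unnormalised MRF prior on spot labels
    for (int k = 0; k < K; ++k) lp += bk[k] * nk[k];
    double same = 0.0;
    for (int i = 0; i < n; ++i)
      for (int ii : nb[i])
        if (z[i] == z[ii]) same += 1.0;
    lp += h * same / 2.0;
    return lp;
  };

  const int U = (iters > burnin) ? (iters - burnin + thin - 1) / thin : 0;
  IntegerMatrix z_draws(U, n), rho_draws(U, p);
  NumericVector pi0_draws(U), log_post(iters);
  int u = 0;

  std::vector<int> spot_order(n), gene_order(p);
  for (int i = 0; i < n; ++i) spot_order[i] = i;
  for (int j = 0; j < p; ++j) gene_order[j] = j;
  std::vector<double> lwK(K), lwR(R + 1);

  for (int it = 0; it < iters; ++it) {
    // ---- spot sweep ----
    shuffle_idx(spot_order);
    for (int oi = 0; oi < n; ++oi) {
      const int i = spot_order[oi];
      const int k0 = z[i];
      Sk[k0] -= s[i];
      nk[k0]--;
      for (int r = 0; r < R; ++r)
        Nrk[(size_t)r + (size_t)R * k0] -= nspot[(size_t)r + (size_t)R * i];
      for (int k = 0; k < K; ++k) {
        double cnt = 0.0;
        for (int ii : nb[i])
          if (z[ii] == k && ii != i) cnt += 1.0;
        double lw = bk[k] + h * cnt;
        for (int r = 0; r < R; ++r) {
          if (Gr[r] <= 0.0) continue;
          const double Ne = Nrk[(size_t)r + (size_t)R * k];
          const double x = nspot[(size_t)r + (size_t)R * i];
          lw += R::lgammafn(amu + Ne + x) - R::lgammafn(amu + Ne) +
                (amu + Ne) * std::log(bmu + Gr[r] * Sk[k]) -
                (amu + Ne + x) * std::log(bmu + Gr[r] * (Sk[k] + s[i]));
        }
        lwK[k] = lw;
      }
      const int k1 = sample_logweights(lwK);
      z[i] = k1;
      Sk[k1] += s[i];
      nk[k1]++;
      for (int r = 0; r < R; ++r)
        Nrk[(size_t)r + (size_t)R * k1] += nspot[(size_t)r + (size_t)R * i];
      if (k1 != k0) {
        for (int j = 0; j < p; ++j) {
          const double y = (double)Y(j, i);
          if (y == 0.0) continue;
          ngene[(size_t)j + (size_t)p * k0] -= y;
          ngene[(size_t)j + (size_t)p * k1] += y;
        }
      }
    }

    // ---- gene sweep ----
    shuffle_idx(gene_order);
    for (int oj = 0; oj < p; ++oj) {
      const int j = gene_order[oj];
      const int r0 = rho[j];
      if (r0 == 0) {
        N0 -= tj[j];
        G0 -= g[j];
        p0--;
      } else {
        const int r = r0 - 1;
        Gr[r] -= g[j];
        pr[r]--;
        for (int k = 0; k < K; ++k)
          Nrk[(size_t)r + (size_t)R * k] -= ngene[(size_t)j + (size_t)p * k];
        for (int i = 0; i < n; ++i) {
          const double y = (double)Y(j, i);
          if (y != 0.0) nspot[(size_t)r + (size_t)R * i] -= y;
        }
      }
      const double d = (double)(p - 1 - p0); // DGs among the other genes
      lwR[0] = std::log(pi0) + lm_block(N0 + tj[j], (G0 + g[j]) * sumS, a0, b0) -
               lm_block(N0, G0 * sumS, a0, b0);
      for (int r = 1; r <= R; ++r) {
        const int m = pr[r - 1];
        double lw = std::log1p(-pi0) +
                    std::log(m > 0 ? (double)m : gam) - std::log(gam + d);
        const double gj = g[j];
        for (int k = 0; k < K; ++k) {
          const double Ne = Nrk[(size_t)(r - 1) + (size_t)R * k];
          const double x = ngene[(size_t)j + (size_t)p * k];
          lw += R::lgammafn(amu + Ne + x) - R::lgammafn(amu + Ne) +
                (amu + Ne) * std::log(bmu + Gr[r - 1] * Sk[k]) -
                (amu + Ne + x) * std::log(bmu + (Gr[r - 1] + gj) * Sk[k]);
        }
        lwR[r] = lw;
      }
      const int r1 = sample_logweights(lwR);
      rho[j] = r1;
      if (r1 == 0) {
        N0 += tj[j];
        G0 += g[j];
        p0++;
      } else {
        const int r = r1 - 1;
        Gr[r] += g[j];
        pr[r]++;
        for (int k = 0; k < K; ++k)
          Nrk[(size_t)r + (size_t)R * k] += ngene[(size_t)j + (size_t)p * k];
        for (int i = 0; i < n; ++i) {
          const double y = (double)Y(j, i);
          if (y != 0.0) nspot[(size_t)r + (size_t)R * i] += y;
        }
      }
    }

    // ---- pi0 ----
    pi0 = R::rbeta(api + p0, bpi + (double)(p - p0));

    log_post[it] = log_joint();

    if (debug_check && ((it + 1) % 25 == 0)) {
      std::vector<double> Sk2(K), Gr2(R), Nrk2((size_t)R * K),
          nspot2((size_t)R * n), ngene2((size_t)p * K);
      std::vector<int> nk2(K), pr2(R);
      double G02, N02;
      int p02;
      recompute(Sk2, Gr2, G02, N02, Nrk2, nspot2, ngene2, nk2, pr2, p02);
      double err = std::fabs(G0 - G02) + std::fabs(N0 - N02);
      for (int k = 0; k < K; ++k) err += std::fabs(Sk[k] - Sk2[k]);
      for (int r = 0; r < R; ++r) err += std::fabs(Gr[r] - Gr2[r]);
      for (size_t q = 0; q < Nrk.size(); ++q) err += std::fabs(Nrk[q] - Nrk2[q]);
      for (size_t q = 0; q < nspot.size(); ++q)
        err += std::fabs(nspot[q] - nspot2[q]);
      for (size_t q = 0; q < ngene.size(); ++q)
        err += std::fabs(ngene[q] - ngene2[q]);
      if (err > 1e-6 || p0 != p02)
        stop("incremental sufficient statistics diverged from recomputation");
    }

    if (it >= burnin && (it - burnin) % thin == 0) {
      for (int i = 0; i < n; ++i) z_draws(u, i) = z[i] + 1;
      for (int j = 0; j < p; ++j) rho_draws(u, j) = rho[j];
      pi0_draws[u] = pi0;
      ++u;
    }
  }

  return List::create(_["z"] = z_draws, _["rho"] = rho_draws,
                      _["pi0"] = pi0_draws, _["log_post"] = log_post);
}

// Pairwise co-clustering frequencies across draws: entry (a, b) is the
// fraction of draws in which items a and b share a label.
// [[Rcpp::export(name = ".ppm_cpp")]]
NumericMatrix ppm_cpp(IntegerMatrix draws) {
  const int U = draws.nrow(), m = draws.ncol();
  NumericMatrix P(m, m);
  for (int u = 0; u < U; ++u)
    for (int a = 0; a < m; ++a) {
      const int la = draws(u, a);
      for (int b = a + 1; b < m; ++b)
        if (la == draws(u, b)) P(a, b) += 1.0;
    }
  for (int a = 0; a < m; ++a) {
    P(a, a) = 1.0;
    for (int b = a + 1; b < m; ++b) {
      P(a, b) /= (double)U;
      P(b, a) = P(a, b);
    }
  }
  return P;
}

// Squared-deviation loss of each draw's co-clustering indicators from the
// PPM, summed over unordered pairs.
// [[Rcpp::export(name = ".ppm_losses_cpp")]]
NumericVector ppm_losses_cpp(IntegerMatrix draws, NumericMatrix ppm) {
  const int U = draws.nrow(), m = draws.ncol();
  NumericVector loss(U);
  for (int u = 0; u < U; ++u) {
    double L = 0.0;
    for (int a = 0; a < m; ++a) {
      const int la = draws(u, a);
      for (int b = a + 1; b < m; ++b) {
        const double ind = (la == draws(u, b)) ? 1.0 : 0.0;
        const double d = ind - ppm(a, b);
        L += d * d;
      }
    }
    loss[u] = L;
  }
  return loss;
}
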
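// Marginalized N-mixture sampler: Metropolis-within-Gibbs on site-year
// log-abundance and per-count detection logits, with the latent abundance N
// summed out of the likelihood; conjugate Gibbs for all Gaussian levels.
#include <Rcpp.h>
using namespace Rcpp;

// log sum_{N >= cmax} Pois(N | lam) * prod_j Bin(c_j | N, p_j),
// evaluated by upward recurrence from N = cmax with adaptive stopping.
static double logT(double lam, const double* p, const int* cc, int J, int cap) {
  int cmax = 0;
  for (int j = 0; j < J; ++j) if (cc[j] > cmax) cmax = cc[j];
  double lt0 = R::dpois(cmax, lam, 1);
  double q1 = 1.0;
  for (int j = 0; j < J; ++j) {
    lt0 += R::dbinom(cc[j], cmax, p[j], 1);
    q1 *= (1.0 - p[j]);
  }
  // zero first term (p_j = 1 with unequal counts): whole sum is zero, since
  // p_j = 1 pins N to c_j and the counts conflict
  if (!R_finite(lt0) && lt0 < 0) return R_NegInf;
  const double base = lam * q1;
  double term = 1.0, sum = 1.0, scale = 0.0, tmax = 1.0;
  int N = cmax;
  const int hi = N + cap;
  while (N < hi) {
    double r = base / (double)(N + 1); // Poisson ratio lam/(N+1)
    for (int j = 0; j < J; ++j) r *= (double)(N + 1) / (double)(N + 1 - cc[j]);
    term *= r;
    sum += term;
    if (term > tmax) tmax = term;
    if (r < 1.0 && term < 1e-14 * tmax) break;
    if (sum > 1e280) { scale += std::log(sum); term /= sum; tmax /= sum; sum = 1.0; }
    ++N;
  }
  return lt0 + scale + std::log(sum);
}

// draw N from its conditional given lam, p, c (inverse-CDF on the recurrence)
static int drawN(double lam, const double* p, const int* cc, int J, int cap) {
  int cmax = 0;
  for (int j = 0; j < J; ++j) if (cc[j] > cmax) cmax = cc[j];
  double q1 = 1.0;
  for (int j = 0; j < J; ++j) q1 *= (1.0 - p[j]);
  const double base = lam * q1;
  // first pass: normalizing constant relative to first term
  double term = 1.0, sum = 1.0;
  int N = cmax;
  const int hi = N + cap;
  double tmax = 1.0;
  while (N < hi) {
    double r = base / (double)(N + 1);
    for (int j = 0; j < J; ++j) r *= (double)(N + 1) / (double)(N + 1 - cc[j]);
    term *= r;
    sum += term;
    if (term > tmax) tmax = term;
    if (r < 1.0 && term < 1e-14 * tmax) break;
    if (sum > 1e280) return cmax; // degenerate; keep lower bound
    ++N;
  }
  double u = R::unif_rand() * sum;
  term = 1.0; double acc = 1.0;
  N = cmax;
  while (acc < u && N < hi) {
    double r = base / (double)(N + 1);
    for (int j = 0; j < J; ++j) r *= (double)(N + 1) / (double)(N + 1 - cc[j]);
    term *= r;
    acc += term;
    ++N;
  }
  return N;
}

// [[Rcpp::export]]
double nmix_logT(double lam, NumericVector p, IntegerVector c, int cap) {
  return logT(lam, p.begin(), c.begin(), p.size(), cap);
}

// [[Rcpp::export]]
List nmix_chain(List dat, List cfg) {
  // --- data (extracted once) ---
  const IntegerVector c_ = dat["count"], syi = dat["syi"], yr = dat["yr"];
  const IntegerVector site = dat["site"], node = dat["node"], syyear = dat["syyear"];
  const NumericVector yearc = dat["yearc"];
  const int S = as<int>(dat["S"]), Nobs = c_.size(), Rs = as<int>(dat["nsites"]);
  const int K = as<int>(dat["nyears"]), Kn = as<int>(dat["nnodes"]);
  // --- config ---
  const int n_burn = as<int>(cfg["burn"]), n_keep = as<int>(cfg["keep"]), thin = as<int>(cfg["thin"]);
  const double pv = as<double>(cfg["prior_var_fixed"]);
  const double ig_shape = as<double>(cfg["ig_shape"]), ig_rate = as<double>(cfg["ig_rate"]);
  const double sd_delta_max = as<double>(cfg["sd_delta_max"]);
  const bool fix_p = as<bool>(cfg["fix_detection"]);
  const double p_fixed = as<double>(cfg["p_value"]);
  const bool delta_unif = as<bool>(cfg["delta_literal_uniform"]);
  const int cap = as<int>(cfg["n_cap"]);
  const bool keep_latent = as<bool>(cfg["keep_latent"]);

  // --- index structures ---
  std::vector<int> ostart(S, -1), olen(S, 0);
  for (int n = 0; n < Nobs; ++n) { int s = syi[n] - 1; if (ostart[s] < 0) ostart[s] = n; olen[s]++; }
  int Jmax = 0;
  for (int s = 0; s < S; ++s) Jmax = std::max(Jmax, olen[s]);
  std::vector<std::vector<int> > sy_of_year(K), sy_of_site(Rs);
  for (int s = 0; s < S; ++s) { sy_of_year[syyear[s]-1].push_back(s); sy_of_site[site[s]-1].push_back(s); }
  std::vector<std::vector<int> > sites_of_node(Kn);
  for (int i = 0; i < Rs; ++i) sites_of_node[node[i]-1].push_back(i);
  std::vector<double> cmaxs(S, 0.0);
  for (int n = 0; n < Nobs; ++n) cmaxs[syi[n]-1] = std::max(cmaxs[syi[n]-1], (double)c_[n]);

  // --- state ---
  std::vector<double> loglam(S), lp(Nobs), pcur(Nobs), omega(Rs);
  std::vector<double> alpha(Kn, 0.0), beta(Kn, 0.0), gamma(K, 0.0);
  double sig2_eps = 0.05, sig2_om = 0.3, sd_delta = 0.3;
  const double p0 = fix_p ? p_fixed : 0.6;
  for (int s = 0; s < S; ++s) loglam[s] = std::log(cmaxs[s] / p0 + 1.0);
  const double lp0 = std::log(p0 / (1.0 - p0 + 1e-12));
  for (int n = 0; n < Nobs; ++n) { lp[n] = lp0; pcur[n] = p0; }
  for (int i = 0; i < Rs; ++i) {
    double m = 0; for (size_t u = 0; u < sy_of_site[i].size(); ++u) m += loglam[sy_of_site[i][u]];
    omega[i] = m / std::max((int)sy_of_site[i].size(), 1);
  }
  for (int k = 0; k < Kn; ++k) {
    double m = 0; for (size_t u = 0; u < sites_of_node[k].size(); ++u) m += omega[sites_of_node[k][u]];
    alpha[k] = m / std::max((int)sites_of_node[k].size(), 1);
  }
  for (int t = 0; t < K; ++t) gamma[t] = lp0;

  // cached site-year log marginal likelihood
  std::vector<double> Tcur(S);
  for (int s = 0; s < S; ++s)
    Tcur[s] = logT(std::exp(loglam[s]), &pcur[ostart[s]], &c_[ostart[s]], olen[s], cap);

  // adaptive proposal log-scales
  std::vector<double> ls_ll(S, -2.0), ls_lp(Nobs, -1.0), ls_j(S, -2.0), ls_y(K, -3.0);
  double ls_lv = -3.5, ls_tr = -5.5;
  std::vector<double> pprop(Jmax), newlp_buf(Nobs), Tprop_buf(S), gshift(K);

  // delta prior log-density (normal with sampled sd, or literal U(0,100))
  // literal variant: lp = gamma_t + delta, delta ~ U(0, 100)
  #define LP_PRIOR(val, t) (delta_unif \
    ? (((val) >= gamma[t] && (val) <= gamma[t] + 100.0) ? -std::log(100.0) : R_NegInf) \
    : R::dnorm4((val), gamma[t], sd_delta, 1))

  const int n_iter = n_burn + n_keep * thin;
  NumericMatrix out_beta(n_keep, Kn), out_alpha(n_keep, Kn), out_gamma(n_keep, K), out_omega(n_keep, Rs);
  NumericVector out_se(n_keep), out_so(n_keep), out_sd(n_keep);
  NumericMatrix out_ll, out_lp; IntegerMatrix out_N;
  if (keep_latent) { out_ll = NumericMatrix(n_keep, S); out_lp = NumericMatrix(n_keep, Nobs); out_N = IntegerMatrix(n_keep, S); }

  GetRNGstate();
  for (int it = 0; it < n_iter; ++it) {
    const bool adapting = it < n_burn;
    const double aw = 2.0 / std::pow(it + 20.0, 0.6);
    const double sde = std::sqrt(sig2_eps);

    // (1) site-year log-abundance
    for (int s = 0; s < S; ++s) {
      const int i = site[s] - 1;
      const double m = omega[i] + beta[node[i]-1] * yearc[s];
      const double cur = loglam[s];
      const double prop = cur + R::norm_rand() * std::exp(ls_ll[s]);
      const double Tprop = logT(std::exp(prop), &pcur[ostart[s]], &c_[ostart[s]], olen[s], cap);
      const double la = Tprop - Tcur[s]
        + R::dnorm4(prop, m, sde, 1) - R::dnorm4(cur, m, sde, 1);
      const bool acc = R_finite(la) && std::log(R::unif_rand()) < la;
      if (acc) { loglam[s] = prop; Tcur[s] = Tprop; }
      if (adapting) ls_ll[s] += aw * ((acc ? 1.0 : 0.0) - 0.44);
    }

    if (!fix_p) {
      // (2) per-count detection logits
      for (int s = 0; s < S; ++s) {
        const double lam = std::exp(loglam[s]);
        for (int j = 0; j < olen[s]; ++j) {
          const int n = ostart[s] + j;
          const double cur = lp[n];
          const double prop = cur + R::norm_rand() * std::exp(ls_lp[n]);
          const double pold = pcur[n];
          pcur[n] = 1.0 / (1.0 + std::exp(-prop));
          const double Tprop = logT(lam, &pcur[ostart[s]], &c_[ostart[s]], olen[s], cap);
          const double la = Tprop - Tcur[s] + LP_PRIOR(prop, yr[n]-1) - LP_PRIOR(cur, yr[n]-1);
          const bool acc = R_finite(la) && std::log(R::unif_rand()) < la;
          if (acc) { lp[n] = prop; Tcur[s] = Tprop; } else pcur[n] = pold;
          if (adapting) ls_lp[n] += aw * ((acc ? 1.0 : 0.0) - 0.44);
        }
      }

      // (3) site-year ridge move: loglam += u, all p scaled by exp(-u)
      for (int s = 0; s < S; ++s) {
        const double u = R::norm_rand() * std::exp(ls_j[s]);
        const double eu = std::exp(-u);
        bool ok = true;
        double ljac = 0.0, lpr = 0.0;
        for (int j = 0; j < olen[s]; ++j) {
          const int n = ostart[s] + j;
          const double pn = pcur[n] * eu;
          if (pn >= 1.0 - 1e-12 || pn <= 1e-300) { ok = false; break; }
          pprop[j] = pn;
          const double lpn = std::log(pn / (1.0 - pn));
          ljac += -u + std::log(pcur[n] * (1.0 - pcur[n])) - std::log(pn * (1.0 - pn));
          lpr += LP_PRIOR(lpn, yr[n]-1) - LP_PRIOR(lp[n], yr[n]-1);
        }
        bool acc = false;
        if (ok) {
          const int i = site[s] - 1;
          const double m = omega[i] + beta[node[i]-1] * yearc[s];
          const double prop = loglam[s] + u;
          const double Tprop = logT(std::exp(prop), pprop.data(), &c_[ostart[s]], olen[s], cap);
          const double la = Tprop - Tcur[s]
            + R::dnorm4(prop, m, sde, 1) - R::dnorm4(loglam[s], m, sde, 1) + lpr + ljac;
          acc = R_finite(la) && std::log(R::unif_rand()) < la;
          if (acc) {
            loglam[s] = prop; Tcur[s] = Tprop;
            for (int j = 0; j < olen[s]; ++j) {
              const int n = ostart[s] + j;
              pcur[n] = pprop[j];
              lp[n] = std::log(pprop[j] / (1.0 - pprop[j]));
            }
          }
        }
        if (adapting) ls_j[s] += aw * ((acc ? 1.0 : 0.0) - 0.30);
      }

      // (4) per-year ridge move: all site-years of year t shifted, detections rescaled
      for (int t = 0; t < K; ++t) {
        const double u = R::norm_rand() * std::exp(ls_y[t]);
        const double eu = std::exp(-u);
        double la = 0.0;
        bool ok = true;
        const std::vector<int>& sv = sy_of_year[t];
        // proposal Ts stored to commit without recompute
        std::vector<double> Tp(sv.size());
        for (size_t v = 0; v < sv.size() && ok; ++v) {
          const int s = sv[v];
          for (int j = 0; j < olen[s]; ++j) {
            const int n = ostart[s] + j;
            const double pn = pcur[n] * eu;
            if (pn >= 1.0 - 1e-12 || pn <= 1e-300) { ok = false; break; }
            pprop[j] = pn;
            const double lpn = std::log(pn / (1.0 - pn));
            newlp_buf[n] = lpn;
            la += -u + std::log(pcur[n] * (1.0 - pcur[n])) - std::log(pn * (1.0 - pn));
            la += LP_PRIOR(lpn, t) - LP_PRIOR(lp[n], t);
          }
          if (!ok) break;
          const int i = site[s] - 1;
          const double m = omega[i] + beta[node[i]-1] * yearc[s];
          const double prop = loglam[s] + u;
          Tp[v] = logT(std::exp(prop), pprop.data(), &c_[ostart[s]], olen[s], cap);
          la += Tp[v] - Tcur[s];
          la += R::dnorm4(prop, m, sde, 1) - R::dnorm4(loglam[s], m, sde, 1);
        }
        bool acc = false;
        if (ok && R_finite(la) && std::log(R::unif_rand()) < la) {
          acc = true;
          for (size_t v = 0; v < sv.size(); ++v) {
            const int s = sv[v];
            loglam[s] += u; Tcur[s] = Tp[v];
            for (int j = 0; j < olen[s]; ++j) {
              const int n = ostart[s] + j;
              lp[n] = newlp_buf[n];
              pcur[n] = 1.0 / (1.0 + std::exp(-lp[n]));
            }
          }
        }
        if (adapting) ls_y[t] += aw * ((acc ? 1.0 : 0.0) - 0.30);
      }

      // (4b) global ridge moves: level (w_s = 1) and trend (w_s = yearc_s).
      // Abundance shifts by u*w_s, detections rescale to keep lambda*p fixed,
      // and gamma_t follows the mean detection-logit shift in its year
      // (triangular map, unit Jacobian in gamma).
      for (int mv = 0; mv < 2; ++mv) {
        const bool trend = (mv == 1);
        const double u = R::norm_rand() * std::exp(trend ? ls_tr : ls_lv);
        double la = 0.0;
        bool ok = true;
        std::vector<double> gsum(K, 0.0);
        std::vector<int> gcnt(K, 0);
        for (int s = 0; s < S && ok; ++s) {
          const double w = trend ? yearc[s] : 1.0;
          const double eu = std::exp(-u * w);
          for (int j = 0; j < olen[s]; ++j) {
            const int n = ostart[s] + j;
            const double pn = pcur[n] * eu;
            if (pn >= 1.0 - 1e-12 || pn <= 1e-300) { ok = false; break; }
            const double lpn = std::log(pn / (1.0 - pn));
            newlp_buf[n] = lpn;
            la += -u * w + std::log(pcur[n] * (1.0 - pcur[n])) - std::log(pn * (1.0 - pn));
            gsum[yr[n]-1] += lpn - lp[n]; gcnt[yr[n]-1]++;
          }
          if (!ok) break;
          const double prop = loglam[s] + u * w;
          // prior mean shifts identically (omega/alpha for level, beta for
          // trend), so the loglam prior term cancels
          for (int j = 0; j < olen[s]; ++j) pprop[j] = 1.0 / (1.0 + std::exp(-newlp_buf[ostart[s]+j]));
          Tprop_buf[s] = logT(std::exp(prop), pprop.data(), &c_[ostart[s]], olen[s], cap);
          la += Tprop_buf[s] - Tcur[s];
        }
        bool acc = false;
        if (ok) {
          for (int t = 0; t < K; ++t) gshift[t] = gcnt[t] ? gsum[t] / gcnt[t] : 0.0;
          // lp prior terms under shifted gamma
          for (int n = 0; n < Nobs && R_finite(la); ++n) {
            const int t = yr[n] - 1;
            if (delta_unif) {
              la += (((newlp_buf[n] >= gamma[t] + gshift[t] && newlp_buf[n] <= gamma[t] + gshift[t] + 100.0) ? -std::log(100.0) : R_NegInf)
                   - ((lp[n] >= gamma[t] && lp[n] <= gamma[t] + 100.0) ? -std::log(100.0) : R_NegInf));
            } else {
              la += R::dnorm4(newlp_buf[n], gamma[t] + gshift[t], sd_delta, 1)
                  - R::dnorm4(lp[n], gamma[t], sd_delta, 1);
            }
          }
          // gamma prior ratio under the shift
          for (int t = 0; t < K; ++t)
            la += R::dnorm4(gamma[t] + gshift[t], 0.0, std::sqrt(pv), 1)
                - R::dnorm4(gamma[t], 0.0, std::sqrt(pv), 1);
          if (trend) {
            for (int k = 0; k < Kn; ++k)
              la += R::dnorm4(beta[k] + u, 0.0, std::sqrt(pv), 1) - R::dnorm4(beta[k], 0.0, std::sqrt(pv), 1);
          } else {
            for (int k = 0; k < Kn; ++k)
              la += R::dnorm4(alpha[k] + u, 0.0, std::sqrt(pv), 1) - R::dnorm4(alpha[k], 0.0, std::sqrt(pv), 1);
          }
          if (R_finite(la) && std::log(R::unif_rand()) < la) {
            acc = true;
            for (int s = 0; s < S; ++s) {
              const double w = trend ? yearc[s] : 1.0;
              loglam[s] += u * w; Tcur[s] = Tprop_buf[s];
              for (int j = 0; j < olen[s]; ++j) {
                const int n = ostart[s] + j;
                lp[n] = newlp_buf[n];
                pcur[n] = 1.0 / (1.0 + std::exp(-lp[n]));
              }
            }
            for (int t = 0; t < K; ++t) gamma[t] += gshift[t];
            if (trend) { for (int k = 0; k < Kn; ++k) beta[k] += u; }
            else { for (int k = 0; k < Kn; ++k) alpha[k] += u; for (int i = 0; i < Rs; ++i) omega[i] += u; }
          }
        }
        if (adapting) { if (trend) ls_tr += aw * ((acc ? 1.0 : 0.0) - 0.30); else ls_lv += aw * ((acc ? 1.0 : 0.0) - 0.30); }
      }
    }

    // (5) conjugate updates for the Gaussian hierarchy
    // omega_i | loglam, beta, alpha, variances
    for (int i = 0; i < Rs; ++i) {
      double sw = 0.0;
      const std::vector<int>& sv = sy_of_site[i];
      for (size_t v = 0; v < sv.size(); ++v) {
        const int s = sv[v];
        sw += loglam[s] - beta[node[i]-1] * yearc[s];
      }
      const double prec = sv.size() / sig2_eps + 1.0 / sig2_om;
      const double mean = (sw / sig2_eps + alpha[node[i]-1] / sig2_om) / prec;
      omega[i] = mean + R::norm_rand() / std::sqrt(prec);
    }
    // alpha_k | omega
    for (int k = 0; k < Kn; ++k) {
      double sm = 0.0;
      const std::vector<int>& iv = sites_of_node[k];
      for (size_t v = 0; v < iv.size(); ++v) sm += omega[iv[v]];
      const double prec = iv.size() / sig2_om + 1.0 / pv;
      const double mean = (sm / sig2_om) / prec;
      alpha[k] = mean + R::norm_rand() / std::sqrt(prec);
    }
    // beta_k | loglam, omega
    for (int k = 0; k < Kn; ++k) {
      double sxy = 0.0, sxx = 0.0;
      const std::vector<int>& iv = sites_of_node[k];
      for (size_t v = 0; v < iv.size(); ++v) {
        const int i = iv[v];
        const std::vector<int>& sv = sy_of_site[i];
        for (size_t w = 0; w < sv.size(); ++w) {
          const int s = sv[w];
          sxy += yearc[s] * (loglam[s] - omega[i]);
          sxx += yearc[s] * yearc[s];
        }
      }
      const double prec = sxx / sig2_eps + 1.0 / pv;
      const double mean = (sxy / sig2_eps) / prec;
      beta[k] = mean + R::norm_rand() / std::sqrt(prec);
    }
    if (!fix_p && !delta_unif) {
      // gamma_t | lp, sd_delta
      for (int t = 0; t < K; ++t) {
        double sg = 0.0; int cg = 0;
        const std::vector<int>& sv = sy_of_year[t];
        for (size_t v = 0; v < sv.size(); ++v) {
          const int s = sv[v];
          for (int j = 0; j < olen[s]; ++j) { sg += lp[ostart[s]+j]; cg++; }
        }
        const double td = sd_delta * sd_delta;
        const double prec = cg / td + 1.0 / pv;
        const double mean = (sg / td) / prec;
        gamma[t] = mean + R::norm_rand() / std::sqrt(prec);
      }
      // sd_delta: uniform(0, sd_delta_max) prior on the sd
      double ssd = 0.0;
      for (int n = 0; n < Nobs; ++n) { const double r = lp[n] - gamma[yr[n]-1]; ssd += r * r; }
      for (int tries = 0; tries < 100; ++tries) {
        const double tau = R::rgamma((Nobs - 1.0) / 2.0, 2.0 / ssd);
        const double sd = 1.0 / std::sqrt(tau);
        if (sd < sd_delta_max) { sd_delta = sd; break; }
      }
    } else if (!fix_p && delta_unif) {
      // literal-uniform variant: gamma_t via random walk (non-conjugate)
      for (int t = 0; t < K; ++t) {
        const double prop = gamma[t] + R::norm_rand() * 0.1;
        double la = R::dnorm4(prop, 0.0, std::sqrt(pv), 1) - R::dnorm4(gamma[t], 0.0, std::sqrt(pv), 1);
        const std::vector<int>& sv = sy_of_year[t];
        for (size_t v = 0; v < sv.size() && R_finite(la); ++v) {
          const int s = sv[v];
          for (int j = 0; j < olen[s]; ++j) {
            const int n = ostart[s] + j;
            la += (delta_unif ? (((lp[n] >= prop && lp[n] <= prop + 100.0) ? -std::log(100.0) : R_NegInf)
                               - ((lp[n] >= gamma[t] && lp[n] <= gamma[t] + 100.0) ? -std::log(100.0) : R_NegInf)) : 0.0);
          }
        }
        if (R_finite(la) && std::log(R::unif_rand()) < la) gamma[t] = prop;
      }
    }
    // sig2_eps | residuals
    {
      double ss = 0.0;
      for (int s = 0; s < S; ++s) {
        const int i = site[s] - 1;
        const double r = loglam[s] - omega[i] - beta[node[i]-1] * yearc[s];
        ss += r * r;
      }
      sig2_eps = 1.0 / R::rgamma(ig_shape + S / 2.0, 1.0 / (ig_rate + ss / 2.0));
      double so = 0.0;
      for (int i = 0; i < Rs; ++i) { const double r = omega[i] - alpha[node[i]-1]; so += r * r; }
      sig2_om = 1.0 / R::rgamma(ig_shape + Rs / 2.0, 1.0 / (ig_rate + so / 2.0));
    }

    // store retained draw
    if (!adapting && ((it - n_burn) % thin == 0)) {
      const int k = (it - n_burn) / thin;
      if (k < n_keep) {
        for (int j = 0; j < Kn; ++j) { out_beta(k, j) = beta[j]; out_alpha(k, j) = alpha[j]; }
        for (int t = 0; t < K; ++t) out_gamma(k, t) = gamma[t];
        for (int i = 0; i < Rs; ++i) out_omega(k, i) = omega[i];
        out_se[k] = sig2_eps; out_so[k] = sig2_om; out_sd[k] = sd_delta;
        if (keep_latent) {
          for (int s = 0; s < S; ++s) {
            out_ll(k, s) = loglam[s];
            out_N(k, s) = drawN(std::exp(loglam[s]), &pcur[ostart[s]], &c_[ostart[s]], olen[s], cap);
          }
          for (int n = 0; n < Nobs; ++n) out_lp(k, n) = lp[n];
        }
      }
    }
  }
  PutRNGstate();
  List out = List::create(_["beta"] = out_beta, _["alpha"] = out_alpha, _["gamma"] = out_gamma,
                          _["omega"] = out_omega, _["sig2_eps"] = out_se, _["sig2_om"] = out_so,
                          _["sd_delta"] = out_sd);
  if (keep_latent) { out["loglam"] = out_ll; out["lp"] = out_lp; out["N"] = out_N; }
  return out;
}
#undef LP_PRIOR
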
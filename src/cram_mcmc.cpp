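// Adaptive Metropolis-within-Gibbs sampler for the capture-recapture animal
// model: hidden-Markov multistate likelihood over {R, M1, M2, Dead} with
// probit liabilities mu*[occ,cohort] + a[i,season] + b[i,season] (+ optional
// iid group effect). Breeding values use the sparse pedigree precision
// A^{-1}; variance components are updated both in the centred
// parameterization and by ancillarity-sufficiency interweaving (rescaling
// the random-effect vector), which keeps mixing acceptable near sigma = 0.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG_FLOOR = 1e-300;

struct CramData {
  IntegerMatrix events;          // n_obs x 5 (occ2..5 code 0..3; col 4 = occ6 0/1)
  IntegerVector cohort;          // n_obs, 0-based
  int C;
  IntegerVector hist_of_ped;     // n_ped, index into events or -1
  IntegerVector ped_of_hist;     // n_obs, index into pedigree rows
  IntegerVector season_of_occ;   // 4, 0-based
  int S;
  // CSR of A-inverse over the full pedigree
  IntegerVector ai_ptr, ai_idx;
  NumericVector ai_val;
  IntegerVector group;           // n_obs (0-based) or empty
  int G;
  std::vector<std::vector<int> > cohort_members;  // obs indices per cohort
  std::vector<std::vector<int> > group_members;   // obs indices per group
};

struct CramState {
  NumericMatrix mu;      // 4 x C
  NumericMatrix phiR;    // 5 x C
  NumericMatrix phiM;    // 4 x C
  NumericMatrix delta;   // 4 x C
  NumericMatrix gamma;   // 3 x C
  NumericMatrix p;       // 12 x C  (state + 3*occ)
  NumericVector p6;      // C
  NumericVector sa, sb, sg;  // S
  NumericMatrix a;       // n_ped x S
  NumericMatrix b;       // n_obs x S
  NumericMatrix g;       // G x S
  NumericVector ll;      // n_obs cached individual log-likelihoods
};

// forward-algorithm log-likelihood for observed individual io, with the
// random-effect values supplied explicitly (so proposals can be evaluated
// without mutating state)
static double indiv_ll(const CramData &d, const CramState &st, int io,
                       const double *aval, const double *bval,
                       const double *gval) {
  const int c = d.cohort[io];
  double al0 = 1.0, al1 = 0.0, al2 = 0.0, al3 = 0.0;
  double ll = 0.0;
  for (int t = 0; t < 4; ++t) {  // interval t -> occasion t+2
    const int s = d.season_of_occ[t];
    double eta = st.mu(t, c) + aval[s] + bval[s];
    if (gval) eta += gval[s];
    const double psi = R::pnorm(eta, 0.0, 1.0, 1, 0);
    const double phR = st.phiR(t, c);
    const double phM = (t >= 1) ? st.phiM(t - 1, c) : 1.0;
    const double de = st.delta(t, c);
    const double ga = (t >= 1) ? st.gamma(t - 1, c) : 0.0;
    const double fromM = (al1 + al2) * phM;
    double n0 = (al0 * phR + fromM) * (1.0 - psi);
    double n1 = al0 * phR * psi * de +
                phM * (al1 * (1.0 - ga) + al2 * ga) * psi;
    double n2 = al0 * phR * psi * (1.0 - de) +
                phM * (al1 * ga + al2 * (1.0 - ga)) * psi;
    double n3 = al3 + al0 * (1.0 - phR) + (al1 + al2) * (1.0 - phM);
    const int e = d.events(io, t);
    const double pR = st.p(0 + 3 * t, c), pM1 = st.p(1 + 3 * t, c),
                 pM2 = st.p(2 + 3 * t, c);
    if (e == 0) {
      n0 *= (1.0 - pR); n1 *= (1.0 - pM1); n2 *= (1.0 - pM2);
    } else if (e == 1) {
      n0 *= pR; n1 = n2 = n3 = 0.0;
    } else if (e == 2) {
      n1 *= pM1; n0 = n2 = n3 = 0.0;
    } else {
      n2 *= pM2; n0 = n1 = n3 = 0.0;
    }
    const double norm = n0 + n1 + n2 + n3;
    if (!(norm > LOG_FLOOR)) return R_NegInf;
    ll += std::log(norm);
    al0 = n0 / norm; al1 = n1 / norm; al2 = n2 / norm; al3 = n3 / norm;
  }
  // interval 5 -> occasion 6 (state-free observation)
  const double phR5 = st.phiR(4, c), phM5 = st.phiM(3, c);
  const double alive = al0 * phR5 + (al1 + al2) * phM5;
  const double dead = al3 + al0 * (1.0 - phR5) + (al1 + al2) * (1.0 - phM5);
  const double pr6 = d.events(io, 4) == 1
                         ? alive * st.p6[c]
                         : alive * (1.0 - st.p6[c]) + dead;
  if (!(pr6 > LOG_FLOOR)) return R_NegInf;
  return ll + std::log(pr6);
}

static double indiv_ll_cur(const CramData &d, const CramState &st, int io) {
  const int ip = d.ped_of_hist[io];
  std::vector<double> av(d.S), bv(d.S), gv(d.S);
  for (int s = 0; s < d.S; ++s) {
    av[s] = st.a(ip, s);
    bv[s] = st.b(io, s);
  }
  const bool has_g = d.group.size() > 0;
  if (has_g) {
    for (int s = 0; s < d.S; ++s) gv[s] = st.g(d.group[io], s);
  }
  return indiv_ll(d, st, io, av.data(), bv.data(),
                  has_g ? gv.data() : (double *)0);
}

static double log_half_t(double x, double df, double scale) {
  if (x < 0) return R_NegInf;
  return M_LN2 + R::dt(x / scale, df, 1) - std::log(scale);
}

// reflect a random-walk proposal into (0, 1); symmetric
static double reflect01(double x) {
  while (x < 0.0 || x > 1.0) {
    if (x < 0.0) x = -x;
    if (x > 1.0) x = 2.0 - x;
  }
  return x;
}

struct Adapt {
  double lstep;
  double target;
  Adapt() : lstep(0.0), target(0.44) {}
  double step() const { return std::exp(lstep); }
  void update(double accp, int t) {
    double rate = 1.0 / std::sqrt((double)(t + 1));
    if (rate > 0.25) rate = 0.25;
    lstep += rate * (accp - target);
    if (lstep < -10) lstep = -10;
    if (lstep > 4) lstep = 4;
  }
};

// conditional prior of a(i,s) given the rest: N(cmean, csd^2)
static void cond_prior_a(const CramData &d, const CramState &st, int i, int s,
                         double &cmean, double &csd) {
  double qii = 1.0, dot = 0.0;
  for (int k = d.ai_ptr[i]; k < d.ai_ptr[i + 1]; ++k) {
    const int j = d.ai_idx[k];
    if (j == i) qii = d.ai_val[k];
    else dot += d.ai_val[k] * st.a(j, s);
  }
  cmean = -dot / qii;
  csd = st.sa[s] / std::sqrt(qii);
}

static double quadform_a(const CramData &d, const CramState &st, int s) {
  double qf = 0.0;
  const int n = st.a.nrow();
  for (int i = 0; i < n; ++i) {
    const double ai = st.a(i, s);
    if (ai == 0.0) continue;
    double row = 0.0;
    for (int k = d.ai_ptr[i]; k < d.ai_ptr[i + 1]; ++k) {
      row += d.ai_val[k] * st.a(d.ai_idx[k], s);
    }
    qf += ai * row;
  }
  return qf;
}

// generic scalar MH update for a structural parameter affecting a set of
// observed individuals; `setter` mutates state, `restore` undoes it.
template <typename SetF>
static double structural_mh(const CramData &d, CramState &st,
                            const std::vector<int> &members, double cur,
                            double prop, double lprior_diff, SetF setter) {
  setter(prop);
  std::vector<double> llnew(members.size());
  double dll = lprior_diff;
  for (size_t k = 0; k < members.size(); ++k) {
    const int io = members[k];
    llnew[k] = indiv_ll_cur(d, st, io);
    dll += llnew[k] - st.ll[io];
  }
  const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
  if (R::unif_rand() < accp) {
    for (size_t k = 0; k < members.size(); ++k) st.ll[members[k]] = llnew[k];
  } else {
    setter(cur);
  }
  return accp;
}

// [[Rcpp::export]]
List cram_mcmc_cpp(IntegerMatrix events, IntegerVector cohort, int C,
                   IntegerVector hist_of_ped, IntegerVector season_of_occ,
                   IntegerVector ai_ptr, IntegerVector ai_idx,
                   NumericVector ai_val, IntegerVector group, int G,
                   List priors, int warmup, int iter, int thin,
                   int monitor_ll, List init) {
  CramData d;
  d.events = events; d.cohort = cohort; d.C = C;
  d.hist_of_ped = hist_of_ped;
  d.season_of_occ = season_of_occ;
  d.S = 0;
  for (int t = 0; t < 4; ++t) d.S = std::max(d.S, season_of_occ[t] + 1);
  d.ai_ptr = ai_ptr; d.ai_idx = ai_idx; d.ai_val = ai_val;
  d.group = group; d.G = G;
  const int n_obs = events.nrow();
  const int n_ped = hist_of_ped.size();
  d.ped_of_hist = IntegerVector(n_obs, -1);
  for (int i = 0; i < n_ped; ++i) {
    if (hist_of_ped[i] >= 0) d.ped_of_hist[hist_of_ped[i]] = i;
  }
  for (int io = 0; io < n_obs; ++io) {
    if (d.ped_of_hist[io] < 0) stop("history without pedigree row");
  }
  d.cohort_members.assign(C, std::vector<int>());
  for (int io = 0; io < n_obs; ++io) d.cohort_members[cohort[io]].push_back(io);
  const bool has_g = group.size() > 0;
  if (has_g) {
    d.group_members.assign(G, std::vector<int>());
    for (int io = 0; io < n_obs; ++io) d.group_members[group[io]].push_back(io);
  }

  const double mu_df = priors["mu_df"], mu_scale = priors["mu_scale"];
  const double sig_df = priors["sigma_df"], sig_scale = priors["sigma_scale"];
  NumericVector pm2 = priors["pM2_shape"];

  RNGScope scope;

  // ---- initial state (moderately dispersed; RNG-driven so chains differ)
  CramState st;
  st.mu = NumericMatrix(4, C);
  st.phiR = NumericMatrix(5, C); st.phiM = NumericMatrix(4, C);
  st.delta = NumericMatrix(4, C); st.gamma = NumericMatrix(3, C);
  st.p = NumericMatrix(12, C); st.p6 = NumericVector(C);
  st.sa = NumericVector(d.S); st.sb = NumericVector(d.S);
  st.sg = NumericVector(d.S);
  st.a = NumericMatrix(n_ped, d.S); st.b = NumericMatrix(n_obs, d.S);
  st.g = NumericMatrix(std::max(G, 1), d.S);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < 4; ++t) st.mu(t, c) = R::norm_rand() * 0.5;
    for (int t = 0; t < 5; ++t) st.phiR(t, c) = 0.5 + 0.3 * R::unif_rand();
    for (int t = 0; t < 4; ++t) st.phiM(t, c) = 0.5 + 0.3 * R::unif_rand();
    for (int t = 0; t < 4; ++t) st.delta(t, c) = 0.3 + 0.4 * R::unif_rand();
    for (int t = 0; t < 3; ++t) st.gamma(t, c) = 0.1 + 0.3 * R::unif_rand();
    for (int k = 0; k < 12; ++k) {
      st.p(k, c) = (k % 3 == 2) ? 0.05 + 0.1 * R::unif_rand()
                                : 0.3 + 0.4 * R::unif_rand();
    }
    st.p6[c] = 0.3 + 0.4 * R::unif_rand();
  }
  for (int s = 0; s < d.S; ++s) {
    st.sa[s] = 0.5 + 0.5 * R::unif_rand();
    st.sb[s] = 0.5 + 0.5 * R::unif_rand();
    st.sg[s] = 0.2 + 0.2 * R::unif_rand();
    for (int i = 0; i < n_ped; ++i) st.a(i, s) = 0.1 * R::norm_rand();
    for (int i = 0; i < n_obs; ++i) st.b(i, s) = 0.1 * R::norm_rand();
    for (int k = 0; k < G; ++k) st.g(k, s) = 0.05 * R::norm_rand();
  }
  if (init.size() > 0) {  // optional overrides (warm starts, diagnostics);
                          // cloned so the sampler never mutates caller data
    if (init.containsElementNamed("mu")) st.mu = clone(as<NumericMatrix>(init["mu"]));
    if (init.containsElementNamed("sa")) st.sa = clone(as<NumericVector>(init["sa"]));
    if (init.containsElementNamed("sb")) st.sb = clone(as<NumericVector>(init["sb"]));
    if (init.containsElementNamed("phiR")) st.phiR = clone(as<NumericMatrix>(init["phiR"]));
    if (init.containsElementNamed("phiM")) st.phiM = clone(as<NumericMatrix>(init["phiM"]));
    if (init.containsElementNamed("delta")) st.delta = clone(as<NumericMatrix>(init["delta"]));
    if (init.containsElementNamed("gamma")) st.gamma = clone(as<NumericMatrix>(init["gamma"]));
    if (init.containsElementNamed("p")) st.p = clone(as<NumericMatrix>(init["p"]));
    if (init.containsElementNamed("p6")) st.p6 = clone(as<NumericVector>(init["p6"]));
    if (init.containsElementNamed("a")) st.a = clone(as<NumericMatrix>(init["a"]));
    if (init.containsElementNamed("b")) st.b = clone(as<NumericMatrix>(init["b"]));
  }
  st.ll = NumericVector(n_obs);
  for (int io = 0; io < n_obs; ++io) {
    st.ll[io] = indiv_ll_cur(d, st, io);
    if (!R_finite(st.ll[io])) stop("non-finite initial likelihood");
  }

  // ---- adaptation bookkeeping
  std::vector<Adapt> ad_mu(4 * C), ad_phiR(5 * C), ad_phiM(4 * C),
      ad_delta(4 * C), ad_gamma(3 * C), ad_p(12 * C), ad_p6(C);
  std::vector<Adapt> ad_a(d.S), ad_b(d.S), ad_g(d.S);
  std::vector<Adapt> ad_sa(d.S), ad_sb(d.S), ad_sg(d.S),
      ad_sa_nc(d.S), ad_sb_nc(d.S), ad_sg_nc(d.S), ad_sab(d.S);
  for (int s = 0; s < d.S; ++s) {
    ad_sa[s].target = ad_sb[s].target = ad_sg[s].target = 0.44;
    ad_sa_nc[s].target = ad_sb_nc[s].target = ad_sg_nc[s].target = 0.44;
    ad_sa[s].lstep = ad_sb[s].lstep = -1.0;
  }
  for (size_t k = 0; k < ad_mu.size(); ++k) ad_mu[k].lstep = -1.5;

  const int n_keep = iter / thin;
  const int P = 4 * C + 2 * d.S + (has_g ? d.S : 0) + 5 * C + 4 * C + 4 * C +
                3 * C + 12 * C + C + (monitor_ll ? 1 : 0);
  NumericMatrix draws(n_keep, P);
  int row = 0;

  std::vector<double> llnew_buf;

  for (int it = 0; it < warmup + iter; ++it) {
    const bool adapting = it < warmup;

    // ---- breeding values a(i, s)
    for (int s = 0; s < d.S; ++s) {
      double acc = 0.0;
      int nacc = 0;
      for (int i = 0; i < n_ped; ++i) {
        double cmean, csd;
        cond_prior_a(d, st, i, s, cmean, csd);
        const int io = d.hist_of_ped[i];
        if (io < 0) {  // no data: exact Gibbs draw from conditional prior
          st.a(i, s) = cmean + csd * R::norm_rand();
          continue;
        }
        const double cur = st.a(i, s);
        const double prop = cur + ad_a[s].step() * csd * R::norm_rand();
        std::vector<double> av(d.S), bv(d.S), gv(d.S);
        for (int q = 0; q < d.S; ++q) {
          av[q] = st.a(i, q); bv[q] = st.b(io, q);
          if (has_g) gv[q] = st.g(d.group[io], q);
        }
        av[s] = prop;
        const double llp = indiv_ll(d, st, io, av.data(), bv.data(),
                                    has_g ? gv.data() : (double *)0);
        const double dpr = R::dnorm(prop, cmean, csd, 1) -
                           R::dnorm(cur, cmean, csd, 1);
        const double dll = llp - st.ll[io] + dpr;
        const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
        acc += accp; ++nacc;
        if (R::unif_rand() < accp) {
          st.a(i, s) = prop;
          st.ll[io] = llp;
        }
        // independence proposal from the conditional prior: acceptance is
        // the bare likelihood ratio; decorrelates fully whenever the
        // individual's data are weakly informative
        {
          const double prop2 = cmean + csd * R::norm_rand();
          av[s] = prop2;
          const double llp2 = indiv_ll(d, st, io, av.data(), bv.data(),
                                       has_g ? gv.data() : (double *)0);
          const double dll2 = llp2 - st.ll[io];
          if (dll2 >= 0 || R::unif_rand() < std::exp(dll2)) {
            st.a(i, s) = prop2;
            st.ll[io] = llp2;
          }
        }
      }
      if (adapting && nacc) ad_a[s].update(acc / nacc, it);
    }

    // ---- individual effects b(io, s)
    for (int s = 0; s < d.S; ++s) {
      double acc = 0.0;
      for (int io = 0; io < n_obs; ++io) {
        const double cur = st.b(io, s);
        const double prop = cur + ad_b[s].step() * st.sb[s] * R::norm_rand();
        const int ip = d.ped_of_hist[io];
        std::vector<double> av(d.S), bv(d.S), gv(d.S);
        for (int q = 0; q < d.S; ++q) {
          av[q] = st.a(ip, q); bv[q] = st.b(io, q);
          if (has_g) gv[q] = st.g(d.group[io], q);
        }
        bv[s] = prop;
        const double llp = indiv_ll(d, st, io, av.data(), bv.data(),
                                    has_g ? gv.data() : (double *)0);
        const double dll = llp - st.ll[io] +
                           R::dnorm(prop, 0.0, st.sb[s], 1) -
                           R::dnorm(cur, 0.0, st.sb[s], 1);
        const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
        acc += accp;
        if (R::unif_rand() < accp) {
          st.b(io, s) = prop;
          st.ll[io] = llp;
        }
        {  // independence proposal from the prior (see a-update)
          const double prop2 = st.sb[s] * R::norm_rand();
          bv[s] = prop2;
          const double llp2 = indiv_ll(d, st, io, av.data(), bv.data(),
                                       has_g ? gv.data() : (double *)0);
          const double dll2 = llp2 - st.ll[io];
          if (dll2 >= 0 || R::unif_rand() < std::exp(dll2)) {
            st.b(io, s) = prop2;
            st.ll[io] = llp2;
          }
        }
      }
      if (adapting) ad_b[s].update(acc / n_obs, it);
    }

    // ---- transfer move: redraw the (a, b) split at fixed sum. Within a
    // season the likelihood depends on a + b only, so this is an exact
    // Gibbs draw from the product of the pedigree-conditional prior of a
    // and the iid prior of b; it decorrelates the additive/individual
    // split, which single-site updates alone mix very slowly.
    for (int s = 0; s < d.S; ++s) {
      const double vb = st.sb[s] * st.sb[s];
      for (int io = 0; io < n_obs; ++io) {
        const int i = d.ped_of_hist[io];
        double cmean, csd;
        cond_prior_a(d, st, i, s, cmean, csd);
        const double va = csd * csd;
        const double sum = st.a(i, s) + st.b(io, s);
        const double prec = 1.0 / va + 1.0 / vb;
        const double pmean = (cmean / va + sum / vb) / prec;
        const double anew = pmean + R::norm_rand() / std::sqrt(prec);
        st.a(i, s) = anew;
        st.b(io, s) = sum - anew;
      }
    }

    // ---- optional group effects g(k, s)
    if (has_g) {
      for (int s = 0; s < d.S; ++s) {
        double acc = 0.0;
        for (int k = 0; k < G; ++k) {
          const double cur = st.g(k, s);
          const double prop = cur + ad_g[s].step() * std::max(st.sg[s], 0.02) *
                                        R::norm_rand();
          const double dpr = R::dnorm(prop, 0.0, st.sg[s], 1) -
                             R::dnorm(cur, 0.0, st.sg[s], 1);
          st.g(k, s) = prop;
          double dll = dpr;
          const std::vector<int> &mem = d.group_members[k];
          llnew_buf.resize(mem.size());
          for (size_t m = 0; m < mem.size(); ++m) {
            llnew_buf[m] = indiv_ll_cur(d, st, mem[m]);
            dll += llnew_buf[m] - st.ll[mem[m]];
          }
          const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
          acc += accp;
          if (R::unif_rand() < accp) {
            for (size_t m = 0; m < mem.size(); ++m) st.ll[mem[m]] = llnew_buf[m];
          } else {
            st.g(k, s) = cur;
          }
        }
        if (adapting && G) ad_g[s].update(acc / G, it);
      }
    }

    // ---- intercepts mu(t, c)
    for (int c = 0; c < C; ++c) {
      for (int t = 0; t < 4; ++t) {
        Adapt &ad = ad_mu[t + 4 * c];
        const double cur = st.mu(t, c);
        const double prop = cur + ad.step() * R::norm_rand();
        const double dpr = R::dt(prop / mu_scale, mu_df, 1) -
                           R::dt(cur / mu_scale, mu_df, 1);
        const double accp = structural_mh(
            d, st, d.cohort_members[c], cur, prop, dpr,
            [&](double v) { st.mu(t, c) = v; });
        if (adapting) ad.update(accp, it);
      }
    }

    // ---- structural probabilities (uniform priors unless noted)
    for (int c = 0; c < C; ++c) {
      const std::vector<int> &mem = d.cohort_members[c];
      for (int t = 0; t < 5; ++t) {
        Adapt &ad = ad_phiR[t + 5 * c];
        const double cur = st.phiR(t, c);
        const double prop = reflect01(cur + ad.step() * R::norm_rand());
        const double accp = structural_mh(d, st, mem, cur, prop, 0.0,
                                          [&](double v) { st.phiR(t, c) = v; });
        if (adapting) ad.update(accp, it);
      }
      for (int t = 0; t < 4; ++t) {
        Adapt &ad = ad_phiM[t + 4 * c];
        const double cur = st.phiM(t, c);
        const double prop = reflect01(cur + ad.step() * R::norm_rand());
        const double accp = structural_mh(d, st, mem, cur, prop, 0.0,
                                          [&](double v) { st.phiM(t, c) = v; });
        if (adapting) ad.update(accp, it);
      }
      for (int t = 0; t < 4; ++t) {
        Adapt &ad = ad_delta[t + 4 * c];
        const double cur = st.delta(t, c);
        const double prop = reflect01(cur + ad.step() * R::norm_rand());
        const double accp = structural_mh(d, st, mem, cur, prop, 0.0,
                                          [&](double v) { st.delta(t, c) = v; });
        if (adapting) ad.update(accp, it);
      }
      for (int t = 0; t < 3; ++t) {
        Adapt &ad = ad_gamma[t + 3 * c];
        const double cur = st.gamma(t, c);
        const double prop = reflect01(cur + ad.step() * R::norm_rand());
        const double accp = structural_mh(d, st, mem, cur, prop, 0.0,
                                          [&](double v) { st.gamma(t, c) = v; });
        if (adapting) ad.update(accp, it);
      }
      for (int k = 0; k < 12; ++k) {
        Adapt &ad = ad_p[k + 12 * c];
        const double cur = st.p(k, c);
        const double prop = reflect01(cur + ad.step() * R::norm_rand());
        double dpr = 0.0;
        if (k % 3 == 2) {  // M2 detection: informative Beta prior
          dpr = R::dbeta(prop, pm2[0], pm2[1], 1) -
                R::dbeta(cur, pm2[0], pm2[1], 1);
        }
        const double accp = structural_mh(d, st, mem, cur, prop, dpr,
                                          [&](double v) { st.p(k, c) = v; });
        if (adapting) ad.update(accp, it);
      }
      {
        Adapt &ad = ad_p6[c];
        const double cur = st.p6[c];
        const double prop = reflect01(cur + ad.step() * R::norm_rand());
        const double accp = structural_mh(d, st, mem, cur, prop, 0.0,
                                          [&](double v) { st.p6[c] = v; });
        if (adapting) ad.update(accp, it);
      }
    }

    // ---- variance components: centred update, then ASIS rescale
    for (int s = 0; s < d.S; ++s) {
      {  // centred: p(sigma | a) via the multivariate-normal prior density
        const double cur = st.sa[s];
        const double prop = cur * std::exp(ad_sa[s].step() * R::norm_rand());
        const double qf = quadform_a(d, st, s);
        const double lp_cur = log_half_t(cur, sig_df, sig_scale) -
                              n_ped * std::log(cur) - qf / (2.0 * cur * cur);
        const double lp_prop = log_half_t(prop, sig_df, sig_scale) -
                               n_ped * std::log(prop) - qf / (2.0 * prop * prop);
        const double dll = lp_prop - lp_cur + std::log(prop / cur);
        const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
        if (R::unif_rand() < accp) st.sa[s] = prop;
        if (adapting) ad_sa[s].update(accp, it);
      }
      {  // ASIS: hold u = a / sigma fixed, rescale a with sigma
        const double cur = st.sa[s];
        const double prop = cur * std::exp(ad_sa_nc[s].step() * R::norm_rand());
        const double r = prop / cur;
        double dll = log_half_t(prop, sig_df, sig_scale) -
                     log_half_t(cur, sig_df, sig_scale) + std::log(r);
        llnew_buf.resize(n_obs);
        for (int io = 0; io < n_obs; ++io) {
          const int ip = d.ped_of_hist[io];
          std::vector<double> av(d.S), bv(d.S), gv(d.S);
          for (int q = 0; q < d.S; ++q) {
            av[q] = st.a(ip, q); bv[q] = st.b(io, q);
            if (has_g) gv[q] = st.g(d.group[io], q);
          }
          av[s] *= r;
          llnew_buf[io] = indiv_ll(d, st, io, av.data(), bv.data(),
                                   has_g ? gv.data() : (double *)0);
          dll += llnew_buf[io] - st.ll[io];
        }
        const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
        if (R::unif_rand() < accp) {
          st.sa[s] = prop;
          for (int i = 0; i < n_ped; ++i) st.a(i, s) *= r;
          for (int io = 0; io < n_obs; ++io) st.ll[io] = llnew_buf[io];
        }
        if (adapting) ad_sa_nc[s].update(accp, it);
      }
      {  // sigma_b centred
        const double cur = st.sb[s];
        const double prop = cur * std::exp(ad_sb[s].step() * R::norm_rand());
        double ssq = 0.0;
        for (int io = 0; io < n_obs; ++io) ssq += st.b(io, s) * st.b(io, s);
        const double lp_cur = log_half_t(cur, sig_df, sig_scale) -
                              n_obs * std::log(cur) - ssq / (2.0 * cur * cur);
        const double lp_prop = log_half_t(prop, sig_df, sig_scale) -
                               n_obs * std::log(prop) - ssq / (2.0 * prop * prop);
        const double dll = lp_prop - lp_cur + std::log(prop / cur);
        const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
        if (R::unif_rand() < accp) st.sb[s] = prop;
        if (adapting) ad_sb[s].update(accp, it);
      }
      {  // sigma_b ASIS
        const double cur = st.sb[s];
        const double prop = cur * std::exp(ad_sb_nc[s].step() * R::norm_rand());
        const double r = prop / cur;
        double dll = log_half_t(prop, sig_df, sig_scale) -
                     log_half_t(cur, sig_df, sig_scale) + std::log(r);
        llnew_buf.resize(n_obs);
        for (int io = 0; io < n_obs; ++io) {
          const int ip = d.ped_of_hist[io];
          std::vector<double> av(d.S), bv(d.S), gv(d.S);
          for (int q = 0; q < d.S; ++q) {
            av[q] = st.a(ip, q); bv[q] = st.b(io, q);
            if (has_g) gv[q] = st.g(d.group[io], q);
          }
          bv[s] *= r;
          llnew_buf[io] = indiv_ll(d, st, io, av.data(), bv.data(),
                                   has_g ? gv.data() : (double *)0);
          dll += llnew_buf[io] - st.ll[io];
        }
        const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
        if (R::unif_rand() < accp) {
          st.sb[s] = prop;
          for (int io = 0; io < n_obs; ++io) {
            st.b(io, s) *= r;
            st.ll[io] = llnew_buf[io];
          }
        }
        if (adapting) ad_sb_nc[s].update(accp, it);
      }
      {  // joint (sigma_a, sigma_b) ASIS: rescale both fields together.
         // With u_a = a/sigma_a and u_b = b/sigma_b held fixed, an
         // anti-correlated 2-D proposal can move variance mass between the
         // additive and individual components, a direction in which the
         // single-component moves mix very slowly.
        const double cura = st.sa[s], curb = st.sb[s];
        const double e1 = ad_sab[s].step() * R::norm_rand();
        const double e2 = ad_sab[s].step() * R::norm_rand();
        const double propa = cura * std::exp(e1 - e2);
        const double propb = curb * std::exp(e2 - e1);
        const double ra = propa / cura, rb = propb / curb;
        double dll = log_half_t(propa, sig_df, sig_scale) -
                     log_half_t(cura, sig_df, sig_scale) +
                     log_half_t(propb, sig_df, sig_scale) -
                     log_half_t(curb, sig_df, sig_scale) +
                     std::log(ra) + std::log(rb);
        llnew_buf.resize(n_obs);
        for (int io = 0; io < n_obs; ++io) {
          const int ip = d.ped_of_hist[io];
          std::vector<double> av(d.S), bv(d.S), gv(d.S);
          for (int q = 0; q < d.S; ++q) {
            av[q] = st.a(ip, q); bv[q] = st.b(io, q);
            if (has_g) gv[q] = st.g(d.group[io], q);
          }
          av[s] *= ra; bv[s] *= rb;
          llnew_buf[io] = indiv_ll(d, st, io, av.data(), bv.data(),
                                   has_g ? gv.data() : (double *)0);
          dll += llnew_buf[io] - st.ll[io];
        }
        const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
        if (R::unif_rand() < accp) {
          st.sa[s] = propa; st.sb[s] = propb;
          for (int i = 0; i < n_ped; ++i) st.a(i, s) *= ra;
          for (int io = 0; io < n_obs; ++io) {
            st.b(io, s) *= rb;
            st.ll[io] = llnew_buf[io];
          }
        }
        if (adapting) ad_sab[s].update(accp, it);
      }
      if (has_g) {  // sigma_g centred + ASIS
        {
          const double cur = st.sg[s];
          const double prop = cur * std::exp(ad_sg[s].step() * R::norm_rand());
          double ssq = 0.0;
          for (int k = 0; k < G; ++k) ssq += st.g(k, s) * st.g(k, s);
          const double dll =
              log_half_t(prop, sig_df, sig_scale) -
              log_half_t(cur, sig_df, sig_scale) -
              G * (std::log(prop) - std::log(cur)) -
              ssq / 2.0 * (1.0 / (prop * prop) - 1.0 / (cur * cur)) +
              std::log(prop / cur);
          const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
          if (R::unif_rand() < accp) st.sg[s] = prop;
          if (adapting) ad_sg[s].update(accp, it);
        }
        {
          const double cur = st.sg[s];
          const double prop = cur * std::exp(ad_sg_nc[s].step() * R::norm_rand());
          const double r = prop / cur;
          double dll = log_half_t(prop, sig_df, sig_scale) -
                       log_half_t(cur, sig_df, sig_scale) + std::log(r);
          llnew_buf.resize(n_obs);
          for (int k = 0; k < G; ++k) st.g(k, s) *= r;
          for (int io = 0; io < n_obs; ++io) {
            llnew_buf[io] = indiv_ll_cur(d, st, io);
            dll += llnew_buf[io] - st.ll[io];
          }
          const double accp = (dll >= 0) ? 1.0 : std::exp(dll);
          if (R::unif_rand() < accp) {
            st.sg[s] = prop;
            for (int io = 0; io < n_obs; ++io) st.ll[io] = llnew_buf[io];
          } else {
            for (int k = 0; k < G; ++k) st.g(k, s) /= r;
          }
          if (adapting) ad_sg_nc[s].update(accp, it);
        }
      }
    }

    // ---- record draw
    if (!adapting && ((it - warmup) % thin == 0)) {
      int col = 0;
      for (int c = 0; c < C; ++c)
        for (int t = 0; t < 4; ++t) draws(row, col++) = st.mu(t, c);
      for (int s = 0; s < d.S; ++s) draws(row, col++) = st.sa[s];
      for (int s = 0; s < d.S; ++s) draws(row, col++) = st.sb[s];
      if (has_g)
        for (int s = 0; s < d.S; ++s) draws(row, col++) = st.sg[s];
      for (int c = 0; c < C; ++c)
        for (int t = 0; t < 5; ++t) draws(row, col++) = st.phiR(t, c);
      for (int c = 0; c < C; ++c)
        for (int t = 0; t < 4; ++t) draws(row, col++) = st.phiM(t, c);
      for (int c = 0; c < C; ++c)
        for (int t = 0; t < 4; ++t) draws(row, col++) = st.delta(t, c);
      for (int c = 0; c < C; ++c)
        for (int t = 0; t < 3; ++t) draws(row, col++) = st.gamma(t, c);
      for (int c = 0; c < C; ++c)
        for (int k = 0; k < 12; ++k) draws(row, col++) = st.p(k, c);
      for (int c = 0; c < C; ++c) draws(row, col++) = st.p6[c];
      if (monitor_ll) {
        double tot = 0.0;
        for (int io = 0; io < n_obs; ++io) tot += st.ll[io];
        draws(row, col++) = tot;
      }
      ++row;
    }

    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws);
}

// forward-algorithm log-likelihoods for a full parameter set; mirror of the
// pure-R implementation, used for cross-validation and fast batch evaluation
// [[Rcpp::export]]
NumericVector cram_loglik_cpp(IntegerMatrix events, IntegerVector cohort,
                              IntegerVector season_of_occ, NumericMatrix mu,
                              NumericMatrix phiR, NumericMatrix phiM,
                              NumericMatrix delta, NumericMatrix gamma,
                              NumericMatrix p, NumericVector p6,
                              NumericMatrix a, NumericMatrix b) {
  CramData d;
  d.events = events; d.cohort = cohort; d.C = p6.size();
  d.season_of_occ = season_of_occ;
  d.S = 0;
  for (int t = 0; t < 4; ++t) d.S = std::max(d.S, season_of_occ[t] + 1);
  CramState st;
  st.mu = mu; st.phiR = phiR; st.phiM = phiM; st.delta = delta;
  st.gamma = gamma; st.p = p; st.p6 = p6;
  const int n = events.nrow();
  NumericVector out(n);
  std::vector<double> av(d.S), bv(d.S);
  for (int io = 0; io < n; ++io) {
    for (int s = 0; s < d.S; ++s) {
      av[s] = a(io, s);
      bv[s] = b(io, s);
    }
    out[io] = indiv_ll(d, st, io, av.data(), bv.data(), (double *)0);
  }
  return out;
}
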
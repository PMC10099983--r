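// Metropolis-within-Gibbs sampler for the integrated population model.
// Scalar parameters use adaptive Gaussian random walks (target acceptance
// 0.44); latent integer abundances use rounded-Gaussian symmetric proposals.
// Adaptation runs in batches during burn-in only, so retained draws come
// from a fixed kernel. All randomness goes through R's RNG (seeded in R).
//
// Performance notes: the CJS multinomial likelihood is cached per m-array
// release row and only affected rows are recomputed per proposal; Poisson /
// binomial log-densities use a lgamma lookup table (all observed and latent
// counts are integers); per-occasion log survival/detection tables are kept
// alongside the natural-scale rates.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// parameter layout ---------------------------------------------------------
// 0..8   mu: pB_Y pB_A CS_Y CS_A pNS sN_Y sN_A sJ sA   (natural scale)
// 9..13  slopes: bR_pNS bT_pNS bR_sN bT_sN bR_sJ       (link scale)
// 14..19 sigma year-effect SDs: pB CS pNS sN sJ sA
// 20     q (yearling share of immigrants)
// 21 + r*T + t            eps[r][t], r in the sigma order above
// O0 + (t-1), t=1..T-1    Omega_tot for (0-based) year t
// L0, L0+1                N_Y[0], N_A[0]
// L0+2+4*(t-1)+k, t>=1    localY, ImmY, survA, ImmA (k = 0..3)
// M0 + m                  imputed standardized covariates

static const int R_PB = 0, R_CS = 1, R_PNS = 2, R_SN = 3, R_SJ = 4, R_SA = 5;
static const double NEG_INF = -std::numeric_limits<double>::infinity();

static std::vector<double> LGTAB; // lgamma(k + 1)
static void ensure_lgtab(int n) {
  int old = LGTAB.size();
  if (old > n) return;
  LGTAB.resize(n + 1);
  for (int k = (old ? old : 1); k <= n; k++)
    LGTAB[k] = LGTAB[k - 1] + std::log((double)k);
}
static inline double lgam1(double x) { // lgamma(x + 1), x integer-valued
  int k = (int)(x + 0.5);
  if (k < (int)LGTAB.size()) return LGTAB[k];
  return std::lgamma(x + 1.0);
}
static inline double lpois(double x, double mu) {
  if (mu <= 0) return x == 0 ? 0.0 : NEG_INF;
  return x * std::log(mu) - mu - lgam1(x);
}
static inline double lbinom(double x, double n, double p) {
  if (x < 0 || x > n) return NEG_INF;
  return lgam1(n) - lgam1(x) - lgam1(n - x)
         + x * std::log(p) + (n - x) * std::log1p(-p);
}
static inline double lnorm(double x, double s) {
  return -0.5 * (x / s) * (x / s) - std::log(s) - 0.9189385332046727;
}

struct Model {
  int T, nmiss;
  // data
  IntegerMatrix marrJ, marrA;
  NumericMatrix clutch_n, clutch_sum, clutch_lfact;
  NumericMatrix nf_nsucc, nf_sumf, nf_sumcf, nf_lchoose;
  IntegerMatrix nf_zero;     // cols: age(0/1), year(0-based), clutch, count
  IntegerVector fc, eggs, fl, nr;
  NumericVector pCapB;
  std::vector<double> cov[3]; // rainPH, tempPH, rainPF (imputed in place)
  IntegerMatrix missIdx;      // cols: var(0..2), year(0-based)
  bool use_cjs, use_clutch, use_nest, use_counts, use_state;
  double omega_max, N1_max, sig_max, beta_bound, cs_max;
  // state
  std::vector<double> par;
  int O0, L0, M0, P;
  // derived natural-scale rates and log caches
  std::vector<double> pB[2], CS[2], sN[2], Fec[2], pNS, sJ, sA, NY, NAd;
  std::vector<double> lsJ, lsA, p_[2], lp[2], l1mp[2];
  // zero-fledged nests grouped by year for nest_ll_year
  std::vector<std::vector<int>> zero_by_year; // indices into nf_zero rows
  // cached log-likelihood components
  std::vector<double> row_ll[2]; // CJS per release row, [0]=juv [1]=ad
  double c_cjs;
  std::vector<double> c_clutch, c_nest, c_counts, c_state;
  double c_eps[6], c_miss;

  double eps(int r, int t) const { return par[21 + r * T + t]; }
  double omega(int t) const { return par[O0 + t - 1]; } // t >= 1
  double latent(int t, int k) const { return par[L0 + 2 + 4 * (t - 1) + k]; }

  static double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
  static double logit(double x) { return std::log(x / (1.0 - x)); }

  void init(List d, NumericVector p0) {
    T = as<int>(d["T"]);
    marrJ = as<IntegerMatrix>(d["marrJ"]);
    marrA = as<IntegerMatrix>(d["marrA"]);
    clutch_n = as<NumericMatrix>(d["clutch_n"]);
    clutch_sum = as<NumericMatrix>(d["clutch_sum"]);
    clutch_lfact = as<NumericMatrix>(d["clutch_lfact"]);
    nf_nsucc = as<NumericMatrix>(d["nf_nsucc"]);
    nf_sumf = as<NumericMatrix>(d["nf_sumf"]);
    nf_sumcf = as<NumericMatrix>(d["nf_sumcf"]);
    nf_lchoose = as<NumericMatrix>(d["nf_lchoose"]);
    nf_zero = as<IntegerMatrix>(d["nf_zero"]);
    fc = as<IntegerVector>(d["fc"]);
    eggs = as<IntegerVector>(d["eggs"]);
    fl = as<IntegerVector>(d["fl"]);
    nr = as<IntegerVector>(d["nr"]);
    pCapB = as<NumericVector>(d["pCapB"]);
    NumericVector r1 = d["rainPH"], r2 = d["tempPH"], r3 = d["rainPF"];
    cov[0].assign(r1.begin(), r1.end());
    cov[1].assign(r2.begin(), r2.end());
    cov[2].assign(r3.begin(), r3.end());
    missIdx = as<IntegerMatrix>(d["missIdx"]);
    nmiss = missIdx.nrow();
    LogicalVector fl_ = d["flags"];
    use_cjs = fl_[0]; use_clutch = fl_[1]; use_nest = fl_[2];
    use_counts = fl_[3]; use_state = fl_[4];
    NumericVector pb = d["prior_bounds"];
    omega_max = pb[0]; N1_max = pb[1]; sig_max = pb[2];
    beta_bound = pb[3]; cs_max = pb[4];
    O0 = 21 + 6 * T;
    L0 = O0 + (T - 1);
    M0 = L0 + 2 + 4 * (T - 1);
    P = M0 + nmiss;
    par.assign(p0.begin(), p0.end());
    if ((int)par.size() != P) stop("parameter vector has wrong length");
    int big = 10;
    for (int t = 0; t < T; t++)
      big = std::max(big, std::max(fc[t], std::max(eggs[t], fl[t])));
    ensure_lgtab((int)std::max((double)big, N1_max * 4 + 1000) + 10);
    for (int a = 0; a < 2; a++) {
      pB[a].assign(T, 0); CS[a].assign(T, 0); sN[a].assign(T, 0);
      Fec[a].assign(T, 0); p_[a].assign(T, 0); lp[a].assign(T, 0);
      l1mp[a].assign(T, 0);
    }
    pNS.assign(T, 0); sJ.assign(T, 0); sA.assign(T, 0);
    lsJ.assign(T, 0); lsA.assign(T, 0);
    NY.assign(T, 0); NAd.assign(T, 0);
    c_clutch.assign(T, 0); c_nest.assign(T, 0);
    c_counts.assign(T, 0); c_state.assign(T, 0);
    row_ll[0].assign(T - 1, 0); row_ll[1].assign(T - 1, 0);
    zero_by_year.assign(T, {});
    for (int z = 0; z < nf_zero.nrow(); z++)
      zero_by_year[nf_zero(z, 1)].push_back(z);
    refresh_all();
  }

  void apply_missing() {
    for (int m = 0; m < nmiss; m++)
      cov[missIdx(m, 0)][missIdx(m, 1)] = par[M0 + m];
  }

  void update_rates_year(int t) {
    pB[0][t] = invlogit(logit(par[0]) + eps(R_PB, t));
    pB[1][t] = invlogit(logit(par[1]) + eps(R_PB, t));
    CS[0][t] = std::exp(std::log(par[2]) + eps(R_CS, t));
    CS[1][t] = std::exp(std::log(par[3]) + eps(R_CS, t));
    pNS[t] = invlogit(logit(par[4]) + par[9] * cov[0][t] + par[10] * cov[1][t]
                      + eps(R_PNS, t));
    sN[0][t] = invlogit(logit(par[5]) + par[11] * cov[0][t]
                        + par[12] * cov[1][t] + eps(R_SN, t));
    sN[1][t] = invlogit(logit(par[6]) + par[11] * cov[0][t]
                        + par[12] * cov[1][t] + eps(R_SN, t));
    sJ[t] = invlogit(logit(par[7]) + par[13] * cov[2][t] + eps(R_SJ, t));
    sA[t] = invlogit(logit(par[8]) + eps(R_SA, t));
    for (int a = 0; a < 2; a++) {
      Fec[a][t] = pB[a][t] * CS[a][t] * pNS[t] * sN[a][t];
      p_[a][t] = pB[a][t] * pCapB[t];
      lp[a][t] = std::log(p_[a][t]);
      l1mp[a][t] = std::log1p(-p_[a][t]);
    }
    lsJ[t] = std::log(sJ[t]);
    lsA[t] = std::log(sA[t]);
  }

  void update_latent_year(int t) { // t >= 1
    NY[t] = latent(t, 0) + latent(t, 1);
    NAd[t] = latent(t, 2) + latent(t, 3);
  }

  // CJS: one release row of one m-array ------------------------------------
  double cjs_row(int arr, int t0) const {
    const IntegerMatrix &m = arr == 0 ? marrJ : marrA;
    double ll = 0.0, cum = 0.0, surv = 1.0, seen = 0.0;
    bool any = false;
    for (int c = 0; c < T; c++) if (m(t0, c)) { any = true; break; }
    if (!any) return 0.0;
    for (int j = t0 + 1; j < T; j++) {
      bool first = (arr == 0 && j == t0 + 1);
      double lphi = first ? lsJ[t0] : lsA[j - 1];
      double phi = first ? sJ[t0] : sA[j - 1];
      int a = first ? 0 : 1;
      int mc = m(t0, j - 1);
      if (mc) ll += mc * (cum + lphi + lp[a][j]);
      seen += surv * phi * p_[a][j];
      cum += lphi + l1mp[a][j];
      surv *= phi * (1.0 - p_[a][j]);
    }
    int mn = m(t0, T - 1);
    if (mn) {
      double nv = 1.0 - seen;
      if (nv <= 0) return NEG_INF;
      ll += mn * std::log(nv);
    }
    return ll;
  }

  double cjs_full() {
    if (!use_cjs) return 0.0;
    double s = 0.0;
    for (int arr = 0; arr < 2; arr++)
      for (int t0 = 0; t0 < T - 1; t0++) {
        row_ll[arr][t0] = cjs_row(arr, t0);
        s += row_ll[arr][t0];
      }
    return s;
  }

  double clutch_ll_year(int t) const {
    if (!use_clutch) return 0.0;
    double ll = 0.0;
    for (int a = 0; a < 2; a++) {
      if (clutch_n(a, t) == 0) continue;
      ll += clutch_sum(a, t) * std::log(CS[a][t]) - clutch_n(a, t) * CS[a][t]
            - clutch_lfact(a, t);
    }
    return std::max(ll, -1e12);
  }

  double nest_ll_year(int t) const {
    if (!use_nest) return 0.0;
    double ll = 0.0;
    for (int a = 0; a < 2; a++) {
      if (nf_nsucc(a, t) > 0) {
        ll += nf_nsucc(a, t) * std::log(pNS[t])
              + nf_sumf(a, t) * std::log(sN[a][t])
              + nf_sumcf(a, t) * std::log1p(-sN[a][t])
              + nf_lchoose(a, t);
      }
    }
    for (int z : zero_by_year[t]) {
      int a = nf_zero(z, 0);
      double pz = (1.0 - pNS[t])
                  + pNS[t] * std::pow(1.0 - sN[a][t], nf_zero(z, 2));
      ll += nf_zero(z, 3) * std::log(pz);
    }
    return std::max(ll, -1e12);
  }

  double counts_ll_year(int t) const {
    if (!use_counts) return 0.0;
    double muB = NY[t] * pB[0][t] + NAd[t] * pB[1][t];
    double muE = NY[t] * pB[0][t] * CS[0][t] + NAd[t] * pB[1][t] * CS[1][t];
    double muF = NY[t] * Fec[0][t] + NAd[t] * Fec[1][t];
    double ll = lpois(fc[t], muB) + lpois(eggs[t], muE) + lpois(fl[t], muF);
    if (t >= 1) ll += lpois(nr[t], pCapB[t] * omega(t));
    return ll;
  }

  double state_ll_year(int t) const { // t >= 1
    if (!use_state) return 0.0;
    double localY = latent(t, 0), immY = latent(t, 1);
    double survA = latent(t, 2), immA = latent(t, 3);
    double Ntot = NY[t - 1] + NAd[t - 1];
    if (localY < 0 || immY < 0 || survA < 0 || immA < 0 || survA > Ntot)
      return NEG_INF;
    double mu_rec = 0.5 * sJ[t - 1]
                    * (NY[t - 1] * Fec[0][t - 1] + NAd[t - 1] * Fec[1][t - 1]);
    double q = par[20];
    return lpois(localY, mu_rec) + lbinom(survA, Ntot, sA[t - 1])
           + lpois(immY, q * omega(t)) + lpois(immA, (1.0 - q) * omega(t));
  }

  double eps_prior(int r) const {
    double s = par[14 + r], ll = 0.0;
    for (int t = 0; t < T; t++) ll += lnorm(eps(r, t), s);
    return ll;
  }

  double miss_prior() const {
    double ll = 0.0;
    for (int m = 0; m < nmiss; m++) ll += lnorm(par[M0 + m], 1.0);
    return ll;
  }

  void refresh_all() {
    apply_missing();
    for (int t = 0; t < T; t++) update_rates_year(t);
    NY[0] = par[L0]; NAd[0] = par[L0 + 1];
    for (int t = 1; t < T; t++) update_latent_year(t);
    c_cjs = cjs_full();
    for (int t = 0; t < T; t++) {
      c_clutch[t] = clutch_ll_year(t);
      c_nest[t] = nest_ll_year(t);
      c_counts[t] = counts_ll_year(t);
      c_state[t] = t >= 1 ? state_ll_year(t) : 0.0;
    }
    for (int r = 0; r < 6; r++) c_eps[r] = eps_prior(r);
    c_miss = miss_prior();
  }

  double total_ll() const {
    double s = c_cjs + c_miss;
    for (int t = 0; t < T; t++)
      s += c_clutch[t] + c_nest[t] + c_counts[t] + c_state[t];
    for (int r = 0; r < 6; r++) s += c_eps[r];
    return s;
  }
};

static int scalar_family(int i) {
  switch (i) {
    case 0: case 1: return R_PB;
    case 2: case 3: return R_CS;
    case 4: case 9: case 10: return R_PNS;
    case 5: case 6: case 11: case 12: return R_SN;
    case 7: case 13: return R_SJ;
    case 8: return R_SA;
    default: return -1;
  }
}
static bool fam_cjs(int r) { return r == R_PB || r == R_SJ || r == R_SA; }
static bool fam_clutch(int r) { return r == R_CS; }
static bool fam_nest(int r) { return r == R_PNS || r == R_SN; }
static bool fam_counts(int r) { return r != R_SJ && r != R_SA; }

struct Sampler {
  Model mod;
  std::vector<double> step;
  std::vector<int> n_prop, n_acc;
  // scratch
  std::vector<std::pair<int,int>> rows;     // affected (arr, row)
  std::vector<double> saved_rows;

  bool in_bounds(int i, double v) const {
    if (i <= 8) {
      if (i == 2 || i == 3) return v > 0 && v <= mod.cs_max;
      return v > 0 && v < 1;
    }
    if (i <= 13) return std::fabs(v) <= mod.beta_bound;
    if (i <= 19) return v > 0 && v <= mod.sig_max;
    if (i == 20) return v > 0 && v < 1;
    if (i >= mod.O0 && i < mod.L0) return v >= 0 && v <= mod.omega_max;
    if (i == mod.L0 || i == mod.L0 + 1) return v >= 0 && v <= mod.N1_max;
    if (i >= mod.L0 + 2 && i < mod.M0) return v >= 0;
    return true;
  }

  void record(int i, bool acc) { n_prop[i]++; if (acc) n_acc[i]++; }

  void adapt_batch() {
    for (size_t i = 0; i < step.size(); i++) {
      if (n_prop[i] == 0) continue;
      double rate = (double)n_acc[i] / n_prop[i];
      step[i] = std::min(std::max(step[i] * (rate > 0.44 ? 1.15 : 0.87),
                                  1e-4), 1e3);
      n_prop[i] = 0; n_acc[i] = 0;
    }
  }

  // which CJS rows a change at year/occasion t affects
  void rows_all() {
    rows.clear();
    for (int arr = 0; arr < 2; arr++)
      for (int t0 = 0; t0 < mod.T - 1; t0++) rows.emplace_back(arr, t0);
  }
  void rows_for_sJ(int t) {
    rows.clear();
    if (t < mod.T - 1) rows.emplace_back(0, t);
  }
  void rows_for_sA(int t) {
    rows.clear();
    if (t >= mod.T - 1) return;
    for (int t0 = 0; t0 < t; t0++) rows.emplace_back(0, t0);
    for (int t0 = 0; t0 <= t; t0++) rows.emplace_back(1, t0);
  }
  void rows_for_p(int t) { // detection occasion t
    rows.clear();
    for (int arr = 0; arr < 2; arr++)
      for (int t0 = 0; t0 < t && t0 < mod.T - 1; t0++)
        rows.emplace_back(arr, t0);
  }

  // recompute the selected rows; returns delta (new - old) and saves old
  double recompute_rows() {
    if (!mod.use_cjs) { rows.clear(); return 0.0; }
    saved_rows.clear();
    double delta = 0.0;
    for (auto &rc : rows) {
      double old = mod.row_ll[rc.first][rc.second];
      saved_rows.push_back(old);
      double nw = mod.cjs_row(rc.first, rc.second);
      mod.row_ll[rc.first][rc.second] = nw;
      delta += nw - old;
    }
    return delta;
  }
  void restore_rows() {
    for (size_t k = 0; k < rows.size(); k++)
      mod.row_ll[rows[k].first][rows[k].second] = saved_rows[k];
  }

  void update_scalar(int i) {
    double old = mod.par[i];
    double prop = old + R::norm_rand() * step[i];
    if (!in_bounds(i, prop)) { record(i, false); return; }
    int fam = scalar_family(i);
    if (fam < 0 && i >= 14 && i <= 19) {          // sigma: eps prior only
      int r = i - 14;
      mod.par[i] = prop;
      double nw = mod.eps_prior(r), delta = nw - mod.c_eps[r];
      if (std::log(R::unif_rand()) < delta) { mod.c_eps[r] = nw;
        record(i, true); }
      else { mod.par[i] = old; record(i, false); }
      return;
    }
    if (fam < 0) {                                 // q: state terms
      mod.par[i] = prop;
      double delta = 0.0;
      std::vector<double> oldst(mod.c_state);
      for (int t = 1; t < mod.T; t++) {
        double nw = mod.state_ll_year(t);
        delta += nw - mod.c_state[t];
        mod.c_state[t] = nw;
      }
      if (std::log(R::unif_rand()) < delta) { record(i, true); return; }
      mod.par[i] = old; mod.c_state = oldst; record(i, false);
      return;
    }
    // rate-family scalar
    mod.par[i] = prop;
    for (int t = 0; t < mod.T; t++) mod.update_rates_year(t);
    double delta = 0.0;
    double cjs_delta = 0.0;
    if (fam_cjs(fam)) { rows_all(); cjs_delta = recompute_rows();
      delta += cjs_delta; }
    std::vector<double> oc, on, oco, ost;
    if (fam_clutch(fam)) { oc = mod.c_clutch;
      for (int t = 0; t < mod.T; t++) { double nw = mod.clutch_ll_year(t);
        delta += nw - mod.c_clutch[t]; mod.c_clutch[t] = nw; } }
    if (fam_nest(fam)) { on = mod.c_nest;
      for (int t = 0; t < mod.T; t++) { double nw = mod.nest_ll_year(t);
        delta += nw - mod.c_nest[t]; mod.c_nest[t] = nw; } }
    if (fam_counts(fam)) { oco = mod.c_counts;
      for (int t = 0; t < mod.T; t++) { double nw = mod.counts_ll_year(t);
        delta += nw - mod.c_counts[t]; mod.c_counts[t] = nw; } }
    ost = mod.c_state;
    for (int t = 1; t < mod.T; t++) { double nw = mod.state_ll_year(t);
      delta += nw - mod.c_state[t]; mod.c_state[t] = nw; }
    if (std::log(R::unif_rand()) < delta) { mod.c_cjs += cjs_delta;
      record(i, true); return; }
    mod.par[i] = old;
    for (int t = 0; t < mod.T; t++) mod.update_rates_year(t);
    if (fam_cjs(fam)) restore_rows();
    if (oc.size()) mod.c_clutch = oc;
    if (on.size()) mod.c_nest = on;
    if (oco.size()) mod.c_counts = oco;
    mod.c_state = ost;
    record(i, false);
  }

  void update_eps(int r, int t) {
    int i = 21 + r * mod.T + t;
    double old = mod.par[i];
    double prop = old + R::norm_rand() * step[i];
    double s = mod.par[14 + r];
    double dprior = lnorm(prop, s) - lnorm(old, s);
    mod.par[i] = prop;
    mod.update_rates_year(t);
    double delta = dprior, cjs_delta = 0.0;
    if (mod.use_cjs && fam_cjs(r)) {
      if (r == R_SJ) rows_for_sJ(t);
      else if (r == R_SA) rows_for_sA(t);
      else rows_for_p(t);
      cjs_delta = recompute_rows();
      delta += cjs_delta;
    }
    double o1 = 0, o2 = 0, o3 = 0, o4 = 0;
    bool hc = fam_clutch(r), hn = fam_nest(r), hco = fam_counts(r);
    if (hc) { o1 = mod.c_clutch[t]; double nw = mod.clutch_ll_year(t);
      delta += nw - o1; mod.c_clutch[t] = nw; }
    if (hn) { o2 = mod.c_nest[t]; double nw = mod.nest_ll_year(t);
      delta += nw - o2; mod.c_nest[t] = nw; }
    if (hco) { o3 = mod.c_counts[t]; double nw = mod.counts_ll_year(t);
      delta += nw - o3; mod.c_counts[t] = nw; }
    if (t + 1 < mod.T) { o4 = mod.c_state[t + 1];
      double nw = mod.state_ll_year(t + 1); delta += nw - o4;
      mod.c_state[t + 1] = nw; }
    if (std::log(R::unif_rand()) < delta) {
      mod.c_cjs += cjs_delta;
      mod.c_eps[r] += dprior;
      record(i, true); return;
    }
    mod.par[i] = old;
    mod.update_rates_year(t);
    if (mod.use_cjs && fam_cjs(r)) restore_rows();
    if (hc) mod.c_clutch[t] = o1;
    if (hn) mod.c_nest[t] = o2;
    if (hco) mod.c_counts[t] = o3;
    if (t + 1 < mod.T) mod.c_state[t + 1] = o4;
    record(i, false);
  }

  void update_omega(int t) { // t >= 1
    int i = mod.O0 + t - 1;
    double old = mod.par[i];
    double prop = old + R::norm_rand() * step[i];
    if (!in_bounds(i, prop)) { record(i, false); return; }
    mod.par[i] = prop;
    double o1 = mod.c_counts[t], o2 = mod.c_state[t];
    double n1 = mod.counts_ll_year(t), n2 = mod.state_ll_year(t);
    if (std::log(R::unif_rand()) < (n1 + n2) - (o1 + o2)) {
      mod.c_counts[t] = n1; mod.c_state[t] = n2; record(i, true);
    } else { mod.par[i] = old; record(i, false); }
  }

  void update_latent(int i) {
    double old = mod.par[i];
    double prop = old + std::round(R::norm_rand() * std::max(step[i], 0.7));
    if (prop == old || !in_bounds(i, prop)) { record(i, false); return; }
    int t = (i == mod.L0 || i == mod.L0 + 1) ? 0
            : 1 + (i - mod.L0 - 2) / 4;
    mod.par[i] = prop;
    if (t == 0) { mod.NY[0] = mod.par[mod.L0];
      mod.NAd[0] = mod.par[mod.L0 + 1]; }
    else mod.update_latent_year(t);
    double oC = mod.c_counts[t], nC = mod.counts_ll_year(t);
    double delta = nC - oC;
    double oS1 = 0, nS1 = 0, oS2 = 0, nS2 = 0;
    if (t >= 1) { oS1 = mod.c_state[t]; nS1 = mod.state_ll_year(t);
      delta += nS1 - oS1; }
    if (t + 1 < mod.T) { oS2 = mod.c_state[t + 1];
      nS2 = mod.state_ll_year(t + 1); delta += nS2 - oS2; }
    if (std::log(R::unif_rand()) < delta) {
      mod.c_counts[t] = nC;
      if (t >= 1) mod.c_state[t] = nS1;
      if (t + 1 < mod.T) mod.c_state[t + 1] = nS2;
      record(i, true); return;
    }
    mod.par[i] = old;
    if (t == 0) { mod.NY[0] = mod.par[mod.L0];
      mod.NAd[0] = mod.par[mod.L0 + 1]; }
    else mod.update_latent_year(t);
    record(i, false);
  }

  // swap moves: exchange delta between two latent slots of year t, keeping
  // their sum fixed. kind 0: localY <-> ImmY (N_Y unchanged, state t only);
  // kind 1: survA <-> ImmA (N_A unchanged, state t only); kind 2:
  // ImmY <-> ImmA (immigrant total unchanged, ages and counts change).
  void update_swap(int t, int kind) {
    int sid = mod.P + 3 * (t - 1) + kind;      // step-table slot
    double delta_step = std::max(step[sid], 0.7);
    double d = std::round(R::norm_rand() * delta_step);
    if (d == 0) { record(sid, false); return; }
    int ia, ib;
    if (kind == 0) { ia = mod.L0 + 2 + 4 * (t - 1);     // localY
                     ib = ia + 1; }                      // ImmY
    else if (kind == 1) { ia = mod.L0 + 2 + 4 * (t - 1) + 2; // survA
                          ib = ia + 1; }                 // ImmA
    else { ia = mod.L0 + 2 + 4 * (t - 1) + 1;            // ImmY
           ib = mod.L0 + 2 + 4 * (t - 1) + 3; }          // ImmA
    double a0 = mod.par[ia], b0 = mod.par[ib];
    if (a0 + d < 0 || b0 - d < 0) { record(sid, false); return; }
    mod.par[ia] = a0 + d; mod.par[ib] = b0 - d;
    if (kind == 2) mod.update_latent_year(t);
    double delta = 0.0;
    double oC = 0, nC = 0, oS1 = mod.c_state[t], oS2 = 0, nS2 = 0;
    double nS1 = mod.state_ll_year(t);
    delta += nS1 - oS1;
    if (kind == 2) {
      oC = mod.c_counts[t]; nC = mod.counts_ll_year(t); delta += nC - oC;
      if (t + 1 < mod.T) { oS2 = mod.c_state[t + 1];
        nS2 = mod.state_ll_year(t + 1); delta += nS2 - oS2; }
    }
    if (std::log(R::unif_rand()) < delta) {
      mod.c_state[t] = nS1;
      if (kind == 2) { mod.c_counts[t] = nC;
        if (t + 1 < mod.T) mod.c_state[t + 1] = nS2; }
      record(sid, true); return;
    }
    mod.par[ia] = a0; mod.par[ib] = b0;
    if (kind == 2) mod.update_latent_year(t);
    record(sid, false);
  }

  // joint ridge move along the weakly identified immigrant-age direction:
  // shift q and re-split every year's immigrant total toward the new value.
  // The per-year shift round(delta * total) is an odd function of delta, so
  // the move is its own reverse under -delta and the proposal is symmetric.
  void update_qshift() {
    int sid = mod.P + 3 * (mod.T - 1);
    double delta = R::norm_rand() * step[sid];
    double q0 = mod.par[20], q1 = q0 + delta;
    if (q1 <= 0 || q1 >= 1) { record(sid, false); return; }
    std::vector<double> oldpar;
    oldpar.reserve(2 * (mod.T - 1));
    bool ok = true;
    for (int t = 1; t < mod.T && ok; t++) {
      int ia = mod.L0 + 2 + 4 * (t - 1) + 1;   // ImmY
      int ib = mod.L0 + 2 + 4 * (t - 1) + 3;   // ImmA
      double tot = mod.par[ia] + mod.par[ib];
      double d = std::round(delta * tot);
      if (mod.par[ia] + d < 0 || mod.par[ib] - d < 0) { ok = false; break; }
      oldpar.push_back(mod.par[ia]);
      oldpar.push_back(mod.par[ib]);
      mod.par[ia] += d;
      mod.par[ib] -= d;
    }
    if (!ok) {
      for (size_t k = 0; k < oldpar.size() / 2; k++) {
        int t = (int)k + 1;
        mod.par[mod.L0 + 2 + 4 * (t - 1) + 1] = oldpar[2 * k];
        mod.par[mod.L0 + 2 + 4 * (t - 1) + 3] = oldpar[2 * k + 1];
      }
      record(sid, false); return;
    }
    mod.par[20] = q1;
    for (int t = 1; t < mod.T; t++) mod.update_latent_year(t);
    std::vector<double> oc(mod.c_counts), os(mod.c_state);
    double d_ll = 0.0;
    for (int t = 1; t < mod.T; t++) {
      double nc = mod.counts_ll_year(t), ns = mod.state_ll_year(t);
      d_ll += (nc - mod.c_counts[t]) + (ns - mod.c_state[t]);
      mod.c_counts[t] = nc; mod.c_state[t] = ns;
    }
    if (std::log(R::unif_rand()) < d_ll) { record(sid, true); return; }
    mod.par[20] = q0;
    for (int t = 1; t < mod.T; t++) {
      mod.par[mod.L0 + 2 + 4 * (t - 1) + 1] = oldpar[2 * (t - 1)];
      mod.par[mod.L0 + 2 + 4 * (t - 1) + 3] = oldpar[2 * (t - 1) + 1];
      mod.update_latent_year(t);
    }
    mod.c_counts = oc; mod.c_state = os;
    record(sid, false);
  }

  void update_missing(int m) {
    int i = mod.M0 + m;
    int v = mod.missIdx(m, 0), t = mod.missIdx(m, 1);
    double old = mod.par[i];
    double prop = old + R::norm_rand() * step[i];
    mod.par[i] = prop;
    mod.cov[v][t] = prop;
    mod.update_rates_year(t);
    double delta = lnorm(prop, 1.0) - lnorm(old, 1.0);
    double dprior = delta;
    double cjs_delta = 0.0;
    if (v == 2) {
      if (mod.use_cjs) { rows_for_sJ(t); cjs_delta = recompute_rows();
        delta += cjs_delta; }
    }
    double o2 = mod.c_nest[t], o3 = mod.c_counts[t], o4 = 0;
    if (v != 2) {
      double n2 = mod.nest_ll_year(t), n3 = mod.counts_ll_year(t);
      delta += (n2 - o2) + (n3 - o3);
      mod.c_nest[t] = n2; mod.c_counts[t] = n3;
    }
    if (t + 1 < mod.T) { o4 = mod.c_state[t + 1];
      double nw = mod.state_ll_year(t + 1); delta += nw - o4;
      mod.c_state[t + 1] = nw; }
    if (std::log(R::unif_rand()) < delta) {
      mod.c_cjs += cjs_delta; mod.c_miss += dprior;
      record(i, true); return;
    }
    mod.par[i] = old; mod.cov[v][t] = old;
    mod.update_rates_year(t);
    if (v == 2 && mod.use_cjs) restore_rows();
    if (v != 2) { mod.c_nest[t] = o2; mod.c_counts[t] = o3; }
    if (t + 1 < mod.T) mod.c_state[t + 1] = o4;
    record(i, false);
  }

  void iterate() {
    bool pop = mod.use_counts || mod.use_state;
    for (int i = 0; i <= 19; i++) update_scalar(i);
    if (pop) update_scalar(20);
    for (int r = 0; r < 6; r++)
      for (int t = 0; t < mod.T; t++) update_eps(r, t);
    if (pop) for (int t = 1; t < mod.T; t++) update_omega(t);
    if (mod.use_state) {
      update_latent(mod.L0); update_latent(mod.L0 + 1);
      for (int t = 1; t < mod.T; t++)
        for (int k = 0; k < 4; k++)
          update_latent(mod.L0 + 2 + 4 * (t - 1) + k);
      // repeated swap/q sweeps: the immigrant age composition is the
      // slowest posterior direction, and these moves are nearly free
      for (int rep = 0; rep < 4; rep++) {
        for (int t = 1; t < mod.T; t++)
          for (int k = 0; k < 3; k++) update_swap(t, k);
        update_scalar(20);
        update_qshift();
      }
    }
    for (int m = 0; m < mod.nmiss; m++) update_missing(m);
  }
};

// [[Rcpp::export]]
List ipm_mcmc_cpp(List data, NumericVector init, NumericVector prop_sd,
                  int n_iter, int n_burn, int thin) {
  Sampler s;
  s.mod.init(data, init);
  s.step.assign(prop_sd.begin(), prop_sd.end());
  if ((int)s.step.size() != s.mod.P) stop("prop_sd has wrong length");
  // extra step-table slots: per-year swap moves plus the joint q shift
  s.step.resize(s.mod.P + 3 * (s.mod.T - 1), 2.0);
  s.step.push_back(0.1);
  s.n_prop.assign(s.step.size(), 0);
  s.n_acc.assign(s.step.size(), 0);
  if (!std::isfinite(s.mod.total_ll()))
    stop("initial state has non-finite posterior density");
  int n_save = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix draws(n_save, s.mod.P);
  NumericVector lp(n_save);
  int row = 0;
  for (int it = 0; it < n_iter; it++) {
    s.iterate();
    if (it < n_burn && (it + 1) % 50 == 0) s.adapt_batch();
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      for (int j = 0; j < s.mod.P; j++) draws(row, j) = s.mod.par[j];
      lp[row] = s.mod.total_ll();
      row++;
    }
    if ((it + 1) % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = draws, _["logpost"] = lp,
                      _["step"] = NumericVector(s.step.begin(),
                                                s.step.end()));
}

// [[Rcpp::export]]
List ipm_logpost_cpp(List data, NumericVector params) {
  Model m;
  m.init(data, params);
  double counts = 0, state = 0, clutch = 0, nest = 0;
  for (int t = 0; t < m.T; t++) {
    counts += m.c_counts[t]; state += m.c_state[t];
    clutch += m.c_clutch[t]; nest += m.c_nest[t];
  }
  double epss = 0;
  for (int r = 0; r < 6; r++) epss += m.c_eps[r];
  return List::create(_["cjs"] = m.c_cjs, _["clutch"] = clutch,
                      _["nest"] = nest, _["counts"] = counts,
                      _["state"] = state, _["eps_prior"] = epss,
                      _["miss_prior"] = m.c_miss,
                      _["total"] = m.total_ll());
}
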
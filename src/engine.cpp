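// MCMC engine: Mk/Mkv pruning likelihood, serially-sampled birth-death
// density, priors and the Metropolis-Hastings loop. Node indexing follows
// the ape convention (0-based here): tips 0..ntip-1, root = ntip,
// internal nodes ntip..2*ntip-2. parent[root] = -1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int MAXK = 10;

// ---------------------------------------------------------------------------
// tree helpers

struct TreeBuf {
  int ntip, nnode, root;
  std::vector<int> parent;      // -1 at root
  std::vector<int> child0, child1; // -1 for tips
  std::vector<int> postorder;   // internal nodes, children before parents

  void build_children() {
    std::fill(child0.begin(), child0.end(), -1);
    std::fill(child1.begin(), child1.end(), -1);
    for (int i = 0; i < nnode; i++) {
      int p = parent[i];
      if (p < 0) { root = i; continue; }
      if (child0[p] < 0) child0[p] = i; else child1[p] = i;
    }
  }
  void build_postorder() {
    postorder.clear();
    // iterative DFS from root collecting internal nodes in reverse topological order
    std::vector<int> stack, out;
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v >= ntip) {
        out.push_back(v);
        stack.push_back(child0[v]);
        stack.push_back(child1[v]);
      }
    }
    postorder.assign(out.rbegin(), out.rend());
  }
  void init(const IntegerVector& par, int ntip_) {
    ntip = ntip_; nnode = par.size();
    parent.assign(par.begin(), par.end());
    child0.assign(nnode, -1); child1.assign(nnode, -1);
    build_children();
    build_postorder();
  }
  void rebuild() { build_children(); build_postorder(); }
};

// ---------------------------------------------------------------------------
// discrete gamma (mean of equal-probability bins, mean rate 1)

static void discrete_gamma(double shape, int ncat, std::vector<double>& rates) {
  rates.assign(ncat, 1.0);
  if (ncat == 1) return;
  // bin edges are quantiles of Gamma(shape, rate = shape); bin means via the
  // CDF of Gamma(shape + 1, rate = shape): E[X; X in (a,b)] = F1(b) - F1(a)
  double prev_q = 0.0, prev_f1 = 0.0;
  double scale = 1.0 / shape;          // R uses scale parameterisation
  for (int i = 0; i < ncat; i++) {
    double q, f1;
    if (i == ncat - 1) { q = R_PosInf; f1 = 1.0; }
    else {
      q = R::qgamma((i + 1.0) / ncat, shape, scale, 1, 0);
      f1 = R::pgamma(q, shape + 1.0, scale, 1, 0);
    }
    rates[i] = ncat * (f1 - prev_f1);
    prev_q = q; prev_f1 = f1;
  }
  (void)prev_q;
  // renormalise against accumulated rounding
  double m = 0; for (double r : rates) m += r;
  m /= ncat;
  for (double& r : rates) r /= m;
}

// [[Rcpp::export]]
NumericVector C_discrete_gamma(double shape, int ncat) {
  std::vector<double> r;
  discrete_gamma(shape, ncat, r);
  return wrap(r);
}

// ---------------------------------------------------------------------------
// Mk pruning likelihood with gamma mixture and optional Mkv conditioning
//
// blen[i]: expected substitutions on the branch above node i (already scaled
// by clock rate and branch multiplier). data: ntip x nchar, -1 = missing.

struct MkWork {
  std::vector<double> partial; // nnode * MAXK scratch per (char, cat)
};

// transition: P_same = 1/k + (k-1)/k * e, P_diff = 1/k - 1/k * e,
// e = exp(-k * t / (k-1))
static inline void trans_terms(int k, double t, double& psame, double& pdiff) {
  double e = std::exp(-double(k) * t / double(k - 1));
  psame = (1.0 + (k - 1.0) * e) / k;
  pdiff = (1.0 - e) / k;
}

// gamma-mixture likelihood of one pattern (tip state via states[t]; -1 =
// missing), all categories in one traversal with a shared scaling factor.
// partial layout: [node][g * k + j]. Returns the log of the category-mean.
static double pattern_loglik(const TreeBuf& T, const int* states, int k,
                             int ncat, const double* psame, const double* pdiff,
                             std::vector<double>& partial) {
  double log_scale = 0.0;
  int stride = ncat * k;
  for (size_t ii = 0; ii < T.postorder.size(); ii++) {
    int v = T.postorder[ii];
    double* pv = &partial[v * stride];
    for (int x = 0; x < stride; x++) pv[x] = 1.0;
    int c[2] = {T.child0[v], T.child1[v]};
    for (int ci = 0; ci < 2; ci++) {
      int w = c[ci];
      const double* trs = &psame[w * ncat];
      const double* trd = &pdiff[w * ncat];
      if (w < T.ntip) {
        int s = states[w];
        if (s < 0) continue;            // missing tip: factor 1 in every state
        for (int g = 0; g < ncat; g++) {
          double ps = trs[g], pd = trd[g];
          double* pvg = pv + g * k;
          for (int j = 0; j < k; j++) pvg[j] *= (j == s) ? ps : pd;
        }
      } else {
        const double* pw = &partial[w * stride];
        for (int g = 0; g < ncat; g++) {
          double ps = trs[g], pd = trd[g];
          const double* pwg = pw + g * k;
          double* pvg = pv + g * k;
          double S = 0; for (int j = 0; j < k; j++) S += pwg[j];
          double coef = ps - pd;
          for (int j = 0; j < k; j++) pvg[j] *= pd * S + coef * pwg[j];
        }
      }
    }
    double mx = 0;
    for (int x = 0; x < stride; x++) if (pv[x] > mx) mx = pv[x];
    if (mx > 0 && mx < 1e-200) {
      for (int x = 0; x < stride; x++) pv[x] /= mx;
      log_scale += std::log(mx);
    }
  }
  const double* pr = &partial[T.root * stride];
  double L = 0;
  for (int x = 0; x < stride; x++) L += pr[x];
  return std::log(L / (k * ncat)) + log_scale;
}

static double mk_loglik_core(const TreeBuf& T, const std::vector<double>& blen,
                             const IntegerMatrix& data, const IntegerVector& kvec,
                             const std::vector<double>& grates, bool mkv) {
  int nchar = data.ncol();
  int ncat = grates.size();
  std::vector<double> partial(T.nnode * ncat * MAXK);
  // raw copy of the data, -1 = missing, column-major
  std::vector<int> dat(T.ntip * nchar);
  for (int c = 0; c < nchar; c++)
    for (int t = 0; t < T.ntip; t++) {
      int s = data(t, c);
      dat[c * T.ntip + t] = (s == NA_INTEGER) ? -1 : s;
    }
  // precompute transition terms per (branch, category) for each distinct k
  std::vector<char> kseen(MAXK + 1, 0);
  for (int c = 0; c < nchar; c++) kseen[kvec[c]] = 1;
  std::vector<std::vector<double>> psame(MAXK + 1), pdiff(MAXK + 1);
  for (int k = 2; k <= MAXK; k++) {
    if (!kseen[k]) continue;
    psame[k].resize(T.nnode * ncat);
    pdiff[k].resize(T.nnode * ncat);
    for (int v = 0; v < T.nnode; v++) {
      if (v == T.root) continue;
      for (int g = 0; g < ncat; g++)
        trans_terms(k, blen[v] * grates[g],
                    psame[k][v * ncat + g], pdiff[k][v * ncat + g]);
    }
  }
  // Mkv: P(constant pattern) per distinct k; by state symmetry of Mk it is
  // k * P(all tips in state 0), averaged over categories.
  std::vector<double> log1m_pconst(MAXK + 1, 0.0);
  if (mkv) {
    std::vector<int> zeros(T.ntip, 0);
    for (int k = 2; k <= MAXK; k++) {
      if (!kseen[k]) continue;
      double lmean = pattern_loglik(T, zeros.data(), k, ncat,
                                    psame[k].data(), pdiff[k].data(), partial);
      log1m_pconst[k] = std::log1p(-double(k) * std::exp(lmean));
    }
  }
  double lnL = 0.0;
  for (int c = 0; c < nchar; c++) {
    int k = kvec[c];
    double lc = pattern_loglik(T, &dat[c * T.ntip], k, ncat,
                               psame[k].data(), pdiff[k].data(), partial);
    if (mkv) lc -= log1m_pconst[k];
    lnL += lc;
  }
  return lnL;
}

// [[Rcpp::export]]
double C_mk_loglik(IntegerVector parent, int ntip, NumericVector blen,
                   IntegerMatrix data, IntegerVector kvec,
                   NumericVector grates, bool mkv) {
  TreeBuf T; T.init(parent, ntip);
  std::vector<double> bl(blen.begin(), blen.end());
  std::vector<double> gr(grates.begin(), grates.end());
  return mk_loglik_core(T, bl, data, kvec, gr, mkv);
}

// ---------------------------------------------------------------------------
// serially-sampled birth-death density, removal on sampling (r = 1),
// rho = 1 at the present, conditioned on the origin age.
//
// log f = log q(x0) + sum_internal [log lambda + log q(x_i)]
//       + sum_{fossil tips} [log psi - log q(y_j)]       (age > 0)
//       + sum_{extant tips} [log rho=0 - log q(0)=0]     (age == 0)

static inline double log_q(double t, double c1, double c2) {
  // q(t) = 4 e^{-c1 t} / (e^{-c1 t}(1-c2) + (1+c2))^2
  double e = std::exp(-c1 * t);
  double denom = e * (1.0 - c2) + (1.0 + c2);
  return std::log(4.0) - c1 * t - 2.0 * std::log(std::fabs(denom));
}

static double bdss_loglik_core(const TreeBuf& T, const std::vector<double>& age,
                               double lambda, double mu, double psi, double origin) {
  if (lambda <= 0 || mu <= 0 || psi <= 0) return R_NegInf;
  if (origin <= age[T.root]) return R_NegInf;
  double c1 = std::sqrt((lambda + mu + psi) * (lambda + mu + psi) - 4.0 * lambda * mu);
  double c2 = (lambda + mu + psi) / c1; // rho = 1
  double ll = log_q(origin, c1, c2);
  for (int v = 0; v < T.nnode; v++) {
    if (v >= T.ntip) {
      ll += std::log(lambda) + log_q(age[v], c1, c2);
    } else if (age[v] > 1e-12) {
      ll += std::log(psi) - log_q(age[v], c1, c2);
    }
    // extant tips: + log(rho) - log q(0) = 0
  }
  return ll;
}

// [[Rcpp::export]]
double C_bdss_loglik(IntegerVector parent, int ntip, NumericVector ages,
                     double lambda, double mu, double psi, double origin) {
  if (lambda <= 0 || mu <= 0 || psi <= 0) stop("rates must be > 0");
  TreeBuf T; T.init(parent, ntip);
  std::vector<double> a(ages.begin(), ages.end());
  if (origin <= a[T.root]) stop("origin_age must exceed root age");
  return bdss_loglik_core(T, a, lambda, mu, psi, origin);
}

// ---------------------------------------------------------------------------
// priors

struct Hyper {
  double cr_mean, cr_offset;   // clock rate: shifted exponential
  double csd_mean;             // clock sd: exponential
  double shape_min, shape_max; // gamma shape: uniform
  double birth_meanreal, birth_sdlog; // lognormal, mean in real space
  double death_mean, sampling_mean;   // exponentials
};

static inline double dexp_log(double x, double mean) {
  if (x < 0) return R_NegInf;
  return -std::log(mean) - x / mean;
}

static double params_log_prior(const std::vector<double>& par, const Hyper& H) {
  // par: 0 clock_rate, 1 clock_sd, 2 shape, 3 lambda, 4 mu, 5 psi
  double lp = 0.0;
  if (par[0] < H.cr_offset) return R_NegInf;
  lp += dexp_log(par[0] - H.cr_offset, H.cr_mean);
  lp += dexp_log(par[1], H.csd_mean);
  if (par[2] < H.shape_min || par[2] > H.shape_max) return R_NegInf;
  lp += -std::log(H.shape_max - H.shape_min);
  double mulog = std::log(H.birth_meanreal) - 0.5 * H.birth_sdlog * H.birth_sdlog;
  lp += R::dlnorm(par[3], mulog, H.birth_sdlog, 1);
  lp += dexp_log(par[4], H.death_mean);
  lp += dexp_log(par[5], H.sampling_mean);
  return lp;
}

static double mult_log_prior(const std::vector<double>& mult, int root, double sdlog) {
  // iid lognormal with mean 1 in real space: mulog = -sdlog^2/2
  double mulog = -0.5 * sdlog * sdlog;
  double lp = 0.0;
  for (size_t i = 0; i < mult.size(); i++) {
    if ((int)i == root) continue;
    if (mult[i] <= 0) return R_NegInf;
    lp += R::dlnorm(mult[i], mulog, sdlog, 1);
  }
  return lp;
}

// ---------------------------------------------------------------------------
// the engine

struct Site {
  std::vector<int> tips; // 0-based tip ids
  double min_age, max_age;
  double age;
  double weight;
};

struct Engine {
  TreeBuf T;
  std::vector<double> age;     // per node, absolute Ma
  std::vector<double> mult;    // branch-rate multipliers per node (root unused)
  std::vector<double> par;     // clock_rate, clock_sd, shape, lambda, mu, psi
  double origin;
  std::vector<Site> sites;
  std::vector<int> rel_below, rel_above; // site indices
  std::vector<int> site_of_tip;          // -1 if none
  IntegerMatrix data;
  IntegerVector kvec;
  int ncat;
  bool mkv, prior_only, fix_tree;
  Hyper H;

  std::vector<double> grates, blen;
  double lnL, lnP;

  void refresh_blen() {
    blen.assign(T.nnode, 0.0);
    for (int v = 0; v < T.nnode; v++) {
      int p = T.parent[v];
      if (p < 0) continue;
      blen[v] = (age[p] - age[v]) * par[0] * mult[v];
    }
  }
  double likelihood() {
    if (prior_only || data.ncol() == 0) return 0.0;
    refresh_blen();
    discrete_gamma(par[2], ncat, grates);
    return mk_loglik_core(T, blen, data, kvec, grates, mkv);
  }
  double prior() {
    double lp = params_log_prior(par, H);
    if (!std::isfinite(lp)) return R_NegInf;
    double lm = mult_log_prior(mult, T.root, par[1]);
    if (!std::isfinite(lm)) return R_NegInf;
    lp += lm;
    // site-age uniform terms and bounds
    for (size_t s = 0; s < sites.size(); s++) {
      const Site& S = sites[s];
      if (S.age < S.min_age - 1e-12 || S.age > S.max_age + 1e-12) return R_NegInf;
      if (S.max_age > S.min_age) lp -= std::log(S.max_age - S.min_age);
    }
    // ordering: below must be >= above
    for (size_t r = 0; r < rel_below.size(); r++)
      if (sites[rel_below[r]].age < sites[rel_above[r]].age - 1e-12) return R_NegInf;
    // tree ages valid
    for (int v = 0; v < T.nnode; v++) {
      int p = T.parent[v];
      if (p >= 0 && age[p] <= age[v]) return R_NegInf;
    }
    if (!fix_tree) {
      if (origin <= age[T.root]) return R_NegInf;
      double lb = bdss_loglik_core(T, age, par[3], par[4], par[5], origin);
      if (!std::isfinite(lb)) return R_NegInf;
      lp += lb;
    }
    return lp;
  }
};

// uniform integer in [0, n)
static inline int rint(int n) {
  int v = (int)std::floor(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// [[Rcpp::export]]
List C_engine_run(IntegerVector parent, int ntip, NumericVector ages0,
                  NumericVector mult0, NumericVector params0, double origin0,
                  List site_tips, NumericVector site_min, NumericVector site_max,
                  NumericVector site_age0, NumericVector site_weight,
                  IntegerVector rel_below, IntegerVector rel_above,
                  IntegerMatrix data, IntegerVector kvec, int ncat,
                  bool mkv, bool prior_only, bool fix_tree,
                  NumericVector std_weights, double scale_beta, double walk_w,
                  double ngen_d, int log_interval) {
  long long ngen = (long long)ngen_d;
  Engine E;
  E.T.init(parent, ntip);
  if (E.T.root != ntip) stop("root must be node ntip + 1");
  E.age.assign(ages0.begin(), ages0.end());
  E.mult.assign(mult0.begin(), mult0.end());
  E.par.assign(params0.begin(), params0.end());
  E.origin = origin0;
  E.data = data; E.kvec = kvec; E.ncat = ncat;
  E.mkv = mkv; E.prior_only = prior_only; E.fix_tree = fix_tree;
  NumericVector hy = params0.attr("hyper");
  E.H.cr_mean = hy[0]; E.H.cr_offset = hy[1]; E.H.csd_mean = hy[2];
  E.H.shape_min = hy[3]; E.H.shape_max = hy[4];
  E.H.birth_meanreal = hy[5]; E.H.birth_sdlog = hy[6];
  E.H.death_mean = hy[7]; E.H.sampling_mean = hy[8];

  int nsite = site_min.size();
  E.site_of_tip.assign(ntip, -1);
  for (int s = 0; s < nsite; s++) {
    Site S;
    IntegerVector tt = site_tips[s];
    S.tips.assign(tt.begin(), tt.end());
    S.min_age = site_min[s]; S.max_age = site_max[s];
    S.age = site_age0[s]; S.weight = site_weight[s];
    for (int t : S.tips) E.site_of_tip[t] = s;
    E.sites.push_back(S);
  }
  E.rel_below.assign(rel_below.begin(), rel_below.end());
  E.rel_above.assign(rel_above.begin(), rel_above.end());

  // operator table: 0..nsite-1 site moves, then standard moves
  // std ops: 0 node_slide, 1 root_scale, 2 narrow_exchange, 3..8 scale
  // (clock_rate, clock_sd, shape, lambda, mu, psi), 9 origin_scale,
  // 10 rate_walk, 11 joint non-centered clock_sd/multiplier scale,
  // 12 uniform shape redraw, 13 additive clock-rate walk
  int nstd = std_weights.size(); // expected 14
  std::vector<double> wts(nsite + nstd);
  for (int s = 0; s < nsite; s++) wts[s] = E.sites[s].weight;
  for (int i = 0; i < nstd; i++) wts[nsite + i] = std_weights[i];
  if (fix_tree) { wts[nsite + 0] = wts[nsite + 1] = wts[nsite + 2] = wts[nsite + 9] = 0; }
  double wtot = 0; for (double w : wts) wtot += w;
  if (wtot <= 0) stop("all operator weights are zero");
  std::vector<double> cum(wts.size());
  double acc = 0;
  for (size_t i = 0; i < wts.size(); i++) { acc += wts[i]; cum[i] = acc; }

  GetRNGstate();

  E.lnL = E.likelihood();
  E.lnP = E.prior();
  if (!std::isfinite(E.lnP) || !std::isfinite(E.lnL)) {
    PutRNGstate();
    stop("zero-probability initial state (prior or likelihood is -Inf)");
  }

  long long nlog = ngen / log_interval + 1;
  int ncol_trace = 12 + nsite;
  NumericMatrix trace(nlog, ncol_trace);
  IntegerMatrix tr_parent(nlog, E.T.nnode);
  NumericMatrix tr_ages(nlog, E.T.nnode);
  std::vector<double> prop_cnt(wts.size(), 0.0), acc_cnt(wts.size(), 0.0);

  long long row = 0;
  auto log_state = [&](long long gen) {
    trace(row, 0) = (double)gen;
    trace(row, 1) = E.lnL + E.lnP;
    trace(row, 2) = E.lnL;
    trace(row, 3) = E.lnP;
    for (int i = 0; i < 6; i++) trace(row, 4 + i) = E.par[i];
    trace(row, 10) = E.origin;
    trace(row, 11) = E.age[E.T.root];
    for (int s = 0; s < nsite; s++) trace(row, 12 + s) = E.sites[s].age;
    for (int v = 0; v < E.T.nnode; v++) {
      tr_parent(row, v) = E.T.parent[v] + 1; // back to 1-based, 0 = root
      tr_ages(row, v) = E.age[v];
    }
    row++;
  };
  log_state(0);

  for (long long gen = 1; gen <= ngen; gen++) {
    // pick operator
    double u = unif_rand() * wtot;
    int op = 0;
    while (op < (int)cum.size() - 1 && u > cum[op]) op++;
    prop_cnt[op] += 1;

    bool hard_reject = false, affects_lik = true;
    double logHR = 0.0;
    // undo buffers
    double old_val = 0.0; int idx = -1; int kind;
    double old_age_a = 0, old_age_b = 0; int node_a = -1, node_b = -1;
    int sw_p = -1, sw_g = -1, sw_a = -1, sw_c = -1; // narrow exchange undo
    std::vector<double> old_mult;                    // joint clock_sd move undo

    if (op < nsite) {
      kind = 0; idx = op;
      Site& S = E.sites[op];
      old_val = S.age;
      double a = (S.max_age > S.min_age)
        ? S.min_age + unif_rand() * (S.max_age - S.min_age) : S.min_age;
      // parent constraint: every tip must stay strictly below its parent
      for (int t : S.tips)
        if (a >= E.age[E.T.parent[t]]) { hard_reject = true; break; }
      // ordering constraints against current neighbour ages (ties allowed)
      if (!hard_reject) {
        for (size_t r = 0; r < E.rel_below.size(); r++) {
          if (E.rel_below[r] == op && a < E.sites[E.rel_above[r]].age) { hard_reject = true; break; }
          if (E.rel_above[r] == op && a > E.sites[E.rel_below[r]].age) { hard_reject = true; break; }
        }
      }
      if (!hard_reject) {
        S.age = a;
        for (int t : S.tips) E.age[t] = a;
      }
    } else {
      int so = op - nsite;
      kind = 1 + so;
      switch (so) {
      case 0: { // node slide: internal non-root, uniform between oldest child and parent
        if (ntip < 3) { hard_reject = true; break; }
        // choose an internal non-root node
        int v = ntip + 1 + rint(ntip - 2); // internal ids ntip..2*ntip-2; root is E.T.root
        if (v == E.T.root) v = ntip; // swap with first internal if collision
        if (v == E.T.root) { hard_reject = true; break; }
        double lo = std::max(E.age[E.T.child0[v]], E.age[E.T.child1[v]]);
        double hi = E.age[E.T.parent[v]];
        node_a = v; old_age_a = E.age[v];
        E.age[v] = lo + unif_rand() * (hi - lo);
        break;
      }
      case 1: { // root gap scale
        int r = E.T.root;
        double mc = std::max(E.age[E.T.child0[r]], E.age[E.T.child1[r]]);
        double f = std::exp((unif_rand() * 2.0 - 1.0) * std::log(scale_beta));
        node_a = r; old_age_a = E.age[r];
        double gap = E.age[r] - mc;
        E.age[r] = mc + f * gap;
        logHR = std::log(f);
        if (!fix_tree && E.age[r] >= E.origin) hard_reject = true;
        break;
      }
      case 2: { // narrow exchange
        if (ntip < 3) { hard_reject = true; break; }
        // pick internal non-root node P; swap its aunt with one of its children
        int P = ntip + 1 + rint(ntip - 2);
        if (P == E.T.root) P = ntip;
        if (P == E.T.root) { hard_reject = true; break; }
        int G = E.T.parent[P];
        int A = (E.T.child0[G] == P) ? E.T.child1[G] : E.T.child0[G];
        int C = (unif_rand() < 0.5) ? E.T.child0[P] : E.T.child1[P];
        if (E.age[A] >= E.age[P]) { hard_reject = true; break; }
        // swap: A becomes child of P, C becomes child of G
        sw_p = P; sw_g = G; sw_a = A; sw_c = C;
        E.T.parent[A] = P; E.T.parent[C] = G;
        E.T.rebuild();
        break;
      }
      case 3: case 4: case 5: case 6: case 7: case 8: { // scalar scale moves
        idx = so - 3;
        double f = 1.0 / scale_beta + unif_rand() * (scale_beta - 1.0 / scale_beta);
        old_val = E.par[idx];
        E.par[idx] = old_val * f;
        logHR = -std::log(f);
        affects_lik = (idx == 0 || idx == 2); // clock rate, shape
        break;
      }
      case 9: { // origin gap scale
        double f = std::exp((unif_rand() * 2.0 - 1.0) * std::log(scale_beta));
        old_val = E.origin;
        double gap = E.origin - E.age[E.T.root];
        E.origin = E.age[E.T.root] + f * gap;
        logHR = std::log(f);
        affects_lik = false;
        break;
      }
      case 10: { // random-walk (log scale) on one branch-rate multiplier
        int v = rint(E.T.nnode - 1);
        if (v >= E.T.root) v++; // skip root slot
        double uu = (unif_rand() * 2.0 - 1.0) * walk_w;
        idx = v; old_val = E.mult[v];
        E.mult[v] = old_val * std::exp(uu);
        logHR = uu;
        break;
      }
      case 11: { // non-centered joint scale of clock_sd and multipliers:
        // hold the standardized latents z_i = (log m_i + sd^2/2)/sd fixed;
        // with the latents fixed the move is cheap to accept, so it takes
        // much bolder steps than the plain scale moves
        double f = std::exp((unif_rand() * 2.0 - 1.0) * std::log(4.0));
        double sd = E.par[1], sd2 = f * sd;
        old_val = sd;
        old_mult = E.mult;
        double sum_dlog = 0.0;
        int nmult = 0;
        for (int v = 0; v < E.T.nnode; v++) {
          if (v == E.T.root) continue;
          double lm = std::log(E.mult[v]);
          double z = (lm + 0.5 * sd * sd) / sd;
          double lm2 = sd2 * z - 0.5 * sd2 * sd2;
          E.mult[v] = std::exp(lm2);
          sum_dlog += lm2 - lm;
          nmult++;
        }
        E.par[1] = sd2;
        logHR = (nmult + 1) * std::log(f) + sum_dlog;
        break;
      }
      case 12: { // uniform redraw of the gamma shape over its prior range
        idx = 2; old_val = E.par[2];
        E.par[2] = E.H.shape_min +
          unif_rand() * (E.H.shape_max - E.H.shape_min);
        affects_lik = true;
        break;
      }
      case 13: { // additive random walk on the clock rate
        idx = 0; old_val = E.par[0];
        E.par[0] = old_val + (unif_rand() * 2.0 - 1.0) * 2.0 * E.H.cr_mean;
        affects_lik = true;
        break;
      }
      }
    }

    bool accepted = false;
    if (!hard_reject) {
      double newP = E.prior();
      double newL = E.lnL;
      if (std::isfinite(newP)) {
        if (affects_lik) newL = E.likelihood();
        double la = (newL + newP) - (E.lnL + E.lnP) + logHR;
        if (la >= 0 || unif_rand() < std::exp(la)) {
          accepted = true;
          E.lnL = newL; E.lnP = newP;
        }
      }
    }
    if (accepted) {
      acc_cnt[op] += 1;
    } else {
      // undo
      if (op < nsite) {
        if (!hard_reject) {
          Site& S = E.sites[op];
          S.age = old_val;
          for (int t : S.tips) E.age[t] = old_val;
        }
      } else {
        int so = op - nsite;
        switch (so) {
        case 0: case 1:
          if (node_a >= 0) E.age[node_a] = old_age_a;
          break;
        case 2:
          if (sw_p >= 0) {
            E.T.parent[sw_a] = sw_g; E.T.parent[sw_c] = sw_p;
            E.T.rebuild();
          }
          break;
        case 3: case 4: case 5: case 6: case 7: case 8:
          if (idx >= 0) E.par[idx] = old_val;
          break;
        case 9:
          E.origin = old_val;
          break;
        case 10:
          if (idx >= 0) E.mult[idx] = old_val;
          break;
        case 11:
          E.par[1] = old_val;
          E.mult = old_mult;
          break;
        case 12: case 13:
          E.par[idx] = old_val;
          break;
        }
      }
    }
    (void)kind; (void)node_b; (void)old_age_b;
    if (gen % log_interval == 0) log_state(gen);
    if (gen % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  PutRNGstate();

  return List::create(
    _["trace"] = trace,
    _["parents"] = tr_parent,
    _["ages"] = tr_ages,
    _["proposed"] = wrap(prop_cnt),
    _["accepted"] = wrap(acc_cnt));
}
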
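// Gaussian-mixture forward/backward filters and the two-filter smoother for
// the two-chromosome continuous-state HMM.
//
// The hidden copy-number pair theta_t sits either at the baseline mu0
// (normal state) or at a segment-specific value drawn from N(z, V)
// (variant state). Conditional on the genotype track, the filtered
// distribution of theta_t is a point mass at mu0 plus one Gaussian
// component per candidate most-recent change time; components carry their
// natural-parameter (precision, precision-mean) form so that conjugate
// updating is a pair of additions. Bounded-complexity (BCMIX) pruning caps
// the number of components at M, always retaining the K most recent
// change times.
//
// All matrix algebra is hand-coded 2x2: the state is bivariate and the
// inner loops run ~1e6 times per chromosome pass.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093453;

struct Mat2 {
  double a, b, d; // symmetric: [[a, b], [b, d]]
};

struct Comp {
  double la, lb, ld; // precision Lambda (symmetric 2x2)
  double h1, h2;     // precision-mean h = Lambda * mean
  double lw;         // log mixture weight
  int origin;        // change-time index (0-based) of the component
};

struct ClassPars {
  double A[4];      // assignment matrix, row-major [a11 a12; a21 a22]
  Mat2 Sinv;        // inverse error covariance
  double logdetS;
  Mat2 AtSA;        // A' Sinv A
  double AtS[4];    // A' Sinv (row-major, not symmetric in general)
  Mat2 AVA;         // A V A' (prior predictive covariance part)
};

static inline double det2(const Mat2 &m) { return m.a * m.d - m.b * m.b; }

static inline Mat2 inv2(const Mat2 &m) {
  double dt = det2(m);
  Mat2 r;
  r.a = m.d / dt; r.b = -m.b / dt; r.d = m.a / dt;
  return r;
}

// log N(u; mean, S) for symmetric 2x2 S
static inline double ldnorm2(double d1, double d2, const Mat2 &S) {
  double dt = det2(S);
  double q = (d1 * d1 * S.d - 2.0 * d1 * d2 * S.b + d2 * d2 * S.a) / dt;
  return -LOG2PI - 0.5 * std::log(dt) - 0.5 * q;
}

// g(Lambda, h) = 0.5 h' Lambda^{-1} h - 0.5 log det Lambda
// (log normalization of the canonical-form Gaussian, 2*pi factors dropped:
// they cancel in the 4-term combination below)
static inline double gfun(double la, double lb, double ld, double h1, double h2) {
  double dt = la * ld - lb * lb;
  double q = (h1 * h1 * ld - 2.0 * h1 * h2 * lb + h2 * h2 * la) / dt;
  return 0.5 * q - 0.5 * std::log(dt);
}

static inline double lse2(double a, double b) {
  double m = std::max(a, b);
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct Hyper {
  double mu0[2], z[2];
  Mat2 V, Vinv;
  double hz1, hz2;      // Vinv * z
  double p, r, s;
  double lp, l1p, lr, ls, l1rs;
  double lpin, lpiv;    // log stationary mass of normal / of all-variant
  std::vector<ClassPars> cls;
};

static Hyper make_hyper(const List &hp) {
  Hyper H;
  NumericVector mu0 = hp["mu0"], z = hp["z"];
  NumericMatrix V = hp["V"];
  double p = hp["p"], r = hp["r"], s = hp["s"];
  H.mu0[0] = mu0[0]; H.mu0[1] = mu0[1];
  H.z[0] = z[0]; H.z[1] = z[1];
  H.V.a = V(0, 0); H.V.b = V(0, 1); H.V.d = V(1, 1);
  H.Vinv = inv2(H.V);
  H.hz1 = H.Vinv.a * z[0] + H.Vinv.b * z[1];
  H.hz2 = H.Vinv.b * z[0] + H.Vinv.d * z[1];
  H.p = p; H.r = r; H.s = s;
  H.lp = std::log(p); H.l1p = std::log1p(-p);
  H.lr = std::log(r); H.ls = (s > 0) ? std::log(s) : R_NegInf;
  H.l1rs = std::log1p(-(r + s));
  double pin = r / (r + p);
  H.lpin = std::log(pin);
  H.lpiv = std::log1p(-pin);
  List sig = hp["sigma"];
  CharacterVector nm = CharacterVector::create("AA", "AB", "BA", "BB", "NP");
  const double Amats[5][4] = {
    {1, 1, 0, 0},   // AA: (x, y) ~ (theta1 + theta2, 0)
    {1, 0, 0, 1},   // AB: identity
    {0, 1, 1, 0},   // BA: swap
    {0, 0, 1, 1},   // BB
    {0.5, 0.5, 0.5, 0.5} // NP: total only
  };
  H.cls.resize(5);
  for (int c = 0; c < 5; ++c) {
    ClassPars &cp = H.cls[c];
    NumericMatrix S = sig[std::string(nm[c])];
    Mat2 Sm; Sm.a = S(0, 0); Sm.b = S(0, 1); Sm.d = S(1, 1);
    cp.Sinv = inv2(Sm);
    cp.logdetS = std::log(det2(Sm));
    for (int i = 0; i < 4; ++i) cp.A[i] = Amats[c][i];
    // A' Sinv
    cp.AtS[0] = cp.A[0] * cp.Sinv.a + cp.A[2] * cp.Sinv.b;
    cp.AtS[1] = cp.A[0] * cp.Sinv.b + cp.A[2] * cp.Sinv.d;
    cp.AtS[2] = cp.A[1] * cp.Sinv.a + cp.A[3] * cp.Sinv.b;
    cp.AtS[3] = cp.A[1] * cp.Sinv.b + cp.A[3] * cp.Sinv.d;
    // A' Sinv A
    cp.AtSA.a = cp.AtS[0] * cp.A[0] + cp.AtS[1] * cp.A[2];
    cp.AtSA.b = cp.AtS[0] * cp.A[1] + cp.AtS[1] * cp.A[3];
    cp.AtSA.d = cp.AtS[2] * cp.A[1] + cp.AtS[3] * cp.A[3];
    // A V A'
    double VA11 = H.V.a * cp.A[0] + H.V.b * cp.A[1];
    double VA12 = H.V.a * cp.A[2] + H.V.b * cp.A[3];
    double VA21 = H.V.b * cp.A[0] + H.V.d * cp.A[1];
    double VA22 = H.V.b * cp.A[2] + H.V.d * cp.A[3];
    cp.AVA.a = cp.A[0] * VA11 + cp.A[1] * VA21;
    cp.AVA.b = cp.A[0] * VA12 + cp.A[1] * VA22;
    cp.AVA.d = cp.A[2] * VA12 + cp.A[3] * VA22;
  }
  return H;
}

struct State {
  double lw0;              // log weight of the point mass at mu0
  std::vector<Comp> comps;
};

static inline double lse_comps(const std::vector<Comp> &cs) {
  if (cs.empty()) return R_NegInf;
  double m = cs[0].lw;
  for (size_t i = 1; i < cs.size(); ++i) m = std::max(m, cs[i].lw);
  double sum = 0;
  for (size_t i = 0; i < cs.size(); ++i) sum += std::exp(cs[i].lw - m);
  return m + std::log(sum);
}

// One filter pass over u[idx[0..n-1]] with genotype classes g[idx[...]].
// Returns per-step states and adds the marginal log likelihood into *ll.
static std::vector<State> run_filter(const NumericMatrix &u,
                                     const IntegerVector &g,
                                     const std::vector<int> &idx,
                                     const Hyper &H, int M, int K,
                                     double *ll) {
  int n = idx.size();
  std::vector<State> out(n);
  State cur;
  *ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int i = idx[t];
    const ClassPars &cp = H.cls[g[i]];
    double u1 = u(i, 0), u2 = u(i, 1);

    // baseline likelihood: u ~ N(A mu0, Sigma)
    double m01 = cp.A[0] * H.mu0[0] + cp.A[1] * H.mu0[1];
    double m02 = cp.A[2] * H.mu0[0] + cp.A[3] * H.mu0[1];
    Mat2 S0 = inv2(cp.Sinv); // Sigma_g

    double l0 = ldnorm2(u1 - m01, u2 - m02, S0);

    // prior predictive for a brand-new variant segment: u ~ N(A z, A V A' + Sigma)
    double mz1 = cp.A[0] * H.z[0] + cp.A[1] * H.z[1];
    double mz2 = cp.A[2] * H.z[0] + cp.A[3] * H.z[1];
    Mat2 Sz; Sz.a = cp.AVA.a + S0.a; Sz.b = cp.AVA.b + S0.b; Sz.d = cp.AVA.d + S0.d;
    double lnew_pred = ldnorm2(u1 - mz1, u2 - mz2, Sz);

    State nxt;
    double prior0, prior_new;
    if (t == 0) {
      prior0 = H.lpin;
      prior_new = H.lpiv;
    } else {
      double lsev = lse_comps(cur.comps);
      prior0 = lse2(cur.lw0 + H.l1p, lsev + H.lr);
      prior_new = lse2(cur.lw0 + H.lp, lsev + H.ls);
    }
    nxt.lw0 = prior0 + l0;

    // continued components: predictive density, then conjugate update
    nxt.comps.reserve((t == 0 ? 0 : cur.comps.size()) + 1);
    if (t > 0) {
      for (size_t k = 0; k < cur.comps.size(); ++k) {
        Comp c = cur.comps[k];
        Mat2 lam; lam.a = c.la; lam.b = c.lb; lam.d = c.ld;
        Mat2 C = inv2(lam);
        double me1 = C.a * c.h1 + C.b * c.h2;
        double me2 = C.b * c.h1 + C.d * c.h2;
        // predictive cov A C A' + Sigma
        double CA11 = C.a * cp.A[0] + C.b * cp.A[1];
        double CA12 = C.a * cp.A[2] + C.b * cp.A[3];
        double CA21 = C.b * cp.A[0] + C.d * cp.A[1];
        double CA22 = C.b * cp.A[2] + C.d * cp.A[3];
        Mat2 Sp;
        Sp.a = cp.A[0] * CA11 + cp.A[1] * CA21 + S0.a;
        Sp.b = cp.A[0] * CA12 + cp.A[1] * CA22 + S0.b;
        Sp.d = cp.A[2] * CA12 + cp.A[3] * CA22 + S0.d;
        double pm1 = cp.A[0] * me1 + cp.A[1] * me2;
        double pm2 = cp.A[2] * me1 + cp.A[3] * me2;
        double lpred = ldnorm2(u1 - pm1, u2 - pm2, Sp);
        c.lw += H.l1rs + lpred;
        c.la += cp.AtSA.a; c.lb += cp.AtSA.b; c.ld += cp.AtSA.d;
        c.h1 += cp.AtS[0] * u1 + cp.AtS[1] * u2;
        c.h2 += cp.AtS[2] * u1 + cp.AtS[3] * u2;
        nxt.comps.push_back(c);
      }
    }
    // fresh component with change time t
    Comp cn;
    cn.la = H.Vinv.a + cp.AtSA.a;
    cn.lb = H.Vinv.b + cp.AtSA.b;
    cn.ld = H.Vinv.d + cp.AtSA.d;
    cn.h1 = H.hz1 + cp.AtS[0] * u1 + cp.AtS[1] * u2;
    cn.h2 = H.hz2 + cp.AtS[2] * u1 + cp.AtS[3] * u2;
    cn.lw = prior_new + lnew_pred;
    cn.origin = t;
    nxt.comps.push_back(cn);

    // normalize; the normalizer is the one-step predictive likelihood
    double tot = lse2(nxt.lw0, lse_comps(nxt.comps));
    *ll += tot;
    nxt.lw0 -= tot;
    for (size_t k = 0; k < nxt.comps.size(); ++k) nxt.comps[k].lw -= tot;

    // BCMIX pruning: always keep the K most recent change times, fill the
    // remaining M - K slots with the largest-weight older components.
    int nc = nxt.comps.size();
    if (nc > M) {
      int keep_recent = std::min(K, M);
      int n_old = nc - keep_recent;
      int keep_old = M - keep_recent;
      // components are stored in origin order; the last keep_recent are newest
      std::vector<int> ord(n_old);
      for (int k = 0; k < n_old; ++k) ord[k] = k;
      std::partial_sort(ord.begin(), ord.begin() + keep_old, ord.end(),
                        [&](int a, int b) {
                          if (nxt.comps[a].lw != nxt.comps[b].lw)
                            return nxt.comps[a].lw > nxt.comps[b].lw;
                          return a < b;
                        });
      std::vector<int> sel(ord.begin(), ord.begin() + keep_old);
      std::sort(sel.begin(), sel.end());
      std::vector<Comp> kept;
      kept.reserve(M);
      for (size_t k = 0; k < sel.size(); ++k) kept.push_back(nxt.comps[sel[k]]);
      for (int k = n_old; k < nc; ++k) kept.push_back(nxt.comps[k]);
      nxt.comps.swap(kept);
      double tot2 = lse2(nxt.lw0, lse_comps(nxt.comps));
      nxt.lw0 -= tot2;
      for (size_t k = 0; k < nxt.comps.size(); ++k) nxt.comps[k].lw -= tot2;
    }
    out[t] = nxt;
    cur = out[t];
  }
  return out;
}

static List state_to_list(const std::vector<State> &st,
                          const std::vector<int> &origin_map) {
  int n = st.size();
  List out(n);
  for (int t = 0; t < n; ++t) {
    int nc = st[t].comps.size();
    NumericVector w(nc), m1(nc), m2(nc), c11(nc), c12(nc), c22(nc);
    IntegerVector org(nc);
    for (int k = 0; k < nc; ++k) {
      const Comp &c = st[t].comps[k];
      Mat2 lam; lam.a = c.la; lam.b = c.lb; lam.d = c.ld;
      Mat2 C = inv2(lam);
      w[k] = std::exp(c.lw);
      m1[k] = C.a * c.h1 + C.b * c.h2;
      m2[k] = C.b * c.h1 + C.d * c.h2;
      c11[k] = C.a; c12[k] = C.b; c22[k] = C.d;
      org[k] = origin_map[c.origin] + 1; // 1-based SNP index in caller order
    }
    out[t] = List::create(_["baseline_weight"] = std::exp(st[t].lw0),
                          _["weight"] = w, _["mean1"] = m1, _["mean2"] = m2,
                          _["cov11"] = c11, _["cov12"] = c12, _["cov22"] = c22,
                          _["origin"] = org);
  }
  return out;
}

// [[Rcpp::export]]
List pscn_filter_cpp(NumericMatrix u, IntegerVector gcode, List hp,
                     int M, int K, bool reverse) {
  int n = u.nrow();
  Hyper H = make_hyper(hp);
  std::vector<int> idx(n);
  for (int t = 0; t < n; ++t) idx[t] = reverse ? (n - 1 - t) : t;
  double ll = 0;
  std::vector<State> st = run_filter(u, gcode, idx, H, M, K, &ll);
  List states = state_to_list(st, idx);
  if (reverse) { // report in genomic order
    List rev(n);
    for (int t = 0; t < n; ++t) rev[t] = states[n - 1 - t];
    states = rev;
  }
  return List::create(_["states"] = states, _["loglik"] = ll);
}

// [[Rcpp::export]]
List pscn_smooth_cpp(NumericMatrix u, IntegerVector gcode, List hp,
                     int M, int K) {
  int n = u.nrow();
  Hyper H = make_hyper(hp);
  std::vector<int> fwd_idx(n), bwd_idx(n);
  for (int t = 0; t < n; ++t) { fwd_idx[t] = t; bwd_idx[t] = n - 1 - t; }
  double llf = 0, llb = 0;
  std::vector<State> F = run_filter(u, gcode, fwd_idx, H, M, K, &llf);
  std::vector<State> B = run_filter(u, gcode, bwd_idx, H, M, K, &llb);

  NumericMatrix theta(n, 2);
  NumericVector pbase(n);
  double g0 = gfun(H.Vinv.a, H.Vinv.b, H.Vinv.d, H.hz1, H.hz2);

  for (int t = 0; t < n; ++t) {
    const State &f = F[t];
    int nf = f.comps.size();
    std::vector<double> lw;       // log weights of all posterior terms
    std::vector<double> me1, me2; // their means
    lw.reserve(1 + nf * (M + 2));
    me1.reserve(1 + nf * (M + 2));
    me2.reserve(1 + nf * (M + 2));

    if (t == n - 1) {
      lw.push_back(f.lw0); me1.push_back(H.mu0[0]); me2.push_back(H.mu0[1]);
      for (int i = 0; i < nf; ++i) {
        const Comp &c = f.comps[i];
        Mat2 lam; lam.a = c.la; lam.b = c.lb; lam.d = c.ld;
        Mat2 C = inv2(lam);
        lw.push_back(c.lw);
        me1.push_back(C.a * c.h1 + C.b * c.h2);
        me2.push_back(C.b * c.h1 + C.d * c.h2);
      }
    } else {
      // backward-filter state holding data u_{t+1..n-1}, propagated one
      // step to time t through the (reversible) transition kernel
      const State &b = B[n - 2 - t];
      double lse_qb = lse_comps(b.comps);
      double lqb0s = lse2(b.lw0 + H.l1p, lse_qb + H.lr);
      double lqbnews = lse2(b.lw0 + H.lp, lse_qb + H.ls);
      int nb = b.comps.size();
      std::vector<double> gks(nb);
      for (int k = 0; k < nb; ++k) {
        const Comp &ck = b.comps[k];
        gks[k] = gfun(ck.la, ck.lb, ck.ld, ck.h1, ck.h2);
      }

      // atom at mu0
      lw.push_back(f.lw0 + lqb0s - H.lpin);
      me1.push_back(H.mu0[0]); me2.push_back(H.mu0[1]);

      for (int i = 0; i < nf; ++i) {
        const Comp &ci = f.comps[i];
        Mat2 lam; lam.a = ci.la; lam.b = ci.lb; lam.d = ci.ld;
        Mat2 C = inv2(lam);
        double mi1 = C.a * ci.h1 + C.b * ci.h2;
        double mi2 = C.b * ci.h1 + C.d * ci.h2;
        double gi = gfun(ci.la, ci.lb, ci.ld, ci.h1, ci.h2);

        // forward run ends at t: future starts a fresh variant (or normal)
        lw.push_back(ci.lw + lqbnews - H.lpiv);
        me1.push_back(mi1); me2.push_back(mi2);

        // forward run continues into a backward run: Bayes combination,
        // precision Lam_i + Lam_k - Vinv, score from the Gaussian algebra.
        // Pairs whose filter-weight product is negligible are skipped: the
        // combination factor logc is a single bivariate Gaussian overlap
        // integral and cannot rescue a product this far below the
        // dominant pair.
        for (int k = 0; k < nb; ++k) {
          const Comp &ck = b.comps[k];
          if (ci.lw + ck.lw < -40) continue;
          double la = ci.la + ck.la - H.Vinv.a;
          double lb2 = ci.lb + ck.lb - H.Vinv.b;
          double ld = ci.ld + ck.ld - H.Vinv.d;
          double h1 = ci.h1 + ck.h1 - H.hz1;
          double h2 = ci.h2 + ck.h2 - H.hz2;
          double gs = gfun(la, lb2, ld, h1, h2);
          double logc = gs - gi - gks[k] + g0;
          double l = ci.lw + ck.lw + H.l1rs - H.lpiv + logc;
          if (l < -46) continue; // weight below ~1e-20 after normalization
          Mat2 lamS; lamS.a = la; lamS.b = lb2; lamS.d = ld;
          Mat2 CS = inv2(lamS);
          lw.push_back(l);
          me1.push_back(CS.a * h1 + CS.b * h2);
          me2.push_back(CS.b * h1 + CS.d * h2);
        }
      }
    }
    // normalize and take the posterior mean (Bayes estimate of theta_t)
    double m = lw[0];
    for (size_t k = 1; k < lw.size(); ++k) m = std::max(m, lw[k]);
    double tot = 0, s1 = 0, s2 = 0;
    for (size_t k = 0; k < lw.size(); ++k) {
      double w = std::exp(lw[k] - m);
      tot += w; s1 += w * me1[k]; s2 += w * me2[k];
    }
    theta(t, 0) = s1 / tot;
    theta(t, 1) = s2 / tot;
    pbase[t] = std::exp(lw[0] - m) / tot;
  }
  return List::create(_["theta_hat"] = theta, _["baseline_prob"] = pbase,
                      _["loglik"] = llf);
}

// Per-SNP MAP genotype configuration given theta_hat: argmax over classes of
// prior * N(u; A(g) theta, Sigma_g). Ties broken by class order
// AA, AB, BA, BB (NP only ever wins through its prior).
// [[Rcpp::export]]
IntegerVector genotype_map_cpp(NumericMatrix u, NumericMatrix theta,
                               NumericMatrix log_prior, List hp) {
  int n = u.nrow();
  Hyper H = make_hyper(hp);
  IntegerVector out(n);
  for (int t = 0; t < n; ++t) {
    double best = R_NegInf;
    int arg = 0;
    for (int c = 0; c < 5; ++c) {
      double lp = log_prior(t, c);
      if (!std::isfinite(lp)) continue;
      const ClassPars &cp = H.cls[c];
      double m1 = cp.A[0] * theta(t, 0) + cp.A[1] * theta(t, 1);
      double m2 = cp.A[2] * theta(t, 0) + cp.A[3] * theta(t, 1);
      Mat2 S = inv2(cp.Sinv);
      double l = lp + ldnorm2(u(t, 0) - m1, u(t, 1) - m2, S);
      if (l > best + 1e-12) { best = l; arg = c; }
    }
    out[t] = arg + 1; // 1-based class code
  }
  return out;
}
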
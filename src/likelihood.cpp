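#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Core likelihood machinery for the germline allele-count model.
//
// Per informative site p with recombination probability r to the candidate
// distorter, the chance that a sampled gamete chromosome carries the
// lyrata-lineage allele is q = k(1 - r) + (1 - k)r.  Sequencing/mapping
// error E mixes this to q' = q(1 - E) + (1 - q)E, and the reference-mapping
// bias acts as a read-sampling odds b, giving the per-read probability
//   p = b q' / (b q' + (1 - q')).
// Binomial coefficients are omitted throughout: they are constant in k so
// cancel in every likelihood ratio and optimisation.

namespace {

struct SiteVecs {
  std::vector<double> nl, nh, r;
};

inline double read_p(double q, double E, double b) {
  double qp = E + (1.0 - 2.0 * E) * q;
  double p = b * qp / (1.0 + (b - 1.0) * qp);
  if (p < 1e-12) p = 1e-12;
  if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
  return p;
}

double loglik_on(const SiteVecs &s, double k, double E, double b) {
  double ll = 0.0;
  for (size_t i = 0; i < s.r.size(); ++i) {
    double q = s.r[i] + k * (1.0 - 2.0 * s.r[i]);
    double p = read_p(q, E, b);
    ll += s.nl[i] * std::log(p) + s.nh[i] * std::log1p(-p);
  }
  return ll;
}

// d logL / d k up to the positive constant b(1 - 2E); only the sign and the
// root matter.  With p = b q' / t, 1 - p = (1 - q') / t, t = 1 + (b - 1) q':
//   dL/dk = sum_i (nl/p - nh/(1-p)) dp/dk,  dp/dk = b(1-2E)(1-2r)/t^2
double score_on(const SiteVecs &s, double k, double E, double b) {
  double a = 1.0 - 2.0 * E;
  double sc = 0.0;
  for (size_t i = 0; i < s.r.size(); ++i) {
    double c1 = 1.0 - 2.0 * s.r[i];
    double q = s.r[i] + k * c1;
    double qp = E + a * q;
    if (qp < 1e-12) qp = 1e-12;
    if (qp > 1.0 - 1e-12) qp = 1.0 - 1e-12;
    double t = 1.0 + (b - 1.0) * qp;
    sc += c1 / t * (s.nl[i] / (b * qp) - s.nh[i] / (1.0 - qp));
  }
  return sc;
}

// Bisection on the score; the chromosome-wide log-likelihood is unimodal in
// k for any realistic count configuration, and boundary cases (monotone
// likelihood) land on the supplied bounds.
double khat_on(const SiteVecs &s, double E, double b, double lo, double hi,
               int iters) {
  if (score_on(s, lo, E, b) <= 0.0) return lo;
  if (score_on(s, hi, E, b) >= 0.0) return hi;
  double a = lo, c = hi;
  for (int it = 0; it < iters; ++it) {
    double m = 0.5 * (a + c);
    if (score_on(s, m, E, b) > 0.0) a = m; else c = m;
  }
  return 0.5 * (a + c);
}

// Assemble per-site (or binned) effective counts and recombination
// probabilities for one candidate at genetic position gc (Morgans).
// Binning pools sites into `bins` equal-width genetic-distance classes,
// evaluated at the depth-weighted mean distance; it is a runtime
// approximation used by the simulation harness, exact mode is bins <= 0.
void build_vecs(const NumericVector &nl, const NumericVector &nh,
                const NumericVector &w, const NumericVector &g, double gc,
                int bins, SiteVecs &out) {
  int n = nl.size();
  out.nl.clear(); out.nh.clear(); out.r.clear();
  if (bins > 0 && n > 2 * bins) {
    std::vector<double> wl(bins, 0.0), wh(bins, 0.0), wd(bins, 0.0),
        wt(bins, 0.0);
    double dmax = 0.0;
    std::vector<double> d(n);
    for (int i = 0; i < n; ++i) {
      d[i] = std::fabs(g[i] - gc);
      if (d[i] > dmax) dmax = d[i];
    }
    double h = dmax > 0.0 ? dmax / bins : 1.0;
    for (int i = 0; i < n; ++i) {
      double dep = nl[i] + nh[i];
      if (w[i] <= 0.0 || dep <= 0.0) continue;
      int idx = (int)(d[i] / h);
      if (idx >= bins) idx = bins - 1;
      wl[idx] += w[i] * nl[i];
      wh[idx] += w[i] * nh[i];
      wt[idx] += w[i] * dep;
      wd[idx] += w[i] * dep * d[i];
    }
    for (int jb = 0; jb < bins; ++jb) {
      if (wt[jb] <= 0.0) continue;
      double dbar = wd[jb] / wt[jb];
      out.nl.push_back(wl[jb]);
      out.nh.push_back(wh[jb]);
      out.r.push_back(0.5 * (1.0 - std::exp(-2.0 * dbar)));
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double dep = nl[i] + nh[i];
      if (w[i] <= 0.0 || dep <= 0.0) continue;
      double dd = std::fabs(g[i] - gc);
      out.nl.push_back(w[i] * nl[i]);
      out.nh.push_back(w[i] * nh[i]);
      out.r.push_back(0.5 * (1.0 - std::exp(-2.0 * dd)));
    }
  }
}

} // namespace

// [[Rcpp::export]]
double cpp_loglik(NumericVector nl, NumericVector nh, NumericVector w,
                  NumericVector r, double k, double E, double b) {
  SiteVecs s;
  int n = nl.size();
  s.nl.reserve(n); s.nh.reserve(n); s.r.reserve(n);
  for (int i = 0; i < n; ++i) {
    double dep = nl[i] + nh[i];
    if (w[i] <= 0.0 || dep <= 0.0) continue;
    s.nl.push_back(w[i] * nl[i]);
    s.nh.push_back(w[i] * nh[i]);
    s.r.push_back(r[i]);
  }
  return loglik_on(s, k, E, b);
}

// Profile of (k-hat, logL at k-hat) over candidate genetic positions gc;
// optionally also logL at a fixed k (kfix > 0), used by the decay-null mode.
// [[Rcpp::export]]
List cpp_scan_profile(NumericVector nl, NumericVector nh, NumericVector w,
                      NumericVector g, NumericVector gc, double E, double b,
                      double lo, double hi, int bins, int iters,
                      double kfix) {
  int m = gc.size();
  NumericVector kh(m), ll(m), llfix(m);
  bool do_fix = R_finite(kfix) && kfix > 0.0;
  SiteVecs s;
  for (int j = 0; j < m; ++j) {
    build_vecs(nl, nh, w, g, gc[j], bins, s);
    kh[j] = khat_on(s, E, b, lo, hi, iters);
    ll[j] = loglik_on(s, kh[j], E, b);
    if (do_fix) llfix[j] = loglik_on(s, kfix, E, b);
  }
  List out = List::create(_["k"] = kh, _["loglik"] = ll);
  if (do_fix) out["loglik_fixed"] = llfix;
  return out;
}

// Greedy left-to-right spacing filter within one chromosome: keep a site
// iff its position exceeds the last kept position by more than min_gap.
// [[Rcpp::export]]
LogicalVector cpp_spacing(NumericVector pos, double min_gap) {
  int n = pos.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  keep[0] = true;
  double last = pos[0];
  for (int i = 1; i < n; ++i) {
    if (pos[i] - last > min_gap) {
      keep[i] = true;
      last = pos[i];
    } else {
      keep[i] = false;
    }
  }
  return keep;
}
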
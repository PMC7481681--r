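#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Agent type codes shared with the R side: 0 = medium, 1 = live, 2 = dead.
// Lattice labels: agent id per site, 0 = medium. All indices 0-based here.

typedef std::unordered_map<int, int> IdIndex;

static IdIndex build_index(const IntegerVector& ids) {
  IdIndex idx;
  idx.reserve(ids.size() * 2);
  for (int i = 0; i < ids.size(); ++i) idx[ids[i]] = i;
  return idx;
}

static inline int lookup(const IdIndex& idx, int id) {
  IdIndex::const_iterator it = idx.find(id);
  if (it == idx.end())
    stop("label %d present in lattice but missing from agent registry", id);
  return it->second;
}

// Change in effective energy for copying the agent id at (sr,sc) onto (tr,tc).
// Volume term uses site counts; contact term is the ordered double-count over
// Moore range-1 pairs, so each changed unordered pair contributes twice.
static double delta_H(const IntegerMatrix& lab,
                      int sr, int sc, int tr, int tc,
                      const IdIndex& idx,
                      const IntegerVector& type_code,
                      const NumericVector& lambda,
                      const NumericVector& vtarget,
                      const IntegerVector& nsites,
                      const NumericMatrix& J) {
  const int s = lab(sr, sc), o = lab(tr, tc);
  if (s == o) return 0.0;
  double dH = 0.0;
  int ts = 0, to = 0;
  if (s != 0) {
    const int i = lookup(idx, s);
    ts = type_code[i];
    const double n = nsites[i], v = vtarget[i];
    dH += lambda[i] * ((n + 1 - v) * (n + 1 - v) - (n - v) * (n - v));
  }
  if (o != 0) {
    const int i = lookup(idx, o);
    to = type_code[i];
    const double n = nsites[i], v = vtarget[i];
    dH += lambda[i] * ((n - 1 - v) * (n - 1 - v) - (n - v) * (n - v));
  }
  const int nr = lab.nrow(), nc = lab.ncol();
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      const int r = tr + dr, c = tc + dc;
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      const int q = lab(r, c);
      const int tq = (q == 0) ? 0 : type_code[lookup(idx, q)];
      if (q != s) dH += 2.0 * J(ts, tq);
      if (q != o) dH -= 2.0 * J(to, tq);
    }
  }
  return dH;
}

// [[Rcpp::export]]
double cpp_delta_energy(IntegerMatrix labels,
                        int sr, int sc, int tr, int tc,
                        IntegerVector ids, IntegerVector type_code,
                        NumericVector lambda, NumericVector vtarget,
                        IntegerVector nsites, NumericMatrix J) {
  IdIndex idx = build_index(ids);
  return delta_H(labels, sr, sc, tr, tc, idx, type_code, lambda, vtarget,
                 nsites, J);
}

// One Monte Carlo step: nattempts copy attempts.  RNG consumption order per
// attempt: (1) source-site uniform, (2) neighbour-direction uniform, then
// (3) one acceptance uniform only when the proposal is valid (in bounds,
// differing ids) and dH > 0.  Out-of-bounds targets are rejected attempts.
// [[Rcpp::export]]
List cpp_monte_carlo_step(IntegerMatrix labels,
                          IntegerVector ids, IntegerVector type_code,
                          NumericVector lambda, NumericVector vtarget,
                          IntegerVector nsites, NumericMatrix J,
                          double Hstar, int nattempts) {
  IntegerMatrix lab = clone(labels);
  IntegerVector cnt = clone(nsites);
  IdIndex idx = build_index(ids);
  const int nr = lab.nrow(), nc = lab.ncol();
  const double nsite = (double) nr * nc;
  const int drs[4] = {-1, 1, 0, 0};
  const int dcs[4] = {0, 0, -1, 1};
  int accepted = 0;
  for (int a = 0; a < nattempts; ++a) {
    int site = (int) (unif_rand() * nsite);
    if (site >= nr * nc) site = nr * nc - 1;
    const int sr = site % nr, sc = site / nr;   // column-major like R
    int d = (int) (unif_rand() * 4.0);
    if (d > 3) d = 3;
    const int tr = sr + drs[d], tc = sc + dcs[d];
    if (tr < 0 || tr >= nr || tc < 0 || tc >= nc) continue;  // edge: rejected
    const int s = lab(sr, sc), o = lab(tr, tc);
    if (s == o) continue;  // no-op attempt, dH = 0
    const double dH = delta_H(lab, sr, sc, tr, tc, idx, type_code, lambda,
                              vtarget, cnt, J);
    bool accept = true;
    if (dH > 0.0) accept = unif_rand() < std::exp(-dH / Hstar);
    if (accept) {
      lab(tr, tc) = s;
      if (s != 0) cnt[lookup(idx, s)] += 1;
      if (o != 0) cnt[lookup(idx, o)] -= 1;
      ++accepted;
    }
  }
  return List::create(_["labels"] = lab, _["n_sites"] = cnt,
                      _["accepted"] = accepted);
}

// Quasi-steady oxygen: projected Gauss-Seidel/SOR on D lap(c) + s = 0 over
// non-medium sites, medium clamped at envc, out-of-domain neighbours treated
// as medium (envc).  Concentrations projected onto c >= 0 (uptake saturates
// at anoxia).  Sweeps are restricted to the bounding box of non-medium
// sites; omega <= 0 selects the optimal SOR factor 2/(1 + sin(pi/(m+1)))
// for the box size m.  Returns relaxed field, sweep count and final
// residual (max-norm of D lap(c) + s over non-medium sites,
// complementarity-aware at c = 0).
// [[Rcpp::export]]
List cpp_relax_quasi_steady(NumericMatrix conc, IntegerMatrix labels,
                            NumericMatrix source, double D, double alpha,
                            double envc, double tol, int max_sweeps,
                            double omega) {
  NumericMatrix c = clone(conc);
  const int nr = c.nrow(), nc = c.ncol();
  const double a2_over_D = alpha * alpha / D;
  // clamp medium and find the occupied bounding box in one pass
  int r0 = nr, r1 = -1, c0 = nc, c1 = -1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (labels(i, j) == 0) {
        c(i, j) = envc;
      } else {
        if (i < r0) r0 = i;
        if (i > r1) r1 = i;
        if (j < c0) c0 = j;
        if (j > c1) c1 = j;
      }
    }
  }
  if (r1 < 0)  // no cells anywhere: clamp is the steady state
    return List::create(_["conc"] = c, _["sweeps"] = 0, _["residual"] = 0.0);
  if (omega <= 0.0) {
    const int m = std::max(r1 - r0, c1 - c0) + 1;
    omega = 2.0 / (1.0 + std::sin(M_PI / (m + 1)));
  }
  double resid = R_PosInf;
  int sweep = 0;
  while (sweep < max_sweeps) {
    ++sweep;
    for (int j = c0; j <= c1; ++j) {
      for (int i = r0; i <= r1; ++i) {
        if (labels(i, j) == 0) continue;
        const double up    = (i > 0)      ? c(i - 1, j) : envc;
        const double down  = (i < nr - 1) ? c(i + 1, j) : envc;
        const double left  = (j > 0)      ? c(i, j - 1) : envc;
        const double right = (j < nc - 1) ? c(i, j + 1) : envc;
        const double gs = (up + down + left + right +
                           source(i, j) * a2_over_D) / 4.0;
        double v = (1.0 - omega) * c(i, j) + omega * gs;
        if (v < 0.0) v = 0.0;
        c(i, j) = v;
      }
    }
    resid = 0.0;
    for (int j = c0; j <= c1; ++j) {
      for (int i = r0; i <= r1; ++i) {
        if (labels(i, j) == 0) continue;
        const double up    = (i > 0)      ? c(i - 1, j) : envc;
        const double down  = (i < nr - 1) ? c(i + 1, j) : envc;
        const double left  = (j > 0)      ? c(i, j - 1) : envc;
        const double right = (j < nc - 1) ? c(i, j + 1) : envc;
        double r = D * (up + down + left + right - 4.0 * c(i, j)) /
                   (alpha * alpha) + source(i, j);
        if (c(i, j) <= 0.0 && r < 0.0) r = 0.0;  // saturated sink site
        if (std::abs(r) > resid) resid = std::abs(r);
      }
    }
    if (resid < tol) break;
  }
  return List::create(_["conc"] = c, _["sweeps"] = sweep,
                      _["residual"] = resid);
}

// nsteps forward-Euler substeps of dt each; medium clamped, c >= 0 enforced.
// [[Rcpp::export]]
NumericMatrix cpp_explicit_substeps(NumericMatrix conc, IntegerMatrix labels,
                                    NumericMatrix source, double D,
                                    double alpha, double envc, double dt,
                                    int nsteps) {
  NumericMatrix c = clone(conc);
  const int nr = c.nrow(), nc = c.ncol();
  NumericMatrix cn(nr, nc);
  const double k = D / (alpha * alpha);
  for (int step = 0; step < nsteps; ++step) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (labels(i, j) == 0) { cn(i, j) = envc; continue; }
        const double up    = (i > 0)      ? c(i - 1, j) : envc;
        const double down  = (i < nr - 1) ? c(i + 1, j) : envc;
        const double left  = (j > 0)      ? c(i, j - 1) : envc;
        const double right = (j < nc - 1) ? c(i, j + 1) : envc;
        double v = c(i, j) + dt * (k * (up + down + left + right -
                                        4.0 * c(i, j)) + source(i, j));
        if (v < 0.0) v = 0.0;
        cn(i, j) = v;
      }
    }
    c = clone(cn);
  }
  return c;
}

// Per-agent mean of a field over the agent's sites (labels > 0).
// [[Rcpp::export]]
List cpp_agent_field_stats(IntegerMatrix labels, NumericMatrix field) {
  std::unordered_map<int, std::pair<double, int> > acc;
  const int nr = labels.nrow(), nc = labels.ncol();
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int id = labels(i, j);
      if (id == 0) continue;
      std::pair<double, int>& p = acc[id];
      p.first += field(i, j);
      p.second += 1;
    }
  }
  const int n = acc.size();
  IntegerVector ids(n), counts(n);
  NumericVector means(n);
  int k = 0;
  for (std::unordered_map<int, std::pair<double, int> >::iterator it =
           acc.begin(); it != acc.end(); ++it, ++k) {
    ids[k] = it->first;
    counts[k] = it->second.second;
    means[k] = it->second.first / it->second.second;
  }
  return List::create(_["id"] = ids, _["mean"] = means, _["n"] = counts);
}
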
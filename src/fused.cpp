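#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Elementwise-weighted 1D fused lasso
//   min_x sum_i [ 0.5*(x_i - y_i)^2 + w0_i |x_i| ]
//         + sum_{j=1..n-1} w1_j |x_{j+1} - x_j|
// solved exactly by dynamic programming over the chain (message passing
// with derivative clipping). The message derivative is piecewise linear
// and non-decreasing; it is stored as a deque of knots, each carrying the
// affine (slope, intercept) increment gained when crossing it left to
// right. Fusion terms clip the derivative at +/- w1_j; the per-node
// |x_i| terms insert a jump knot at zero. Backtracking through the
// per-step clipping bounds recovers the exact minimizer.

struct WflResult {
  std::vector<double> x;
};

static std::vector<double> dp_weighted_fused(const std::vector<double>& y,
                                             const std::vector<double>& w0,
                                             const std::vector<double>& w1) {
  const int n = y.size();
  std::vector<double> beta(n);
  if (n == 1) {
    // soft threshold
    double v = y[0];
    double t = w0[0];
    beta[0] = (v > t) ? v - t : ((v < -t) ? v + t : 0.0);
    return beta;
  }

  const int cap = 3 * n + 8;
  std::vector<double> xk(cap), ak(cap), bk(cap);
  std::vector<double> tm(n - 1), tp(n - 1);
  int l, r;

  // first node: message derivative is x - y0 + w0_0 * sign(x)
  // knots: possibly a jump at 0, then clip at +/- w1_0
  // Build initial deque for the UNCLIPPED first-node derivative, then the
  // main loop performs clipping lazily via the lo/hi scans.
  l = cap / 2;
  r = l - 1;  // empty deque; leftmost affine piece below
  double afirst = 1.0, bfirst = -y[0] - w0[0];
  double alast = -1.0, blast = y[0] - w0[0];  // negated right piece
  if (w0[0] > 0) {
    // jump knot at zero: crossing adds (0, 2*w0)
    ++r;
    xk[r] = 0.0;
    ak[r] = 0.0;
    bk[r] = 2.0 * w0[0];
  }

  for (int k = 0; k < n - 1; ++k) {
    double lam = w1[k];

    // scan from the left for where the derivative exceeds -lam; knots at
    // one position are crossed together (zero-width pieces carry no info)
    double alo = afirst, blo = bfirst;
    double left_bound = R_NegInf;
    int lo = l;
    while (lo <= r &&
           (xk[lo] <= left_bound || alo * xk[lo] + blo <= -lam)) {
      alo += ak[lo];
      blo += bk[lo];
      left_bound = xk[lo];
      ++lo;
    }
    double t_minus = (-lam - blo) / alo;
    if (t_minus < left_bound) t_minus = left_bound;  // jump landed past it
    tm[k] = t_minus;

    // scan from the right for where the derivative drops below +lam
    double ahi = alast, bhi = blast;
    double right_bound = R_PosInf;
    int hi = r;
    while (hi >= lo &&
           (xk[hi] >= right_bound || -ahi * xk[hi] - bhi >= lam)) {
      ahi += ak[hi];
      bhi += bk[hi];
      right_bound = xk[hi];
      --hi;
    }
    double t_plus = (lam + bhi) / (-ahi);
    if (t_plus > right_bound) t_plus = right_bound;
    if (t_plus < t_minus) t_plus = t_minus;
    tp[k] = t_plus;

    // collapse the deque to [lo, hi] plus the two new boundary knots
    l = lo - 1;
    r = hi + 1;
    xk[l] = t_minus;
    ak[l] = alo;
    bk[l] = blo + lam;
    xk[r] = t_plus;
    ak[r] = ahi;
    bk[r] = bhi + lam;

    // next node's data (+ node-L1) term
    double w0k = w0[k + 1];
    afirst = 1.0;
    bfirst = -y[k + 1] - lam - w0k;
    alast = -1.0;
    blast = y[k + 1] - lam - w0k;
    if (w0k > 0) {
      // insert jump knot at zero, keeping positions sorted
      int pos = l;
      while (pos <= r && xk[pos] < 0.0) ++pos;
      // shift the shorter side
      if (pos - l <= r - pos + 1) {
        --l;
        for (int i = l; i < pos - 1; ++i) {
          xk[i] = xk[i + 1];
          ak[i] = ak[i + 1];
          bk[i] = bk[i + 1];
        }
        --pos;
      } else {
        ++r;
        for (int i = r; i > pos; --i) {
          xk[i] = xk[i - 1];
          ak[i] = ak[i - 1];
          bk[i] = bk[i - 1];
        }
      }
      xk[pos] = 0.0;
      ak[pos] = 0.0;
      bk[pos] = 2.0 * w0k;
    }
  }

  // minimize the final message: scan for the zero of the derivative
  double alo = afirst, blo = bfirst;
  double left_bound = R_NegInf;
  int lo = l;
  while (lo <= r &&
         (xk[lo] <= left_bound || alo * xk[lo] + blo <= 0.0)) {
    alo += ak[lo];
    blo += bk[lo];
    left_bound = xk[lo];
    ++lo;
  }
  double bstar = -blo / alo;
  if (bstar < left_bound) bstar = left_bound;
  beta[n - 1] = bstar;
  for (int k = n - 2; k >= 0; --k) {
    if (beta[k + 1] > tp[k]) beta[k] = tp[k];
    else if (beta[k + 1] < tm[k]) beta[k] = tm[k];
    else beta[k] = beta[k + 1];
  }
  return beta;
}

static double wfl_objective(const std::vector<double>& x,
                            const std::vector<double>& y,
                            const std::vector<double>& w0,
                            const std::vector<double>& w1) {
  const int n = y.size();
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = y[i] - x[i];
    obj += 0.5 * r * r + w0[i] * std::fabs(x[i]);
    if (i > 0) obj += w1[i - 1] * std::fabs(x[i] - x[i - 1]);
  }
  return obj;
}

// [[Rcpp::export]]
List cpp_weighted_fused(NumericVector y, NumericVector w0, NumericVector w1) {
  const int n = y.size();
  if (n == 0) stop("empty input");
  if (w0.size() != n) stop("w0 must have length n");
  if (w1.size() != std::max(n - 1, 0)) stop("w1 must have length n - 1");
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> w0v(w0.begin(), w0.end());
  std::vector<double> w1v(w1.begin(), w1.end());
  std::vector<double> x = dp_weighted_fused(yv, w0v, w1v);
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["objective"] = wfl_objective(x, yv, w0v, w1v));
}

// Concave penalty transform f(t, a) = (1 - exp(-a t)) / a on t >= 0,
// with f -> t as a -> 0. Derivative f'(t) = exp(-a t) <= 1.
static inline double f_trans(double t, double a) {
  if (a < 1e-10) return t;
  return (1.0 - std::exp(-a * t)) / a;
}

// [[Rcpp::export]]
double cpp_cf_objective(NumericVector y, NumericVector x,
                        double lambda0, double lambda1, double a0, double a1) {
  const int n = y.size();
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = y[i] - x[i];
    obj += 0.5 * r * r;
    obj += lambda0 * f_trans(std::fabs(x[i]), a0);
    if (i > 0) obj += lambda1 * f_trans(std::fabs(x[i] - x[i - 1]), a1);
  }
  return obj;
}

// Majorize-minimize for the convex fused lasso
//   min_x 0.5*||y-x||^2 + lambda0 sum f(|x_i|, a0)
//         + lambda1 sum f(|x_i - x_{i-1}|, a1)
// (convex whenever 1 - a0*lambda0 - 4*a1*lambda1 >= 0). Each concave f is
// majorized by its tangent at the current iterate, giving an elementwise
// weighted fused lasso solved exactly by the DP above; the objective
// never increases across iterations.
// [[Rcpp::export]]
List cpp_convex_fused(NumericVector y, double lambda0, double lambda1,
                      double a0, double a1, double tol = 1e-8,
                      int max_iter = 100) {
  const int n = y.size();
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> x(yv);
  std::vector<double> w0(n), w1(std::max(n - 1, 0));
  NumericVector xr(y.begin(), y.end());
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  trace.push_back(cpp_cf_objective(y, xr, lambda0, lambda1, a0, a1));

  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int i = 0; i < n; ++i)
      w0[i] = lambda0 * std::exp(-a0 * std::fabs(x[i]));
    for (int j = 0; j + 1 < n; ++j)
      w1[j] = lambda1 * std::exp(-a1 * std::fabs(x[j + 1] - x[j]));
    x = dp_weighted_fused(yv, w0, w1);
    for (int i = 0; i < n; ++i) xr[i] = x[i];
    double obj = cpp_cf_objective(y, xr, lambda0, lambda1, a0, a1);
    double prev = trace.back();
    trace.push_back(obj);
    if (std::fabs(prev - obj) <= tol * std::max(1.0, std::fabs(prev))) {
      converged = true;
      ++iter;
      break;
    }
  }

  return List::create(_["x"] = xr,
                      _["objective"] = trace.back(),
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
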
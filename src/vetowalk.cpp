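#include <Rcpp.h>
using namespace Rcpp;

// Simulate `nsteps` transitions of a finite Markov chain from 0-based state
// `start`. Returns the 0-based states visited after each step (start state
// excluded). Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector sim_chain_path_cpp(NumericMatrix P, int start, int nsteps) {
  const int K = P.nrow();
  if (start < 0 || start >= K) stop("start state out of range");
  // row-wise cumulative probabilities
  NumericMatrix cum(K, K);
  for (int i = 0; i < K; ++i) {
    double acc = 0.0;
    for (int j = 0; j < K; ++j) {
      acc += P(i, j);
      cum(i, j) = acc;
    }
    cum(i, K - 1) = 1.0; // guard against rounding
  }
  IntegerVector out(nsteps);
  int s = start;
  for (int t = 0; t < nsteps; ++t) {
    const double u = unif_rand();
    int j = 0;
    while (cum(s, j) < u && j < K - 1) ++j;
    s = j;
    out[t] = s;
  }
  return out;
}

// ----------------------------------------------------------------------------
// Soft-margin linear SVM on scalar features, standard formulation:
//   min 1/2 w^2 + C sum_i max(0, 1 - y_i (w x_i + b))
// solved in the dual by SMO with maximal-violating-pair selection (the
// libsvm algorithm specialised to a 1-D linear kernel). Bias b is recovered
// from the KKT conditions. Labels are +/-1.
// ----------------------------------------------------------------------------

struct SvmFit {
  double w;
  double b;
  bool converged;
  int iter;
};

static SvmFit smo_fit_1d(const std::vector<double>& x,
                         const std::vector<int>& y,
                         double C, double eps, int max_iter) {
  const int m = (int)x.size();
  std::vector<double> alpha(m, 0.0);
  // f_i = sum_j alpha_j y_j K(x_j, x_i)  (decision value without bias)
  std::vector<double> f(m, 0.0);
  const double tau = 1e-12;

  int iter = 0;
  bool converged = false;
  for (; iter < max_iter; ++iter) {
    // maximal violating pair:
    //   i in I_up  maximising  -y_i grad_i  = y_i - y_i*... (grad_i = y_i f_i - 1)
    //   j in I_low minimising the same quantity
    double g_max = -std::numeric_limits<double>::infinity();
    double g_min = std::numeric_limits<double>::infinity();
    int i = -1, j = -1;
    for (int t = 0; t < m; ++t) {
      const double v = y[t] - f[t]; // = -y_t * grad_t since y_t^2 = 1
      const bool in_up  = (y[t] == 1 && alpha[t] < C - tau) ||
                          (y[t] == -1 && alpha[t] > tau);
      const bool in_low = (y[t] == 1 && alpha[t] > tau) ||
                          (y[t] == -1 && alpha[t] < C - tau);
      if (in_up && v > g_max) { g_max = v; i = t; }
      if (in_low && v < g_min) { g_min = v; j = t; }
    }
    if (i < 0 || j < 0 || g_max - g_min < eps) { converged = true; break; }

    // analytic two-variable update (Platt), working on alpha_j
    const double Kii = x[i] * x[i], Kjj = x[j] * x[j], Kij = x[i] * x[j];
    double eta = Kii + Kjj - 2.0 * Kij;
    const int s = y[i] * y[j];
    double L, H;
    if (s < 0) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    // E_i - E_j is bias-free
    const double dE = (f[i] - y[i]) - (f[j] - y[j]);
    double aj_new;
    if (eta > tau) {
      aj_new = alpha[j] + y[j] * dE / eta;
      if (aj_new < L) aj_new = L;
      if (aj_new > H) aj_new = H;
    } else {
      // flat direction (identical features): the dual objective is linear
      // along the segment with slope -y_j*dE; move to the minimising bound
      aj_new = (y[j] * dE < 0) ? L : H;
    }
    const double d = aj_new - alpha[j];
    if (std::fabs(d) < tau) { converged = true; break; }
    alpha[i] -= s * d;
    alpha[j] = aj_new;
    for (int t = 0; t < m; ++t)
      f[t] += d * y[j] * x[j] * x[t] - s * d * y[i] * x[i] * x[t];
  }

  double w = 0.0;
  for (int t = 0; t < m; ++t) w += alpha[t] * y[t] * x[t];

  // bias from KKT: average y_i - w x_i over free support vectors; otherwise
  // midpoint of the feasible interval
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < m; ++t)
    if (alpha[t] > tau && alpha[t] < C - tau) { b += y[t] - w * x[t]; ++nfree; }
  if (nfree > 0) {
    b /= nfree;
  } else {
    // KKT: alpha=0 gives y(wx+b) >= 1, alpha=C gives <= 1; in terms of
    // v = y - w x this bounds b above on {y=+1,a=C} u {y=-1,a=0} and below
    // on {y=+1,a=0} u {y=-1,a=C}
    double ub = std::numeric_limits<double>::infinity();
    double lb = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < m; ++t) {
      const double v = y[t] - w * x[t];
      const bool bounds_above = (y[t] == 1 && alpha[t] >= C - tau) ||
                                (y[t] == -1 && alpha[t] <= tau);
      const bool bounds_below = (y[t] == 1 && alpha[t] <= tau) ||
                                (y[t] == -1 && alpha[t] >= C - tau);
      if (bounds_above && v < ub) ub = v;
      if (bounds_below && v > lb) lb = v;
    }
    if (std::isfinite(ub) && std::isfinite(lb)) b = (ub + lb) / 2.0;
    else if (std::isfinite(ub)) b = ub;
    else if (std::isfinite(lb)) b = lb;
  }
  SvmFit fit; fit.w = w; fit.b = b; fit.converged = converged; fit.iter = iter;
  return fit;
}

// [[Rcpp::export]]
List svm_fit_cpp(NumericVector x, IntegerVector y, double C,
                 double eps = 1e-6, int max_iter = 100000) {
  if (x.size() != y.size()) stop("x and y differ in length");
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> yv(y.begin(), y.end());
  for (size_t t = 0; t < yv.size(); ++t)
    if (yv[t] != 1 && yv[t] != -1) stop("labels must be +1/-1");
  SvmFit fit = smo_fit_1d(xv, yv, C, eps, max_iter);
  return List::create(_["w"] = fit.w, _["b"] = fit.b,
                      _["converged"] = fit.converged, _["iter"] = fit.iter);
}

// Leave-one-pair-out CV accuracy at one time point. xl, xr hold the M "left"
// and M "right" scalar features; fold i tests (xl[i], xr[i]) against the SVM
// fitted on the remaining 2M-2. Each fold scores 0/50/100; mean is returned.
// Labels: right = +1, left = -1; decision-value ties classify as "right".
// Degenerate folds (all training features identical) predict the class of
// the first training example.
// [[Rcpp::export]]
double loo_pair_accuracy_cpp(NumericVector xl, NumericVector xr, double C,
                             double eps = 1e-6, int max_iter = 100000) {
  const int M = xl.size();
  if (xr.size() != M) stop("class imbalance: need M left and M right trials");
  if (M < 2) stop("need at least two trials per class");
  const int m = 2 * M - 2;
  std::vector<double> x(m);
  std::vector<int> y(m);
  double total = 0.0;
  for (int i = 0; i < M; ++i) {
    int p = 0;
    for (int t = 0; t < M; ++t) if (t != i) { x[p] = xl[t]; y[p] = -1; ++p; }
    for (int t = 0; t < M; ++t) if (t != i) { x[p] = xr[t]; y[p] = 1; ++p; }
    double xmin = x[0], xmax = x[0];
    for (int t = 1; t < m; ++t) {
      if (x[t] < xmin) xmin = x[t];
      if (x[t] > xmax) xmax = x[t];
    }
    int correct = 0;
    if (xmax - xmin < 1e-12) {
      const int pred = y[0]; // class of the first training example
      if (pred == -1) ++correct;          // left test trial
      if (pred == 1) ++correct;           // right test trial
      // exactly one of the two is correct -> 50
    } else {
      SvmFit fit = smo_fit_1d(x, y, C, eps, max_iter);
      const int pred_l = (fit.w * xl[i] + fit.b >= 0) ? 1 : -1;
      const int pred_r = (fit.w * xr[i] + fit.b >= 0) ? 1 : -1;
      if (pred_l == -1) ++correct;
      if (pred_r == 1) ++correct;
    }
    total += 50.0 * correct;
  }
  return total / M;
}
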
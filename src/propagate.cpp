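// Discrete-step evidence propagation between two absorbing thresholds.
//
// The decision variable starts at 0 and, per subunit, gains the subunit's
// weight plus Gaussian noise (sd sigma).  Mass strictly above theta_plus or
// strictly below theta_minus is absorbed and bookkept per step; surviving
// mass lives on a bin grid spanning [theta_minus, theta_plus] with a bin
// edge pinned at 0 so the end-of-song sign rule is exact at bin level.
// The first step is taken analytically from the point mass at 0; later
// steps apply a per-subunit-type transition matrix built from normal-CDF
// differences at the bin edges (midpoint source approximation).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double norm_cdf(double z) {
  return 0.5 * std::erfc(-z * M_SQRT1_2);
}

namespace {

struct Grid {
  std::vector<double> edges;    // n + 1 edges, edges[n_neg] == 0
  std::vector<double> centers;  // n bin centers
  int n_neg, n_pos, n;
};

Grid make_grid(double th_minus, double th_plus, int n_neg, int n_pos) {
  Grid g;
  g.n_neg = n_neg;
  g.n_pos = n_pos;
  g.n = n_neg + n_pos;
  g.edges.resize(g.n + 1);
  for (int i = 0; i <= n_neg; ++i)
    g.edges[i] = th_minus * (1.0 - double(i) / n_neg);
  g.edges[n_neg] = 0.0;
  for (int j = 1; j <= n_pos; ++j)
    g.edges[n_neg + j] = th_plus * (double(j) / n_pos);
  g.centers.resize(g.n);
  for (int i = 0; i < g.n; ++i)
    g.centers[i] = 0.5 * (g.edges[i] + g.edges[i + 1]);
  return g;
}

// One-step distribution from source point x with drift w: absorbed tails and
// interior bin masses.  Exact (up to CDF accuracy) for the given source.
void step_from_point(const Grid &g, double x, double w, double sigma,
                     double th_minus, double th_plus,
                     double *interior, double &up, double &low) {
  const double mu = x + w;
  up = 1.0 - norm_cdf((th_plus - mu) / sigma);
  low = norm_cdf((th_minus - mu) / sigma);
  double prev = norm_cdf((g.edges[0] - mu) / sigma);
  for (int j = 0; j < g.n; ++j) {
    double cur = norm_cdf((g.edges[j + 1] - mu) / sigma);
    interior[j] = cur - prev;
    prev = cur;
  }
}

struct Kernel {
  std::vector<double> T;   // n x n, column-major by source bin
  std::vector<double> up;  // per source bin
  std::vector<double> low;
};

Kernel make_kernel(const Grid &g, double w, double sigma,
                   double th_minus, double th_plus) {
  Kernel k;
  k.T.assign(size_t(g.n) * g.n, 0.0);
  k.up.resize(g.n);
  k.low.resize(g.n);
  for (int i = 0; i < g.n; ++i)
    step_from_point(g, g.centers[i], w, sigma, th_minus, th_plus,
                    &k.T[size_t(i) * g.n], k.up[i], k.low[i]);
  return k;
}

// Propagate one song; fills per-step absorbed masses and mean clamped
// evidence if the pointers are non-null.
void propagate_song(const IntegerVector &seq, const std::vector<Kernel> &ker,
                    const Grid &g, double th_minus, double th_plus,
                    double sigma, const NumericVector &omega,
                    double &p_respond, double &end_respond, double &end_reject,
                    std::vector<double> *abs_up, std::vector<double> *abs_low,
                    std::vector<double> *mean_traj) {
  const int L = seq.size();
  std::vector<double> d(g.n), dn(g.n);
  double cum_up = 0.0, cum_low = 0.0;
  for (int t = 0; t < L; ++t) {
    const int lab = seq[t] - 1;
    double su = 0.0, sl = 0.0;
    if (t == 0) {
      step_from_point(g, 0.0, omega[lab], sigma, th_minus, th_plus,
                      d.data(), su, sl);
    } else {
      const Kernel &k = ker[lab];
      std::fill(dn.begin(), dn.end(), 0.0);
      for (int i = 0; i < g.n; ++i) {
        const double di = d[i];
        if (di < 1e-300) continue;
        su += k.up[i] * di;
        sl += k.low[i] * di;
        const double *col = &k.T[size_t(i) * g.n];
        for (int j = 0; j < g.n; ++j) dn[j] += col[j] * di;
      }
      d.swap(dn);
    }
    cum_up += su;
    cum_low += sl;
    if (abs_up) (*abs_up)[t] = su;
    if (abs_low) (*abs_low)[t] = sl;
    if (mean_traj) {
      double m = cum_up * th_plus + cum_low * th_minus;
      for (int j = 0; j < g.n; ++j) m += g.centers[j] * d[j];
      (*mean_traj)[t] = m;
    }
  }
  end_respond = 0.0;
  end_reject = 0.0;
  for (int j = 0; j < g.n_neg; ++j) end_reject += d[j];
  for (int j = g.n_neg; j < g.n; ++j) end_respond += d[j];
  p_respond = cum_up + end_respond;
}

} // namespace

// [[Rcpp::export(name = ".ddm_propagate_cpp")]]
List ddm_propagate_cpp(IntegerVector seq, NumericVector omega, double sigma,
                       double theta_minus, double theta_plus,
                       int n_neg, int n_pos) {
  if (sigma <= 0) stop("sigma must be > 0 for density propagation");
  if (!(theta_minus < 0 && theta_plus > 0))
    stop("thresholds must satisfy theta_minus < 0 < theta_plus");
  const int L = seq.size();
  Grid g = make_grid(theta_minus, theta_plus, n_neg, n_pos);
  const int K = omega.size();
  std::vector<bool> used(K, false);
  for (int t = 1; t < L; ++t) used[seq[t] - 1] = true;
  std::vector<Kernel> ker(K);
  for (int k = 0; k < K; ++k)
    if (used[k]) ker[k] = make_kernel(g, omega[k], sigma, theta_minus, theta_plus);
  std::vector<double> up(L), low(L), traj(L);
  double p, er, ej;
  propagate_song(seq, ker, g, theta_minus, theta_plus, sigma, omega,
                 p, er, ej, &up, &low, &traj);
  return List::create(_["p_respond"] = p,
                      _["abs_upper"] = NumericVector(up.begin(), up.end()),
                      _["abs_lower"] = NumericVector(low.begin(), low.end()),
                      _["end_respond"] = er,
                      _["end_reject"] = ej,
                      _["mean_traj"] = NumericVector(traj.begin(), traj.end()));
}

// Response probability for every song in a dataset under one parameter set.
// Kernels are built once per subunit type and shared across songs; this is
// the fitting objective's workhorse.
// [[Rcpp::export(name = ".ddm_dataset_probs_cpp")]]
NumericVector ddm_dataset_probs_cpp(List songs, NumericVector omega,
                                    double sigma, double theta_minus,
                                    double theta_plus, int n_neg, int n_pos) {
  if (sigma <= 0) stop("sigma must be > 0 for density propagation");
  if (!(theta_minus < 0 && theta_plus > 0))
    stop("thresholds must satisfy theta_minus < 0 < theta_plus");
  Grid g = make_grid(theta_minus, theta_plus, n_neg, n_pos);
  const int K = omega.size();
  const int S = songs.size();
  std::vector<bool> used(K, false);
  for (int s = 0; s < S; ++s) {
    IntegerVector seq = songs[s];
    for (int t = 1; t < seq.size(); ++t) used[seq[t] - 1] = true;
  }
  std::vector<Kernel> ker(K);
  for (int k = 0; k < K; ++k)
    if (used[k]) ker[k] = make_kernel(g, omega[k], sigma, theta_minus, theta_plus);
  NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector seq = songs[s];
    double p, er, ej;
    propagate_song(seq, ker, g, theta_minus, theta_plus, sigma, omega,
                   p, er, ej, nullptr, nullptr, nullptr);
    out[s] = p;
  }
  return out;
}
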
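#include <Rcpp.h>
using namespace Rcpp;

// Fast inner loops for trajectory replay and choice likelihoods.
// All inputs are pre-discretized: observed RTs arrive as 1-based grid bins,
// Phi and E are the basis and eligibility matrices evaluated at the bin
// centers (n_basis x n_grid). Learning state resets at run starts.

static double entropy_nats(const std::vector<double>& w) {
  double tot = 0.0;
  for (double x : w) tot += x;
  if (tot < 1e-12) return std::log((double)w.size());
  double h = 0.0;
  for (double x : w) {
    if (x > 0) {
      double p = x / tot;
      h -= p * std::log(p);
    }
  }
  return h;
}

// log softmax probability of bin `j` (0-based) for values v / beta
static double log_softmax_prob(const std::vector<double>& v, double beta,
                               int j) {
  double mx = v[0];
  for (double x : v) if (x > mx) mx = x;
  double s = 0.0;
  for (double x : v) s += std::exp((x - mx) / beta);
  return (v[j] - mx) / beta - std::log(s);
}

// variant: 1 = selective maintenance, 2 = full maintenance
// [[Rcpp::export]]
double cpp_sceptic_nll(IntegerVector bins, NumericVector rewards,
                       LogicalVector run_start, NumericMatrix Phi,
                       NumericMatrix E, double alpha, double gamma,
                       double beta, int variant) {
  const int n = bins.size(), B = Phi.nrow(), G = Phi.ncol();
  std::vector<double> w(B, 0.0), v(G);
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (run_start[i]) std::fill(w.begin(), w.end(), 0.0);
    const int j = bins[i] - 1;
    for (int g = 0; g < G; ++g) {
      double acc = 0.0;
      for (int b = 0; b < B; ++b) acc += w[b] * Phi(b, g);
      v[g] = acc;
    }
    nll -= log_softmax_prob(v, beta, j);
    const double r = rewards[i];
    for (int b = 0; b < B; ++b) {
      double e = E(b, j);
      double wn = w[b] + e * alpha * (r - w[b]);
      if (variant == 1) wn -= gamma * (1.0 - e) * w[b];
      w[b] = wn;
    }
  }
  return nll;
}

// [[Rcpp::export]]
List cpp_sceptic_traj(IntegerVector bins, NumericVector rewards,
                      LogicalVector run_start, NumericMatrix Phi,
                      NumericMatrix E, double alpha, double gamma,
                      int variant) {
  const int n = bins.size(), B = Phi.nrow(), G = Phi.ncol();
  std::vector<double> w(B, 0.0), v(G);
  NumericVector rpe(n), ent(n), vmax(n), vchosen(n);
  IntegerVector vmax_bin(n);
  NumericMatrix W(n, B);
  for (int i = 0; i < n; ++i) {
    if (run_start[i]) std::fill(w.begin(), w.end(), 0.0);
    const int j = bins[i] - 1;
    int amax = 0;
    for (int g = 0; g < G; ++g) {
      double acc = 0.0;
      for (int b = 0; b < B; ++b) acc += w[b] * Phi(b, g);
      v[g] = acc;
      if (v[g] > v[amax]) amax = g;
    }
    ent[i] = entropy_nats(w);
    vmax[i] = v[amax];
    vmax_bin[i] = amax + 1;
    vchosen[i] = v[j];
    const double r = rewards[i];
    rpe[i] = r - v[j];
    for (int b = 0; b < B; ++b) {
      double e = E(b, j);
      double wn = w[b] + e * alpha * (r - w[b]);
      if (variant == 1) wn -= gamma * (1.0 - e) * w[b];
      w[b] = wn;
      W(i, b) = wn;
    }
  }
  return List::create(_["rpe"] = rpe, _["entropy"] = ent,
                      _["v_max"] = vmax, _["v_max_bin"] = vmax_bin,
                      _["v_chosen"] = vchosen, _["weights"] = W);
}

// [[Rcpp::export]]
double cpp_kf_nll(IntegerVector bins, NumericVector rewards,
                  LogicalVector run_start, NumericMatrix Phi, NumericMatrix E,
                  double alpha, double beta, double tau, double sigma_rew) {
  const int n = bins.size(), B = Phi.nrow(), G = Phi.ncol();
  std::vector<double> mu(B, 0.0), sig(B, sigma_rew), q(G);
  const double s2rew = sigma_rew * sigma_rew;
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (run_start[i]) {
      std::fill(mu.begin(), mu.end(), 0.0);
      std::fill(sig.begin(), sig.end(), sigma_rew);
    }
    const int j = bins[i] - 1;
    for (int g = 0; g < G; ++g) {
      double av = 0.0, au = 0.0;
      for (int b = 0; b < B; ++b) {
        av += mu[b] * Phi(b, g);
        au += sig[b] * Phi(b, g);
      }
      q[g] = av + tau * au;
    }
    nll -= log_softmax_prob(q, beta, j);
    const double r = rewards[i];
    for (int b = 0; b < B; ++b) {
      double e = E(b, j);
      double k = sig[b] * sig[b] / (sig[b] * sig[b] + s2rew);
      mu[b] += e * alpha * (r - mu[b]);
      sig[b] *= (1.0 - e * k);
    }
  }
  return nll;
}

// [[Rcpp::export]]
List cpp_kf_traj(IntegerVector bins, NumericVector rewards,
                 LogicalVector run_start, NumericMatrix Phi, NumericMatrix E,
                 double alpha, double tau, double sigma_rew) {
  const int n = bins.size(), B = Phi.nrow(), G = Phi.ncol();
  std::vector<double> mu(B, 0.0), sig(B, sigma_rew), v(G), u(G);
  const double s2rew = sigma_rew * sigma_rew;
  NumericVector rpe(n), ent(n), vmax(n), vchosen(n), uchosen(n), upct(n);
  IntegerVector vmax_bin(n);
  for (int i = 0; i < n; ++i) {
    if (run_start[i]) {
      std::fill(mu.begin(), mu.end(), 0.0);
      std::fill(sig.begin(), sig.end(), sigma_rew);
    }
    const int j = bins[i] - 1;
    int amax = 0;
    for (int g = 0; g < G; ++g) {
      double av = 0.0, au = 0.0;
      for (int b = 0; b < B; ++b) {
        av += mu[b] * Phi(b, g);
        au += sig[b] * Phi(b, g);
      }
      v[g] = av;
      u[g] = au;
      if (v[g] > v[amax]) amax = g;
    }
    ent[i] = entropy_nats(mu);
    vmax[i] = v[amax];
    vmax_bin[i] = amax + 1;
    vchosen[i] = v[j];
    uchosen[i] = u[j];
    // midrank percentile of u[j] within u, scaled 0-100; near-equal values
    // (within 1e-3 of the trial maximum) count as ties so that the basis
    // envelope's tiny interior ripple does not break them arbitrarily
    double umax = 0.0;
    for (int g = 0; g < G; ++g) if (std::fabs(u[g]) > umax) umax = std::fabs(u[g]);
    const double tol = 1e-3 * umax;
    double below = 0.0, equal = 0.0;
    for (int g = 0; g < G; ++g) {
      if (u[g] < u[j] - tol) below += 1.0;
      else if (std::fabs(u[g] - u[j]) <= tol) equal += 1.0;
    }
    double rank = below + (equal + 1.0) / 2.0;
    upct[i] = 100.0 * (rank - 0.5) / G;
    const double r = rewards[i];
    rpe[i] = r - v[j];
    for (int b = 0; b < B; ++b) {
      double e = E(b, j);
      double k = sig[b] * sig[b] / (sig[b] * sig[b] + s2rew);
      mu[b] += e * alpha * (r - mu[b]);
      sig[b] *= (1.0 - e * k);
    }
  }
  return List::create(_["rpe"] = rpe, _["entropy"] = ent,
                      _["v_max"] = vmax, _["v_max_bin"] = vmax_bin,
                      _["v_chosen"] = vchosen, _["u_chosen"] = uchosen,
                      _["u_percentile"] = upct);
}
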
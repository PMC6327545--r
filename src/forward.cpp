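#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a homogeneous Bernoulli-emission HMM.
// Returns log( delta P(x1) Gamma P(x2) ... Gamma P(xn) 1 ), rescaling the
// forward vector at every step so intermediate products cannot underflow.
// [[Rcpp::export(name = ".forward_homog_cpp")]]
double forward_homog_cpp(IntegerVector obs, NumericVector delta,
                         NumericMatrix Gamma, NumericVector pis) {
  const int n = obs.size(), N = pis.size();
  std::vector<double> phi(N), v(N);
  double s = 0.0, ll = 0.0;
  for (int i = 0; i < N; ++i) {
    const double p = obs[0] == 1 ? pis[i] : 1.0 - pis[i];
    phi[i] = delta[i] * p;
    s += phi[i];
  }
  if (s <= 0.0) return R_NegInf;
  ll = std::log(s);
  for (int i = 0; i < N; ++i) phi[i] /= s;
  for (int t = 1; t < n; ++t) {
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += phi[i] * Gamma(i, j);
      const double p = obs[t] == 1 ? pis[j] : 1.0 - pis[j];
      v[j] = a * p;
      s += v[j];
    }
    if (s <= 0.0) return R_NegInf;
    ll += std::log(s);
    for (int j = 0; j < N; ++j) phi[j] = v[j] / s;
  }
  return ll;
}

// Scaled forward recursion for a two-state chain with time-varying
// transition probabilities: g12[t-2] and g21[t-2] drive the transition
// into position t (t = 2..n).
// [[Rcpp::export(name = ".forward_inhom2_cpp")]]
double forward_inhom2_cpp(IntegerVector obs, NumericVector delta,
                          NumericVector g12, NumericVector g21,
                          NumericVector pis) {
  const int n = obs.size();
  double p1 = obs[0] == 1 ? pis[0] : 1.0 - pis[0];
  double p2 = obs[0] == 1 ? pis[1] : 1.0 - pis[1];
  double phi1 = delta[0] * p1, phi2 = delta[1] * p2;
  double s = phi1 + phi2;
  if (s <= 0.0) return R_NegInf;
  double ll = std::log(s);
  phi1 /= s; phi2 /= s;
  for (int t = 1; t < n; ++t) {
    const double a = g12[t - 1], b = g21[t - 1];
    p1 = obs[t] == 1 ? pis[0] : 1.0 - pis[0];
    p2 = obs[t] == 1 ? pis[1] : 1.0 - pis[1];
    const double v1 = (phi1 * (1.0 - a) + phi2 * b) * p1;
    const double v2 = (phi1 * a + phi2 * (1.0 - b)) * p2;
    s = v1 + v2;
    if (s <= 0.0) return R_NegInf;
    ll += std::log(s);
    phi1 = v1 / s; phi2 = v2 / s;
  }
  return ll;
}
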
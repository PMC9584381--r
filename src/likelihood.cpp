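#include <Rcpp.h>
using namespace Rcpp;

// Stable log p(collect) and log p(refrain) for a two-action softmax with
// weight difference d = w_collect - w_refrain.
static inline double log_p_collect(double d) {
  return (d > 0) ? -log1p(std::exp(-d)) : d - log1p(std::exp(d));
}
static inline double log_p_refrain(double d) {
  return (d > 0) ? -d - log1p(std::exp(-d)) : -log1p(std::exp(d));
}

// Replay an instrumental trial sequence under the canonical parameterization
// par = (eps_rew, eps_pun, rho_rew, rho_pun, b). Encodings: stim 0 = good,
// 1 = bad; action 1 = collect, 0 = refrain; feedback +1 / -1.
// Returns the summed choice log-likelihood and the final value table.
// [[Rcpp::export]]
List instr_replay_cpp(NumericVector par, IntegerVector stim,
                      IntegerVector action, IntegerVector feedback) {
  const double eps_rew = par[0], eps_pun = par[1];
  const double rho_rew = par[2], rho_pun = par[3], b = par[4];
  double Q[2][2] = {{0.0, 0.0}, {0.0, 0.0}};  // [stim][action]
  double ll = 0.0;
  const int n = stim.size();
  for (int t = 0; t < n; ++t) {
    const int s = stim[t];
    const double d = (Q[s][1] + b) - Q[s][0];
    ll += (action[t] == 1) ? log_p_collect(d) : log_p_refrain(d);
    const int a = action[t];
    const double r = static_cast<double>(feedback[t]);
    const double eps = (r > 0) ? eps_rew : eps_pun;
    const double rho = (r > 0) ? rho_rew : rho_pun;
    Q[s][a] += eps * (rho * r - Q[s][a]);
  }
  NumericMatrix Qout(2, 2);  // rows good/bad, cols collect/refrain
  Qout(0, 0) = Q[0][1]; Qout(0, 1) = Q[0][0];
  Qout(1, 0) = Q[1][1]; Qout(1, 1) = Q[1][0];
  return List::create(_["loglik"] = ll, _["Q"] = Qout);
}

// Transfer-stage (extinction) choice log-likelihood. Carryover Q is a
// 2 x 2 matrix (rows good/bad, cols collect/refrain); bias is the frozen
// collect bias. f = (f_plus, f_zero, f_minus); eta = (eta_good, eta_bad);
// cue encoding 0 = CS+, 1 = CS0, 2 = CS-. No feedback updates; the value
// table decays by alpha after every trial (alpha = 1: lossless transfer).
// [[Rcpp::export]]
double pit_loglik_cpp(NumericVector f, double alpha, NumericVector eta,
                      NumericMatrix Qmat, double bias, IntegerVector stim,
                      IntegerVector cue, IntegerVector action) {
  double Q[2][2] = {{Qmat(0, 0), Qmat(0, 1)}, {Qmat(1, 0), Qmat(1, 1)}};
  double ll = 0.0;
  const int n = stim.size();
  for (int t = 0; t < n; ++t) {
    const int s = stim[t];
    const double wc = Q[s][0] + bias + f[cue[t]] + eta[s];
    const double wr = Q[s][1];
    const double d = wc - wr;
    ll += (action[t] == 1) ? log_p_collect(d) : log_p_refrain(d);
    Q[0][0] *= alpha; Q[0][1] *= alpha;
    Q[1][0] *= alpha; Q[1][1] *= alpha;
  }
  return ll;
}
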
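// Compiled kernels: matrix exponential, run-compressed forward filter for
// aggregated event sequences, and exact CTMC (Gillespie) simulation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Scaling-and-squaring Pade matrix exponential (Armadillo's expmat).
// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& M) {
  return arma::expmat(M);
}

// Lazily extend the cache of scaled binary powers of B:
// pows[j] ~ B^(2^j) up to a factor exp(logs[j]) taken out to avoid
// over/underflow during repeated squaring.
static void ensure_power(std::vector<arma::mat>& pows,
                         std::vector<double>& logs, int j) {
  while ((int)pows.size() <= j) {
    arma::mat S = pows.back() * pows.back();
    double lg = 2.0 * logs.back();
    double mx = S.max();
    if (mx > 0.0) {
      S /= mx;
      lg += std::log(mx);
    }
    pows.push_back(S);
    logs.push_back(lg);
  }
}

// Log-likelihood of a run-length-encoded event sequence under transition
// matrix A (one sampling interval) with 0/1 diagonal class projections.
//
// A          : n x n row-stochastic matrix exp(Q tau)
// run_class  : 0-based class index per run
// run_len    : samples per run (>= 1)
// class_states: list, per class, of 0-based state indices of that class
// p0         : initial distribution over all n states (restricted to the
//              first run's class and renormalized here: the likelihood is
//              conditional on the first event)
//
// A run of m identical classes contributes (A theta_c)^m, evaluated by
// binary exponentiation with cached scaled squarings; the filter vector is
// renormalized after every run and the log scale accumulated.
// [[Rcpp::export]]
double cpp_loglik_runs(const arma::mat& A, const IntegerVector& run_class,
                       const IntegerVector& run_len,
                       const List& class_states, const arma::rowvec& p0) {
  const int n = A.n_rows;
  const int R = run_class.size();
  const int K = class_states.size();
  const double neg_inf = -std::numeric_limits<double>::infinity();

  std::vector<arma::uvec> idx(K);
  std::vector<arma::mat> B(K);
  std::vector<std::vector<arma::mat>> pows(K);
  std::vector<std::vector<double>> plogs(K);
  for (int c = 0; c < K; ++c) {
    idx[c] = as<arma::uvec>(class_states[c]);
    arma::mat Bc(n, n, arma::fill::zeros);
    if (idx[c].n_elem > 0) Bc.cols(idx[c]) = A.cols(idx[c]);
    B[c] = Bc;
    pows[c].push_back(Bc);
    plogs[c].push_back(0.0);
  }

  // restrict p0 to the first event's class
  arma::rowvec v(n, arma::fill::zeros);
  int c0 = run_class[0];
  if (idx[c0].n_elem == 0) return neg_inf;
  v.cols(idx[c0]) = p0.cols(idx[c0]);
  double s0 = arma::accu(v);
  if (!(s0 > 0.0)) return neg_inf;
  v /= s0;  // conditioning on the first event: no log contribution

  double ll = 0.0;
  for (int r = 0; r < R; ++r) {
    int c = run_class[r];
    long m = run_len[r];
    if (r == 0) m -= 1;  // first sample of the sequence already consumed
    if (m > 0) {
      // v <- v * B_c^m via binary expansion of m
      for (int j = 0; m > 0; ++j, m >>= 1) {
        if (m & 1L) {
          ensure_power(pows[c], plogs[c], j);
          v = v * pows[c][j];
          ll += plogs[c][j];
        }
      }
      double s = arma::accu(v);
      if (!(s > 0.0) || !std::isfinite(s)) return neg_inf;
      ll += std::log(s);
      v /= s;
    }
  }
  return ll;
}

// Exact CTMC simulation. Q in ms^-1, init 0-based. Stops at `duration` ms
// or after `max_events` sojourns, whichever comes first (pass a huge
// duration to simulate a fixed number of events). Uses R's RNG so results
// are reproducible via set.seed(). An absorbing state ends the path there,
// holding until `duration`.
// [[Rcpp::export]]
List cpp_gillespie(const arma::mat& Q, double duration, int init,
                   long max_events) {
  const int n = Q.n_rows;
  std::vector<int> state;
  std::vector<double> t_in, t_out;
  int cur = init;
  double t = 0.0;
  long ev = 0;
  bool truncated = false;
  while (t < duration && ev < max_events) {
    double r = -Q(cur, cur);
    double hold;
    if (r <= 0.0) {          // absorbing: dwell out the remaining duration
      hold = duration - t;
      state.push_back(cur + 1);
      t_in.push_back(t);
      t_out.push_back(duration);
      t = duration;
      ++ev;
      break;
    }
    hold = R::rexp(1.0 / r);
    double t_end = t + hold;
    if (t_end >= duration) {
      t_end = duration;
      truncated = true;
    }
    state.push_back(cur + 1);
    t_in.push_back(t);
    t_out.push_back(t_end);
    ++ev;
    if (t_end >= duration) { t = duration; break; }
    // choose the next state with probability q_ij / r
    double u = R::unif_rand() * r;
    double acc = 0.0;
    int nxt = -1;
    for (int j = 0; j < n; ++j) {
      if (j == cur) continue;
      acc += Q(cur, j);
      if (u <= acc) { nxt = j; break; }
    }
    if (nxt < 0) {  // numerical guard
      for (int j = n - 1; j >= 0; --j) {
        if (j != cur && Q(cur, j) > 0) { nxt = j; break; }
      }
    }
    cur = nxt;
    t = t_end;
  }
  return List::create(_["state"] = wrap(state),
                      _["t_entry"] = wrap(t_in),
                      _["t_exit"] = wrap(t_out),
                      _["truncated"] = truncated);
}
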
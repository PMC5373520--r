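// Euler integration core for the leaky-integrator circuit.
//
// The network is synchronous: the input I(t) of every unit is assembled from
// the activations of the PREVIOUS step, all potentials are advanced together,
// and activations are recomputed from the new potentials.  Noise is one fresh
// Gaussian draw per unit per step taken from R's RNG stream (so that R-side
// set.seed() makes whole simulations reproducible and a pure-R reference
// implementation can consume the identical stream).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double rate_activation(double u, double thr) {
  // tanh remapped to [-400, 400] on both axes (unity gain at rest), then
  // thresholded and rectified.
  double a = 400.0 * std::tanh(u / 400.0) - thr;
  return a > 0.0 ? a : 0.0;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(const arma::mat& W,
              const arma::vec& u0,
              const arma::vec& tau,
              const arma::vec& r,
              const arma::vec& thr,
              const arma::vec& noise_mean,
              const arma::vec& noise_sd,
              const arma::uvec& d1_idx,   // 0-based StrD1 unit indices
              const arma::uvec& d2_idx,   // 0-based StrD2 unit indices
              const int da_idx,           // 0-based DA unit index
              const double b_d1, const double d_d1,
              const double b_d2, const double d_d2,
              const double da_min, const double da_max,
              const double dt,
              const int n_steps,
              const NumericMatrix& pulses,        // cols: unit0, height, sd, center_s
              const IntegerMatrix& windows,       // cols: start_step0, length
              const bool record_da = true) {
  const arma::uword n = W.n_rows;
  if (u0.n_elem != n || tau.n_elem != n || r.n_elem != n || thr.n_elem != n)
    stop("parameter vectors and weight matrix disagree on the number of units");

  arma::vec u = u0;
  arma::vec a(n), I(n), noise(n);

  // initial activations (DA potential clamped, identity activation)
  u(da_idx) = std::min(std::max(u(da_idx), da_min), da_max);
  for (arma::uword i = 0; i < n; ++i) a(i) = rate_activation(u(i), thr(i));
  a(da_idx) = u(da_idx);

  const int n_win = windows.nrow();
  std::vector<arma::mat> recs(n_win);
  for (int w = 0; w < n_win; ++w) {
    recs[w] = arma::mat(windows(w, 1), n, arma::fill::zeros);
  }

  NumericVector u_da_trace(record_da ? n_steps : 0);

  const int n_pulse = pulses.nrow();

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    // input assembled from previous-step activations
    I = r + W * a;

    for (arma::uword i = 0; i < n; ++i) {
      // draw for every unit (even sd = 0) to keep the stream layout fixed
      noise(i) = noise_mean(i) + noise_sd(i) * norm_rand();
    }
    I += noise;

    for (int p = 0; p < n_pulse; ++p) {
      const double c = pulses(p, 3), sd = pulses(p, 2);
      if (std::abs(t - c) < 6.0 * sd) {
        const double z = (t - c) / sd;
        I((arma::uword) pulses(p, 0)) += pulses(p, 1) * std::exp(-0.5 * z * z);
      }
    }

    // dopaminergic modulation of the striatum multiplies the whole input
    const double a_da = a(da_idx);
    const double f1 = b_d1 + d_d1 * a_da;
    const double den = b_d2 + d_d2 * a_da;
    if (den <= 0.0) stop("non-positive StrD2 dopamine denominator");
    const double f2 = f1 / den;
    for (arma::uword k = 0; k < d1_idx.n_elem; ++k) I(d1_idx(k)) *= f1;
    for (arma::uword k = 0; k < d2_idx.n_elem; ++k) I(d2_idx(k)) *= f2;

    // synchronous Euler update; the DA potential is hard-clamped
    u += (dt / tau) % (-u + I);
    u(da_idx) = std::min(std::max(u(da_idx), da_min), da_max);

    for (arma::uword i = 0; i < n; ++i) a(i) = rate_activation(u(i), thr(i));
    a(da_idx) = u(da_idx);

    if (!u.is_finite())
      stop("non-finite activation potential at step %d", s);

    if (record_da) u_da_trace[s] = u(da_idx);

    for (int w = 0; w < n_win; ++w) {
      const int off = s - windows(w, 0);
      if (off >= 0 && off < windows(w, 1)) {
        recs[w].row(off) = a.t();
      }
    }
  }

  List rec(n_win);
  for (int w = 0; w < n_win; ++w) rec[w] = wrap(recs[w]);

  return List::create(_["windows"] = rec,
                      _["u_da"] = u_da_trace,
                      _["u_final"] = u,
                      _["a_final"] = a);
}
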
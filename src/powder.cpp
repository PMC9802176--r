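// Field-swept powder averaging kernel.
//
// For every orientation node (theta, phi) of the field direction and every
// field value B, the projected Hamiltonian H0 + g muB B * (u . S) is
// diagonalized and golden-rule transition intensities are accumulated with
// a normalized Gaussian lineshape in |E_k - E_n| - h nu.  The microwave
// field average over the plane perpendicular to B0 is done analytically as
// the mean of two orthogonal polarizations.  All energies in cm^-1, fields
// in Gauss.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export]]
arma::vec powder_sweep_cpp(const arma::cx_mat& H0,
                           const arma::cx_mat& Sx,
                           const arma::cx_mat& Sy,
                           const arma::cx_mat& Sz,
                           const arma::vec& theta,
                           const arma::vec& phi,
                           const arma::vec& weight,
                           const arma::vec& fields,
                           const double zeeman_per_G,
                           const double quantum_cm,
                           const double delta,
                           const double temperature_K) {
  const uword nb = fields.n_elem;
  const uword nnode = theta.n_elem;
  const double norm = 1.0 / std::sqrt(2.0 * M_PI * delta * delta);
  const double kb = 0.69503480; // cm^-1 / K
  vec out(nb, fill::zeros);

  vec vals;
  cx_mat vecs, Hb, A1, A2;

  for (uword i = 0; i < nnode; ++i) {
    const double st = std::sin(theta(i)), ct = std::cos(theta(i));
    const double sp = std::sin(phi(i)),   cp = std::cos(phi(i));
    // field direction u and two perpendicular unit vectors
    const cx_mat Su  = st * cp * Sx + st * sp * Sy + ct * Sz;
    const cx_mat Sv1 = ct * cp * Sx + ct * sp * Sy - st * Sz;
    const cx_mat Sv2 = -sp * Sx + cp * Sy;
    const double w = weight(i);

    for (uword b = 0; b < nb; ++b) {
      Hb = H0 + (zeeman_per_G * fields(b)) * Su;
      if (!eig_sym(vals, vecs, Hb)) Rcpp::stop("eigensolver failed");
      A1 = vecs.t() * Sv1 * vecs;
      A2 = vecs.t() * Sv2 * vecs;

      vec pop;
      if (temperature_K > 0) {
        pop = exp(-(vals - vals.min()) / (kb * temperature_K));
        pop /= accu(pop);
      }

      double acc = 0.0;
      const uword n = vals.n_elem;
      for (uword a = 0; a < n - 1; ++a) {
        for (uword k = a + 1; k < n; ++k) {
          const double x = std::fabs(vals(k) - vals(a)) - quantum_cm;
          if (std::fabs(x) > 8.0 * delta) continue;
          const double rho = norm * std::exp(-x * x / (2.0 * delta * delta));
          const double amp = 0.5 * (std::norm(A1(k, a)) + std::norm(A2(k, a)));
          double pw = 1.0;
          if (temperature_K > 0) pw = pop(a) - pop(k);
          acc += rho * amp * pw;
        }
      }
      out(b) += w * acc;
    }
  }
  return out;
}
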
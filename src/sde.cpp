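// Compiled numerical core: Euler-Maruyama integration of the linearized
// stochastic system, cross-spectral density via the resolvent formula
// evaluated through a complex Schur decomposition, and a Bartels-Stewart
// solver for the Lyapunov equation.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Euler-Maruyama simulation of dx = J x dt + L dW (deviations from the
// fixed point). Returns recorded channels A x at every `record_every`-th
// step and the running second-moment matrix of the states listed in
// `cov_idx` (1-based), accumulated every `cov_thin`-th step after `burn`
// steps.
// [[Rcpp::export]]
Rcpp::List em_simulate_cpp(const arma::sp_mat& J, const arma::sp_mat& L,
                           const arma::vec& x0, double dt, int n_steps,
                           const arma::mat& A, int record_every,
                           const arma::uvec& cov_idx, int cov_thin,
                           int burn) {
  const uword N = J.n_rows;
  const uword n_noise = L.n_cols;
  const uword m = A.n_rows;
  Rcpp::RNGScope scope;  // noise drawn from R's RNG: seed with set.seed()

  vec x = x0;
  const double sq_dt = std::sqrt(dt);
  const uword n_rec = (record_every > 0) ? (n_steps / record_every) : 0;
  mat rec(m, n_rec, fill::zeros);

  const uword nc = cov_idx.n_elem;
  mat cov(nc, nc, fill::zeros);
  vec mu(nc, fill::zeros);
  uvec ci = cov_idx - 1;
  unsigned long n_cov = 0;

  uword r = 0;
  for (int t = 1; t <= n_steps; ++t) {
    vec dw = randn<vec>(n_noise) * sq_dt;
    x += dt * (J * x) + L * dw;
    if (!x.is_finite()) {
      Rcpp::stop("state diverged (non-finite) at t = %f ms", t * dt);
    }
    if (record_every > 0 && t % record_every == 0 && r < n_rec) {
      rec.col(r++) = A * x;
    }
    if (t > burn && (t - burn) % cov_thin == 0) {
      vec xs = x.elem(ci);
      cov += xs * xs.t();
      mu += xs;
      ++n_cov;
    }
  }
  if (n_cov > 0) {
    cov /= static_cast<double>(n_cov);
    mu /= static_cast<double>(n_cov);
  }
  return Rcpp::List::create(
    Rcpp::Named("recorded") = rec,
    Rcpp::Named("moment2") = cov,
    Rcpp::Named("mean") = mu,
    Rcpp::Named("n_cov") = static_cast<double>(n_cov),
    Rcpp::Named("final_state") = x);
}

// Cross-spectral density of the selected channels A x for the linear system
// dx = J x dt + forcing, where the forcing has the diagonal spectral density
// q0 + q1 / (1 + (omega tau_n)^2) (white plus low-pass filtered channels,
// already scaled by the membrane time constants). omegas are angular
// frequencies in rad/ms. Returns an m x m x nfreq complex array,
// S(omega) = A (i omega I + J)^-1 Q(omega) (-i omega I + J)^-T A^T.
// [[Rcpp::export]]
arma::cx_cube psd_resolvent_cpp(const arma::mat& J, const arma::mat& A,
                                const arma::vec& q0, const arma::vec& q1,
                                const arma::vec& omegas, double tau_n) {
  const uword N = J.n_rows;
  const uword m = A.n_rows;
  cx_mat U, T;
  // complex Schur of -J: i w I + J = i w I - (-J); work with J directly:
  schur(U, T, cx_mat(J, mat(N, N, fill::zeros)));
  // J = U T U^H  =>  (i w I + J)^-1 = U (i w I + T)^-1 U^H
  cx_mat AU = cx_mat(A, mat(m, N, fill::zeros)) * U;   // m x N
  cx_mat AUh = AU.t();                                  // N x m (conj.)
  cx_cube S(m, m, omegas.n_elem);
  for (uword k = 0; k < omegas.n_elem; ++k) {
    const double w = omegas(k);
    cx_mat M = T;
    M.diag() += cx_double(0.0, w);
    // rows of A R: (A R)^H = (i w I + J)^-H A^H = U (i w I + T)^-H U^H A^H
    cx_mat X = solve(trimatl(M.t()), AUh);   // N x m
    cx_mat AR = X.t() * U.t();               // m x N  ( = A (iwI+J)^-1 )
    vec q = q0 + q1 / (1.0 + (w * tau_n) * (w * tau_n));
    cx_mat ARq = AR;
    ARq.each_row() %= conv_to<cx_rowvec>::from(q.t());
    S.slice(k) = ARq * AR.t();
  }
  return S;
}

// Solve J C + C J^T = -Q for the stationary covariance C (J stable, Q
// symmetric PSD) by Bartels-Stewart on the complex Schur form.
// [[Rcpp::export]]
arma::mat lyap_solve_cpp(const arma::mat& J, const arma::mat& Q) {
  const uword N = J.n_rows;
  cx_mat U, T;
  schur(U, T, cx_mat(J, mat(N, N, fill::zeros)));
  cx_mat Qt = U.t() * cx_mat(Q, mat(N, N, fill::zeros)) * U;
  // Solve T Y + Y T^H = -Qt column by column. T^H is lower triangular, so
  // column j of (Y T^H) involves columns k >= j of Y: iterate backwards.
  cx_mat Y(N, N, fill::zeros);
  for (uword jj = N; jj > 0; --jj) {
    const uword j = jj - 1;
    cx_vec rhs = -Qt.col(j);
    if (j + 1 < N) {
      rhs -= Y.cols(j + 1, N - 1) * conj(T.submat(j, j + 1, j, N - 1)).st();
    }
    cx_mat M = T;
    M.diag() += std::conj(T(j, j));
    Y.col(j) = solve(trimatu(M), rhs);
  }
  mat C = real(U * Y * U.t());
  return 0.5 * (C + C.t());
}
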
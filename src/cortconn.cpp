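// Core numerics for sliding-window MVAR connectivity.
//
// The Vieira-Morf lattice is order-recursive, so a single pass to pmax
// yields coefficient matrices and residual covariances for every order
// 1..pmax; the order-selection stage relies on that.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Ensemble Vieira-Morf lattice estimation of a VAR(p) model.
//
// X: cube [M x w x N] (channels x samples x trials), assumed zero-mean.
// Returns, for each order m = 1..pmax, the coefficient cube A (M x M x m)
// in the convention x_t = sum_k A_k x_{t-k} + e_t, and the forward
// residual covariance Sigma.
// [[Rcpp::export]]
Rcpp::List cpp_vm_lattice(const arma::cube& X, int pmax) {
  const uword M = X.n_rows, w = X.n_cols, N = X.n_slices;
  if (pmax < 1) Rcpp::stop("model order must be >= 1");
  if ((uword)pmax >= w) Rcpp::stop("model order must be smaller than the window length");

  cube ef = X, eb = X;
  mat Pf(M, M, fill::zeros);
  for (uword n = 0; n < N; ++n) Pf += X.slice(n) * X.slice(n).t();
  Pf /= double(w * N);
  mat Pb = Pf;

  std::vector<mat> Af, Bb;            // forward/backward predictor matrices
  Rcpp::List A_out(pmax), Sig_out(pmax);
  const mat I = eye<mat>(M, M);

  for (int m = 1; m <= pmax; ++m) {
    mat D(M, M, fill::zeros);
    for (uword n = 0; n < N; ++n)
      D += ef.slice(n).cols(m, w - 1) * eb.slice(n).cols(m - 1, w - 2).t();
    D /= double(N * (w - m));

    mat Sf, Sb;
    if (!chol(Sf, Pf, "lower") || !chol(Sb, Pb, "lower"))
      Rcpp::stop("singular prediction-error covariance at order %d", m);
    mat Sfi = inv(trimatl(Sf)), Sbi = inv(trimatl(Sb));
    mat rho = Sfi * D * Sbi.t();      // normalized partial cross-correlation
    mat Kf = -Sf * rho * Sbi;
    mat Kb = -Sb * rho.t() * Sfi;

    std::vector<mat> Afn(m), Bbn(m);
    for (int k = 1; k <= m - 1; ++k) {
      Afn[k - 1] = Af[k - 1] + Kf * Bb[m - k - 1];
      Bbn[k - 1] = Bb[k - 1] + Kb * Af[m - k - 1];
    }
    Afn[m - 1] = Kf;
    Bbn[m - 1] = Kb;
    Af = Afn; Bb = Bbn;

    for (uword n = 0; n < N; ++n) {
      mat efo = ef.slice(n).cols(m, w - 1);
      mat ebo = eb.slice(n).cols(m - 1, w - 2);
      ef.slice(n).cols(m, w - 1) = efo + Kf * ebo;
      eb.slice(n).cols(m, w - 1) = ebo + Kb * efo;
    }

    Pf = Sf * (I - rho * rho.t()) * Sf.t();
    Pb = Sb * (I - rho.t() * rho) * Sb.t();
    Pf = (Pf + Pf.t()) / 2.0;
    Pb = (Pb + Pb.t()) / 2.0;

    cube A(M, M, m);
    for (int k = 0; k < m; ++k) A.slice(k) = -Af[k];
    A_out[m - 1] = A;
    Sig_out[m - 1] = Pf;
  }
  return Rcpp::List::create(Rcpp::Named("A") = A_out,
                            Rcpp::Named("Sigma") = Sig_out);
}

// Transfer matrix, cross-spectrum, partial coherence and SdDTF for one
// fitted VAR model on a fixed frequency grid (freqs in Hz).
//
// squared = true uses |H|^2 |P|^2 in the numerator (values sum to one over
// all pairs and frequencies); squared = false uses |H||P| with the same
// denominator.
// [[Rcpp::export]]
Rcpp::List cpp_sddtf_model(const arma::cube& A, const arma::mat& Sigma,
                           const arma::vec& freqs, double fs, bool squared,
                           bool want_spectra) {
  const uword M = A.n_rows, p = A.n_slices, F = freqs.n_elem;
  const cx_mat I = eye<cx_mat>(M, M);

  cx_cube H(M, M, F), S(M, M, F), P(M, M, F);
  cube num(M, M, F);
  double den = 0.0;

  for (uword fi = 0; fi < F; ++fi) {
    cx_mat Abar = I;
    for (uword k = 0; k < p; ++k) {
      std::complex<double> ph = std::exp(std::complex<double>(0.0,
        -2.0 * datum::pi * freqs(fi) * double(k + 1) / fs));
      Abar -= cx_mat(A.slice(k), mat(M, M, fill::zeros)) * ph;
    }
    cx_mat Hf;
    if (!inv(Hf, Abar))
      Rcpp::stop("transfer matrix singular at %.3f Hz", freqs(fi));
    cx_mat Sf = Hf * cx_mat(Sigma, mat(M, M, fill::zeros)) * Hf.t() / fs;
    cx_mat G;
    if (!inv(G, Sf)) {
      // ridge-stabilized inverse of a numerically singular spectrum
      double jit = 1e-10 * real(trace(Sf)) / double(M);
      inv(G, Sf + jit * eye<cx_mat>(M, M));
    }
    cx_mat Pf(M, M);
    for (uword i = 0; i < M; ++i)
      for (uword j = 0; j < M; ++j)
        Pf(i, j) = G(i, j) / std::sqrt(std::abs(G(i, i)) * std::abs(G(j, j)));

    H.slice(fi) = Hf; S.slice(fi) = Sf; P.slice(fi) = Pf;
    for (uword i = 0; i < M; ++i)
      for (uword j = 0; j < M; ++j) {
        double hp2 = std::norm(Hf(i, j)) * std::norm(Pf(i, j));
        den += hp2;
        num(i, j, fi) = squared ? hp2 : std::abs(Hf(i, j)) * std::abs(Pf(i, j));
      }
  }
  if (den <= 0.0) Rcpp::stop("degenerate model: SdDTF normalization sum is zero");
  num /= den;

  if (want_spectra)
    return Rcpp::List::create(Rcpp::Named("eta2") = num,
                              Rcpp::Named("H") = H,
                              Rcpp::Named("S") = S,
                              Rcpp::Named("P") = P);
  return Rcpp::List::create(Rcpp::Named("eta2") = num);
}

// Sliding-window driver: fit VAR(p) per window and evaluate SdDTF.
// X: cube [M x T x N]; starts: 0-based window start samples.
// Returns eta2 [M x M x F x W] (flat vector with dim attribute) plus the
// per-window log stability index.
// [[Rcpp::export]]
Rcpp::List cpp_window_sddtf(const arma::cube& X, const arma::ivec& starts,
                            int w, int p, const arma::vec& freqs, double fs,
                            bool squared) {
  const uword M = X.n_rows, N = X.n_slices, W = starts.n_elem,
              F = freqs.n_elem;
  Rcpp::NumericVector eta(M * M * F * W);
  vec stab(W);

  for (uword wi = 0; wi < W; ++wi) {
    uword a = starts(wi), b = a + w - 1;
    if (b >= X.n_cols) Rcpp::stop("window exceeds epoch length");
    cube Xw(M, w, N);
    for (uword n = 0; n < N; ++n) Xw.slice(n) = X.slice(n).cols(a, b);
    Rcpp::List fit = cpp_vm_lattice(Xw, p);
    cube A = Rcpp::as<cube>(Rcpp::as<Rcpp::List>(fit["A"])[p - 1]);
    mat Sigma = Rcpp::as<mat>(Rcpp::as<Rcpp::List>(fit["Sigma"])[p - 1]);

    // companion spectral radius
    mat C(M * p, M * p, fill::zeros);
    for (int k = 0; k < p; ++k) C.submat(0, k * M, M - 1, (k + 1) * M - 1) = A.slice(k);
    if (p > 1) C.submat(M, 0, M * p - 1, M * (p - 1) - 1) = eye<mat>(M * (p - 1), M * (p - 1));
    cx_vec ev = eig_gen(C);
    stab(wi) = std::log(max(abs(ev)));

    Rcpp::List sd = cpp_sddtf_model(A, Sigma, freqs, fs, squared, false);
    cube e2 = Rcpp::as<cube>(sd["eta2"]);
    std::copy(e2.begin(), e2.end(), eta.begin() + wi * M * M * F);
  }
  eta.attr("dim") = Rcpp::IntegerVector::create(M, M, F, W);
  return Rcpp::List::create(Rcpp::Named("eta2") = eta,
                            Rcpp::Named("stability") = stab);
}

// Residuals of a fitted VAR: e_t = x_t - sum_k A_k x_{t-k}, t = p..w-1.
// [[Rcpp::export]]
arma::cube cpp_var_residuals(const arma::cube& X, const arma::cube& A) {
  const uword M = X.n_rows, w = X.n_cols, N = X.n_slices, p = A.n_slices;
  if (w <= p) Rcpp::stop("too few samples for residual computation");
  cube E(M, w - p, N);
  for (uword n = 0; n < N; ++n) {
    mat pred(M, w - p, fill::zeros);
    for (uword k = 0; k < p; ++k)
      pred += A.slice(k) * X.slice(n).cols(p - k - 1, w - k - 2);
    E.slice(n) = X.slice(n).cols(p, w - 1) - pred;
  }
  return E;
}

// Simulate a (possibly time-varying) VAR process for one trial ensemble.
// Acoef: cube [M x M*p x S] with S coefficient regimes; regime: ivec length
// T giving the 0-based regime index per output sample; innov: cube
// [M x (T + burn) x N] of pre-generated innovations (burn-in included so
// the R side owns all randomness).
// [[Rcpp::export]]
arma::cube cpp_var_simulate(const arma::cube& Acoef, int p,
                            const arma::ivec& regime, int burn,
                            const arma::cube& innov) {
  const uword M = Acoef.n_rows, N = innov.n_slices;
  const uword Ttot = innov.n_cols, T = regime.n_elem;
  if (Ttot != T + (uword)burn) Rcpp::stop("innovation length mismatch");
  cube Y(M, T, N);
  for (uword n = 0; n < N; ++n) {
    mat xfull(M, Ttot, fill::zeros);
    for (uword t = 0; t < Ttot; ++t) {
      // pre-burn samples follow the first regime
      uword s = (t < (uword)burn) ? (uword)regime(0) : (uword)regime(t - burn);
      vec x = innov.slice(n).col(t);
      for (uword k = 0; k < (uword)p && k < t; ++k)
        x += Acoef.slice(s).cols(k * M, (k + 1) * M - 1) * xfull.col(t - k - 1);
      xfull.col(t) = x;
    }
    Y.slice(n) = xfull.cols(burn, Ttot - 1);
  }
  return Y;
}
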
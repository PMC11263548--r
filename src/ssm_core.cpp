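// Compiled hot path of the structured state-space layer: the kernel
// recurrence (forward state trajectory + taps), its adjoint sweep, and the
// per-channel bilinear discretization with its backward. Complex gradients
// follow the conjugate convention used on the R side (G = dL/dRe + i dL/dIm;
// a holomorphic linear map y = a x backpropagates as G_x = conj(a) G_y).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// K(k,h) = Re( sum_n C(n,h) * x_k(n,h) ), x_0 = Bbar, x_k = Abar x_{k-1}
// [[Rcpp::export]]
List cpp_kernel_states(const arma::cx_cube& Abar, const arma::cx_mat& Bbar,
                       const arma::cx_mat& C, int L, bool keep_states) {
  const int N = Abar.n_rows, H = Abar.n_slices;
  arma::mat K(L, H);
  arma::cx_cube X;
  if (keep_states) X.set_size(N, H, L);
  arma::cx_mat cur = Bbar;
  for (int k = 0; k < L; ++k) {
    if (keep_states) X.slice(k) = cur;
    for (int h = 0; h < H; ++h) {
      K(k, h) = std::real(arma::accu(C.col(h) % cur.col(h)));
    }
    if (k < L - 1) {
      arma::cx_mat nxt(N, H);
      for (int h = 0; h < H; ++h) nxt.col(h) = Abar.slice(h) * cur.col(h);
      cur = std::move(nxt);
    }
  }
  if (keep_states) return List::create(_["K"] = K, _["X"] = X);
  return List::create(_["K"] = K);
}

// adjoint of cpp_kernel_states w.r.t. C, Abar, Bbar given dL/dK
// [[Rcpp::export]]
List cpp_kernel_backward(const arma::cx_cube& Abar, const arma::cx_cube& X,
                         const arma::mat& gK, const arma::cx_mat& C) {
  const int N = Abar.n_rows, H = Abar.n_slices, L = X.n_slices;
  arma::cx_mat G_C(N, H, arma::fill::zeros);
  arma::cx_cube G_Abar(N, N, H, arma::fill::zeros);
  arma::cx_mat alpha(N, H, arma::fill::zeros);
  const arma::cx_mat Cc = arma::conj(C);
  for (int k = L - 1; k >= 0; --k) {
    for (int h = 0; h < H; ++h) {
      arma::cx_vec direct = Cc.col(h) * gK(k, h);
      if (k == L - 1) {
        alpha.col(h) = direct;
      } else {
        // .t() on a complex matrix is the conjugate transpose
        alpha.col(h) = Abar.slice(h).t() * alpha.col(h) + direct;
      }
      if (k >= 1) {
        G_Abar.slice(h) += alpha.col(h) * X.slice(k - 1).col(h).t();
      }
      G_C.col(h) += arma::conj(X.slice(k).col(h)) * gK(k, h);
    }
  }
  return List::create(_["G_C"] = G_C, _["G_Abar"] = G_Abar,
                      _["G_Bbar"] = alpha);
}

// bilinear (Tustin) discretization, all channels:
// Abar = (I - dt/2 A)^{-1} (I + dt/2 A), Bbar = (I - dt/2 A)^{-1} dt B,
// with A = diag(Lambda) - P Q^H
// [[Rcpp::export]]
List cpp_discretize(const arma::cx_mat& Lambda, const arma::cx_mat& P,
                    const arma::cx_mat& Q, const arma::cx_mat& B,
                    const arma::vec& dt) {
  const int N = Lambda.n_rows, H = Lambda.n_cols;
  arma::cx_cube Abar(N, N, H);
  arma::cx_mat Bbar(N, H);
  const arma::cx_mat I = arma::eye<arma::cx_mat>(N, N);
  for (int h = 0; h < H; ++h) {
    const double d = dt(h) / 2.0;
    arma::cx_mat A = arma::diagmat(Lambda.col(h)) - P.col(h) * Q.col(h).t();
    arma::cx_mat M = I - d * A;
    arma::cx_mat rhs = arma::join_rows(I + d * A,
                                       arma::cx_mat(dt(h) * B.col(h)));
    arma::cx_mat sol;
    if (!arma::solve(sol, M, rhs)) {
      stop("bilinear discretization singular on channel %d (dt=%g)",
           h + 1, dt(h));
    }
    Abar.slice(h) = sol.head_cols(N);
    Bbar.col(h) = sol.col(N);
  }
  return List::create(_["Abar"] = Abar, _["Bbar"] = Bbar);
}

// adjoint of cpp_discretize w.r.t. Lambda, P, Q, B and log(dt)
// [[Rcpp::export]]
List cpp_discretize_backward(const arma::cx_mat& Lambda, const arma::cx_mat& P,
                             const arma::cx_mat& Q, const arma::cx_mat& B,
                             const arma::vec& dt,
                             const arma::cx_cube& Abar, const arma::cx_mat& Bbar,
                             const arma::cx_cube& G_Abar,
                             const arma::cx_mat& G_Bbar) {
  const int N = Lambda.n_rows, H = Lambda.n_cols;
  arma::cx_mat G_Lambda(N, H), G_P(N, H), G_Q(N, H), G_B(N, H);
  arma::vec G_logdt(H);
  const arma::cx_mat I = arma::eye<arma::cx_mat>(N, N);
  for (int h = 0; h < H; ++h) {
    const double d = dt(h) / 2.0;
    arma::cx_mat A = arma::diagmat(Lambda.col(h)) - P.col(h) * Q.col(h).t();
    arma::cx_mat MH = (I - d * A).t();          // M^H
    arma::cx_mat S = arma::solve(MH, G_Abar.slice(h));
    arma::cx_mat G_N = S;
    arma::cx_mat G_M = -S * Abar.slice(h).t();
    arma::cx_vec Tv = arma::solve(MH, arma::cx_vec(G_Bbar.col(h)));
    G_B.col(h) = dt(h) * Tv;
    const double G_dt_B = std::real(arma::cdot(Tv, B.col(h)));
    G_M -= Tv * Bbar.col(h).t();
    arma::cx_mat GNM = G_N - G_M;
    arma::cx_mat G_A = d * GNM;
    const double G_delta = std::real(arma::accu(arma::conj(GNM) % A));
    G_Lambda.col(h) = G_A.diag();
    G_P.col(h) = -G_A * Q.col(h);
    G_Q.col(h) = -G_A.t() * P.col(h);
    const double G_dt = G_delta / 2.0 + G_dt_B;
    G_logdt(h) = G_dt * dt(h);
  }
  return List::create(_["Lambda"] = G_Lambda, _["P"] = G_P, _["Q"] = G_Q,
                      _["B"] = G_B, _["log_dt"] = G_logdt);
}
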
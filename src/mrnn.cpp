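// Batched MRNN passes used by training and decoding.
//
// Cube layout convention: inputs U are (E x B x T), activations X are
// (N x B x T), outputs Z are (M x B x T); slice t holds all B sequences'
// vectors for time bin t. The Euler leak is alpha = dt / tau.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List mrnn_forward_cpp(const arma::mat& Jxf, const arma::mat& Jfu, const arma::mat& Jfx,
                            const arma::vec& bx, const arma::mat& Wo, const arma::vec& bz,
                            double alpha, const arma::cube& U, const arma::mat& X0) {
  const uword N = Jxf.n_rows, M = Wo.n_rows;
  const uword B = U.n_cols, T = U.n_slices;
  cube X(N, B, T), Z(M, B, T);
  mat x = X0, r = tanh(X0);
  for (uword t = 0; t < T; ++t) {
    mat f = (Jfu * U.slice(t)) % (Jfx * r);
    mat drive = Jxf * f;
    drive.each_col() += bx;
    x = (1.0 - alpha) * x + alpha * drive;
    X.slice(t) = x;
    r = tanh(x);
    mat z = Wo * r;
    z.each_col() += bz;
    Z.slice(t) = z;
  }
  return Rcpp::List::create(Rcpp::Named("X") = X, Rcpp::Named("Z") = Z);
}

// Backpropagation through time. dZ is the gradient of the loss with respect
// to the outputs (already masked/scaled by the caller). Returns gradients
// for the trained set {Jxf, Jfu, Jfx, bx, Wo, bz}.
// [[Rcpp::export]]
Rcpp::List mrnn_bptt_cpp(const arma::mat& Jxf, const arma::mat& Jfu, const arma::mat& Jfx,
                         const arma::vec& bx, const arma::mat& Wo, const arma::vec& bz,
                         double alpha, const arma::cube& U, const arma::mat& X0,
                         const arma::cube& X, const arma::cube& dZ) {
  const uword N = Jxf.n_rows, F = Jxf.n_cols, E = Jfu.n_cols, M = Wo.n_rows;
  const uword B = U.n_cols, T = U.n_slices;
  mat dJxf(N, F, fill::zeros), dJfu(F, E, fill::zeros),
      dJfx(F, N, fill::zeros), dWo(M, N, fill::zeros);
  vec dbx(N, fill::zeros), dbz(M, fill::zeros);
  mat gx_next(N, B, fill::zeros), gr_carry(N, B, fill::zeros);
  for (uword ti = T; ti-- > 0;) {
    mat r_t = tanh(X.slice(ti));
    mat r_prev = (ti == 0) ? tanh(X0) : mat(tanh(X.slice(ti - 1)));
    const arma::mat& dZt = dZ.slice(ti);
    dWo += dZt * r_t.t();
    dbz += sum(dZt, 1);
    mat gr = Wo.t() * dZt + gr_carry;
    mat gx = gr % (1.0 - square(r_t)) + (1.0 - alpha) * gx_next;
    mat fu = Jfu * U.slice(ti);
    mat fx = Jfx * r_prev;
    mat agx = alpha * gx;
    dJxf += agx * (fu % fx).t();
    dbx += sum(agx, 1);
    mat df = Jxf.t() * agx;
    dJfu += (df % fx) * U.slice(ti).t();
    mat dffu = df % fu;
    dJfx += dffu * r_prev.t();
    gr_carry = Jfx.t() * dffu;
    gx_next = gx;
  }
  return Rcpp::List::create(
      Rcpp::Named("J_xf") = dJxf, Rcpp::Named("J_fu") = dJfu,
      Rcpp::Named("J_fx") = dJfx, Rcpp::Named("b_x") = dbx,
      Rcpp::Named("W_o") = dWo, Rcpp::Named("b_z") = dbz);
}

// Forward directional derivative (R-operator): the derivative of the output
// trajectory along a parameter direction {dJxf, dJfu, dJfx, dbx, dWo, dbz},
// evaluated on the stored forward activations X. Initial-state direction is
// zero (x0 is not a trained parameter).
// [[Rcpp::export]]
arma::cube mrnn_rop_cpp(const arma::mat& Jxf, const arma::mat& Jfu, const arma::mat& Jfx,
                        const arma::vec& bx, const arma::mat& Wo, const arma::vec& bz,
                        double alpha, const arma::cube& U, const arma::mat& X0,
                        const arma::cube& X,
                        const arma::mat& dJxf, const arma::mat& dJfu, const arma::mat& dJfx,
                        const arma::vec& dbx, const arma::mat& dWo, const arma::vec& dbz) {
  const uword N = Jxf.n_rows, M = Wo.n_rows;
  const uword B = U.n_cols, T = U.n_slices;
  cube dZ(M, B, T);
  mat dx(N, B, fill::zeros), dr(N, B, fill::zeros);
  mat r_prev = tanh(X0);
  for (uword t = 0; t < T; ++t) {
    mat fu = Jfu * U.slice(t);
    mat fx = Jfx * r_prev;
    mat dfu = dJfu * U.slice(t);
    mat dfx = dJfx * r_prev + Jfx * dr;
    mat df = dfu % fx + fu % dfx;
    mat ddrive = dJxf * (fu % fx) + Jxf * df;
    ddrive.each_col() += dbx;
    dx = (1.0 - alpha) * dx + alpha * ddrive;
    mat r_t = tanh(X.slice(t));
    dr = (1.0 - square(r_t)) % dx;
    mat dz = dWo * r_t + Wo * dr;
    dz.each_col() += dbz;
    dZ.slice(t) = dz;
    r_prev = r_t;
  }
  return dZ;
}
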
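// Linearized ERP neural-mass network: Jacobian assembly, delay correction,
// eigendecomposition-based transfer functions and cross-spectral prediction.
//
// State layout per source (8 states, source-major blocks):
//   1 v_stellate  2 i_stellate  3 v_pyr_e  4 i_pyr_e
//   5 v_pyr_i     6 i_pyr_i     7 v_inh    8 i_inh
// Innovations enter the stellate current equation; the observed signal is the
// pyramidal depolarization v_pyr = v_pyr_e - v_pyr_i.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Assemble the full Jacobian from the fixed intrinsic part and the
// exponentiated extrinsic couplings (triplet representation).
// [[Rcpp::export(name = ".cppBuildJ")]]
arma::mat cppBuildJ(const arma::vec& gains, const arma::mat& J0,
                    const arma::ivec& trEdge, const arma::ivec& trRow,
                    const arma::ivec& trCol, const arma::vec& trCoef) {
  mat J = J0;
  for (uword t = 0; t < trEdge.n_elem; ++t) {
    double g = gains(trEdge(t));
    double w = std::isfinite(g) ? std::exp(g) : 0.0; // -Inf => coupling off
    J(trRow(t), trCol(t)) += w * trCoef(t);
  }
  return J;
}

// First-order Taylor folding of conduction delays: xdot = (I + J.*D)^{-1} J x
// [[Rcpp::export(name = ".cppDelayCorrect")]]
arma::mat cppDelayCorrect(const arma::mat& J, const arma::mat& D) {
  mat A = eye(J.n_rows, J.n_cols) + J % D;
  mat Jd;
  if (!solve(Jd, A, J)) Rcpp::stop("delay correction: singular system");
  return Jd;
}

// Transfer functions from per-source innovations to pyramidal output at each
// frequency, via one eigendecomposition of the delay-corrected Jacobian.
// Returns list(transfer = n_s x n_u x n_f complex cube, maxre, ok).
// [[Rcpp::export(name = ".cppTransfer")]]
Rcpp::List cppTransfer(const arma::mat& Jd, const arma::mat& Bu,
                       const arma::mat& Cx, const arma::vec& freqs) {
  cx_vec d;
  cx_mat V;
  if (!eig_gen(d, V, Jd)) Rcpp::stop("eigendecomposition failed");
  double maxre = max(real(d));
  const uword nf = freqs.n_elem;
  cx_cube T(Cx.n_rows, Bu.n_cols, nf);
  cx_mat cB(Bu, mat(Bu.n_rows, Bu.n_cols, fill::zeros));
  cx_mat cC(Cx, mat(Cx.n_rows, Cx.n_cols, fill::zeros));
  cx_mat W;
  // near-defective eigenbases (e.g. decoupled identical sources) fall back
  // to direct per-frequency resolvents
  bool viaEig = rcond(V) > 1e-10 && solve(W, V, cB, solve_opts::no_approx);
  if (viaEig) {
    cx_mat A = cC * V;
    for (uword k = 0; k < nf; ++k) {
      cx_vec s = cx_double(0.0, 2.0 * datum::pi * freqs(k)) - d;
      cx_mat Wk = W;
      Wk.each_col() /= s; // diag(1/(i2pif - d)) * W
      T.slice(k) = A * Wk;
    }
  } else {
    cx_mat I(Jd.n_rows, Jd.n_cols, fill::eye);
    cx_mat cJ(Jd, mat(Jd.n_rows, Jd.n_cols, fill::zeros));
    for (uword k = 0; k < nf; ++k) {
      cx_mat R = solve(cx_double(0.0, 2.0 * datum::pi * freqs(k)) * I - cJ,
                       cB);
      T.slice(k) = cC * R;
    }
  }
  return Rcpp::List::create(Rcpp::Named("transfer") = T,
                            Rcpp::Named("maxre") = maxre);
}

static void theta_to_parts(const arma::vec& theta, int nE, int nS,
                           arma::vec& gains, arma::vec& a0, double& a1,
                           double& b0, double& b1) {
  gains = theta.subvec(0, nE > 0 ? nE - 1 : 0);
  if (nE == 0) gains.reset();
  a0 = theta.subvec(nE, nE + nS - 1);
  a1 = theta(nE + nS);
  b0 = theta(nE + nS + 1);
  b1 = theta(nE + nS + 2);
}

// Full forward sweep: theta -> sensor CSD cubes (+ stability info).
// ctx: list(J0, trEdge, trRow, trCol, trCoef, D, Bu, Cx, L, freqs, nE, nS)
static Rcpp::List forward_csd(const arma::vec& theta, const Rcpp::List& ctx,
                              bool wantCubes) {
  const int nE = Rcpp::as<int>(ctx["nE"]);
  const int nS = Rcpp::as<int>(ctx["nS"]);
  vec gains, a0;
  double a1, b0, b1;
  theta_to_parts(theta, nE, nS, gains, a0, a1, b0, b1);

  mat J = cppBuildJ(gains, Rcpp::as<mat>(ctx["J0"]),
                    Rcpp::as<ivec>(ctx["trEdge"]), Rcpp::as<ivec>(ctx["trRow"]),
                    Rcpp::as<ivec>(ctx["trCol"]), Rcpp::as<vec>(ctx["trCoef"]));
  mat Jd = cppDelayCorrect(J, Rcpp::as<mat>(ctx["D"]));

  cx_vec d;
  cx_mat V;
  if (!eig_gen(d, V, Jd)) Rcpp::stop("eigendecomposition failed");
  double maxre = max(real(d));
  bool ok = maxre < 0.0;

  const mat Bu = Rcpp::as<mat>(ctx["Bu"]);
  const mat Cx = Rcpp::as<mat>(ctx["Cx"]);
  const mat L = Rcpp::as<mat>(ctx["L"]);
  const vec freqs = Rcpp::as<vec>(ctx["freqs"]);
  const uword nf = freqs.n_elem, m = L.n_rows;

  cx_cube Sn(m, m, nf, fill::zeros), Sy(m, m, nf, fill::zeros);
  cx_cube Se(m, m, nf, fill::zeros);
  if (ok) {
    cx_mat cB(Bu, mat(Bu.n_rows, Bu.n_cols, fill::zeros));
    cx_mat LCr = cx_mat(L * Cx, mat(m, Cx.n_cols, fill::zeros));
    cx_mat LC = LCr * V; // m x n_x
    cx_mat W;
    bool viaEig = rcond(V) > 1e-10 && solve(W, V, cB, solve_opts::no_approx);
    cx_mat I(Jd.n_rows, Jd.n_cols, fill::eye);
    cx_mat cJ(Jd, mat(Jd.n_rows, Jd.n_cols, fill::zeros));
    for (uword k = 0; k < nf; ++k) {
      double f = freqs(k);
      cx_mat T;
      if (viaEig) {
        cx_vec s = cx_double(0.0, 2.0 * datum::pi * f) - d;
        cx_mat Wk = W;
        Wk.each_col() /= s;
        T = LC * Wk; // m x n_u sensor-level transfer
      } else {
        T = LCr * solve(cx_double(0.0, 2.0 * datum::pi * f) * I - cJ, cB);
      }
      vec gu(nS);
      for (int u = 0; u < nS; ++u)
        gu(u) = std::exp(a0(u)) * (1.0 + std::exp(a1) / f);
      cx_mat Tg = T;
      for (int u = 0; u < nS; ++u) Tg.col(u) *= gu(u);
      cx_mat Sk = Tg * T.t(); // T diag(gu) T^H  (arma .t() is conj-transpose)
      Sk = 0.5 * (Sk + Sk.t());
      double gn = std::exp(b0) + std::exp(b1) / f;
      Sn.slice(k) = Sk;
      Se.slice(k).diag() += gn;
      Sy.slice(k) = Sk + Se.slice(k);
    }
  }
  if (wantCubes)
    return Rcpp::List::create(
        Rcpp::Named("total") = Sy, Rcpp::Named("neuronal") = Sn,
        Rcpp::Named("noise") = Se, Rcpp::Named("maxre") = maxre,
        Rcpp::Named("ok") = ok);

  // stacked real feature vector: per frequency Re(diag), Re(upper), Im(upper)
  const uword per = m * m;
  vec feat(nf * per, fill::zeros);
  if (ok) {
    uword p = 0;
    for (uword k = 0; k < nf; ++k) {
      const cx_mat& S = Sy.slice(k);
      for (uword i = 0; i < m; ++i) feat(p++) = S(i, i).real();
      for (uword j = 1; j < m; ++j)
        for (uword i = 0; i < j; ++i) feat(p++) = S(i, j).real();
      for (uword j = 1; j < m; ++j)
        for (uword i = 0; i < j; ++i) feat(p++) = S(i, j).imag();
    }
  }
  return Rcpp::List::create(Rcpp::Named("features") = feat,
                            Rcpp::Named("maxre") = maxre,
                            Rcpp::Named("ok") = ok);
}

// [[Rcpp::export(name = ".cppCsd")]]
Rcpp::List cppCsd(const arma::vec& theta, const Rcpp::List& ctx) {
  return forward_csd(theta, ctx, true);
}

// [[Rcpp::export(name = ".cppFeatures")]]
Rcpp::List cppFeatures(const arma::vec& theta, const Rcpp::List& ctx) {
  return forward_csd(theta, ctx, false);
}

// Central finite-difference Jacobian of the stacked feature map.
// [[Rcpp::export(name = ".cppFeatureJacobian")]]
Rcpp::List cppFeatureJacobian(const arma::vec& theta, const Rcpp::List& ctx,
                              const double h) {
  Rcpp::List f0 = forward_csd(theta, ctx, false);
  bool ok = Rcpp::as<bool>(f0["ok"]);
  vec y0 = Rcpp::as<vec>(f0["features"]);
  mat J(y0.n_elem, theta.n_elem, fill::zeros);
  if (ok) {
    for (uword j = 0; j < theta.n_elem; ++j) {
      vec tp = theta, tm = theta;
      tp(j) += h;
      tm(j) -= h;
      Rcpp::List fp = forward_csd(tp, ctx, false);
      Rcpp::List fm = forward_csd(tm, ctx, false);
      if (!(Rcpp::as<bool>(fp["ok"]) && Rcpp::as<bool>(fm["ok"]))) {
        ok = false;
        break;
      }
      J.col(j) = (Rcpp::as<vec>(fp["features"]) - Rcpp::as<vec>(fm["features"])) /
                 (2.0 * h);
    }
  }
  return Rcpp::List::create(Rcpp::Named("f0") = y0, Rcpp::Named("J") = J,
                            Rcpp::Named("ok") = ok);
}
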
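// Hot loops of the recurrent forward/backward passes.
//
// Batches are time-stacked: Xs is a (T*B) x d matrix whose row block
// ((t-1)*B):(t*B-1) holds the batch inputs at step t. Only elementwise work
// and the recurrent-kernel products run inside the time loop; input-kernel
// products and weight-gradient accumulations are single BLAS calls.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export(rng = false)]]
List bi_forward_cpp(const arma::mat& Xs, const arma::mat& U, const arma::mat& Ua, const arma::mat& Uc,
                    const arma::mat& Wa, const arma::mat& Wc, const arma::vec& wa, const arma::vec& wc,
                    const arma::vec& b, const arma::vec& ba, const arma::vec& bc,
                    bool diag_rec, bool has_bias, int Tn, int B, bool keep) {
  const uword n = U.n_cols;
  mat Pa = Xs * Ua, Pc = Xs * Uc, Ph = Xs * U;
  if (has_bias) {
    Pa.each_row() += ba.t();
    Pc.each_row() += bc.t();
    Ph.each_row() += b.t();
  }
  mat H(Tn * B, n), TA, CC, CAND, HPREV;
  if (keep) {
    TA.set_size(Tn * B, n); CC.set_size(Tn * B, n);
    CAND.set_size(Tn * B, n); HPREV.set_size(Tn * B, n);
  }
  mat h(B, n, fill::zeros);
  for (int t = 0; t < Tn; ++t) {
    const uword r0 = (uword)t * B, r1 = r0 + B - 1;
    mat pa = Pa.rows(r0, r1), pc = Pc.rows(r0, r1);
    if (diag_rec) {
      pa += h.each_row() % wa.t();
      pc += h.each_row() % wc.t();
    } else {
      pa += h * Wa;
      pc += h * Wc;
    }
    mat ta = tanh(pa);
    mat cc = sigm(pc);
    mat cand = tanh(Ph.rows(r0, r1) + (1.0 + ta) % h);
    mat hn = cc % h + (1.0 - cc) % cand;
    if (keep) {
      TA.rows(r0, r1) = ta; CC.rows(r0, r1) = cc;
      CAND.rows(r0, r1) = cand; HPREV.rows(r0, r1) = h;
    }
    H.rows(r0, r1) = hn;
    h = hn;
  }
  return List::create(Named("H") = H, Named("h_final") = h,
                      Named("TA") = TA, Named("CC") = CC,
                      Named("CAND") = CAND, Named("HPREV") = HPREV);
}

// [[Rcpp::export(rng = false)]]
List bi_backward_cpp(const arma::mat& Xs, const arma::mat& U, const arma::mat& Ua, const arma::mat& Uc,
                     const arma::mat& Wa, const arma::mat& Wc, const arma::vec& wa, const arma::vec& wc,
                     const arma::mat& TA, const arma::mat& CC, const arma::mat& CAND,
                     const arma::mat& HPREV, const arma::mat& Dinj,
                     bool diag_rec, bool has_bias, int Tn, int B) {
  const uword n = U.n_cols;
  mat Dph(Tn * B, n), Dpa(Tn * B, n), Dpc(Tn * B, n);
  mat carry(B, n, fill::zeros);
  for (int t = Tn - 1; t >= 0; --t) {
    const uword r0 = (uword)t * B, r1 = r0 + B - 1;
    mat dh = carry + Dinj.rows(r0, r1);
    mat hprev = HPREV.rows(r0, r1);
    mat cand = CAND.rows(r0, r1);
    mat cc = CC.rows(r0, r1);
    mat ta = TA.rows(r0, r1);
    mat dph = dh % (1.0 - cc) % (1.0 - cand % cand);
    mat dpa = dph % hprev % (1.0 - ta % ta);
    mat dpc = (dh % (hprev - cand)) % cc % (1.0 - cc);
    Dph.rows(r0, r1) = dph; Dpa.rows(r0, r1) = dpa; Dpc.rows(r0, r1) = dpc;
    carry = dh % cc + dph % (1.0 + ta);
    if (diag_rec) {
      carry += dpa.each_row() % wa.t();
      carry += dpc.each_row() % wc.t();
    } else {
      carry += dpa * Wa.t() + dpc * Wc.t();
    }
  }
  mat gWa, gWc;
  vec gwa, gwc, gba, gbc, gb;
  if (diag_rec) {
    gwa = sum(Dpa % HPREV, 0).t();
    gwc = sum(Dpc % HPREV, 0).t();
  } else {
    gWa = HPREV.t() * Dpa;
    gWc = HPREV.t() * Dpc;
  }
  if (has_bias) {
    gba = sum(Dpa, 0).t();
    gbc = sum(Dpc, 0).t();
    gb = sum(Dph, 0).t();
  }
  return List::create(
    Named("gU") = Xs.t() * Dph,
    Named("gUa") = Xs.t() * Dpa,
    Named("gUc") = Xs.t() * Dpc,
    Named("gwa") = gwa, Named("gwc") = gwc,
    Named("gWa") = gWa, Named("gWc") = gWc,
    Named("gba") = gba, Named("gbc") = gbc, Named("gb") = gb,
    Named("Dx") = Dph * U.t() + Dpa * Ua.t() + Dpc * Uc.t());
}

// [[Rcpp::export(rng = false)]]
List gru_forward_cpp(const arma::mat& Xs, const arma::mat& Uz, const arma::mat& Ur, const arma::mat& Uh,
                     const arma::mat& Wz, const arma::mat& Wr, const arma::mat& Wh,
                     const arma::vec& bz, const arma::vec& br, const arma::vec& bh,
                     bool has_bias, int Tn, int B, bool keep) {
  const uword n = Uz.n_cols;
  mat Pz = Xs * Uz, Pr = Xs * Ur, Ph = Xs * Uh;
  if (has_bias) {
    Pz.each_row() += bz.t();
    Pr.each_row() += br.t();
    Ph.each_row() += bh.t();
  }
  mat H(Tn * B, n), Z, R, WHm, CAND, HPREV;
  if (keep) {
    Z.set_size(Tn * B, n); R.set_size(Tn * B, n); WHm.set_size(Tn * B, n);
    CAND.set_size(Tn * B, n); HPREV.set_size(Tn * B, n);
  }
  mat h(B, n, fill::zeros);
  for (int t = 0; t < Tn; ++t) {
    const uword r0 = (uword)t * B, r1 = r0 + B - 1;
    mat z = sigm(Pz.rows(r0, r1) + h * Wz);
    mat r = sigm(Pr.rows(r0, r1) + h * Wr);
    mat wh = h * Wh;
    mat cand = tanh(Ph.rows(r0, r1) + r % wh);
    mat hn = z % h + (1.0 - z) % cand;
    if (keep) {
      Z.rows(r0, r1) = z; R.rows(r0, r1) = r; WHm.rows(r0, r1) = wh;
      CAND.rows(r0, r1) = cand; HPREV.rows(r0, r1) = h;
    }
    H.rows(r0, r1) = hn;
    h = hn;
  }
  return List::create(Named("H") = H, Named("h_final") = h,
                      Named("Z") = Z, Named("R") = R, Named("WH") = WHm,
                      Named("CAND") = CAND, Named("HPREV") = HPREV);
}

// [[Rcpp::export(rng = false)]]
List gru_backward_cpp(const arma::mat& Xs, const arma::mat& Uz, const arma::mat& Ur, const arma::mat& Uh,
                      const arma::mat& Wz, const arma::mat& Wr, const arma::mat& Wh,
                      const arma::mat& Z, const arma::mat& R, const arma::mat& WH,
                      const arma::mat& CAND, const arma::mat& HPREV, const arma::mat& Dinj,
                      bool has_bias, int Tn, int B) {
  const uword n = Uz.n_cols;
  mat Dpz(Tn * B, n), Dpr(Tn * B, n), Dph(Tn * B, n), Dwh(Tn * B, n);
  mat carry(B, n, fill::zeros);
  for (int t = Tn - 1; t >= 0; --t) {
    const uword r0 = (uword)t * B, r1 = r0 + B - 1;
    mat dh = carry + Dinj.rows(r0, r1);
    mat hprev = HPREV.rows(r0, r1);
    mat z = Z.rows(r0, r1);
    mat r = R.rows(r0, r1);
    mat cand = CAND.rows(r0, r1);
    mat dph = dh % (1.0 - z) % (1.0 - cand % cand);
    mat dr = dph % WH.rows(r0, r1);
    mat dwh = dph % r;
    mat dpz = (dh % (hprev - cand)) % z % (1.0 - z);
    mat dpr = dr % r % (1.0 - r);
    Dpz.rows(r0, r1) = dpz; Dpr.rows(r0, r1) = dpr;
    Dph.rows(r0, r1) = dph; Dwh.rows(r0, r1) = dwh;
    carry = dh % z + dwh * Wh.t() + dpz * Wz.t() + dpr * Wr.t();
  }
  vec gbz, gbr, gbh;
  if (has_bias) {
    gbz = sum(Dpz, 0).t();
    gbr = sum(Dpr, 0).t();
    gbh = sum(Dph, 0).t();
  }
  return List::create(
    Named("gUz") = Xs.t() * Dpz,
    Named("gUr") = Xs.t() * Dpr,
    Named("gUh") = Xs.t() * Dph,
    Named("gWz") = HPREV.t() * Dpz,
    Named("gWr") = HPREV.t() * Dpr,
    Named("gWh") = HPREV.t() * Dwh,
    Named("gbz") = gbz, Named("gbr") = gbr, Named("gbh") = gbh,
    Named("Dx") = Dph * Uh.t() + Dpz * Uz.t() + Dpr * Ur.t());
}
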
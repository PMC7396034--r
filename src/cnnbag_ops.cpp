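// Compiled kernels for the hot inner loops: im2col convolution forward /
// backward, max-pooling forward / backward, and the CART split search.
// All layout conventions (channel-first activations as (C*H*W) x n
// matrices, 1-based index vectors precomputed in R) are owned by the R
// callers; these functions only move numbers. The im2col matrix is
// regathered in the backward pass rather than shipped across the R
// boundary twice: the gather is far cheaper than the copy.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
using namespace arma;

static mat gather_im2col(const mat& xm, const uvec& inside, const uvec& idx,
                         int p_len, uword k) {
  const uword f = xm.n_rows, n = xm.n_cols;
  const uword km = idx.n_elem;
  const uword m = km / k;
  mat xcol(k, m * n);
  vec pad(p_len, fill::zeros);
  double* pd = pad.memptr();
  const uword* in_p = inside.memptr();
  const uword* id_p = idx.memptr();
  for (uword s = 0; s < n; ++s) {
    const double* xs = xm.colptr(s);
    for (uword i = 0; i < f; ++i) pd[in_p[i] - 1] = xs[i];
    double* xc = xcol.colptr(s * m);
    for (uword t = 0; t < km; ++t) xc[t] = pd[id_p[t] - 1];
  }
  return xcol;
}

// xm: (Cin*H*W) x n input; inside: linear positions of real cells in the
// padded block (1-based); idx: im2col gather indices (1-based, K fastest,
// then output position); p_len: padded block length; wmat: K x Cout;
// b: Cout. Returns z and a = relu(z), both Cout x (M*n).
// [[Rcpp::export]]
Rcpp::List conv_forward_cpp(const arma::mat& xm, const arma::uvec& inside,
                            const arma::uvec& idx, int p_len,
                            const arma::mat& wmat, const arma::vec& b) {
  mat xcol = gather_im2col(xm, inside, idx, p_len, wmat.n_rows);
  mat z = wmat.t() * xcol;
  z.each_col() += b;
  mat a = z;
  a.for_each([](double& v) { if (v < 0) v = 0; });
  return Rcpp::List::create(Rcpp::Named("z") = z, Rcpp::Named("a") = a);
}

// d_act, z: Cout x (M*n); the ReLU derivative is applied here. xm is the
// layer input the forward pass saw (for the im2col regather). Returns the
// batch-summed kernel gradient (Cout x K), bias gradient, and the gradient
// wrt the layer input ((Cin*H*W) x n) via col2im scatter-add.
// [[Rcpp::export]]
Rcpp::List conv_backward_cpp(const arma::mat& d_act, const arma::mat& z,
                             const arma::mat& xm, const arma::mat& wmat,
                             const arma::uvec& inside, const arma::uvec& idx,
                             int p_len) {
  mat dz = d_act;
  dz.elem(find(z <= 0)).zeros();
  mat xcol = gather_im2col(xm, inside, idx, p_len, wmat.n_rows);
  mat d_wmat = dz * xcol.t();
  vec d_b = sum(dz, 1);
  mat dxcol = wmat * dz;                       // K x (M*n)
  const uword f = xm.n_rows, n = xm.n_cols;
  const uword k = wmat.n_rows;
  const uword km = idx.n_elem;
  const uword m = km / k;
  mat dxm(f, n);
  vec dpad(p_len);
  const uword* in_p = inside.memptr();
  const uword* id_p = idx.memptr();
  for (uword s = 0; s < n; ++s) {
    dpad.zeros();
    double* dp = dpad.memptr();
    const double* dc = dxcol.colptr(s * m);
    for (uword t = 0; t < km; ++t) dp[id_p[t] - 1] += dc[t];
    double* dx = dxm.colptr(s);
    for (uword i = 0; i < f; ++i) dx[i] = dp[in_p[i] - 1];
  }
  return Rcpp::List::create(Rcpp::Named("d_wmat") = d_wmat,
                            Rcpp::Named("d_b") = d_b,
                            Rcpp::Named("d_input") = dxm);
}

// xm: (C*H*W) x n; off: m x (wh*ww) window-member indices (1-based),
// columns in row-major window scan order. Strict '>' keeps the first
// maximum of the scan on ties. Returns pooled values and the winning
// window-offset column per output cell.
// [[Rcpp::export]]
Rcpp::List pool_forward_cpp(const arma::mat& xm, const arma::umat& off) {
  const uword m = off.n_rows, kw = off.n_cols, n = xm.n_cols;
  mat a(m, n);
  imat winner(m, n);
  for (uword s = 0; s < n; ++s) {
    const double* col = xm.colptr(s);
    double* ac = a.colptr(s);
    arma::sword* wc = winner.colptr(s);
    for (uword r = 0; r < m; ++r) {
      double best = col[off(r, 0) - 1];
      uword wk = 0;
      for (uword k = 1; k < kw; ++k) {
        double v = col[off(r, k) - 1];
        if (v > best) { best = v; wk = k; }
      }
      ac[r] = best;
      wc[r] = static_cast<arma::sword>(wk) + 1;
    }
  }
  return Rcpp::List::create(Rcpp::Named("a") = a,
                            Rcpp::Named("winner") = winner);
}

// Routes each error to its recorded argmax position; overlapping windows
// accumulate additively (error mass is conserved).
// [[Rcpp::export]]
arma::mat pool_backward_cpp(const arma::mat& d_out, const arma::imat& winner,
                            const arma::umat& off, int f) {
  const uword m = off.n_rows, n = d_out.n_cols;
  mat din(f, n, fill::zeros);
  for (uword s = 0; s < n; ++s) {
    double* dcol = din.colptr(s);
    const double* dv = d_out.colptr(s);
    const arma::sword* wc = winner.colptr(s);
    for (uword r = 0; r < m; ++r) {
      dcol[off(r, static_cast<uword>(wc[r]) - 1) - 1] += dv[r];
    }
  }
  return din;
}

// Exhaustive CART split search over all features and midpoints between
// consecutive distinct sorted values, minimizing weighted Gini impurity.
// rows are 1-based indices into x / y; y holds +1/-1. Ties break to the
// first feature, then the smallest threshold (strict improvement test).
// Returns feature = 0 when no valid split exists. Uses Rcpp proxy types
// (no copy of the full feature matrix per node).
// [[Rcpp::export]]
Rcpp::List best_split_cpp(const Rcpp::NumericMatrix& x,
                          const Rcpp::IntegerVector& y,
                          const Rcpp::IntegerVector& rows, int min_leaf) {
  const int n = rows.size(), p = x.ncol();
  double best_gini = std::numeric_limits<double>::infinity(), best_thr = 0.0;
  int best_f = 0;
  std::vector<double> xv(n);
  std::vector<int> o(n);
  int total_pos = 0;
  for (int i = 0; i < n; ++i) if (y[rows[i] - 1] == 1) total_pos++;
  for (int j = 0; j < p; ++j) {
    const double* col = &x(0, j);
    for (int i = 0; i < n; ++i) xv[i] = col[rows[i] - 1];
    for (int i = 0; i < n; ++i) o[i] = i;
    std::stable_sort(o.begin(), o.end(),
                     [&xv](int a, int b) { return xv[a] < xv[b]; });
    int cpos = 0;
    for (int i = 0; i + 1 < n; ++i) {
      if (y[rows[o[i]] - 1] == 1) cpos++;
      const double lo = xv[o[i]], hi = xv[o[i + 1]];
      if (!(hi > lo)) continue;
      const int kk = i + 1;
      if (kk < min_leaf || (n - kk) < min_leaf) continue;
      const double pl = static_cast<double>(cpos) / kk;
      const double pr = static_cast<double>(total_pos - cpos) / (n - kk);
      const double g = (kk * 2.0 * pl * (1.0 - pl) +
                        (n - kk) * 2.0 * pr * (1.0 - pr)) / n;
      if (g < best_gini - 1e-12) {
        best_gini = g;
        best_f = j + 1;
        best_thr = (lo + hi) / 2.0;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("feature") = best_f,
                            Rcpp::Named("threshold") = best_thr,
                            Rcpp::Named("gini") = best_gini);
}

// ---------------------------------------------------------------------------
// Whole-epoch training step: forward, backward and plain gradient-descent
// updates for every minibatch of one pass, in a single call. The math is
// the same as the per-layer kernels above (shared helpers); a parity test
// in the suite checks that one epoch here equals the R-stepped layer path.
//
// plan: list of layers; each a list with
//   type: 1 conv (inside, idx, p_len, k, cout), 2 pool (off, f_in),
//         3 dense, 4 output (softmax)
// params_in: per layer, list(w, b) or R_NilValue; conv w arrays are used
//   as (k x cout) matrices (memory layout matches).
// Returns updated params, summed cross-entropy loss and correct count.
// [[Rcpp::export]]
Rcpp::List train_epoch_cpp(const Rcpp::List& plan, const Rcpp::List& params_in,
                           const arma::mat& xm_all, const arma::mat& y_all,
                           const Rcpp::IntegerVector& perm, int batch_size,
                           double lr) {
  const int l_n = plan.size();
  const uword n = xm_all.n_cols;
  std::vector<int> type(l_n, 0);
  std::vector<mat> w(l_n), dw(l_n);
  std::vector<vec> b(l_n), db(l_n);
  std::vector<uvec> c_inside(l_n), c_idx(l_n);
  std::vector<int> c_plen(l_n), c_k(l_n);
  std::vector<umat> p_off(l_n);
  std::vector<int> p_fin(l_n);
  for (int l = 0; l < l_n; ++l) {
    Rcpp::List lay = plan[l];
    type[l] = Rcpp::as<int>(lay["type"]);
    if (type[l] == 1) {
      c_inside[l] = Rcpp::as<uvec>(lay["inside"]);
      c_idx[l] = Rcpp::as<uvec>(lay["idx"]);
      c_plen[l] = Rcpp::as<int>(lay["p_len"]);
      c_k[l] = Rcpp::as<int>(lay["k"]);
      Rcpp::List pr = params_in[l];
      Rcpp::NumericVector wv = pr["w"];
      const int cout = wv.size() / c_k[l];
      w[l] = mat(wv.begin(), c_k[l], cout);          // copy
      b[l] = Rcpp::as<vec>(pr["b"]);
    } else if (type[l] == 2) {
      p_off[l] = Rcpp::as<umat>(lay["off"]);
      p_fin[l] = Rcpp::as<int>(lay["f_in"]);
    } else if (type[l] >= 3) {
      Rcpp::List pr = params_in[l];
      w[l] = Rcpp::as<mat>(pr["w"]);
      b[l] = Rcpp::as<vec>(pr["b"]);
    }
  }

  std::vector<mat> acts(l_n + 1), zs(l_n), xcols(l_n);
  std::vector<imat> winners(l_n);
  double loss = 0.0;
  int correct = 0;

  for (uword b0 = 0; b0 < n; b0 += batch_size) {
    const uword bs = std::min<uword>(batch_size, n - b0);
    mat a0(xm_all.n_rows, bs);
    for (uword i = 0; i < bs; ++i) {
      a0.col(i) = xm_all.col(perm[b0 + i] - 1);
    }
    acts[0] = std::move(a0);
    mat yb(2, bs);
    for (uword i = 0; i < bs; ++i) yb.col(i) = y_all.col(perm[b0 + i] - 1);

    // forward
    for (int l = 0; l < l_n; ++l) {
      const mat& ap = acts[l];
      if (type[l] == 1) {
        xcols[l] = gather_im2col(ap, c_inside[l], c_idx[l], c_plen[l],
                                 c_k[l]);
        mat z = w[l].t() * xcols[l];
        z.each_col() += b[l];
        zs[l] = z;
        z.for_each([](double& v) { if (v < 0) v = 0; });
        z.reshape(z.n_elem / bs, bs);   // (cout, m*bs) -> (cout*m, bs)
        acts[l + 1] = std::move(z);
      } else if (type[l] == 2) {
        const umat& off = p_off[l];
        const uword m = off.n_rows, kw = off.n_cols;
        mat a(m, bs);
        imat win(m, bs);
        for (uword s = 0; s < bs; ++s) {
          const double* col = ap.colptr(s);
          double* ac = a.colptr(s);
          sword* wc = win.colptr(s);
          for (uword r = 0; r < m; ++r) {
            double bestv = col[off(r, 0) - 1];
            uword wk = 0;
            for (uword k = 1; k < kw; ++k) {
              double v = col[off(r, k) - 1];
              if (v > bestv) { bestv = v; wk = k; }
            }
            ac[r] = bestv;
            wc[r] = static_cast<sword>(wk) + 1;
          }
        }
        winners[l] = std::move(win);
        acts[l + 1] = std::move(a);
      } else {
        mat z = w[l] * ap;
        z.each_col() += b[l];
        zs[l] = z;
        if (type[l] == 3) {
          z.for_each([](double& v) { if (v < 0) v = 0; });
        } else {                       // softmax over 2 classes
          for (uword s = 0; s < bs; ++s) {
            double m0 = z(0, s), m1 = z(1, s);
            double mx = m0 > m1 ? m0 : m1;
            double e0 = std::exp(m0 - mx), e1 = std::exp(m1 - mx);
            double tot = e0 + e1;
            z(0, s) = e0 / tot;
            z(1, s) = e1 / tot;
          }
        }
        acts[l + 1] = std::move(z);
      }
    }

    // loss and accuracy from the softmax output
    const mat& probs = acts[l_n];
    for (uword s = 0; s < bs; ++s) {
      double pt = probs(0, s) * yb(0, s) + probs(1, s) * yb(1, s);
      loss -= std::log(std::max(pt, 1e-12));
      int pred = probs(1, s) > probs(0, s) ? 1 : 0;
      int truth = yb(1, s) > 0.5 ? 1 : 0;
      if (pred == truth) ++correct;
    }

    // backward + update (batch-summed gradients, plain gradient descent)
    mat delta = probs - yb;
    mat d_act;
    for (int l = l_n - 1; l >= 0; --l) {
      if (type[l] >= 3) {
        if (type[l] == 3) {
          delta = d_act;
          const mat& z = zs[l];
          delta.elem(find(z <= 0)).zeros();
        }
        mat dwl = delta * acts[l].t();
        vec dbl = sum(delta, 1);
        d_act = w[l].t() * delta;
        w[l] -= lr * dwl;
        b[l] -= lr * dbl;
      } else if (type[l] == 2) {
        const umat& off = p_off[l];
        const imat& win = winners[l];
        const uword m = off.n_rows;
        mat din(p_fin[l], bs, fill::zeros);
        for (uword s = 0; s < bs; ++s) {
          double* dcol = din.colptr(s);
          const double* dv = d_act.colptr(s);
          const sword* wc = win.colptr(s);
          for (uword r = 0; r < m; ++r) {
            dcol[off(r, static_cast<uword>(wc[r]) - 1) - 1] += dv[r];
          }
        }
        d_act = std::move(din);
      } else {
        mat dz = d_act;
        dz.elem(find(zs[l] <= 0)).zeros();
        dz.reshape(zs[l].n_rows, zs[l].n_cols);    // (cout, m*bs)
        mat dwl = dz * xcols[l].t();               // cout x k
        vec dbl = sum(dz, 1);
        const uword km = c_idx[l].n_elem;
        const uword m = km / c_k[l];
        mat dxcol = w[l] * dz;
        const uword f = acts[l].n_rows;
        mat dxm(f, bs);
        vec dpad(c_plen[l]);
        const uword* in_p = c_inside[l].memptr();
        const uword* id_p = c_idx[l].memptr();
        for (uword s = 0; s < bs; ++s) {
          dpad.zeros();
          double* dp = dpad.memptr();
          const double* dc = dxcol.colptr(s * m);
          for (uword t = 0; t < km; ++t) dp[id_p[t] - 1] += dc[t];
          double* dx = dxm.colptr(s);
          for (uword i = 0; i < f; ++i) dx[i] = dp[in_p[i] - 1];
        }
        w[l] -= lr * dwl.t();
        b[l] -= lr * dbl;
        d_act = std::move(dxm);
      }
    }
  }

  // write parameters back, preserving the R-side shapes
  Rcpp::List params_out(l_n);
  for (int l = 0; l < l_n; ++l) {
    if (type[l] == 0 || type[l] == 2) continue;
    Rcpp::List pr = Rcpp::clone(Rcpp::as<Rcpp::List>(params_in[l]));
    if (type[l] == 1) {
      Rcpp::NumericVector wv = Rcpp::clone(Rcpp::as<Rcpp::NumericVector>(
          Rcpp::as<Rcpp::List>(params_in[l])["w"]));
      std::copy(w[l].begin(), w[l].end(), wv.begin());
      pr["w"] = wv;
    } else {
      pr["w"] = Rcpp::wrap(w[l]);
    }
    pr["b"] = Rcpp::NumericVector(b[l].begin(), b[l].end());
    params_out[l] = pr;
  }
  return Rcpp::List::create(Rcpp::Named("params") = params_out,
                            Rcpp::Named("loss") = loss,
                            Rcpp::Named("correct") = correct);
}
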
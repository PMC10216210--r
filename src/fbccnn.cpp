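// Batched forward/backward pass of the two-convolution complex-spectrum
// network. Layout conventions (column-major, matching the R side):
//   X    : Nch x (W*B), sample b occupies columns [b*W, (b+1)*W).
//   Pat  : (Nk1*K2) x (T*B), im2col patches, position t of sample b in
//          column b*T + t; a patch is a contiguous Nk1 x K2 block of D1.
//   Fm   : (Nk2*T) x B, flattened second-layer output.
// Dropout masks are drawn from R's RNG (unif_rand), so a set.seed() on the
// R side makes training bit-reproducible.

#include <RcppArmadillo.h>
#if defined(__GLIBC__)
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Keep multi-megabyte workspace blocks on the heap instead of handing them
// back to the OS after every batch; repeated mmap/munmap of the per-batch
// temporaries otherwise dominates the training loop with page faults.
static void keep_large_allocs() {
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
}

// Row-wise mean and (population) variance in one pass, no temporaries.
static void row_stats(const arma::mat& Z, arma::vec& m, arma::vec& v) {
  const arma::uword R = Z.n_rows, C = Z.n_cols;
  m.zeros(R);
  v.zeros(R);
  for (arma::uword j = 0; j < C; ++j) {
    const double* z = Z.colptr(j);
    for (arma::uword i = 0; i < R; ++i) {
      m[i] += z[i];
      v[i] += z[i] * z[i];
    }
  }
  m /= static_cast<double>(C);
  v = v / static_cast<double>(C) - arma::square(m);
}

static const double BN_EPS = 1e-5;

// PReLU + inverted dropout in one pass. Writes the dropout mask (already
// scaled by 1/(1-p), 0 for dropped units) into `mask` when training.
static void prelu_dropout(const arma::mat& A, arma::mat& out, arma::mat& mask,
                          double slope, double dropout, bool training) {
  const arma::uword n = A.n_elem;
  const double* a = A.memptr();
  double* o = out.memptr();
  if (training && dropout > 0) {
    const double keep = 1.0 - dropout;
    double* m = mask.memptr();
    for (arma::uword i = 0; i < n; ++i) {
      const double mi = (unif_rand() >= dropout) ? 1.0 / keep : 0.0;
      m[i] = mi;
      const double v = a[i] > 0 ? a[i] : slope * a[i];
      o[i] = v * mi;
    }
  } else {
    for (arma::uword i = 0; i < n; ++i) {
      o[i] = a[i] > 0 ? a[i] : slope * a[i];
    }
  }
}

// Backward through dropout + PReLU: given dOut (gradient at the dropout
// output), accumulates dA (gradient at the pre-activation) and the slope
// gradient. mask may be empty (inference-style pass never calls this).
static double prelu_dropout_backward(const arma::mat& dOut,
                                     const arma::mat& A,
                                     const arma::mat& mask, double slope,
                                     bool has_mask, arma::mat& dA) {
  const arma::uword n = A.n_elem;
  const double* d = dOut.memptr();
  const double* a = A.memptr();
  const double* m = has_mask ? mask.memptr() : nullptr;
  double* g = dA.memptr();
  double gslope = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    const double dp = has_mask ? d[i] * m[i] : d[i];
    if (a[i] > 0) {
      g[i] = dp;
    } else {
      g[i] = dp * slope;
      gslope += dp * a[i];
    }
  }
  return gslope;
}

// Normalize rows of Z with (mean, invstd), then scale/shift: A = g*Zh + be.
static void bn_apply(const arma::mat& Z, const arma::vec& mu,
                     const arma::vec& inv, const arma::vec& g,
                     const arma::vec& be, arma::mat& Zh, arma::mat& A) {
  const arma::uword R = Z.n_rows, C = Z.n_cols;
  for (arma::uword j = 0; j < C; ++j) {
    const double* z = Z.colptr(j);
    double* zh = Zh.colptr(j);
    double* av = A.colptr(j);
    for (arma::uword i = 0; i < R; ++i) {
      const double h = (z[i] - mu[i]) * inv[i];
      zh[i] = h;
      av[i] = g[i] * h + be[i];
    }
  }
}

// Standard batch-norm backward over rows; returns dZ, fills dg/dbe.
static arma::mat bn_backward(const arma::mat& dA, const arma::mat& Zh,
                             const arma::vec& inv, const arma::vec& g,
                             arma::vec& dg, arma::vec& dbe) {
  const double M = static_cast<double>(dA.n_cols);
  arma::mat dZh = dA.each_col() % g;
  dg = arma::sum(dA % Zh, 1);
  dbe = arma::sum(dA, 1);
  arma::vec s1 = arma::sum(dZh, 1);
  arma::vec s2 = arma::sum(dZh % Zh, 1);
  arma::mat dZ = M * dZh;
  dZ.each_col() -= s1;
  dZ -= Zh.each_col() % s2;
  dZ.each_col() %= inv / M;
  return dZ;
}

// One forward (and optional backward) pass over a batch.
// [[Rcpp::export]]
List cpp_fbccnn_batch(const arma::mat& X, const List params,
                      const List bn_state, const IntegerVector dims,
                      double dropout, bool training,
                      const arma::ivec& y) {
  const int Nch = dims["nch"], W = dims["width"], K2 = dims["k2"],
            S2 = dims["s2"], T = dims["n_pos"], Ncl = dims["n_classes"];
  const arma::mat W1 = params["W1"], W2 = params["W2"], W3 = params["W3"];
  const arma::vec b1 = params["b1"], g1 = params["g1"], be1 = params["be1"];
  const arma::vec b2 = params["b2"], g2 = params["g2"], be2 = params["be2"];
  const arma::vec b3 = params["b3"];
  const double a1 = params["a1"], a2 = params["a2"];
  const int Nk1 = W1.n_rows, Nk2 = W2.n_rows;
  const int B = X.n_cols / W;

  // ---- layer 1: channel-mixing convolution ----
  arma::mat Z1 = W1 * X;
  Z1.each_col() += b1;
  arma::vec m1, v1;
  if (training) {
    m1 = arma::mean(Z1, 1);
    v1 = arma::mean(arma::square(Z1), 1) - arma::square(m1);
  } else {
    m1 = as<arma::vec>(bn_state["m1"]);
    v1 = as<arma::vec>(bn_state["v1"]);
  }
  arma::vec inv1 = 1.0 / arma::sqrt(v1 + BN_EPS);
  arma::mat Z1h(Z1.n_rows, Z1.n_cols), A1(Z1.n_rows, Z1.n_cols);
  bn_apply(Z1, m1, inv1, g1, be1, Z1h, A1);
  arma::mat mask1, D1(A1.n_rows, A1.n_cols);
  if (training && dropout > 0) mask1.set_size(A1.n_rows, A1.n_cols);
  prelu_dropout(A1, D1, mask1, a1, dropout, training);

  // ---- layer 2: width convolution via im2col ----
  const int patch = Nk1 * K2;
  arma::mat Pat(patch, T * B);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      std::memcpy(Pat.colptr(b * T + t), D1.colptr(b * W + t * S2),
                  patch * sizeof(double));
    }
  }
  arma::mat Z2 = W2 * Pat;
  Z2.each_col() += b2;
  arma::vec m2, v2;
  if (training) {
    m2 = arma::mean(Z2, 1);
    v2 = arma::mean(arma::square(Z2), 1) - arma::square(m2);
  } else {
    m2 = as<arma::vec>(bn_state["m2"]);
    v2 = as<arma::vec>(bn_state["v2"]);
  }
  arma::vec inv2 = 1.0 / arma::sqrt(v2 + BN_EPS);
  arma::mat Z2h(Z2.n_rows, Z2.n_cols), A2(Z2.n_rows, Z2.n_cols);
  bn_apply(Z2, m2, inv2, g2, be2, Z2h, A2);
  arma::mat mask2, D2(A2.n_rows, A2.n_cols);
  if (training && dropout > 0) mask2.set_size(A2.n_rows, A2.n_cols);
  prelu_dropout(A2, D2, mask2, a2, dropout, training);

  // ---- dense output ----
  const arma::mat Fm(D2.memptr(), Nk2 * T, B);   // reshape view
  arma::mat S = W3 * Fm;
  S.each_col() += b3;

  List out = List::create(Named("scores") = S);
  if (y.n_elem == 0) return out;

  // ---- softmax cross-entropy + backward ----
  arma::mat P = S;
  P.each_row() -= arma::max(P, 0);
  P = arma::exp(P);
  P.each_row() /= arma::sum(P, 0);
  double loss = 0.0;
  int hits = 0;
  arma::mat dS = P;
  for (int b = 0; b < B; ++b) {
    const int k = y[b] - 1;
    loss -= std::log(std::max(P(k, b), 1e-12));
    dS(k, b) -= 1.0;
    if (static_cast<int>(arma::index_max(S.col(b))) == k) ++hits;
  }
  dS /= static_cast<double>(B);

  arma::mat gW3 = dS * Fm.t();
  arma::vec gb3 = arma::sum(dS, 1);
  arma::mat dFm = W3.t() * dS;
  const arma::mat dD2(dFm.memptr(), Nk2, T * B);

  const bool has_mask = training && dropout > 0;
  arma::mat dOut2 = has_mask ? dD2 % mask2 : dD2;  // dropout backward
  arma::mat dA2(Nk2, T * B);
  // reuse prelu backward on the already-unmasked gradient
  double ga2 = prelu_dropout_backward(dOut2, A2, mask2, a2, false, dA2);
  arma::vec gg2, gbe2;
  arma::mat dZ2 = bn_backward(dA2, Z2h, inv2, g2, gg2, gbe2);
  arma::mat gW2 = dZ2 * Pat.t();
  arma::vec gb2 = arma::sum(dZ2, 1);
  arma::mat dPat = W2.t() * dZ2;

  arma::mat dD1(Nk1, W * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      double* dst = dD1.colptr(b * W + t * S2);
      const double* src = dPat.colptr(b * T + t);
      for (int i = 0; i < patch; ++i) dst[i] += src[i];
    }
  }
  arma::mat dOut1 = has_mask ? dD1 % mask1 : dD1;
  arma::mat dA1(Nk1, W * B);
  double ga1 = prelu_dropout_backward(dOut1, A1, mask1, a1, false, dA1);
  arma::vec gg1, gbe1;
  arma::mat dZ1 = bn_backward(dA1, Z1h, inv1, g1, gg1, gbe1);
  arma::mat gW1 = dZ1 * X.t();
  arma::vec gb1 = arma::sum(dZ1, 1);

  out["loss"] = loss;
  out["hits"] = hits;
  out["grads"] = List::create(
    Named("W1") = gW1, Named("b1") = gb1, Named("g1") = gg1,
    Named("be1") = gbe1, Named("a1") = ga1,
    Named("W2") = gW2, Named("b2") = gb2, Named("g2") = gg2,
    Named("be2") = gbe2, Named("a2") = ga2,
    Named("W3") = gW3, Named("b3") = gb3);
  out["batch_stats"] = List::create(
    Named("m1") = m1, Named("v1") = v1,
    Named("m2") = m2, Named("v2") = v2);
  return out;
}

// ---------------------------------------------------------------------------
// Full training loop. Same mathematics as cpp_fbccnn_batch (the two are
// cross-checked in the test suite) but with persistent workspaces, fused
// elementwise passes and an internal xorshift128+ RNG for dropout masks and
// shuffling, seeded from R's RNG stream so a set.seed() on the R side makes
// the whole run reproducible.
// ---------------------------------------------------------------------------

struct XorShift {
  uint64_t s0, s1;
  void seed_from_r() {
    s0 = (static_cast<uint64_t>(unif_rand() * 4294967295.0) << 32) |
         static_cast<uint64_t>(unif_rand() * 4294967295.0);
    s1 = (static_cast<uint64_t>(unif_rand() * 4294967295.0) << 32) |
         static_cast<uint64_t>(unif_rand() * 4294967295.0);
    if (s0 == 0 && s1 == 0) s1 = 0x9E3779B97F4A7C15ULL;
  }
  inline uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double runif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  inline int below(int n) { return static_cast<int>(runif() * n); }
};

struct ParamState {
  arma::mat val, m, v;   // value and Adam moments (scalars are 1x1)
};

static void adam_update(ParamState& p, const arma::mat& grad, double lr,
                        double b1, double b2, double eps, double corr) {
  p.m = b1 * p.m + (1 - b1) * grad;
  p.v = b2 * p.v + (1 - b2) * arma::square(grad);
  p.val -= corr * lr * p.m / (arma::sqrt(p.v) + eps);
}


// Fused BN-apply + PReLU + inverted dropout over one layer's maps.
// Reads Z (pre-normalization), writes the dropped activations into `out`
// and the per-element keep decision (0/1) into `mask`.
static void fused_forward(const arma::mat& Z, const arma::vec& mu,
                          const arma::vec& inv, const arma::mat& g,
                          const arma::mat& be, double slope, double dropout,
                          double keep, XorShift& rng, arma::mat& out,
                          std::vector<unsigned char>& mask) {
  const arma::uword R = Z.n_rows, C = Z.n_cols;
  const double inv_keep = dropout > 0 ? 1.0 / keep : 1.0;
  const double* gp = g.memptr();
  const double* bp = be.memptr();
  const double* mp = mu.memptr();
  const double* ip = inv.memptr();
  const double* z = Z.memptr();
  double* d = out.memptr();
  unsigned char* mk = mask.data();
  if (dropout > 0) {
    for (arma::uword j = 0; j < C; ++j, z += R, d += R, mk += R) {
      for (arma::uword i = 0; i < R; ++i) {
        const double a = gp[i] * (z[i] - mp[i]) * ip[i] + bp[i];
        const double pr = a > 0 ? a : slope * a;
        const unsigned char m = rng.runif() >= dropout;
        mk[i] = m;
        d[i] = pr * (m * inv_keep);
      }
    }
  } else {
    for (arma::uword j = 0; j < C; ++j, z += R, d += R) {
      for (arma::uword i = 0; i < R; ++i) {
        const double a = gp[i] * (z[i] - mp[i]) * ip[i] + bp[i];
        d[i] = a > 0 ? a : slope * a;
      }
    }
  }
}

// Fused backward through dropout + PReLU + the reduction half of batch
// norm: writes dA (gradient at the BN output scaled path) and accumulates
// the row sums needed for the BN gradient, then finishes dZ in a second
// pass (dA is overwritten with dZ). Returns the PReLU slope gradient.
static double fused_backward(const arma::mat& dOut,
                             const std::vector<unsigned char>& mask,
                             const arma::mat& Z, const arma::vec& mu,
                             const arma::vec& inv, const arma::mat& g,
                             const arma::mat& be, double slope,
                             double dropout, double keep, arma::mat& dA,
                             arma::vec& s_dg, arma::vec& s_dbe,
                             arma::vec& s_1, arma::vec& s_2) {
  const arma::uword R = Z.n_rows, C = Z.n_cols;
  const double inv_keep = dropout > 0 ? 1.0 / keep : 1.0;
  const double* gp = g.memptr();
  const double* bp = be.memptr();
  const double* mp = mu.memptr();
  const double* ip = inv.memptr();
  const double* z = Z.memptr();
  const double* dd = dOut.memptr();
  const unsigned char* mk = mask.data();
  double* da = dA.memptr();
  double ga = 0.0;
  {
    const double* zj = z;
    const double* ddj = dd;
    const unsigned char* mkj = mk;
    double* daj = da;
    for (arma::uword j = 0; j < C; ++j, zj += R, ddj += R, mkj += R,
                   daj += R) {
      for (arma::uword i = 0; i < R; ++i) {
        const double zh = (zj[i] - mp[i]) * ip[i];
        const double a = gp[i] * zh + bp[i];
        const double dp =
            dropout > 0 ? ddj[i] * (mkj[i] * inv_keep) : ddj[i];
        double dai;
        if (a > 0) {
          dai = dp;
        } else {
          dai = dp * slope;
          ga += dp * a;
        }
        daj[i] = dai;
        s_dg[i] += dai * zh;
        s_dbe[i] += dai;
        const double dzh = dai * gp[i];
        s_1[i] += dzh;
        s_2[i] += dzh * zh;
      }
    }
  }
  const double M = static_cast<double>(C);
  {
    const double* zj = z;
    double* daj = da;
    for (arma::uword j = 0; j < C; ++j, zj += R, daj += R) {
      for (arma::uword i = 0; i < R; ++i) {
        const double zh = (zj[i] - mp[i]) * ip[i];
        const double dzh = daj[i] * gp[i];
        daj[i] = (ip[i] / M) * (M * dzh - s_1[i] - zh * s_2[i]);
      }
    }
  }
  return ga;
}

// [[Rcpp::export]]
List cpp_fbccnn_train(const arma::cube& x, const arma::ivec& y,
                      const List params, const List bn_state,
                      const IntegerVector dims, double dropout,
                      int n_epochs, int batch_size, double lr) {
  const int W = dims["width"], K2 = dims["k2"], S2 = dims["s2"],
            T = dims["n_pos"], Ncl = dims["n_classes"];
  const int Nch = x.n_rows, N = x.n_slices;
  ParamState W1{as<arma::mat>(params["W1"])}, b1{as<arma::mat>(params["b1"])},
      g1{as<arma::mat>(params["g1"])}, be1{as<arma::mat>(params["be1"])},
      a1{as<arma::mat>(params["a1"])}, W2{as<arma::mat>(params["W2"])},
      b2{as<arma::mat>(params["b2"])}, g2{as<arma::mat>(params["g2"])},
      be2{as<arma::mat>(params["be2"])}, a2{as<arma::mat>(params["a2"])},
      W3{as<arma::mat>(params["W3"])}, b3{as<arma::mat>(params["b3"])};
  ParamState* all[] = {&W1, &b1, &g1, &be1, &a1, &W2, &b2, &g2, &be2, &a2,
                       &W3, &b3};
  for (ParamState* p : all) {
    p->m = arma::zeros(p->val.n_rows, p->val.n_cols);
    p->v = p->m;
  }
  const int Nk1 = W1.val.n_rows, Nk2 = W2.val.n_rows;
  const int patch = Nk1 * K2, Nf = Nk2 * T;
  arma::vec rm1 = as<arma::vec>(bn_state["m1"]),
            rv1 = as<arma::vec>(bn_state["v1"]),
            rm2 = as<arma::vec>(bn_state["m2"]),
            rv2 = as<arma::vec>(bn_state["v2"]);

  XorShift rng;
  rng.seed_from_r();
  keep_large_allocs();

  // Workspaces, (re)sized only when the batch width changes.
  arma::mat X, Z1, D1, dA1, Pat, Z2, D2, dA2, S, dPat;
  std::vector<unsigned char> mask1, mask2;
  int curB = -1;
  auto size_ws = [&](int B) {
    if (B == curB) return;
    curB = B;
    X.set_size(Nch, W * B);
    Z1.set_size(Nk1, W * B); D1.set_size(Nk1, W * B);
    mask1.resize(static_cast<size_t>(Nk1) * W * B);
    dA1.set_size(Nk1, W * B);
    Pat.set_size(patch, T * B); dPat.set_size(patch, T * B);
    Z2.set_size(Nk2, T * B); D2.set_size(Nk2, T * B);
    mask2.resize(static_cast<size_t>(Nk2) * T * B);
    dA2.set_size(Nk2, T * B);
    S.set_size(Ncl, B);
  };

  arma::vec m1(Nk1), v1(Nk1), inv1(Nk1), m2(Nk2), v2(Nk2), inv2(Nk2);
  arma::vec s_dg(std::max(Nk1, Nk2)), s_dbe(std::max(Nk1, Nk2)),
      s_1(std::max(Nk1, Nk2)), s_2(std::max(Nk1, Nk2));
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  arma::mat history(n_epochs, 2);
  const double keep = 1.0 - dropout;
  const double adam_b1 = 0.9, adam_b2 = 0.999, adam_eps = 1e-8;
  long t_step = 0;

  for (int ep = 0; ep < n_epochs; ++ep) {
    // Fisher-Yates shuffle
    for (int i = N - 1; i > 0; --i) {
      std::swap(order[i], order[rng.below(i + 1)]);
    }
    double ep_loss = 0.0;
    long ep_hits = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int B = std::min(batch_size, N - start);
      size_ws(B);
      for (int b = 0; b < B; ++b) {
        std::memcpy(X.colptr(b * W), x.slice_colptr(order[start + b], 0),
                    Nch * W * sizeof(double));
      }

      // ---- forward, layer 1 ----
      Z1 = W1.val * X;
      Z1.each_col() += b1.val.col(0);
      row_stats(Z1, m1, v1);
      inv1 = 1.0 / arma::sqrt(v1 + BN_EPS);
      rm1 = 0.9 * rm1 + 0.1 * m1;
      rv1 = 0.9 * rv1 + 0.1 * v1;
      fused_forward(Z1, m1, inv1, g1.val, be1.val, a1.val(0, 0), dropout,
                    keep, rng, D1, mask1);

      // ---- forward, layer 2 ----
      for (int b = 0; b < B; ++b) {
        for (int t = 0; t < T; ++t) {
          std::memcpy(Pat.colptr(b * T + t), D1.colptr(b * W + t * S2),
                      patch * sizeof(double));
        }
      }
      Z2 = W2.val * Pat;
      Z2.each_col() += b2.val.col(0);
      row_stats(Z2, m2, v2);
      inv2 = 1.0 / arma::sqrt(v2 + BN_EPS);
      rm2 = 0.9 * rm2 + 0.1 * m2;
      rv2 = 0.9 * rv2 + 0.1 * v2;
      fused_forward(Z2, m2, inv2, g2.val, be2.val, a2.val(0, 0), dropout,
                    keep, rng, D2, mask2);

      // ---- dense + softmax ----
      const arma::mat Fm(D2.memptr(), Nf, B, false, true);
      S = W3.val * Fm;
      S.each_col() += b3.val.col(0);
      arma::mat P = S;
      P.each_row() -= arma::max(P, 0);
      P = arma::exp(P);
      P.each_row() /= arma::sum(P, 0);
      for (int b = 0; b < B; ++b) {
        const int k = y[order[start + b]] - 1;
        ep_loss -= std::log(std::max(P(k, b), 1e-12));
        if (static_cast<int>(arma::index_max(S.col(b))) == k) ++ep_hits;
        P(k, b) -= 1.0;
      }
      P /= static_cast<double>(B);    // now the score gradient

      arma::mat gW3 = P * Fm.t();
      arma::mat gb3 = arma::sum(P, 1);
      arma::mat dFm = W3.val.t() * P;
      arma::mat dD2(dFm.memptr(), Nk2, T * B, false, true);

      // ---- backward, layer 2 (two fused passes) ----
      s_dg.zeros(); s_dbe.zeros(); s_1.zeros(); s_2.zeros();
      const double ga2 =
          fused_backward(dD2, mask2, Z2, m2, inv2, g2.val, be2.val,
                         a2.val(0, 0), dropout, keep, dA2, s_dg, s_dbe,
                         s_1, s_2);
      arma::mat gg2 = s_dg.head(Nk2), gbe2 = s_dbe.head(Nk2);
      arma::mat gW2 = dA2 * Pat.t();           // dA2 now holds dZ2
      arma::mat gb2 = arma::sum(dA2, 1);
      dPat = W2.val.t() * dA2;

      // ---- col2im ----
      D1.zeros();                              // reuse D1 as dD1
      for (int b = 0; b < B; ++b) {
        for (int t = 0; t < T; ++t) {
          double* dst = D1.colptr(b * W + t * S2);
          const double* src = dPat.colptr(b * T + t);
          for (int i = 0; i < patch; ++i) dst[i] += src[i];
        }
      }

      // ---- backward, layer 1 ----
      s_dg.zeros(); s_dbe.zeros(); s_1.zeros(); s_2.zeros();
      const double ga1 =
          fused_backward(D1, mask1, Z1, m1, inv1, g1.val, be1.val,
                         a1.val(0, 0), dropout, keep, dA1, s_dg, s_dbe,
                         s_1, s_2);
      arma::mat gg1 = s_dg.head(Nk1), gbe1 = s_dbe.head(Nk1);
      arma::mat gW1 = dA1 * X.t();             // dA1 now holds dZ1
      arma::mat gb1 = arma::sum(dA1, 1);

      // ---- Adam ----
      ++t_step;
      const double corr = std::sqrt(1.0 - std::pow(adam_b2, t_step)) /
                          (1.0 - std::pow(adam_b1, t_step));
      adam_update(W1, gW1, lr, adam_b1, adam_b2, adam_eps, corr);
      adam_update(b1, gb1, lr, adam_b1, adam_b2, adam_eps, corr);
      adam_update(g1, gg1, lr, adam_b1, adam_b2, adam_eps, corr);
      adam_update(be1, gbe1, lr, adam_b1, adam_b2, adam_eps, corr);
      adam_update(a1, arma::mat(1, 1, arma::fill::value(ga1)), lr, adam_b1,
                  adam_b2, adam_eps, corr);
      adam_update(W2, gW2, lr, adam_b1, adam_b2, adam_eps, corr);
      adam_update(b2, gb2, lr, adam_b1, adam_b2, adam_eps, corr);
      adam_update(g2, gg2, lr, adam_b1, adam_b2, adam_eps, corr);
      adam_update(be2, gbe2, lr, adam_b1, adam_b2, adam_eps, corr);
      adam_update(a2, arma::mat(1, 1, arma::fill::value(ga2)), lr, adam_b1,
                  adam_b2, adam_eps, corr);
      adam_update(W3, gW3, lr, adam_b1, adam_b2, adam_eps, corr);
      adam_update(b3, gb3, lr, adam_b1, adam_b2, adam_eps, corr);
    }
    history(ep, 0) = ep_loss / N;
    history(ep, 1) = 100.0 * ep_hits / N;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    Named("params") = List::create(
      Named("W1") = W1.val, Named("b1") = b1.val, Named("g1") = g1.val,
      Named("be1") = be1.val, Named("a1") = a1.val(0, 0),
      Named("W2") = W2.val, Named("b2") = b2.val, Named("g2") = g2.val,
      Named("be2") = be2.val, Named("a2") = a2.val(0, 0),
      Named("W3") = W3.val, Named("b3") = b3.val),
    Named("bn") = List::create(Named("m1") = rm1, Named("v1") = rv1,
                               Named("m2") = rm2, Named("v2") = rv2),
    Named("history") = history);
}
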
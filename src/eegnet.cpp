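// Compact convolutional EEG decoder: forward, backward and saliency kernels.
//
// The architecture is the EEGNet-8,2 family: temporal convolution (F1 kernels
// shared across channels) -> batch-norm -> depthwise spatial convolution over
// all C channels (depth multiplier D, max-norm constrained in R) -> batch-norm
// -> ELU -> average-pool -> dropout -> one or more separable convolution
// blocks (depthwise temporal + pointwise) -> flatten -> dense -> softmax.
//
// Activations are held as cubes (feature_rows x time x batch).  Batch-norm
// uses population statistics within the batch during training and running
// statistics at inference; dropout is inverted (scaled at train time) and
// drawn from the R RNG so that R-level set.seed() fixes training exactly.

#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

// y(t) = sum_l x(t + l - padL) w(l), zero padded, padL = (L-1)/2 ("same")
static void conv_rows_same(const mat& X, const vec& w, mat& Y) {
  const int T = X.n_cols, L = w.n_elem, padL = (L - 1) / 2;
  Y.zeros(X.n_rows, T);
  for (int l = 0; l < L; ++l) {
    int shift = l - padL;
    int t0 = std::max(0, -shift), t1 = std::min(T, T - shift);
    if (t1 <= t0) continue;
    Y.cols(t0, t1 - 1) += w(l) * X.cols(t0 + shift, t1 - 1 + shift);
  }
}

// dX(t+shift) += dY(t) w(l)
static void conv_rows_same_backX(const mat& dY, const vec& w, mat& dX) {
  const int T = dY.n_cols, L = w.n_elem, padL = (L - 1) / 2;
  for (int l = 0; l < L; ++l) {
    int shift = l - padL;
    int t0 = std::max(0, -shift), t1 = std::min(T, T - shift);
    if (t1 <= t0) continue;
    dX.cols(t0 + shift, t1 - 1 + shift) += w(l) * dY.cols(t0, t1 - 1);
  }
}

// dw(l) += sum_rows,t dY(t) x(t+shift)
static void conv_rows_same_backW(const mat& dY, const mat& X, vec& dw) {
  const int T = dY.n_cols, L = dw.n_elem, padL = (L - 1) / 2;
  for (int l = 0; l < L; ++l) {
    int shift = l - padL;
    int t0 = std::max(0, -shift), t1 = std::min(T, T - shift);
    if (t1 <= t0) continue;
    dw(l) += accu(dY.cols(t0, t1 - 1) % X.cols(t0 + shift, t1 - 1 + shift));
  }
}

struct BNCache {
  vec mu, invsd;   // per group
  cube xhat;
};

// Grouped batch-norm over rows: row r belongs to group grp(r); statistics are
// taken over all rows of the group, all time points and the whole batch.
static void bn_forward(const cube& X, const uvec& grp, int G,
                       const vec& gamma, const vec& beta,
                       vec& run_m, vec& run_v,
                       bool train, cube& Y, BNCache& cache) {
  const int R = X.n_rows, T = X.n_cols, N = X.n_slices;
  vec mu(G), var(G);
  if (train) {
    vec s1(G, fill::zeros), s2(G, fill::zeros), cnt(G, fill::zeros);
    for (int n = 0; n < N; ++n) {
      vec rs = sum(X.slice(n), 1);
      vec rs2 = sum(square(X.slice(n)), 1);
      for (int r = 0; r < R; ++r) {
        s1(grp(r)) += rs(r);
        s2(grp(r)) += rs2(r);
        cnt(grp(r)) += T;
      }
    }
    mu = s1 / cnt;
    var = s2 / cnt - square(mu);
    var.transform([](double v) { return v > 0 ? v : 0.0; });
    run_m = (1.0 - BN_MOMENTUM) * run_m + BN_MOMENTUM * mu;
    run_v = (1.0 - BN_MOMENTUM) * run_v + BN_MOMENTUM * var;
  } else {
    mu = run_m;
    var = run_v;
  }
  vec invsd = 1.0 / sqrt(var + BN_EPS);
  vec mu_r(R), is_r(R), g_r(R), b_r(R);
  for (int r = 0; r < R; ++r) {
    mu_r(r) = mu(grp(r));
    is_r(r) = invsd(grp(r));
    g_r(r) = gamma(grp(r));
    b_r(r) = beta(grp(r));
  }
  Y.set_size(R, T, N);
  cache.xhat.set_size(R, T, N);
  for (int n = 0; n < N; ++n) {
    mat& xs = cache.xhat.slice(n);
    xs = X.slice(n);
    xs.each_col() -= mu_r;
    xs.each_col() %= is_r;
    mat& ys = Y.slice(n);
    ys = xs;
    ys.each_col() %= g_r;
    ys.each_col() += b_r;
  }
  cache.mu = mu;
  cache.invsd = invsd;
}

// Backward through grouped batch-norm (training statistics).  When
// `train_stats` is false the layer used running statistics, so the pass is a
// plain affine map.
static void bn_backward(const cube& dY, const BNCache& cache, const uvec& grp,
                        int G, const vec& gamma, bool train_stats,
                        cube& dX, vec& dgamma, vec& dbeta) {
  const int R = dY.n_rows, T = dY.n_cols, N = dY.n_slices;
  dgamma.zeros(G);
  dbeta.zeros(G);
  vec cnt(G, fill::zeros);
  for (int n = 0; n < N; ++n) {
    vec sdy = sum(dY.slice(n), 1);
    vec sdyxh = sum(dY.slice(n) % cache.xhat.slice(n), 1);
    for (int r = 0; r < R; ++r) {
      dbeta(grp(r)) += sdy(r);
      dgamma(grp(r)) += sdyxh(r);
      cnt(grp(r)) += T;
    }
  }
  vec a_r(R), m1_r(R), m2_r(R);
  for (int r = 0; r < R; ++r) {
    int g = grp(r);
    a_r(r) = gamma(g) * cache.invsd(g);
    m1_r(r) = dbeta(g) / cnt(g);
    m2_r(r) = dgamma(g) / cnt(g);
  }
  dX.set_size(R, T, N);
  for (int n = 0; n < N; ++n) {
    mat& ds = dX.slice(n);
    ds = dY.slice(n);
    if (train_stats) {
      ds.each_col() -= m1_r;
      mat t = cache.xhat.slice(n);
      t.each_col() %= m2_r;
      ds -= t;
    }
    ds.each_col() %= a_r;
  }
}

static void elu_forward(const cube& X, cube& Y) {
  Y = X;
  Y.transform([](double v) { return v > 0 ? v : std::expm1(v); });
}

static void elu_backward(const cube& dY, const cube& Yact, cube& dX) {
  dX = dY;
  const int n = dX.n_elem;
  for (int i = 0; i < n; ++i)
    if (Yact(i) <= 0) dX(i) *= (Yact(i) + 1.0);
}

// non-overlapping average pooling along time
static void pool_forward(const cube& X, int p, cube& Y) {
  const int R = X.n_rows, T = X.n_cols, N = X.n_slices, To = T / p;
  Y.zeros(R, To, N);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < To; ++t)
      Y.slice(n).col(t) = mean(X.slice(n).cols(t * p, t * p + p - 1), 1);
}

static void pool_backward(const cube& dY, int p, int T, cube& dX) {
  const int R = dY.n_rows, To = dY.n_cols, N = dY.n_slices;
  dX.zeros(R, T, N);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < To; ++t)
      for (int j = 0; j < p; ++j)
        dX.slice(n).col(t * p + j) = dY.slice(n).col(t) / p;
}

struct Spec {
  int C, T, Z, F1, D, M2, F2, L, Ls, pool1, pool2, nblocks;
};

static Spec read_spec(const List& spec) {
  Spec s;
  s.C = as<int>(spec["C"]); s.T = as<int>(spec["T"]); s.Z = as<int>(spec["Z"]);
  s.F1 = as<int>(spec["F1"]); s.D = as<int>(spec["D"]); s.F2 = as<int>(spec["F2"]);
  s.L = as<int>(spec["L"]); s.Ls = as<int>(spec["Ls"]);
  s.pool1 = as<int>(spec["pool1"]); s.pool2 = as<int>(spec["pool2"]);
  s.nblocks = as<int>(spec["nblocks"]);
  s.M2 = s.F1 * s.D;
  return s;
}

// persistent im2col buffer: avoids re-faulting ~80 MB of pages every batch
static mat& patch_buffer() {
  static mat P;
  return P;
}

struct Acts {
  mat* P;                   // im2col patches of the input, (N*C*T) x L
  cube A1, A1bn;            // temporal conv and its BN output
  BNCache bn1;
  cube Z2, Z2bn, E2, P1, D1;  // depthwise conv, BN, ELU, pool, dropout
  BNCache bn2;
  std::vector<cube> Bdep, Bpt, Bbn, Belu, Bpool, Bdrop;
  std::vector<BNCache> bn3;
  mat flat, logits, probs;
  std::vector<cube> masks;    // dropout masks (post-pool1 and per block)
};

// Full forward pass.  train: batch BN stats + dropout; freeze_front: the
// first four layers (temporal conv, BN, depthwise conv, BN) run with running
// statistics even while training (fine-tuning contract).
static void forward_pass(const List& par, const Spec& s, const cube& X,
                         bool train, bool freeze_front, double dropout,
                         Acts& a, List& par_out) {
  const int N = X.n_slices;
  mat Wt = as<mat>(par["Wt"]);           // L x F1
  mat Wdw = as<mat>(par["Wdw"]);         // C x M2
  vec g1 = as<vec>(par["g1"]), b1 = as<vec>(par["b1"]);
  vec m1 = as<vec>(par["m1"]), v1 = as<vec>(par["v1"]);
  vec g2 = as<vec>(par["g2"]), b2 = as<vec>(par["b2"]);
  vec m2 = as<vec>(par["m2"]), v2 = as<vec>(par["v2"]);

  bool front_train = train && !freeze_front;

  // temporal convolution as im2col + gemm; row order (f*C + c)
  a.A1.set_size(s.F1 * s.C, s.T, N);
  const int NC = N * s.C, padL = (s.L - 1) / 2;
  mat XB(NC, s.T);
  for (int n = 0; n < N; ++n)
    XB.rows(n * s.C, (n + 1) * s.C - 1) = X.slice(n);
  mat& P = patch_buffer();
  P.set_size((size_t)NC * s.T, s.L);
  a.P = &P;
  for (int l = 0; l < s.L; ++l) {
    int shift = l - padL;
    int t0 = std::max(0, -shift), t1 = std::min(s.T, s.T - shift);
    double* pc = P.colptr(l);
    if (t0 > 0)
      std::fill(pc, pc + (size_t)t0 * NC, 0.0);
    if (t1 < s.T)
      std::fill(pc + (size_t)t1 * NC, pc + (size_t)s.T * NC, 0.0);
    if (t1 > t0)
      std::memcpy(pc + (size_t)t0 * NC, XB.colptr(t0 + shift),
                  sizeof(double) * (size_t)NC * (t1 - t0));
  }
  mat Yall = P * Wt;   // (NC*T) x F1
  for (int f = 0; f < s.F1; ++f) {
    mat Yf(Yall.colptr(f), NC, s.T, false, true);
    for (int n = 0; n < N; ++n)
      a.A1.slice(n).rows(f * s.C, (f + 1) * s.C - 1) =
        Yf.rows(n * s.C, (n + 1) * s.C - 1);
  }
  uvec grp1(s.F1 * s.C);
  for (int f = 0; f < s.F1; ++f)
    for (int c = 0; c < s.C; ++c) grp1(f * s.C + c) = f;
  bn_forward(a.A1, grp1, s.F1, g1, b1, m1, v1, front_train, a.A1bn, a.bn1);

  // depthwise spatial convolution: out row m = f*D + d mixes rows of block f
  a.Z2.set_size(s.M2, s.T, N);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < s.F1; ++f) {
      mat W_f = Wdw.cols(f * s.D, (f + 1) * s.D - 1);   // C x D
      a.Z2.slice(n).rows(f * s.D, (f + 1) * s.D - 1) =
        W_f.t() * a.A1bn.slice(n).rows(f * s.C, (f + 1) * s.C - 1);
    }
  uvec grp2 = regspace<uvec>(0, s.M2 - 1);
  bn_forward(a.Z2, grp2, s.M2, g2, b2, m2, v2, front_train, a.Z2bn, a.bn2);
  elu_forward(a.Z2bn, a.E2);
  pool_forward(a.E2, s.pool1, a.P1);

  const int T1 = s.T / s.pool1;
  a.masks.clear();
  cube mask1(s.M2, T1, N, fill::ones);
  if (train && dropout > 0) {
    for (uword i = 0; i < mask1.n_elem; ++i)
      mask1(i) = (R::unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
  }
  a.masks.push_back(mask1);
  a.D1 = a.P1 % mask1;

  // separable blocks
  a.Bdep.assign(s.nblocks, cube()); a.Bpt.assign(s.nblocks, cube());
  a.Bbn.assign(s.nblocks, cube()); a.Belu.assign(s.nblocks, cube());
  a.Bpool.assign(s.nblocks, cube()); a.Bdrop.assign(s.nblocks, cube());
  a.bn3.assign(s.nblocks, BNCache());
  cube cur = a.D1;
  for (int k = 0; k < s.nblocks; ++k) {
    std::string sk = std::to_string(k);
    mat Wdep = as<mat>(par["Wdep" + sk]);   // Lk x Min
    mat Wpt = as<mat>(par["Wpt" + sk]);     // Mout x Min
    vec g3 = as<vec>(par["g3" + sk]), b3 = as<vec>(par["b3" + sk]);
    vec m3 = as<vec>(par["m3" + sk]), v3 = as<vec>(par["v3" + sk]);
    const int Min = Wpt.n_cols, Mout = Wpt.n_rows, Tk = cur.n_cols;
    cube dep(Min, Tk, N);
    mat Bm(N, Tk), Om;
    for (int m = 0; m < Min; ++m) {
      for (int n = 0; n < N; ++n) Bm.row(n) = cur.slice(n).row(m);
      conv_rows_same(Bm, Wdep.col(m), Om);
      for (int n = 0; n < N; ++n) dep.slice(n).row(m) = Om.row(n);
    }
    a.Bdep[k] = dep;
    cube pt(Mout, Tk, N);
    for (int n = 0; n < N; ++n) pt.slice(n) = Wpt * dep.slice(n);
    a.Bpt[k] = pt;
    uvec grp3 = regspace<uvec>(0, Mout - 1);
    cube bnout;
    bn_forward(pt, grp3, Mout, g3, b3, m3, v3, train, bnout, a.bn3[k]);
    a.Bbn[k] = bnout;
    cube eluo;
    elu_forward(bnout, eluo);
    a.Belu[k] = eluo;
    cube pooled;
    if (k == 0) pool_forward(eluo, s.pool2, pooled); else pooled = eluo;
    a.Bpool[k] = pooled;
    cube mk(pooled.n_rows, pooled.n_cols, N, fill::ones);
    if (train && dropout > 0) {
      for (uword i = 0; i < mk.n_elem; ++i)
        mk(i) = (R::unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
    }
    a.masks.push_back(mk);
    a.Bdrop[k] = pooled % mk;
    cur = a.Bdrop[k];
    // write updated running stats back
    if (train) { par_out["m3" + sk] = m3; par_out["v3" + sk] = v3; }
  }
  if (front_train) {
    par_out["m1"] = m1; par_out["v1"] = v1;
    par_out["m2"] = m2; par_out["v2"] = v2;
  }

  // flatten (row-major over rows then time) and dense softmax
  const int feat = cur.n_rows * cur.n_cols;
  a.flat.set_size(feat, N);
  for (int n = 0; n < N; ++n)
    a.flat.col(n) = vectorise(cur.slice(n));
  mat Wfc = as<mat>(par["Wfc"]);
  vec bfc = as<vec>(par["bfc"]);
  a.logits = Wfc * a.flat;
  a.logits.each_col() += bfc;
  a.probs.set_size(s.Z, N);
  for (int n = 0; n < N; ++n) {
    vec l = a.logits.col(n);
    l -= l.max();
    vec e = exp(l);
    a.probs.col(n) = e / accu(e);
  }
}

// [[Rcpp::export]]
List eegnet_pass(List par, List spec, const arma::cube& X,
                 const arma::ivec& y, bool train, bool freeze_front,
                 double dropout) {
  Spec s = read_spec(spec);
  const int N = X.n_slices;
  List par_out = List::create();   // updated running stats only
  Acts a;
  forward_pass(par, s, X, train, freeze_front, dropout, a, par_out);

  // cross-entropy
  double loss = 0;
  mat dlogits = a.probs;
  for (int n = 0; n < N; ++n) {
    loss -= std::log(std::max(a.probs(y(n), n), 1e-12));
    dlogits(y(n), n) -= 1.0;
  }
  loss /= N;
  dlogits /= N;

  List grads = List::create();
  mat Wfc = as<mat>(par["Wfc"]);
  grads["Wfc"] = mat(dlogits * a.flat.t());
  grads["bfc"] = vec(sum(dlogits, 1));
  mat dflat = Wfc.t() * dlogits;

  // back through separable blocks
  cube cur_in = (s.nblocks > 0) ? a.D1 : cube();
  const int lastR = a.Bdrop[s.nblocks - 1].n_rows,
            lastT = a.Bdrop[s.nblocks - 1].n_cols;
  cube dcur(lastR, lastT, N);
  for (int n = 0; n < N; ++n)
    dcur.slice(n) = reshape(dflat.col(n), lastR, lastT);

  for (int k = s.nblocks - 1; k >= 0; --k) {
    std::string sk = std::to_string(k);
    mat Wdep = as<mat>(par["Wdep" + sk]);
    mat Wpt = as<mat>(par["Wpt" + sk]);
    vec g3 = as<vec>(par["g3" + sk]);
    const int Min = Wpt.n_cols, Mout = Wpt.n_rows;
    const cube& blk_in = (k == 0) ? a.D1 : a.Bdrop[k - 1];
    const int Tk = blk_in.n_cols;

    dcur %= a.masks[k + 1];                       // dropout
    cube dpool;
    if (k == 0) pool_backward(dcur, s.pool2, Tk, dpool);
    else dpool = dcur;
    cube delu;
    elu_backward(dpool, a.Belu[k], delu);
    uvec grp3 = regspace<uvec>(0, Mout - 1);
    cube dbn; vec dg3, db3;
    bn_backward(delu, a.bn3[k], grp3, Mout, g3, train, dbn, dg3, db3);
    grads["g3" + sk] = dg3; grads["b3" + sk] = db3;
    mat dWpt(Mout, Min, fill::zeros);
    cube ddep(Min, Tk, N);
    for (int n = 0; n < N; ++n) {
      dWpt += dbn.slice(n) * a.Bdep[k].slice(n).t();
      ddep.slice(n) = Wpt.t() * dbn.slice(n);
    }
    grads["Wpt" + sk] = dWpt;
    mat dWdep(Wdep.n_rows, Min, fill::zeros);
    cube dblk_in(Min, Tk, N, fill::zeros);
    mat dYm(N, Tk), Xm(N, Tk), dXm;
    for (int m = 0; m < Min; ++m) {
      for (int n = 0; n < N; ++n) {
        dYm.row(n) = ddep.slice(n).row(m);
        Xm.row(n) = blk_in.slice(n).row(m);
      }
      vec dw(Wdep.n_rows, fill::zeros);
      conv_rows_same_backW(dYm, Xm, dw);
      dWdep.col(m) = dw;
      dXm.zeros(N, Tk);
      conv_rows_same_backX(dYm, Wdep.col(m), dXm);
      for (int n = 0; n < N; ++n) dblk_in.slice(n).row(m) = dXm.row(n);
    }
    grads["Wdep" + sk] = dWdep;
    dcur = dblk_in;
  }

  if (!freeze_front) {
    // through dropout1, pool1, ELU, BN2, depthwise conv, BN1, temporal conv
    dcur %= a.masks[0];
    cube dP1;
    pool_backward(dcur, s.pool1, s.T, dP1);
    cube dE2;
    elu_backward(dP1, a.E2, dE2);
    uvec grp2 = regspace<uvec>(0, s.M2 - 1);
    vec g2 = as<vec>(par["g2"]);
    cube dZ2; vec dg2, db2;
    bn_backward(dE2, a.bn2, grp2, s.M2, g2, train, dZ2, dg2, db2);
    grads["g2"] = dg2; grads["b2"] = db2;

    mat Wdw = as<mat>(par["Wdw"]);
    mat dWdw(s.C, s.M2, fill::zeros);
    cube dA1bn(s.F1 * s.C, s.T, N, fill::zeros);
    for (int n = 0; n < N; ++n)
      for (int f = 0; f < s.F1; ++f) {
        mat a1 = a.A1bn.slice(n).rows(f * s.C, (f + 1) * s.C - 1); // C x T
        mat dz = dZ2.slice(n).rows(f * s.D, (f + 1) * s.D - 1);    // D x T
        dWdw.cols(f * s.D, (f + 1) * s.D - 1) += a1 * dz.t();
        dA1bn.slice(n).rows(f * s.C, (f + 1) * s.C - 1) =
          Wdw.cols(f * s.D, (f + 1) * s.D - 1) * dz;
      }
    grads["Wdw"] = dWdw;

    uvec grp1(s.F1 * s.C);
    for (int f = 0; f < s.F1; ++f)
      for (int c = 0; c < s.C; ++c) grp1(f * s.C + c) = f;
    vec g1 = as<vec>(par["g1"]);
    cube dA1; vec dg1, db1;
    bn_backward(dA1bn, a.bn1, grp1, s.F1, g1, train, dA1, dg1, db1);
    grads["g1"] = dg1; grads["b1"] = db1;

    const int NC = N * s.C;
    mat dYall((size_t)NC * s.T, s.F1);
    for (int f = 0; f < s.F1; ++f) {
      mat dYf(dYall.colptr(f), NC, s.T, false, true);
      for (int n = 0; n < N; ++n)
        dYf.rows(n * s.C, (n + 1) * s.C - 1) =
          dA1.slice(n).rows(f * s.C, (f + 1) * s.C - 1);
    }
    grads["Wt"] = mat(a.P->t() * dYall);   // L x F1
  }

  return List::create(_["loss"] = loss,
                      _["probs"] = a.probs,
                      _["grads"] = grads,
                      _["running"] = par_out);
}

// [[Rcpp::export]]
arma::mat eegnet_forward_cpp(List par, List spec, const arma::cube& X) {
  Spec s = read_spec(spec);
  Acts a;
  List dummy = List::create();
  forward_pass(par, s, X, false, false, 0.0, a, dummy);
  return a.probs;
}

// Gradient of the probability of class cls(n) with respect to the input, per
// instance (inference-mode batch-norm; no dropout).
// [[Rcpp::export]]
arma::cube eegnet_input_grad(List par, List spec, const arma::cube& X,
                             const arma::ivec& cls) {
  Spec s = read_spec(spec);
  const int N = X.n_slices;
  Acts a;
  List dummy = List::create();
  forward_pass(par, s, X, false, false, 0.0, a, dummy);

  // d p_k / d logits = p_k (e_k - p)
  mat dlogits(s.Z, N);
  for (int n = 0; n < N; ++n) {
    vec p = a.probs.col(n);
    vec d = -p(cls(n)) * p;
    d(cls(n)) += p(cls(n));
    dlogits.col(n) = d;
  }
  mat Wfc = as<mat>(par["Wfc"]);
  mat dflat = Wfc.t() * dlogits;

  const int lastR = a.Bdrop[s.nblocks - 1].n_rows,
            lastT = a.Bdrop[s.nblocks - 1].n_cols;
  cube dcur(lastR, lastT, N);
  for (int n = 0; n < N; ++n)
    dcur.slice(n) = reshape(dflat.col(n), lastR, lastT);

  for (int k = s.nblocks - 1; k >= 0; --k) {
    std::string sk = std::to_string(k);
    mat Wdep = as<mat>(par["Wdep" + sk]);
    mat Wpt = as<mat>(par["Wpt" + sk]);
    vec g3 = as<vec>(par["g3" + sk]);
    const int Min = Wpt.n_cols, Mout = Wpt.n_rows;
    const cube& blk_in = (k == 0) ? a.D1 : a.Bdrop[k - 1];
    const int Tk = blk_in.n_cols;
    cube dpool;
    if (k == 0) pool_backward(dcur, s.pool2, Tk, dpool);
    else dpool = dcur;
    cube delu;
    elu_backward(dpool, a.Belu[k], delu);
    uvec grp3 = regspace<uvec>(0, Mout - 1);
    cube dbn; vec dg3, db3;
    bn_backward(delu, a.bn3[k], grp3, Mout, g3, false, dbn, dg3, db3);
    cube ddep(Min, Tk, N);
    for (int n = 0; n < N; ++n) ddep.slice(n) = Wpt.t() * dbn.slice(n);
    cube dblk_in(Min, Tk, N, fill::zeros);
    for (int n = 0; n < N; ++n)
      for (int m = 0; m < Min; ++m) {
        mat dy1 = ddep.slice(n).row(m);
        mat dx1(1, Tk, fill::zeros);
        conv_rows_same_backX(dy1, Wdep.col(m), dx1);
        dblk_in.slice(n).row(m) += dx1;
      }
    dcur = dblk_in;
  }

  cube dP1;
  pool_backward(dcur, s.pool1, s.T, dP1);
  cube dE2;
  elu_backward(dP1, a.E2, dE2);
  uvec grp2 = regspace<uvec>(0, s.M2 - 1);
  vec g2 = as<vec>(par["g2"]);
  cube dZ2; vec dg2, db2;
  bn_backward(dE2, a.bn2, grp2, s.M2, g2, false, dZ2, dg2, db2);
  mat Wdw = as<mat>(par["Wdw"]);
  cube dA1bn(s.F1 * s.C, s.T, X.n_slices, fill::zeros);
  for (uword n = 0; n < X.n_slices; ++n)
    for (int f = 0; f < s.F1; ++f)
      dA1bn.slice(n).rows(f * s.C, (f + 1) * s.C - 1) =
        Wdw.cols(f * s.D, (f + 1) * s.D - 1) *
        dZ2.slice(n).rows(f * s.D, (f + 1) * s.D - 1);
  uvec grp1(s.F1 * s.C);
  for (int f = 0; f < s.F1; ++f)
    for (int c = 0; c < s.C; ++c) grp1(f * s.C + c) = f;
  vec g1 = as<vec>(par["g1"]);
  cube dA1; vec dg1, db1;
  bn_backward(dA1bn, a.bn1, grp1, s.F1, g1, false, dA1, dg1, db1);

  mat Wt = as<mat>(par["Wt"]);
  cube dX(s.C, s.T, X.n_slices, fill::zeros);
  for (uword n = 0; n < X.n_slices; ++n)
    for (int f = 0; f < s.F1; ++f)
      conv_rows_same_backX(dA1.slice(n).rows(f * s.C, (f + 1) * s.C - 1),
                           Wt.col(f), dX.slice(n));
  return dX;
}
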
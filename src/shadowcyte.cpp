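// Compiled core: 8-connected component labelling for the object-recognition
// step, and the SELU convolutional network (forward, training, Grad-CAM).
// Convolutions are 3x3 / stride 1 / pad 1, realised as im2col + sgemm over
// the whole minibatch; pooling is 2x2 max with floor division.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>

using arma::fmat;
using arma::fvec;
using arma::uvec;

// ---------------------------------------------------------------------------
// 8-connected component labelling (union-find)
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int> &p, int i) {
  while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; }
  return i;
}

// [[Rcpp::export(name = ".label8")]]
Rcpp::IntegerMatrix label8(const Rcpp::IntegerMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  Rcpp::IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused (background)
  // first pass: assign provisional labels, union with W, NW, N, NE neighbours
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) continue;
      int best = 0;
      const int dr[4] = {-1, -1, 0, -1};
      const int dc[4] = {0, -1, -1, 1};
      int nbr[4];
      int nn = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        // neighbours already visited in column-major order: (r-1,c), (r-1,c-1),
        // (r,c-1), (r-1,c+1) is NOT yet visited in column-major order -> use
        // (r+1, c-1) instead (SW), which is visited.
        if (k == 3) { rr = r + 1; cc = c - 1; }
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l > 0) nbr[nn++] = uf_find(parent, l);
      }
      if (nn == 0) {
        best = (int)parent.size();
        parent.push_back(best);
      } else {
        best = nbr[0];
        for (int k = 1; k < nn; ++k) if (nbr[k] < best) best = nbr[k];
        for (int k = 0; k < nn; ++k) parent[nbr[k]] = best;
      }
      lab(r, c) = best;
    }
  }
  // second pass: flatten and renumber 1..K in first-encounter order
  std::vector<int> newlab(parent.size(), 0);
  int K = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (newlab[root] == 0) newlab[root] = ++K;
      lab(r, c) = newlab[root];
    }
  return lab;
}

// ---------------------------------------------------------------------------
// SELU network
// ---------------------------------------------------------------------------

static const float SELU_LAMBDA = 1.0507f;
static const float SELU_ALPHA  = 1.6732f;

static inline void selu_inplace(fmat &z) {
  z.transform([](float x) {
    return x >= 0.0f ? SELU_LAMBDA * x
                     : SELU_LAMBDA * SELU_ALPHA * (std::exp(x) - 1.0f);
  });
}

// derivative of SELU as a function of the PRE-activation z
static inline fmat selu_deriv(const fmat &z) {
  fmat d = z;
  d.transform([](float x) {
    return x >= 0.0f ? SELU_LAMBDA : SELU_LAMBDA * SELU_ALPHA * std::exp(x);
  });
  return d;
}

// im2col for a 3x3, pad-1 convolution over a batch.
// x: (C, B*H*W) activations, pixel index p = r + c*H within each image block.
// out: (9*C, B*H*W); offset block k = (dr+1) + 3*(dc+1) holds x shifted by
// (-dr, -dc) with zero padding.
static void im2col3(const fmat &x, int C, int B, int H, int W, fmat &out) {
  out.zeros(9 * C, (size_t)B * H * W);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * H * W;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = (dr + 1) + 3 * (dc + 1);
        for (int c = 0; c < W; ++c) {
          const int cs = c + dc;
          if (cs < 0 || cs >= W) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          if (r0 >= r1) continue;
          // destination pixels (r, c), source pixels (r+dr, cs)
          out.submat(k * C, off + c * H + r0, (k + 1) * C - 1,
                     off + c * H + r1 - 1) =
              x.submat(0, off + cs * H + r0 + dr, C - 1,
                       off + cs * H + r1 - 1 + dr);
        }
      }
    }
  }
}

// reverse of im2col3: scatter-add columns back to image grid
static void col2im3(const fmat &cols, int C, int B, int H, int W, fmat &out) {
  out.zeros(C, (size_t)B * H * W);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * H * W;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = (dr + 1) + 3 * (dc + 1);
        for (int c = 0; c < W; ++c) {
          const int cs = c + dc;
          if (cs < 0 || cs >= W) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          if (r0 >= r1) continue;
          out.submat(0, off + cs * H + r0 + dr, C - 1,
                     off + cs * H + r1 - 1 + dr) +=
              cols.submat(k * C, off + c * H + r0, (k + 1) * C - 1,
                          off + c * H + r1 - 1);
        }
      }
    }
  }
}

// 2x2 max pool, stride 2, floor division; records argmax linear indices
static void maxpool2(const fmat &x, int C, int B, int H, int W, fmat &out,
                     arma::umat &amax) {
  const int H2 = H / 2, W2 = W / 2;
  out.set_size(C, (size_t)B * H2 * W2);
  amax.set_size(C, (size_t)B * H2 * W2);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * H * W, off2 = (size_t)b * H2 * W2;
    for (int c2 = 0; c2 < W2; ++c2) {
      for (int r2 = 0; r2 < H2; ++r2) {
        const size_t dst = off2 + (size_t)c2 * H2 + r2;
        const size_t p00 = off + (size_t)(2 * c2) * H + 2 * r2;
        const size_t cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
        for (int ch = 0; ch < C; ++ch) {
          float best = x(ch, cand[0]);
          size_t bi = cand[0];
          for (int k = 1; k < 4; ++k)
            if (x(ch, cand[k]) > best) { best = x(ch, cand[k]); bi = cand[k]; }
          out(ch, dst) = best;
          amax(ch, dst) = bi;
        }
      }
    }
  }
}

struct NetSpec {
  std::vector<int> ch;        // conv output channels (length n_conv)
  std::vector<bool> pool;     // pool after conv l?
  std::vector<int> fcw;       // fully connected widths, last = n classes
  int in_size;                // input spatial size (50)
  int n_conv() const { return (int)ch.size(); }
  // spatial size entering conv layer l (and final size after last pool)
  std::vector<int> spatial() const {
    std::vector<int> sp;
    int s = in_size;
    for (int l = 0; l < n_conv(); ++l) {
      sp.push_back(s);
      if (pool[l]) s /= 2;
    }
    sp.push_back(s);
    return sp;
  }
};

struct Weights {
  std::vector<fmat> Wc; std::vector<fvec> bc;
  std::vector<fmat> Wf; std::vector<fvec> bf;
};

static NetSpec spec_from_r(const Rcpp::List &spec) {
  NetSpec s;
  Rcpp::IntegerVector ch = spec["conv_channels"];
  Rcpp::LogicalVector pl = spec["pool_after"];
  Rcpp::IntegerVector fc = spec["fc_widths"];
  s.in_size = Rcpp::as<int>(spec["input_size"]);
  for (int i = 0; i < ch.size(); ++i) s.ch.push_back(ch[i]);
  for (int i = 0; i < pl.size(); ++i) s.pool.push_back(pl[i]);
  for (int i = 0; i < fc.size(); ++i) s.fcw.push_back(fc[i]);
  return s;
}

static Weights weights_from_r(const Rcpp::List &w) {
  Weights W;
  Rcpp::List conv = w["conv"], fc = w["fc"];
  for (int l = 0; l < conv.size(); ++l) {
    Rcpp::List lay = conv[l];
    W.Wc.push_back(arma::conv_to<fmat>::from(
        Rcpp::as<arma::mat>(lay["W"])));
    W.bc.push_back(arma::conv_to<fvec>::from(
        Rcpp::as<arma::vec>(lay["b"])));
  }
  for (int l = 0; l < fc.size(); ++l) {
    Rcpp::List lay = fc[l];
    W.Wf.push_back(arma::conv_to<fmat>::from(
        Rcpp::as<arma::mat>(lay["W"])));
    W.bf.push_back(arma::conv_to<fvec>::from(
        Rcpp::as<arma::vec>(lay["b"])));
  }
  return W;
}

static Rcpp::List weights_to_r(const Weights &W) {
  Rcpp::List conv(W.Wc.size()), fc(W.Wf.size());
  for (size_t l = 0; l < W.Wc.size(); ++l)
    conv[l] = Rcpp::List::create(
        Rcpp::Named("W") = arma::conv_to<arma::mat>::from(W.Wc[l]),
        Rcpp::Named("b") = arma::conv_to<arma::vec>::from(W.bc[l]));
  for (size_t l = 0; l < W.Wf.size(); ++l)
    fc[l] = Rcpp::List::create(
        Rcpp::Named("W") = arma::conv_to<arma::mat>::from(W.Wf[l]),
        Rcpp::Named("b") = arma::conv_to<arma::vec>::from(W.bf[l]));
  return Rcpp::List::create(Rcpp::Named("conv") = conv,
                            Rcpp::Named("fc") = fc);
}

// Cached forward state for one minibatch
struct ForwardState {
  std::vector<fmat> Xcol;   // im2col input of each conv layer
  std::vector<fmat> Zc;     // conv pre-activations
  std::vector<fmat> Ac;     // conv post-SELU (pre-pool)
  std::vector<fmat> Xin;    // activations entering each conv layer
  std::vector<arma::umat> amax;
  std::vector<fmat> Zf, Af; // fc pre/post activations (Af.back() = logits)
  fmat flat;                // flattened conv output (features x B)
};

static void forward(const NetSpec &s, const Weights &W, const fmat &x0, int B,
                    ForwardState &st, bool keep_cache) {
  std::vector<int> sp = s.spatial();
  const int L = s.n_conv();
  st.Xcol.assign(L, fmat()); st.Zc.assign(L, fmat());
  st.Ac.assign(L, fmat());   st.Xin.assign(L, fmat());
  st.amax.assign(L, arma::umat());
  fmat x = x0;
  int Cin = 1;
  for (int l = 0; l < L; ++l) {
    const int H = sp[l];
    if (keep_cache) st.Xin[l] = x;
    fmat cols;
    im2col3(x, Cin, B, H, H, cols);
    fmat z = W.Wc[l] * cols;
    z.each_col() += W.bc[l];
    if (keep_cache) { st.Xcol[l] = std::move(cols); st.Zc[l] = z; }
    selu_inplace(z);
    if (keep_cache) st.Ac[l] = z;
    if (s.pool[l]) {
      fmat pooled; arma::umat am;
      maxpool2(z, s.ch[l], B, H, H, pooled, am);
      if (keep_cache) st.amax[l] = std::move(am);
      x = std::move(pooled);
    } else {
      x = std::move(z);
    }
    Cin = s.ch[l];
  }
  // flatten: (C_last * final^2, B)
  const int final_sp = sp[L];
  const int feat = s.ch[L - 1] * final_sp * final_sp;
  st.flat = fmat(const_cast<float *>(x.memptr()), feat, B, true, false);
  const int F = (int)s.fcw.size();
  st.Zf.assign(F, fmat()); st.Af.assign(F, fmat());
  fmat a = st.flat;
  for (int l = 0; l < F; ++l) {
    fmat z = W.Wf[l] * a;
    z.each_col() += W.bf[l];
    st.Zf[l] = z;
    if (l < F - 1) selu_inplace(z);
    st.Af[l] = z;
    a = st.Af[l];
  }
}

// softmax over 2 (or k) rows, column-wise, in place; returns mean CE loss
static float softmax_ce(fmat &logits, const arma::uvec &y, fvec *losses) {
  const int B = (int)logits.n_cols;
  float loss = 0.0f;
  for (int j = 0; j < B; ++j) {
    fvec c = logits.col(j);
    const float m = c.max();
    fvec e = arma::exp(c - m);
    const float Z = arma::accu(e);
    logits.col(j) = e / Z;
    const float p = logits(y(j), j);
    const float li = -std::log(std::max(p, 1e-30f));
    loss += li;
    if (losses) (*losses)(j) = li;
  }
  return loss / B;
}

struct Grads {
  std::vector<fmat> Wc; std::vector<fvec> bc;
  std::vector<fmat> Wf; std::vector<fvec> bf;
};

static void backward(const NetSpec &s, const Weights &W, ForwardState &st,
                     const arma::uvec &y, int B, Grads &g) {
  std::vector<int> sp = s.spatial();
  const int L = s.n_conv(), F = (int)s.fcw.size();
  g.Wc.assign(L, fmat()); g.bc.assign(L, fvec());
  g.Wf.assign(F, fmat()); g.bf.assign(F, fvec());
  // d loss / d logits
  fmat delta = st.Af[F - 1];
  softmax_ce(delta, y, nullptr);
  for (int j = 0; j < B; ++j) delta(y(j), j) -= 1.0f;
  delta /= (float)B;
  for (int l = F - 1; l >= 0; --l) {
    const fmat &below = (l == 0) ? st.flat : st.Af[l - 1];
    g.Wf[l] = delta * below.t();
    g.bf[l] = arma::sum(delta, 1);
    if (l > 0) {
      fmat d = W.Wf[l].t() * delta;
      delta = d % selu_deriv(st.Zf[l - 1]);
    } else {
      delta = W.Wf[0].t() * delta;  // gradient w.r.t. flattened conv output
    }
  }
  // reshape to (C_last, B * final^2)
  const int final_sp = sp[L];
  fmat dx(s.ch[L - 1], (size_t)B * final_sp * final_sp);
  {
    // flat layout is (C*final^2) x B with pixel-major within image; transpose
    // back to channel rows x (B*pixels) columns
    const int npix = final_sp * final_sp, C = s.ch[L - 1];
    for (int b = 0; b < B; ++b)
      for (int p = 0; p < npix; ++p)
        for (int c = 0; c < C; ++c)
          dx(c, (size_t)b * npix + p) = delta(c + (size_t)p * C, b);
  }
  for (int l = L - 1; l >= 0; --l) {
    const int H = sp[l], H2 = H / 2;
    fmat dz;
    if (s.pool[l]) {
      dz.zeros(s.ch[l], (size_t)B * H * H);
      const arma::umat &am = st.amax[l];
      for (size_t j = 0; j < dx.n_cols; ++j)
        for (int c = 0; c < s.ch[l]; ++c)
          dz(c, am(c, j)) += dx(c, j);
      (void)H2;
    } else {
      dz = std::move(dx);
    }
    dz %= selu_deriv(st.Zc[l]);
    g.Wc[l] = dz * st.Xcol[l].t();
    g.bc[l] = arma::sum(dz, 1);
    if (l > 0) {
      fmat dcols = W.Wc[l].t() * dz;
      const int Cin = s.ch[l - 1];
      col2im3(dcols, Cin, B, H, H, dx);
    }
  }
}

struct AdamState {
  std::vector<fmat> m, v;
  std::vector<fvec> mb, vb;
  int t = 0;
};

static void adam_init(const Weights &W, AdamState &cs, AdamState &fs) {
  for (auto &w : W.Wc) { cs.m.push_back(arma::zeros<fmat>(arma::size(w)));
                         cs.v.push_back(arma::zeros<fmat>(arma::size(w))); }
  for (auto &b : W.bc) { cs.mb.push_back(arma::zeros<fvec>(arma::size(b)));
                         cs.vb.push_back(arma::zeros<fvec>(arma::size(b))); }
  for (auto &w : W.Wf) { fs.m.push_back(arma::zeros<fmat>(arma::size(w)));
                         fs.v.push_back(arma::zeros<fmat>(arma::size(w))); }
  for (auto &b : W.bf) { fs.mb.push_back(arma::zeros<fvec>(arma::size(b)));
                         fs.vb.push_back(arma::zeros<fvec>(arma::size(b))); }
}

static void adam_step(fmat &w, const fmat &g, fmat &m, fmat &v, float lr,
                      float b1c, float b2c) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * (g % g);
  w -= lr * (m / b1c) / (arma::sqrt(v / b2c) + 1e-8f);
}
static void adam_step(fvec &w, const fvec &g, fvec &m, fvec &v, float lr,
                      float b1c, float b2c) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * (g % g);
  w -= lr * (m / b1c) / (arma::sqrt(v / b2c) + 1e-8f);
}

// assemble minibatch columns from the (50, 50, N) cube
static fmat gather_batch(const arma::cube &x, const std::vector<int> &idx) {
  const int H = (int)x.n_rows, W = (int)x.n_cols, B = (int)idx.size();
  fmat out(1, (size_t)B * H * W);
  for (int b = 0; b < B; ++b) {
    const arma::mat &sl = x.slice(idx[b]);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        out(0, (size_t)b * H * W + (size_t)c * H + r) = (float)sl(r, c);
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_forward")]]
arma::mat cnn_forward(const Rcpp::List &spec, const Rcpp::List &weights,
                      const arma::cube &x) {
  NetSpec s = spec_from_r(spec);
  Weights W = weights_from_r(weights);
  const int N = (int)x.n_slices;
  const int k = s.fcw.back();
  arma::mat logits(N, k);
  const int CH = 256;  // chunk to bound memory
  ForwardState st;
  for (int i0 = 0; i0 < N; i0 += CH) {
    const int B = std::min(CH, N - i0);
    std::vector<int> idx(B);
    for (int b = 0; b < B; ++b) idx[b] = i0 + b;
    fmat x0 = gather_batch(x, idx);
    forward(s, W, x0, B, st, false);
    for (int b = 0; b < B; ++b)
      for (int j = 0; j < k; ++j)
        logits(i0 + b, j) = st.Af.back()(j, b);
  }
  return logits;
}

static void eval_set(const NetSpec &s, const Weights &W, const arma::cube &x,
                     const arma::uvec &y, double &acc, double &loss) {
  const int N = (int)x.n_slices;
  const int CH = 256;
  ForwardState st;
  double nc = 0, lsum = 0;
  for (int i0 = 0; i0 < N; i0 += CH) {
    const int B = std::min(CH, N - i0);
    std::vector<int> idx(B);
    for (int b = 0; b < B; ++b) idx[b] = i0 + b;
    fmat x0 = gather_batch(x, idx);
    forward(s, W, x0, B, st, false);
    fmat probs = st.Af.back();
    arma::uvec yb = y.subvec(i0, i0 + B - 1);
    fvec losses(B);
    softmax_ce(probs, yb, &losses);
    lsum += arma::accu(losses);
    for (int b = 0; b < B; ++b)
      if (probs.col(b).index_max() == yb(b)) nc += 1;
  }
  acc = nc / N;
  loss = lsum / N;
}

// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train(const Rcpp::List &spec, const Rcpp::List &weights,
                     const arma::cube &xtr, const arma::uvec &ytr,
                     const arma::cube &xval, const arma::uvec &yval,
                     int epochs, int batch_size, double lr, int seed,
                     bool verbose) {
  NetSpec s = spec_from_r(spec);
  Weights W = weights_from_r(weights);
  AdamState cs, fs;
  adam_init(W, cs, fs);
  const int N = (int)xtr.n_slices;
  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  arma::vec tr_acc(epochs), tr_loss(epochs), va_acc(epochs), va_loss(epochs);
  Weights best = W;
  double best_acc = -1.0;
  int best_epoch = 0;
  ForwardState st;
  Grads g;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double nc = 0, lsum = 0;
    for (int i0 = 0; i0 < N; i0 += batch_size) {
      const int B = std::min(batch_size, N - i0);
      std::vector<int> idx(order.begin() + i0, order.begin() + i0 + B);
      fmat x0 = gather_batch(xtr, idx);
      arma::uvec yb(B);
      for (int b = 0; b < B; ++b) yb(b) = ytr(idx[b]);
      forward(s, W, x0, B, st, true);
      {
        fmat probs = st.Af.back();
        fvec losses(B);
        softmax_ce(probs, yb, &losses);
        lsum += arma::accu(losses);
        for (int b = 0; b < B; ++b)
          if (probs.col(b).index_max() == yb(b)) nc += 1;
      }
      backward(s, W, st, yb, B, g);
      fs.t = ++cs.t;
      const float b1c = 1.0f - std::pow(0.9f, (float)cs.t);
      const float b2c = 1.0f - std::pow(0.999f, (float)cs.t);
      for (size_t l = 0; l < W.Wc.size(); ++l) {
        adam_step(W.Wc[l], g.Wc[l], cs.m[l], cs.v[l], (float)lr, b1c, b2c);
        adam_step(W.bc[l], g.bc[l], cs.mb[l], cs.vb[l], (float)lr, b1c, b2c);
      }
      for (size_t l = 0; l < W.Wf.size(); ++l) {
        adam_step(W.Wf[l], g.Wf[l], fs.m[l], fs.v[l], (float)lr, b1c, b2c);
        adam_step(W.bf[l], g.bf[l], fs.mb[l], fs.vb[l], (float)lr, b1c, b2c);
      }
    }
    tr_acc(ep) = nc / N;
    tr_loss(ep) = lsum / N;
    double va, vl;
    if (xval.n_slices > 0) {
      eval_set(s, W, xval, yval, va, vl);
    } else {
      va = NA_REAL; vl = NA_REAL;
    }
    va_acc(ep) = va;
    va_loss(ep) = vl;
    if (xval.n_slices > 0 && va > best_acc) {
      best_acc = va; best = W; best_epoch = ep + 1;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << " train_acc=" << tr_acc(ep) << " val_acc=" << va
                  << " train_loss=" << tr_loss(ep) << std::endl;
    Rcpp::checkUserInterrupt();
  }
  if (best_acc < 0) { best = W; best_epoch = epochs; }
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights_to_r(best),
      Rcpp::Named("final_weights") = weights_to_r(W),
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("train_acc") = tr_acc, Rcpp::Named("val_acc") = va_acc,
      Rcpp::Named("train_loss") = tr_loss, Rcpp::Named("val_loss") = va_loss);
}

// mean cross-entropy loss of a labelled batch (used by tests to verify the
// analytic gradients against finite differences)
// [[Rcpp::export(name = ".cnn_loss")]]
double cnn_loss(const Rcpp::List &spec, const Rcpp::List &weights,
                const arma::cube &x, const arma::uvec &y) {
  NetSpec s = spec_from_r(spec);
  Weights W = weights_from_r(weights);
  double acc, loss;
  eval_set(s, W, x, y, acc, loss);
  return loss;
}

// analytic gradients of the mean cross-entropy over one batch
// [[Rcpp::export(name = ".cnn_grad")]]
Rcpp::List cnn_grad(const Rcpp::List &spec, const Rcpp::List &weights,
                    const arma::cube &x, const arma::uvec &y) {
  NetSpec s = spec_from_r(spec);
  Weights W = weights_from_r(weights);
  const int B = (int)x.n_slices;
  std::vector<int> idx(B);
  for (int b = 0; b < B; ++b) idx[b] = b;
  fmat x0 = gather_batch(x, idx);
  ForwardState st;
  forward(s, W, x0, B, st, true);
  Grads g;
  backward(s, W, st, y, B, g);
  Weights G;
  G.Wc = g.Wc; G.bc = g.bc; G.Wf = g.Wf; G.bf = g.bf;
  return weights_to_r(G);
}

// Grad-CAM on the last conv layer (post-SELU, pre-pool): returns the raw
// ReLU'd class-activation map at the last conv layer's spatial resolution.
// [[Rcpp::export(name = ".cnn_gradcam")]]
arma::mat cnn_gradcam(const Rcpp::List &spec, const Rcpp::List &weights,
                      const arma::mat &x, int target_class) {
  NetSpec s = spec_from_r(spec);
  Weights W = weights_from_r(weights);
  std::vector<int> sp = s.spatial();
  const int L = s.n_conv(), F = (int)s.fcw.size();
  arma::cube xc(x.n_rows, x.n_cols, 1);
  xc.slice(0) = x;
  fmat x0 = gather_batch(xc, {0});
  ForwardState st;
  forward(s, W, x0, 1, st, true);
  // backprop d logit[target] / d A_lastconv (no softmax: raw class score)
  fmat delta(s.fcw.back(), 1, arma::fill::zeros);
  delta(target_class, 0) = 1.0f;
  for (int l = F - 1; l >= 0; --l) {
    if (l > 0) {
      fmat d = W.Wf[l].t() * delta;
      delta = d % selu_deriv(st.Zf[l - 1]);
    } else {
      delta = W.Wf[0].t() * delta;
    }
  }
  const int final_sp = sp[L], C = s.ch[L - 1];
  const int npix = final_sp * final_sp;
  fmat dx(C, npix);
  for (int p = 0; p < npix; ++p)
    for (int c = 0; c < C; ++c) dx(c, p) = delta(c + (size_t)p * C, 0);
  // unpool through the last pool (if any) to the conv activation grid
  const int Hl = sp[L - 1];
  fmat dA;
  if (s.pool[L - 1]) {
    dA.zeros(C, (size_t)Hl * Hl);
    const arma::umat &am = st.amax[L - 1];
    for (arma::uword j = 0; j < dx.n_cols; ++j)
      for (int c = 0; c < C; ++c) dA(c, am(c, j)) += dx(c, j);
  } else {
    dA = dx;
  }
  const fmat &A = st.Ac[L - 1];  // post-SELU activations of the last conv
  // channel weights: global-average of gradients; cam = ReLU(sum_c a_c A_c)
  fvec alpha = arma::mean(dA, 1);
  arma::frowvec cam = alpha.t() * A;
  arma::mat out(Hl, Hl);
  for (int c = 0; c < Hl; ++c)
    for (int r = 0; r < Hl; ++r)
      out(r, c) = std::max(0.0f, cam((size_t)c * Hl + r));
  return out;
}
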
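// Transformer encoder core: forward pass, masked-LM + Fourier-prior loss and
// analytic gradients. Single-precision throughout; all stochasticity (masking
// plans, sampling) lives on the R side, so these routines are deterministic.
//
// The whole batch is processed as one (B*L) x d matrix (rows seq-major) so
// that LayerNorm, projections and feed-forward run as large GEMMs; only the
// attention score/mix step loops over sequences and heads.

#include <RcppArmadillo.h>
#include <cstring>

// Direct single-precision GEMM into caller-owned memory (avoids the
// temporaries Armadillo materializes when writing through aliases).
extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Cfg {
  int d, nb, H, ff, dh;
  float rope_base;
};

struct BlockP {
  fvec ln1_g, ln1_b, b_qkv, b_o, ln2_g, ln2_b, b_ff1, b_ff2;
  fmat w_qkv, w_o, w_ff1, w_ff2;
};

struct Par {
  fmat E; // 6 x d; row 5 (N token) pinned at zero
  std::vector<BlockP> blocks;
  fvec lnf_g, lnf_b;
  fmat head_w1, head_w2;
  fvec head_b1, head_b2, head_ln_g, head_ln_b;
};

static fvec get_v(const Rcpp::List& L, const std::string& nm) {
  return conv_to<fvec>::from(Rcpp::as<vec>(L[nm]));
}
static fmat get_m(const Rcpp::List& L, const std::string& nm) {
  return conv_to<fmat>::from(Rcpp::as<mat>(L[nm]));
}

static Cfg parse_cfg(const Rcpp::List& cfg) {
  Cfg c;
  c.d = Rcpp::as<int>(cfg["embed_dim"]);
  c.nb = Rcpp::as<int>(cfg["n_blocks"]);
  c.H = Rcpp::as<int>(cfg["n_heads"]);
  c.ff = Rcpp::as<int>(cfg["ff_dim"]);
  c.rope_base = (float)Rcpp::as<double>(cfg["rope_base"]);
  c.dh = c.d / c.H;
  return c;
}

static Par parse_par(const Rcpp::List& p, const Cfg& cfg) {
  Par out;
  out.E = get_m(p, "embed");
  out.blocks.resize(cfg.nb);
  for (int b = 0; b < cfg.nb; ++b) {
    std::string pre = "b" + std::to_string(b) + "_";
    BlockP& bl = out.blocks[b];
    bl.ln1_g = get_v(p, pre + "ln1_g"); bl.ln1_b = get_v(p, pre + "ln1_b");
    bl.w_qkv = get_m(p, pre + "w_qkv"); bl.b_qkv = get_v(p, pre + "b_qkv");
    bl.w_o = get_m(p, pre + "w_o");     bl.b_o = get_v(p, pre + "b_o");
    bl.ln2_g = get_v(p, pre + "ln2_g"); bl.ln2_b = get_v(p, pre + "ln2_b");
    bl.w_ff1 = get_m(p, pre + "w_ff1"); bl.b_ff1 = get_v(p, pre + "b_ff1");
    bl.w_ff2 = get_m(p, pre + "w_ff2"); bl.b_ff2 = get_v(p, pre + "b_ff2");
  }
  out.lnf_g = get_v(p, "lnf_g"); out.lnf_b = get_v(p, "lnf_b");
  out.head_w1 = get_m(p, "head_w1"); out.head_b1 = get_v(p, "head_b1");
  out.head_ln_g = get_v(p, "head_ln_g"); out.head_ln_b = get_v(p, "head_ln_b");
  out.head_w2 = get_m(p, "head_w2"); out.head_b2 = get_v(p, "head_b2");
  return out;
}

static Par zeros_like(const Par& p) {
  Par g;
  g.E = fmat(size(p.E), fill::zeros);
  g.blocks.resize(p.blocks.size());
  for (size_t b = 0; b < p.blocks.size(); ++b) {
    const BlockP& s = p.blocks[b];
    BlockP& d = g.blocks[b];
    d.ln1_g = fvec(size(s.ln1_g), fill::zeros); d.ln1_b = fvec(size(s.ln1_b), fill::zeros);
    d.w_qkv = fmat(size(s.w_qkv), fill::zeros); d.b_qkv = fvec(size(s.b_qkv), fill::zeros);
    d.w_o = fmat(size(s.w_o), fill::zeros);     d.b_o = fvec(size(s.b_o), fill::zeros);
    d.ln2_g = fvec(size(s.ln2_g), fill::zeros); d.ln2_b = fvec(size(s.ln2_b), fill::zeros);
    d.w_ff1 = fmat(size(s.w_ff1), fill::zeros); d.b_ff1 = fvec(size(s.b_ff1), fill::zeros);
    d.w_ff2 = fmat(size(s.w_ff2), fill::zeros); d.b_ff2 = fvec(size(s.b_ff2), fill::zeros);
  }
  g.lnf_g = fvec(size(p.lnf_g), fill::zeros); g.lnf_b = fvec(size(p.lnf_b), fill::zeros);
  g.head_w1 = fmat(size(p.head_w1), fill::zeros); g.head_b1 = fvec(size(p.head_b1), fill::zeros);
  g.head_ln_g = fvec(size(p.head_ln_g), fill::zeros); g.head_ln_b = fvec(size(p.head_ln_b), fill::zeros);
  g.head_w2 = fmat(size(p.head_w2), fill::zeros); g.head_b2 = fvec(size(p.head_b2), fill::zeros);
  return g;
}

// ---- primitive layers -------------------------------------------------------

struct LNCache { fmat xhat; fvec inv_sd; };

static fmat layernorm_fwd(const fmat& X, const fvec& g, const fvec& b, LNCache& c) {
  fvec mu = mean(X, 1);
  fmat Xc = X.each_col() - mu;
  fvec v = mean(square(Xc), 1);
  c.inv_sd = 1.0f / sqrt(v + 1e-5f);
  c.xhat = Xc.each_col() % c.inv_sd;
  fmat Y = c.xhat;
  Y.each_row() %= g.t();
  Y.each_row() += b.t();
  return Y;
}

static fmat layernorm_bwd(const fmat& dY, const LNCache& c, const fvec& g,
                          fvec& dg, fvec& db) {
  dg += sum(dY % c.xhat, 0).t();
  db += sum(dY, 0).t();
  fmat h = dY;
  h.each_row() %= g.t();
  fvec mh = mean(h, 1);
  fvec mhx = mean(h % c.xhat, 1);
  fmat dX = h;
  dX.each_col() -= mh;
  dX -= c.xhat.each_col() % mhx;
  dX.each_col() %= c.inv_sd;
  return dX;
}

static const float GELU_C = 0.7978845608028654f; // sqrt(2/pi)

// Polynomial exp2-based single-precision exp (relative error ~1e-7); the
// attention softmax and GeLU evaluate millions of exponentials per batch and
// libm dominates the runtime otherwise. Deterministic like any arithmetic.
static inline float fast_exp(float x) {
  x = std::max(x * 1.4426950408889634f, -126.0f); // to base 2, clamped
  // floor() via truncation of the shifted value (x + 127 > 0 always here);
  // keeps the loop free of libm calls so it vectorizes at baseline -march
  float xi = (float)((int)(x + 127.0f)) - 127.0f;
  float xf = x - xi;
  float p = 1.0f + xf * (0.693147182f + xf * (0.240226507f + xf * (0.0555041086f +
            xf * (0.00961812910f + xf * 0.00133335581f))));
  int32_t bits = ((int32_t)xi + 127) << 23;
  float s;
  std::memcpy(&s, &bits, sizeof(s));
  return s * p;
}

// Branch-free array version; written so the compiler can vectorize it.
static void vexp_inplace(float* p, uword n) {
  for (uword i = 0; i < n; ++i) p[i] = fast_exp(p[i]);
}

static inline float fast_tanh(float x) {
  float ax = std::fabs(x);
  if (ax > 9.0f) return x > 0 ? 1.0f : -1.0f;
  float t = fast_exp(-2.0f * ax);
  float r = (1.0f - t) / (1.0f + t);
  return x >= 0 ? r : -r;
}

// GeLU (tanh approximation); T receives tanh(u) for reuse in the backward.
static fmat gelu_fwd(const fmat& Z, fmat& T) {
  T.set_size(size(Z));
  fmat Y(size(Z));
  const float* z = Z.memptr();
  float* t = T.memptr();
  float* y = Y.memptr();
  uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i) {
    float u = GELU_C * (z[i] + 0.044715f * z[i] * z[i] * z[i]);
    t[i] = fast_tanh(u);
    y[i] = 0.5f * z[i] * (1.0f + t[i]);
  }
  return Y;
}

static fmat gelu_bwd(const fmat& Z, const fmat& T) {
  fmat G(size(Z));
  const float* z = Z.memptr();
  const float* t = T.memptr();
  float* g = G.memptr();
  uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i) {
    float du = GELU_C * (1.0f + 3.0f * 0.044715f * z[i] * z[i]);
    g[i] = 0.5f * (1.0f + t[i]) + 0.5f * z[i] * (1.0f - t[i] * t[i]) * du;
  }
  return G;
}

// Numerically stabilized softmax over each column, in place.
static void softmax_cols(float* mem, uword nrow, uword ncol) {
  for (uword j = 0; j < ncol; ++j) {
    float* p = mem + j * nrow;
    float mx = p[0];
    for (uword i = 1; i < nrow; ++i) mx = std::max(mx, p[i]);
    for (uword i = 0; i < nrow; ++i) p[i] -= mx;
    vexp_inplace(p, nrow);
    float sum = 0.0f;
    for (uword i = 0; i < nrow; ++i) sum += p[i];
    float inv = 1.0f / sum;
    for (uword i = 0; i < nrow; ++i) p[i] *= inv;
  }
}

// Rotary tables tiled over the batch: row s*L + t gets position t.
static void rope_tables(int B, int L, int dh, float base, fmat& cosT, fmat& sinT) {
  int half = dh / 2;
  cosT.set_size((uword)B * L, half);
  sinT.set_size((uword)B * L, half);
  for (int m = 0; m < half; ++m) {
    float freq = std::pow(base, -2.0f * m / dh);
    for (int t = 0; t < L; ++t) {
      float c = std::cos(t * freq), s = std::sin(t * freq);
      for (int b = 0; b < B; ++b) {
        cosT((uword)b * L + t, m) = c;
        sinT((uword)b * L + t, m) = s;
      }
    }
  }
}

// Rotate query/key pairs in place; inverse = transpose rotation (backward).
static void rope_apply(fmat& Q, int H, int dh, const fmat& cosT, const fmat& sinT,
                       bool inverse) {
  int half = dh / 2;
  for (int h = 0; h < H; ++h) {
    int off = h * dh;
    for (int m = 0; m < half; ++m) {
      fvec q0 = Q.col(off + 2 * m), q1 = Q.col(off + 2 * m + 1);
      const fvec c = cosT.col(m), s = sinT.col(m);
      if (!inverse) {
        Q.col(off + 2 * m) = q0 % c - q1 % s;
        Q.col(off + 2 * m + 1) = q0 % s + q1 % c;
      } else {
        Q.col(off + 2 * m) = q0 % c + q1 % s;
        Q.col(off + 2 * m + 1) = -q0 % s + q1 % c;
      }
    }
  }
}

// ---- batched transformer blocks ---------------------------------------------

struct BlockCache {
  fmat Xin, U, Q, K, V, O, X1, U2, Z, G, Tff; // (B*L) x {d, ff}
  LNCache ln1, ln2;
  fcube P;     // transposed attention, slice per (seq, head); grad path only
  fmat scratch; // reusable L x L score buffer for the no-grad path
};

struct HeadCache {
  fmat Hf, Z1, G1, N1, T1;
  LNCache lnf, lnh;
};

static fmat block_fwd(const fmat& X, const BlockP& p, const Cfg& cfg, int B, int L,
                      const fmat& cosT, const fmat& sinT, BlockCache& c,
                      bool want_cache) {
  int d = cfg.d, dh = cfg.dh, H = cfg.H;
  c.Xin = X;
  c.U = layernorm_fwd(X, p.ln1_g, p.ln1_b, c.ln1);
  fmat QKV = c.U * p.w_qkv;
  QKV.each_row() += p.b_qkv.t();
  c.Q = QKV.cols(0, d - 1);
  c.K = QKV.cols(d, 2 * d - 1);
  c.V = QKV.cols(2 * d, 3 * d - 1);
  rope_apply(c.Q, H, dh, cosT, sinT, false);
  rope_apply(c.K, H, dh, cosT, sinT, false);
  float scale = 1.0f / std::sqrt((float)dh);
  bool keep = want_cache;
  if (keep) c.P.set_size(L, L, (uword)B * H);
  else c.scratch.set_size(L, L);
  c.O.set_size(X.n_rows, d);
  for (int s = 0; s < B; ++s) {
    uword r0 = (uword)s * L, r1 = r0 + L - 1;
    for (int h = 0; h < H; ++h) {
      uword c0 = (uword)h * dh, c1 = c0 + dh - 1;
      // transposed scores: column j = query position j (softmax walks
      // contiguous memory); written straight into preallocated storage
      float* mem = keep ? c.P.slice_memptr((uword)s * H + h) : c.scratch.memptr();
      const float* Kp = c.K.colptr(c0) + r0;
      const float* Qp = c.Q.colptr(c0) + r0;
      const float* Vp = c.V.colptr(c0) + r0;
      int ld = c.K.n_rows;
      // St = K_h Q_h^T * scale, written straight into preallocated storage
      sgemm('N', 'T', L, L, dh, scale, Kp, ld, Qp, ld, 0.0f, mem, L);
      softmax_cols(mem, L, L);
      // O_h = St^T V_h
      sgemm('T', 'N', L, dh, L, 1.0f, mem, L, Vp, ld, 0.0f,
            c.O.colptr(c0) + r0, c.O.n_rows);
    }
  }
  fmat A = c.O * p.w_o;
  A.each_row() += p.b_o.t();
  c.X1 = X + A;
  c.U2 = layernorm_fwd(c.X1, p.ln2_g, p.ln2_b, c.ln2);
  c.Z = c.U2 * p.w_ff1;
  c.Z.each_row() += p.b_ff1.t();
  c.G = gelu_fwd(c.Z, c.Tff);
  fmat F = c.G * p.w_ff2;
  F.each_row() += p.b_ff2.t();
  return c.X1 + F;
}

static fmat block_bwd(const fmat& dX2, const BlockP& p, BlockP& g, const Cfg& cfg,
                      int B, int L, const fmat& cosT, const fmat& sinT,
                      BlockCache& c) {
  int dh = cfg.dh, H = cfg.H;
  // feed-forward branch
  g.w_ff2 += c.G.t() * dX2;
  g.b_ff2 += sum(dX2, 0).t();
  fmat dG = dX2 * p.w_ff2.t();
  fmat dZ = dG % gelu_bwd(c.Z, c.Tff);
  g.w_ff1 += c.U2.t() * dZ;
  g.b_ff1 += sum(dZ, 0).t();
  fmat dU2 = dZ * p.w_ff1.t();
  fmat dX1 = dX2 + layernorm_bwd(dU2, c.ln2, p.ln2_g, g.ln2_g, g.ln2_b);
  // attention branch
  g.w_o += c.O.t() * dX1;
  g.b_o += sum(dX1, 0).t();
  fmat dO = dX1 * p.w_o.t();
  float scale = 1.0f / std::sqrt((float)dh);
  fmat dQ(size(c.Q), fill::none), dK(size(c.K), fill::none), dV(size(c.V), fill::none);
  fmat dPt_buf, dSt_buf;
  for (int s = 0; s < B; ++s) {
    uword r0 = (uword)s * L, r1 = r0 + L - 1;
    for (int h = 0; h < H; ++h) {
      uword c0 = (uword)h * dh, c1 = c0 + dh - 1;
      const float* Pt = c.P.slice_memptr((uword)s * H + h);
      const float* Kp = c.K.colptr(c0) + r0;
      const float* Qp = c.Q.colptr(c0) + r0;
      const float* Vp = c.V.colptr(c0) + r0;
      const float* dOp = dO.colptr(c0) + r0;
      int ld = c.K.n_rows, ldO = dO.n_rows;
      // dV_h = Pt dO_h
      sgemm('N', 'N', L, dh, L, 1.0f, Pt, L, dOp, ldO, 0.0f,
            dV.colptr(c0) + r0, dV.n_rows);
      // dPt = V_h dO_h^T
      dPt_buf.set_size(L, L);
      dSt_buf.set_size(L, L);
      sgemm('N', 'T', L, L, dh, 1.0f, Vp, ld, dOp, ldO, 0.0f,
            dPt_buf.memptr(), L);
      for (uword j = 0; j < (uword)L; ++j) {
        const float* pp = Pt + j * L;
        const float* dp = dPt_buf.colptr(j);
        float* ds = dSt_buf.colptr(j);
        float rs = 0.0f;
        for (int i = 0; i < L; ++i) rs += pp[i] * dp[i];
        for (int i = 0; i < L; ++i) ds[i] = pp[i] * (dp[i] - rs);
      }
      // dQ_h = dSt^T K_h * scale ; dK_h = dSt Q_h * scale
      sgemm('T', 'N', L, dh, L, scale, dSt_buf.memptr(), L, Kp, ld, 0.0f,
            dQ.colptr(c0) + r0, dQ.n_rows);
      sgemm('N', 'N', L, dh, L, scale, dSt_buf.memptr(), L, Qp, ld, 0.0f,
            dK.colptr(c0) + r0, dK.n_rows);
    }
  }
  rope_apply(dQ, H, dh, cosT, sinT, true);
  rope_apply(dK, H, dh, cosT, sinT, true);
  fmat dQKV = join_rows(join_rows(dQ, dK), dV);
  g.w_qkv += c.U.t() * dQKV;
  g.b_qkv += sum(dQKV, 0).t();
  fmat dU = dQKV * p.w_qkv.t();
  return dX1 + layernorm_bwd(dU, c.ln1, p.ln1_g, g.ln1_g, g.ln1_b);
}

static fmat head_fwd(const fmat& X, const Par& p, HeadCache& c) {
  c.Hf = layernorm_fwd(X, p.lnf_g, p.lnf_b, c.lnf);
  c.Z1 = c.Hf * p.head_w1;
  c.Z1.each_row() += p.head_b1.t();
  c.G1 = gelu_fwd(c.Z1, c.T1);
  c.N1 = layernorm_fwd(c.G1, p.head_ln_g, p.head_ln_b, c.lnh);
  fmat logits = c.N1 * p.head_w2;
  logits.each_row() += p.head_b2.t();
  return logits;
}

static fmat head_bwd(const fmat& dlogits, const Par& p, Par& g, HeadCache& c) {
  g.head_w2 += c.N1.t() * dlogits;
  g.head_b2 += sum(dlogits, 0).t();
  fmat dN1 = dlogits * p.head_w2.t();
  fmat dG1 = layernorm_bwd(dN1, c.lnh, p.head_ln_g, g.head_ln_g, g.head_ln_b);
  fmat dZ1 = dG1 % gelu_bwd(c.Z1, c.T1);
  g.head_w1 += c.Hf.t() * dZ1;
  g.head_b1 += sum(dZ1, 0).t();
  fmat dHf = dZ1 * p.head_w1.t();
  return layernorm_bwd(dHf, c.lnf, p.lnf_g, g.lnf_g, g.lnf_b);
}

// Row-wise softmax for the (B*L) x 4 logits.
static fmat softmax_rows4(const fmat& logits) {
  fmat S = logits;
  fvec mx = max(S, 1);
  S.each_col() -= mx;
  S = exp(S);
  fvec sm = sum(S, 1);
  S.each_col() /= sm;
  return S;
}

// Forward for the whole batch; logits (B*L) x 4, rows seq-major.
static fmat forward_batch(const Rcpp::IntegerMatrix& tokens, const Par& p,
                          const Cfg& cfg, const fmat& cosT, const fmat& sinT,
                          std::vector<BlockCache>& bc, HeadCache& hc,
                          std::vector<fmat>* hidden, bool want_cache) {
  int B = tokens.nrow(), L = tokens.ncol();
  fmat X((uword)B * L, cfg.d);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < L; ++t)
      X.row((uword)s * L + t) = p.E.row(tokens(s, t) - 1);
  for (int b = 0; b < cfg.nb; ++b) {
    X = block_fwd(X, p.blocks[b], cfg, B, L, cosT, sinT, bc[b], want_cache);
    if (hidden) (*hidden)[b] = X;
  }
  return head_fwd(X, p, hc);
}

// ---- exported entry points --------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_forward(Rcpp::List params, Rcpp::List config,
                       Rcpp::IntegerMatrix tokens, bool return_hidden,
                       bool return_logits) {
  Cfg cfg = parse_cfg(config);
  Par par = parse_par(params, cfg);
  int B = tokens.nrow(), L = tokens.ncol();
  fmat cosT, sinT;
  rope_tables(B, L, cfg.dh, cfg.rope_base, cosT, sinT);
  std::vector<BlockCache> bc(cfg.nb);
  HeadCache hc;
  std::vector<fmat> hidden(cfg.nb);
  fmat logits = forward_batch(tokens, par, cfg, cosT, sinT, bc, hc,
                              return_hidden ? &hidden : nullptr, false);
  fmat probs = softmax_rows4(logits);
  Rcpp::NumericVector probs_out((R_xlen_t)B * L * 4);
  probs_out.attr("dim") = Rcpp::IntegerVector::create(B, L, 4);
  Rcpp::NumericVector logits_out;
  if (return_logits) {
    logits_out = Rcpp::NumericVector((R_xlen_t)B * L * 4);
    logits_out.attr("dim") = Rcpp::IntegerVector::create(B, L, 4);
  }
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < L; ++t)
      for (int k = 0; k < 4; ++k) {
        probs_out[s + (R_xlen_t)B * (t + (R_xlen_t)L * k)] = probs((uword)s * L + t, k);
        if (return_logits)
          logits_out[s + (R_xlen_t)B * (t + (R_xlen_t)L * k)] = logits((uword)s * L + t, k);
      }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("probs") = probs_out);
  if (return_logits) out["logits"] = logits_out;
  if (return_hidden) {
    Rcpp::NumericVector hidden_out((R_xlen_t)B * cfg.nb * L * cfg.d);
    hidden_out.attr("dim") = Rcpp::IntegerVector::create(B, cfg.nb, L, cfg.d);
    for (int s = 0; s < B; ++s)
      for (int b = 0; b < cfg.nb; ++b)
        for (int t = 0; t < L; ++t)
          for (int k = 0; k < cfg.d; ++k)
            hidden_out[s + (R_xlen_t)B * (b + (R_xlen_t)cfg.nb * (t + (R_xlen_t)L * k))] =
                hidden[b]((uword)s * L + t, k);
    out["hidden"] = hidden_out;
  }
  return out;
}

static void push_grads(Rcpp::List& out, const Par& g, const Cfg& cfg) {
  out["embed"] = conv_to<mat>::from(g.E);
  for (int b = 0; b < cfg.nb; ++b) {
    std::string pre = "b" + std::to_string(b) + "_";
    const BlockP& bl = g.blocks[b];
    out[pre + "ln1_g"] = conv_to<vec>::from(bl.ln1_g);
    out[pre + "ln1_b"] = conv_to<vec>::from(bl.ln1_b);
    out[pre + "w_qkv"] = conv_to<mat>::from(bl.w_qkv);
    out[pre + "b_qkv"] = conv_to<vec>::from(bl.b_qkv);
    out[pre + "w_o"] = conv_to<mat>::from(bl.w_o);
    out[pre + "b_o"] = conv_to<vec>::from(bl.b_o);
    out[pre + "ln2_g"] = conv_to<vec>::from(bl.ln2_g);
    out[pre + "ln2_b"] = conv_to<vec>::from(bl.ln2_b);
    out[pre + "w_ff1"] = conv_to<mat>::from(bl.w_ff1);
    out[pre + "b_ff1"] = conv_to<vec>::from(bl.b_ff1);
    out[pre + "w_ff2"] = conv_to<mat>::from(bl.w_ff2);
    out[pre + "b_ff2"] = conv_to<vec>::from(bl.b_ff2);
  }
  out["lnf_g"] = conv_to<vec>::from(g.lnf_g);
  out["lnf_b"] = conv_to<vec>::from(g.lnf_b);
  out["head_w1"] = conv_to<mat>::from(g.head_w1);
  out["head_b1"] = conv_to<vec>::from(g.head_b1);
  out["head_ln_g"] = conv_to<vec>::from(g.head_ln_g);
  out["head_ln_b"] = conv_to<vec>::from(g.head_ln_b);
  out["head_w2"] = conv_to<mat>::from(g.head_w2);
  out["head_b2"] = conv_to<vec>::from(g.head_b2);
}

// Masked-LM loss (mean NLL of the original base over loss positions) plus the
// Fourier prior on the per-position probability of the original base, with N
// positions mean-filled. Loss positions never include N positions (enforced on
// the R side when plans are built). Returns loss components and, optionally,
// gradients with respect to every parameter.
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List params, Rcpp::List config,
                         Rcpp::IntegerMatrix toks_in, Rcpp::IntegerMatrix toks_orig,
                         Rcpp::IntegerMatrix loss_mask, double lambda,
                         bool use_prior, Rcpp::NumericVector watt, double eps,
                         bool want_grad) {
  Cfg cfg = parse_cfg(config);
  Par par = parse_par(params, cfg);
  Par grad = want_grad ? zeros_like(par) : Par();
  int B = toks_in.nrow(), L = toks_in.ncol();
  int K = L / 2;
  fmat cosT, sinT;
  rope_tables(B, L, cfg.dh, cfg.rope_base, cosT, sinT);

  // DFT tables for the prior
  fmat Cdft, Sdft;
  fvec w_att;
  if (use_prior) {
    Cdft.set_size(K, L);
    Sdft.set_size(K, L);
    for (int i = 1; i <= K; ++i)
      for (int t = 0; t < L; ++t) {
        double th = 2.0 * M_PI * (double)i * t / L;
        Cdft(i - 1, t) = (float)std::cos(th);
        Sdft(i - 1, t) = (float)std::sin(th);
      }
    w_att = conv_to<fvec>::from(Rcpp::as<vec>(watt));
  }

  std::vector<BlockCache> bc(cfg.nb);
  HeadCache hc;
  fmat logits = forward_batch(toks_in, par, cfg, cosT, sinT, bc, hc, nullptr,
                              want_grad);
  fmat probs = softmax_rows4(logits);

  std::vector<int> n_loss(B, 0);
  int b_eff = 0, n_loss_total = 0;
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < L; ++t)
      if (loss_mask(s, t)) n_loss[s]++;
    if (n_loss[s] > 0) b_eff++;
    n_loss_total += n_loss[s];
  }

  double mlm_sum = 0.0, att_sum = 0.0;
  fmat dlogits;
  if (want_grad) dlogits = fmat((uword)B * L, 4, fill::zeros);

  for (int s = 0; s < B; ++s) {
    uword r0 = (uword)s * L;
    if (n_loss[s] > 0) {
      double nll = 0.0;
      float inv = 1.0f / ((float)n_loss[s] * std::max(b_eff, 1));
      for (int t = 0; t < L; ++t) {
        if (!loss_mask(s, t)) continue;
        int tgt = toks_orig(s, t) - 1; // 0..3, N excluded upstream
        float pt = std::max(probs(r0 + t, tgt), 1e-12f);
        nll += -std::log((double)pt);
        if (want_grad)
          for (int k = 0; k < 4; ++k)
            dlogits(r0 + t, k) += (probs(r0 + t, k) - (k == tgt ? 1.0f : 0.0f)) * inv;
      }
      mlm_sum += nll / n_loss[s];
    }

    if (use_prior) {
      // profile of the original base; N positions mean-filled
      fvec prof(L);
      std::vector<int> nn_idx;
      nn_idx.reserve(L);
      double nn_sum = 0.0;
      for (int t = 0; t < L; ++t) {
        int o = toks_orig(s, t);
        if (o <= 4) {
          prof(t) = probs(r0 + t, o - 1);
          nn_sum += prof(t);
          nn_idx.push_back(t);
        }
      }
      int nn = nn_idx.size();
      if (nn >= 4) {
        float fill = (float)(nn_sum / nn);
        for (int t = 0; t < L; ++t) if (toks_orig(s, t) > 4) prof(t) = fill;
        fvec Re = Cdft * prof;
        fvec Im = -(Sdft * prof);
        fvec m = sqrt(square(Re) + square(Im));
        float S = accu(m) + (float)eps;
        fvec a = m / S;
        float l_att = 1.0f - dot(w_att, a);
        att_sum += l_att;
        if (want_grad && lambda > 0) {
          fvec dLdm = -(w_att - dot(w_att, a)) / S;
          fvec cre(K), cim(K);
          for (int i = 0; i < K; ++i) {
            if (m(i) > 0) {
              cre(i) = dLdm(i) * Re(i) / m(i);
              cim(i) = dLdm(i) * Im(i) / m(i);
            } else {
              cre(i) = 0; cim(i) = 0;
            }
          }
          fvec gp = Cdft.t() * cre - Sdft.t() * cim; // dL_att/d prof
          // mean-fill chain rule: N entries distribute over non-N entries
          double gsum_n = 0.0;
          for (int t = 0; t < L; ++t) if (toks_orig(s, t) > 4) gsum_n += gp(t);
          float add = (float)(gsum_n / nn);
          float sc = (float)lambda / B;
          for (int t : nn_idx) {
            float gph = (gp(t) + add) * sc;
            int o = toks_orig(s, t) - 1;
            float po = probs(r0 + t, o);
            for (int k = 0; k < 4; ++k)
              dlogits(r0 + t, k) += gph * po * ((k == o ? 1.0f : 0.0f) - probs(r0 + t, k));
          }
        }
      }
    }
  }

  if (want_grad) {
    fmat dX = head_bwd(dlogits, par, grad, hc);
    for (int b = cfg.nb - 1; b >= 0; --b)
      dX = block_bwd(dX, par.blocks[b], grad.blocks[b], cfg, B, L, cosT, sinT, bc[b]);
    for (int s = 0; s < B; ++s)
      for (int t = 0; t < L; ++t)
        grad.E.row(toks_in(s, t) - 1) += dX.row((uword)s * L + t);
    grad.E.row(4).zeros(); // N embedding is pinned at zero, never updated
  }

  double mlm = b_eff > 0 ? mlm_sum / b_eff : 0.0;
  double att = use_prior ? att_sum / B : 0.0;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("mlm") = mlm, Rcpp::Named("att") = att,
      Rcpp::Named("total") = mlm + lambda * att,
      Rcpp::Named("n_loss") = n_loss_total);
  if (want_grad) {
    Rcpp::List gl;
    push_grads(gl, grad, cfg);
    out["grads"] = gl;
  }
  return out;
}
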
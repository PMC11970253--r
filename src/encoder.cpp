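// Transformer encoder core: pre-norm blocks (multi-head self-attention +
// GELU feedforward), masked-token cross-entropy, sequence classification
// head, and analytic backpropagation. Kept in C++ so that desk-scale
// pretraining and fine-tuning run inside test budgets.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uvec;

namespace {

struct Cfg {
  int L, d, h, dh, dff, V, n_layers, pad_id;
  bool tied;  // output head shares the token embedding matrix
};

Cfg read_cfg(const List& config) {
  Cfg c;
  c.L = as<int>(config["max_positions"]);
  c.d = as<int>(config["d_model"]);
  c.h = as<int>(config["n_heads"]);
  c.dff = as<int>(config["d_ff"]);
  c.V = as<int>(config["vocab_size"]);
  c.n_layers = as<int>(config["n_layers"]);
  c.pad_id = as<int>(config["pad_id"]);
  c.tied = config.containsElementNamed("tie_weights") &&
           as<bool>(config["tie_weights"]);
  if (c.d % c.h != 0) stop("d_model must be divisible by n_heads");
  c.dh = c.d / c.h;
  return c;
}

const double LN_EPS = 1e-5;

struct LnCache {
  mat xhat;   // L x d
  vec istd;   // L
};

mat layernorm_fwd(const mat& x, const vec& g, const vec& b, LnCache& cache) {
  vec mu = arma::mean(x, 1);
  vec va = arma::var(x, 1, 1);  // population variance by row
  cache.istd = 1.0 / arma::sqrt(va + LN_EPS);
  cache.xhat = (x.each_col() - mu);
  cache.xhat.each_col() %= cache.istd;
  mat y = cache.xhat;
  y.each_row() %= g.t();
  y.each_row() += b.t();
  return y;
}

// returns dx; accumulates dg, db
mat layernorm_bwd(const mat& dy, const vec& g, const LnCache& cache,
                  vec& dg, vec& db) {
  dg += arma::sum(dy % cache.xhat, 0).t();
  db += arma::sum(dy, 0).t();
  mat dxhat = dy;
  dxhat.each_row() %= g.t();
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cache.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  mat xh2 = cache.xhat;
  xh2.each_col() %= m2;
  dx -= xh2;
  dx.each_col() %= cache.istd;
  return dx;
}

// Fast exponential: range reduction to x = n ln2 + r, degree-7
// polynomial on |r| <= ln2/2 (relative error ~5e-9), scale by 2^n via
// exponent bits. Pure arithmetic, so the compiler can vectorize the
// elementwise loops below.
inline double vexp(double x) {
  if (x < -700.0) return 0.0;
  if (x > 700.0) x = 700.0;
  const double inv_ln2 = 1.4426950408889634;
  const double ln2_hi = 6.93147180369123816490e-01;
  const double ln2_lo = 1.90821492927058770002e-10;
  double nf = std::floor(x * inv_ln2 + 0.5);
  long long n = (long long)nf;
  double r = (x - nf * ln2_hi) - nf * ln2_lo;
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040)))))));
  union { double d; long long i; } u;
  u.i = (n + 1023LL) << 52;
  return p * u.d;
}

inline void fast_exp_inplace(mat& x) {
  double* p = x.memptr();
  const arma::uword n = x.n_elem;
  for (arma::uword i = 0; i < n; ++i) p[i] = vexp(p[i]);
}

// GELU in its sigmoid form: gelu(x) = x * s(1.702 x). The gradient
// formulas below differentiate exactly this forward definition.
inline void gelu_sig(const mat& x, mat& sig_out) {
  sig_out.set_size(x.n_rows, x.n_cols);
  const double* xi = x.memptr();
  double* oi = sig_out.memptr();
  const arma::uword n = x.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    oi[i] = 1.0 / (1.0 + vexp(-1.702 * xi[i]));
  }
}

// grad = s + 1.702 x s (1 - s), with s cached from the forward pass
inline mat gelu_grad_from(const mat& x, const mat& sig) {
  return sig + 1.702 * (x % sig % (1.0 - sig));
}

struct LayerCache {
  mat x_in;          // input to block
  LnCache ln1, ln2;
  mat A;             // ln1 output
  mat Q, K, Vv;      // projections
  std::vector<mat> attn;  // per head L x L
  mat ctx;           // concatenated head contexts
  mat x_mid;         // after attention residual
  mat Bn;            // ln2 output
  mat H1;            // pre-GELU
  mat Sig1;          // s(1.702 H1), cached for backward
  mat G1;            // GELU output
};

struct FwdCache {
  arma::ivec tok;    // 0-based token ids
  uvec pad_keys;     // indices of PAD positions
  mat x0;
  std::vector<LayerCache> layers;
  LnCache lnf;
  mat H;             // final hidden states (after final layer norm)
};

// Parameters converted once per exported call; accessed by reference.
struct PMap {
  std::map<std::string, mat> m;
  explicit PMap(const List& p) {
    CharacterVector nms = p.names();
    for (int i = 0; i < p.size(); ++i) {
      m.emplace(std::string(nms[i]), as<mat>(p[i]));
    }
  }
  const mat& at(const std::string& nm) const {
    auto it = m.find(nm);
    if (it == m.end()) stop("missing parameter: " + nm);
    return it->second;
  }
};

const mat& getm(const PMap& p, const std::string& nm) { return p.at(nm); }
vec getv(const PMap& p, const std::string& nm) {
  const mat& x = p.at(nm);
  return vec(const_cast<double*>(x.memptr()), x.n_rows, false, true);
}
std::string lname(int l, const char* suffix) {
  return "l" + std::to_string(l + 1) + "_" + suffix;
}

// Run tokens through n_blocks encoder blocks (+ final LN). Blocks use the
// pre-norm layout: x + MHA(LN1(x)), then x + FF(LN2(x)).
void forward_seq(const IntegerVector& tokens, const PMap& params,
                 const Cfg& cfg, const mat& pos, int n_blocks,
                 FwdCache& cache, bool keep_attn) {
  const int L = tokens.size(), d = cfg.d;
  cache.tok.set_size(L);
  std::vector<arma::uword> padv;
  const mat& emb = getm(params, "emb");
  cache.x0.set_size(L, d);
  // token embeddings scaled by sqrt(d_model) so they are commensurate
  // with the unit-amplitude sinusoidal positions
  const double emb_scale = std::sqrt((double)d);
  for (int i = 0; i < L; ++i) {
    int id = tokens[i] - 1;  // to 0-based
    if (id < 0 || id >= cfg.V) stop("token id out of vocabulary");
    cache.tok[i] = id;
    cache.x0.row(i) = emb.row(id) * emb_scale;
    if (tokens[i] == cfg.pad_id) padv.push_back(i);
  }
  cache.x0 += pos.rows(0, L - 1);
  cache.pad_keys = uvec(padv);

  mat x = cache.x0;
  cache.layers.resize(n_blocks);
  const double scale = 1.0 / std::sqrt((double)cfg.dh);
  for (int l = 0; l < n_blocks; ++l) {
    LayerCache& lc = cache.layers[l];
    lc.x_in = x;
    lc.A = layernorm_fwd(x, getv(params, lname(l, "ln1_g")),
                         getv(params, lname(l, "ln1_b")), lc.ln1);
    lc.Q = lc.A * getm(params, lname(l, "Wq"));
    lc.Q.each_row() += getv(params, lname(l, "bq")).t();
    lc.K = lc.A * getm(params, lname(l, "Wk"));
    lc.K.each_row() += getv(params, lname(l, "bk")).t();
    lc.Vv = lc.A * getm(params, lname(l, "Wv"));
    lc.Vv.each_row() += getv(params, lname(l, "bv")).t();
    lc.ctx.set_size(L, d);
    lc.attn.resize(cfg.h);
    for (int hh = 0; hh < cfg.h; ++hh) {
      int c0 = hh * cfg.dh, c1 = (hh + 1) * cfg.dh - 1;
      mat Qh = lc.Q.cols(c0, c1), Kh = lc.K.cols(c0, c1),
          Vh = lc.Vv.cols(c0, c1);
      mat S = Qh * Kh.t() * scale;
      if (!cache.pad_keys.is_empty()) {
        for (arma::uword j = 0; j < cache.pad_keys.n_elem; ++j)
          S.col(cache.pad_keys[j]).fill(-1e30);
      }
      // row-wise softmax
      vec mx = arma::max(S, 1);
      S.each_col() -= mx;
      fast_exp_inplace(S);
      vec sm = arma::sum(S, 1);
      S.each_col() /= sm;
      lc.attn[hh] = S;
      lc.ctx.cols(c0, c1) = S * Vh;
    }
    mat attn_out = lc.ctx * getm(params, lname(l, "Wo"));
    attn_out.each_row() += getv(params, lname(l, "bo")).t();
    lc.x_mid = x + attn_out;
    lc.Bn = layernorm_fwd(lc.x_mid, getv(params, lname(l, "ln2_g")),
                          getv(params, lname(l, "ln2_b")), lc.ln2);
    lc.H1 = lc.Bn * getm(params, lname(l, "W1"));
    lc.H1.each_row() += getv(params, lname(l, "b1")).t();
    gelu_sig(lc.H1, lc.Sig1);
    lc.G1 = lc.H1 % lc.Sig1;
    mat ff = lc.G1 * getm(params, lname(l, "W2"));
    ff.each_row() += getv(params, lname(l, "b2")).t();
    x = lc.x_mid + ff;
    (void)keep_attn;  // attention is cached regardless (needed by backward)
  }
  cache.H = layernorm_fwd(x, getv(params, "lnf_g"), getv(params, "lnf_b"),
                          cache.lnf);
}

struct GradStore {
  std::map<std::string, mat> g;
  mat& at(const std::string& nm, int r, int c) {
    auto it = g.find(nm);
    if (it == g.end()) {
      it = g.emplace(nm, mat(r, c, arma::fill::zeros)).first;
    }
    return it->second;
  }
};

// Backprop dH (gradient at final hidden states) through the blocks down to
// the embedding table. Blocks with index < freeze_below still propagate
// gradient but their parameter grads are skipped.
void backward_seq(const mat& dH_in, const PMap& params, const Cfg& cfg,
                  FwdCache& cache, GradStore& gs, int n_blocks,
                  int freeze_below) {
  const int d = cfg.d, dff = cfg.dff;
  const double scale = 1.0 / std::sqrt((double)cfg.dh);
  vec g_lnf_g(d, arma::fill::zeros), g_lnf_b(d, arma::fill::zeros);
  mat dx = layernorm_bwd(dH_in, getv(params, "lnf_g"), cache.lnf,
                         g_lnf_g, g_lnf_b);
  { // accumulate into store (as column matrices)
    gs.at("lnf_g", d, 1) += g_lnf_g;
    gs.at("lnf_b", d, 1) += g_lnf_b;
  }

  for (int l = n_blocks - 1; l >= 0; --l) {
    LayerCache& lc = cache.layers[l];
    const int L = lc.x_in.n_rows;
    bool trainable = (l >= freeze_below);
    // FF branch: x_out = x_mid + G1 W2 + b2
    mat dG1 = dx * getm(params, lname(l, "W2")).t();
    if (trainable) {
      gs.at(lname(l, "W2"), dff, d) += lc.G1.t() * dx;
      gs.at(lname(l, "b2"), d, 1) += arma::sum(dx, 0).t();
    }
    mat dH1 = dG1 % gelu_grad_from(lc.H1, lc.Sig1);
    mat dBn = dH1 * getm(params, lname(l, "W1")).t();
    if (trainable) {
      gs.at(lname(l, "W1"), d, dff) += lc.Bn.t() * dH1;
      gs.at(lname(l, "b1"), dff, 1) += arma::sum(dH1, 0).t();
    }
    vec g2g(d, arma::fill::zeros), g2b(d, arma::fill::zeros);
    mat dx_mid = layernorm_bwd(dBn, getv(params, lname(l, "ln2_g")),
                               lc.ln2, g2g, g2b);
    if (trainable) {
      gs.at(lname(l, "ln2_g"), d, 1) += g2g;
      gs.at(lname(l, "ln2_b"), d, 1) += g2b;
    }
    dx_mid += dx;  // residual

    // attention branch: x_mid = x_in + ctx Wo + bo
    mat dctx = dx_mid * getm(params, lname(l, "Wo")).t();
    if (trainable) {
      gs.at(lname(l, "Wo"), d, d) += lc.ctx.t() * dx_mid;
      gs.at(lname(l, "bo"), d, 1) += arma::sum(dx_mid, 0).t();
    }
    mat dQ(L, d, arma::fill::zeros), dK(L, d, arma::fill::zeros),
        dV(L, d, arma::fill::zeros);
    for (int hh = 0; hh < cfg.h; ++hh) {
      int c0 = hh * cfg.dh, c1 = (hh + 1) * cfg.dh - 1;
      mat dctx_h = dctx.cols(c0, c1);
      const mat& W = lc.attn[hh];
      mat Vh = lc.Vv.cols(c0, c1);
      mat dW = dctx_h * Vh.t();
      dV.cols(c0, c1) = W.t() * dctx_h;
      vec rs = arma::sum(dW % W, 1);
      dW.each_col() -= rs;
      mat dS = W % dW;
      dQ.cols(c0, c1) = dS * lc.K.cols(c0, c1) * scale;
      dK.cols(c0, c1) = dS.t() * lc.Q.cols(c0, c1) * scale;
    }
    mat dA = dQ * getm(params, lname(l, "Wq")).t() +
             dK * getm(params, lname(l, "Wk")).t() +
             dV * getm(params, lname(l, "Wv")).t();
    if (trainable) {
      gs.at(lname(l, "Wq"), d, d) += lc.A.t() * dQ;
      gs.at(lname(l, "bq"), d, 1) += arma::sum(dQ, 0).t();
      gs.at(lname(l, "Wk"), d, d) += lc.A.t() * dK;
      gs.at(lname(l, "bk"), d, 1) += arma::sum(dK, 0).t();
      gs.at(lname(l, "Wv"), d, d) += lc.A.t() * dV;
      gs.at(lname(l, "bv"), d, 1) += arma::sum(dV, 0).t();
    }
    vec g1g(d, arma::fill::zeros), g1b(d, arma::fill::zeros);
    mat dx_in = layernorm_bwd(dA, getv(params, lname(l, "ln1_g")),
                              lc.ln1, g1g, g1b);
    if (trainable) {
      gs.at(lname(l, "ln1_g"), d, 1) += g1g;
      gs.at(lname(l, "ln1_b"), d, 1) += g1b;
    }
    dx = dx_in + dx_mid;  // residual into block input
  }

  // embedding gradient (positional encoding is fixed); the sqrt(d)
  // input scaling enters the chain rule
  if (freeze_below <= 0) {
    const double emb_scale = std::sqrt((double)d);
    mat& demb = gs.at("emb", cfg.V, d);
    for (arma::uword i = 0; i < cache.tok.n_elem; ++i) {
      demb.row(cache.tok[i]) += dx.row(i) * emb_scale;
    }
  }
}

List grads_to_list(GradStore& gs) {
  List out;
  CharacterVector nms;
  for (auto& kv : gs.g) {
    out.push_back(wrap(kv.second));
    nms.push_back(kv.first);
  }
  out.attr("names") = nms;
  return out;
}

// softmax cross-entropy at selected rows of H against target token ids.
// Returns loss (mean over rows); fills dH rows if dH != nullptr.
double token_ce(const mat& H, const uvec& rows, const arma::ivec& targets,
                const PMap& params, GradStore* gs, mat* dH, const Cfg& cfg) {
  const int V = cfg.V;
  const mat& Wout = cfg.tied ? getm(params, "emb")
                             : getm(params, "Wout");
  vec bout = getv(params, "bout");
  const int m = rows.n_elem;
  mat Hm(m, H.n_cols);
  for (int i = 0; i < m; ++i) Hm.row(i) = H.row(rows[i]);
  mat Z = cfg.tied ? mat(Hm * Wout.t()) : mat(Hm * Wout);
  Z.each_row() += bout.t();
  vec mx = arma::max(Z, 1);
  Z.each_col() -= mx;
  mat E = arma::exp(Z);
  vec sm = arma::sum(E, 1);
  mat P = E;
  P.each_col() /= sm;
  double loss = 0.0;
  for (int i = 0; i < m; ++i) {
    loss -= std::log(std::max(P(i, targets[i]), 1e-300));
  }
  loss /= m;
  if (gs && dH) {
    mat dZ = P;
    for (int i = 0; i < m; ++i) dZ(i, targets[i]) -= 1.0;
    dZ /= m;
    if (cfg.tied) {
      gs->at("emb", V, H.n_cols) += dZ.t() * Hm;
    } else {
      gs->at("Wout", H.n_cols, V) += Hm.t() * dZ;
    }
    gs->at("bout", V, 1) += arma::sum(dZ, 0).t();
    mat dHm = cfg.tied ? mat(dZ * Wout) : mat(dZ * Wout.t());
    for (int i = 0; i < m; ++i) dH->row(rows[i]) += dHm.row(i);
  }
  return loss;
}

}  // namespace

// Forward pass for inference: final hidden states, optional token
// probability rows, optional attention maps.
// tokens: B x L integer matrix of 1-based ids.
// prob_positions: list (length B) of 1-based positions wanting q rows
//                 (NULL elements -> none).
// [[Rcpp::export]]
List cpp_encoder_forward(IntegerMatrix tokens, List params, List config,
                         arma::mat pos, Nullable<List> prob_positions,
                         bool want_states, bool want_attn) {
  Cfg cfg = read_cfg(config);
  PMap pm(params);
  const int B = tokens.nrow();
  List states(B), probs(B), attn(B);
  List pp;
  bool has_pp = prob_positions.isNotNull();
  if (has_pp) pp = List(prob_positions);
  const mat& Wout = cfg.tied ? getm(pm, "emb") : getm(pm, "Wout");
  vec bout = getv(pm, "bout");
  for (int b = 0; b < B; ++b) {
    FwdCache cache;
    forward_seq(tokens(b, _), pm, cfg, pos, cfg.n_layers, cache, true);
    if (want_states) states[b] = wrap(cache.H);
    if (has_pp && !Rf_isNull(pp[b])) {
      IntegerVector q = pp[b];
      mat Hm(q.size(), cfg.d);
      for (int i = 0; i < q.size(); ++i) Hm.row(i) = cache.H.row(q[i] - 1);
      mat Z = cfg.tied ? mat(Hm * Wout.t()) : mat(Hm * Wout);
      Z.each_row() += bout.t();
      vec mx = arma::max(Z, 1);
      Z.each_col() -= mx;
      mat E = arma::exp(Z);
      vec sm = arma::sum(E, 1);
      E.each_col() /= sm;
      probs[b] = wrap(E);
    }
    if (want_attn) {
      List layer_maps(cfg.n_layers);
      for (int l = 0; l < cfg.n_layers; ++l) {
        arma::cube cb(tokens.ncol(), tokens.ncol(), cfg.h);
        for (int hh = 0; hh < cfg.h; ++hh) {
          cb.slice(hh) = cache.layers[l].attn[hh];
        }
        layer_maps[l] = wrap(cb);
      }
      attn[b] = layer_maps;
    }
  }
  return List::create(_["states"] = states, _["probs"] = probs,
                      _["attn"] = attn);
}

// Masked-LM loss (mean over sequences of per-sequence mean CE) and,
// optionally, parameter gradients accumulated over the batch.
// [[Rcpp::export]]
List cpp_masked_lm_fb(IntegerMatrix tokens, List mask_positions,
                      List target_ids, List params, List config,
                      arma::mat pos, bool want_grad) {
  Cfg cfg = read_cfg(config);
  PMap pm(params);
  const int B = tokens.nrow();
  if (mask_positions.size() != B || target_ids.size() != B) {
    stop("mask_positions/target_ids must have one element per sequence");
  }
  GradStore gs;
  double total = 0.0;
  for (int b = 0; b < B; ++b) {
    IntegerVector mp = mask_positions[b];
    IntegerVector ti = target_ids[b];
    if (mp.size() == 0) stop("empty mask set in batch");
    if (mp.size() != ti.size()) stop("mask/target length mismatch");
    FwdCache cache;
    forward_seq(tokens(b, _), pm, cfg, pos, cfg.n_layers, cache, false);
    uvec rows(mp.size());
    arma::ivec tg(ti.size());
    for (int i = 0; i < mp.size(); ++i) {
      rows[i] = mp[i] - 1;
      tg[i] = ti[i] - 1;
    }
    if (want_grad) {
      mat dH(tokens.ncol(), cfg.d, arma::fill::zeros);
      total += token_ce(cache.H, rows, tg, pm, &gs, &dH, cfg);
      backward_seq(dH, pm, cfg, cache, gs, cfg.n_layers, 0);
    } else {
      total += token_ce(cache.H, rows, tg, pm, nullptr, nullptr, cfg);
    }
  }
  total /= B;
  if (want_grad) {
    for (auto& kv : gs.g) kv.second /= B;
  }
  if (want_grad) {
    return List::create(_["loss"] = total, _["grads"] = grads_to_list(gs));
  }
  return List::create(_["loss"] = total);
}

// Classification forward/backward. The encoder stack has
// n_layers + 1 blocks: the pretrained blocks plus an appended
// task-specific block (params l{n_layers+1}_*). Mean-pooled final states
// feed a linear softmax head (clf_W, clf_b). freeze_below: number of
// leading blocks (and the embedding, if > 0) excluded from gradients.
// [[Rcpp::export]]
List cpp_classifier_fb(IntegerMatrix tokens, IntegerVector labels,
                       List params, List config, arma::mat pos,
                       int freeze_below, bool want_grad) {
  Cfg cfg = read_cfg(config);
  PMap pm(params);
  const int B = tokens.nrow();
  const int n_blocks = cfg.n_layers + 1;
  const mat& Wc = getm(pm, "clf_W");
  vec bc = getv(pm, "clf_b");
  const int K = Wc.n_cols;
  GradStore gs;
  double total = 0.0;
  const int L = tokens.ncol();
  for (int b = 0; b < B; ++b) {
    FwdCache cache;
    forward_seq(tokens(b, _), pm, cfg, pos, n_blocks, cache, false);
    rowvec pooled = arma::mean(cache.H, 0);
    rowvec z = pooled * Wc + bc.t();
    z -= z.max();
    rowvec e = arma::exp(z);
    rowvec p = e / arma::accu(e);
    int y = labels[b] - 1;
    total -= std::log(std::max(p(y), 1e-300));
    if (want_grad) {
      rowvec dz = p;
      dz(y) -= 1.0;
      dz /= B;
      gs.at("clf_W", cfg.d, K) += pooled.t() * dz;
      gs.at("clf_b", K, 1) += dz.t();
      rowvec dpooled = dz * Wc.t();
      rowvec dpr = dpooled / (double)L;
      mat dH(L, cfg.d);
      dH.each_row() = dpr;
      backward_seq(dH, pm, cfg, cache, gs, n_blocks, freeze_below);
    }
  }
  total /= B;
  if (want_grad) {
    return List::create(_["loss"] = total, _["grads"] = grads_to_list(gs));
  }
  return List::create(_["loss"] = total);
}

// Class probability matrix (B x K) for the classifier stack.
// [[Rcpp::export]]
arma::mat cpp_classifier_forward(IntegerMatrix tokens, List params,
                                 List config, arma::mat pos) {
  Cfg cfg = read_cfg(config);
  PMap pm(params);
  const int B = tokens.nrow();
  const int n_blocks = cfg.n_layers + 1;
  const mat& Wc = getm(pm, "clf_W");
  vec bc = getv(pm, "clf_b");
  mat out(B, Wc.n_cols);
  for (int b = 0; b < B; ++b) {
    FwdCache cache;
    forward_seq(tokens(b, _), pm, cfg, pos, n_blocks, cache, false);
    rowvec pooled = arma::mean(cache.H, 0);
    rowvec z = pooled * Wc + bc.t();
    z -= z.max();
    rowvec e = arma::exp(z);
    out.row(b) = e / arma::accu(e);
  }
  return out;
}
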
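// Compiled kernels for the decoder-only transformer: full-sequence forward,
// backward from arbitrary logit gradients, and the autoregressive decoding
// loop.  The R implementations of the same math remain available as the
// reference backend; tests assert agreement between the two.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;

namespace {

struct Cfg {
  int n_layers, n_heads, d_model, head_dim, ffn_hidden, vocab, max_len;
  double rope_base, ln_eps;
  bool tie;
};

Cfg read_cfg(const List& config) {
  Cfg c;
  c.n_layers = as<int>(config["n_layers"]);
  c.n_heads = as<int>(config["n_heads"]);
  c.d_model = as<int>(config["d_model"]);
  c.head_dim = as<int>(config["head_dim"]);
  c.ffn_hidden = as<int>(config["ffn_hidden"]);
  c.vocab = as<int>(config["vocab_size"]);
  c.max_len = as<int>(config["max_len"]);
  c.rope_base = as<double>(config["rope_base"]);
  c.ln_eps = as<double>(config["ln_eps"]);
  c.tie = as<bool>(config["tie_embeddings"]);
  return c;
}

// no-copy views into the R parameter list
mat getm(const List& p, const std::string& nm) {
  NumericMatrix m = p[nm];
  return mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
vec getv(const List& p, const std::string& nm) {
  NumericVector v = p[nm];
  return vec(v.begin(), v.size(), false, true);
}
std::string lname(int k, const char* suffix) {
  return "l" + std::to_string(k + 1) + "." + suffix;
}

struct LnCache { mat xhat; vec inv_sd; };

mat ln_forward(const mat& x, const vec& g, const vec& b, double eps,
               LnCache* cache) {
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  vec v = arma::mean(xc % xc, 1);
  vec inv_sd = 1.0 / arma::sqrt(v + eps);
  mat xhat = xc.each_col() % inv_sd;
  if (cache) { cache->xhat = xhat; cache->inv_sd = inv_sd; }
  mat y = xhat.each_row() % g.t();
  y.each_row() += b.t();
  return y;
}

// backward through layer norm; accumulates dg/db, returns dx
mat ln_backward(const mat& dy, const LnCache& c, const vec& g,
                vec& dg, vec& db) {
  dg = arma::sum(dy % c.xhat, 0).t();
  db = arma::sum(dy, 0).t();
  mat dxhat = dy.each_row() % g.t();
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % c.xhat, 1);
  mat dx = dxhat.each_col() - m1;
  dx -= c.xhat.each_col() % m2;
  dx.each_col() %= c.inv_sd;
  return dx;
}

// rotary tables: cos/sin, (max_pos x half)
void rope_tables(int max_pos, int head_dim, double base, mat& C, mat& S) {
  int half = head_dim / 2;
  C.set_size(max_pos, half);
  S.set_size(max_pos, half);
  for (int j = 0; j < half; ++j) {
    double inv_freq = std::pow(base, -2.0 * j / head_dim);
    for (int t = 0; t < max_pos; ++t) {
      C(t, j) = std::cos(t * inv_freq);
      S(t, j) = std::sin(t * inv_freq);
    }
  }
}

// apply rotary rotation in place to all heads of a (N x d) matrix whose row
// positions are given by pos (0-based); inverse = transpose rotation.
void rope_rotate(mat& X, const arma::ivec& pos, const mat& C, const mat& S,
                 int n_heads, int head_dim, bool inverse) {
  int half = head_dim / 2;
  for (int h = 0; h < n_heads; ++h) {
    int off = h * head_dim;
    for (arma::uword r = 0; r < X.n_rows; ++r) {
      int t = pos(r);
      for (int j = 0; j < half; ++j) {
        double x1 = X(r, off + j), x2 = X(r, off + half + j);
        double c = C(t, j), s = S(t, j);
        if (!inverse) {
          X(r, off + j) = x1 * c - x2 * s;
          X(r, off + half + j) = x1 * s + x2 * c;
        } else {
          X(r, off + j) = x1 * c + x2 * s;
          X(r, off + half + j) = -x1 * s + x2 * c;
        }
      }
    }
  }
}

struct LayerCache {
  mat x_in, Q, K, V, O, x_mid, G, U, sigG, SU;
  LnCache ln1, ln2;
  std::vector<mat> P;  // attention probs per (b, h)
};

struct FwdCache {
  std::vector<LayerCache> layers;
  LnCache lnf;
  mat x_final_in, hf;
};

// full-sequence forward; ids (B x T) 0-based; rows of activations are
// grouped by sequence: row b*T + t.
mat forward_core(const List& params, const Cfg& cfg, const arma::imat& ids,
                 FwdCache* FC) {
  int B = ids.n_rows, T = ids.n_cols, d = cfg.d_model;
  int nh = cfg.n_heads, hd = cfg.head_dim;
  double scale = 1.0 / std::sqrt((double)hd);
  mat RC, RS;
  rope_tables(T, hd, cfg.rope_base, RC, RS);
  arma::ivec pos_of_row(B * T);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) pos_of_row(b * T + t) = t;
  const mat emb = getm(params, "tok_emb");
  mat x(B * T, d);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) x.row(b * T + t) = emb.row(ids(b, t));
  if (FC) FC->layers.resize(cfg.n_layers);
  for (int k = 0; k < cfg.n_layers; ++k) {
    LayerCache* L = FC ? &FC->layers[k] : nullptr;
    const vec ln1_g = getv(params, lname(k, "ln1_g"));
    const vec ln1_b = getv(params, lname(k, "ln1_b"));
    LnCache ln1c;
    mat a = ln_forward(x, ln1_g, ln1_b, cfg.ln_eps, &ln1c);
    mat qkv = a * getm(params, lname(k, "w_qkv"));
    mat Q = qkv.cols(0, d - 1);
    mat K = qkv.cols(d, 2 * d - 1);
    mat V = qkv.cols(2 * d, 3 * d - 1);
    rope_rotate(Q, pos_of_row, RC, RS, nh, hd, false);
    rope_rotate(K, pos_of_row, RC, RS, nh, hd, false);
    mat O(B * T, d, arma::fill::zeros);
    if (L) L->P.resize((size_t)B * nh);
    for (int b = 0; b < B; ++b) {
      int r0 = b * T;
      for (int h = 0; h < nh; ++h) {
        int c0 = h * hd;
        mat Qb = Q.submat(r0, c0, r0 + T - 1, c0 + hd - 1);
        mat Kb = K.submat(r0, c0, r0 + T - 1, c0 + hd - 1);
        mat S = Qb * Kb.t() * scale;
        // causal softmax row-wise over columns 0..i
        for (int i = 0; i < T; ++i) {
          double mx = S(i, 0);
          for (int j = 1; j <= i; ++j) mx = std::max(mx, S(i, j));
          double sum = 0;
          for (int j = 0; j <= i; ++j) { S(i, j) = std::exp(S(i, j) - mx); sum += S(i, j); }
          for (int j = 0; j <= i; ++j) S(i, j) /= sum;
          for (int j = i + 1; j < T; ++j) S(i, j) = 0;
        }
        O.submat(r0, c0, r0 + T - 1, c0 + hd - 1) =
          S * V.submat(r0, c0, r0 + T - 1, c0 + hd - 1);
        if (L) L->P[(size_t)b * nh + h] = S;
      }
    }
    mat attn = O * getm(params, lname(k, "w_o"));
    mat x_mid = x + attn;
    LnCache ln2c;
    mat a2 = ln_forward(x_mid, getv(params, lname(k, "ln2_g")),
                        getv(params, lname(k, "ln2_b")), cfg.ln_eps, &ln2c);
    mat G = a2 * getm(params, lname(k, "w_gate"));
    mat U = a2 * getm(params, lname(k, "w_up"));
    mat sigG = 1.0 / (1.0 + arma::exp(-G));
    mat SU = (G % sigG) % U;
    mat ffn = SU * getm(params, lname(k, "w_down"));
    if (L) {
      L->x_in = x; L->ln1 = ln1c; L->Q = Q; L->K = K; L->V = V; L->O = O;
      L->x_mid = x_mid; L->ln2 = ln2c; L->G = G; L->U = U; L->sigG = sigG;
      L->SU = SU;
    }
    x = x_mid + ffn;
  }
  LnCache lnfc;
  mat hf = ln_forward(x, getv(params, "lnf_g"), getv(params, "lnf_b"),
                      cfg.ln_eps, &lnfc);
  mat w_head = cfg.tie ? getm(params, "tok_emb").t() : getm(params, "w_head");
  if (FC) { FC->lnf = lnfc; FC->x_final_in = x; FC->hf = hf; }
  return hf * w_head;  // (B*T x V), rows grouped by sequence
}

} // namespace

namespace {

NumericVector logits_to_array(const mat& logits, int B, int T, int V) {
  NumericVector out((size_t)B * T * V);
  out.attr("dim") = IntegerVector::create(B, T, V);
  for (int v = 0; v < V; ++v)
    for (int t = 0; t < T; ++t)
      for (int b = 0; b < B; ++b)
        out[(size_t)v * B * T + (size_t)t * B + b] = logits(b * T + t, v);
  return out;
}

arma::imat ids_to_imat(const IntegerMatrix& ids) {
  arma::imat idm(ids.nrow(), ids.ncol());
  for (int b = 0; b < ids.nrow(); ++b)
    for (int t = 0; t < ids.ncol(); ++t) idm(b, t) = ids(b, t);
  return idm;
}

List backward_core(List& params, const Cfg& cfg, const arma::imat& idm,
                   const NumericVector& dlogits, FwdCache& FC);

} // namespace

// [[Rcpp::export(name = ".cpp_forward")]]
NumericVector cpp_forward(List params, List config, IntegerMatrix ids) {
  Cfg cfg = read_cfg(config);
  arma::imat idm = ids_to_imat(ids);
  mat logits = forward_core(params, cfg, idm, nullptr);
  return logits_to_array(logits, ids.nrow(), ids.ncol(), cfg.vocab);
}

// Forward pass that keeps its activation cache alive as an external pointer,
// so a subsequent backward call does not recompute the forward.
// [[Rcpp::export(name = ".cpp_forward_cache")]]
List cpp_forward_cache(List params, List config, IntegerMatrix ids) {
  Cfg cfg = read_cfg(config);
  arma::imat idm = ids_to_imat(ids);
  XPtr<FwdCache> fc(new FwdCache(), true);
  mat logits = forward_core(params, cfg, idm, fc.get());
  return List::create(
    _["logits"] = logits_to_array(logits, ids.nrow(), ids.ncol(), cfg.vocab),
    _["cache"] = fc);
}

// [[Rcpp::export(name = ".cpp_backward_cached")]]
List cpp_backward_cached(List params, List config, IntegerMatrix ids,
                         NumericVector dlogits, SEXP cache) {
  Cfg cfg = read_cfg(config);
  arma::imat idm = ids_to_imat(ids);
  XPtr<FwdCache> fc(cache);
  return backward_core(params, cfg, idm, dlogits, *fc.get());
}

// [[Rcpp::export(name = ".cpp_backward")]]
List cpp_backward(List params, List config, IntegerMatrix ids,
                  NumericVector dlogits) {
  Cfg cfg = read_cfg(config);
  arma::imat idm = ids_to_imat(ids);
  FwdCache FC;
  forward_core(params, cfg, idm, &FC);
  return backward_core(params, cfg, idm, dlogits, FC);
}

namespace {

List backward_core(List& params, const Cfg& cfg, const arma::imat& idm,
                   const NumericVector& dlogits, FwdCache& FC) {
  int B = idm.n_rows, T = idm.n_cols, d = cfg.d_model;
  int nh = cfg.n_heads, hd = cfg.head_dim;
  double scale = 1.0 / std::sqrt((double)hd);
  // dlogits array (B,T,V) -> (B*T x V) rows grouped by sequence
  mat dl(B * T, cfg.vocab);
  for (int v = 0; v < cfg.vocab; ++v)
    for (int t = 0; t < T; ++t)
      for (int b = 0; b < B; ++b)
        dl(b * T + t, v) = dlogits[(size_t)v * B * T + (size_t)t * B + b];
  List grads;
  mat w_head = cfg.tie ? getm(params, "tok_emb").t() : getm(params, "w_head");
  mat g_head = FC.hf.t() * dl;
  mat dy = dl * w_head.t();
  vec dg, db;
  mat dx = ln_backward(dy, FC.lnf, getv(params, "lnf_g"), dg, db);
  grads["lnf_g"] = wrap(dg);
  grads["lnf_b"] = wrap(db);
  mat RC, RS;
  rope_tables(T, hd, cfg.rope_base, RC, RS);
  arma::ivec pos_of_row(B * T);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) pos_of_row(b * T + t) = t;
  for (int k = cfg.n_layers - 1; k >= 0; --k) {
    LayerCache& L = FC.layers[k];
    // FFN
    mat g_wdown = L.SU.t() * dx;
    mat dSU = dx * getm(params, lname(k, "w_down")).t();
    mat dS_act = dSU % L.U;
    mat dU = dSU % (L.G % L.sigG);
    mat dG = dS_act % (L.sigG % (1.0 + L.G % (1.0 - L.sigG)));
    mat a2 = ln_forward(L.x_mid, getv(params, lname(k, "ln2_g")),
                        getv(params, lname(k, "ln2_b")), cfg.ln_eps, nullptr);
    mat g_wgate = a2.t() * dG;
    mat g_wup = a2.t() * dU;
    mat dA2 = dG * getm(params, lname(k, "w_gate")).t() +
              dU * getm(params, lname(k, "w_up")).t();
    vec dg2, db2;
    mat dx_mid = dx + ln_backward(dA2, L.ln2, getv(params, lname(k, "ln2_g")),
                                  dg2, db2);
    // attention
    mat g_wo = L.O.t() * dx_mid;
    mat dO = dx_mid * getm(params, lname(k, "w_o")).t();
    mat dQ(B * T, d, arma::fill::zeros);
    mat dK(B * T, d, arma::fill::zeros);
    mat dV(B * T, d, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      int r0 = b * T;
      for (int h = 0; h < nh; ++h) {
        int c0 = h * hd;
        const mat& P = L.P[(size_t)b * nh + h];
        mat dOb = dO.submat(r0, c0, r0 + T - 1, c0 + hd - 1);
        mat Vb = L.V.submat(r0, c0, r0 + T - 1, c0 + hd - 1);
        mat dP = dOb * Vb.t();
        dV.submat(r0, c0, r0 + T - 1, c0 + hd - 1) = P.t() * dOb;
        vec rs = arma::sum(dP % P, 1);
        mat dS = P % (dP.each_col() - rs);
        dQ.submat(r0, c0, r0 + T - 1, c0 + hd - 1) =
          dS * L.K.submat(r0, c0, r0 + T - 1, c0 + hd - 1) * scale;
        dK.submat(r0, c0, r0 + T - 1, c0 + hd - 1) =
          dS.t() * L.Q.submat(r0, c0, r0 + T - 1, c0 + hd - 1) * scale;
      }
    }
    rope_rotate(dQ, pos_of_row, RC, RS, nh, hd, true);
    rope_rotate(dK, pos_of_row, RC, RS, nh, hd, true);
    mat dQKV = arma::join_rows(dQ, dK, dV);
    mat a1 = ln_forward(L.x_in, getv(params, lname(k, "ln1_g")),
                        getv(params, lname(k, "ln1_b")), cfg.ln_eps, nullptr);
    mat g_wqkv = a1.t() * dQKV;
    mat dA1 = dQKV * getm(params, lname(k, "w_qkv")).t();
    vec dg1, db1;
    mat dxl = ln_backward(dA1, L.ln1, getv(params, lname(k, "ln1_g")),
                          dg1, db1);
    dx = dx_mid + dxl;
    grads[lname(k, "w_down")] = wrap(g_wdown);
    grads[lname(k, "w_gate")] = wrap(g_wgate);
    grads[lname(k, "w_up")] = wrap(g_wup);
    grads[lname(k, "ln2_g")] = wrap(dg2);
    grads[lname(k, "ln2_b")] = wrap(db2);
    grads[lname(k, "w_o")] = wrap(g_wo);
    grads[lname(k, "w_qkv")] = wrap(g_wqkv);
    grads[lname(k, "ln1_g")] = wrap(dg1);
    grads[lname(k, "ln1_b")] = wrap(db1);
  }
  mat demb(cfg.vocab, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      demb.row(idm(b, t)) += dx.row(b * T + t);
  if (cfg.tie) {
    demb += g_head.t();
  } else {
    grads["w_head"] = wrap(g_head);
  }
  grads["tok_emb"] = wrap(demb);
  return grads;
}

} // namespace

// [[Rcpp::export(name = ".cpp_generate")]]
List cpp_generate(List params, List config, IntegerVector prompt, int n,
                  int max_len, double temperature, IntegerVector forbid,
                  int eos_id, bool greedy) {
  Cfg cfg = read_cfg(config);
  int d = cfg.d_model, nh = cfg.n_heads, hd = cfg.head_dim, V = cfg.vocab;
  double scale = 1.0 / std::sqrt((double)hd);
  mat RC, RS;
  rope_tables(max_len, hd, cfg.rope_base, RC, RS);
  const mat emb = getm(params, "tok_emb");
  mat w_head = cfg.tie ? getm(params, "tok_emb").t() : getm(params, "w_head");
  std::vector<cube> Kc(cfg.n_layers), Vc(cfg.n_layers);
  for (int k = 0; k < cfg.n_layers; ++k) {
    Kc[k].set_size(d, n, max_len);
    Vc[k].set_size(d, n, max_len);
  }
  std::vector<bool> forb(V, false);
  for (int i = 0; i < forbid.size(); ++i) forb[forbid[i]] = true;
  std::vector<std::vector<int>> out_ids(n);
  std::vector<std::vector<double>> out_logp(n);
  std::vector<bool> alive(n, true);
  int n_alive = n;
  mat logits(n, V);
  arma::ivec cur(n);
  int plen = prompt.size();
  vec pvec(V);
  for (int pos = 0; pos < max_len; ++pos) {
    // decide inputs at this position
    if (pos < plen) {
      for (int b = 0; b < n; ++b) cur(b) = prompt[pos];
    } else {
      // sample from previous logits
      for (int b = 0; b < n; ++b) {
        if (!alive[b]) { cur(b) = eos_id; continue; }
        double mx = -arma::datum::inf;
        for (int v = 0; v < V; ++v) {
          pvec(v) = forb[v] ? -arma::datum::inf : logits(b, v) / temperature;
          if (pvec(v) > mx) mx = pvec(v);
        }
        int pick;
        if (greedy) {
          pick = 0; double best = -arma::datum::inf;
          for (int v = 0; v < V; ++v)
            if (pvec(v) > best) { best = pvec(v); pick = v; }
        } else {
          double sum = 0;
          for (int v = 0; v < V; ++v) { pvec(v) = std::exp(pvec(v) - mx); sum += pvec(v); }
          double u = R::unif_rand() * sum, acc = 0;
          pick = V - 1;
          for (int v = 0; v < V; ++v) {
            acc += pvec(v);
            if (u <= acc) { pick = v; break; }
          }
          // guard against picking a forbidden zero-probability token
          while (forb[pick] && pick > 0) --pick;
          out_logp[b].push_back(std::log(pvec(pick) / sum));
        }
        if (greedy) out_logp[b].push_back(0.0);
        out_ids[b].push_back(pick);
        cur(b) = pick;
        if (pick == eos_id) { alive[b] = false; --n_alive; }
      }
      if (n_alive == 0) break;
    }
    if (pos == max_len - 1) break;  // no room to sample another token
    // forward one position
    mat x(n, d);
    for (int b = 0; b < n; ++b) x.row(b) = emb.row(cur(b));
    arma::ivec posv(n, arma::fill::value(pos));
    for (int k = 0; k < cfg.n_layers; ++k) {
      mat a = ln_forward(x, getv(params, lname(k, "ln1_g")),
                         getv(params, lname(k, "ln1_b")), cfg.ln_eps, nullptr);
      mat qkv = a * getm(params, lname(k, "w_qkv"));
      mat q = qkv.cols(0, d - 1);
      mat kk = qkv.cols(d, 2 * d - 1);
      mat vv = qkv.cols(2 * d, 3 * d - 1);
      rope_rotate(q, posv, RC, RS, nh, hd, false);
      rope_rotate(kk, posv, RC, RS, nh, hd, false);
      Kc[k].slice(pos) = kk.t();
      Vc[k].slice(pos) = vv.t();
      mat o(n, d, arma::fill::zeros);
      vec w(pos + 1);
      for (int b = 0; b < n; ++b) {
        if (!alive[b] && pos >= plen) continue;  // skip finished rows
        for (int h = 0; h < nh; ++h) {
          int c0 = h * hd;
          double mx = -arma::datum::inf;
          for (int t = 0; t <= pos; ++t) {
            double s = 0;
            const double* kcol = Kc[k].slice(t).colptr(b);
            for (int c = 0; c < hd; ++c) s += q(b, c0 + c) * kcol[c0 + c];
            s *= scale;
            w(t) = s;
            if (s > mx) mx = s;
          }
          double sum = 0;
          for (int t = 0; t <= pos; ++t) { w(t) = std::exp(w(t) - mx); sum += w(t); }
          for (int t = 0; t <= pos; ++t) {
            double wt = w(t) / sum;
            const double* vcol = Vc[k].slice(t).colptr(b);
            for (int c = 0; c < hd; ++c) o(b, c0 + c) += wt * vcol[c0 + c];
          }
        }
      }
      x += o * getm(params, lname(k, "w_o"));
      mat a2 = ln_forward(x, getv(params, lname(k, "ln2_g")),
                          getv(params, lname(k, "ln2_b")), cfg.ln_eps,
                          nullptr);
      mat G = a2 * getm(params, lname(k, "w_gate"));
      mat U = a2 * getm(params, lname(k, "w_up"));
      mat sigG = 1.0 / (1.0 + arma::exp(-G));
      x += ((G % sigG) % U) * getm(params, lname(k, "w_down"));
    }
    mat hf = ln_forward(x, getv(params, "lnf_g"), getv(params, "lnf_b"),
                        cfg.ln_eps, nullptr);
    logits = hf * w_head;
  }
  List ids_out(n), logp_out(n);
  for (int b = 0; b < n; ++b) {
    ids_out[b] = IntegerVector(out_ids[b].begin(), out_ids[b].end());
    logp_out[b] = NumericVector(out_logp[b].begin(), out_logp[b].end());
  }
  return List::create(_["ids"] = ids_out, _["logp"] = logp_out);
}
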
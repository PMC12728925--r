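// Recurrent next-token policy over SMILES tokens: batched sampling,
// sequence log-probabilities, and backpropagation-through-time gradients
// for weighted log-likelihood objectives (cross-entropy pretraining and
// REINFORCE both reduce to a weighted sum of sequence log-probs).
//
// Parameter layout (R list):
//   emb : E x V    token embeddings, one column per vocabulary index
//   Wx  : list, per layer, 3H x in   (in = E for layer 1, H above)
//   Wh  : list, per layer, 3H x H
//   bx, bh : list, per layer, 3H x 1
//   Wo  : V x H    output projection, bo : V x 1
// Gate row blocks within 3H: [reset; update; candidate].
// Token indices are 1-based (R vocabulary indices); 0 marks padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct GruParams {
  arma::mat emb;
  std::vector<arma::mat> Wx, Wh;
  std::vector<arma::vec> bx, bh;
  arma::mat Wo;
  arma::vec bo;
  int E, H, V, L;
};

GruParams unpack(const List& params) {
  GruParams p;
  p.emb = as<arma::mat>(params["emb"]);
  List Wx = params["Wx"], Wh = params["Wh"], bx = params["bx"], bh = params["bh"];
  p.L = Wx.size();
  for (int l = 0; l < p.L; ++l) {
    p.Wx.push_back(as<arma::mat>(Wx[l]));
    p.Wh.push_back(as<arma::mat>(Wh[l]));
    p.bx.push_back(as<arma::vec>(bx[l]));
    p.bh.push_back(as<arma::vec>(bh[l]));
  }
  p.Wo = as<arma::mat>(params["Wo"]);
  p.bo = as<arma::vec>(params["bo"]);
  p.E = p.emb.n_rows;
  p.V = p.emb.n_cols;
  p.H = p.Wh[0].n_cols;
  return p;
}

inline arma::mat sigmoid(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// One GRU cell step for a whole batch (columns). Optionally records the
// intermediate activations needed for the backward pass.
struct CellCache {
  arma::mat in, h_prev, r, z, n, ah_n;
};

arma::mat gru_cell(const GruParams& p, int l, const arma::mat& in,
                   const arma::mat& h_prev, CellCache* cache) {
  const int H = p.H;
  arma::mat ax = p.Wx[l] * in;
  ax.each_col() += p.bx[l];
  arma::mat ah = p.Wh[l] * h_prev;
  ah.each_col() += p.bh[l];
  arma::mat r = sigmoid(ax.rows(0, H - 1) + ah.rows(0, H - 1));
  arma::mat z = sigmoid(ax.rows(H, 2 * H - 1) + ah.rows(H, 2 * H - 1));
  arma::mat ah_n = ah.rows(2 * H, 3 * H - 1);
  arma::mat n = arma::tanh(ax.rows(2 * H, 3 * H - 1) + r % ah_n);
  arma::mat h = (1.0 - z) % n + z % h_prev;
  if (cache) {
    cache->in = in; cache->h_prev = h_prev; cache->r = r; cache->z = z;
    cache->n = n; cache->ah_n = ah_n;
  }
  return h;
}

// Column-wise log-softmax.
arma::mat log_softmax(const arma::mat& logits) {
  arma::rowvec mx = arma::max(logits, 0);
  arma::mat shifted = logits;
  shifted.each_row() -= mx;
  arma::rowvec lse = arma::log(arma::sum(arma::exp(shifted), 0));
  shifted.each_row() -= lse;
  return shifted;
}

// Deterministic uniform in [0,1) from a mersenne twister, independent of
// compiler-specific distribution implementations.
inline double runif53(std::mt19937_64& rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".clm_sample_cpp")]]
List clm_sample_cpp(List params, int n, int max_len, int bos, int eos,
                    double seed) {
  GruParams p = unpack(params);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  IntegerMatrix tokens(n, max_len);
  IntegerVector lengths(n);
  NumericVector logp(n);
  std::vector<arma::mat> h(p.L, arma::mat(p.H, n, arma::fill::zeros));
  arma::mat in = arma::repmat(p.emb.col(bos - 1), 1, n);
  std::vector<bool> done(n, false);
  int n_done = 0;
  for (int t = 0; t < max_len && n_done < n; ++t) {
    arma::mat x = in;
    for (int l = 0; l < p.L; ++l) {
      h[l] = gru_cell(p, l, x, h[l], nullptr);
      x = h[l];
    }
    arma::mat logits = p.Wo * x;
    logits.each_col() += p.bo;
    arma::mat lsm = log_softmax(logits);
    arma::mat probs = arma::exp(lsm);
    for (int b = 0; b < n; ++b) {
      double u = runif53(rng);  // one draw per column per step, stream-stable
      if (done[b]) continue;
      double acc = 0.0;
      int pick = p.V - 1;
      for (int v = 0; v < p.V; ++v) {
        acc += probs(v, b);
        if (u < acc) { pick = v; break; }
      }
      tokens(b, t) = pick + 1;
      logp[b] += lsm(pick, b);
      lengths[b] = t + 1;
      if (pick + 1 == eos) { done[b] = true; ++n_done; }
      in.col(b) = p.emb.col(pick);
    }
  }
  return List::create(_["tokens"] = tokens, _["lengths"] = lengths,
                      _["logp"] = logp);
}

//' @noRd
// [[Rcpp::export(name = ".clm_logprob_cpp")]]
NumericVector clm_logprob_cpp(List params, IntegerMatrix tokens,
                              IntegerVector lengths, int bos) {
  GruParams p = unpack(params);
  const int B = tokens.nrow();
  int T = 0;
  for (int b = 0; b < B; ++b) T = std::max(T, lengths[b]);
  NumericVector logp(B);
  std::vector<arma::mat> h(p.L, arma::mat(p.H, B, arma::fill::zeros));
  arma::mat in(p.E, B);
  for (int b = 0; b < B; ++b) in.col(b) = p.emb.col(bos - 1);
  for (int t = 0; t < T; ++t) {
    arma::mat x = in;
    for (int l = 0; l < p.L; ++l) {
      h[l] = gru_cell(p, l, x, h[l], nullptr);
      x = h[l];
    }
    arma::mat logits = p.Wo * x;
    logits.each_col() += p.bo;
    arma::mat lsm = log_softmax(logits);
    for (int b = 0; b < B; ++b) {
      if (t < lengths[b]) {
        int tok = tokens(b, t);
        logp[b] += lsm(tok - 1, b);
        in.col(b) = p.emb.col(tok - 1);
      }
    }
  }
  return logp;
}

//' @noRd
// [[Rcpp::export(name = ".clm_grad_cpp")]]
List clm_grad_cpp(List params, IntegerMatrix tokens, IntegerVector lengths,
                  int bos, NumericVector weights) {
  GruParams p = unpack(params);
  const int B = tokens.nrow();
  int T = 0;
  for (int b = 0; b < B; ++b) T = std::max(T, lengths[b]);

  // ---- forward, caching activations -------------------------------------
  std::vector<std::vector<CellCache>> cache(T, std::vector<CellCache>(p.L));
  std::vector<arma::mat> htop(T);           // top-layer state per step
  arma::imat input_tokens(T, B, arma::fill::zeros);
  NumericVector logp(B);
  std::vector<arma::mat> h(p.L, arma::mat(p.H, B, arma::fill::zeros));
  arma::mat in(p.E, B);
  for (int b = 0; b < B; ++b) in.col(b) = p.emb.col(bos - 1);
  arma::imat cur_tok(1, B);
  cur_tok.fill(bos);
  std::vector<arma::mat> dlogits_store(T);
  for (int t = 0; t < T; ++t) {
    input_tokens.row(t) = cur_tok.row(0);
    arma::mat x = in;
    for (int l = 0; l < p.L; ++l) {
      h[l] = gru_cell(p, l, x, h[l], &cache[t][l]);
      x = h[l];
    }
    htop[t] = x;
    arma::mat logits = p.Wo * x;
    logits.each_col() += p.bo;
    arma::mat lsm = log_softmax(logits);
    arma::mat probs = arma::exp(lsm);
    // dL/dlogits for L = -(1/B) sum_b w_b logp_b
    arma::mat dlog(p.V, B, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      if (t < lengths[b]) {
        int tok = tokens(b, t);
        logp[b] += lsm(tok - 1, b);
        double w = weights[b] / B;  // dL/dlogits = w * (probs - onehot)
        dlog.col(b) = w * probs.col(b);
        dlog(tok - 1, b) -= w;
        cur_tok(0, b) = tok;
        in.col(b) = p.emb.col(tok - 1);
      }
    }
    dlogits_store[t] = dlog;
  }

  // ---- backward ----------------------------------------------------------
  arma::mat g_emb(p.E, p.V, arma::fill::zeros);
  std::vector<arma::mat> g_Wx, g_Wh;
  std::vector<arma::vec> g_bx, g_bh;
  for (int l = 0; l < p.L; ++l) {
    g_Wx.push_back(arma::mat(arma::size(p.Wx[l]), arma::fill::zeros));
    g_Wh.push_back(arma::mat(arma::size(p.Wh[l]), arma::fill::zeros));
    g_bx.push_back(arma::vec(3 * p.H, arma::fill::zeros));
    g_bh.push_back(arma::vec(3 * p.H, arma::fill::zeros));
  }
  arma::mat g_Wo(arma::size(p.Wo), arma::fill::zeros);
  arma::vec g_bo(p.V, arma::fill::zeros);
  std::vector<arma::mat> carry(p.L, arma::mat(p.H, B, arma::fill::zeros));
  const int H = p.H;
  for (int t = T - 1; t >= 0; --t) {
    const arma::mat& dlog = dlogits_store[t];
    g_Wo += dlog * htop[t].t();
    g_bo += arma::sum(dlog, 1);
    arma::mat dfrom_above = p.Wo.t() * dlog;
    for (int l = p.L - 1; l >= 0; --l) {
      const CellCache& c = cache[t][l];
      arma::mat dh = carry[l] + dfrom_above;
      arma::mat dn = dh % (1.0 - c.z);
      arma::mat dz = dh % (c.h_prev - c.n);
      arma::mat dhprev = dh % c.z;
      arma::mat dan = dn % (1.0 - c.n % c.n);
      arma::mat dah_n = dan % c.r;
      arma::mat dr = dan % c.ah_n;
      arma::mat dar = dr % c.r % (1.0 - c.r);
      arma::mat daz = dz % c.z % (1.0 - c.z);
      arma::mat dax = arma::join_cols(dar, arma::join_cols(daz, dan));
      arma::mat dah = arma::join_cols(dar, arma::join_cols(daz, dah_n));
      g_Wx[l] += dax * c.in.t();
      g_Wh[l] += dah * c.h_prev.t();
      g_bx[l] += arma::sum(dax, 1);
      g_bh[l] += arma::sum(dah, 1);
      carry[l] = dhprev + p.Wh[l].t() * dah;
      dfrom_above = p.Wx[l].t() * dax;  // gradient w.r.t. this layer's input
    }
    // dfrom_above is now the gradient w.r.t. the embedding columns fed at t
    for (int b = 0; b < B; ++b) {
      int tok = input_tokens(t, b);
      g_emb.col(tok - 1) += dfrom_above.col(b);
    }
  }

  double loss = 0.0;
  for (int b = 0; b < B; ++b) loss += -weights[b] * logp[b] / B;
  List gWx(p.L), gWh(p.L), gbx(p.L), gbh(p.L);
  for (int l = 0; l < p.L; ++l) {
    gWx[l] = g_Wx[l]; gWh[l] = g_Wh[l];
    gbx[l] = NumericVector(g_bx[l].begin(), g_bx[l].end());
    gbh[l] = NumericVector(g_bh[l].begin(), g_bh[l].end());
  }
  List grads = List::create(_["emb"] = g_emb, _["Wx"] = gWx, _["Wh"] = gWh,
                            _["bx"] = gbx, _["bh"] = gbh, _["Wo"] = g_Wo,
                            _["bo"] = NumericVector(g_bo.begin(), g_bo.end()));
  return List::create(_["loss"] = loss, _["logp"] = logp, _["grads"] = grads);
}

//' @noRd
// [[Rcpp::export(name = ".clm_step_probs_cpp")]]
NumericVector clm_step_probs_cpp(List params, IntegerVector prefix, int bos) {
  GruParams p = unpack(params);
  std::vector<arma::mat> h(p.L, arma::mat(p.H, 1, arma::fill::zeros));
  arma::mat in = p.emb.col(bos - 1);
  arma::mat x;
  for (int i = 0; i <= prefix.size(); ++i) {
    x = in;
    for (int l = 0; l < p.L; ++l) {
      h[l] = gru_cell(p, l, x, h[l], nullptr);
      x = h[l];
    }
    if (i < prefix.size()) in = p.emb.col(prefix[i] - 1);
  }
  arma::mat logits = p.Wo * x;
  logits.each_col() += p.bo;
  arma::mat lsm = log_softmax(logits);
  return NumericVector(wrap(arma::exp(lsm.col(0))));
}
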
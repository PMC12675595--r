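// Compiled forward/backward core of the TAPB model. Mirrors the base-R
// reference implementation in R/model.R exactly (same architecture, caches
// and gradient formulas); the R unit tests assert numerical equivalence of
// the two paths.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double LN_EPS = 1e-5;

static inline mat addb(const mat& m, const rowvec& b) {
  mat out = m;
  out.each_row() += b;
  return out;
}

static mat softmax_rows(mat s) {
  vec mx = arma::max(s, 1);
  s.each_col() -= mx;
  s = arma::exp(s);
  vec rs = arma::sum(s, 1);
  s.each_col() /= rs;
  return s;
}

static inline double norm_cdf(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}
static inline double norm_pdf(double x) {
  return std::exp(-0.5 * x * x) * 0.39894228040143267794;
}

static mat gelu(const mat& x) {
  mat y = x;
  y.for_each([](double& v) { v = v * norm_cdf(v); });
  return y;
}

static mat gelu_grad(const mat& x) {
  mat y = x;
  y.for_each([](double& v) { v = norm_cdf(v) + v * norm_pdf(v); });
  return y;
}

// ---- parameter structs ----------------------------------------------------

struct AttnP {
  mat Wq, Wk, Wv, Wo;
  rowvec bq, bk, bv, bo;
};

struct LnP { rowvec g, b; };
struct FfP { mat W1, W2; rowvec b1, b2; };
struct EncBlockP { AttnP sa; LnP ln1; FfP ff; LnP ln2; };
struct AggBlockP { AttnP sa; LnP ln1; AttnP ca; LnP ln2; FfP ff; LnP ln3; };
struct HeadP { mat Wy; rowvec by; };

struct ModelP {
  mat emb;
  std::vector<EncBlockP> enc;
  std::vector<AggBlockP> agg;
  HeadP head, headp;
  mat mlmW; rowvec mlmb;
  bool use_cam;
  // cam (single: Wv, Wg, bg; all adds Wq, Wk) or nocam (Wg, bg)
  mat camWv, camWg, camWq, camWk;
  rowvec cambg;
  bool cam_all;
};

static AttnP load_attn(const List& l) {
  AttnP p;
  p.Wq = as<mat>(l["Wq"]); p.bq = as<rowvec>(l["bq"]);
  p.Wk = as<mat>(l["Wk"]); p.bk = as<rowvec>(l["bk"]);
  p.Wv = as<mat>(l["Wv"]); p.bv = as<rowvec>(l["bv"]);
  p.Wo = as<mat>(l["Wo"]); p.bo = as<rowvec>(l["bo"]);
  return p;
}

static LnP load_ln(const List& l) {
  LnP p;
  p.g = as<rowvec>(l["g"]);
  p.b = as<rowvec>(l["b"]);
  return p;
}

static FfP load_ff(const List& l) {
  FfP p;
  p.W1 = as<mat>(l["W1"]); p.b1 = as<rowvec>(l["b1"]);
  p.W2 = as<mat>(l["W2"]); p.b2 = as<rowvec>(l["b2"]);
  return p;
}

static ModelP load_model(const List& params, bool use_cam, bool cam_all) {
  ModelP m;
  m.emb = as<mat>(params["emb"]);
  List enc = params["enc"];
  for (int l = 0; l < enc.size(); ++l) {
    List bl = enc[l];
    EncBlockP b;
    b.sa = load_attn(bl["sa"]); b.ln1 = load_ln(bl["ln1"]);
    b.ff = load_ff(bl["ff"]); b.ln2 = load_ln(bl["ln2"]);
    m.enc.push_back(b);
  }
  List agg = params["agg"];
  for (int l = 0; l < agg.size(); ++l) {
    List bl = agg[l];
    AggBlockP b;
    b.sa = load_attn(bl["sa"]); b.ln1 = load_ln(bl["ln1"]);
    b.ca = load_attn(bl["ca"]); b.ln2 = load_ln(bl["ln2"]);
    b.ff = load_ff(bl["ff"]); b.ln3 = load_ln(bl["ln3"]);
    m.agg.push_back(b);
  }
  List head = params["head"];
  m.head.Wy = as<mat>(head["Wy"]); m.head.by = as<rowvec>(head["by"]);
  List headp = params["headp"];
  m.headp.Wy = as<mat>(headp["Wy"]); m.headp.by = as<rowvec>(headp["by"]);
  List mlm = params["mlm"];
  m.mlmW = as<mat>(mlm["W"]); m.mlmb = as<rowvec>(mlm["b"]);
  m.use_cam = use_cam;
  m.cam_all = cam_all;
  if (use_cam) {
    List cam = params["cam"];
    m.camWv = as<mat>(cam["Wv"]);
    m.camWg = as<mat>(cam["Wg"]);
    m.cambg = as<rowvec>(cam["bg"]);
    if (cam_all) {
      m.camWq = as<mat>(cam["Wq"]);
      m.camWk = as<mat>(cam["Wk"]);
    }
  } else {
    List nocam = params["nocam"];
    m.camWg = as<mat>(nocam["Wg"]);
    m.cambg = as<rowvec>(nocam["bg"]);
  }
  return m;
}

// gradient accumulators mirror the parameter structs (zero-initialized)
struct AttnG {
  mat Wq, Wk, Wv, Wo;
  rowvec bq, bk, bv, bo;
  void init(const AttnP& p) {
    Wq.zeros(arma::size(p.Wq)); bq.zeros(p.bq.n_elem);
    Wk.zeros(arma::size(p.Wk)); bk.zeros(p.bk.n_elem);
    Wv.zeros(arma::size(p.Wv)); bv.zeros(p.bv.n_elem);
    Wo.zeros(arma::size(p.Wo)); bo.zeros(p.bo.n_elem);
  }
};
struct LnG {
  rowvec g, b;
  void init(const LnP& p) { g.zeros(p.g.n_elem); b.zeros(p.b.n_elem); }
};
struct FfG {
  mat W1, W2; rowvec b1, b2;
  void init(const FfP& p) {
    W1.zeros(arma::size(p.W1)); b1.zeros(p.b1.n_elem);
    W2.zeros(arma::size(p.W2)); b2.zeros(p.b2.n_elem);
  }
};
struct EncBlockG { AttnG sa; LnG ln1; FfG ff; LnG ln2; };
struct AggBlockG { AttnG sa; LnG ln1; AttnG ca; LnG ln2; FfG ff; LnG ln3; };

struct ModelG {
  mat emb;
  std::vector<EncBlockG> enc;
  std::vector<AggBlockG> agg;
  mat headWy; rowvec headby;
  mat headpWy; rowvec headpby;
  mat mlmW; rowvec mlmb;
  mat camWv, camWg, camWq, camWk;
  rowvec cambg;
  void init(const ModelP& m) {
    emb.zeros(arma::size(m.emb));
    enc.resize(m.enc.size());
    for (size_t l = 0; l < m.enc.size(); ++l) {
      enc[l].sa.init(m.enc[l].sa); enc[l].ln1.init(m.enc[l].ln1);
      enc[l].ff.init(m.enc[l].ff); enc[l].ln2.init(m.enc[l].ln2);
    }
    agg.resize(m.agg.size());
    for (size_t l = 0; l < m.agg.size(); ++l) {
      agg[l].sa.init(m.agg[l].sa); agg[l].ln1.init(m.agg[l].ln1);
      agg[l].ca.init(m.agg[l].ca); agg[l].ln2.init(m.agg[l].ln2);
      agg[l].ff.init(m.agg[l].ff); agg[l].ln3.init(m.agg[l].ln3);
    }
    headWy.zeros(arma::size(m.head.Wy)); headby.zeros(m.head.by.n_elem);
    headpWy.zeros(arma::size(m.headp.Wy)); headpby.zeros(m.headp.by.n_elem);
    mlmW.zeros(arma::size(m.mlmW)); mlmb.zeros(m.mlmb.n_elem);
    camWv.zeros(arma::size(m.camWv));
    camWg.zeros(arma::size(m.camWg));
    cambg.zeros(m.cambg.n_elem);
    if (m.cam_all) {
      camWq.zeros(arma::size(m.camWq));
      camWk.zeros(arma::size(m.camWk));
    }
  }
};

// ---- layer forward/backward ----------------------------------------------

static void rope_apply_inplace(mat& x, const mat& rc, const mat& rs) {
  int half = x.n_cols / 2;
  for (int k = 0; k < half; ++k) {
    for (arma::uword r = 0; r < x.n_rows; ++r) {
      double c = rc(r, k), s = rs(r, k);
      double x1 = x(r, 2 * k), x2 = x(r, 2 * k + 1);
      x(r, 2 * k) = x1 * c - x2 * s;
      x(r, 2 * k + 1) = x1 * s + x2 * c;
    }
  }
}

static void rope_unapply_inplace(mat& d, const mat& rc, const mat& rs) {
  int half = d.n_cols / 2;
  for (int k = 0; k < half; ++k) {
    for (arma::uword r = 0; r < d.n_rows; ++r) {
      double c = rc(r, k), s = rs(r, k);
      double d1 = d(r, 2 * k), d2 = d(r, 2 * k + 1);
      d(r, 2 * k) = d1 * c + d2 * s;
      d(r, 2 * k + 1) = -d1 * s + d2 * c;
    }
  }
}

struct MhaCache {
  mat O, xq, xkv;
  std::vector<mat> Q, K, V, A;
};

static mat mha_fwd(const mat& xq, const mat& xkv, const AttnP& p, int H,
                   const mat* ropeC, const mat* ropeS, MhaCache& c) {
  int Dm = p.Wq.n_cols;
  int dk = Dm / H;
  double scale = 1.0 / std::sqrt((double)dk);
  mat Q = addb(xq * p.Wq, p.bq);
  mat K = addb(xkv * p.Wk, p.bk);
  mat V = addb(xkv * p.Wv, p.bv);
  c.O.set_size(xq.n_rows, Dm);
  c.Q.resize(H); c.K.resize(H); c.V.resize(H); c.A.resize(H);
  for (int h = 0; h < H; ++h) {
    int a = h * dk, b = (h + 1) * dk - 1;
    mat Qh = Q.cols(a, b);
    mat Kh = K.cols(a, b);
    if (ropeC) {
      mat rcq = ropeC->rows(0, xq.n_rows - 1);
      mat rsq = ropeS->rows(0, xq.n_rows - 1);
      rope_apply_inplace(Qh, rcq, rsq);
      mat rck = ropeC->rows(0, xkv.n_rows - 1);
      mat rsk = ropeS->rows(0, xkv.n_rows - 1);
      rope_apply_inplace(Kh, rck, rsk);
    }
    mat Vh = V.cols(a, b);
    mat A = softmax_rows(Qh * Kh.t() * scale);
    c.O.cols(a, b) = A * Vh;
    c.Q[h] = Qh; c.K[h] = Kh; c.V[h] = Vh; c.A[h] = A;
  }
  c.xq = xq;
  c.xkv = xkv;
  return addb(c.O * p.Wo, p.bo);
}

static void mha_bwd(const mat& dout, const MhaCache& c, const AttnP& p, int H,
                    const mat* ropeC, const mat* ropeS,
                    mat& dxq, mat& dxkv, AttnG& g) {
  int Dm = p.Wq.n_cols;
  int dk = Dm / H;
  double scale = 1.0 / std::sqrt((double)dk);
  g.Wo += c.O.t() * dout;
  g.bo += arma::sum(dout, 0);
  mat dO = dout * p.Wo.t();
  mat dQ(c.xq.n_rows, Dm), dK(c.xkv.n_rows, Dm), dV(c.xkv.n_rows, Dm);
  for (int h = 0; h < H; ++h) {
    int a = h * dk, b = (h + 1) * dk - 1;
    mat dOh = dO.cols(a, b);
    mat dA = dOh * c.V[h].t();
    mat dVh = c.A[h].t() * dOh;
    mat dS = c.A[h] % (dA.each_col() - arma::sum(dA % c.A[h], 1));
    mat dQh = dS * c.K[h] * scale;
    mat dKh = dS.t() * c.Q[h] * scale;
    if (ropeC) {
      mat rcq = ropeC->rows(0, c.xq.n_rows - 1);
      mat rsq = ropeS->rows(0, c.xq.n_rows - 1);
      rope_unapply_inplace(dQh, rcq, rsq);
      mat rck = ropeC->rows(0, c.xkv.n_rows - 1);
      mat rsk = ropeS->rows(0, c.xkv.n_rows - 1);
      rope_unapply_inplace(dKh, rck, rsk);
    }
    dQ.cols(a, b) = dQh;
    dK.cols(a, b) = dKh;
    dV.cols(a, b) = dVh;
  }
  g.Wq += c.xq.t() * dQ; g.bq += arma::sum(dQ, 0);
  g.Wk += c.xkv.t() * dK; g.bk += arma::sum(dK, 0);
  g.Wv += c.xkv.t() * dV; g.bv += arma::sum(dV, 0);
  dxq = dQ * p.Wq.t();
  dxkv = dK * p.Wk.t() + dV * p.Wv.t();
}

struct LnCache { mat xhat; vec inv; };

static mat ln_fwd(const mat& x, const LnP& p, LnCache& c) {
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  c.inv = 1.0 / arma::sqrt(arma::mean(xc % xc, 1) + LN_EPS);
  c.xhat = xc.each_col() % c.inv;
  mat out = c.xhat;
  out.each_row() %= p.g;
  out.each_row() += p.b;
  return out;
}

static void ln_bwd(const mat& dout, const LnCache& c, const LnP& p,
                   mat& dx, LnG& g) {
  mat dxhat = dout;
  dxhat.each_row() %= p.g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % c.xhat, 1);
  dx = dxhat;
  dx.each_col() -= m1;
  dx -= c.xhat.each_col() % m2;
  dx.each_col() %= c.inv;
  g.g += arma::sum(dout % c.xhat, 0);
  g.b += arma::sum(dout, 0);
}

struct FfCache { mat x, h, a; };

static mat ff_fwd(const mat& x, const FfP& p, FfCache& c) {
  c.x = x;
  c.h = addb(x * p.W1, p.b1);
  c.a = gelu(c.h);
  return addb(c.a * p.W2, p.b2);
}

static void ff_bwd(const mat& dout, const FfCache& c, const FfP& p,
                   mat& dx, FfG& g) {
  mat da = dout * p.W2.t();
  mat dh = da % gelu_grad(c.h);
  g.W1 += c.x.t() * dh; g.b1 += arma::sum(dh, 0);
  g.W2 += c.a.t() * dout; g.b2 += arma::sum(dout, 0);
  dx = dh * p.W1.t();
}

// ---- whole-model sample forward/backward ----------------------------------

struct SampleCache {
  arma::uvec ids;                 // 0-based token ids
  std::vector<MhaCache> enc_sa;
  std::vector<LnCache> enc_ln1, enc_ln2;
  std::vector<FfCache> enc_ff;
  mat enc_out;
  // cam
  mat E, camM, camQ, camK, camV;
  std::vector<mat> camA;
  mat camLinX;                    // M + E (input to Wg)
  mat Tm;
  std::vector<MhaCache> agg_sa, agg_ca;
  std::vector<LnCache> agg_ln1, agg_ln2, agg_ln3;
  std::vector<FfCache> agg_ff;
  std::vector<bool> agg_ffn_used;
  mat F, pooled_seg;
  rowvec pooled_full;
  mat cond;                       // I x 2
  rowvec backdoor, plain;
  // mlm
  arma::uvec sel;                 // 0-based positions
  mat mlm_probs;
  arma::uvec mlm_true;            // 0-based true ids at sel
};

struct Cfg {
  int d_m, d_e, H, I, n_enc, n_agg;
  bool use_cam, use_backdoor, use_mlm, cam_all, pre_ffn;
};

static void forward_sample(const ModelP& mp, const Cfg& cf,
                           const arma::uvec& ids, const mat& E,
                           const mat& centers, const vec& weights,
                           const mat& ropeC, const mat& ropeS,
                           const arma::uvec& sel, const arma::uvec& true_ids,
                           SampleCache& sc,
                           const mat* Doverride, const mat* Toverride) {
  sc.ids = ids;
  int L = ids.n_elem;
  mat X = mp.emb.rows(ids);
  sc.enc_sa.resize(cf.n_enc); sc.enc_ln1.resize(cf.n_enc);
  sc.enc_ff.resize(cf.n_enc); sc.enc_ln2.resize(cf.n_enc);
  for (int l = 0; l < cf.n_enc; ++l) {
    const EncBlockP& b = mp.enc[l];
    mat sa = mha_fwd(X, X, b.sa, cf.H, &ropeC, &ropeS, sc.enc_sa[l]);
    mat x1 = ln_fwd(X + sa, b.ln1, sc.enc_ln1[l]);
    mat ff = ff_fwd(x1, b.ff, sc.enc_ff[l]);
    X = ln_fwd(x1 + ff, b.ln2, sc.enc_ln2[l]);
  }
  sc.enc_out = X;
  // target branch
  sc.E = E;
  int d_seg = cf.d_e / cf.I;
  if (cf.use_cam) {
    mat M(E.n_rows, cf.d_e, arma::fill::zeros);
    if (!cf.cam_all) {
      sc.camV = centers * mp.camWv;
      for (int i = 0; i < cf.I; ++i) {
        int a = i * d_seg, b = (i + 1) * d_seg - 1;
        M.cols(a, b) = arma::repmat(sc.camV.submat(i, a, i, b), E.n_rows, 1);
      }
    } else {
      sc.camQ = E * mp.camWq;
      sc.camK = centers * mp.camWk;
      sc.camV = centers * mp.camWv;
      sc.camA.resize(cf.I);
      double scale = 1.0 / std::sqrt((double)d_seg);
      for (int i = 0; i < cf.I; ++i) {
        int a = i * d_seg, b = (i + 1) * d_seg - 1;
        mat A = softmax_rows(sc.camQ.cols(a, b) * sc.camK.cols(a, b).t() * scale);
        M.cols(a, b) = A * sc.camV.cols(a, b);
        sc.camA[i] = A;
      }
    }
    sc.camM = M;
    sc.camLinX = M + E;
    sc.Tm = addb(sc.camLinX * mp.camWg, mp.cambg);
  } else {
    sc.camLinX = E;
    sc.Tm = addb(E * mp.camWg, mp.cambg);
  }
  // aggregator
  mat Fm = (Doverride != nullptr) ? *Doverride : sc.enc_out;
  mat Tuse = (Toverride != nullptr) ? *Toverride : sc.Tm;
  sc.agg_sa.resize(cf.n_agg); sc.agg_ln1.resize(cf.n_agg);
  sc.agg_ca.resize(cf.n_agg); sc.agg_ln2.resize(cf.n_agg);
  sc.agg_ff.resize(cf.n_agg); sc.agg_ln3.resize(cf.n_agg);
  sc.agg_ffn_used.resize(cf.n_agg);
  for (int l = 0; l < cf.n_agg; ++l) {
    const AggBlockP& b = mp.agg[l];
    bool last = (l == cf.n_agg - 1);
    mat sa = mha_fwd(Fm, Fm, b.sa, cf.H, &ropeC, &ropeS, sc.agg_sa[l]);
    mat f1 = ln_fwd(Fm + sa, b.ln1, sc.agg_ln1[l]);
    mat ca = mha_fwd(f1, Tuse, b.ca, cf.H, nullptr, nullptr, sc.agg_ca[l]);
    mat f2 = ln_fwd(f1 + ca, b.ln2, sc.agg_ln2[l]);
    if (last && cf.pre_ffn) {
      sc.agg_ffn_used[l] = false;
      Fm = f2;
    } else {
      sc.agg_ffn_used[l] = true;
      mat ff = ff_fwd(f2, b.ff, sc.agg_ff[l]);
      Fm = ln_fwd(f2 + ff, b.ln3, sc.agg_ln3[l]);
    }
  }
  sc.F = Fm;
  int dk = cf.d_m / cf.I;
  sc.pooled_seg.set_size(cf.I, dk);
  for (int i = 0; i < cf.I; ++i) {
    sc.pooled_seg.row(i) = arma::mean(Fm.cols(i * dk, (i + 1) * dk - 1), 0);
  }
  sc.cond = softmax_rows(addb(sc.pooled_seg * mp.head.Wy, mp.head.by));
  sc.backdoor = weights.t() * sc.cond;
  sc.pooled_full = arma::mean(Fm, 0);
  sc.plain = softmax_rows(sc.pooled_full * mp.headp.Wy + mp.headp.by);
  // mlm
  sc.sel = sel;
  if (cf.use_mlm && sel.n_elem > 0) {
    mat H_sel = sc.enc_out.rows(sel);
    sc.mlm_probs = softmax_rows(addb(H_sel * mp.mlmW, mp.mlmb));
    sc.mlm_true.set_size(sel.n_elem);
    for (arma::uword j = 0; j < sel.n_elem; ++j) {
      sc.mlm_true[j] = true_ids[sel[j]];
    }
  }
  (void)L;
}

static void backward_sample(const ModelP& mp, const Cfg& cf,
                            const SampleCache& sc, const mat& centers,
                            const vec& weights,
                            const mat& ropeC, const mat& ropeS,
                            int label, double cls_weight, double mlm_weight,
                            ModelG& g) {
  int L = sc.F.n_rows;
  int I = cf.I;
  int dk = cf.d_m / I;
  mat dF(L, cf.d_m, arma::fill::zeros);
  if (cf.use_backdoor) {
    rowvec dpred(2, arma::fill::zeros);
    dpred[label] = -cls_weight / std::max(sc.backdoor[label], 1e-12);
    mat dcond = weights * dpred;                    // I x 2
    const mat& s = sc.cond;
    mat dlog = s % (dcond.each_col() - arma::sum(dcond % s, 1));
    g.headWy += sc.pooled_seg.t() * dlog;
    g.headby += arma::sum(dlog, 0);
    mat dpooled = dlog * mp.head.Wy.t();            // I x dk
    for (int i = 0; i < I; ++i) {
      dF.cols(i * dk, (i + 1) * dk - 1) =
        arma::repmat(dpooled.row(i) / (double)L, L, 1);
    }
  } else {
    rowvec dpred(2, arma::fill::zeros);
    dpred[label] = -cls_weight / std::max(sc.plain[label], 1e-12);
    const rowvec& s = sc.plain;
    rowvec dlog = s % (dpred - arma::accu(dpred % s));
    g.headpWy += sc.pooled_full.t() * dlog;
    g.headpby += dlog;
    rowvec dpooled = (mp.headp.Wy * dlog.t()).t();
    dF += arma::repmat(dpooled / (double)L, L, 1);
  }
  // aggregator backward
  mat dT(sc.Tm.n_rows, cf.d_m, arma::fill::zeros);
  for (int l = cf.n_agg - 1; l >= 0; --l) {
    const AggBlockP& b = mp.agg[l];
    AggBlockG& gb = g.agg[l];
    mat d2;
    if (sc.agg_ffn_used[l]) {
      mat d3;
      ln_bwd(dF, sc.agg_ln3[l], b.ln3, d3, gb.ln3);
      mat dffx;
      ff_bwd(d3, sc.agg_ff[l], b.ff, dffx, gb.ff);
      d2 = d3 + dffx;
    } else {
      d2 = dF;
    }
    mat d2x;
    ln_bwd(d2, sc.agg_ln2[l], b.ln2, d2x, gb.ln2);
    mat dxq, dxkv;
    mha_bwd(d2x, sc.agg_ca[l], b.ca, cf.H, nullptr, nullptr, dxq, dxkv, gb.ca);
    dT += dxkv;
    mat d1 = d2x + dxq;
    mat d1x;
    ln_bwd(d1, sc.agg_ln1[l], b.ln1, d1x, gb.ln1);
    mat dsq, dskv;
    mha_bwd(d1x, sc.agg_sa[l], b.sa, cf.H, &ropeC, &ropeS, dsq, dskv, gb.sa);
    dF = d1x + dsq + dskv;
  }
  mat dD = dF;
  // MLM branch adds gradient at the selected encoder-output rows
  if (cf.use_mlm && sc.sel.n_elem > 0) {
    mat dlogits = sc.mlm_probs;
    for (arma::uword j = 0; j < sc.sel.n_elem; ++j) {
      dlogits(j, sc.mlm_true[j]) -= 1.0;
    }
    dlogits *= mlm_weight;
    mat H_sel = sc.enc_out.rows(sc.sel);
    g.mlmW += H_sel.t() * dlogits;
    g.mlmb += arma::sum(dlogits, 0);
    mat dH = dlogits * mp.mlmW.t();
    for (arma::uword j = 0; j < sc.sel.n_elem; ++j) {
      dD.row(sc.sel[j]) += dH.row(j);
    }
  }
  // target branch backward (stops at E: the feature provider and the
  // dictionary centers are fixed buffers, not parameters)
  int d_seg = cf.d_e / I;
  g.camWg += sc.camLinX.t() * dT;
  g.cambg += arma::sum(dT, 0);
  if (cf.use_cam) {
    mat dME = dT * mp.camWg.t();                    // Lt x d_e
    if (!cf.cam_all) {
      for (int i = 0; i < I; ++i) {
        int a = i * d_seg, b = (i + 1) * d_seg - 1;
        rowvec dVi = arma::sum(dME.cols(a, b), 0);
        g.camWv.cols(a, b) += centers.row(i).t() * dVi;
      }
    } else {
      double scale = 1.0 / std::sqrt((double)d_seg);
      mat dQ(sc.E.n_rows, cf.d_e, arma::fill::zeros);
      mat dK(I, cf.d_e, arma::fill::zeros);
      mat dV(I, cf.d_e, arma::fill::zeros);
      for (int i = 0; i < I; ++i) {
        int a = i * d_seg, b = (i + 1) * d_seg - 1;
        const mat& A = sc.camA[i];
        mat dMblk = dME.cols(a, b);
        mat dA = dMblk * sc.camV.cols(a, b).t();
        dV.cols(a, b) = A.t() * dMblk;
        mat dS = A % (dA.each_col() - arma::sum(dA % A, 1));
        dQ.cols(a, b) = dS * sc.camK.cols(a, b) * scale;
        dK.cols(a, b) = dS.t() * sc.camQ.cols(a, b) * scale;
      }
      g.camWq += sc.E.t() * dQ;
      g.camWk += centers.t() * dK;
      g.camWv += centers.t() * dV;
    }
  }
  // drug encoder backward
  mat dX = dD;
  for (int l = cf.n_enc - 1; l >= 0; --l) {
    const EncBlockP& b = mp.enc[l];
    EncBlockG& gb = g.enc[l];
    mat d2;
    ln_bwd(dX, sc.enc_ln2[l], b.ln2, d2, gb.ln2);
    mat dffx;
    ff_bwd(d2, sc.enc_ff[l], b.ff, dffx, gb.ff);
    mat d1 = d2 + dffx;
    mat d1x;
    ln_bwd(d1, sc.enc_ln1[l], b.ln1, d1x, gb.ln1);
    mat dsq, dskv;
    mha_bwd(d1x, sc.enc_sa[l], b.sa, cf.H, &ropeC, &ropeS, dsq, dskv, gb.sa);
    dX = d1x + dsq + dskv;
  }
  for (arma::uword j = 0; j < sc.ids.n_elem; ++j) {
    g.emb.row(sc.ids[j]) += dX.row(j);
  }
}

// ---- R interface ----------------------------------------------------------

static Cfg load_cfg(const List& cfg) {
  Cfg c;
  c.d_m = as<int>(cfg["d_m"]);
  c.d_e = as<int>(cfg["d_e"]);
  c.H = as<int>(cfg["n_heads"]);
  c.I = as<int>(cfg["dict_size"]);
  c.n_enc = as<int>(cfg["n_enc_layers"]);
  c.n_agg = as<int>(cfg["n_agg_layers"]);
  c.use_cam = as<bool>(cfg["use_cam"]);
  c.use_backdoor = as<bool>(cfg["use_backdoor"]);
  c.use_mlm = as<bool>(cfg["use_mlm"]);
  c.cam_all = as<std::string>(cfg["cam_keys"]) == "all";
  c.pre_ffn = as<std::string>(cfg["partition_point"]) == "pre_ffn";
  return c;
}

static List attn_to_list(const AttnG& g) {
  return List::create(
    _["Wq"] = g.Wq, _["bq"] = g.bq, _["Wk"] = g.Wk, _["bk"] = g.bk,
    _["Wv"] = g.Wv, _["bv"] = g.bv, _["Wo"] = g.Wo, _["bo"] = g.bo);
}

static List ln_to_list(const LnG& g) {
  return List::create(_["g"] = g.g, _["b"] = g.b);
}

static List ff_to_list(const FfG& g) {
  return List::create(_["W1"] = g.W1, _["b1"] = g.b1,
                      _["W2"] = g.W2, _["b2"] = g.b2);
}

// gradient tree in the exact shape and order of the R parameter tree
static List grads_to_list(const ModelG& g, const Cfg& cf, bool use_cam) {
  List enc(g.enc.size());
  for (size_t l = 0; l < g.enc.size(); ++l) {
    enc[l] = List::create(
      _["sa"] = attn_to_list(g.enc[l].sa), _["ln1"] = ln_to_list(g.enc[l].ln1),
      _["ff"] = ff_to_list(g.enc[l].ff), _["ln2"] = ln_to_list(g.enc[l].ln2));
  }
  List agg(g.agg.size());
  for (size_t l = 0; l < g.agg.size(); ++l) {
    agg[l] = List::create(
      _["sa"] = attn_to_list(g.agg[l].sa), _["ln1"] = ln_to_list(g.agg[l].ln1),
      _["ca"] = attn_to_list(g.agg[l].ca), _["ln2"] = ln_to_list(g.agg[l].ln2),
      _["ff"] = ff_to_list(g.agg[l].ff), _["ln3"] = ln_to_list(g.agg[l].ln3));
  }
  List out = List::create(
    _["emb"] = g.emb, _["enc"] = enc, _["agg"] = agg,
    _["head"] = List::create(_["Wy"] = g.headWy, _["by"] = g.headby),
    _["headp"] = List::create(_["Wy"] = g.headpWy, _["by"] = g.headpby),
    _["mlm"] = List::create(_["W"] = g.mlmW, _["b"] = g.mlmb));
  if (use_cam) {
    if (cf.cam_all) {
      out["cam"] = List::create(_["Wv"] = g.camWv, _["Wg"] = g.camWg,
                                _["bg"] = g.cambg, _["Wq"] = g.camWq,
                                _["Wk"] = g.camWk);
    } else {
      out["cam"] = List::create(_["Wv"] = g.camWv, _["Wg"] = g.camWg,
                                _["bg"] = g.cambg);
    }
  } else {
    out["nocam"] = List::create(_["Wg"] = g.camWg, _["bg"] = g.cambg);
  }
  return out;
}

static arma::uvec to_uvec0(const IntegerVector& x) {
  arma::uvec out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = (arma::uword)(x[i] - 1);
  return out;
}

// one optimization batch: accumulated gradients plus summed losses
// [[Rcpp::export]]
List tapb_batch_cpp(List params, List cfg, arma::mat centers,
                    arma::vec weights, arma::mat ropeC, arma::mat ropeS,
                    List batch, double cls_weight, double mlm_weight) {
  Cfg cf = load_cfg(cfg);
  ModelP mp = load_model(params, cf.use_cam, cf.cam_all);
  ModelG g;
  g.init(mp);
  double loss_cls = 0.0, loss_mlm = 0.0;
  int n_masked = 0;
  for (int k = 0; k < batch.size(); ++k) {
    List smp = batch[k];
    arma::uvec ids = to_uvec0(smp["ids"]);
    mat E = as<mat>(smp["E"]);
    arma::uvec sel = to_uvec0(smp["sel"]);
    arma::uvec true_ids = to_uvec0(smp["true_ids"]);
    int y = as<int>(smp["y"]);
    SampleCache sc;
    forward_sample(mp, cf, ids, E, centers, weights, ropeC, ropeS,
                   sel, true_ids, sc, nullptr, nullptr);
    double pred = cf.use_backdoor ? sc.backdoor[y] : sc.plain[y];
    loss_cls += -std::log(std::max(pred, 1e-12));
    if (cf.use_mlm && sel.n_elem > 0) {
      for (arma::uword j = 0; j < sel.n_elem; ++j) {
        loss_mlm += -std::log(std::max(sc.mlm_probs(j, sc.mlm_true[j]), 1e-12));
      }
      n_masked += sel.n_elem;
    }
    backward_sample(mp, cf, sc, centers, weights, ropeC, ropeS, y,
                    cls_weight, mlm_weight, g);
  }
  return List::create(_["grads"] = grads_to_list(g, cf, cf.use_cam),
                      _["loss_cls"] = loss_cls, _["loss_mlm"] = loss_mlm,
                      _["n_masked"] = n_masked);
}

// forward-only scoring; probe_mode 1 replaces the target tensor with the
// supplied noise matrix, 2 replaces the drug tensor
// [[Rcpp::export]]
List tapb_scores_cpp(List params, List cfg, arma::mat centers,
                     arma::vec weights, arma::mat ropeC, arma::mat ropeS,
                     List samples, int probe_mode, bool want_features) {
  Cfg cf = load_cfg(cfg);
  ModelP mp = load_model(params, cf.use_cam, cf.cam_all);
  int n = samples.size();
  NumericVector scores(n);
  mat feats;
  if (want_features) feats.zeros(n, cf.d_m);
  arma::uvec empty;
  for (int k = 0; k < n; ++k) {
    List smp = samples[k];
    arma::uvec ids = to_uvec0(smp["ids"]);
    mat E = as<mat>(smp["E"]);
    SampleCache sc;
    mat noise;
    const mat* Dov = nullptr;
    const mat* Tov = nullptr;
    if (probe_mode > 0) {
      noise = as<mat>(smp["noise"]);
      if (probe_mode == 1) Tov = &noise; else Dov = &noise;
    }
    forward_sample(mp, cf, ids, E, centers, weights, ropeC, ropeS,
                   empty, empty, sc, Dov, Tov);
    scores[k] = cf.use_backdoor ? sc.backdoor[1] : sc.plain[1];
    if (want_features) feats.row(k) = sc.pooled_full;
  }
  return List::create(_["scores"] = scores, _["features"] = feats);
}
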
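// Compiled training kernels: fused forward/backward over one disjoint graph
// union, plus the Adam update on flat parameter vectors. The math mirrors the
// R reference implementation (model-forward.R / model-backward.R) exactly;
// the R path remains the documented reference and the two are asserted equal
// in the test suite.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// activation ids: 0 leaky_relu, 1 relu, 2 tanh, 3 identity
mat act_f(const mat& z, int id) {
  switch (id) {
    case 0: return z % (0.01 + 0.99 * conv_to<mat>::from(z > 0));
    case 1: return z % conv_to<mat>::from(z > 0);
    case 2: return tanh(z);
    default: return z;
  }
}

mat act_df(const mat& z, int id) {
  switch (id) {
    case 0: return 0.01 + 0.99 * conv_to<mat>::from(z > 0);
    case 1: return conv_to<mat>::from(z > 0);
    case 2: return 1 - square(tanh(z));
    default: return ones<mat>(z.n_rows, z.n_cols);
  }
}

mat sigmoid(const mat& z) { return 1 / (1 + exp(-z)); }

struct Layout {
  // sequential reader over one flat vector (copies into owning matrices)
  const double* base;
  size_t off = 0;
  mat view(size_t r, size_t c) {
    mat m(base + off, r, c);  // owning copy
    off += r * c;
    return m;
  }
  vec vview(size_t n) {
    vec v(base + off, n);
    off += n;
    return v;
  }
};

struct MLP { mat W1; vec b1; mat W2; vec b2; };
struct S2S { mat Wx; mat Wh; vec b; };

struct Params {
  mat W1, W2, W3, W4, W5;
  std::vector<mat> th_i, th_q, th_e;
  MLP mlp_i, mlp_q, mlp_e;
  S2S ro_q, ro_e;
  std::vector<mat> headW;
  std::vector<vec> headb;
};

// must match the R-side leaf order (collect_leaves over the params list)
Params map_params(const double* base, const Rcpp::List& cfg) {
  int d1 = cfg["d1"], d2 = cfg["d2"], d3 = cfg["d3"], de = cfg["de"];
  int n_env = cfg["n_env"];
  int k_intra = cfg["k_intra"], k_inter = cfg["k_inter"];
  bool share = cfg["share_theta"];
  bool s2s = cfg["set2set"];
  Rcpp::IntegerVector head_widths = cfg["head_widths"];  // incl. input dim
  int nd = d1 + d2, ndq = nd + d3;
  Layout L{base};
  Params p;
  p.W1 = L.view(6, d1);
  p.W2 = L.view(n_env, d2);
  p.W3 = L.view(66, d3);
  p.W4 = L.view(7, de);
  p.W5 = L.view(5, de);
  int nti = share ? 1 : k_intra, ntq = share ? 1 : k_inter;
  for (int k = 0; k < nti; k++) p.th_i.push_back(L.view(nd, nd));
  for (int k = 0; k < ntq; k++) p.th_q.push_back(L.view(ndq, ndq));
  for (int k = 0; k < ntq; k++) p.th_e.push_back(L.view(nd, nd));
  p.mlp_i = {L.view(de, nd), L.vview(nd), L.view(nd, nd), L.vview(nd)};
  p.mlp_q = {L.view(de, ndq), L.vview(ndq), L.view(ndq, ndq), L.vview(ndq)};
  p.mlp_e = {L.view(2 * de, nd), L.vview(nd), L.view(nd, nd), L.vview(nd)};
  if (s2s) {
    p.ro_q = {L.view(2 * ndq, 4 * ndq), L.view(ndq, 4 * ndq), L.vview(4 * ndq)};
    p.ro_e = {L.view(2 * nd, 4 * nd), L.view(nd, 4 * nd), L.vview(4 * nd)};
  }
  for (int l = 0; l + 1 < head_widths.size(); l++) {
    p.headW.push_back(L.view(head_widths[l], head_widths[l + 1]));
    p.headb.push_back(L.vview(head_widths[l + 1]));
  }
  return p;
}

// a same-shaped all-zero gradient container
Params zero_like(const Params& p) {
  Params g;
  g.W1 = zeros<mat>(size(p.W1)); g.W2 = zeros<mat>(size(p.W2));
  g.W3 = zeros<mat>(size(p.W3)); g.W4 = zeros<mat>(size(p.W4));
  g.W5 = zeros<mat>(size(p.W5));
  for (auto& m : p.th_i) g.th_i.push_back(zeros<mat>(size(m)));
  for (auto& m : p.th_q) g.th_q.push_back(zeros<mat>(size(m)));
  for (auto& m : p.th_e) g.th_e.push_back(zeros<mat>(size(m)));
  auto zmlp = [](const MLP& m) {
    return MLP{zeros<mat>(size(m.W1)), zeros<vec>(m.b1.n_elem),
               zeros<mat>(size(m.W2)), zeros<vec>(m.b2.n_elem)};
  };
  g.mlp_i = zmlp(p.mlp_i); g.mlp_q = zmlp(p.mlp_q); g.mlp_e = zmlp(p.mlp_e);
  auto zs2s = [](const S2S& s) {
    return S2S{zeros<mat>(size(s.Wx)), zeros<mat>(size(s.Wh)),
               zeros<vec>(s.b.n_elem)};
  };
  g.ro_q = zs2s(p.ro_q); g.ro_e = zs2s(p.ro_e);
  for (auto& m : p.headW) g.headW.push_back(zeros<mat>(size(m)));
  for (auto& b : p.headb) g.headb.push_back(zeros<vec>(b.n_elem));
  return g;
}

// write back into a flat vector, exactly mirroring map_params order
void serialize_params(const Params& p, bool s2s, double* out) {
  size_t off = 0;
  auto put_m = [&](const mat& m) {
    std::memcpy(out + off, m.memptr(), m.n_elem * sizeof(double));
    off += m.n_elem;
  };
  auto put_v = [&](const vec& v) {
    std::memcpy(out + off, v.memptr(), v.n_elem * sizeof(double));
    off += v.n_elem;
  };
  put_m(p.W1); put_m(p.W2); put_m(p.W3); put_m(p.W4); put_m(p.W5);
  for (auto& m : p.th_i) put_m(m);
  for (auto& m : p.th_q) put_m(m);
  for (auto& m : p.th_e) put_m(m);
  for (auto* m : {&p.mlp_i, &p.mlp_q, &p.mlp_e}) {
    put_m(m->W1); put_v(m->b1); put_m(m->W2); put_v(m->b2);
  }
  if (s2s) {
    put_m(p.ro_q.Wx); put_m(p.ro_q.Wh); put_v(p.ro_q.b);
    put_m(p.ro_e.Wx); put_m(p.ro_e.Wh); put_v(p.ro_e.b);
  }
  for (size_t l = 0; l < p.headW.size(); l++) {
    put_m(p.headW[l]); put_v(p.headb[l]);
  }
}

mat add_bias(mat z, const vec& b) { z.each_row() += b.t(); return z; }

struct GateCache { mat Z1, A1, G; };

GateCache gate_mlp(const mat& X, const MLP& m, int act) {
  GateCache g;
  g.Z1 = add_bias(X * m.W1, m.b1);
  g.A1 = act_f(g.Z1, act);
  g.G = add_bias(g.A1 * m.W2, m.b2);
  return g;
}

// k rounds of gated-mean passing; returns all states H^0..H^k
std::vector<mat> pass_rounds(const mat& H0, const uvec& src, const uvec& dst,
                             const vec& inv_deg,
                             const mat& gate, const std::vector<mat>& thetas,
                             int k_rounds, bool share) {
  std::vector<mat> Hs{H0};
  size_t N = H0.n_rows, E = src.n_elem, D = H0.n_cols;
  for (int k = 0; k < k_rounds; k++) {
    const mat& th = thetas[share ? 0 : k];
    const mat& Hk = Hs.back();
    mat agg(N, D, fill::zeros);
    for (size_t e = 0; e < E; e++) {
      agg.row(dst[e]) += Hk.row(src[e]) % gate.row(e);
    }
    agg.each_col() %= inv_deg;
    Hs.push_back(Hk * th + agg);
  }
  return Hs;
}

struct S2SCache {
  std::vector<mat> x, h_in, c_in, ii, ff, oo, gg, tc, q;
  std::vector<vec> a;
  mat out;
};

S2SCache set2set_fwd(const mat& M, const uvec& gnode, size_t G, const S2S& rp,
                     int steps) {
  size_t d = M.n_cols, N = M.n_rows;
  mat qstar(G, 2 * d, fill::zeros), h(G, d, fill::zeros), c(G, d, fill::zeros);
  S2SCache cc;
  for (int t = 0; t < steps; t++) {
    mat Z = add_bias(qstar * rp.Wx + h * rp.Wh, rp.b);
    mat ii = sigmoid(Z.cols(0, d - 1));
    mat ff = sigmoid(Z.cols(d, 2 * d - 1));
    mat oo = sigmoid(Z.cols(2 * d, 3 * d - 1));
    mat gg = tanh(Z.cols(3 * d, 4 * d - 1));
    mat c_new = ff % c + ii % gg;
    mat tc = tanh(c_new);
    mat q = oo % tc;
    vec logits(N);
    for (size_t i = 0; i < N; i++) logits[i] = dot(M.row(i), q.row(gnode[i]));
    vec mx(G); mx.fill(-datum::inf);
    for (size_t i = 0; i < N; i++) mx[gnode[i]] = std::max(mx[gnode[i]], logits[i]);
    vec ex(N), ssum(G, fill::zeros);
    for (size_t i = 0; i < N; i++) { ex[i] = std::exp(logits[i] - mx[gnode[i]]); ssum[gnode[i]] += ex[i]; }
    vec a(N);
    mat r(G, d, fill::zeros);
    for (size_t i = 0; i < N; i++) { a[i] = ex[i] / ssum[gnode[i]]; r.row(gnode[i]) += M.row(i) * a[i]; }
    cc.x.push_back(qstar); cc.h_in.push_back(h); cc.c_in.push_back(c);
    cc.ii.push_back(ii); cc.ff.push_back(ff); cc.oo.push_back(oo);
    cc.gg.push_back(gg); cc.tc.push_back(tc); cc.q.push_back(q);
    cc.a.push_back(a);
    qstar = join_rows(q, r);
    h = q;
    c = c_new;
  }
  cc.out = qstar;
  return cc;
}

struct S2SGrads { mat dM, dWx, dWh; vec db; };

S2SGrads set2set_bwd(const mat& M, const uvec& gnode, size_t G, const S2S& rp,
                     const S2SCache& cc, const mat& dOut) {
  size_t d = M.n_cols, N = M.n_rows;
  int steps = cc.x.size();
  S2SGrads gr;
  gr.dM = zeros<mat>(N, d);
  gr.dWx = zeros<mat>(size(rp.Wx));
  gr.dWh = zeros<mat>(size(rp.Wh));
  gr.db = zeros<vec>(rp.b.n_elem);
  mat dqstar = dOut;
  mat dh_carry(G, d, fill::zeros), dc_carry(G, d, fill::zeros);
  for (int t = steps - 1; t >= 0; t--) {
    mat dq = dqstar.cols(0, d - 1);
    mat dr = dqstar.cols(d, 2 * d - 1);
    vec da(N), sg(G, fill::zeros);
    for (size_t i = 0; i < N; i++) {
      gr.dM.row(i) += cc.a[t][i] * dr.row(gnode[i]);
      da[i] = dot(M.row(i), dr.row(gnode[i]));
      sg[gnode[i]] += cc.a[t][i] * da[i];
    }
    for (size_t i = 0; i < N; i++) {
      double dlog = cc.a[t][i] * (da[i] - sg[gnode[i]]);
      gr.dM.row(i) += dlog * cc.q[t].row(gnode[i]);
      dq.row(gnode[i]) += dlog * M.row(i);
    }
    mat dh_total = dq + dh_carry;
    mat do_ = dh_total % cc.tc[t];
    mat dc_total = dc_carry + dh_total % cc.oo[t] % (1 - square(cc.tc[t]));
    mat di = dc_total % cc.gg[t];
    mat df_ = dc_total % cc.c_in[t];
    mat dg = dc_total % cc.ii[t];
    mat dZ = join_rows(join_rows(di % cc.ii[t] % (1 - cc.ii[t]),
                                 df_ % cc.ff[t] % (1 - cc.ff[t])),
                       join_rows(do_ % cc.oo[t] % (1 - cc.oo[t]),
                                 dg % (1 - square(cc.gg[t]))));
    gr.dWx += cc.x[t].t() * dZ;
    gr.dWh += cc.h_in[t].t() * dZ;
    gr.db += sum(dZ, 0).t();
    dqstar = dZ * rp.Wx.t();
    dh_carry = dZ * rp.Wh.t();
    dc_carry = dc_total % cc.ff[t];
  }
  return gr;
}

struct PassGrads { mat dH0, dGate; std::vector<mat> dTh; };

PassGrads pass_bwd(const std::vector<mat>& Hs, const uvec& src,
                   const uvec& dst, const vec& inv_deg, const mat& gate,
                   const std::vector<mat>& thetas, bool share,
                   const mat& dH_final) {
  int k_rounds = Hs.size() - 1;
  size_t E = src.n_elem;
  PassGrads gr;
  for (auto& th : thetas) gr.dTh.push_back(zeros<mat>(size(th)));
  gr.dGate = zeros<mat>(gate.n_rows, gate.n_cols);
  mat dH = dH_final;
  for (int k = k_rounds - 1; k >= 0; k--) {
    int idx = share ? 0 : k;
    const mat& Hk1 = Hs[k];
    gr.dTh[idx] += Hk1.t() * dH;
    mat dH_prev = dH * thetas[idx].t();
    for (size_t e = 0; e < E; e++) {
      rowvec dMsg = dH.row(dst[e]) * inv_deg[dst[e]];
      dH_prev.row(src[e]) += dMsg % gate.row(e);
      gr.dGate.row(e) += dMsg % Hk1.row(src[e]);
    }
    dH = dH_prev;
  }
  gr.dH0 = dH;
  return gr;
}

struct GateGrads { mat dW1; vec db1; mat dW2; vec db2; mat dX; };

GateGrads gate_bwd(const mat& X, const GateCache& g, const MLP& m, int act,
                   const mat& dG) {
  GateGrads gr;
  gr.dW2 = g.A1.t() * dG;
  gr.db2 = sum(dG, 0).t();
  mat dA1 = dG * m.W2.t();
  mat dZ1 = dA1 % act_df(g.Z1, act);
  gr.dW1 = X.t() * dZ1;
  gr.db1 = sum(dZ1, 0).t();
  gr.dX = dZ1 * m.W1.t();
  return gr;
}


struct Batch {
  mat Xa, Xb, Ea, Hc, Eb;
  uvec src, dst, gnode, gedge;
  vec inv_deg;
  vec y;       // standardized targets
  size_t N, G, E;
};

Batch make_batch(const Rcpp::List& b, const Rcpp::NumericVector& y) {
  Batch B;
  B.Xa = Rcpp::as<mat>(b["Xa"]); B.Xb = Rcpp::as<mat>(b["Xb"]);
  B.Ea = Rcpp::as<mat>(b["Ea"]);
  B.Hc = Rcpp::as<mat>(b["Hc"]); B.Eb = Rcpp::as<mat>(b["Eb"]);
  B.src = Rcpp::as<uvec>(b["src"]) - 1;
  B.dst = Rcpp::as<uvec>(b["dst"]) - 1;
  B.gnode = Rcpp::as<uvec>(b["graph_node"]) - 1;
  B.gedge = Rcpp::as<uvec>(b["graph_edge"]) - 1;
  vec deg = Rcpp::as<vec>(b["deg"]);
  B.N = B.Xa.n_rows; B.G = B.Hc.n_rows; B.E = B.src.n_elem;
  B.inv_deg = vec(B.N, fill::zeros);
  for (size_t i = 0; i < B.N; i++) if (deg[i] > 0) B.inv_deg[i] = 1.0 / deg[i];
  B.y = Rcpp::as<vec>(y);
  return B;
}

// fused forward (+ optional backward accumulated into Gp); returns loss and
// fills y_hat
double forward_backward(const Params& P, const Batch& B, const Rcpp::List& cfg,
                        bool want_grads, Params* Gp, vec& y_hat_out) {
  int act = cfg["act"];
  int k_intra = cfg["k_intra"], k_inter = cfg["k_inter"];
  bool share = cfg["share_theta"], s2s = cfg["set2set"];
  int steps = cfg["processing_steps"];
  size_t N = B.N, G = B.G, E = B.E;
  const uvec& src = B.src; const uvec& dst = B.dst;
  const uvec& gnode = B.gnode; const uvec& gedge = B.gedge;
  const vec& inv_deg = B.inv_deg;

  mat Za = B.Xa * P.W1, Zb = B.Xb * P.W2;
  mat H0 = join_rows(act_f(Za, act), act_f(Zb, act));
  size_t nd = H0.n_cols;
  mat Zpa = B.Ea * P.W4;
  mat Pa = act_f(Zpa, act);
  GateCache g_i = gate_mlp(Pa, P.mlp_i, act);
  auto Hs_i = pass_rounds(H0, src, dst, inv_deg, g_i.G, P.th_i, k_intra, share);
  const mat& Hprime = Hs_i.back();
  mat Zc = B.Hc * P.W3;
  mat Hcg = act_f(Zc, act);
  mat Hq0 = join_rows(Hprime, Hcg.rows(gnode));
  mat Zw5 = B.Eb * P.W5;
  mat P5 = act_f(Zw5, act);
  mat Ec = E ? join_rows(Pa, P5.rows(gedge)) : mat(0, 2 * P5.n_cols);
  GateCache g_q = gate_mlp(Pa, P.mlp_q, act);
  auto Hs_q = pass_rounds(Hq0, src, dst, inv_deg, g_q.G, P.th_q, k_inter, share);
  GateCache g_e = gate_mlp(Ec, P.mlp_e, act);
  auto Hs_e = pass_rounds(Hprime, src, dst, inv_deg, g_e.G, P.th_e, k_inter, share);

  S2SCache ro_q, ro_e;
  mat out_q, out_e;
  if (s2s) {
    ro_q = set2set_fwd(Hs_q.back(), gnode, G, P.ro_q, steps);
    ro_e = set2set_fwd(Hs_e.back(), gnode, G, P.ro_e, steps);
    out_q = ro_q.out; out_e = ro_e.out;
  } else {
    out_q = zeros<mat>(G, Hs_q.back().n_cols);
    out_e = zeros<mat>(G, Hs_e.back().n_cols);
    for (size_t i = 0; i < N; i++) {
      out_q.row(gnode[i]) += Hs_q.back().row(i);
      out_e.row(gnode[i]) += Hs_e.back().row(i);
    }
  }
  mat hG = join_rows(out_q, out_e);
  int L = P.headW.size();
  std::vector<mat> Zs(L), As(L + 1);
  As[0] = hG;
  for (int l = 0; l < L; l++) {
    Zs[l] = add_bias(As[l] * P.headW[l], P.headb[l]);
    As[l + 1] = (l < L - 1) ? act_f(Zs[l], act) : Zs[l];
  }
  vec y_hat = Zs[L - 1].col(0);
  y_hat_out = y_hat;
  vec resid = y_hat - B.y;
  double loss = dot(resid, resid) / G;
  if (!want_grads) return loss;

  Params& Gr = *Gp;
  vec dY = 2 * resid / G;
  mat dZ = mat(dY);
  for (int l = L - 1; l >= 0; l--) {
    if (l < L - 1) dZ = dZ % act_df(Zs[l], act);
    Gr.headW[l] += As[l].t() * dZ;
    Gr.headb[l] += sum(dZ, 0).t();
    dZ = dZ * P.headW[l].t();
  }
  size_t wq = out_q.n_cols;
  mat d_roq = dZ.cols(0, wq - 1);
  mat d_roe = dZ.cols(wq, dZ.n_cols - 1);

  mat dMq, dMe;
  if (s2s) {
    S2SGrads gq = set2set_bwd(Hs_q.back(), gnode, G, P.ro_q, ro_q, d_roq);
    S2SGrads ge = set2set_bwd(Hs_e.back(), gnode, G, P.ro_e, ro_e, d_roe);
    dMq = gq.dM; dMe = ge.dM;
    Gr.ro_q.Wx += gq.dWx; Gr.ro_q.Wh += gq.dWh; Gr.ro_q.b += gq.db;
    Gr.ro_e.Wx += ge.dWx; Gr.ro_e.Wh += ge.dWh; Gr.ro_e.b += ge.db;
  } else {
    dMq = d_roq.rows(gnode);
    dMe = d_roe.rows(gnode);
  }

  PassGrads pq = pass_bwd(Hs_q, src, dst, inv_deg, g_q.G, P.th_q, share, dMq);
  PassGrads pe = pass_bwd(Hs_e, src, dst, inv_deg, g_e.G, P.th_e, share, dMe);
  for (size_t k = 0; k < Gr.th_q.size(); k++) Gr.th_q[k] += pq.dTh[k];
  for (size_t k = 0; k < Gr.th_e.size(); k++) Gr.th_e[k] += pe.dTh[k];

  mat dHprime = pq.dH0.cols(0, nd - 1) + pe.dH0;
  mat dHcg(G, Hcg.n_cols, fill::zeros);
  for (size_t i = 0; i < N; i++) {
    dHcg.row(gnode[i]) += pq.dH0.row(i).cols(nd, pq.dH0.n_cols - 1);
  }
  Gr.W3 += B.Hc.t() * (dHcg % act_df(Zc, act));

  PassGrads pi = pass_bwd(Hs_i, src, dst, inv_deg, g_i.G, P.th_i, share,
                          dHprime);
  for (size_t k = 0; k < Gr.th_i.size(); k++) Gr.th_i[k] += pi.dTh[k];

  GateGrads gi = gate_bwd(Pa, g_i, P.mlp_i, act, pi.dGate);
  GateGrads gq2 = gate_bwd(Pa, g_q, P.mlp_q, act, pq.dGate);
  GateGrads ge2 = gate_bwd(Ec, g_e, P.mlp_e, act, pe.dGate);
  Gr.mlp_i.W1 += gi.dW1; Gr.mlp_i.b1 += gi.db1;
  Gr.mlp_i.W2 += gi.dW2; Gr.mlp_i.b2 += gi.db2;
  Gr.mlp_q.W1 += gq2.dW1; Gr.mlp_q.b1 += gq2.db1;
  Gr.mlp_q.W2 += gq2.dW2; Gr.mlp_q.b2 += gq2.db2;
  Gr.mlp_e.W1 += ge2.dW1; Gr.mlp_e.b1 += ge2.db1;
  Gr.mlp_e.W2 += ge2.dW2; Gr.mlp_e.b2 += ge2.db2;

  size_t de = Pa.n_cols;
  mat dPa = gi.dX + gq2.dX;
  mat dP5(G, de, fill::zeros);
  if (E) {
    dPa += ge2.dX.cols(0, de - 1);
    for (size_t e = 0; e < E; e++) {
      dP5.row(gedge[e]) += ge2.dX.row(e).cols(de, 2 * de - 1);
    }
  }
  Gr.W5 += B.Eb.t() * (dP5 % act_df(Zw5, act));
  Gr.W4 += B.Ea.t() * (dPa % act_df(Zpa, act));

  mat dH0 = pi.dH0;
  size_t d1 = Za.n_cols;
  Gr.W1 += B.Xa.t() * (dH0.cols(0, d1 - 1) % act_df(Za, act));
  Gr.W2 += B.Xb.t() * (dH0.cols(d1, nd - 1) % act_df(Zb, act));
  return loss;
}

void zero_params(Params& g) {
  g.W1.zeros(); g.W2.zeros(); g.W3.zeros(); g.W4.zeros(); g.W5.zeros();
  for (auto& m : g.th_i) m.zeros();
  for (auto& m : g.th_q) m.zeros();
  for (auto& m : g.th_e) m.zeros();
  for (auto* m : {&g.mlp_i, &g.mlp_q, &g.mlp_e}) {
    m->W1.zeros(); m->b1.zeros(); m->W2.zeros(); m->b2.zeros();
  }
  g.ro_q.Wx.zeros(); g.ro_q.Wh.zeros(); g.ro_q.b.zeros();
  g.ro_e.Wx.zeros(); g.ro_e.Wh.zeros(); g.ro_e.b.zeros();
  for (auto& m : g.headW) m.zeros();
  for (auto& b : g.headb) b.zeros();
}

} // namespace

// forward (+ optional backward) for one batch; params and grads are flat
// vectors in the R collect_leaves() order
// [[Rcpp::export]]
Rcpp::List cpp_loss_grads(Rcpp::NumericVector params_flat, Rcpp::List cfg,
                          Rcpp::List batch, Rcpp::NumericVector y,
                          bool want_grads) {
  Params P = map_params(REAL(params_flat), cfg);
  Batch B = make_batch(batch, y);
  vec y_hat;
  if (!want_grads) {
    double loss = forward_backward(P, B, cfg, false, nullptr, y_hat);
    return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("y_hat") = Rcpp::NumericVector(y_hat.begin(), y_hat.end()));
  }
  Params Gp = zero_like(P);
  double loss = forward_backward(P, B, cfg, true, &Gp, y_hat);
  bool s2s = cfg["set2set"];
  Rcpp::NumericVector grads_flat(params_flat.size());
  serialize_params(Gp, s2s, REAL(grads_flat));
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("y_hat") = Rcpp::NumericVector(y_hat.begin(), y_hat.end()),
    Rcpp::Named("grads") = grads_flat);
}

// full training loop: fixed batch partition, per-epoch batch order from R
// (reproducible), Adam updates, optional validation-based early stopping.
// params_flat, m, v are updated in place; returns traces and the best
// parameter vector.
// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::NumericVector params_flat, Rcpp::List cfg,
                     Rcpp::List batches, Rcpp::List batch_targets,
                     Rcpp::List val_batches, Rcpp::List val_targets,
                     Rcpp::IntegerMatrix batch_plan,
                     Rcpp::NumericVector m, Rcpp::NumericVector v,
                     Rcpp::LogicalVector frozen_mask,
                     double lr, int patience, double std_sd,
                     Rcpp::NumericVector val_y_raw, double std_mean) {
  bool s2s = cfg["set2set"];
  size_t npar = params_flat.size();
  std::vector<Batch> Bs;
  int n_train = 0;
  for (int b = 0; b < batches.size(); b++) {
    Bs.push_back(make_batch(batches[b], batch_targets[b]));
    n_train += Bs.back().G;
  }
  std::vector<Batch> Vs;
  for (int b = 0; b < val_batches.size(); b++) {
    Vs.push_back(make_batch(val_batches[b], val_targets[b]));
  }
  Params P = map_params(REAL(params_flat), cfg);
  Params Gp = zero_like(P);
  int epochs = batch_plan.ncol();
  int n_batches = batch_plan.nrow();
  double* mp = REAL(m); double* vp = REAL(v);
  bool any_frozen = (size_t)frozen_mask.size() == npar;
  vec best_flat(npar);
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, epochs_run = 0, t_adam = 0;
  mat traces(epochs, 2, fill::value(datum::nan));
  vec flat_buf(npar);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  for (int ep = 0; ep < epochs; ep++) {
    double abs_err = 0;
    for (int bi = 0; bi < n_batches; bi++) {
      Batch& B = Bs[batch_plan(bi, ep) - 1];
      vec y_hat;
      zero_params(Gp);
      double loss = forward_backward(P, B, cfg, true, &Gp, y_hat);
      if (!std::isfinite(loss)) {
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      }
      abs_err += accu(abs(y_hat - B.y)) * std_sd;
      serialize_params(Gp, s2s, flat_buf.memptr());
      t_adam++;
      double bc1 = 1 - std::pow(beta1, t_adam);
      double bc2 = 1 - std::pow(beta2, t_adam);
      double* pp = REAL(params_flat);
      const double* gp = flat_buf.memptr();
      for (size_t i = 0; i < npar; i++) {
        if (any_frozen && frozen_mask[i]) continue;
        mp[i] = beta1 * mp[i] + (1 - beta1) * gp[i];
        vp[i] = beta2 * vp[i] + (1 - beta2) * gp[i] * gp[i];
        pp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
      }
      P = map_params(REAL(params_flat), cfg);
    }
    traces(ep, 0) = abs_err / n_train;
    epochs_run = ep + 1;
    if (!Vs.empty()) {
      double vmae = 0; int nv = 0; size_t off = 0;
      for (auto& VB : Vs) {
        vec y_hat;
        forward_backward(P, VB, cfg, false, nullptr, y_hat);
        for (size_t g = 0; g < VB.G; g++) {
          double pred = y_hat[g] * std_sd + std_mean;
          vmae += std::abs(pred - val_y_raw[off + g]);
        }
        nv += VB.G; off += VB.G;
      }
      vmae /= nv;
      traces(ep, 1) = vmae;
      if (vmae < best_val - 1e-12) {
        best_val = vmae;
        best_epoch = ep + 1;
        std::memcpy(best_flat.memptr(), REAL(params_flat),
                    npar * sizeof(double));
        wait = 0;
      } else if (++wait >= patience) break;
    }
  }
  if (Vs.empty()) {
    std::memcpy(best_flat.memptr(), REAL(params_flat), npar * sizeof(double));
    best_epoch = epochs_run;
    best_val = datum::nan;
  }
  return Rcpp::List::create(
    Rcpp::Named("best_flat") = Rcpp::NumericVector(best_flat.begin(),
                                                   best_flat.end()),
    Rcpp::Named("traces") = traces,
    Rcpp::Named("epochs_run") = epochs_run,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val") = best_val);
}

// in-place Adam update on flat parameter/state vectors
// [[Rcpp::export]]
void cpp_adam_step(Rcpp::NumericVector p, Rcpp::NumericVector g,
                   Rcpp::NumericVector m, Rcpp::NumericVector v,
                   Rcpp::LogicalVector frozen_mask,
                   int t, double lr, double beta1, double beta2, double eps) {
  double bc1 = 1 - std::pow(beta1, t);
  double bc2 = 1 - std::pow(beta2, t);
  R_xlen_t n = p.size();
  bool any_frozen = frozen_mask.size() == n;
  for (R_xlen_t i = 0; i < n; i++) {
    if (any_frozen && frozen_mask[i]) continue;
    m[i] = beta1 * m[i] + (1 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    p[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}
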
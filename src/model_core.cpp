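// Fast per-sample forward/backward core for the sparse hierarchical graph
// network. Mirrors the reference R implementation (model-forward.R /
// model-backward.R) operation for operation; the two paths are cross-checked
// in the test suite. All computation in double precision.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Config {
  int n, d, nE2E, LAtt, pAtt;
  double ratio, slope;
  int mode; // 0 identity, 1 e2e, 2 averaging
};

struct Params {
  std::vector<cube> e2eR, e2eC; // per layer: n x dIn x dOut
  cube e2n;                     // n x d x d
  mat embedR, embedC;           // n x d (mode e2e only)
  std::vector<mat> attW0, attW1;
  std::vector<mat> mlpW;
  std::vector<vec> mlpB;
};

struct LayerState {
  mat X, A, P, Q0, H1, H1a, Q1;
  vec S, Sk;
  uvec keep;
  mat Xk, Xn;
  std::vector<uword> amax; // argmax row per feature column of Xn
};

struct Forward {
  std::vector<cube> fmaps; // nE2E+1 tensors (index 0 = input map)
  std::vector<cube> pres;
  mat Epre, E, R, A1;
  std::vector<LayerState> layers;
  vec z;
  std::vector<vec> mpre, acts;
  double pred;
};

inline mat lrelu(const mat& x, double s) {
  return clamp(x, 0.0, datum::inf) + s * clamp(x, -datum::inf, 0.0);
}
inline cube lreluC(const cube& x, double s) {
  cube y = x;
  y.transform([s](double v) { return v >= 0 ? v : s * v; });
  return y;
}
inline mat lgrad(const mat& x, double s) {
  mat g(size(x));
  for (uword i = 0; i < x.n_elem; ++i) g(i) = x(i) >= 0 ? 1.0 : s;
  return g;
}
inline cube lgradC(const cube& x, double s) {
  cube g(size(x));
  for (uword i = 0; i < x.n_elem; ++i) g(i) = x(i) >= 0 ? 1.0 : s;
  return g;
}

Config readConfig(const Rcpp::List& cfg) {
  Config c;
  c.n = cfg["n"];
  c.d = cfg["d"];
  c.nE2E = cfg["nE2E"];
  c.LAtt = cfg["LAtt"];
  c.pAtt = cfg["pAtt"];
  c.ratio = cfg["ratio"];
  c.slope = cfg["slope"];
  c.mode = cfg["mode"];
  return c;
}

Params readParams(const Rcpp::List& p, const Config& cfg) {
  Params out;
  Rcpp::List e2e = p["e2e"];
  for (int l = 0; l < cfg.nE2E; ++l) {
    Rcpp::List lay = e2e[l];
    Rcpp::NumericVector r = lay["r"], c = lay["c"];
    Rcpp::IntegerVector dr = r.attr("dim");
    out.e2eR.emplace_back(cube(r.begin(), dr[0], dr[1], dr[2]));
    out.e2eC.emplace_back(cube(c.begin(), dr[0], dr[1], dr[2]));
  }
  Rcpp::NumericVector w = p["e2n"];
  Rcpp::IntegerVector dw = w.attr("dim");
  out.e2n = cube(w.begin(), dw[0], dw[1], dw[2]);
  if (cfg.mode == 1) {
    out.embedR = Rcpp::as<mat>(p["embedR"]);
    out.embedC = Rcpp::as<mat>(p["embedC"]);
  }
  Rcpp::List att = p["att"];
  for (int l = 0; l < cfg.LAtt; ++l) {
    Rcpp::List lay = att[l];
    out.attW0.push_back(Rcpp::as<mat>(lay["W0"]));
    out.attW1.push_back(Rcpp::as<mat>(lay["W1"]));
  }
  Rcpp::List mlp = p["mlp"];
  Rcpp::List W = mlp["W"], b = mlp["b"];
  for (int i = 0; i < W.size(); ++i) {
    out.mlpW.push_back(Rcpp::as<mat>(W[i]));
    out.mlpB.push_back(Rcpp::as<vec>(b[i]));
  }
  return out;
}

// pre[i,j,b] = sum_a sum_k r[k,a,b] f[i,k,a] + c[k,a,b] f[k,j,a]
cube e2ePre(const cube& f, const cube& r, const cube& c) {
  const uword n = f.n_rows, dIn = f.n_slices, dOut = r.n_slices;
  cube pre(n, n, dOut);
  for (uword b = 0; b < dOut; ++b) {
    vec Rrow(n, fill::zeros), Ccol(n, fill::zeros);
    for (uword a = 0; a < dIn; ++a) {
      Rrow += f.slice(a) * r.slice(b).col(a);
      Ccol += f.slice(a).t() * c.slice(b).col(a);
    }
    pre.slice(b) = repmat(Rrow, 1, n) + repmat(Ccol.t(), n, 1);
  }
  return pre;
}

mat e2nPre(const cube& f, const cube& w) {
  const uword n = f.n_rows, dIn = f.n_slices, dOut = w.n_slices;
  mat E(n, dOut, fill::zeros);
  for (uword b = 0; b < dOut; ++b)
    for (uword a = 0; a < dIn; ++a)
      E.col(b) += f.slice(a) * w.slice(b).col(a);
  return E;
}

mat normAdj(const mat& A) {
  mat At = A + eye(A.n_rows, A.n_rows);
  vec s = 1.0 / sqrt(sum(At, 1));
  return At % (s * s.t());
}

// gradient of P = normAdj(A) w.r.t. A, given dL/dP
mat gradNormAdj(const mat& dP, const mat& A) {
  mat At = A + eye(A.n_rows, A.n_rows);
  vec deg = sum(At, 1);
  vec s = 1.0 / sqrt(deg);
  mat P = At % (s * s.t());
  vec dd = -(sum(dP % P, 1) + sum(dP % P, 0).t()) / (2.0 * deg);
  return (s * s.t()) % dP + repmat(dd, 1, A.n_cols);
}

Forward forwardPass(const mat& g, const Params& P, const Config& cfg) {
  Forward fw;
  const int n = cfg.n;
  const double sl = cfg.slope;
  fw.fmaps.resize(cfg.nE2E + 1);
  fw.pres.resize(cfg.nE2E);
  fw.fmaps[0] = cube(n, n, 1);
  fw.fmaps[0].slice(0) = g;
  for (int l = 0; l < cfg.nE2E; ++l) {
    fw.pres[l] = e2ePre(fw.fmaps[l], P.e2eR[l], P.e2eC[l]);
    fw.fmaps[l + 1] = lreluC(fw.pres[l], sl);
  }
  const cube& fL = fw.fmaps[cfg.nE2E];
  fw.Epre = e2nPre(fL, P.e2n);
  fw.E = lrelu(fw.Epre, sl);

  // adjacency embedding
  if (cfg.mode == 0) {
    fw.R = g;
  } else if (cfg.mode == 2) {
    fw.R = mean(fL, 2);
  } else {
    vec Rrow(n, fill::zeros), Ccol(n, fill::zeros);
    for (uword a = 0; a < fL.n_slices; ++a) {
      Rrow += fL.slice(a) * P.embedR.col(a);
      Ccol += fL.slice(a).t() * P.embedC.col(a);
    }
    fw.R = repmat(Rrow, 1, n) + repmat(Ccol.t(), n, 1);
  }
  mat B = conv_to<mat>::from(fw.R >= 0.0);
  fw.A1 = conv_to<mat>::from((B + B.t()) > 0.0);

  mat X = fw.E, A = fw.A1;
  fw.layers.resize(cfg.LAtt);
  for (int l = 0; l < cfg.LAtt; ++l) {
    LayerState& st = fw.layers[l];
    st.X = X;
    st.A = A;
    st.P = normAdj(A);
    st.Q0 = st.P * X;
    st.H1 = st.Q0 * P.attW0[l];
    st.H1a = lrelu(st.H1, sl);
    st.Q1 = st.P * st.H1a;
    mat H2 = st.Q1 * P.attW1[l];
    st.S = 1.0 / (1.0 + exp(-H2.col(0)));
    const uword nl = st.S.n_elem;
    const uword k = (uword)std::ceil(cfg.ratio * nl);
    // rank by score descending, ties by lowest index
    std::vector<uword> idx(nl);
    for (uword i = 0; i < nl; ++i) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(), [&](uword a, uword b) {
      return st.S(a) > st.S(b);
    });
    idx.resize(k);
    std::sort(idx.begin(), idx.end());
    st.keep = uvec(idx);
    st.Xk = X.rows(st.keep);
    st.Sk = st.S(st.keep);
    st.Xn = st.Xk.each_col() % (1.0 + st.Sk);
    st.amax.resize(st.Xn.n_cols);
    for (uword c = 0; c < st.Xn.n_cols; ++c)
      st.amax[c] = st.Xn.col(c).index_max();
    X = st.Xn;
    A = A.submat(st.keep, st.keep);
  }

  const int m = cfg.d;
  fw.z = vec(2 * m, fill::zeros);
  for (int l = 0; l < cfg.LAtt; ++l) {
    const mat& Xn = fw.layers[l].Xn;
    fw.z.subvec(0, m - 1) += mean(Xn, 0).t();
    fw.z.subvec(m, 2 * m - 1) += max(Xn, 0).t();
  }

  const int nh = P.mlpW.size();
  fw.acts.resize(nh + 1);
  fw.mpre.resize(nh);
  fw.acts[0] = fw.z;
  for (int i = 0; i < nh; ++i) {
    fw.mpre[i] = P.mlpW[i].t() * fw.acts[i] + P.mlpB[i];
    fw.acts[i + 1] = (i < nh - 1) ? vec(lrelu(fw.mpre[i], sl)) : fw.mpre[i];
  }
  fw.pred = fw.acts[nh](0);
  return fw;
}

struct Grads {
  std::vector<cube> e2eR, e2eC;
  cube e2n;
  mat embedR, embedC;
  std::vector<mat> attW0, attW1;
  std::vector<mat> mlpW;
  std::vector<vec> mlpB;
  mat dInput;

  void init(const Params& P, const Config& cfg) {
    for (size_t l = 0; l < P.e2eR.size(); ++l) {
      e2eR.emplace_back(cube(size(P.e2eR[l]), fill::zeros));
      e2eC.emplace_back(cube(size(P.e2eC[l]), fill::zeros));
    }
    e2n = cube(size(P.e2n), fill::zeros);
    if (cfg.mode == 1) {
      embedR = mat(size(P.embedR), fill::zeros);
      embedC = mat(size(P.embedC), fill::zeros);
    }
    for (size_t l = 0; l < P.attW0.size(); ++l) {
      attW0.emplace_back(mat(size(P.attW0[l]), fill::zeros));
      attW1.emplace_back(mat(size(P.attW1[l]), fill::zeros));
    }
    for (size_t i = 0; i < P.mlpW.size(); ++i) {
      mlpW.emplace_back(mat(size(P.mlpW[i]), fill::zeros));
      mlpB.emplace_back(vec(size(P.mlpB[i]), fill::zeros));
    }
    dInput = mat(size(mat(1, 1)), fill::zeros);
  }
};

// accumulate gradients of dy * prediction into G
void backwardPass(const Forward& fw, const Params& P, const Config& cfg,
                  double dy, bool straight, Grads& G) {
  const int n = cfg.n, m = cfg.d;
  const double sl = cfg.slope;

  // prediction head
  const int nh = P.mlpW.size();
  vec da(1);
  da(0) = dy;
  for (int i = nh - 1; i >= 0; --i) {
    vec dpre = (i < nh - 1) ? vec(da % vec(lgrad(fw.mpre[i], sl))) : da;
    G.mlpW[i] += fw.acts[i] * dpre.t();
    G.mlpB[i] += dpre;
    da = P.mlpW[i] * dpre;
  }
  vec dzMean = da.subvec(0, m - 1), dzMax = da.subvec(m, 2 * m - 1);

  // attention-pooling layers, last to first
  mat dXdown, dAdown;
  bool haveDown = false;
  for (int l = cfg.LAtt - 1; l >= 0; --l) {
    const LayerState& st = fw.layers[l];
    const uword nl = st.S.n_elem, k = st.keep.n_elem;
    mat dXn = repmat(dzMean.t() / (double)k, k, 1);
    for (int c = 0; c < m; ++c) dXn(st.amax[c], c) += dzMax(c);
    if (haveDown) dXn += dXdown;
    mat dXk = dXn.each_col() % (1.0 + st.Sk);
    vec dSk = sum(dXn % st.Xk, 1);
    mat dX(nl, m, fill::zeros);
    dX.rows(st.keep) = dXk;
    vec dS(nl, fill::zeros);
    dS(st.keep) = dSk;
    mat dA(nl, nl, fill::zeros);
    if (haveDown && straight) dA.submat(st.keep, st.keep) = dAdown;

    mat dH2 = mat(dS % st.S % (1.0 - st.S));
    G.attW1[l] += st.Q1.t() * dH2;
    mat dH1a = (st.P * dH2) * P.attW1[l].t();
    mat dH1 = dH1a % lgrad(st.H1, sl);
    G.attW0[l] += st.Q0.t() * dH1;
    dX += (st.P * dH1) * P.attW0[l].t();
    if (straight) {
      mat dP = dH2 * (st.H1a * P.attW1[l]).t() + dH1 * (st.X * P.attW0[l]).t();
      dA += gradNormAdj(dP, st.A);
    }
    dXdown = dX;
    dAdown = dA;
    haveDown = true;
  }
  mat dE = dXdown;

  const cube& fL = fw.fmaps[cfg.nE2E];
  cube dfL(size(fL), fill::zeros);
  mat dG(n, n, fill::zeros);

  // adjacency embedding (straight-through)
  if (straight) {
    mat sig = 1.0 / (1.0 + exp(-fw.R));
    mat dR = ((dAdown + dAdown.t()) / 2.0) % sig % (1.0 - sig);
    if (cfg.mode == 0) {
      dG += dR;
    } else if (cfg.mode == 2) {
      const double dl = fL.n_slices;
      for (uword a = 0; a < fL.n_slices; ++a) dfL.slice(a) += dR / dl;
    } else {
      vec u = sum(dR, 1), v = sum(dR, 0).t();
      for (uword a = 0; a < fL.n_slices; ++a) {
        G.embedR.col(a) += fL.slice(a).t() * u;
        G.embedC.col(a) += fL.slice(a) * v;
        dfL.slice(a) += u * P.embedR.col(a).t() + P.embedC.col(a) * v.t();
      }
    }
  }

  // edge-to-node layer
  mat dEpre = dE % lgrad(fw.Epre, sl);
  for (uword b = 0; b < P.e2n.n_slices; ++b)
    for (uword a = 0; a < fL.n_slices; ++a) {
      G.e2n.slice(b).col(a) += fL.slice(a).t() * dEpre.col(b);
      dfL.slice(a) += dEpre.col(b) * P.e2n.slice(b).col(a).t();
    }

  // edge-to-edge layers, last to first
  cube dOutMaps = dfL;
  for (int l = cfg.nE2E - 1; l >= 0; --l) {
    cube dPre = dOutMaps % lgradC(fw.pres[l], sl);
    const cube& f = fw.fmaps[l];
    const uword dI = f.n_slices, dO = dPre.n_slices;
    cube dIn(size(f), fill::zeros);
    for (uword b = 0; b < dO; ++b) {
      vec u = sum(dPre.slice(b), 1), v = sum(dPre.slice(b), 0).t();
      for (uword a = 0; a < dI; ++a) {
        G.e2eR[l].slice(b).col(a) += f.slice(a).t() * u;
        G.e2eC[l].slice(b).col(a) += f.slice(a) * v;
        dIn.slice(a) += u * P.e2eR[l].slice(b).col(a).t() +
          P.e2eC[l].slice(b).col(a) * v.t();
      }
    }
    dOutMaps = dIn;
  }
  dG += dOutMaps.slice(0);
  G.dInput = dG;
}

Rcpp::List gradsToList(const Grads& G, const Config& cfg) {
  Rcpp::List e2e(cfg.nE2E);
  for (int l = 0; l < cfg.nE2E; ++l)
    e2e[l] = Rcpp::List::create(Rcpp::Named("r") = G.e2eR[l],
                                Rcpp::Named("c") = G.e2eC[l]);
  Rcpp::List att(cfg.LAtt);
  for (int l = 0; l < cfg.LAtt; ++l)
    att[l] = Rcpp::List::create(Rcpp::Named("W0") = G.attW0[l],
                                Rcpp::Named("W1") = G.attW1[l]);
  Rcpp::List W(G.mlpW.size()), b(G.mlpB.size());
  for (size_t i = 0; i < G.mlpW.size(); ++i) {
    W[i] = G.mlpW[i];
    b[i] = G.mlpB[i];
  }
  Rcpp::List mlp = Rcpp::List::create(Rcpp::Named("W") = W,
                                      Rcpp::Named("b") = b);
  if (cfg.mode == 1)
    return Rcpp::List::create(
      Rcpp::Named("e2e") = e2e, Rcpp::Named("e2n") = G.e2n,
      Rcpp::Named("embedR") = G.embedR, Rcpp::Named("embedC") = G.embedC,
      Rcpp::Named("att") = att, Rcpp::Named("mlp") = mlp);
  return Rcpp::List::create(
    Rcpp::Named("e2e") = e2e, Rcpp::Named("e2n") = G.e2n,
    Rcpp::Named("att") = att, Rcpp::Named("mlp") = mlp);
}

} // namespace

// [[Rcpp::export]]
double cppPredict(const arma::mat& g, const Rcpp::List& params,
                  const Rcpp::List& cfg) {
  Config c = readConfig(cfg);
  Params P = readParams(params, c);
  return forwardPass(g, P, c).pred;
}

// [[Rcpp::export]]
arma::vec cppPredictMany(const Rcpp::List& gs, const Rcpp::List& params,
                         const Rcpp::List& cfg) {
  Config c = readConfig(cfg);
  Params P = readParams(params, c);
  vec out(gs.size());
  for (int i = 0; i < gs.size(); ++i)
    out(i) = forwardPass(Rcpp::as<mat>(gs[i]), P, c).pred;
  return out;
}

// Mean-squared-error loss and summed parameter gradients over a mini-batch.
// dy per sample is 2 * (pred - y) / B.
// [[Rcpp::export]]
Rcpp::List cppBatchGrad(const Rcpp::List& gs, const arma::vec& y,
                        const Rcpp::List& params, const Rcpp::List& cfg,
                        bool straight) {
  Config c = readConfig(cfg);
  Params P = readParams(params, c);
  const int B = gs.size();
  Grads G;
  G.init(P, c);
  double loss = 0.0;
  for (int i = 0; i < B; ++i) {
    Forward fw = forwardPass(Rcpp::as<mat>(gs[i]), P, c);
    double err = fw.pred - y(i);
    loss += err * err;
    backwardPass(fw, P, c, 2.0 * err / B, straight, G);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss / B,
                            Rcpp::Named("grads") = gradsToList(G, c));
}

// Single-sample gradients of the raw prediction (for cross-checks).
// [[Rcpp::export]]
Rcpp::List cppPredictionGrad(const arma::mat& g, const Rcpp::List& params,
                             const Rcpp::List& cfg, bool straight) {
  Config c = readConfig(cfg);
  Params P = readParams(params, c);
  Grads G;
  G.init(P, c);
  Forward fw = forwardPass(g, P, c);
  backwardPass(fw, P, c, 1.0, straight, G);
  return Rcpp::List::create(Rcpp::Named("prediction") = fw.pred,
                            Rcpp::Named("grads") = gradsToList(G, c),
                            Rcpp::Named("dInput") = G.dInput);
}
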
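// SleepNet compute core: 1D-convolutional pre-activation residual feature
// extractor, bidirectional LSTM over the night's epoch sequence, two
// fully-connected prediction layers, and per-task self-supervision heads.
// Forward and backward passes are written out explicitly; the R side owns
// parameter initialisation, batching and the Adam optimizer.
//
// Layout conventions:
//   - a batch of windows is a cube (channels x time x N), slice = window;
//   - windows are ordered sequence-major: slice n = b*S + s for sequence b,
//     within-sequence epoch s (s fastest);
//   - parameters and gradients travel as named R lists of matrices/vectors.

#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-5;

struct ConvSpec {
  int in, out, k, stride, pad;
};

static ConvSpec conv_spec(const Rcpp::List& l) {
  ConvSpec s;
  s.in = Rcpp::as<int>(l["in"]);
  s.out = Rcpp::as<int>(l["out"]);
  s.k = Rcpp::as<int>(l["k"]);
  s.stride = Rcpp::as<int>(l["stride"]);
  s.pad = (s.k - 1) / 2;
  return s;
}

static int conv_out_len(int T, const ConvSpec& s) {
  return (T + 2 * s.pad - s.k) / s.stride + 1;
}

// ---------------------------------------------------------------------------
// parameter store

struct PStore {
  Rcpp::List params;
  std::map<std::string, mat> grads;
  bool want_grad;

  mat P(const std::string& n) const {
    if (!params.containsElementNamed(n.c_str()))
      Rcpp::stop("missing parameter: " + n);
    return Rcpp::as<mat>(params[n]);
  }
  vec Pv(const std::string& n) const {
    if (!params.containsElementNamed(n.c_str()))
      Rcpp::stop("missing parameter: " + n);
    return Rcpp::as<vec>(params[n]);
  }
  void acc(const std::string& n, const mat& g) {
    if (!want_grad) return;
    auto it = grads.find(n);
    if (it == grads.end()) grads[n] = g; else it->second += g;
  }
  Rcpp::List grad_list() const {
    Rcpp::List out;
    for (auto& kv : grads) out[kv.first] = kv.second;
    return out;
  }
};

// ---------------------------------------------------------------------------
// conv1d via im2col

static mat im2col(const mat& A, const ConvSpec& s, int T_out) {
  const int C = A.n_rows, T = A.n_cols;
  mat col(C * s.k, T_out, fill::zeros);
  for (int t = 0; t < T_out; ++t) {
    const int t0 = t * s.stride - s.pad;
    for (int j = 0; j < s.k; ++j) {
      const int src = t0 + j;
      if (src >= 0 && src < T) {
        for (int c = 0; c < C; ++c) col(c * s.k + j, t) = A(c, src);
      }
    }
  }
  return col;
}

static void col2im_acc(mat& dA, const mat& dcol, const ConvSpec& s) {
  const int C = dA.n_rows, T = dA.n_cols, T_out = dcol.n_cols;
  for (int t = 0; t < T_out; ++t) {
    const int t0 = t * s.stride - s.pad;
    for (int j = 0; j < s.k; ++j) {
      const int src = t0 + j;
      if (src >= 0 && src < T) {
        for (int c = 0; c < C; ++c) dA(c, src) += dcol(c * s.k + j, t);
      }
    }
  }
}

struct ConvCache {
  std::vector<mat> cols; // per slice
};

static cube conv_forward(const cube& A, const mat& W, const vec& b,
                         const ConvSpec& s, ConvCache& cache, bool keep_cols) {
  const int N = A.n_slices;
  const int T_out = conv_out_len(A.n_cols, s);
  cube Y(s.out, T_out, N);
  if (keep_cols) cache.cols.resize(N);
  for (int n = 0; n < N; ++n) {
    mat col = im2col(A.slice(n), s, T_out);
    Y.slice(n) = W * col;
    Y.slice(n).each_col() += b;
    if (keep_cols) cache.cols[n] = std::move(col);
  }
  return Y;
}

// returns dA; accumulates dW, db into store under given names
static cube conv_backward(const cube& A_in, const cube& dY, const mat& W,
                          const ConvSpec& s, const ConvCache& cache,
                          PStore& ps, const std::string& wname,
                          const std::string& bname) {
  const int N = dY.n_slices;
  cube dA(A_in.n_rows, A_in.n_cols, N, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_rows, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const mat& dYn = dY.slice(n);
    dW += dYn * cache.cols[n].t();
    db += sum(dYn, 1);
    mat dcol = W.t() * dYn;
    col2im_acc(dA.slice(n), dcol, s);
  }
  ps.acc(wname, dW);
  ps.acc(bname, db);
  return dA;
}

// ---------------------------------------------------------------------------
// batch normalisation over (time x slices) per channel

struct BNCache {
  vec mean, invstd;
  cube xhat;
};

static cube bn_forward(const cube& X, const vec& g, const vec& b,
                       Rcpp::List& run_stats, const std::string& prefix,
                       bool training, double momentum, BNCache& cache) {
  const int C = X.n_rows, T = X.n_cols, N = X.n_slices;
  const double m = static_cast<double>(T) * N;
  vec mean(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const rowvec r = X.slice(n).row(c);
        s += accu(r);
        s2 += accu(r % r);
      }
      mean(c) = s / m;
      var(c) = std::max(s2 / m - mean(c) * mean(c), 0.0);
    }
    std::string mn = prefix + "_mean", vn = prefix + "_var";
    vec rm = Rcpp::as<vec>(run_stats[mn]);
    vec rv = Rcpp::as<vec>(run_stats[vn]);
    run_stats[mn] = momentum * rm + (1 - momentum) * mean;
    run_stats[vn] = momentum * rv + (1 - momentum) * var;
  } else {
    mean = Rcpp::as<vec>(run_stats[prefix + "_mean"]);
    var = Rcpp::as<vec>(run_stats[prefix + "_var"]);
  }
  cache.mean = mean;
  cache.invstd = 1.0 / sqrt(var + BN_EPS);
  cache.xhat.set_size(C, T, N);
  cube Y(C, T, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      rowvec xh = (X.slice(n).row(c) - mean(c)) * cache.invstd(c);
      cache.xhat.slice(n).row(c) = xh;
      Y.slice(n).row(c) = g(c) * xh + b(c);
    }
  }
  return Y;
}

static cube bn_backward(const cube& dY, const vec& g, const BNCache& cache,
                        bool training, PStore& ps, const std::string& gname,
                        const std::string& bname) {
  const int C = dY.n_rows, T = dY.n_cols, N = dY.n_slices;
  const double m = static_cast<double>(T) * N;
  vec dg(C, fill::zeros), db(C, fill::zeros);
  cube dX(C, T, N);
  for (int c = 0; c < C; ++c) {
    double sum_dy = 0, sum_dyx = 0;
    for (int n = 0; n < N; ++n) {
      const rowvec dyr = dY.slice(n).row(c);
      const rowvec xhr = cache.xhat.slice(n).row(c);
      sum_dy += accu(dyr);
      sum_dyx += accu(dyr % xhr);
    }
    dg(c) = sum_dyx;
    db(c) = sum_dy;
    const double mdy = sum_dy / m, mdyx = sum_dyx / m;
    for (int n = 0; n < N; ++n) {
      const rowvec dyr = dY.slice(n).row(c);
      const rowvec xhr = cache.xhat.slice(n).row(c);
      if (training) {
        dX.slice(n).row(c) =
            g(c) * cache.invstd(c) * (dyr - mdy - xhr * mdyx);
      } else {
        dX.slice(n).row(c) = g(c) * cache.invstd(c) * dyr;
      }
    }
  }
  ps.acc(gname, dg);
  ps.acc(bname, db);
  return dX;
}

static cube relu(const cube& X) {
  cube Y = X;
  Y.transform([](double v) { return v > 0 ? v : 0.0; });
  return Y;
}

static cube relu_backward(const cube& dY, const cube& pre) {
  cube dX = dY;
  const uword n = dX.n_elem;
  for (uword i = 0; i < n; ++i) if (pre(i) <= 0) dX(i) = 0;
  return dX;
}

// ---------------------------------------------------------------------------
// extractor: stem conv -> pre-activation residual blocks -> BN/ReLU -> GAP

struct BlockCache {
  cube A_in, bn1_pre, h1relu, conv1_out, bn2_pre, h2relu;
  BNCache bn1, bn2;
  ConvCache c1, c2, cs;
  bool proj;
  ConvSpec s1, s2, ss;
};

struct ExtractorCache {
  cube X, stem_out;
  ConvCache stem_cols;
  ConvSpec stem_spec;
  std::vector<BlockCache> blocks;
  cube final_pre; // BN output before final ReLU
  BNCache bnf;
  cube final_relu;
  int T_final;
};

static mat extractor_forward(const cube& X, PStore& ps, const Rcpp::List& cfg,
                             Rcpp::List& run_stats, bool training,
                             double momentum, ExtractorCache& ec,
                             bool keep_cache) {
  // optional fixed input features: a vector-magnitude channel (rectified
  // movement envelope the convolutions can smooth and differentiate
  // directly) and per-window per-channel mean removal, so the slowly
  // varying gravity component does not dominate the movement signal
  bool add_vm = cfg.containsElementNamed("input_vm") &&
                Rcpp::as<bool>(cfg["input_vm"]);
  if (add_vm) {
    ec.X.set_size(X.n_rows + 1, X.n_cols, X.n_slices);
    for (uword n = 0; n < X.n_slices; ++n) {
      ec.X.slice(n).rows(0, X.n_rows - 1) = X.slice(n);
      ec.X.slice(n).row(X.n_rows) = sqrt(sum(square(X.slice(n)), 0));
    }
  } else {
    ec.X = X;
  }
  bool center = cfg.containsElementNamed("center_input")
                    ? Rcpp::as<bool>(cfg["center_input"])
                    : true;
  if (center) {
    for (uword n = 0; n < ec.X.n_slices; ++n) {
      ec.X.slice(n).each_col() -= mean(ec.X.slice(n), 1);
    }
  }
  ec.stem_spec = conv_spec(cfg["stem"]);
  cube A = conv_forward(ec.X, ps.P("stem_W"), ps.Pv("stem_b"), ec.stem_spec,
                        ec.stem_cols, keep_cache);
  ec.stem_out = A;

  Rcpp::List blocks = cfg["blocks"];
  ec.blocks.resize(blocks.size());
  for (int i = 0; i < blocks.size(); ++i) {
    BlockCache& bc = ec.blocks[i];
    std::string p = "b" + std::to_string(i + 1) + "_";
    ConvSpec s1 = conv_spec(blocks[i]);
    bc.s1 = s1;
    bc.s2 = {s1.out, s1.out, s1.k, 1, (s1.k - 1) / 2};
    bc.proj = (s1.in != s1.out) || (s1.stride != 1);
    bc.ss = {s1.in, s1.out, 1, s1.stride, 0};
    bc.A_in = A;

    bc.bn1_pre = bn_forward(A, ps.Pv(p + "bn1_g"), ps.Pv(p + "bn1_b"),
                            run_stats, p + "bn1", training, momentum, bc.bn1);
    bc.h1relu = relu(bc.bn1_pre);
    cube sc = bc.proj
                  ? conv_forward(bc.h1relu, ps.P(p + "Ws"), ps.Pv(p + "bs"),
                                 bc.ss, bc.cs, keep_cache)
                  : A;
    bc.conv1_out = conv_forward(bc.h1relu, ps.P(p + "W1"), ps.Pv(p + "b1"),
                                s1, bc.c1, keep_cache);
    bc.bn2_pre = bn_forward(bc.conv1_out, ps.Pv(p + "bn2_g"),
                            ps.Pv(p + "bn2_b"), run_stats, p + "bn2",
                            training, momentum, bc.bn2);
    bc.h2relu = relu(bc.bn2_pre);
    cube out = conv_forward(bc.h2relu, ps.P(p + "W2"), ps.Pv(p + "b2"),
                            bc.s2, bc.c2, keep_cache);
    A = out + sc;
  }

  ec.final_pre = bn_forward(A, ps.Pv("final_bn_g"), ps.Pv("final_bn_b"),
                            run_stats, "final_bn", training, momentum, ec.bnf);
  ec.final_relu = relu(ec.final_pre);
  ec.T_final = ec.final_relu.n_cols;

  const int F = ec.final_relu.n_rows, N = ec.final_relu.n_slices;
  mat feats(F, N);
  for (int n = 0; n < N; ++n) feats.col(n) = mean(ec.final_relu.slice(n), 1);
  return feats;
}

// backward from a gradient on the final (post-ReLU) feature map
static void extractor_backward_map(const cube& dmap, PStore& ps,
                                   const Rcpp::List& cfg, bool training,
                                   ExtractorCache& ec) {
  cube dA = relu_backward(dmap, ec.final_pre);
  dA = bn_backward(dA, ps.Pv("final_bn_g"), ec.bnf, training, ps,
                   "final_bn_g", "final_bn_b");

  for (int i = static_cast<int>(ec.blocks.size()) - 1; i >= 0; --i) {
    BlockCache& bc = ec.blocks[i];
    std::string p = "b" + std::to_string(i + 1) + "_";
    // dA is the gradient of the block output (conv2 out + shortcut)
    cube dH2relu = conv_backward(bc.h2relu, dA, ps.P(p + "W2"), bc.s2, bc.c2,
                                 ps, p + "W2", p + "b2");
    cube dconv1 = relu_backward(dH2relu, bc.bn2_pre);
    dconv1 = bn_backward(dconv1, ps.Pv(p + "bn2_g"), bc.bn2, training, ps,
                         p + "bn2_g", p + "bn2_b");
    cube dH1relu = conv_backward(bc.h1relu, dconv1, ps.P(p + "W1"), bc.s1,
                                 bc.c1, ps, p + "W1", p + "b1");
    cube dA_in;
    if (bc.proj) {
      dH1relu += conv_backward(bc.h1relu, dA, ps.P(p + "Ws"), bc.ss, bc.cs,
                               ps, p + "Ws", p + "bs");
      dA_in = zeros<cube>(bc.A_in.n_rows, bc.A_in.n_cols, bc.A_in.n_slices);
    } else {
      dA_in = dA; // identity shortcut
    }
    cube dpre1 = relu_backward(dH1relu, bc.bn1_pre);
    dA_in += bn_backward(dpre1, ps.Pv(p + "bn1_g"), bc.bn1, training, ps,
                         p + "bn1_g", p + "bn1_b");
    dA = dA_in;
  }
  conv_backward(ec.X, dA, ps.P("stem_W"), ec.stem_spec, ec.stem_cols, ps,
                "stem_W", "stem_b");
}

// backward from a gradient on the pooled (GAP) feature vectors
static void extractor_backward(const mat& dfeats, PStore& ps,
                               const Rcpp::List& cfg, bool training,
                               ExtractorCache& ec) {
  const int F = dfeats.n_rows, N = dfeats.n_cols, Tf = ec.T_final;
  cube dA(F, Tf, N);
  for (int n = 0; n < N; ++n) {
    dA.slice(n) = repmat(dfeats.col(n) / Tf, 1, Tf);
  }
  extractor_backward_map(dA, ps, cfg, training, ec);
}

// ---------------------------------------------------------------------------
// bidirectional LSTM + two FC layers

struct LSTMDirCache {
  mat i, f, g, o, c, tanhc, h; // H x S each
  mat x;                       // F x S inputs (in processing order)
};

static void lstm_dir_forward(const mat& xs, const mat& W, const mat& U,
                             const vec& b, LSTMDirCache& lc) {
  const int H = U.n_rows / 4, S = xs.n_cols;
  lc.i.set_size(H, S); lc.f.set_size(H, S); lc.g.set_size(H, S);
  lc.o.set_size(H, S); lc.c.set_size(H, S); lc.tanhc.set_size(H, S);
  lc.h.set_size(H, S);
  lc.x = xs;
  vec h_prev(H, fill::zeros), c_prev(H, fill::zeros);
  for (int s = 0; s < S; ++s) {
    vec z = W * xs.col(s) + U * h_prev + b;
    vec zi = z.subvec(0, H - 1), zf = z.subvec(H, 2 * H - 1),
        zg = z.subvec(2 * H, 3 * H - 1), zo = z.subvec(3 * H, 4 * H - 1);
    vec ig = 1.0 / (1.0 + exp(-zi));
    vec fg = 1.0 / (1.0 + exp(-zf));
    vec gg = tanh(zg);
    vec og = 1.0 / (1.0 + exp(-zo));
    vec cc = fg % c_prev + ig % gg;
    vec tc = tanh(cc);
    lc.i.col(s) = ig; lc.f.col(s) = fg; lc.g.col(s) = gg; lc.o.col(s) = og;
    lc.c.col(s) = cc; lc.tanhc.col(s) = tc;
    lc.h.col(s) = og % tc;
    h_prev = lc.h.col(s);
    c_prev = cc;
  }
}

// dh_ext: H x S external gradient on hidden states (processing order);
// returns dx (F x S); accumulates parameter grads.
static mat lstm_dir_backward(const LSTMDirCache& lc, const mat& W,
                             const mat& U, const mat& dh_ext, PStore& ps,
                             const std::string& prefix) {
  const int H = lc.h.n_rows, S = lc.h.n_cols, F = lc.x.n_rows;
  mat dW(4 * H, F, fill::zeros), dU(4 * H, H, fill::zeros);
  vec db(4 * H, fill::zeros);
  mat dx(F, S, fill::zeros);
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (int s = S - 1; s >= 0; --s) {
    vec dh = dh_ext.col(s) + dh_next;
    vec do_ = dh % lc.tanhc.col(s);
    vec dc = dh % lc.o.col(s) % (1.0 - square(lc.tanhc.col(s))) + dc_next;
    vec c_prev = (s > 0) ? vec(lc.c.col(s - 1)) : vec(H, fill::zeros);
    vec h_prev = (s > 0) ? vec(lc.h.col(s - 1)) : vec(H, fill::zeros);
    vec di = dc % lc.g.col(s);
    vec df = dc % c_prev;
    vec dg = dc % lc.i.col(s);
    vec dzi = di % lc.i.col(s) % (1.0 - lc.i.col(s));
    vec dzf = df % lc.f.col(s) % (1.0 - lc.f.col(s));
    vec dzg = dg % (1.0 - square(lc.g.col(s)));
    vec dzo = do_ % lc.o.col(s) % (1.0 - lc.o.col(s));
    vec dz = join_vert(join_vert(dzi, dzf), join_vert(dzg, dzo));
    dW += dz * lc.x.col(s).t();
    dU += dz * h_prev.t();
    db += dz;
    dx.col(s) += W.t() * dz;
    dh_next = U.t() * dz;
    dc_next = dc % lc.f.col(s);
  }
  ps.acc(prefix + "W", dW);
  ps.acc(prefix + "U", dU);
  ps.acc(prefix + "b", db);
  return dx;
}

// ---------------------------------------------------------------------------
// staging loss (weighted cross-entropy over labelled epochs)

// [[Rcpp::export]]
Rcpp::List cpp_sleepnet_pass(const arma::cube& X, const arma::ivec& y,
                             Rcpp::List params, Rcpp::List cfg,
                             Rcpp::List run_stats, const arma::vec& class_weights,
                             int B, int S, bool training, bool want_grad,
                             double dropout = 0.0) {
  if (static_cast<int>(X.n_slices) != B * S)
    Rcpp::stop("X slices != B * S");
  PStore ps;
  ps.params = params;
  ps.want_grad = want_grad;
  const double momentum = 0.9;
  Rcpp::List rs = Rcpp::clone(run_stats);

  ExtractorCache ec;
  mat feats = extractor_forward(X, ps, cfg, rs, training, momentum, ec,
                                true);
  const int F = feats.n_rows;

  mat Wf = ps.P("lstm_fwd_W"), Uf = ps.P("lstm_fwd_U");
  vec bf = ps.Pv("lstm_fwd_b");
  mat Wb = ps.P("lstm_bwd_W"), Ub = ps.P("lstm_bwd_U");
  vec bb = ps.Pv("lstm_bwd_b");
  const int H = Uf.n_rows / 4;
  mat W1 = ps.P("fc1_W"), W2 = ps.P("fc2_W");
  vec b1 = ps.Pv("fc1_b"), b2 = ps.Pv("fc2_b");
  const int ncls = W2.n_rows;

  std::vector<LSTMDirCache> fwd(B), bwd(B);
  mat Useq(2 * H, B * S);
  for (int b = 0; b < B; ++b) {
    mat xs = feats.cols(b * S, b * S + S - 1);
    lstm_dir_forward(xs, Wf, Uf, bf, fwd[b]);
    lstm_dir_forward(fliplr(xs), Wb, Ub, bb, bwd[b]);
    mat hb = fliplr(bwd[b].h);
    for (int s = 0; s < S; ++s) {
      Useq.col(b * S + s) =
          join_vert(fwd[b].h.col(s), hb.col(s));
    }
  }

  // dropout mask on the LSTM output (training only)
  mat drop_mask;
  if (training && dropout > 0.0) {
    drop_mask.set_size(Useq.n_rows, Useq.n_cols);
    for (uword i = 0; i < drop_mask.n_elem; ++i) {
      drop_mask(i) = (R::unif_rand() > dropout) ? 1.0 / (1.0 - dropout) : 0.0;
    }
    Useq %= drop_mask;
  }

  mat pre1 = W1 * Useq;
  pre1.each_col() += b1;
  mat R1 = pre1;
  R1.transform([](double v) { return v > 0 ? v : 0.0; });
  mat logits = W2 * R1;
  logits.each_col() += b2;

  // softmax + weighted CE
  const int N = B * S;
  mat probs(ncls, N);
  double loss = 0.0, wsum = 0.0;
  for (int n = 0; n < N; ++n) {
    vec l = logits.col(n);
    l -= l.max();
    vec e = exp(l);
    probs.col(n) = e / accu(e);
    if (y(n) >= 0) {
      double w = class_weights(y(n));
      loss += -w * std::log(std::max(probs(y(n), n), 1e-12));
      wsum += w;
    }
  }
  if (wsum > 0) loss /= wsum;

  Rcpp::List out;
  out["loss"] = loss;
  out["probs"] = probs;
  out["run_stats"] = rs;
  if (!want_grad) return out;
  if (wsum <= 0) Rcpp::stop("no labelled epochs in batch");

  mat dlogits(ncls, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    if (y(n) < 0) continue;
    vec d = probs.col(n);
    d(y(n)) -= 1.0;
    dlogits.col(n) = class_weights(y(n)) / wsum * d;
  }
  ps.acc("fc2_W", dlogits * R1.t());
  ps.acc("fc2_b", sum(dlogits, 1));
  mat dR1 = W2.t() * dlogits;
  for (uword i = 0; i < dR1.n_elem; ++i) if (pre1(i) <= 0) dR1(i) = 0;
  ps.acc("fc1_W", dR1 * Useq.t());
  ps.acc("fc1_b", sum(dR1, 1));
  mat dU = W1.t() * dR1;
  if (training && dropout > 0.0) dU %= drop_mask;

  mat dfeats(F, N, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat dh_f(H, S), dh_b_rev(H, S);
    for (int s = 0; s < S; ++s) {
      vec d = dU.col(b * S + s);
      dh_f.col(s) = d.subvec(0, H - 1);
      dh_b_rev.col(S - 1 - s) = d.subvec(H, 2 * H - 1);
    }
    mat dx_f = lstm_dir_backward(fwd[b], Wf, Uf, dh_f, ps, "lstm_fwd_");
    mat dx_b = lstm_dir_backward(bwd[b], Wb, Ub, dh_b_rev, ps, "lstm_bwd_");
    dx_b = fliplr(dx_b);
    for (int s = 0; s < S; ++s) {
      dfeats.col(b * S + s) = dx_f.col(s) + dx_b.col(s);
    }
  }

  extractor_backward(dfeats, ps, cfg, training, ec);
  out["grads"] = ps.grad_list();
  return out;
}

// ---------------------------------------------------------------------------
// self-supervision pass: extractor + one logistic head per task

// [[Rcpp::export]]
Rcpp::List cpp_ssl_pass(const arma::cube& X, const arma::mat& task_labels,
                        Rcpp::List params, Rcpp::List cfg,
                        Rcpp::List run_stats, bool training, bool want_grad) {
  PStore ps;
  ps.params = params;
  ps.want_grad = want_grad;
  const double momentum = 0.9;
  Rcpp::List rs = Rcpp::clone(run_stats);
  const int N = X.n_slices;
  if (static_cast<int>(task_labels.n_cols) != N)
    Rcpp::stop("task_labels must have one column per window");

  ExtractorCache ec;
  extractor_forward(X, ps, cfg, rs, training, momentum, ec, true);
  // the discrimination heads read the final feature map before pooling by
  // default: the transformations act on the time axis, which pooling would
  // erase; a pooled head is available via cfg$ssl_head = "gap"
  const bool gap_head = cfg.containsElementNamed("ssl_head") &&
      Rcpp::as<std::string>(cfg["ssl_head"]) == "gap";
  const int F = ec.final_relu.n_rows, Tf = ec.T_final;
  mat feats;
  if (gap_head) {
    feats.set_size(F, N);
    for (int n = 0; n < N; ++n) feats.col(n) = mean(ec.final_relu.slice(n), 1);
  } else {
    feats.set_size(F * Tf, N);
    for (int n = 0; n < N; ++n) feats.col(n) = vectorise(ec.final_relu.slice(n));
  }
  mat Wh = ps.P("ssl_W"); // n_tasks x (F * Tf)
  vec bh = ps.Pv("ssl_b");
  const int K = Wh.n_rows;

  mat z = Wh * feats;
  z.each_col() += bh;
  mat p = 1.0 / (1.0 + exp(-z));
  double loss = 0.0;
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < K; ++k) {
      double pk = std::min(std::max(p(k, n), 1e-12), 1.0 - 1e-12);
      loss += task_labels(k, n) > 0.5 ? -std::log(pk) : -std::log(1.0 - pk);
    }
  }
  loss /= (N * K);

  Rcpp::List out;
  out["loss"] = loss;
  out["probs"] = p;
  out["run_stats"] = rs;
  if (!want_grad) return out;

  mat dz = (p - task_labels) / (static_cast<double>(N) * K);
  ps.acc("ssl_W", dz * feats.t());
  ps.acc("ssl_b", sum(dz, 1));
  mat dflat = Wh.t() * dz;
  if (gap_head) {
    extractor_backward(dflat, ps, cfg, training, ec);
  } else {
    cube dmap(F, Tf, N);
    for (int n = 0; n < N; ++n) {
      dmap.slice(n) = reshape(dflat.col(n), F, Tf);
    }
    extractor_backward_map(dmap, ps, cfg, training, ec);
  }
  out["grads"] = ps.grad_list();
  return out;
}
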
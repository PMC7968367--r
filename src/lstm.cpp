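// Stacked-LSTM probabilistic forecaster: forward pass, backpropagation
// through time, Adam, and early stopping. Single precision, single thread,
// explicit mt19937_64 RNG so identical seed + data reproduce training
// bit-for-bit on a given platform.
//
// Architecture: input (L x C) -> LSTM(H, full sequence) -> dropout ->
// LSTM(H, last vector) -> dense(D1, relu) -> dense(D2, relu) -> head.
// Heads: "gaussian" emits (mean, log-variance); "exponential" emits a single
// exp-activated mean with one global learned log-variance parameter.
// Loss: Gaussian negative log-likelihood, mean over samples.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const float LOGVAR_MIN = -15.0f, LOGVAR_MAX = 15.0f;
static const double LOG2PI = 1.8378770664093453;

struct Config {
  int layers, H, D1, D2, L, C;
  int head; // 0 = gaussian two-param, 1 = single exponential
  float dropout, lr, clip;
  int batch, max_epochs, patience;
};

static Config read_config(const List& cfg) {
  Config c;
  c.layers = Rcpp::as<int>(cfg["n_recurrent_layers"]);
  c.H = Rcpp::as<int>(cfg["hidden_units"]);
  Rcpp::IntegerVector ds = cfg["dense_sizes"];
  c.D1 = ds[0]; c.D2 = ds[1];
  c.L = Rcpp::as<int>(cfg["L"]);
  c.C = Rcpp::as<int>(cfg["n_channels"]);
  std::string head = Rcpp::as<std::string>(cfg["output_head"]);
  c.head = (head == "single_exponential") ? 1 : 0;
  c.dropout = Rcpp::as<double>(cfg["dropout_rate"]);
  c.lr = Rcpp::as<double>(cfg["learning_rate"]);
  c.clip = Rcpp::as<double>(cfg["grad_clip"]);
  c.batch = Rcpp::as<int>(cfg["batch_size"]);
  c.max_epochs = Rcpp::as<int>(cfg["max_epochs"]);
  c.patience = Rcpp::as<int>(cfg["patience"]);
  return c;
}

// parameter vector layout
struct Params {
  std::vector<fmat> W;           // ordered parameter matrices
  std::vector<std::string> names;
  void add(const std::string& nm, fmat m) { names.push_back(nm); W.push_back(std::move(m)); }
};

static std::vector<std::string> param_names(const Config& c) {
  std::vector<std::string> nm = {"W1", "b1"};
  if (c.layers == 2) { nm.push_back("W2"); nm.push_back("b2"); }
  nm.insert(nm.end(), {"Wd1", "bd1", "Wd2", "bd2", "Wo", "bo"});
  if (c.head == 1) nm.push_back("logvar");
  return nm;
}

static Params params_from_list(const List& plist, const Config& c) {
  Params p;
  for (const std::string& nm : param_names(c)) {
    mat m = Rcpp::as<mat>(plist[nm]);
    p.add(nm, conv_to<fmat>::from(m));
  }
  return p;
}

static List params_to_list(const Params& p) {
  List out;
  for (size_t i = 0; i < p.W.size(); ++i)
    out[p.names[i]] = conv_to<mat>::from(p.W[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_lstm_init(List cfg, int seed) {
  Config c = read_config(cfg);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  auto glorot = [&](int nin, int nout) {
    float lim = std::sqrt(6.0f / (nin + nout));
    std::uniform_real_distribution<float> U(-lim, lim);
    fmat m(nin, nout);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword i = 0; i < m.n_rows; ++i) m(i, j) = U(rng);
    return m;
  };
  auto lstm_bias = [&](int H) {
    fmat b(1, 4 * H, fill::zeros);
    b.cols(H, 2 * H - 1).fill(1.0f); // forget-gate bias 1 (standard init)
    return b;
  };
  Params p;
  p.add("W1", glorot(c.C + c.H, 4 * c.H));
  p.add("b1", lstm_bias(c.H));
  if (c.layers == 2) {
    p.add("W2", glorot(2 * c.H, 4 * c.H));
    p.add("b2", lstm_bias(c.H));
  }
  p.add("Wd1", glorot(c.H, c.D1));
  p.add("bd1", fmat(1, c.D1, fill::zeros));
  p.add("Wd2", glorot(c.D1, c.D2));
  p.add("bd2", fmat(1, c.D2, fill::zeros));
  int out_dim = (c.head == 0) ? 2 : 1;
  p.add("Wo", glorot(c.D2, out_dim));
  p.add("bo", fmat(1, out_dim, fill::zeros));
  if (c.head == 1) p.add("logvar", fmat(1, 1, fill::zeros));
  return params_to_list(p);
}

// per-timestep caches of one LSTM layer forward pass
struct LstmCache {
  std::vector<fmat> concat, gi, gf, gg, go, cst, tanhc;
  std::vector<fmat> h; // h[0] is the initial zero state, h[t+1] output at t
};

static void lstm_forward_layer(const std::vector<fmat>& X, const fmat& W,
                               const fmat& b, int H, LstmCache* cache,
                               std::vector<fmat>* hs_out) {
  const int L = X.size();
  const uword B = X[0].n_rows;
  fmat h(B, H, fill::zeros), cstate(B, H, fill::zeros);
  if (cache) cache->h.push_back(h);
  for (int t = 0; t < L; ++t) {
    fmat cc = join_rows(X[t], h);
    fmat Z = cc * W;
    Z.each_row() += b;
    fmat gi = 1.0f / (1.0f + exp(-Z.cols(0, H - 1)));
    fmat gf = 1.0f / (1.0f + exp(-Z.cols(H, 2 * H - 1)));
    fmat gg = tanh(Z.cols(2 * H, 3 * H - 1));
    fmat go = 1.0f / (1.0f + exp(-Z.cols(3 * H, 4 * H - 1)));
    fmat c_prev = cstate;
    cstate = gf % cstate + gi % gg;
    fmat th = tanh(cstate);
    h = go % th;
    if (hs_out) hs_out->push_back(h);
    if (cache) {
      cache->concat.push_back(std::move(cc));
      cache->gi.push_back(std::move(gi));
      cache->gf.push_back(std::move(gf));
      cache->gg.push_back(std::move(gg));
      cache->go.push_back(std::move(go));
      cache->cst.push_back(cstate);
      cache->tanhc.push_back(std::move(th));
      cache->h.push_back(h);
    }
  }
  if (!hs_out && !cache) Rcpp::stop("internal: no output requested");
}

// backward through one LSTM layer; dh_ext[t] external gradient on h_t (may
// be empty mats). Returns gradient w.r.t. layer inputs; accumulates dW, db.
static std::vector<fmat> lstm_backward_layer(const std::vector<fmat>& X,
                                             const fmat& W, const LstmCache& cache,
                                             const std::vector<fmat>& dh_ext,
                                             int H, fmat& dW, fmat& db) {
  const int L = X.size();
  const uword B = X[0].n_rows;
  const int In = X[0].n_cols;
  std::vector<fmat> dX(L);
  fmat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    fmat dh = dh_next;
    if (dh_ext[t].n_elem) dh += dh_ext[t];
    const fmat& th = cache.tanhc[t];
    fmat dgo = dh % th;
    fmat dc = dc_next + dh % cache.go[t] % (1.0f - th % th);
    fmat c_prev = (t == 0) ? fmat(B, H, fill::zeros) : cache.cst[t - 1];
    fmat dgi = dc % cache.gg[t];
    fmat dgf = dc % c_prev;
    fmat dgg = dc % cache.gi[t];
    fmat dZ(B, 4 * H);
    dZ.cols(0, H - 1) = dgi % cache.gi[t] % (1.0f - cache.gi[t]);
    dZ.cols(H, 2 * H - 1) = dgf % cache.gf[t] % (1.0f - cache.gf[t]);
    dZ.cols(2 * H, 3 * H - 1) = dgg % (1.0f - cache.gg[t] % cache.gg[t]);
    dZ.cols(3 * H, 4 * H - 1) = dgo % cache.go[t] % (1.0f - cache.go[t]);
    dW += cache.concat[t].t() * dZ;
    db += sum(dZ, 0);
    fmat dcc = dZ * W.t();
    dX[t] = dcc.cols(0, In - 1);
    dh_next = dcc.cols(In, In + H - 1);
    dc_next = dc % cache.gf[t];
  }
  return dX;
}

struct ForwardOut {
  fmat mu, logvar;        // B x 1 each (clamped logvar)
  // caches for backward
  LstmCache c1, c2;
  std::vector<fmat> drop_mask; // per timestep, empty if no dropout
  std::vector<fmat> h1;        // layer-1 outputs (post dropout when training)
  fmat hT, A1, A2, pre;        // dense-path caches
};

static void model_forward(const std::vector<fmat>& X, const Params& p,
                          const Config& c, bool training,
                          std::mt19937_64* rng, ForwardOut& f) {
  const int L = X.size();
  const uword B = X[0].n_rows;
  int pi = 0;
  const fmat& W1 = p.W[pi++]; const fmat& b1 = p.W[pi++];
  const fmat *W2 = nullptr, *b2 = nullptr;
  if (c.layers == 2) { W2 = &p.W[pi++]; b2 = &p.W[pi++]; }
  const fmat& Wd1 = p.W[pi++]; const fmat& bd1 = p.W[pi++];
  const fmat& Wd2 = p.W[pi++]; const fmat& bd2 = p.W[pi++];
  const fmat& Wo = p.W[pi++]; const fmat& bo = p.W[pi++];

  f.h1.clear(); f.drop_mask.assign(L, fmat());
  lstm_forward_layer(X, W1, b1, c.H, training ? &f.c1 : nullptr,
                     training ? nullptr : &f.h1);
  if (training) {
    f.h1.assign(f.c1.h.begin() + 1, f.c1.h.end());
  }
  // dropout after the first LSTM layer (inverted scaling)
  if (training && c.dropout > 0.0f && rng) {
    std::uniform_real_distribution<float> U(0.0f, 1.0f);
    float keep = 1.0f - c.dropout;
    for (int t = 0; t < L; ++t) {
      fmat m(B, f.h1[t].n_cols);
      for (uword j = 0; j < m.n_cols; ++j)
        for (uword i = 0; i < m.n_rows; ++i)
          m(i, j) = (U(*rng) < keep) ? 1.0f / keep : 0.0f;
      f.drop_mask[t] = m;
      f.h1[t] = f.h1[t] % m;
    }
  }
  if (c.layers == 2) {
    std::vector<fmat> h2;
    lstm_forward_layer(f.h1, *W2, *b2, c.H, training ? &f.c2 : nullptr,
                       training ? nullptr : &h2);
    f.hT = training ? f.c2.h.back() : h2.back();
  } else {
    f.hT = f.h1.back();
  }
  f.A1 = f.hT * Wd1; f.A1.each_row() += bd1; f.A1 = clamp(f.A1, 0.0f, fdatum::inf);
  f.A2 = f.A1 * Wd2; f.A2.each_row() += bd2; f.A2 = clamp(f.A2, 0.0f, fdatum::inf);
  f.pre = f.A2 * Wo; f.pre.each_row() += bo;
  if (c.head == 0) {
    f.mu = f.pre.col(0);
    f.logvar = clamp(f.pre.col(1), LOGVAR_MIN, LOGVAR_MAX);
  } else {
    f.mu = exp(clamp(f.pre.col(0), -30.0f, 30.0f));
    float lv = p.W.back()(0, 0);
    f.logvar = fmat(B, 1);
    f.logvar.fill(std::min(std::max(lv, LOGVAR_MIN), LOGVAR_MAX));
  }
}

static double nll_of(const fmat& mu, const fmat& logvar, const fvec& y) {
  double s = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    double lv = logvar(i, 0), m = mu(i, 0);
    double r = (double)y(i) - m;
    s += 0.5 * (LOG2PI + lv + r * r / std::exp(lv));
  }
  return s / y.n_elem;
}

// backward from the NLL through the whole model; returns gradients in the
// same layout as the parameter vector.
static std::vector<fmat> model_backward(const std::vector<fmat>& X,
                                        const Params& p, const Config& c,
                                        const fvec& y, ForwardOut& f) {
  const uword B = X[0].n_rows;
  const int L = X.size();
  std::vector<fmat> g(p.W.size());
  for (size_t i = 0; i < p.W.size(); ++i)
    g[i] = fmat(p.W[i].n_rows, p.W[i].n_cols, fill::zeros);
  int pi = 0;
  int iW1 = pi++; int ib1 = pi++;
  int iW2 = -1, ib2 = -1;
  if (c.layers == 2) { iW2 = pi++; ib2 = pi++; }
  int iWd1 = pi++, ibd1 = pi++, iWd2 = pi++, ibd2 = pi++, iWo = pi++, ibo = pi++;
  int ilv = (c.head == 1) ? pi : -1;

  fvec invvar(B), resid(B);
  for (uword i = 0; i < B; ++i) {
    invvar(i) = std::exp(-f.logvar(i, 0));
    resid(i) = f.mu(i, 0) - y(i);
  }
  fmat dpre(B, f.pre.n_cols, fill::zeros);
  float scale = 1.0f / B;
  if (c.head == 0) {
    for (uword i = 0; i < B; ++i) {
      dpre(i, 0) = resid(i) * invvar(i) * scale;
      float lv = f.logvar(i, 0);
      float dlv = 0.5f * (1.0f - resid(i) * resid(i) * invvar(i)) * scale;
      if (lv <= LOGVAR_MIN || lv >= LOGVAR_MAX) dlv = 0.0f;
      dpre(i, 1) = dlv;
    }
  } else {
    float dlv_sum = 0.0f;
    for (uword i = 0; i < B; ++i) {
      dpre(i, 0) = resid(i) * invvar(i) * scale * f.mu(i, 0); // d/dpre of exp
      dlv_sum += 0.5f * (1.0f - resid(i) * resid(i) * invvar(i)) * scale;
    }
    g[ilv](0, 0) = dlv_sum;
  }
  g[iWo] = f.A2.t() * dpre;
  g[ibo] = sum(dpre, 0);
  fmat dA2 = dpre * p.W[iWo].t();
  dA2 = dA2 % conv_to<fmat>::from(f.A2 > 0.0f);
  g[iWd2] = f.A1.t() * dA2;
  g[ibd2] = sum(dA2, 0);
  fmat dA1 = dA2 * p.W[iWd2].t();
  dA1 = dA1 % conv_to<fmat>::from(f.A1 > 0.0f);
  g[iWd1] = f.hT.t() * dA1;
  g[ibd1] = sum(dA1, 0);
  fmat dhT = dA1 * p.W[iWd1].t();

  std::vector<fmat> dh_ext(L);
  if (c.layers == 2) {
    dh_ext[L - 1] = dhT;
    std::vector<fmat> dh1 = lstm_backward_layer(f.h1, p.W[iW2], f.c2, dh_ext,
                                                c.H, g[iW2], g[ib2]);
    for (int t = 0; t < L; ++t) {
      if (f.drop_mask[t].n_elem) dh1[t] = dh1[t] % f.drop_mask[t];
      dh_ext[t] = dh1[t];
    }
  } else {
    for (int t = 0; t < L - 1; ++t) dh_ext[t] = fmat();
    fmat d = dhT;
    if (f.drop_mask[L - 1].n_elem) d = d % f.drop_mask[L - 1];
    dh_ext[L - 1] = d;
  }
  lstm_backward_layer(X, p.W[iW1], f.c1, dh_ext, c.H, g[iW1], g[ib1]);
  return g;
}

// convert an n x L x C cube into per-timestep (n x C) float matrices
static std::vector<fmat> slice_time(const cube& X) {
  std::vector<fmat> out(X.n_cols);
  for (uword t = 0; t < X.n_cols; ++t) {
    mat m(X.n_rows, X.n_slices);
    for (uword ch = 0; ch < X.n_slices; ++ch) m.col(ch) = X.slice(ch).col(t);
    out[t] = conv_to<fmat>::from(m);
  }
  return out;
}

static std::vector<fmat> take_rows(const std::vector<fmat>& Xt, const uvec& idx) {
  std::vector<fmat> out(Xt.size());
  for (size_t t = 0; t < Xt.size(); ++t) out[t] = Xt[t].rows(idx);
  return out;
}

static double eval_nll(const std::vector<fmat>& Xt, const fvec& y,
                       const Params& p, const Config& c) {
  const uword n = y.n_elem;
  double total = 0.0;
  for (uword start = 0; start < n; start += c.batch) {
    uword end = std::min<uword>(start + c.batch, n) - 1;
    uvec idx = regspace<uvec>(start, end);
    ForwardOut f;
    model_forward(take_rows(Xt, idx), p, c, false, nullptr, f);
    total += nll_of(f.mu, f.logvar, y.rows(idx)) * idx.n_elem;
  }
  return total / n;
}

// [[Rcpp::export]]
List cpp_lstm_train(const arma::cube& Xtr, const arma::vec& ytr,
                    const arma::cube& Xval, const arma::vec& yval,
                    List params, List cfg, int seed) {
  Config c = read_config(cfg);
  Params p = params_from_list(params, c);
  std::vector<fmat> Xt = slice_time(Xtr), Xv = slice_time(Xval);
  fvec yt = conv_to<fvec>::from(ytr), yv = conv_to<fvec>::from(yval);
  const uword n = yt.n_elem;
  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9e3779b9ULL);

  // Adam state
  std::vector<fmat> m(p.W.size()), v(p.W.size());
  for (size_t i = 0; i < p.W.size(); ++i) {
    m[i] = fmat(p.W[i].n_rows, p.W[i].n_cols, fill::zeros);
    v[i] = m[i];
  }
  const float b1 = 0.9f, b2c = 0.999f, eps = 1e-7f;
  long step = 0;

  Params best = p;
  double best_val = datum::inf;
  int best_epoch = 0, since_best = 0, stopped = c.max_epochs;
  std::vector<double> log_train, log_val;

  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 1; epoch <= c.max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    uword seen = 0;
    for (uword start = 0; start < n; start += c.batch) {
      uword len = std::min<uword>(c.batch, n - start);
      uvec idx(len);
      for (uword i = 0; i < len; ++i) idx(i) = order[start + i];
      std::vector<fmat> Xb = take_rows(Xt, idx);
      fvec yb = yt.rows(idx);
      ForwardOut f;
      model_forward(Xb, p, c, true, &rng, f);
      double loss = nll_of(f.mu, f.logvar, yb);
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d", epoch);
      epoch_loss += loss * len;
      seen += len;
      std::vector<fmat> g = model_backward(Xb, p, c, yb, f);
      // global-norm gradient clipping
      double norm2 = 0.0;
      for (auto& gi : g) norm2 += accu(conv_to<mat>::from(gi % gi));
      double gn = std::sqrt(norm2);
      float gscale = (gn > c.clip) ? (float)(c.clip / gn) : 1.0f;
      ++step;
      float corr1 = 1.0f - std::pow(b1, (float)step);
      float corr2 = 1.0f - std::pow(b2c, (float)step);
      for (size_t i = 0; i < p.W.size(); ++i) {
        fmat gi = g[i] * gscale;
        m[i] = b1 * m[i] + (1.0f - b1) * gi;
        v[i] = b2c * v[i] + (1.0f - b2c) * (gi % gi);
        p.W[i] -= c.lr * (m[i] / corr1) / (sqrt(v[i] / corr2) + eps);
      }
    }
    double val = eval_nll(Xv, yv, p, c);
    log_train.push_back(epoch_loss / seen);
    log_val.push_back(val);
    if (val < best_val) {
      best_val = val;
      best = p;
      best_epoch = epoch;
      since_best = 0;
    } else if (++since_best >= c.patience) {
      stopped = epoch;
      break;
    }
    stopped = epoch;
  }

  mat logm(log_train.size(), 2);
  for (size_t i = 0; i < log_train.size(); ++i) {
    logm(i, 0) = log_train[i];
    logm(i, 1) = log_val[i];
  }
  return List::create(
    Named("params") = params_to_list(best),
    Named("log") = logm,
    Named("best_epoch") = best_epoch,
    Named("best_val_nll") = best_val,
    Named("stopped_epoch") = stopped);
}

// [[Rcpp::export]]
arma::mat cpp_lstm_forward(const arma::cube& X, List params, List cfg) {
  Config c = read_config(cfg);
  Params p = params_from_list(params, c);
  std::vector<fmat> Xt = slice_time(X);
  const uword n = X.n_rows;
  mat out(n, 2);
  for (uword start = 0; start < n; start += c.batch) {
    uword end = std::min<uword>(start + c.batch, n) - 1;
    uvec idx = regspace<uvec>(start, end);
    ForwardOut f;
    model_forward(take_rows(Xt, idx), p, c, false, nullptr, f);
    for (uword i = 0; i < idx.n_elem; ++i) {
      out(start + i, 0) = f.mu(i, 0);
      out(start + i, 1) = f.logvar(i, 0);
    }
  }
  return out;
}
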
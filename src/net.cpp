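// Convolutional triplet-embedding network: shared conv trunk (conv ->
// batch-norm -> leaky-ReLU blocks with striding), parallel attention-pooling
// and global max-pooling branches, concatenation and a dense projection to a
// d-dimensional (optionally unit-norm) embedding.
//
// Forward and backward are hand-written. Feature maps for the whole batch
// live in one (channels x positions*images) single-precision matrix per
// layer, so each conv is a single large GEMM; position index within an
// image is pos = y*W + x.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef arma::fmat fm;
typedef arma::fvec fv;

struct LayerSpec {
  int c_in, c_out, k, s, p;
  int H_in, W_in, H_out, W_out;
  int P_in, P_out;
};

static std::vector<LayerSpec> build_specs(const List& config) {
  IntegerVector channels = config["channels"];
  const int k = as<int>(config["kernel"]);
  const int s = as<int>(config["stride"]);
  const int p = (k - 1) / 2;
  IntegerVector input_shape = config["input_shape"];
  int H = input_shape[0], W = input_shape[1], c_in = 1;
  std::vector<LayerSpec> specs;
  for (int l = 0; l < channels.size(); ++l) {
    LayerSpec L;
    L.c_in = c_in; L.c_out = channels[l]; L.k = k; L.s = s; L.p = p;
    L.H_in = H; L.W_in = W;
    L.H_out = (H + 2 * p - k) / s + 1;
    L.W_out = (W + 2 * p - k) / s + 1;
    L.P_in = H * W;
    L.P_out = L.H_out * L.W_out;
    specs.push_back(L);
    H = L.H_out; W = L.W_out; c_in = L.c_out;
  }
  return specs;
}

// Gather one image's input patch columns into the batch cols matrix.
// A_img: c_in x P_in block of the input activations for this image;
// writes into cols columns [img*P_out, (img+1)*P_out).
static void im2col_img(const fm& acts, int img, const LayerSpec& L,
                       fm& cols) {
  const int base_in = img * L.P_in;
  const int base_out = img * L.P_out;
  for (int i = 0; i < L.H_out; ++i) {
    for (int j = 0; j < L.W_out; ++j) {
      float* dst = cols.colptr(base_out + i * L.W_out + j);
      for (int ki = 0; ki < L.k; ++ki) {
        const int y = i * L.s - L.p + ki;
        for (int kj = 0; kj < L.k; ++kj) {
          const int x = j * L.s - L.p + kj;
          float* d = dst + (ki * L.k + kj);
          if (y < 0 || y >= L.H_in || x < 0 || x >= L.W_in) {
            for (int c = 0; c < L.c_in; ++c) d[c * L.k * L.k] = 0.0f;
          } else {
            const float* src = acts.colptr(base_in + y * L.W_in + x);
            for (int c = 0; c < L.c_in; ++c) d[c * L.k * L.k] = src[c];
          }
        }
      }
    }
  }
}

static void col2im_img(const fm& dcols, int img, const LayerSpec& L,
                       fm& dacts) {
  const int base_in = img * L.P_in;
  const int base_out = img * L.P_out;
  for (int i = 0; i < L.H_out; ++i) {
    for (int j = 0; j < L.W_out; ++j) {
      const float* src = dcols.colptr(base_out + i * L.W_out + j);
      for (int ki = 0; ki < L.k; ++ki) {
        const int y = i * L.s - L.p + ki;
        if (y < 0 || y >= L.H_in) continue;
        for (int kj = 0; kj < L.k; ++kj) {
          const int x = j * L.s - L.p + kj;
          if (x < 0 || x >= L.W_in) continue;
          float* d = dacts.colptr(base_in + y * L.W_in + x);
          const float* s = src + (ki * L.k + kj);
          for (int c = 0; c < L.c_in; ++c) d[c] += s[c * L.k * L.k];
        }
      }
    }
  }
}

// [[Rcpp::export]]
List net_run_cpp(const List& params, const List& config, const arma::cube& X,
                 const IntegerMatrix& triplets, const NumericVector& u,
                 const double delta, const std::string loss_type,
                 const bool train_mode, const List& bn_state,
                 const double bn_momentum) {
  const std::vector<LayerSpec> specs = build_specs(config);
  const int nL = specs.size();
  const int N = X.n_slices;
  const bool use_bn = as<bool>(config["batch_norm"]);
  const bool unit_norm = as<bool>(config["unit_normalise"]);
  const float slope = (float) as<double>(config["slope"]);
  const float bn_eps = 1e-5f;

  List conv_W = params["conv_W"], conv_b = params["conv_b"];
  List bn_gamma = params["bn_gamma"], bn_beta = params["bn_beta"];
  fv att_v = arma::conv_to<fv>::from(as<arma::vec>(params["att_v"]));
  const float att_b = (float) as<double>(params["att_b"]);
  fm dense_W = arma::conv_to<fm>::from(as<arma::mat>(params["dense_W"]));
  fv dense_b = arma::conv_to<fv>::from(as<arma::vec>(params["dense_b"]));
  List run_mean = bn_state["mean"], run_var = bn_state["var"];

  const int d = dense_W.n_rows;
  const int cL = specs[nL - 1].c_out;
  const int P_L = specs[nL - 1].P_out;
  const bool want_grad = triplets.nrow() > 0;

  std::vector<fm> Wl(nL);
  std::vector<fv> bl(nL), gl(nL), bel(nL);
  for (int l = 0; l < nL; ++l) {
    Wl[l] = arma::conv_to<fm>::from(as<arma::mat>(conv_W[l]));
    bl[l] = arma::conv_to<fv>::from(as<arma::vec>(conv_b[l]));
    gl[l] = arma::conv_to<fv>::from(as<arma::vec>(bn_gamma[l]));
    bel[l] = arma::conv_to<fv>::from(as<arma::vec>(bn_beta[l]));
  }

  // ---- forward trunk --------------------------------------------------
  // acts[l]: activations entering layer l (acts[0] = input), one batch
  // matrix (c x P*N); zs[l]: conv output of layer l before BN/activation;
  // cols[l]: im2col patches, kept for the backward pass.
  std::vector<fm> acts(nL + 1), zs(nL), cols(nL);
  std::vector<fv> mu(nL), inv_sd(nL);
  acts[0].set_size(1, specs[0].P_in * N);
  for (int img = 0; img < N; ++img) {
    const arma::mat sl = X.slice(img);
    // pos = y*W + x: row-major flattening of the (H x W) image
    for (int y = 0; y < specs[0].H_in; ++y)
      for (int x = 0; x < specs[0].W_in; ++x)
        acts[0](0, img * specs[0].P_in + y * specs[0].W_in + x) =
          (float) sl(y, x);
  }
  for (int l = 0; l < nL; ++l) {
    const LayerSpec& L = specs[l];
    cols[l].set_size(L.c_in * L.k * L.k, L.P_out * N);
    for (int img = 0; img < N; ++img) im2col_img(acts[l], img, L, cols[l]);
    zs[l] = Wl[l] * cols[l];
    zs[l].each_col() += bl[l];
    fv m(L.c_out), v(L.c_out);
    if (use_bn) {
      if (train_mode) {
        m = arma::mean(zs[l], 1);
        v = arma::var(zs[l], 1, 1); // population variance across columns
        arma::vec rm = as<arma::vec>(run_mean[l]);
        arma::vec rv = as<arma::vec>(run_var[l]);
        run_mean[l] = wrap((1 - bn_momentum) * rm +
                           bn_momentum * arma::conv_to<arma::vec>::from(m));
        run_var[l] = wrap((1 - bn_momentum) * rv +
                          bn_momentum * arma::conv_to<arma::vec>::from(v));
      } else {
        m = arma::conv_to<fv>::from(as<arma::vec>(run_mean[l]));
        v = arma::conv_to<fv>::from(as<arma::vec>(run_var[l]));
      }
    } else {
      m.zeros(L.c_out);
      v.ones(L.c_out);
      v -= bn_eps;
    }
    mu[l] = m;
    inv_sd[l] = 1.0f / arma::sqrt(v + bn_eps);
    fm a = zs[l];
    a.each_col() -= m;
    a.each_col() %= inv_sd[l] % gl[l];
    a.each_col() += bel[l];
    a.transform([slope](float x) { return x > 0 ? x : slope * x; });
    acts[l + 1] = std::move(a);
  }

  // ---- head: attention + max pooling -> dense -> normalise ------------
  fm emb(d, N), pre(d, N);
  fm alphas(P_L, N);
  arma::umat argmaxs(cL, N);
  fm heads(2 * cL, N);
  for (int img = 0; img < N; ++img) {
    const fm A = acts[nL].cols(img * P_L, (img + 1) * P_L - 1);
    arma::frowvec s = att_v.t() * A + att_b;
    s -= s.max();
    arma::frowvec al = arma::exp(s);
    al /= arma::accu(al);
    alphas.col(img) = al.t();
    fv att = A * al.t();
    fv mx(cL);
    for (int c = 0; c < cL; ++c) {
      arma::uword idx;
      mx(c) = A.row(c).max(idx);
      argmaxs(c, img) = idx;
    }
    heads.col(img) = arma::join_cols(att, mx);
    fv zd = dense_W * heads.col(img) + dense_b;
    pre.col(img) = zd;
    if (unit_norm) {
      float nrm = arma::norm(zd);
      if (nrm < 1e-12f) nrm = 1e-12f;
      emb.col(img) = zd / nrm;
    } else {
      emb.col(img) = zd;
    }
  }

  arma::mat emb_out =
    arma::conv_to<arma::mat>::from(emb.t()); // N x d for R
  if (!want_grad) {
    return List::create(_["emb"] = emb_out,
                        _["bn_state"] = List::create(_["mean"] = run_mean,
                                                     _["var"] = run_var));
  }

  // ---- triplet losses and dL/dEmbedding -------------------------------
  const int nT = triplets.nrow();
  fm dE(d, N, arma::fill::zeros);
  arma::vec tl(nT);
  for (int t = 0; t < nT; ++t) {
    const int a = triplets(t, 0), p = triplets(t, 1), n = triplets(t, 2);
    const fv ea = emb.col(a), ep = emb.col(p), en = emb.col(n);
    const double dap2 = arma::accu(arma::square(ea - ep));
    const double dan2 = arma::accu(arma::square(ea - en));
    double loss = 0.0, g_dap2 = 0.0, g_dan2 = 0.0;
    if (loss_type == "mixed") {
      const double ut = u[t];
      const double pu = dan2 - dap2 - delta;
      const double pa = dan2 - dap2;
      const double raw = ut * (1.0 - std::exp(pu)) +
        (1.0 - ut) * (1.0 - std::exp(-std::fabs(pa)));
      if (raw > 0.0) {
        loss = raw;
        const double gu = -std::exp(pu);
        double ga = 0.0;
        if (pa != 0.0)
          ga = std::exp(-std::fabs(pa)) * (pa > 0 ? 1.0 : -1.0);
        g_dan2 = ut * gu + (1.0 - ut) * ga;
        g_dap2 = -g_dan2;
      }
    } else if (loss_type == "hinge_sq") {
      const double raw = dap2 - dan2 + delta;
      if (raw > 0.0) { loss = raw; g_dap2 = 1.0; g_dan2 = -1.0; }
    } else { // "hinge": unsquared Euclidean distances
      const double dap = std::sqrt(dap2), dan = std::sqrt(dan2);
      const double raw = dap - dan + delta;
      if (raw > 0.0) {
        loss = raw;
        g_dap2 = dap > 1e-12 ? 0.5 / dap : 0.0;
        g_dan2 = dan > 1e-12 ? -0.5 / dan : 0.0;
      }
    }
    tl(t) = loss;
    if (g_dap2 != 0.0 || g_dan2 != 0.0) {
      const fv d_ap = 2.0f * (ea - ep);
      const fv d_an = 2.0f * (ea - en);
      dE.col(a) += ((float) (g_dap2 / nT)) * d_ap +
        ((float) (g_dan2 / nT)) * d_an;
      dE.col(p) += ((float) (-g_dap2 / nT)) * d_ap;
      dE.col(n) += ((float) (-g_dan2 / nT)) * d_an;
    }
  }
  const double total_loss = arma::mean(tl);

  // ---- backward head ---------------------------------------------------
  fm g_dense_W(arma::size(dense_W), arma::fill::zeros);
  fv g_dense_b(d, arma::fill::zeros);
  fv g_att_v(cL, arma::fill::zeros);
  float g_att_b = 0.0f;
  fm dact(cL, P_L * N, arma::fill::zeros);
  for (int img = 0; img < N; ++img) {
    const fv de = dE.col(img);
    fv dzd;
    if (unit_norm) {
      const fv zd = pre.col(img);
      float nrm = arma::norm(zd);
      if (nrm < 1e-12f) nrm = 1e-12f;
      const fv e = zd / nrm;
      dzd = (de - e * arma::dot(e, de)) / nrm;
    } else {
      dzd = de;
    }
    g_dense_W += dzd * heads.col(img).t();
    g_dense_b += dzd;
    const fv dh = dense_W.t() * dzd;
    const fv datt = dh.subvec(0, cL - 1);
    const fv dmax = dh.subvec(cL, 2 * cL - 1);
    const fm A = acts[nL].cols(img * P_L, (img + 1) * P_L - 1);
    fm dA(cL, P_L, arma::fill::zeros);
    for (int c = 0; c < cL; ++c)
      dA(c, argmaxs(c, img)) += dmax(c);
    const fv al = alphas.col(img);
    const fv gpos = (datt.t() * A).t();
    const float dot_ag = arma::dot(al, gpos);
    const fv ds = al % (gpos - dot_ag);
    g_att_v += A * ds;
    g_att_b += arma::accu(ds);
    dA += datt * al.t();
    dA += att_v * ds.t();
    dact.cols(img * P_L, (img + 1) * P_L - 1) = dA;
  }

  // ---- backward trunk --------------------------------------------------
  List g_conv_W(nL), g_conv_b(nL), g_bn_gamma(nL), g_bn_beta(nL);
  for (int l = nL - 1; l >= 0; --l) {
    const LayerSpec& L = specs[l];
    // through leaky ReLU (output sign recovers the mask)
    fm dy = std::move(dact);
    const fm& a_out = acts[l + 1];
    for (arma::uword idx = 0; idx < dy.n_elem; ++idx)
      if (a_out(idx) <= 0) dy(idx) *= slope;
    fm xhat = zs[l];
    xhat.each_col() -= mu[l];
    xhat.each_col() %= inv_sd[l];
    const fv dgamma = arma::sum(dy % xhat, 1);
    const fv dbeta = arma::sum(dy, 1);
    fm dz;
    if (use_bn && train_mode) {
      const float cnt = (float) dy.n_cols;
      dz = dy;
      dz.each_col() -= dbeta / cnt;
      xhat.each_col() %= dgamma / cnt;
      dz -= xhat;
      dz.each_col() %= gl[l] % inv_sd[l];
    } else {
      dz = dy;
      dz.each_col() %= gl[l] % inv_sd[l];
    }
    g_conv_W[l] = wrap(arma::conv_to<arma::mat>::from(dz * cols[l].t()));
    g_conv_b[l] = wrap(arma::conv_to<arma::vec>::from(arma::sum(dz, 1)));
    g_bn_gamma[l] = wrap(arma::conv_to<arma::vec>::from(dgamma));
    g_bn_beta[l] = wrap(arma::conv_to<arma::vec>::from(dbeta));
    if (l > 0) {
      const fm dcols = Wl[l].t() * dz;
      dact.zeros(L.c_in, L.P_in * N);
      for (int img = 0; img < N; ++img)
        col2im_img(dcols, img, L, dact);
    }
  }

  List grads = List::create(
      _["conv_W"] = g_conv_W, _["conv_b"] = g_conv_b,
      _["bn_gamma"] = g_bn_gamma, _["bn_beta"] = g_bn_beta,
      _["att_v"] = wrap(arma::conv_to<arma::vec>::from(g_att_v)),
      _["att_b"] = (double) g_att_b,
      _["dense_W"] = wrap(arma::conv_to<arma::mat>::from(g_dense_W)),
      _["dense_b"] = wrap(arma::conv_to<arma::vec>::from(g_dense_b)));
  return List::create(
      _["emb"] = emb_out, _["loss"] = total_loss, _["triplet_losses"] = tl,
      _["grads"] = grads,
      _["bn_state"] = List::create(_["mean"] = run_mean,
                                   _["var"] = run_var));
}
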
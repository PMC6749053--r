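// Six-block convolutional network (conv -> batch norm -> ReLU -> 2x2 average
// pool, then fully connected + softmax) trained with plain SGD.
//
// The implementation is written for a single CPU core: convolutions are
// im2col + single-precision GEMM, every large buffer lives in a persistent
// workspace reused across mini-batches and epochs, and the batch-norm /
// ReLU / pooling stages are fused single-pass kernels (memory bandwidth is
// the limiting factor at these layer shapes).
//
// Layout conventions
//   * An activation batch is an (H*W*B) x C column-major array: image b
//     occupies rows [b*H*W, (b+1)*H*W), spatial order column-major within
//     the image (row index fastest), matching R matrix storage.
//   * Conv weights are (k*k*Cin) x Cout with patch index kr + kc*k + c*k*k,
//     the column-major flattening of an R array dim c(k, k, Cin, Cout).
//   * The feature vector entering the fully connected head is channel-major:
//     feature j = c*(H*W) + s for channel c and spatial index s; for the
//     224-input architecture this is the length-288 LCA vector.

#include <Rcpp.h>
#include <cstring>
#include <cmath>
#include <vector>

extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*);

static void xgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb, float beta,
                  float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

static const float BN_EPS = 1e-5f;

struct Layer {
  int k, cin, cout, pad;
  std::vector<float> W, b, gamma, beta;   // W: (k*k*cin) x cout
  std::vector<float> rmean, rvar;         // running batch-norm statistics
};

struct Net {
  std::vector<Layer> conv;
  std::vector<float> Wfc, bfc;            // Wfc: K x D column-major
  int K = 0, D = 0;
};

// ---------------------------------------------------------------- R <-> C++

static std::vector<float> to_f(const Rcpp::NumericVector& v) {
  std::vector<float> out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static Rcpp::NumericVector from_f(const std::vector<float>& v) {
  Rcpp::NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i];
  return out;
}

static Net load_net(const Rcpp::List& params, const Rcpp::List& run_stats) {
  Net net;
  Rcpp::List convs = params["conv"];
  for (int l = 0; l < convs.size(); ++l) {
    Rcpp::List cl = convs[l];
    Rcpp::NumericVector W = cl["W"];
    Rcpp::IntegerVector d = W.attr("dim");
    Layer L;
    L.k = d[0];
    L.cin = d[2];
    L.cout = d[3];
    L.pad = (L.k - 1) / 2;
    L.W = to_f(W);
    L.b = to_f(cl["b"]);
    L.gamma = to_f(cl["gamma"]);
    L.beta = to_f(cl["beta"]);
    Rcpp::List rs = run_stats[l];
    L.rmean = to_f(rs["mean"]);
    L.rvar = to_f(rs["var"]);
    net.conv.push_back(std::move(L));
  }
  Rcpp::List fc = params["fc"];
  Rcpp::NumericMatrix Wfc = fc["W"];
  net.K = Wfc.nrow();
  net.D = Wfc.ncol();
  net.Wfc = to_f(Rcpp::NumericVector(Wfc));
  net.bfc = to_f(fc["b"]);
  return net;
}

static Rcpp::List store_net(const Net& net) {
  Rcpp::List convs(net.conv.size());
  Rcpp::List runs(net.conv.size());
  for (size_t l = 0; l < net.conv.size(); ++l) {
    const Layer& L = net.conv[l];
    Rcpp::NumericVector W = from_f(L.W);
    W.attr("dim") = Rcpp::IntegerVector::create(L.k, L.k, L.cin, L.cout);
    convs[l] = Rcpp::List::create(
        Rcpp::Named("W") = W, Rcpp::Named("b") = from_f(L.b),
        Rcpp::Named("gamma") = from_f(L.gamma),
        Rcpp::Named("beta") = from_f(L.beta));
    runs[l] = Rcpp::List::create(Rcpp::Named("mean") = from_f(L.rmean),
                                 Rcpp::Named("var") = from_f(L.rvar));
  }
  Rcpp::NumericVector Wfc = from_f(net.Wfc);
  Wfc.attr("dim") = Rcpp::IntegerVector::create(net.K, net.D);
  return Rcpp::List::create(
      Rcpp::Named("params") = Rcpp::List::create(
          Rcpp::Named("conv") = convs,
          Rcpp::Named("fc") = Rcpp::List::create(
              Rcpp::Named("W") = Wfc, Rcpp::Named("b") = from_f(net.bfc))),
      Rcpp::Named("run_stats") = runs);
}

// ---------------------------------------------------------------- workspace

struct Workspace {
  int nb = 0, side = 0, capB = 0;
  std::vector<int> H, Wd;                  // input grid of each block
  int Hf = 0, Wf = 0;                      // final pooled grid
  std::vector<std::vector<float>> Z;       // per block: conv output cache
  std::vector<std::vector<float>> A;       // nb+1 activation stages
  std::vector<std::vector<float>> mu, istd;
  std::vector<float> cols, dcols;          // im2col scratch (per image)
  std::vector<float> dP, dY;               // gradient ping-pong buffers
  std::vector<float> F, dF, logits, dW;
  std::vector<double> dgamma, dbeta, dbconv;

  void ensure(const Net& net, int side_, int B) {
    const int nb_ = (int)net.conv.size();
    if (nb_ == nb && side_ == side && B <= capB) {
      // same geometry, but the head (n_classes, feature length) may differ
      // from the network that sized this workspace
      F.resize((size_t)capB * net.D);
      dF.resize((size_t)capB * net.D);
      logits.resize((size_t)capB * std::max(net.K, 1));
      return;
    }
    nb = nb_;
    side = side_;
    capB = B;
    H.assign(nb, 0);
    Wd.assign(nb, 0);
    Z.assign(nb, {});
    A.assign(nb + 1, {});
    mu.assign(nb, {});
    istd.assign(nb, {});
    size_t maxcols = 0, maxgrad = 0, maxdW = 0;
    int maxcout = 1;
    int h = side, w = side;
    for (int l = 0; l < nb; ++l) {
      const Layer& L = net.conv[l];
      H[l] = h;
      Wd[l] = w;
      A[l].resize((size_t)h * w * B * L.cin);
      Z[l].resize((size_t)h * w * B * L.cout);
      mu[l].resize(L.cout);
      istd[l].resize(L.cout);
      maxcols = std::max(maxcols, (size_t)h * w * L.k * L.k * L.cin);
      maxgrad = std::max(maxgrad, (size_t)h * w * B *
                                      std::max(L.cout, L.cin));
      maxdW = std::max(maxdW, (size_t)L.k * L.k * L.cin * L.cout);
      maxcout = std::max(maxcout, L.cout);
      h /= 2;
      w /= 2;
    }
    Hf = h;
    Wf = w;
    A[nb].resize((size_t)h * w * B * net.conv.back().cout);
    cols.resize(maxcols);
    dcols.resize(maxcols);
    dP.resize(maxgrad);
    dY.resize(maxgrad);
    F.resize((size_t)capB * net.D);
    dF.resize((size_t)capB * net.D);
    logits.resize((size_t)capB * std::max(net.K, 1));
    dW.resize(maxdW);
    dgamma.resize(maxcout);
    dbeta.resize(maxcout);
    dbconv.resize(maxcout);
  }
};

static Workspace& ws_global() {
  static Workspace ws;
  return ws;
}

// ------------------------------------------------------------------- im2col

// Patches of image `bimg` of the (H*W*B) x C activation `A` (leading
// dimension ldA = H*W*B) into `cols` ((H*W) x (k*k*C), leading dim H*W),
// zero-filling outside the padded support.
static void im2col(const float* A, size_t ldA, int bimg, int H, int W, int C,
                   int k, int pad, float* cols) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const float* src = A + (size_t)c * ldA + (size_t)bimg * HW;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        float* dst = cols + (((size_t)c * k + kc) * k + kr) * HW;
        const int dr = kr - pad, dc = kc - pad;
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int oc = 0; oc < W; ++oc) {
          float* d = dst + (size_t)oc * H;
          const int ic = oc + dc;
          if (ic < 0 || ic >= W || r1 <= r0) {
            std::memset(d, 0, (size_t)H * sizeof(float));
            continue;
          }
          if (r0 > 0) std::memset(d, 0, (size_t)r0 * sizeof(float));
          std::memcpy(d + r0, src + (size_t)ic * H + r0 + dr,
                      (size_t)(r1 - r0) * sizeof(float));
          if (r1 < H) std::memset(d + r1, 0, (size_t)(H - r1) * sizeof(float));
        }
      }
    }
  }
}

// Scatter-add patch gradients back onto image `bimg` of dA.
static void col2im(const float* cols, size_t ldA, int bimg, int H, int W,
                   int C, int k, int pad, float* dA) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    float* dst = dA + (size_t)c * ldA + (size_t)bimg * HW;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const float* src = cols + (((size_t)c * k + kc) * k + kr) * HW;
        const int dr = kr - pad, dc = kc - pad;
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        if (r1 <= r0) continue;
        for (int oc = 0; oc < W; ++oc) {
          const int ic = oc + dc;
          if (ic < 0 || ic >= W) continue;
          const float* s = src + (size_t)oc * H + r0;
          float* d = dst + (size_t)ic * H + r0 + dr;
          for (int i = 0; i < r1 - r0; ++i) d[i] += s[i];
        }
      }
    }
  }
}

// ------------------------------------------------------------ forward pass

// mode: 0 = inference (running stats), 1 = training (batch stats, update
// running stats), 2 = batch stats without updating (for loss checks).
static void forward(Net& net, Workspace& ws, int B, int mode,
                    double bn_momentum) {
  const int nb = ws.nb;
  for (int l = 0; l < nb; ++l) {
    Layer& L = net.conv[l];
    const int H = ws.H[l], W = ws.Wd[l];
    const size_t HW = (size_t)H * W, M = HW * B;
    const int K2 = L.k * L.k * L.cin;
    float* Z = ws.Z[l].data();
    const float* Ain = ws.A[l].data();

    for (int b = 0; b < B; ++b) {
      im2col(Ain, M, b, H, W, L.cin, L.k, L.pad, ws.cols.data());
      xgemm('N', 'N', (int)HW, L.cout, K2, 1.f, ws.cols.data(), (int)HW,
            L.W.data(), K2, 0.f, Z + b * HW, (int)M);
    }

    // bias + batch statistics in one pass
    for (int c = 0; c < L.cout; ++c) {
      float* z = Z + (size_t)c * M;
      const float bc = L.b[c];
      double s = 0, s2 = 0;
      for (size_t i = 0; i < M; ++i) {
        z[i] += bc;
        s += z[i];
        s2 += (double)z[i] * z[i];
      }
      if (mode == 0) {
        ws.mu[l][c] = L.rmean[c];
        ws.istd[l][c] = 1.f / std::sqrt(L.rvar[c] + BN_EPS);
      } else {
        const float m = (float)(s / M);
        float v = (float)(s2 / M - (double)m * m);
        if (v < 0) v = 0;
        ws.mu[l][c] = m;
        ws.istd[l][c] = 1.f / std::sqrt(v + BN_EPS);
        if (mode == 1) {
          L.rmean[c] = (1.f - (float)bn_momentum) * L.rmean[c] +
                       (float)bn_momentum * m;
          L.rvar[c] = (1.f - (float)bn_momentum) * L.rvar[c] +
                      (float)bn_momentum * v;
        }
      }
    }

    // fused batch-norm + ReLU + 2x2 average pool (floor on odd sizes)
    const int H2 = H / 2, W2 = W / 2;
    const size_t HW2 = (size_t)H2 * W2, M2 = HW2 * B;
    float* Aout = ws.A[l + 1].data();
    for (int c = 0; c < L.cout; ++c) {
      const float a = L.gamma[c] * ws.istd[l][c];
      const float d = L.beta[c] - ws.mu[l][c] * a;
      const float* z = Z + (size_t)c * M;
      float* p = Aout + (size_t)c * M2;
      for (int b = 0; b < B; ++b) {
        const float* zb = z + (size_t)b * HW;
        float* pb = p + (size_t)b * HW2;
        for (int oc = 0; oc < W2; ++oc) {
          const float* z0 = zb + (size_t)(2 * oc) * H;
          const float* z1 = z0 + H;
          float* pp = pb + (size_t)oc * H2;
          for (int r = 0; r < H2; ++r) {
            float y00 = a * z0[2 * r] + d;
            float y01 = a * z0[2 * r + 1] + d;
            float y10 = a * z1[2 * r] + d;
            float y11 = a * z1[2 * r + 1] + d;
            if (y00 < 0) y00 = 0;
            if (y01 < 0) y01 = 0;
            if (y10 < 0) y10 = 0;
            if (y11 < 0) y11 = 0;
            pp[r] = 0.25f * (y00 + y01 + y10 + y11);
          }
        }
      }
    }
  }

  // head: gather channel-major features, fully connected, softmax
  const size_t HWf = (size_t)ws.Hf * ws.Wf, Mf = HWf * B;
  const int C = net.conv.back().cout;
  const float* Af = ws.A[nb].data();
  float* F = ws.F.data();
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b)
      for (size_t s = 0; s < HWf; ++s)
        F[((size_t)c * HWf + s) * B + b] = Af[(size_t)c * Mf + b * HWf + s];

  float* logits = ws.logits.data();
  xgemm('N', 'T', B, net.K, net.D, 1.f, F, B, net.Wfc.data(), net.K, 0.f,
        logits, B);
  for (int b = 0; b < B; ++b) {
    float mx = -1e30f;
    for (int j = 0; j < net.K; ++j)
      mx = std::max(mx, logits[(size_t)j * B + b] + net.bfc[j]);
    double sum = 0;
    for (int j = 0; j < net.K; ++j) {
      float& v = logits[(size_t)j * B + b];
      v = std::exp(v + net.bfc[j] - mx);
      sum += v;
    }
    for (int j = 0; j < net.K; ++j) logits[(size_t)j * B + b] /= (float)sum;
  }
}

// --------------------------------------------------- backward + SGD update

// Expects ws.logits to hold softmax probabilities; consumes them.
static void backward(Net& net, Workspace& ws, int B, const int* y,
                     double lr) {
  const int nb = ws.nb;
  const float flr = (float)lr;

  // dLogits = (P - onehot) / B, in place
  float* dL = ws.logits.data();
  for (int b = 0; b < B; ++b) dL[(size_t)y[b] * B + b] -= 1.f;
  for (size_t i = 0; i < (size_t)B * net.K; ++i) dL[i] /= (float)B;

  // head gradients
  float* dF = ws.dF.data();
  xgemm('N', 'N', B, net.D, net.K, 1.f, dL, B, net.Wfc.data(), net.K, 0.f,
        dF, B);
  // Wfc -= lr * dL^T F   (update via GEMM with beta = 1 on Wfc)
  xgemm('T', 'N', net.K, net.D, B, -flr, dL, B, ws.F.data(), B, 1.f,
        net.Wfc.data(), net.K);
  for (int j = 0; j < net.K; ++j) {
    double s = 0;
    for (int b = 0; b < B; ++b) s += dL[(size_t)j * B + b];
    net.bfc[j] -= flr * (float)s;
  }

  // scatter dF into the pooled-activation gradient of the last block
  const size_t HWf = (size_t)ws.Hf * ws.Wf, Mf = HWf * B;
  const int C = net.conv.back().cout;
  float* dP = ws.dP.data();
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b)
      for (size_t s = 0; s < HWf; ++s)
        dP[(size_t)c * Mf + b * HWf + s] = dF[((size_t)c * HWf + s) * B + b];

  float* dYbuf = ws.dY.data();
  for (int l = nb - 1; l >= 0; --l) {
    Layer& L = net.conv[l];
    const int H = ws.H[l], W = ws.Wd[l], H2 = H / 2, W2 = W / 2;
    const size_t HW = (size_t)H * W, M = HW * B;
    const size_t HW2 = (size_t)H2 * W2, M2 = HW2 * B;
    const int K2 = L.k * L.k * L.cin;
    const float* Z = ws.Z[l].data();

    // pass 1: un-pool + ReLU mask; accumulate dgamma/dbeta
    for (int c = 0; c < L.cout; ++c) {
      const float a = L.gamma[c] * ws.istd[l][c];
      const float d = L.beta[c] - ws.mu[l][c] * a;
      const float muc = ws.mu[l][c], ic = ws.istd[l][c];
      const float* z = Z + (size_t)c * M;
      const float* dp = dP + (size_t)c * M2;
      float* dy = dYbuf + (size_t)c * M;
      std::memset(dy, 0, M * sizeof(float));
      double dg = 0, db = 0;
      for (int b = 0; b < B; ++b) {
        const float* zb = z + (size_t)b * HW;
        const float* dpb = dp + (size_t)b * HW2;
        float* dyb = dy + (size_t)b * HW;
        for (int oc = 0; oc < W2; ++oc) {
          const size_t o0 = (size_t)(2 * oc) * H, o1 = o0 + H;
          const float* dpp = dpb + (size_t)oc * H2;
          for (int r = 0; r < H2; ++r) {
            const float g = 0.25f * dpp[r];
            const size_t idx[4] = {o0 + (size_t)2 * r, o0 + 2 * r + 1,
                                   o1 + (size_t)2 * r, o1 + 2 * r + 1};
            for (int q = 0; q < 4; ++q) {
              const float zz = zb[idx[q]];
              if (a * zz + d > 0) {
                dyb[idx[q]] = g;
                dg += (double)g * (zz - muc) * ic;
                db += g;
              }
            }
          }
        }
      }
      ws.dgamma[c] = dg;
      ws.dbeta[c] = db;
    }

    // pass 2: batch-norm backward, in place on dY; accumulate conv db
    for (int c = 0; c < L.cout; ++c) {
      const float muc = ws.mu[l][c], ic = ws.istd[l][c];
      const float s = L.gamma[c] * ic / (float)M;
      const float sg = (float)ws.dgamma[c], sb = (float)ws.dbeta[c];
      const float* z = Z + (size_t)c * M;
      float* dy = dYbuf + (size_t)c * M;
      double dbc = 0;
      for (size_t i = 0; i < M; ++i) {
        const float xh = (z[i] - muc) * ic;
        const float v = s * ((float)M * dy[i] - sb - xh * sg);
        dy[i] = v;
        dbc += v;
      }
      ws.dbconv[c] = dbc;
    }

    // conv backward: dW, and dA for the next (lower) block
    const float* Ain = ws.A[l].data();
    std::memset(ws.dW.data(), 0, (size_t)K2 * L.cout * sizeof(float));
    const bool need_dA = l > 0;
    if (need_dA) {
      std::memset(dP, 0, (size_t)L.cin * M * sizeof(float));
    }
    for (int b = 0; b < B; ++b) {
      im2col(Ain, M, b, H, W, L.cin, L.k, L.pad, ws.cols.data());
      xgemm('T', 'N', K2, L.cout, (int)HW, 1.f, ws.cols.data(), (int)HW,
            dYbuf + b * HW, (int)M, 1.f, ws.dW.data(), K2);
      if (need_dA) {
        xgemm('N', 'T', (int)HW, K2, L.cout, 1.f, dYbuf + b * HW, (int)M,
              L.W.data(), K2, 0.f, ws.dcols.data(), (int)HW);
        col2im(ws.dcols.data(), M, b, H, W, L.cin, L.k, L.pad, dP);
      }
    }

    // SGD updates (weights used above are pre-update)
    for (size_t i = 0; i < L.W.size(); ++i) L.W[i] -= flr * ws.dW[i];
    for (int c = 0; c < L.cout; ++c) {
      L.b[c] -= flr * (float)ws.dbconv[c];
      L.gamma[c] -= flr * (float)ws.dgamma[c];
      L.beta[c] -= flr * (float)ws.dbeta[c];
    }
    // dP now holds dA for block l-1 (gradient w.r.t. its pooled output)
  }
}

// --------------------------------------------------------------- utilities

static void gather(const std::vector<float>& images, int npix, const int* idx,
                   int B, float* dst) {
  for (int i = 0; i < B; ++i)
    std::memcpy(dst + (size_t)i * npix, images.data() + (size_t)idx[i] * npix,
                (size_t)npix * sizeof(float));
}

static std::vector<float> images_f(const Rcpp::NumericMatrix& images) {
  std::vector<float> out(images.size());
  const double* p = images.begin();
  for (size_t i = 0; i < out.size(); ++i) out[i] = (float)p[i];
  return out;
}

// ------------------------------------------------------------------ exports

// Run one training epoch.  `images` is (side*side) x N (one image per
// column), `labels` 1-based class ids, `order` a 1-based permutation
// defining mini-batch composition.
// [[Rcpp::export]]
Rcpp::List cnn_train_epoch(Rcpp::NumericMatrix images,
                           Rcpp::IntegerVector labels, Rcpp::List params,
                           Rcpp::List run_stats, double lr,
                           Rcpp::IntegerVector order, int batch_size,
                           double bn_momentum, int side) {
  const int N = images.ncol();
  const int npix = side * side;
  if (images.nrow() != npix) Rcpp::stop("image size does not match `side`");
  if (batch_size < 1) Rcpp::stop("batch_size must be >= 1");

  Net net = load_net(params, run_stats);
  std::vector<float> imgs = images_f(images);
  Workspace& ws = ws_global();
  ws.ensure(net, side, std::min(batch_size, N));

  double loss_sum = 0;
  int correct = 0, seen = 0;
  std::vector<int> idx, y;
  for (int start = 0; start < N; start += batch_size) {
    const int B = std::min(batch_size, N - start);
    idx.resize(B);
    y.resize(B);
    for (int i = 0; i < B; ++i) {
      idx[i] = order[start + i] - 1;
      y[i] = labels[idx[i]] - 1;
    }
    gather(imgs, npix, idx.data(), B, ws.A[0].data());
    forward(net, ws, B, 1, bn_momentum);
    const float* P = ws.logits.data();
    for (int b = 0; b < B; ++b) {
      const float p = P[(size_t)y[b] * B + b];
      loss_sum -= std::log(std::max(p, 1e-12f));
      int arg = 0;
      float best = -1;
      for (int j = 0; j < net.K; ++j)
        if (P[(size_t)j * B + b] > best) { best = P[(size_t)j * B + b]; arg = j; }
      if (arg == y[b]) ++correct;
    }
    seen += B;
    backward(net, ws, B, y.data(), lr);
  }

  Rcpp::List stored = store_net(net);
  return Rcpp::List::create(Rcpp::Named("params") = stored["params"],
                            Rcpp::Named("run_stats") = stored["run_stats"],
                            Rcpp::Named("loss") = loss_sum / seen,
                            Rcpp::Named("accuracy") = (double)correct / seen);
}

// Forward pass: class probabilities and the flattened pooled activations of
// the last convolutional block (the LCA feature vector) for every image.
// With batch_stats = TRUE the whole set is normalized by its own batch
// statistics in a single chunk; otherwise running statistics are used.
// [[Rcpp::export]]
Rcpp::List cnn_forward(Rcpp::NumericMatrix images, Rcpp::List params,
                       Rcpp::List run_stats, int side, int chunk = 16,
                       bool batch_stats = false) {
  const int N = images.ncol();
  const int npix = side * side;
  if (images.nrow() != npix) Rcpp::stop("image size does not match `side`");
  Net net = load_net(params, run_stats);
  std::vector<float> imgs = images_f(images);
  const int step = batch_stats ? N : std::min(std::max(1, chunk), N);
  Workspace& ws = ws_global();
  ws.ensure(net, side, step);

  Rcpp::NumericMatrix probs(N, net.K), lca(N, net.D);
  std::vector<int> idx;
  for (int start = 0; start < N; start += step) {
    const int B = std::min(step, N - start);
    idx.resize(B);
    for (int i = 0; i < B; ++i) idx[i] = start + i;
    gather(imgs, npix, idx.data(), B, ws.A[0].data());
    forward(net, ws, B, batch_stats ? 2 : 0, 0.0);
    for (int b = 0; b < B; ++b) {
      for (int j = 0; j < net.K; ++j)
        probs(start + b, j) = ws.logits[(size_t)j * B + b];
      for (int j = 0; j < net.D; ++j)
        lca(start + b, j) = ws.F[(size_t)j * B + b];
    }
  }
  return Rcpp::List::create(Rcpp::Named("probs") = probs,
                            Rcpp::Named("lca") = lca);
}

// Forward one probe image and report each stage's actual output dimensions.
// [[Rcpp::export]]
Rcpp::List cnn_activation_trace(Rcpp::NumericMatrix image, Rcpp::List params,
                                Rcpp::List run_stats, int side) {
  Net net = load_net(params, run_stats);
  std::vector<float> img = images_f(image);
  Workspace& ws = ws_global();
  ws.ensure(net, side, 1);
  std::memcpy(ws.A[0].data(), img.data(), img.size() * sizeof(float));
  forward(net, ws, 1, 0, 0.0);
  Rcpp::List stages;
  for (int l = 0; l < ws.nb; ++l) {
    stages.push_back(Rcpp::List::create(
        Rcpp::Named("conv") = Rcpp::IntegerVector::create(
            ws.H[l], ws.Wd[l], net.conv[l].cout),
        Rcpp::Named("pool") = Rcpp::IntegerVector::create(
            ws.H[l] / 2, ws.Wd[l] / 2, net.conv[l].cout)));
  }
  return Rcpp::List::create(
      Rcpp::Named("stages") = stages,
      Rcpp::Named("lca_length") = ws.Hf * ws.Wf * net.conv.back().cout,
      Rcpp::Named("n_classes") = net.K);
}

// Re-estimate the batch-norm running statistics as the arithmetic mean of
// per-chunk batch statistics over the given images (the weights are left
// untouched).  With SGD at the learning rates used for short schedules the
// exponential running estimates lag the weights; re-estimation makes
// inference-mode normalization consistent with the current weights.
// [[Rcpp::export]]
Rcpp::List cnn_update_bn(Rcpp::NumericMatrix images, Rcpp::List params,
                         Rcpp::List run_stats, int side, int chunk = 16) {
  const int N = images.ncol();
  const int npix = side * side;
  if (images.nrow() != npix) Rcpp::stop("image size does not match `side`");
  Net net = load_net(params, run_stats);
  for (size_t l = 0; l < net.conv.size(); ++l) {
    net.conv[l].rmean.assign(net.conv[l].rmean.size(), 0.f);
    net.conv[l].rvar.assign(net.conv[l].rvar.size(), 0.f);
  }
  std::vector<float> imgs = images_f(images);
  const int step = std::min(std::max(2, chunk), N);
  Workspace& ws = ws_global();
  ws.ensure(net, side, step);
  std::vector<int> idx;
  int t = 0;
  for (int start = 0; start < N; start += step) {
    const int B = std::min(step, N - start);
    if (B < 2) break;  // a single image gives no variance estimate
    ++t;
    idx.resize(B);
    for (int i = 0; i < B; ++i) idx[i] = start + i;
    gather(imgs, npix, idx.data(), B, ws.A[0].data());
    forward(net, ws, B, 1, 1.0 / t);   // running = mean of chunk stats
  }
  Rcpp::List stored = store_net(net);
  return stored["run_stats"];
}

// Mean cross-entropy loss of a labelled set under batch statistics: the
// quantity train_step descends on, used for finite-difference gradient
// verification.
// [[Rcpp::export]]
double cnn_batch_loss(Rcpp::NumericMatrix images, Rcpp::IntegerVector labels,
                      Rcpp::List params, Rcpp::List run_stats, int side) {
  const int N = images.ncol();
  Net net = load_net(params, run_stats);
  std::vector<float> imgs = images_f(images);
  Workspace& ws = ws_global();
  ws.ensure(net, side, N);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  gather(imgs, side * side, idx.data(), N, ws.A[0].data());
  forward(net, ws, N, 2, 0.0);
  double loss = 0;
  for (int b = 0; b < N; ++b) {
    const float p = ws.logits[(size_t)(labels[b] - 1) * N + b];
    loss -= std::log(std::max(p, 1e-12f));
  }
  return loss / N;
}
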
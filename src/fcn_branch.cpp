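// Fused FCN branch: three temporal-convolution + batch-norm + ReLU blocks
// followed by global average pooling, for batches of univariate series.
//
// The branch is memory-bound at realistic widths (activation planes are
// tens of MB per batch), so activations live in single-precision buffers
// owned by a persistent context that never crosses into R, convolutions
// are computed with position-blocked direct loops so each plane is read
// and written once per pass, and batch-norm statistics are accumulated
// during the convolution store. Parameters, reductions and the classifier
// head stay in double precision on the R side.
//
// Plane layout: a batch of B series of length L occupies, per channel c,
// a contiguous float row of L*B positions, index (b*L + p); series are
// zero-padded at their own edges only (no bleed between batch elements).

#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>

using namespace Rcpp;

static const int CHUNK = 768;   // positions per block (working set ~L1/L2)

struct FcnLayer {
  int C = 0, F = 0, K = 0;
  std::vector<float> xhat;              // F planes: normalized conv output
  std::vector<float> w;                 // taps, [f*C*K + c*K + k]
  std::vector<double> bias, gamma, beta;
  std::vector<double> mu, invstd;       // stats used by the last forward
};

struct FcnCtx {
  int L = 0, Bmax = 0, B = 0;
  std::vector<float> x0;                // input series plane (C = 1)
  FcnLayer lay[3];
  std::vector<float> dy_buf, dx_buf;    // backward scratch (maxF planes)
};

// [[Rcpp::export]]
SEXP cpp_fcn_ctx_new(IntegerVector filters, IntegerVector kernels, int L,
                     int Bmax) {
  FcnCtx* ctx = new FcnCtx();
  ctx->L = L;
  ctx->Bmax = Bmax;
  const size_t plane = (size_t)L * Bmax;
  ctx->x0.assign(plane, 0.0f);
  int Cprev = 1, maxF = 1;
  for (int i = 0; i < 3; ++i) {
    FcnLayer& ly = ctx->lay[i];
    ly.C = Cprev;
    ly.F = filters[i];
    ly.K = kernels[i];
    ly.xhat.assign((size_t)ly.F * plane, 0.0f);
    ly.mu.assign(ly.F, 0.0);
    ly.invstd.assign(ly.F, 1.0);
    Cprev = ly.F;
    if (ly.F > maxF) maxF = ly.F;
  }
  ctx->dy_buf.assign((size_t)maxF * plane, 0.0f);
  ctx->dx_buf.assign((size_t)maxF * plane, 0.0f);
  return XPtr<FcnCtx>(ctx, true);
}

static void load_params(FcnCtx* ctx, const List& params) {
  // params: list(W1, b1, gamma1, beta1, W2, ..., beta3); W_i is the R-side
  // F x (C*K) double matrix whose column block k holds the C channel taps
  for (int i = 0; i < 3; ++i) {
    FcnLayer& ly = ctx->lay[i];
    NumericMatrix W = params[4 * i];
    NumericVector b = params[4 * i + 1];
    NumericVector ga = params[4 * i + 2];
    NumericVector be = params[4 * i + 3];
    ly.bias.assign(b.begin(), b.end());
    ly.gamma.assign(ga.begin(), ga.end());
    ly.beta.assign(be.begin(), be.end());
    ly.w.resize((size_t)ly.F * ly.C * ly.K);
    for (int k = 0; k < ly.K; ++k)
      for (int c = 0; c < ly.C; ++c)
        for (int f = 0; f < ly.F; ++f)
          ly.w[((size_t)f * ly.C + c) * ly.K + k] = (float)W(f, k * ly.C + c);
  }
}

// channel-resolved chunk loader
static inline void load_chunk_row(float* dst, const float* row, int b, int p0,
                                  int n, int K, int pad_left, int L, bool act,
                                  float ga, float be) {
  const int nq = n + K - 1;
  const size_t base = (size_t)b * L;
  for (int q = 0; q < nq; ++q) {
    const int p = p0 + q - pad_left;
    float v = (p < 0 || p >= L) ? 0.0f : row[base + p];
    if (act) {
      v = ga * v + be;
      if (v < 0.0f) v = 0.0f;
    }
    dst[q] = v;
  }
}

// [[Rcpp::export]]
List cpp_fcn_forward_ctx(SEXP ctx_ptr, NumericMatrix xb, List params,
                         List running, bool train, double momentum,
                         double eps, int train_from = 0) {
  XPtr<FcnCtx> ctx(ctx_ptr);
  const int L = ctx->L;
  const int B = xb.ncol();
  if (xb.nrow() != L) stop("series length mismatch");
  if (B > ctx->Bmax) stop("batch larger than context capacity");
  ctx->B = B;
  load_params(ctx, params);
  const size_t plane = (size_t)L * ctx->Bmax;
  // input series -> float plane
  for (size_t i = 0; i < (size_t)L * B; ++i) ctx->x0[i] = (float)xb[i];

  List running_out(3);
  std::vector<float> xc((size_t)256 * (CHUNK + 64));
  std::vector<float> acc(CHUNK);
  for (int i = 0; i < 3; ++i) {
    FcnLayer& ly = ctx->lay[i];
    const int C = ly.C, F = ly.F, K = ly.K;
    const int pl = (K - 1) / 2;
    const int nq_max = CHUNK + K - 1;
    const float* in_base = (i == 0) ? ctx->x0.data() : ctx->lay[i - 1].xhat.data();
    const bool act = i > 0;
    const std::vector<double>& ga_in = act ? ctx->lay[i - 1].gamma : ly.gamma;
    const std::vector<double>& be_in = act ? ctx->lay[i - 1].beta : ly.beta;
    std::vector<double> sum(F, 0.0), sumsq(F, 0.0);
    for (int b = 0; b < B; ++b) {
      for (int p0 = 0; p0 < L; p0 += CHUNK) {
        const int n = std::min(CHUNK, L - p0);
        for (int c = 0; c < C; ++c) {
          load_chunk_row(&xc[(size_t)c * nq_max], in_base + (size_t)c * plane,
                         b, p0, n, K, pl, L, act,
                         act ? (float)ga_in[c] : 1.0f,
                         act ? (float)be_in[c] : 0.0f);
        }
        for (int f = 0; f < F; ++f) {
          const float bf = (float)ly.bias[f];
          for (int p = 0; p < n; ++p) acc[p] = bf;
          const float* wf = &ly.w[(size_t)f * C * K];
          for (int c = 0; c < C; ++c) {
            const float* x = &xc[(size_t)c * nq_max];
            const float* wfc = wf + (size_t)c * K;
            for (int k = 0; k < K; ++k) {
              const float wv = wfc[k];
              const float* xk = x + k;
              for (int p = 0; p < n; ++p) acc[p] += wv * xk[p];
            }
          }
          float* out = &ly.xhat[(size_t)f * plane + (size_t)b * L + p0];
          double s = 0.0, s2 = 0.0;
          for (int p = 0; p < n; ++p) {
            const float v = acc[p];
            out[p] = v;
            s += v;
            s2 += (double)v * v;
          }
          sum[f] += s;
          sumsq[f] += s2;
        }
      }
    }
    // batch-norm statistics and in-place normalization
    NumericVector run_mu = as<List>(running[i])[0];
    NumericVector run_va = as<List>(running[i])[1];
    NumericVector new_mu(F), new_va(F);
    const double N = (double)L * B;
    const bool train_i = train && i >= train_from;
    for (int f = 0; f < F; ++f) {
      double m, v;
      if (train_i) {
        m = sum[f] / N;
        v = sumsq[f] / N - m * m;
        if (v < 0) v = 0;
        new_mu[f] = momentum * run_mu[f] + (1.0 - momentum) * m;
        new_va[f] = momentum * run_va[f] + (1.0 - momentum) * v;
      } else {
        m = run_mu[f];
        v = run_va[f];
        new_mu[f] = m;
        new_va[f] = v;
      }
      ly.mu[f] = m;
      ly.invstd[f] = 1.0 / std::sqrt(v + eps);
      const float mf = (float)m, sf = (float)ly.invstd[f];
      float* row = &ly.xhat[(size_t)f * plane];
      for (int b = 0; b < B; ++b) {
        float* r = row + (size_t)b * L;
        for (int p = 0; p < L; ++p) r[p] = (r[p] - mf) * sf;
      }
    }
    running_out[i] = List::create(_["mu"] = new_mu, _["va"] = new_va);
  }
  // global average pooling over relu(gamma*xhat + beta)
  const FcnLayer& l3 = ctx->lay[2];
  NumericMatrix gap(l3.F, B);
  for (int f = 0; f < l3.F; ++f) {
    const float ga = (float)l3.gamma[f], be = (float)l3.beta[f];
    const float* row = &l3.xhat[(size_t)f * plane];
    for (int b = 0; b < B; ++b) {
      const float* r = row + (size_t)b * L;
      double s = 0.0;
      for (int p = 0; p < L; ++p) {
        const float v = ga * r[p] + be;
        if (v > 0.0f) s += v;
      }
      gap(f, b) = s / L;
    }
  }
  return List::create(_["gap"] = gap, _["running"] = running_out);
}

// [[Rcpp::export]]
List cpp_fcn_backward_ctx(SEXP ctx_ptr, NumericMatrix dgap) {
  XPtr<FcnCtx> ctx(ctx_ptr);
  const int L = ctx->L;
  const int B = ctx->B;
  const size_t plane = (size_t)L * ctx->Bmax;
  List out(12);
  CharacterVector nms(12);
  // upper gradient source: for layer 3 it is dgap broadcast over positions;
  // for layers 2/1 it is dx_buf (gradient wrt that layer's relu output)
  std::vector<float> xc((size_t)256 * (CHUNK + 64));
  std::vector<float> dyc((size_t)256 * (CHUNK + 64));
  for (int i = 2; i >= 0; --i) {
    FcnLayer& ly = ctx->lay[i];
    const int C = ly.C, F = ly.F, K = ly.K;
    const int pl = (K - 1) / 2;
    const int pr = K - 1 - pl;
    const bool top = (i == 2);
    // pass A: da = upstream * relu-mask; accumulate S1 = sum(da),
    // S2 = sum(da * xhat); write da into dy_buf
    std::vector<double> S1(F, 0.0), S2(F, 0.0);
    for (int f = 0; f < F; ++f) {
      const float ga = (float)ly.gamma[f], be = (float)ly.beta[f];
      const float* xrow = &ly.xhat[(size_t)f * plane];
      float* drow = &ctx->dy_buf[(size_t)f * plane];
      const float* urow = top ? nullptr : &ctx->dx_buf[(size_t)f * plane];
      double s1 = 0.0, s2 = 0.0;
      for (int b = 0; b < B; ++b) {
        const float* xr = xrow + (size_t)b * L;
        float* dr = drow + (size_t)b * L;
        const float gtop = top ? (float)(dgap(f, b) / L) : 0.0f;
        const float* ur = top ? nullptr : urow + (size_t)b * L;
        for (int p = 0; p < L; ++p) {
          const float pre = ga * xr[p] + be;
          float d = (pre > 0.0f) ? (top ? gtop : ur[p]) : 0.0f;
          dr[p] = d;
          s1 += d;
          s2 += (double)d * xr[p];
        }
      }
      S1[f] = s1;
      S2[f] = s2;
    }
    NumericVector dgamma(F), dbeta(F), db(F);
    const double N = (double)L * B;
    // pass B: dy = invstd * (gamma*da - m1 - xhat*m2), in place in dy_buf
    for (int f = 0; f < F; ++f) {
      dgamma[f] = S2[f];
      dbeta[f] = S1[f];
      const float ga = (float)ly.gamma[f];
      const float m1 = (float)(ly.gamma[f] * S1[f] / N);
      const float m2 = (float)(ly.gamma[f] * S2[f] / N);
      const float is = (float)ly.invstd[f];
      const float* xrow = &ly.xhat[(size_t)f * plane];
      float* drow = &ctx->dy_buf[(size_t)f * plane];
      double dbf = 0.0;
      for (int b = 0; b < B; ++b) {
        const float* xr = xrow + (size_t)b * L;
        float* dr = drow + (size_t)b * L;
        for (int p = 0; p < L; ++p) {
          const float v = is * (ga * dr[p] - m1 - xr[p] * m2);
          dr[p] = v;
          dbf += v;
        }
      }
      db[f] = dbf;
    }
    // pass C: dW (and dx into dx_buf, except for the first layer)
    const float* in_base = (i == 0) ? ctx->x0.data() : ctx->lay[i - 1].xhat.data();
    const bool act = i > 0;
    const int nq_max = CHUNK + K - 1;
    std::vector<double> dW((size_t)F * C * K, 0.0);
    const bool want_dx = (i > 0);
    if (want_dx) {
      std::memset(ctx->dx_buf.data(), 0,
                  sizeof(float) * (size_t)C * plane);
    }
    for (int b = 0; b < B; ++b) {
      for (int p0 = 0; p0 < L; p0 += CHUNK) {
        const int n = std::min(CHUNK, L - p0);
        for (int c = 0; c < C; ++c) {
          load_chunk_row(&xc[(size_t)c * nq_max],
                         in_base + (size_t)c * plane, b, p0, n, K, pl, L, act,
                         act ? (float)ctx->lay[i - 1].gamma[c] : 1.0f,
                         act ? (float)ctx->lay[i - 1].beta[c] : 0.0f);
        }
        for (int f = 0; f < F; ++f) {
          load_chunk_row(&dyc[(size_t)f * nq_max],
                         &ctx->dy_buf[(size_t)f * plane], b, p0, n, K, pr, L,
                         false, 1.0f, 0.0f);
        }
        // dW[f][c][k] += sum_p dy[f][p] * x[c][p + k] (dy unpadded view)
        for (int f = 0; f < F; ++f) {
          const float* dyp = &dyc[(size_t)f * nq_max + pr];
          double* dwf = &dW[(size_t)f * C * K];
          for (int c = 0; c < C; ++c) {
            const float* x = &xc[(size_t)c * nq_max];
            for (int k = 0; k < K; ++k) {
              const float* xk = x + k;
              double s = 0.0;
              for (int p = 0; p < n; ++p) s += (double)dyp[p] * xk[p];
              dwf[(size_t)c * K + k] += s;
            }
          }
        }
        // dx[c][q] = sum_{f,k} w[f][c][K-1-k] * dy_pad[f][q + k]
        if (want_dx) {
          for (int c = 0; c < C; ++c) {
            float accv[CHUNK];
            for (int q = 0; q < n; ++q) accv[q] = 0.0f;
            for (int f = 0; f < F; ++f) {
              const float* wfc = &ly.w[((size_t)f * C + c) * K];
              const float* dyp = &dyc[(size_t)f * nq_max];
              for (int k = 0; k < K; ++k) {
                const float wv = wfc[K - 1 - k];
                const float* dk = dyp + k;
                for (int q = 0; q < n; ++q) accv[q] += wv * dk[q];
              }
            }
            float* dst = &ctx->dx_buf[(size_t)c * plane + (size_t)b * L + p0];
            std::memcpy(dst, accv, sizeof(float) * n);
          }
        }
      }
    }
    // repack dW to the R-side F x (C*K) layout (column block k)
    NumericMatrix dWr(F, C * K);
    for (int k = 0; k < K; ++k)
      for (int c = 0; c < C; ++c)
        for (int f = 0; f < F; ++f)
          dWr(f, k * C + c) = dW[((size_t)f * C + c) * K + k];
    out[4 * i] = dWr;
    nms[4 * i] = "W" + std::to_string(i + 1);
    out[4 * i + 1] = db;
    nms[4 * i + 1] = "b" + std::to_string(i + 1);
    out[4 * i + 2] = dgamma;
    nms[4 * i + 2] = "gamma" + std::to_string(i + 1);
    out[4 * i + 3] = dbeta;
    nms[4 * i + 3] = "beta" + std::to_string(i + 1);
  }
  out.attr("names") = nms;
  return out;
}
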
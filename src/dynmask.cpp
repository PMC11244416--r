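// Fused single-precision training/inference path for the dynamic
// multi-scale masked convolution network. Semantics are defined by the
// double-precision R reference implementation (R/model-grad.R); the two
// are cross-checked in the test suite.
//
// The depthwise convolution (scale x channel maps over the padded epoch)
// dominates the cost; it and the batch-norm/classifier elementwise passes
// are implemented with AVX-512 register-tiled kernels behind a runtime
// CPU check, each with a portable scalar fallback.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdint>
#include <algorithm>
#include <memory>

#if defined(__x86_64__) && defined(__GNUC__)
#define DYNMASK_AVX 1
#include <immintrin.h>
#endif

using namespace Rcpp;

static const double BN_EPS = 1e-5;

// ---------------------------------------------------------------------
// depthwise convolution kernels
// layout: Sp[j*stride + t] (channel-contiguous time), Wv[i*l + p],
//         D[(i*C + j)*T + t]
// fwd:  D[i,j,t] = sum_p Wv[i,p] * Sp[j, t+p]
// bwd:  dWv[i,p] = sum_{j,t} dD[i,j,t] * Sp[j, t+p]
// Sp must be readable 64 floats past its logical end (guard padding).
// ---------------------------------------------------------------------

static void conv_fwd_scalar(const float* Sp, const float* Wv, float* D,
                            int C, int T, int l, int K, long sStride) {
  for (int i = 0; i < K; ++i) {
    const float* w = Wv + (size_t)i * l;
    for (int j = 0; j < C; ++j) {
      const float* s = Sp + (size_t)j * sStride;
      float* d = D + ((size_t)i * C + j) * T;
      int t = 0;
      for (; t + 8 <= T; t += 8) {
        float acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
        for (int p = 0; p < l; ++p) {
          const float wp = w[p];
          const float* sp = s + t + p;
          for (int u = 0; u < 8; ++u) acc[u] += wp * sp[u];
        }
        for (int u = 0; u < 8; ++u) d[t + u] = acc[u];
      }
      for (; t < T; ++t) {
        float a = 0;
        for (int p = 0; p < l; ++p) a += w[p] * s[t + p];
        d[t] = a;
      }
    }
  }
}

static void conv_bwd_scalar(const float* Sp, const float* dD, float* dWv,
                            int C, int T, int l, int K, long sStride) {
  for (size_t x = 0; x < (size_t)K * l; ++x) dWv[x] = 0.0f;
  for (int i = 0; i < K; ++i) {
    float* dw = dWv + (size_t)i * l;
    for (int j = 0; j < C; ++j) {
      const float* s = Sp + (size_t)j * sStride;
      const float* g = dD + ((size_t)i * C + j) * T;
      int p = 0;
      for (; p + 8 <= l; p += 8) {
        float acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
        for (int t = 0; t < T; ++t) {
          const float gt = g[t];
          const float* sp = s + t + p;
          for (int u = 0; u < 8; ++u) acc[u] += gt * sp[u];
        }
        for (int u = 0; u < 8; ++u) dw[p + u] += acc[u];
      }
      for (; p < l; ++p) {
        float a = 0;
        for (int t = 0; t < T; ++t) a += g[t] * s[t + p];
        dw[p] += a;
      }
    }
  }
}

#ifdef DYNMASK_AVX

__attribute__((target("avx512f")))
static inline void fwd_block10(const float* __restrict sp0,
                               const float* __restrict Wv,
                               size_t l, int i0, __m512 acc[10][2]) {
  for (int p = 0; p < (int)l; ++p) {
    __m512 s0 = _mm512_loadu_ps(sp0 + p), s1 = _mm512_loadu_ps(sp0 + p + 16);
    const float* wcol = Wv + (size_t)i0 * l + p;
#define DYN_STEP(a) { __m512 w = _mm512_set1_ps(wcol[(size_t)a * l]); \
    acc[a][0] = _mm512_fmadd_ps(w, s0, acc[a][0]); \
    acc[a][1] = _mm512_fmadd_ps(w, s1, acc[a][1]); }
    DYN_STEP(0) DYN_STEP(1) DYN_STEP(2) DYN_STEP(3) DYN_STEP(4)
    DYN_STEP(5) DYN_STEP(6) DYN_STEP(7) DYN_STEP(8) DYN_STEP(9)
#undef DYN_STEP
  }
}

__attribute__((target("avx512f")))
static void conv_fwd_avx(const float* __restrict Sp, const float* __restrict Wv,
                         float* __restrict D, int C, int T, int l, int K,
                         long sStride) {
  for (int j = 0; j < C; ++j) {
    const float* s = Sp + (size_t)j * sStride;
    for (int t0 = 0; t0 < T; t0 += 32) {
      const int tn = std::min(32, T - t0);
      __mmask16 m0 = (tn >= 16) ? (__mmask16)0xFFFF : (__mmask16)((1u << tn) - 1);
      __mmask16 m1 = (tn >= 32) ? (__mmask16)0xFFFF
                   : (tn > 16 ? (__mmask16)((1u << (tn - 16)) - 1) : (__mmask16)0);
      for (int i0 = 0; i0 < K; i0 += 10) {
        const int in = std::min(10, K - i0);
        __m512 acc[10][2];
        for (int a = 0; a < 10; ++a) {
          acc[a][0] = _mm512_setzero_ps(); acc[a][1] = _mm512_setzero_ps();
        }
        const float* sp0 = s + t0;
        if (in == 10) {
          fwd_block10(sp0, Wv, (size_t)l, i0, acc);
        } else {
          for (int p = 0; p < l; ++p) {
            __m512 s0 = _mm512_loadu_ps(sp0 + p), s1 = _mm512_loadu_ps(sp0 + p + 16);
            for (int a = 0; a < in; ++a) {
              __m512 w = _mm512_set1_ps(Wv[(size_t)(i0 + a) * l + p]);
              acc[a][0] = _mm512_fmadd_ps(w, s0, acc[a][0]);
              acc[a][1] = _mm512_fmadd_ps(w, s1, acc[a][1]);
            }
          }
        }
        for (int a = 0; a < in; ++a) {
          float* d = D + ((size_t)(i0 + a) * C + j) * T + t0;
          _mm512_mask_storeu_ps(d, m0, acc[a][0]);
          if (tn > 16) _mm512_mask_storeu_ps(d + 16, m1, acc[a][1]);
        }
      }
    }
  }
}

__attribute__((target("avx512f")))
static inline void bwd_block10(const float* __restrict sp0,
                               const float* __restrict dD,
                               int C, int T, int i0, int j,
                               __m512 acc[10][2]) {
  for (int t = 0; t < T; ++t) {
    __m512 s0 = _mm512_loadu_ps(sp0 + t), s1 = _mm512_loadu_ps(sp0 + t + 16);
#define DYN_STEP(a) { __m512 g = _mm512_set1_ps(dD[((size_t)(i0 + a) * C + j) * T + t]); \
    acc[a][0] = _mm512_fmadd_ps(g, s0, acc[a][0]); \
    acc[a][1] = _mm512_fmadd_ps(g, s1, acc[a][1]); }
    DYN_STEP(0) DYN_STEP(1) DYN_STEP(2) DYN_STEP(3) DYN_STEP(4)
    DYN_STEP(5) DYN_STEP(6) DYN_STEP(7) DYN_STEP(8) DYN_STEP(9)
#undef DYN_STEP
  }
}

__attribute__((target("avx512f")))
static void conv_bwd_avx(const float* __restrict Sp, const float* __restrict dD,
                         float* __restrict dWv, int C, int T, int l, int K,
                         long sStride) {
  for (size_t x = 0; x < (size_t)K * l; ++x) dWv[x] = 0.0f;
  for (int j = 0; j < C; ++j) {
    const float* s = Sp + (size_t)j * sStride;
    for (int p0 = 0; p0 < l; p0 += 32) {
      const int pn = std::min(32, l - p0);
      __mmask16 m0 = (pn >= 16) ? (__mmask16)0xFFFF : (__mmask16)((1u << pn) - 1);
      __mmask16 m1 = (pn >= 32) ? (__mmask16)0xFFFF
                   : (pn > 16 ? (__mmask16)((1u << (pn - 16)) - 1) : (__mmask16)0);
      for (int i0 = 0; i0 < K; i0 += 10) {
        const int in = std::min(10, K - i0);
        __m512 acc[10][2];
        for (int a = 0; a < 10; ++a) {
          acc[a][0] = _mm512_setzero_ps(); acc[a][1] = _mm512_setzero_ps();
        }
        const float* sp0 = s + p0;
        if (in == 10) {
          bwd_block10(sp0, dD, C, T, i0, j, acc);
        } else {
          for (int t = 0; t < T; ++t) {
            __m512 s0 = _mm512_loadu_ps(sp0 + t), s1 = _mm512_loadu_ps(sp0 + t + 16);
            for (int a = 0; a < in; ++a) {
              __m512 g = _mm512_set1_ps(dD[((size_t)(i0 + a) * C + j) * T + t]);
              acc[a][0] = _mm512_fmadd_ps(g, s0, acc[a][0]);
              acc[a][1] = _mm512_fmadd_ps(g, s1, acc[a][1]);
            }
          }
        }
        for (int a = 0; a < in; ++a) {
          float* dw = dWv + (size_t)(i0 + a) * l + p0;
          __m512 o0 = _mm512_maskz_loadu_ps(m0, dw);
          _mm512_mask_storeu_ps(dw, m0, _mm512_add_ps(o0, acc[a][0]));
          if (pn > 16) {
            __m512 o1 = _mm512_maskz_loadu_ps(m1, dw + 16);
            _mm512_mask_storeu_ps(dw + 16, m1, _mm512_add_ps(o1, acc[a][1]));
          }
        }
      }
    }
  }
}

static bool have_avx512() {
  static int flag = -1;
  if (flag < 0) flag = __builtin_cpu_supports("avx512f") ? 1 : 0;
  return flag == 1;
}
#endif

static void conv_fwd(const float* Sp, const float* Wv, float* D,
                     int C, int T, int l, int K, long sStride) {
#ifdef DYNMASK_AVX
  if (have_avx512()) { conv_fwd_avx(Sp, Wv, D, C, T, l, K, sStride); return; }
#endif
  conv_fwd_scalar(Sp, Wv, D, C, T, l, K, sStride);
}

static void conv_bwd(const float* Sp, const float* dD, float* dWv,
                     int C, int T, int l, int K, long sStride) {
#ifdef DYNMASK_AVX
  if (have_avx512()) { conv_bwd_avx(Sp, dD, dWv, C, T, l, K, sStride); return; }
#endif
  conv_bwd_scalar(Sp, dD, dWv, C, T, l, K, sStride);
}

// ---------------------------------------------------------------------
// elementwise per-(sample, scale) map passes
// keep == nullptr means dropout off (keep factor 1).
// ---------------------------------------------------------------------

static inline int keep_bit(const uint16_t* kp, size_t x) {
  return (kp[x >> 4] >> (x & 15)) & 1;
}

// sum and sum of squares
static void map_stats_scalar(const float* d, size_t n, double* sum, double* sumsq) {
  double a = 0, a2 = 0;
  for (size_t x = 0; x < n; ++x) { a += d[x]; a2 += (double)d[x] * d[x]; }
  *sum = a; *sumsq = a2;
}

// acc += w . ((d - mk) * ik * gk2 + bk2) * keep
static double map_logit_scalar(const float* d, const float* w, const uint16_t* keep,
                               size_t n, float gk2, float bk2, float mk, float ik) {
  double a = 0;
  for (size_t x = 0; x < n; ++x) {
    float z = gk2 * ((d[x] - mk) * ik) + bk2;
    if (keep && !keep_bit(keep, x)) z = 0.0f;
    a += (double)w[x] * z;
  }
  return a;
}

// reductions for batch-norm backward: dz = gys2 * w * keep,
// xh = (d - mk) * ik; returns sum(dz) and sum(dz * xh)
static void map_pass1_scalar(const float* d, const float* w, const uint16_t* keep,
                             size_t n, float gys2, float mk, float ik,
                             double* sumdz, double* sumdzxh) {
  double sb = 0, sx = 0;
  for (size_t x = 0; x < n; ++x) {
    float dz = gys2 * w[x];
    if (keep && !keep_bit(keep, x)) dz = 0.0f;
    const float xh = (d[x] - mk) * ik;
    sb += dz; sx += (double)dz * xh;
  }
  *sumdz = sb; *sumdzxh = sx;
}

// emit dD, accumulate classifier-weight gradient, return sum(dD)
static double map_pass2_scalar(const float* d, const float* w, const uint16_t* keep,
                               float* gw, float* dd, size_t n,
                               float gys, float gys2, float gk, float gk2,
                               float bk2, float mk, float ik,
                               float c1, float c2) {
  double sbv = 0;
  for (size_t x = 0; x < n; ++x) {
    const float xh = (d[x] - mk) * ik;
    float z = gk2 * xh + bk2;
    float dz = gys2 * w[x];
    if (keep && !keep_bit(keep, x)) { z = 0.0f; dz = 0.0f; }
    gw[x] += gys * z;
    const float val = ik * (dz * gk - c1 - xh * c2);
    dd[x] = val;
    sbv += val;
  }
  return sbv;
}

#ifdef DYNMASK_AVX

__attribute__((target("avx512f,avx512dq")))
static inline double hsum(__m512d a) { return _mm512_reduce_add_pd(a); }

__attribute__((target("avx512f,avx512dq")))
static inline __m512d accum(__m512d acc, __m512 v) {
  // add both halves of a float vector into a double accumulator
  acc = _mm512_add_pd(acc, _mm512_cvtps_pd(_mm512_castps512_ps256(v)));
  acc = _mm512_add_pd(acc, _mm512_cvtps_pd(_mm512_extractf32x8_ps(v, 1)));
  return acc;
}

__attribute__((target("avx512f,avx512bw,avx512dq,avx512vl")))
static void map_stats_avx(const float* d, size_t n, double* sum, double* sumsq) {
  __m512d a = _mm512_setzero_pd(), a2 = _mm512_setzero_pd();
  size_t x = 0;
  for (; x + 16 <= n; x += 16) {
    __m512 v = _mm512_loadu_ps(d + x);
    a = accum(a, v);
    a2 = accum(a2, _mm512_mul_ps(v, v));
  }
  double s = hsum(a), s2 = hsum(a2);
  for (; x < n; ++x) { s += d[x]; s2 += (double)d[x] * d[x]; }
  *sum = s; *sumsq = s2;
}

__attribute__((target("avx512f,avx512bw,avx512dq,avx512vl")))
static double map_logit_avx(const float* d, const float* w, const uint16_t* keep,
                            size_t n, float gk2, float bk2, float mk, float ik) {
  const __m512 vg = _mm512_set1_ps(gk2), vb = _mm512_set1_ps(bk2),
               vm = _mm512_set1_ps(mk), vi = _mm512_set1_ps(ik);
  __m512d acc = _mm512_setzero_pd();
  size_t x = 0;
  for (; x + 16 <= n; x += 16) {
    __m512 xh = _mm512_mul_ps(_mm512_sub_ps(_mm512_loadu_ps(d + x), vm), vi);
    __m512 z = _mm512_fmadd_ps(vg, xh, vb);
    if (keep) z = _mm512_maskz_mov_ps((__mmask16)keep[x >> 4], z);
    acc = accum(acc, _mm512_mul_ps(_mm512_loadu_ps(w + x), z));
  }
  double a = hsum(acc);
  for (; x < n; ++x) {
    float z = gk2 * ((d[x] - mk) * ik) + bk2;
    if (keep && !keep_bit(keep, x)) z = 0.0f;
    a += (double)w[x] * z;
  }
  return a;
}

__attribute__((target("avx512f,avx512bw,avx512dq,avx512vl")))
static void map_pass1_avx(const float* d, const float* w, const uint16_t* keep,
                          size_t n, float gys2, float mk, float ik,
                          double* sumdz, double* sumdzxh) {
  const __m512 vg = _mm512_set1_ps(gys2), vm = _mm512_set1_ps(mk),
               vi = _mm512_set1_ps(ik);
  __m512d sb = _mm512_setzero_pd(), sx = _mm512_setzero_pd();
  size_t x = 0;
  for (; x + 16 <= n; x += 16) {
    __m512 dz = _mm512_mul_ps(vg, _mm512_loadu_ps(w + x));
    if (keep) dz = _mm512_maskz_mov_ps((__mmask16)keep[x >> 4], dz);
    __m512 xh = _mm512_mul_ps(_mm512_sub_ps(_mm512_loadu_ps(d + x), vm), vi);
    sb = accum(sb, dz);
    sx = accum(sx, _mm512_mul_ps(dz, xh));
  }
  double b = hsum(sb), s = hsum(sx);
  for (; x < n; ++x) {
    float dz = gys2 * w[x];
    if (keep && !keep_bit(keep, x)) dz = 0.0f;
    const float xh = (d[x] - mk) * ik;
    b += dz; s += (double)dz * xh;
  }
  *sumdz = b; *sumdzxh = s;
}

__attribute__((target("avx512f,avx512bw,avx512dq,avx512vl")))
static double map_pass2_avx(const float* d, const float* w, const uint16_t* keep,
                            float* gw, float* dd, size_t n,
                            float gys, float gys2, float gk, float gk2,
                            float bk2, float mk, float ik, float c1, float c2) {
  const __m512 vgk2 = _mm512_set1_ps(gk2), vbk2 = _mm512_set1_ps(bk2),
               vm = _mm512_set1_ps(mk), vi = _mm512_set1_ps(ik),
               vgys = _mm512_set1_ps(gys), vgys2 = _mm512_set1_ps(gys2),
               vgk = _mm512_set1_ps(gk), vc1 = _mm512_set1_ps(c1),
               vc2 = _mm512_set1_ps(c2);
  __m512d sbv = _mm512_setzero_pd();
  size_t x = 0;
  for (; x + 16 <= n; x += 16) {
    __m512 xh = _mm512_mul_ps(_mm512_sub_ps(_mm512_loadu_ps(d + x), vm), vi);
    __m512 z = _mm512_fmadd_ps(vgk2, xh, vbk2);
    __m512 dz = _mm512_mul_ps(vgys2, _mm512_loadu_ps(w + x));
    if (keep) {
      const __mmask16 km = (__mmask16)keep[x >> 4];
      z = _mm512_maskz_mov_ps(km, z);
      dz = _mm512_maskz_mov_ps(km, dz);
    }
    _mm512_storeu_ps(gw + x,
        _mm512_fmadd_ps(vgys, z, _mm512_loadu_ps(gw + x)));
    __m512 val = _mm512_mul_ps(vi,
        _mm512_sub_ps(_mm512_fmsub_ps(dz, vgk, vc1), _mm512_mul_ps(xh, vc2)));
    _mm512_storeu_ps(dd + x, val);
    sbv = accum(sbv, val);
  }
  double sv = hsum(sbv);
  for (; x < n; ++x) {
    const float xh = (d[x] - mk) * ik;
    float z = gk2 * xh + bk2;
    float dz = gys2 * w[x];
    if (keep && !keep_bit(keep, x)) { z = 0.0f; dz = 0.0f; }
    gw[x] += gys * z;
    const float val = ik * (dz * gk - c1 - xh * c2);
    dd[x] = val;
    sv += val;
  }
  return sv;
}

static bool have_avx512bw() {
  static int flag = -1;
  if (flag < 0)
    flag = (__builtin_cpu_supports("avx512f") &&
            __builtin_cpu_supports("avx512bw") &&
            __builtin_cpu_supports("avx512vl") &&
            __builtin_cpu_supports("avx512dq")) ? 1 : 0;
  return flag == 1;
}
#endif

static void map_stats(const float* d, size_t n, double* sum, double* sumsq) {
#ifdef DYNMASK_AVX
  if (have_avx512bw()) { map_stats_avx(d, n, sum, sumsq); return; }
#endif
  map_stats_scalar(d, n, sum, sumsq);
}

static double map_logit(const float* d, const float* w, const uint16_t* keep,
                        size_t n, float gk2, float bk2, float mk, float ik) {
#ifdef DYNMASK_AVX
  if (have_avx512bw()) return map_logit_avx(d, w, keep, n, gk2, bk2, mk, ik);
#endif
  return map_logit_scalar(d, w, keep, n, gk2, bk2, mk, ik);
}

static void map_pass1(const float* d, const float* w, const uint16_t* keep,
                      size_t n, float gys2, float mk, float ik,
                      double* sumdz, double* sumdzxh) {
#ifdef DYNMASK_AVX
  if (have_avx512bw()) {
    map_pass1_avx(d, w, keep, n, gys2, mk, ik, sumdz, sumdzxh); return;
  }
#endif
  map_pass1_scalar(d, w, keep, n, gys2, mk, ik, sumdz, sumdzxh);
}

static double map_pass2(const float* d, const float* w, const uint16_t* keep,
                        float* gw, float* dd, size_t n,
                        float gys, float gys2, float gk, float gk2,
                        float bk2, float mk, float ik, float c1, float c2) {
#ifdef DYNMASK_AVX
  if (have_avx512bw())
    return map_pass2_avx(d, w, keep, gw, dd, n, gys, gys2, gk, gk2, bk2,
                         mk, ik, c1, c2);
#endif
  return map_pass2_scalar(d, w, keep, gw, dd, n, gys, gys2, gk, gk2, bk2,
                          mk, ik, c1, c2);
}

// ---------------------------------------------------------------------
// packed epoch store
// ---------------------------------------------------------------------

struct PackedEpochs {
  std::vector<float> S;      // n * C * (T+l) + 64 guard
  std::vector<float> Sbar;   // n * (T+2h) + 64 guard
  int n, C, T, l, h;
};

// data: numeric array [T, C, n] (time fastest), l: kernel length,
// h: feature-conv half width
// [[Rcpp::export(name = ".packEpochs")]]
SEXP packEpochs(NumericVector data, IntegerVector dims, int l, int h) {
  const int T = dims[0], C = dims[1], n = dims[2];
  PackedEpochs* pk = new PackedEpochs();
  pk->n = n; pk->C = C; pk->T = T; pk->l = l; pk->h = h;
  const long Tp = (long)T + l;
  pk->S.assign((size_t)n * C * Tp + 64, 0.0f);
  pk->Sbar.assign((size_t)n * (T + 2 * h) + 64, 0.0f);
  const double* src = data.begin();
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < C; ++c) {
      const double* s = src + ((size_t)i * C + c) * T;
      float* dst = pk->S.data() + ((size_t)i * C + c) * Tp;
      for (int t = 0; t < T; ++t) dst[t] = (float)s[t];
    }
    float* sb = pk->Sbar.data() + (size_t)i * (T + 2 * h) + h;
    for (int t = 0; t < T; ++t) {
      double a = 0;
      for (int c = 0; c < C; ++c) a += src[((size_t)i * C + c) * T + t];
      sb[t] = (float)(a / C);
    }
  }
  XPtr<PackedEpochs> ptr(pk, true);
  return ptr;
}

// ---------------------------------------------------------------------
// small helpers
// ---------------------------------------------------------------------

static inline float sigmf(float x) { return 1.0f / (1.0f + std::exp(-x)); }

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed)
    : s(seed ? seed * 0x9E3779B97F4A7C15ull : 0x853C49E6748FEA9Bull) {
    for (int i = 0; i < 4; ++i) next();
  }
  uint64_t next() { s ^= s << 13; s ^= s >> 7; s ^= s << 17; return s; }
  float unif() { return (float)((next() >> 40) * (1.0 / 16777216.0)); }
};

// Bernoulli(1-q) keep masks, 16 lanes per entry; one 64-bit draw covers
// four entries when q = 0.5
static void gen_keep(uint16_t* kp, size_t nvec, double q, XorShift64& rng) {
  if (q == 0.5) {
    size_t v = 0;
    for (; v + 4 <= nvec; v += 4) {
      uint64_t u = rng.next();
      kp[v] = (uint16_t)u; kp[v + 1] = (uint16_t)(u >> 16);
      kp[v + 2] = (uint16_t)(u >> 32); kp[v + 3] = (uint16_t)(u >> 48);
    }
    if (v < nvec) {
      uint64_t u = rng.next();
      for (; v < nvec; ++v, u >>= 16) kp[v] = (uint16_t)u;
    }
  } else {
    for (size_t v = 0; v < nvec; ++v) {
      uint16_t m = 0;
      for (int b = 0; b < 16; ++b)
        if (rng.unif() >= (float)q) m |= (uint16_t)(1u << b);
      kp[v] = m;
    }
  }
}

static std::vector<float> asFloat(NumericVector x) {
  std::vector<float> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (float)x[i];
  return out;
}

struct FloatParams {
  std::vector<float> Wf, bf, W, bv, Wm1, bm1, Wm2, gamma, beta, w, runMean, runVar;
  float bm2, b;
  int K, l, fw;
};

// params$w arrives as an array with dim (K, C, T) (k fastest); repack to
// the internal [k][c][t] layout (t fastest).
static void loadParams(List params, int C, int T, FloatParams& fp) {
  NumericMatrix Wf = params["Wf"];
  fp.K = Wf.nrow(); fp.fw = Wf.ncol();
  NumericMatrix W = params["W"];
  fp.l = W.ncol();
  fp.bf = asFloat(params["bf"]);
  // R matrices are column-major; transpose W and Wf to row-contiguous
  std::vector<float> Wt((size_t)fp.K * fp.l);
  for (int i = 0; i < fp.K; ++i)
    for (int p = 0; p < fp.l; ++p)
      Wt[(size_t)i * fp.l + p] = (float)W(i, p);
  fp.W = Wt;
  std::vector<float> Wft((size_t)fp.K * fp.fw);
  for (int i = 0; i < fp.K; ++i)
    for (int u = 0; u < fp.fw; ++u)
      Wft[(size_t)i * fp.fw + u] = (float)Wf(i, u);
  fp.Wf = Wft;
  fp.bv = asFloat(params["bv"]);
  fp.Wm1 = asFloat(params["Wm1"]);       // column-major l x 2l, kept as is
  fp.bm1 = asFloat(params["bm1"]);
  fp.Wm2 = asFloat(params["Wm2"]);
  fp.bm2 = (float)as<double>(params["bm2"]);
  fp.gamma = asFloat(params["gamma"]);
  fp.beta = asFloat(params["beta"]);
  fp.runMean = asFloat(params["runMean"]);
  fp.runVar = asFloat(params["runVar"]);
  fp.b = (float)as<double>(params["b"]);
  NumericVector wv = params["w"];
  fp.w.assign((size_t)fp.K * C * T, 0.0f);
  const double* wp = wv.begin();
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < C; ++c) {
      const double* col = wp + ((size_t)t * C + c) * fp.K;
      for (int k = 0; k < fp.K; ++k)
        fp.w[((size_t)k * C + c) * T + t] = (float)col[k];
    }
}


// fc1 forward: z1 = bm1 + Wm1 . cat  (Wm1 column-major l x 2l)
static void fc1_fwd_scalar(const float* Wm1, const float* bm1,
                           const float* cat, float* z1, int l) {
  for (int o = 0; o < l; ++o) z1[o] = bm1[o];
  for (int i = 0; i < 2 * l; ++i) {
    const float v = cat[i];
    const float* col = Wm1 + (size_t)i * l;
    for (int o = 0; o < l; ++o) z1[o] += col[o] * v;
  }
}

// fc1 backward: gWm1 += dz1 (x) cat, dcat = Wm1^T . dz1
static void fc1_bwd_scalar(const float* Wm1, const float* dz1,
                           const float* cat, float* gWm1, float* dcat, int l) {
  for (int i = 0; i < 2 * l; ++i) {
    const float ci = cat[i];
    const float* col = Wm1 + (size_t)i * l;
    float* gcol = gWm1 + (size_t)i * l;
    float dc = 0;
    for (int o = 0; o < l; ++o) {
      gcol[o] += dz1[o] * ci;
      dc += col[o] * dz1[o];
    }
    dcat[i] = dc;
  }
}

#ifdef DYNMASK_AVX
__attribute__((target("avx512f")))
static void fc1_fwd_avx(const float* Wm1, const float* bm1,
                        const float* cat, float* z1, int l) {
  int o0 = 0;
  for (; o0 + 64 <= l; o0 += 64) {
    __m512 a0 = _mm512_loadu_ps(bm1 + o0), a1 = _mm512_loadu_ps(bm1 + o0 + 16),
           a2 = _mm512_loadu_ps(bm1 + o0 + 32), a3 = _mm512_loadu_ps(bm1 + o0 + 48);
    for (int i = 0; i < 2 * l; ++i) {
      const float* col = Wm1 + (size_t)i * l + o0;
      __m512 v = _mm512_set1_ps(cat[i]);
      a0 = _mm512_fmadd_ps(v, _mm512_loadu_ps(col), a0);
      a1 = _mm512_fmadd_ps(v, _mm512_loadu_ps(col + 16), a1);
      a2 = _mm512_fmadd_ps(v, _mm512_loadu_ps(col + 32), a2);
      a3 = _mm512_fmadd_ps(v, _mm512_loadu_ps(col + 48), a3);
    }
    _mm512_storeu_ps(z1 + o0, a0); _mm512_storeu_ps(z1 + o0 + 16, a1);
    _mm512_storeu_ps(z1 + o0 + 32, a2); _mm512_storeu_ps(z1 + o0 + 48, a3);
  }
  for (int o = o0; o < l; ++o) {
    float a = bm1[o];
    for (int i = 0; i < 2 * l; ++i) a += Wm1[(size_t)i * l + o] * cat[i];
    z1[o] = a;
  }
}

__attribute__((target("avx512f")))
static void fc1_bwd_avx(const float* Wm1, const float* dz1,
                        const float* cat, float* gWm1, float* dcat, int l) {
  const int lv = l / 16 * 16;
  for (int i = 0; i < 2 * l; ++i) {
    const float ci = cat[i];
    const __m512 vc = _mm512_set1_ps(ci);
    const float* col = Wm1 + (size_t)i * l;
    float* gcol = gWm1 + (size_t)i * l;
    __m512 acc = _mm512_setzero_ps();
    int o = 0;
    for (; o < lv; o += 16) {
      const __m512 dz = _mm512_loadu_ps(dz1 + o);
      _mm512_storeu_ps(gcol + o,
          _mm512_fmadd_ps(dz, vc, _mm512_loadu_ps(gcol + o)));
      acc = _mm512_fmadd_ps(_mm512_loadu_ps(col + o), dz, acc);
    }
    float dc = _mm512_reduce_add_ps(acc);
    for (; o < l; ++o) {
      gcol[o] += dz1[o] * ci;
      dc += col[o] * dz1[o];
    }
    dcat[i] = dc;
  }
}
#endif

static void fc1_fwd(const float* Wm1, const float* bm1, const float* cat,
                    float* z1, int l) {
#ifdef DYNMASK_AVX
  if (have_avx512()) { fc1_fwd_avx(Wm1, bm1, cat, z1, l); return; }
#endif
  fc1_fwd_scalar(Wm1, bm1, cat, z1, l);
}

static void fc1_bwd(const float* Wm1, const float* dz1, const float* cat,
                    float* gWm1, float* dcat, int l) {
#ifdef DYNMASK_AVX
  if (have_avx512()) { fc1_bwd_avx(Wm1, dz1, cat, gWm1, dcat, l); return; }
#endif
  fc1_bwd_scalar(Wm1, dz1, cat, gWm1, dcat, l);
}

#if defined(__x86_64__) && defined(__GNUC__)
#define DYNMASK_CLONES __attribute__((target_clones("arch=x86-64-v3","default")))
#else
#define DYNMASK_CLONES
#endif

// per-sample mask-generator forward; fills cat2 [K*2l], z1 [K*l], r [K],
// M [K*l] and the masked kernels Wv [K*l]
DYNMASK_CLONES
static void maskForward(const FloatParams& fp, const float* sbar,
                        int P, float lambda,
                        float* cat2, float* z1, float* r,
                        float* M, float* Wv) {
  const int K = fp.K, l = fp.l, fw = fp.fw;
  for (int k = 0; k < K; ++k) {
    float* ck = cat2 + (size_t)k * 2 * l;
    // first half: feature-conv output over the window [P, P+l)
    // (Ewin[k, j] = sum_u Wf[k, u] * sbarpad[P + j + u] + bf[k])
    for (int j = 0; j < l; ++j) {
      float a = fp.bf[k];
      const float* sb = sbar + P + j;   // sbar points at padded start
      for (int u = 0; u < fw; ++u) a += fp.Wf[(size_t)k * fw + u] * sb[u];
      ck[j] = a;
    }
    std::memcpy(ck + l, fp.W.data() + (size_t)k * l, sizeof(float) * l);
    float* zk = z1 + (size_t)k * l;
    fc1_fwd(fp.Wm1.data(), fp.bm1.data(), ck, zk, l);
    float z2 = fp.bm2;
    for (int o = 0; o < l; ++o) z2 += fp.Wm2[o] * zk[o];
    r[k] = sigmf(z2);
    const float li = r[k] * l;
    float* mk = M + (size_t)k * l;
    float* wk = Wv + (size_t)k * l;
    const float* bk = fp.W.data() + (size_t)k * l;
    for (int j = 0; j < l; ++j) {
      mk[j] = sigmf(lambda * (li - (float)(j + 1)));
      wk[j] = bk[j] * mk[j];
    }
  }
}

// per-sample mask-generator backward: consumes the per-sample kernel
// gradient dWv and accumulates into the shared parameter gradients
DYNMASK_CLONES
static void maskBackward(const FloatParams& fp, float lambda, int P,
                         const float* M, const float* r, const float* z1,
                         const float* cat2, const float* dWv,
                         const float* sbar,
                         float* gW, float* gWm1, float* gbm1, float* gWm2,
                         double* gbm2, float* gWf, float* gbf) {
  const int K = fp.K, l = fp.l, fw = fp.fw;
  std::vector<float> dz1((size_t)K * l), dcat((size_t)K * 2 * l);
  for (int k = 0; k < K; ++k) {
    const float* mk = M + (size_t)k * l;
    const float* bk = fp.W.data() + (size_t)k * l;
    const float* dwk = dWv + (size_t)k * l;
    float* gWk = gW + (size_t)k * l;
    double dli = 0;
    for (int j = 0; j < l; ++j) {
      gWk[j] += dwk[j] * mk[j];
      const float dM = dwk[j] * bk[j];
      dli += (double)dM * lambda * mk[j] * (1.0f - mk[j]);
    }
    const float dz2 = (float)(dli * l * r[k] * (1.0f - r[k]));
    const float* z1k = z1 + (size_t)k * l;
    *gbm2 += dz2;
    for (int o = 0; o < l; ++o) gWm2[o] += dz2 * z1k[o];
    float* dz1k = dz1.data() + (size_t)k * l;
    for (int o = 0; o < l; ++o) dz1k[o] = dz2 * fp.Wm2[o];
  }
  // fc1 gradients and propagation to the concatenated input
  for (int k = 0; k < K; ++k) {
    const float* dz1k = dz1.data() + (size_t)k * l;
    const float* ck = cat2 + (size_t)k * 2 * l;
    float* dck = dcat.data() + (size_t)k * 2 * l;
    for (int o = 0; o < l; ++o) gbm1[o] += dz1k[o];
    fc1_bwd(fp.Wm1.data(), dz1k, ck, gWm1, dck, l);
  }
  // dcat -> base kernels (second half) and feature conv (first half)
  for (int k = 0; k < K; ++k) {
    const float* dck = dcat.data() + (size_t)k * 2 * l;
    float* gWk = gW + (size_t)k * l;
    for (int j = 0; j < l; ++j) gWk[j] += dck[l + j];
    float gb_k = 0;
    for (int j = 0; j < l; ++j) gb_k += dck[j];
    gbf[k] += gb_k;
    for (int u = 0; u < fw; ++u) {
      float a = 0;
      const float* sb = sbar + P + u;
      for (int j = 0; j < l; ++j) a += dck[j] * sb[j];
      gWf[(size_t)k * fw + u] += a;
    }
  }
}

// [[Rcpp::export(name = ".batchStep")]]
List batchStep(SEXP xptr, IntegerVector idx, NumericVector y, List params,
               List cfg, double posWeight, double rngSeed) {
  XPtr<PackedEpochs> pk(xptr);
  const int C = pk->C, T = pk->T, n = pk->n;
  const int B = idx.size();
  const int P = as<int>(cfg["P"]);
  const float lambda = (float)as<double>(cfg["lambda"]);
  const double q = as<double>(cfg["dropoutRate"]);
  const bool masked = as<bool>(cfg["masked"]);
  FloatParams fp;
  loadParams(params, C, T, fp);
  const int K = fp.K, l = fp.l;
  if (l != pk->l) stop("packed kernel length mismatch");
  const long Tp = (long)T + l;
  const size_t mapSz = (size_t)K * C * T;
  const size_t CT = (size_t)C * T;
  for (int s = 0; s < B; ++s)
    if (idx[s] < 1 || idx[s] > n) stop("trial index out of range");

  std::unique_ptr<float[]> D(new float[(size_t)B * mapSz]);
  const size_t kvec = (CT + 15) / 16;       // dropout mask entries per map
  std::unique_ptr<uint16_t[]> keep;
  if (q > 0) keep.reset(new uint16_t[(size_t)B * K * kvec]);

  // per-sample mask caches
  std::vector<float> cat2a((size_t)B * K * 2 * l), z1a((size_t)B * K * l),
      ra((size_t)B * K), Ma((size_t)B * K * l), Wv((size_t)K * l);

  for (int s = 0; s < B; ++s) {
    const long i0 = idx[s] - 1;
    const float* Sp = pk->S.data() + (size_t)i0 * C * Tp;
    if (masked) {
      const float* sbar = pk->Sbar.data() + (size_t)i0 * (T + 2 * pk->h);
      maskForward(fp, sbar, P, lambda,
                  cat2a.data() + (size_t)s * K * 2 * l,
                  z1a.data() + (size_t)s * K * l,
                  ra.data() + (size_t)s * K,
                  Ma.data() + (size_t)s * K * l, Wv.data());
      conv_fwd(Sp, Wv.data(), D.get() + (size_t)s * mapSz, C, T, l, K, Tp);
    } else {
      conv_fwd(Sp, fp.W.data(), D.get() + (size_t)s * mapSz, C, T, l, K, Tp);
    }
  }

  // batch-norm statistics per scale; D holds raw convolution output, the
  // per-scale bias bv shifts the mean but not the variance, so it is
  // folded into the reported mean and cancels in normalisation.
  const double N = (double)B * CT;
  std::vector<double> mu(K, 0.0), var(K, 0.0);
  for (int s = 0; s < B; ++s)
    for (int k = 0; k < K; ++k) {
      double a, a2;
      map_stats(D.get() + (size_t)s * mapSz + (size_t)k * CT, CT, &a, &a2);
      mu[k] += a; var[k] += a2;
    }
  for (int k = 0; k < K; ++k) {
    mu[k] /= N;
    var[k] = var[k] / N - mu[k] * mu[k];
    if (var[k] < 0) var[k] = 0;
  }
  std::vector<float> inv(K), muf(K);
  for (int k = 0; k < K; ++k) {
    inv[k] = (float)(1.0 / std::sqrt(var[k] + BN_EPS));
    muf[k] = (float)mu[k];   // raw-conv mean; reported mean adds bv below
  }

  // dropout masks + logits
  XorShift64 rng((uint64_t)(int64_t)rngSeed);
  const float scale = (q > 0) ? (float)(1.0 / (1.0 - q)) : 1.0f;
  if (q > 0) gen_keep(keep.get(), (size_t)B * K * kvec, q, rng);
  std::vector<double> logits(B);
  for (int s = 0; s < B; ++s) {
    double acc = fp.b;
    for (int k = 0; k < K; ++k) {
      const uint16_t* kp = q > 0 ? keep.get() + ((size_t)s * K + k) * kvec : nullptr;
      acc += map_logit(D.get() + (size_t)s * mapSz + (size_t)k * CT,
                       fp.w.data() + (size_t)k * CT, kp, CT,
                       fp.gamma[k] * scale, fp.beta[k] * scale,
                       muf[k], inv[k]);
    }
    logits[s] = acc;
  }

  // loss and logit gradients
  double loss = 0;
  std::vector<double> gY(B);
  for (int s = 0; s < B; ++s) {
    const double z = logits[s], ys = y[s];
    const double wgt = posWeight * ys + (1 - ys);
    const double softplus = z > 0 ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
    loss += (ys > 0.5 ? posWeight * (softplus - z) : softplus);
    const double p = 1.0 / (1.0 + std::exp(-z));
    gY[s] = (p * wgt - posWeight * ys) / B;
  }
  loss /= B;
  if (!std::isfinite(loss)) stop("non-finite training loss");

  // backward
  std::vector<float> gWf((size_t)K * fp.fw, 0.0f), gbf(K, 0.0f),
      gW((size_t)K * l, 0.0f), gbv(K, 0.0f),
      gWm1((size_t)l * 2 * l, 0.0f), gbm1(l, 0.0f), gWm2(l, 0.0f),
      ggamma(K, 0.0f), gbeta(K, 0.0f), gw(mapSz, 0.0f);
  double gbm2 = 0, gb = 0;

  // pass 1: reductions (dz sums feed both BN backward and gamma/beta)
  std::vector<double> S1(K, 0.0), S2(K, 0.0);
  for (int s = 0; s < B; ++s) {
    const float gys2 = (float)(gY[s] * scale);
    gb += gY[s];
    for (int k = 0; k < K; ++k) {
      const uint16_t* kp = q > 0 ? keep.get() + ((size_t)s * K + k) * kvec : nullptr;
      double sdz, sdzxh;
      map_pass1(D.get() + (size_t)s * mapSz + (size_t)k * CT,
                fp.w.data() + (size_t)k * CT, kp, CT, gys2,
                muf[k], inv[k], &sdz, &sdzxh);
      // dxh = dz * gamma  =>  sums scale by gamma
      S1[k] += fp.gamma[k] * sdz;
      S2[k] += fp.gamma[k] * sdzxh;
      ggamma[k] += (float)sdzxh;
      gbeta[k] += (float)sdz;
    }
  }

  // pass 2: dD, conv backward, mask backward, classifier weight grad
  std::unique_ptr<float[]> dD(new float[mapSz]);
  std::vector<float> dWv((size_t)K * l);
  for (int s = 0; s < B; ++s) {
    const long i0 = idx[s] - 1;
    const float* Sp = pk->S.data() + (size_t)i0 * C * Tp;
    const float gys = (float)gY[s];
    const float gys2 = (float)(gY[s] * scale);
    for (int k = 0; k < K; ++k) {
      const uint16_t* kp = q > 0 ? keep.get() + ((size_t)s * K + k) * kvec : nullptr;
      const double sbv = map_pass2(
          D.get() + (size_t)s * mapSz + (size_t)k * CT,
          fp.w.data() + (size_t)k * CT, kp,
          gw.data() + (size_t)k * CT, dD.get() + (size_t)k * CT, CT,
          gys, gys2, fp.gamma[k], fp.gamma[k] * scale, fp.beta[k] * scale,
          muf[k], inv[k], (float)(S1[k] / N), (float)(S2[k] / N));
      gbv[k] += (float)sbv;
    }
    conv_bwd(Sp, dD.get(), dWv.data(), C, T, l, K, Tp);
    if (masked) {
      const float* sbar = pk->Sbar.data() + (size_t)i0 * (T + 2 * pk->h);
      maskBackward(fp, lambda, P,
                   Ma.data() + (size_t)s * K * l,
                   ra.data() + (size_t)s * K,
                   z1a.data() + (size_t)s * K * l,
                   cat2a.data() + (size_t)s * K * 2 * l,
                   dWv.data(), sbar,
                   gW.data(), gWm1.data(), gbm1.data(), gWm2.data(), &gbm2,
                   gWf.data(), gbf.data());
    } else {
      for (size_t x = 0; x < (size_t)K * l; ++x) gW[x] += dWv[x];
    }
  }

  // repack gradients to R conventions
  NumericMatrix outWf(K, fp.fw), outW(K, l), outWm1(l, 2 * l);
  for (int k = 0; k < K; ++k)
    for (int u = 0; u < fp.fw; ++u) outWf(k, u) = gWf[(size_t)k * fp.fw + u];
  for (int k = 0; k < K; ++k)
    for (int p = 0; p < l; ++p) outW(k, p) = gW[(size_t)k * l + p];
  for (int i = 0; i < 2 * l; ++i)
    for (int o = 0; o < l; ++o) outWm1(o, i) = gWm1[(size_t)i * l + o];
  NumericVector outw((R_xlen_t)mapSz);
  double* op = outw.begin();
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < C; ++c) {
      double* col = op + ((size_t)t * C + c) * K;
      for (int k = 0; k < K; ++k)
        col[k] = gw[((size_t)k * C + c) * T + t];
    }
  outw.attr("dim") = IntegerVector::create(K, C, T);

  // reported batch mean includes the per-scale bias
  NumericVector outMu(K), outVar(K);
  for (int k = 0; k < K; ++k) { outMu[k] = mu[k] + fp.bv[k]; outVar[k] = var[k]; }

  return List::create(
    _["loss"] = loss,
    _["logits"] = NumericVector(logits.begin(), logits.end()),
    _["batchMean"] = outMu,
    _["batchVar"] = outVar,
    _["grads"] = List::create(
      _["Wf"] = outWf, _["bf"] = NumericVector(gbf.begin(), gbf.end()),
      _["W"] = outW, _["bv"] = NumericVector(gbv.begin(), gbv.end()),
      _["Wm1"] = outWm1, _["bm1"] = NumericVector(gbm1.begin(), gbm1.end()),
      _["Wm2"] = NumericVector(gWm2.begin(), gWm2.end()), _["bm2"] = gbm2,
      _["gamma"] = NumericVector(ggamma.begin(), ggamma.end()),
      _["beta"] = NumericVector(gbeta.begin(), gbeta.end()),
      _["w"] = outw, _["b"] = gb));
}

// evaluation-mode logits (running BN statistics, no dropout)
// [[Rcpp::export(name = ".batchLogits")]]
NumericVector batchLogits(SEXP xptr, IntegerVector idx, List params, List cfg) {
  XPtr<PackedEpochs> pk(xptr);
  const int C = pk->C, T = pk->T;
  const int P = as<int>(cfg["P"]);
  const float lambda = (float)as<double>(cfg["lambda"]);
  const bool masked = as<bool>(cfg["masked"]);
  FloatParams fp;
  loadParams(params, C, T, fp);
  const int K = fp.K, l = fp.l;
  if (l != pk->l) stop("packed kernel length mismatch");
  const long Tp = (long)T + l;
  const size_t CT = (size_t)C * T;
  std::vector<float> D((size_t)K * CT), cat2((size_t)K * 2 * l),
      z1((size_t)K * l), r(K), M((size_t)K * l), Wv((size_t)K * l);
  NumericVector out(idx.size());
  for (R_xlen_t s = 0; s < idx.size(); ++s) {
    const long i0 = idx[s] - 1;
    if (i0 < 0 || i0 >= pk->n) stop("trial index out of range");
    const float* Sp = pk->S.data() + (size_t)i0 * C * Tp;
    const float* kernels;
    if (masked) {
      const float* sbar = pk->Sbar.data() + (size_t)i0 * (T + 2 * pk->h);
      maskForward(fp, sbar, P, lambda, cat2.data(), z1.data(), r.data(),
                  M.data(), Wv.data());
      kernels = Wv.data();
    } else {
      kernels = fp.W.data();
    }
    conv_fwd(Sp, kernels, D.data(), C, T, l, K, Tp);
    double acc = fp.b;
    for (int k = 0; k < K; ++k) {
      // D lacks the bias bv; shift the running mean instead
      const float mk = fp.runMean[k] - fp.bv[k];
      const float ik = (float)(1.0 / std::sqrt((double)fp.runVar[k] + BN_EPS));
      acc += map_logit(D.data() + (size_t)k * CT, fp.w.data() + (size_t)k * CT,
                       nullptr, CT, fp.gamma[k], fp.beta[k], mk, ik);
    }
    out[s] = acc;
  }
  return out;
}
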
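#ifndef SPIKEVERIFY_SOLVERS_H
#define SPIKEVERIFY_SOLVERS_H

#include "qformat.h"

// variant 0: grid Euler (threshold at grid point, v in two 0.5 ms half-steps,
//            u in one full step, symplectic ordering)
// variant 1: sub-stepped symplectic Euler (substeps per 1 ms grid step);
//            precise -> threshold tested and reset after every substep
struct SolverCfg {
  int variant;
  int substeps;
  bool precise;
  bool fxp;
  bool prescaled;   // fixed point only: evaluate 0.04*v^2 as ((10.24*v)*2^-8)*v
};

static inline double izh_rhs_v(double v, double u, double I) {
  return 0.04 * (v * v) + 5.0 * v + 140.0 - u + I;
}

static inline bool step_float(double& v, double& u, double I,
                              double a, double b, double c, double d,
                              double theta, const SolverCfg& cfg) {
  bool spiked = false;
  if (cfg.variant == 0) {
    if (v >= theta) { v = c; u += d; spiked = true; }
    v += 0.5 * izh_rhs_v(v, u, I);
    v += 0.5 * izh_rhs_v(v, u, I);
    u += a * (b * v - u);
    return spiked;
  }
  double h = (cfg.substeps == 16) ? 0.0625 : 1.0 / cfg.substeps;
  if (!cfg.precise && v >= theta) { v = c; u += d; spiked = true; }
  for (int k = 0; k < cfg.substeps; k++) {
    v += h * izh_rhs_v(v, u, I);
    u += h * (a * (b * v - u));
    if (cfg.precise && v >= theta) { v = c; u += d; spiked = true; }
  }
  return spiked;
}

// All state and constants as s16.15 raw words; overflow wraps and is counted.
struct FxpConsts {
  int f;
  int64_t h;              // enc(1/substeps)
  int64_t c04, c1024;     // enc(0.04) and enc(10.24)
  int64_t five, c140, theta, c, d;
  int64_t a_, b_;         // prescaled: pre-scaled by 2^8, compensated by asr(.,8)
};

static inline FxpConsts make_fxp_consts(double a, double b, double c, double d,
                                        double theta, int substeps, bool prescaled) {
  FxpConsts K;
  K.f = 15;
  long long dummy = 0;
  K.h = q_encode1(1.0 / substeps, 15, false, &dummy);
  K.c04 = q_encode1(0.04, 15, false, &dummy);
  K.c1024 = q_encode1(10.24, 15, false, &dummy);
  K.five = q_encode1(5.0, 15, false, &dummy);
  K.c140 = q_encode1(140.0, 15, false, &dummy);
  K.theta = q_encode1(theta, 15, false, &dummy);
  K.c = q_encode1(c, 15, false, &dummy);
  K.d = q_encode1(d, 15, false, &dummy);
  if (prescaled) {
    K.a_ = q_encode1(a * 256.0, 15, false, &dummy);
    K.b_ = q_encode1(b * 256.0, 15, false, &dummy);
  } else {
    K.a_ = q_encode1(a, 15, false, &dummy);
    K.b_ = q_encode1(b, 15, false, &dummy);
  }
  return K;
}

static inline bool step_fxp(int64_t& v, int64_t& u, int64_t I,
                            const FxpConsts& K, const SolverCfg& cfg,
                            long long* wraps) {
  bool spiked = false;
  if (!cfg.precise && v >= K.theta) {
    v = K.c; u = wrap32(u + K.d, wraps); spiked = true;
  }
  for (int k = 0; k < cfg.substeps; k++) {
    int64_t quad;
    if (cfg.prescaled) {
      int64_t t1 = q_mul1(K.c1024, v, K.f, wraps);
      int64_t t2 = asr(t1, 8);
      quad = q_mul1(t2, v, K.f, wraps);
    } else {
      quad = q_mul1(q_mul1(K.c04, v, K.f, wraps), v, K.f, wraps);
    }
    int64_t dv = wrap32(quad + q_mul1(K.five, v, K.f, wraps), wraps);
    dv = wrap32(dv + K.c140, wraps);
    dv = wrap32(dv - u, wraps);
    dv = wrap32(dv + I, wraps);
    v = wrap32(v + q_mul1(K.h, dv, K.f, wraps), wraps);
    int64_t bv = cfg.prescaled ? asr(q_mul1(K.b_, v, K.f, wraps), 8)
                         : q_mul1(K.b_, v, K.f, wraps);
    int64_t diff = wrap32(bv - u, wraps);
    int64_t du = cfg.prescaled ? asr(q_mul1(K.a_, diff, K.f, wraps), 8)
                         : q_mul1(K.a_, diff, K.f, wraps);
    u = wrap32(u + q_mul1(K.h, du, K.f, wraps), wraps);
    if (cfg.precise && v >= K.theta) {
      v = K.c; u = wrap32(u + K.d, wraps); spiked = true;
    }
  }
  return spiked;
}

#endif
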
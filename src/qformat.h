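#ifndef SPIKEVERIFY_QFORMAT_H
#define SPIKEVERIFY_QFORMAT_H

#include <cstdint>
#include <cmath>

// Reduce modulo 2^32 into the signed 32-bit range; counts wrap events.
static inline int64_t wrap32(int64_t x, long long* wraps) {
  int64_t y = x & 0xFFFFFFFFLL;          // low 32 bits, in [0, 2^32)
  if (y > 2147483647LL) y -= 4294967296LL;
  if (y != x && wraps) (*wraps)++;
  return y;
}

// Arithmetic right shift: floor division by 2^n, sign preserving.
static inline int64_t asr(int64_t x, int n) {
  int64_t d = (int64_t)1 << n;
  int64_t q = x / d;
  if ((x % d != 0) && (x < 0)) q--;
  return q;
}

// Float -> raw word. Default truncates toward zero (C cast semantics);
// floor_mode truncates toward -Inf. Out-of-range values wrap, never saturate.
static inline int64_t q_encode1(double x, int frac_bits, bool floor_mode,
                                long long* wraps) {
  double scaled = x * std::ldexp(1.0, frac_bits);
  double t = floor_mode ? std::floor(scaled) : std::trunc(scaled);
  if (std::fabs(t) >= 9.0e18) {
    const double m = 4294967296.0;   // keep the cast to int64 well-defined
    t -= std::floor(t / m) * m;
  }
  return wrap32((int64_t)t, wraps);
}

// Raw multiply: exact 64-bit product, arithmetic shift by f, wrap to 32 bits.
static inline int64_t q_mul1(int64_t a, int64_t b, int frac_bits,
                             long long* wraps) {
  return wrap32(asr(a * b, frac_bits), wraps);
}

#endif
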
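// Emulation of 32-bit signed fixed-point (Q-format) arithmetic with
// non-saturating wrap-around overflow, as found on integer-only
// neuromorphic ARM cores. Raw words are carried in R doubles (exact for
// 32-bit integers) and manipulated here as int64_t.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include "qformat.h"

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_q_encode(NumericVector x, int frac_bits, bool floor_mode) {
  int n = x.size();
  NumericVector raw(n);
  long long wraps = 0;
  for (int i = 0; i < n; i++)
    raw[i] = (double)q_encode1(x[i], frac_bits, floor_mode, &wraps);
  return List::create(_["raw"] = raw, _["wraps"] = (double)wraps);
}

// [[Rcpp::export]]
List cpp_q_add(NumericVector a, NumericVector b) {
  int n = a.size();
  NumericVector raw(n);
  long long wraps = 0;
  for (int i = 0; i < n; i++)
    raw[i] = (double)wrap32((int64_t)a[i] + (int64_t)b[i], &wraps);
  return List::create(_["raw"] = raw, _["wraps"] = (double)wraps);
}

// [[Rcpp::export]]
List cpp_q_mul(NumericVector a, NumericVector b, int frac_bits) {
  int n = a.size();
  NumericVector raw(n);
  long long wraps = 0;
  for (int i = 0; i < n; i++)
    raw[i] = (double)q_mul1((int64_t)a[i], (int64_t)b[i], frac_bits, &wraps);
  return List::create(_["raw"] = raw, _["wraps"] = (double)wraps);
}

// [[Rcpp::export]]
NumericVector cpp_q_shr(NumericVector a, int nbits) {
  int n = a.size();
  NumericVector raw(n);
  for (int i = 0; i < n; i++)
    raw[i] = (double)asr((int64_t)a[i], nbits);
  return raw;
}
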
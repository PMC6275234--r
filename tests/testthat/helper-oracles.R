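# Independent oracles used across the test suite. These deliberately share
# no code with the package internals.

# Exact mod-2^32 integer arithmetic on doubles via 16-bit limb splitting.
# Raw words are 32-bit signed integers carried in doubles; all intermediate
# limb products stay below 2^53, so every double operation here is exact.
oracle_to_unsigned <- function(x) ifelse(x < 0, x + 2^32, x)
oracle_to_signed <- function(x) ifelse(x > 2^31 - 1, x - 2^32, x)

oracle_add32 <- function(a, b) {
  s <- (oracle_to_unsigned(a) + oracle_to_unsigned(b)) %% 2^32
  oracle_to_signed(s)
}

# floor((a * b) / 2^f) mod 2^32, signed: compute the unsigned 64-bit-style
# product limb by limb, apply two's-complement sign handling, then shift.
oracle_mul32 <- function(a, b, f) {
  neg <- xor(a < 0, b < 0)
  ua <- abs(a); ub <- abs(b)
  a_lo <- ua %% 2^16; a_hi <- (ua - a_lo) / 2^16
  b_lo <- ub %% 2^16; b_hi <- (ub - b_lo) / 2^16
  # |a*b| = a_hi*b_hi*2^32 + (a_hi*b_lo + a_lo*b_hi)*2^16 + a_lo*b_lo,
  # assembled in pieces so no double exceeds 2^53
  mid <- a_hi * b_lo + a_lo * b_hi
  mid_lo <- mid %% 2^16; mid_hi <- (mid - mid_lo) / 2^16
  lo <- a_lo * b_lo + mid_lo * 2^16          # < 2^33
  carry <- floor(lo / 2^32)
  lo <- lo - carry * 2^32
  hi <- a_hi * b_hi + mid_hi + carry         # < 2^32
  # |p| = hi*2^32 + lo with hi < 2^32, lo < 2^32. Since 2^(32-f) is an
  # integer, floor(|p|/2^f) = hi*2^(32-f) + floor(lo/2^f)  (< 2^49, exact).
  # Arithmetic shift of a negative product is floor division:
  # floor(-|p|/2^f) = -ceil(|p|/2^f) = -floor((|p| + 2^f - 1)/2^f).
  q <- numeric(length(a))
  for (i in seq_along(a)) {
    if (!neg[i]) {
      qi <- hi[i] * 2^(32 - f) + floor(lo[i] / 2^f)
    } else {
      num_lo <- lo[i] + (2^f - 1)
      c2 <- floor(num_lo / 2^32)
      num_lo <- num_lo - c2 * 2^32
      qi <- -((hi[i] + c2) * 2^(32 - f) + floor(num_lo / 2^f))
    }
    q[i] <- oracle_to_signed(qi %% 2^32)
  }
  q
}

# Plain forward Euler at a very fine step as a brute-force integration
# oracle for first-spike times (threshold reset included).
oracle_fine_euler <- function(params, I, duration, h, v0, u0) {
  n <- ceiling(duration / h)
  v <- v0; u <- u0
  spikes <- numeric(0)
  for (k in seq_len(n)) {
    v <- v + h * (0.04 * v^2 + 5 * v + 140 - u + I)
    u <- u + h * (params$a * (params$b * v - u))
    if (v >= params$theta) {
      spikes <- c(spikes, k * h)
      v <- params$c
      u <- u + params$d
    }
  }
  spikes
}

# tiny hand-rolled Poisson/regular generators are not needed: the package's
# fixture generators are themselves under test against analytic expectations

rs_params <- function() spikeverify::izh_params("rs")

# protocol used for the single-neuron timing comparisons: start from the
# post-reset state so the recording does not open with an onset spike
protocol_init <- function(params) {
  list(v0 = params$c, u0 = params$b * params$c + params$d)
}
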
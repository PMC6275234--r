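#' Signed 32-bit fixed-point (Q) formats
#'
#' A Q-format splits a 32-bit two's-complement word into `int_bits` integer
#' bits, `frac_bits` fraction bits and one sign bit. The two formats used on
#' SpiNNaker-style integer cores are `s16.15` (the native accum type) and
#' `s8.23` (higher fractional precision, narrower range). A stored word
#' `raw` represents the value `raw * 2^-frac_bits`; arithmetic is carried
#' out on the raw words as plain integer arithmetic and wraps around on
#' overflow (no saturation).
#'
#' @param int_bits integer bits \eqn{i}.
#' @param frac_bits fraction bits \eqn{f}; `int_bits + frac_bits + 1` must
#'   equal 32.
#' @return An object of class `qformat`.
#' @examples
#' qformat(16, 15)   # s16.15
#' q_range(qformat(8, 23))
#' @export
qformat <- function(int_bits, frac_bits) {
  int_bits <- as.integer(int_bits)
  frac_bits <- as.integer(frac_bits)
  if (length(int_bits) != 1L || length(frac_bits) != 1L ||
      is.na(int_bits) || is.na(frac_bits) ||
      int_bits < 0L || frac_bits < 0L)
    stop("int_bits and frac_bits must be single non-negative integers")
  if (int_bits + frac_bits + 1L != 32L)
    stop("invalid Q format: int_bits + frac_bits + 1 must equal 32, got ",
         int_bits + frac_bits + 1L, " bits")
  structure(list(int_bits = int_bits, frac_bits = frac_bits),
            class = "qformat")
}

#' @rdname qformat
#' @export
q_s16_15 <- function() qformat(16L, 15L)

#' @rdname qformat
#' @export
q_s8_23 <- function() qformat(8L, 23L)

#' @export
print.qformat <- function(x, ...) {
  r <- q_range(x)
  cat(sprintf("s%d.%d fixed-point format, range [%.10g, %.10g]\n",
              x$int_bits, x$frac_bits, r[1], r[2]))
  invisible(x)
}

as_qformat <- function(fmt) {
  if (inherits(fmt, "qformat")) return(fmt)
  stop("'fmt' must be a qformat object")
}

#' Representable range of a Q format
#'
#' The closed range of an `s i.f` format is \eqn{[-2^i, 2^i - 2^{-f}]}.
#'
#' @param fmt a [qformat()].
#' @return Numeric vector `c(min, max)`.
#' @export
q_range <- function(fmt) {
  fmt <- as_qformat(fmt)
  c(-2^fmt$int_bits, 2^fmt$int_bits - 2^-fmt$frac_bits)
}

new_qvalue <- function(raw, fmt) {
  structure(list(raw = as.numeric(raw), fmt = fmt), class = "qvalue")
}

#' Fixed-point values
#'
#' `q_encode()` converts real numbers to fixed point by scaling with
#' `2^frac_bits` and truncating the fraction (toward zero by default,
#' matching a C float-to-integer cast; `round = "floor"` truncates toward
#' `-Inf`). Values outside the representable range wrap around modulo
#' `2^32` -- this non-saturating behaviour is deliberate, since it is what
#' the emulated hardware does. `q_decode()` returns `raw * 2^-frac_bits`
#' exactly. The raw words round-trip: `q_encode(q_decode(q), fmt)`
#' reproduces an identical word.
#'
#' @param x numeric vector of finite values.
#' @param fmt a [qformat()].
#' @param round truncation direction for the fractional part.
#' @param q a `qvalue`.
#' @return `q_encode()` a `qvalue` (vectorized raw words); `q_decode()` a
#'   numeric vector.
#' @examples
#' q_decode(q_encode(0.04, q_s16_15()))   # 1310/32768 = 0.03997802...
#' @export
q_encode <- function(x, fmt, round = c("trunc", "floor")) {
  fmt <- as_qformat(fmt)
  round <- match.arg(round)
  if (any(!is.finite(x))) stop("x must be finite")
  res <- cpp_q_encode(as.numeric(x), fmt$frac_bits, round == "floor")
  q_count_wraps(res$wraps)
  new_qvalue(res$raw, fmt)
}

#' @rdname q_encode
#' @export
q_decode <- function(q) {
  stopifnot(inherits(q, "qvalue"))
  q$raw * 2^-q$fmt$frac_bits
}

#' @rdname q_encode
#' @export
q_raw <- function(q) {
  stopifnot(inherits(q, "qvalue"))
  q$raw
}

#' @export
print.qvalue <- function(x, ...) {
  cat(sprintf("qvalue (s%d.%d)\n", x$fmt$int_bits, x$fmt$frac_bits))
  show <- utils::head(seq_along(x$raw), 10L)
  cat(sprintf("  %s  raw %12.0f  = %.10g\n",
              q_hex(x)[show], x$raw[show], q_decode(x)[show]), sep = "")
  if (length(x$raw) > 10L) cat("  ...\n")
  invisible(x)
}

#' Hexadecimal rendering of raw fixed-point words
#'
#' @param q a `qvalue`.
#' @return Character vector of `0x`-prefixed 8-digit words, e.g.
#'   `"0x0000051E"` for 0.04 in s16.15.
#' @export
q_hex <- function(q) {
  stopifnot(inherits(q, "qvalue"))
  raw <- ifelse(q$raw < 0, q$raw + 2^32, q$raw)
  hi <- floor(raw / 65536)
  lo <- raw - hi * 65536
  sprintf("0x%04X%04X", as.integer(hi), as.integer(lo))
}

check_same_fmt <- function(a, b) {
  stopifnot(inherits(a, "qvalue"), inherits(b, "qvalue"))
  if (a$fmt$int_bits != b$fmt$int_bits || a$fmt$frac_bits != b$fmt$frac_bits)
    stop("operands have different Q formats")
}

#' Fixed-point arithmetic on raw words
#'
#' `q_add()` adds the raw words and reduces modulo `2^32`; `q_mul()` forms
#' the exact 64-bit product of the raw words, shifts it arithmetically right
#' by `frac_bits` (truncation toward `-Inf` on the raw word) and wraps the
#' result to 32 bits; `q_shr(a, n)` is a sign-preserving arithmetic right
#' shift, i.e. multiplication by `2^-n`. None of these saturate: an
#' overflow wraps around, exactly as on the emulated hardware, and is
#' tallied by the diagnostic counter (see [q_wrap_counter()]). Because the
#' product is truncated, `q_mul()` is not associative; expressions are
#' evaluated in precisely the order written by the caller.
#'
#' @param a,b `qvalue` operands of identical format.
#' @param n shift amount, `0 <= n <= 31`.
#' @return A `qvalue`.
#' @examples
#' f <- q_s16_15()
#' q_decode(q_mul(q_encode(300, f), q_encode(300, f)))  # wraps: -41072
#' @export
q_add <- function(a, b) {
  check_same_fmt(a, b)
  res <- cpp_q_add(a$raw, b$raw)
  q_count_wraps(res$wraps)
  new_qvalue(res$raw, a$fmt)
}

#' @rdname q_add
#' @export
q_mul <- function(a, b) {
  check_same_fmt(a, b)
  res <- cpp_q_mul(a$raw, b$raw, a$fmt$frac_bits)
  q_count_wraps(res$wraps)
  new_qvalue(res$raw, a$fmt)
}

#' @rdname q_add
#' @export
q_shr <- function(a, n) {
  stopifnot(inherits(a, "qvalue"))
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L || n > 31L)
    stop("n must be a single integer in [0, 31]")
  new_qvalue(cpp_q_shr(a$raw, n), a$fmt)
}

.qstate <- new.env(parent = emptyenv())
.qstate$wraps <- 0

q_count_wraps <- function(k) {
  .qstate$wraps <- .qstate$wraps + k
  invisible(k)
}

#' Diagnostic overflow counter
#'
#' Fixed-point overflow never raises an error (wrap-around is the defined
#' behaviour), but every wrap event in [q_encode()], [q_add()] and
#' [q_mul()] increments a package-level counter, so that tests and demos
#' can show where the wrap artifacts come from.
#'
#' @param reset if `TRUE`, zero the counter after reading it.
#' @return The number of wrap events since the last reset.
#' @export
q_wrap_counter <- function(reset = FALSE) {
  k <- .qstate$wraps
  if (reset) .qstate$wraps <- 0
  k
}
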
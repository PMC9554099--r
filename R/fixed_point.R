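# 24-bit sign-magnitude fixed point: 1 sign bit, 7 integer bits, 16 fraction
# bits. Value = (-1)^sign * (integer + fraction/2^16). All rounding is
# truncation toward zero (what a right-shifting barrel shifter does);
# out-of-range values saturate at the maximum magnitude, never wrap.

FX_FRAC_BITS <- 16L
FX_SCALE <- 65536          # 2^16
FX_MAX_RAW <- 8388607      # 2^23 - 1, maximum magnitude in raw units

#' Quantize real values to the 24-bit fixed-point lattice
#'
#' The workhorse of the hardware backend: maps each value to the nearest
#' representable fixed-point value in the direction of zero (truncation),
#' saturating at the largest representable magnitude
#' (127 + 65535/65536). Results are returned as ordinary doubles whose
#' values are exact multiples of 2^-16; every arithmetic intermediate of
#' the hardware backend is passed through this function.
#'
#' @param x numeric vector.
#' @return numeric vector of quantized values.
#' @export
#' @examples
#' fx_quantize(0.1) * 2^16 # 6553, truncated from 6553.6
fx_quantize <- function(x) {
  raw <- trunc(x * FX_SCALE)
  raw <- pmin(pmax(raw, -FX_MAX_RAW), FX_MAX_RAW)
  raw / FX_SCALE
}

#' Encode real values as 24-bit sign-magnitude fixed point
#'
#' Splits each value into the sign bit, the 7-bit unsigned integer part and
#' the 16-bit fraction numerator. Rounding is truncation toward zero;
#' values beyond the representable range saturate. Negative zero (and any
#' negative value that truncates to zero) normalizes to +0.
#'
#' @param x finite numeric vector.
#' @return An object of class `fixed_point24`: a list with integer vectors
#'   `sign`, `integer` (0..127) and `fraction` (0..65535).
#' @export
#' @examples
#' fx_encode(1.5)   # sign 0, integer 1, fraction 32768
#' fx_encode(-0.75) # sign 1, integer 0, fraction 49152
fx_encode <- function(x) {
  if (!all(is.finite(x))) stop("fx_encode: all inputs must be finite")
  raw <- pmin(trunc(abs(x) * FX_SCALE), FX_MAX_RAW)
  sign <- as.integer(x < 0 & raw > 0)
  structure(list(sign = sign,
                 integer = as.integer(raw %/% FX_SCALE),
                 fraction = as.integer(raw %% FX_SCALE)),
            class = "fixed_point24")
}

#' Decode 24-bit sign-magnitude fixed point to real values
#'
#' @param v a `fixed_point24` object (or a list with `sign`, `integer`,
#'   `fraction` fields).
#' @return numeric vector: `(-1)^sign * (integer + fraction/2^16)`, exact.
#' @export
#' @examples
#' fx_decode(fx_encode(1.5)) # 1.5
fx_decode <- function(v) {
  stopifnot(all(v$sign %in% 0:1),
            all(v$integer >= 0 & v$integer <= 127),
            all(v$fraction >= 0 & v$fraction <= FX_SCALE - 1))
  (-1)^v$sign * (v$integer + v$fraction / FX_SCALE)
}

#' @export
print.fixed_point24 <- function(x, ...) {
  n <- length(x$sign)
  cat(sprintf("<fixed_point24[%d]>\n", n))
  print(data.frame(sign = x$sign, integer = x$integer,
                   fraction = x$fraction, value = fx_decode(x)))
  invisible(x)
}

#' Shift-add multiplication of two fixed-point variables
#'
#' Emulates the shift-multiplier circuit: the integer and sign bits of `a`
#' are dropped, its 16 fraction bits are split on a bus, and for each set
#' bit `b` is shifted right by that bit's position (1 for the most
#' significant fraction bit through 16 for the least significant), each
#' shift truncating toward zero. The gated shifts are summed in a parallel
#' adder and the result saturates on overflow. `a` is therefore expected in
#' `[0, 1)` for an exact-to-truncation product; the result carries the sign
#' of `b`.
#'
#' @param a,b numeric vectors (recycled); interpreted as fixed-point values.
#' @return numeric vector of fixed-point products.
#' @export
#' @examples
#' shift_mul(0.5, 0.5)  # 0.25 exactly
#' shift_mul(0.75, 1.0) # 0.75: (1 >> 1) + (1 >> 2)
shift_mul <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  a_frac <- trunc(abs(a) * FX_SCALE) %% FX_SCALE # integer+sign bits dropped
  b_raw <- pmin(trunc(abs(b) * FX_SCALE), FX_MAX_RAW)
  acc <- numeric(n)
  for (i in 1:16) {
    bit <- (a_frac %/% 2^(16 - i)) %% 2
    acc <- acc + bit * (b_raw %/% 2^i)
  }
  acc <- pmin(acc, FX_MAX_RAW)
  sign(b) * acc / FX_SCALE
}

# Constant-times-variable shift-add multiplier: the constant is decomposed
# into its fixed-point bits and the variable is shifted per set bit with
# truncation toward zero (left shifts for integer bits are exact). Used by
# the hardware backend wherever a variable meets a compile-time constant
# (PWL slopes, phi_max, 1/window scaling).
fx_const_mul <- function(const, v) {
  c_raw <- pmin(trunc(abs(const) * FX_SCALE), FX_MAX_RAW)
  v_raw <- pmin(trunc(abs(v) * FX_SCALE), FX_MAX_RAW)
  acc <- numeric(length(v))
  bits <- which((c_raw %/% 2^(0:23)) %% 2 == 1)
  for (bpos in bits) { # bpos in 1..24 -> bit value 2^(bpos-1) in raw units
    sh <- FX_FRAC_BITS - (bpos - 1L)
    acc <- acc + if (sh > 0) v_raw %/% 2^sh else v_raw * 2^(-sh)
  }
  acc <- pmin(acc, FX_MAX_RAW)
  sign(const) * sign(v) * acc / FX_SCALE
}
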
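# Deterministic 32-bit integer mixing used by the circular fingerprint.
#
# R has no native unsigned 32-bit arithmetic; products are formed in double
# precision on 16-bit halves so every intermediate stays below 2^53. The
# constants are the FNV-1a offset basis and prime. Output is folded to a
# non-negative 31-bit integer so it is storable in an R integer vector.

FNV_OFFSET <- 2166136261
FNV_PRIME <- 16777619
TWO32 <- 4294967296

mul_mod32 <- function(a, b) {
  # (a * b) mod 2^32 without loss of precision
  a_lo <- a %% 65536
  a_hi <- (a - a_lo) / 65536
  (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% TWO32
}

#' Hash a vector of non-negative integers to a 31-bit identifier
#'
#' FNV-1a over the 4 bytes of each value, in order. Deterministic across
#' platforms; used for circular-fingerprint atom identifiers.
#' @noRd
hash31 <- function(values) {
  h <- FNV_OFFSET
  for (v in values) {
    v <- v %% TWO32
    for (shift in c(1, 256, 65536, 16777216)) {
      byte <- (v %/% shift) %% 256
      h <- mul_mod32(bitwXor_dbl(h, byte), FNV_PRIME)
    }
  }
  h %% 2147483648
}

bitwXor_dbl <- function(a, b) {
  # xor of doubles holding values < 2^32
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}
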
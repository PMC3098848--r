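# Counter-based uniform random numbers (splitmix32).
#
# Simulated observers must be reproducible per trial: the draw for trial k
# depends only on (seed, k), never on how many draws happened before. That
# way reordering trials, or adding diagnostics that consume random numbers,
# cannot silently change an observer's responses. R's stream-based RNG cannot
# give that guarantee cheaply, so a small counter-based generator is used for
# observer decisions; heavyweight bulk noise (BOLD lattices) uses the regular
# R stream seeded once per call.
#
# All arithmetic is done in doubles; every intermediate stays below 2^53 so
# the 32-bit modular arithmetic is exact.

.TWO32 <- 4294967296 # 2^32
.GOLDEN32 <- 2654435769 # 0x9E3779B9, the splitmix increment

# (a * b) mod 2^32, exact for a, b in [0, 2^32)
.mul32 <- function(a, b) {
  a1 <- floor(a / 65536)
  a0 <- a - a1 * 65536
  (((a1 * b) %% 65536) * 65536 + a0 * b) %% .TWO32
}

# bitwise xor of values in [0, 2^32), via 16-bit halves
.xor32 <- function(a, b) {
  a1 <- floor(a / 65536); a0 <- a - a1 * 65536
  b1 <- floor(b / 65536); b0 <- b - b1 * 65536
  bitwXor(as.integer(a1), as.integer(b1)) * 65536 +
    bitwXor(as.integer(a0), as.integer(b0))
}

.shr32 <- function(x, k) floor(x / 2^k)

# splitmix32 finalizer
.mix32 <- function(z) {
  z <- .xor32(z, .shr32(z, 16))
  z <- .mul32(z, 569420461)  # 0x21f0aaad
  z <- .xor32(z, .shr32(z, 15))
  z <- .mul32(z, 1935289751) # 0x735a2d97
  .xor32(z, .shr32(z, 15))
}

#' Deterministic per-index uniform deviates
#'
#' Returns uniforms in (0, 1) that depend only on `seed` and `index`
#' (a counter such as a trial number), independent of R's RNG state and of
#' any draws made before. Used for all simulated-observer decisions.
#'
#' @param seed non-negative integer master seed.
#' @param index vector of non-negative counters (trial indices, possibly
#'   offset to carve out independent channels within a trial).
#' @return numeric vector of uniforms in (0, 1), same length as `index`.
#' @export
counter_uniform <- function(seed, index) {
  stopifnot(length(seed) == 1L, is.finite(seed), seed >= 0,
            all(is.finite(index)), all(index >= 0))
  x <- (seed %% .TWO32 + (index %% .TWO32) * .GOLDEN32) %% .TWO32
  (.mix32(x) + 0.5) / .TWO32
}

#' @rdname counter_uniform
#' @export
counter_norm <- function(seed, index) stats::qnorm(counter_uniform(seed, index))

#' Derive a child seed for an independent sub-stream
#'
#' Hashes (seed, index) to an integer below 2^31, giving each simulated
#' observer, run or repetition its own reproducible stream.
#'
#' @inheritParams counter_uniform
#' @return numeric vector of derived seeds in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, index) {
  floor(.mix32((seed %% .TWO32 + (index %% .TWO32) * .GOLDEN32) %% .TWO32) / 2)
}
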
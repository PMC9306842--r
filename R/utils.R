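#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"), which does
#' not reproduce the half-up convention used when reporting percentages and
#' ratios (e.g. 12.5% -> 13%, 0.625 -> 0.63). All user-facing rounding in
#' this package goes through this helper; internal arithmetic is always kept
#' at full double precision.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(12.5)        # 13, where round(12.5) gives 12
#' round_half_up(0.625, 2)    # 0.63
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a per-replicate RNG seed
#'
#' Deterministic mixing of a base seed and a replicate index so that
#' replicates are reproducible and mutually decorrelated. The result is
#' always a valid 32-bit integer seed.
#'
#' @param base_seed integer base seed.
#' @param index non-negative integer replicate index.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, index) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime used by Lehmer generators
  s <- (as.numeric(base_seed) %% m) * 48271 + (as.numeric(index) + 1) * 16807
  as.integer(s %% m)
}

# x^p with the convention 0^p = 0 for every p >= 0 (including p = 0).
# Rate factors k^p and (n(n-1))^p must vanish when no lineage of that class
# is present, not collapse to 1 at p = 0.
pow0 <- function(x, p) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos]^p
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gmyc <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "gmycsampler_error")))
}
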
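# internal helpers

.assertScalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  invisible(x)
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

# clamp progression values into [0, 1], reporting how many were moved
.clampProgression <- function(p, quiet = FALSE) {
  out <- sum(p < 0 | p > 1, na.rm = TRUE)
  if (out > 0 && !quiet)
    message(out, " progression value(s) clamped into [0, 1]")
  .clamp01(p)
}

# stable seed derivation for sub-stages; keeps results < 2^31
.deriveSeed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}

.upperTri <- function(m) m[upper.tri(m)]
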
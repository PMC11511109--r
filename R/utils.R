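# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "ppginv_invalid_input")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

check_finite_vector <- function(x, arg = "x") {
  if (!is.numeric(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a nonempty numeric vector.", arg),
          class = "ppginv_invalid_input")
  }
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    abort(sprintf("`%s` contains a non-finite value at index %d.", arg, bad[1L]),
          class = "ppginv_invalid_input")
  }
  invisible(x)
}

check_scalar_in <- function(x, lo, hi, arg, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%s, %s%s.",
                  arg, if (open) "(" else "[", format(lo), format(hi),
                  if (open) ")" else "]"),
          class = "ppginv_invalid_input")
  }
  invisible(x)
}

# Least-squares amplitude of a sinusoid of known frequency; used by the
# filter-contract tests and exported for reuse there.
fit_tone_amplitude <- function(y, t, freq) {
  m <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- qr.solve(m, y)
  sqrt(sum(cf^2))
}
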
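# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a fixed RNG state when seed is given, without disturbing the
# caller's stream otherwise
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_domain <- function(...) stop(..., call. = FALSE)

assert_finite_numeric <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_domain(name, " must be finite numeric")
  }
  invisible(x)
}
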
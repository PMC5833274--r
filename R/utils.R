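# internal validation helpers ------------------------------------------------

stop_portalsim <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "portalsim_error"), ...)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    stop_portalsim(
      sprintf("`%s` must be a single finite number in %s%s, %s%s (got %s)",
              name, if (strict_lower) "(" else "[", format(lower),
              format(upper), if (strict_upper) ")" else "]",
              paste(format(x), collapse = ", ")),
      class = "portalsim_invalid_argument"
    )
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_portalsim(sprintf("`%s` must be TRUE or FALSE", name),
                   class = "portalsim_invalid_argument")
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG state when `seed` is given, leaving the
# caller's RNG untouched; fall back to the ambient RNG when seed is NULL.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive reproducible child seeds from a parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n)))
}

unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop_portalsim("direction vector must be non-zero",
                              class = "portalsim_invalid_argument")
  v / nv
}

# sample standard deviation (n - 1 denominator), NA-safe
sample_sd <- function(x) stats::sd(x)
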
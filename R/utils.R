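# Condition-signalling helpers. Every user-visible failure carries a class so
# callers (and the command-line wrapper) can map it to an exit code:
#   config/usage problems -> "tempodiff_config_error" / "tempodiff_parse_error"
#   bad data values       -> "tempodiff_data_error"
#   inconsistent design   -> "tempodiff_design_error"

stop_config <- function(msg, ...) {
  abort(msg, class = "tempodiff_config_error", ...)
}

stop_data <- function(msg, ...) {
  abort(msg, class = "tempodiff_data_error", ...)
}

stop_design <- function(msg, ...) {
  abort(msg, class = "tempodiff_design_error", ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = "tempodiff_parse_error", ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_count <- function(x) {
  is_scalar_number(x) && x >= 0 && x == floor(x)
}

# Run an expression with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Row-wise sample variance of a numeric matrix (denominator ncol - 1).
row_vars <- function(m, population = FALSE) {
  n <- ncol(m)
  mu <- rowMeans(m)
  ss <- rowSums((m - mu)^2)
  ss / (if (population) n else n - 1L)
}

loguniform <- function(n, lo, hi) {
  exp(runif(n, log(lo), log(hi)))
}
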
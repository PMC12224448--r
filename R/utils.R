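`%||%` <- function(a, b) if (is.null(a)) b else a

# standardize a vector; errors on zero variance unless allow_constant
std1 <- function(x, what = "vector") {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps^0.5) {
    stop("cannot standardize near-constant ", what, call. = FALSE)
  }
  (x - mean(x)) / s
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# deterministic child seeds below 2^31, derived from a parent seed
child_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647
}

assert_cols <- function(df, cols, where = "data") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("missing columns in ", where, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
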
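# Internal helpers shared across modules.

# Centered moving average with a window that shrinks at the edges: frame i
# averages over [i - h, i + h] intersected with the series, h = (w - 1)/2.
rolling_mean_centered <- function(x, w = 3L) {
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) {
    abort("`smooth_window` must be a positive odd integer.", class = "mgca_parameter_error")
  }
  n <- length(x)
  if (w == 1L || n == 0L) {
    return(x)
  }
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Validate a strictly increasing, uniform time grid (relative tol on the step).
check_uniform_time <- function(time, rel_tol = 1e-6, what = "time") {
  if (length(time) >= 2L) {
    dt <- diff(time)
    if (any(dt <= 0)) {
      abort(sprintf("`%s` must be strictly increasing.", what), class = "mgca_timing_error")
    }
    if ((max(dt) - min(dt)) > rel_tol * median(dt)) {
      abort(sprintf("`%s` must be uniformly spaced (relative tolerance %g).", what, rel_tol),
            class = "mgca_timing_error")
    }
  }
  invisible(time)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar.", name),
          class = "mgca_parameter_error")
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a non-negative finite scalar.", name),
          class = "mgca_parameter_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.", what,
                  paste0("`", missing, "`", collapse = ", ")),
          class = "mgca_schema_error")
  }
  invisible(df)
}

# Run `expr` under a seed without disturbing the caller's RNG state; a NULL
# seed uses (and advances) the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Euclidean norm of rows of a 2-column matrix.
row_norm <- function(m) sqrt(m[, 1L]^2 + m[, 2L]^2)
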
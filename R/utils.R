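# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(...) {
  stop(paste0(...), call. = FALSE)
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input(name, " must be a single finite number")
  }
  if (x < lo || x > hi) {
    abort_input(name, " must be in [", lo, ", ", hi, "], got ", x)
  }
  invisible(x)
}

assert_increasing <- function(x, name, strict = TRUE) {
  d <- diff(x)
  ok <- if (strict) all(d > 0) else all(d >= 0)
  if (!ok) abort_input(name, " must be ", if (strict) "strictly ", "increasing")
  invisible(x)
}

# Run code under a fixed RNG state without touching the caller's stream.
with_seed <- function(seed, code) {
  assert_scalar_num(seed, "seed")
  withr::with_seed(as.integer(seed), code)
}

# Ordinary least squares y ~ x returning slope, se, r2 without lm() overhead.
ols_line <- function(x, y) {
  n <- length(x)
  if (n < 2L) {
    return(list(slope = NA_real_, intercept = NA_real_, se = NA_real_, r2 = NA_real_, n = n))
  }
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) {
    return(list(slope = NA_real_, intercept = my, se = NA_real_, r2 = NA_real_, n = n))
  }
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  se <- if (n > 2L) sqrt(sum(res^2) / (n - 2L) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, se = se, r2 = r2, n = n)
}

# Centered moving average, window must be odd; edges use shrunken windows.
moving_average <- function(y, k) {
  if (k <= 1L) return(y)
  n <- length(y)
  half <- (k - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    out[i] <- mean(y[j])
  }
  out
}

# Single-trace accessor: accepts a one-trace tibble/data.frame with time_s and
# signal_au columns and validates the time axis.
check_assembly_trace <- function(trace) {
  if (!is.data.frame(trace)) abort_input("trace must be a data frame")
  if (!all(c("time_s", "signal_au") %in% names(trace))) {
    abort_input("trace must have columns time_s and signal_au")
  }
  if ("trace_id" %in% names(trace) && length(unique(trace$trace_id)) > 1L) {
    abort_input("trace contains more than one trace_id; supply a single trace")
  }
  assert_increasing(trace$time_s, "time_s")
  trace
}
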
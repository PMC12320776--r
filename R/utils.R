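#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Deterministic sub-seed derived from a parent seed and a stage label.
# Keeps one global seed fanning out to independent per-stage streams.
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}

# OLS slope of y on x; returns c(slope, intercept, r_squared).
ols_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate regressor: no variation in x")
  sxy <- sum((x - mx) * (y - my))
  b <- sxy / sxx
  a <- my - b * mx
  ss_res <- sum((y - a - b * x)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  c(slope = b, intercept = a, r_squared = r2)
}

# Smoothed derivative of a uniformly sampled series by local quadratic
# (Savitzky-Golay) filtering. order = 0 smooths, 1 first derivative,
# 2 second derivative; dt is the sampling interval in seconds.
sg_deriv <- function(x, dt, order = 1, window = 5, degree = 2) {
  stopifnot(window %% 2 == 1, window > degree, order <= degree)
  if (length(x) < window) {
    stop("series shorter than the smoothing window (", window, " samples)")
  }
  signal::sgolayfilt(x, p = degree, n = window, m = order, ts = dt)
}

# Truncate (not round) to a number of decimal places, as used for
# reporting frame-quantized latencies.
trunc_dp <- function(x, digits = 2) trunc(x * 10^digits) / 10^digits

`%||%` <- function(a, b) if (is.null(a)) b else a
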
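## Diel thermal-regime characterization.
##
## Hourly logger records are averaged across co-located loggers, pooled by
## hour of day for each site x month, and smoothed with a LOESS whose span
## and degree are chosen by k-fold cross-validation. Circular time is
## handled by replicating the data +/- 6 h beyond the day's edges before
## fitting. Cycle parameters (mean, extrema, their times, range) come from
## the smoothed curve; the thermal-volatility index is the hour-wise SD of
## the raw records around the smooth, signed by the mean residual.

#' Average loggers and pool records by hour of day
#'
#' @param logs A `temperature_log` data.frame (`site`, `month`, `logger_id`,
#'   `day`, `hour`, `temp_c`).
#' @param site,month Optional filters.
#' @return data.frame with `site`, `month`, `day`, `hour`, `temp_c`, one row
#'   per site x month x day x hour (mean across loggers).
#' @export
hourly_aggregate <- function(logs, site = NULL, month = NULL) {
  d <- logs
  if (!is.null(site)) d <- d[d$site %in% site, , drop = FALSE]
  if (!is.null(month)) d <- d[d$month %in% month, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for the requested site/month")
  agg <- stats::aggregate(temp_c ~ site + month + day + hour, data = d,
                          FUN = mean)
  agg[order(agg$site, agg$month, agg$day, agg$hour), , drop = FALSE]
}

#' Fit a cross-validated LOESS diel cycle
#'
#' Smooths pooled hourly records against hour of day with a tricube-weighted
#' local polynomial. The data are replicated 6 h beyond both edges of the
#' day (circular wrap) so the fit has no boundary bias at midnight. Span and
#' degree are chosen by `n_folds`-fold cross-validated squared prediction
#' error over `span_grid` x `degree_grid`.
#'
#' @param hourly Output of [hourly_aggregate()] for one site x month.
#' @param span_grid Candidate LOESS spans (default 0.2-0.9 by 0.1).
#' @param degree_grid Candidate local polynomial degrees (default 1:2).
#' @param n_folds Cross-validation folds (default 5).
#' @param grid_step Hour step of the evaluation grid (default 0.25 h).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `diel_cycle`: list with `hour_grid`,
#'   `smoothed` (deg C on the grid), `span`, `degree`, `cv_table`, `hourly`
#'   (the input records), `site`, `month`.
#' @export
fit_diel_loess <- function(hourly, span_grid = seq(0.2, 0.9, by = 0.1),
                           degree_grid = 1:2, n_folds = 5,
                           grid_step = 0.25, seed = 1) {
  if (length(unique(hourly$hour)) < 24) {
    stop("need records at all 24 hours of day after pooling")
  }
  set.seed(as.integer(seed))
  h <- hourly$hour
  y <- hourly$temp_c
  n <- length(y)
  # circular replication: copy the last 6 h before hour 0 and the first
  # 6 h after hour 23
  wrap <- function(hh, yy) {
    lo <- hh >= 18
    hi <- hh <= 5
    list(h = c(hh[lo] - 24, hh, hh[hi] + 24), y = c(yy[lo], yy, yy[hi]))
  }
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  cv <- expand.grid(span = span_grid, degree = degree_grid)
  cv$mse <- NA_real_
  for (i in seq_len(nrow(cv))) {
    err <- 0; m <- 0; ok <- TRUE
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      w <- wrap(h[tr], y[tr])
      fit <- tryCatch(
        suppressWarnings(stats::loess(
          y ~ h, data = data.frame(h = w$h, y = w$y),
          span = cv$span[i], degree = cv$degree[i],
          control = stats::loess.control(surface = "interpolate"))),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pred <- stats::predict(fit, newdata = data.frame(h = h[!tr]))
      err <- err + sum((y[!tr] - pred)^2, na.rm = TRUE)
      m <- m + sum(is.finite(pred))
    }
    cv$mse[i] <- if (ok && m > 0) err / m else NA_real_
  }
  if (all(is.na(cv$mse))) stop("no LOESS candidate could be fitted")
  best <- cv[which.min(cv$mse), ]
  w <- wrap(h, y)
  fit <- suppressWarnings(stats::loess(
    y ~ h, data = data.frame(h = w$h, y = w$y),
    span = best$span, degree = best$degree,
    control = stats::loess.control(surface = "interpolate")))
  hour_grid <- seq(0, 24 - grid_step, by = grid_step)
  smoothed <- stats::predict(fit, newdata = data.frame(h = hour_grid))
  structure(list(hour_grid = hour_grid, smoothed = as.numeric(smoothed),
                 span = best$span, degree = best$degree, cv_table = cv,
                 hourly = hourly,
                 site = hourly$site[1], month = hourly$month[1]),
            class = "diel_cycle")
}

#' Derived diel-cycle parameters
#'
#' Mean over the 24-h grid, extrema of the smoothed curve, their times
#' (rounded to the hour), and the daily range. A flat cycle (range below
#' `flat_tol`) is flagged and its extremum times set to `NA`.
#'
#' @param cycle A `diel_cycle`.
#' @param flat_tol Range below which the cycle counts as flat, deg C.
#' @return One-row data.frame: `site`, `month`, `mean_c`, `min_c`,
#'   `time_min_h`, `max_c`, `time_max_h`, `range_c`, `flat`.
#' @export
derive_cycle_params <- function(cycle, flat_tol = 1e-6) {
  s <- cycle$smoothed
  g <- cycle$hour_grid
  rng <- max(s) - min(s)
  flat <- rng < flat_tol
  data.frame(site = cycle$site, month = cycle$month,
             mean_c = mean(s), min_c = min(s),
             time_min_h = if (flat) NA_real_ else round(g[which.min(s)]) %% 24,
             max_c = max(s),
             time_max_h = if (flat) NA_real_ else round(g[which.max(s)]) %% 24,
             range_c = rng, flat = flat,
             stringsAsFactors = FALSE)
}

#' Thermal-volatility index
#'
#' For each hour of day, the SD of the raw hourly records around the
#' smoothed cycle, signed by the direction of the mean residual: positive
#' values indicate a tendency to run warmer than the smooth (warming risk),
#' negative values cooler. Hours where the mean residual is small relative
#' to its standard error are flagged low-confidence (the sign is unstable).
#'
#' @param cycle A `diel_cycle` (carries its raw hourly records).
#' @param sign_z Threshold on |mean residual| / SE below which the sign is
#'   flagged low-confidence (default 1).
#' @return data.frame: `hour`, `volatility_c` (signed), `sd_c`, `n`,
#'   `low_confidence`.
#' @export
volatility_index <- function(cycle, sign_z = 1) {
  h <- cycle$hourly$hour
  y <- cycle$hourly$temp_c
  pred <- stats::approx(cycle$hour_grid, cycle$smoothed, xout = h,
                        rule = 2)$y
  res <- y - pred
  out <- do.call(rbind, lapply(0:23, function(hr) {
    r <- res[h == hr]
    sdr <- stats::sd(r)
    mr <- mean(r)
    se <- sdr / sqrt(length(r))
    data.frame(hour = hr, volatility_c = sign(mr) * sdr, sd_c = sdr,
               n = length(r),
               low_confidence = is.finite(se) && se > 0 && abs(mr) / se < sign_z)
  }))
  out
}

#' Time per day spent inside a temperature window
#'
#' Measures how much of the smoothed 24-h cycle lies inside
#' `[lower, upper]` — typically the 80%-of-peak aerobic-scope breadth — in
#' hours per day and as a fraction.
#'
#' @param cycle A `diel_cycle`.
#' @param lower,upper Window bounds, deg C (`lower < upper`).
#' @return Named numeric: `hours`, `fraction`.
#' @export
time_in_breadth <- function(cycle, lower, upper) {
  if (lower >= upper) stop("need lower < upper")
  inside <- cycle$smoothed >= lower & cycle$smoothed <= upper
  step <- diff(cycle$hour_grid[1:2])
  hrs <- sum(inside) * step
  c(hours = hrs, fraction = hrs / 24)
}
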
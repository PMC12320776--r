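## Intermittent-flow respirometry: oxygen-uptake extraction.
##
## A 24-h trial on the 2-s / 5-min measure / 10-min flush schedule yields 96
## DO decline slopes per shark (4 per hour). Whole-animal uptake is the
## decline slope times the effective water volume; rates are mass-scaled by
## the intraspecific exponent 0.89. The trial minimum is the mean of the
## lowest 10% of determinations; the maximum is the steepest 30-s rolling
## regression within the first hour post-exercise.

#' Split a dissolved-oxygen trace into measurement windows
#'
#' Assigns samples to the measurement phases of the measure/flush schedule.
#' Windows are half-open `[start, start + measure_duration)`; flush-phase
#' samples are excluded and windows never straddle a flush.
#'
#' @param trace A `do_trace` (see [gen_do_trace()]) or a list with `time`,
#'   `do_conc` and `schedule`.
#' @return A list of data.frames (`time`, `do_conc`), one per window, with
#'   attribute `window_starts` (s).
#' @export
segment_cycles <- function(trace) {
  sch <- trace$schedule
  period <- sch$measure_duration + sch$flush_duration
  t <- trace$time
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  idx <- floor(t / period)
  phase <- t - idx * period
  in_measure <- phase < sch$measure_duration
  keep <- which(in_measure)
  if (length(keep) == 0) {
    warning("trace contains no measurement-phase samples; no windows")
    return(structure(list(), window_starts = numeric(0)))
  }
  windows <- split(keep, idx[keep])
  starts <- as.numeric(names(windows)) * period
  out <- lapply(windows, function(i) {
    data.frame(time = t[i], do_conc = trace$do_conc[i])
  })
  names(out) <- NULL
  structure(out, window_starts = starts)
}

#' Oxygen uptake from a single measurement window
#'
#' Ordinary-least-squares DO decline slope converted to whole-animal uptake:
#' `mo2_whole = -slope * v_eff * 3600` with effective volume
#' `v_eff = chamber_volume - body_mass` (body density 1 kg l^-1), and
#' mass-scaled uptake `mo2_whole / body_mass^b`.
#'
#' @param window data.frame with `time` (s) and `do_conc` (mg l^-1).
#' @param chamber_volume Chamber volume, litres.
#' @param body_mass Body mass, kg.
#' @param b Mass-scaling exponent (default 0.89).
#' @return One-row data.frame: `mo2_whole`, `mo2_scaled`, `r_squared`,
#'   `slope`, `flag_rising` (TRUE when DO rose over the window).
#' @export
window_mo2 <- function(window, chamber_volume, body_mass, b = 0.89) {
  if (nrow(window) < 10) stop("need >= 10 samples per window")
  if (chamber_volume <= body_mass) stop("chamber_volume must exceed body volume")
  fit <- ols_slope(window$time, window$do_conc)
  v_eff <- chamber_volume - body_mass
  mo2 <- -fit[["slope"]] * v_eff * 3600
  data.frame(mo2_whole = mo2, mo2_scaled = mo2 / body_mass^b,
             r_squared = fit[["r_squared"]], slope = fit[["slope"]],
             flag_rising = fit[["slope"]] > 0)
}

#' Per-window oxygen uptake series for a whole trial
#'
#' @inheritParams window_mo2
#' @param trace A `do_trace`.
#' @return data.frame (class `mo2_series`) with one row per measurement
#'   window: `window_index`, `window_start`, `mo2_whole`, `mo2_scaled`,
#'   `r_squared`, `flag_rising`.
#' @export
mo2_series <- function(trace, b = 0.89) {
  wins <- segment_cycles(trace)
  starts <- attr(wins, "window_starts")
  rows <- lapply(wins, window_mo2, chamber_volume = trace$chamber_volume,
                 body_mass = trace$body_mass, b = b)
  out <- do.call(rbind, rows)
  out <- cbind(window_index = seq_along(wins), window_start = starts, out)
  class(out) <- c("mo2_series", "data.frame")
  out
}

#' Minimum oxygen uptake: mean of the lowest 10% of determinations
#'
#' Averages the `ceil(0.10 * n)` smallest mass-scaled uptake values from a
#' trial's uptake series (ties broken by window order).
#'
#' @param series An `mo2_series` data.frame or a numeric vector of scaled
#'   uptake values.
#' @param frac Fraction of lowest values to average (default 0.10).
#' @return Scaled uptake, mg O2 h^-1 kg^-0.89.
#' @export
mo2_min <- function(series, frac = 0.10) {
  x <- if (is.data.frame(series)) series$mo2_scaled else series
  n <- length(x)
  if (n < 10) stop("need >= 10 uptake determinations (got ", n, ")")
  k <- ceiling(frac * n)
  mean(x[order(x)[seq_len(k)]])
}

#' Maximum oxygen uptake by 30-s rolling regression
#'
#' Scans every contiguous 30-s sub-window (advancing one sample at a time,
#' never crossing a flush) within the first `horizon` hours post-exercise —
#' on the default schedule, the first four DO declines — and returns the
#' mass-scaled uptake implied by the steepest decline.
#'
#' @param trace A `do_trace`.
#' @param horizon Search horizon, hours (default 1).
#' @param window_span Rolling-regression span, seconds (default 30).
#' @param b Mass-scaling exponent.
#' @return Scaled uptake, mg O2 h^-1 kg^-0.89, with attributes
#'   `window_index` and `sub_start` locating the steepest sub-window.
#' @export
mo2_max <- function(trace, horizon = 1, window_span = 30, b = 0.89) {
  sch <- trace$schedule
  n_sub <- round(window_span / sch$sample_interval)
  wins <- segment_cycles(trace)
  starts <- attr(wins, "window_starts")
  keep <- starts < horizon * 3600
  if (!any(keep)) stop("trace does not cover the search horizon")
  wins <- wins[keep]
  best <- Inf; best_w <- NA_integer_; best_t <- NA_real_
  found <- FALSE
  for (w in seq_along(wins)) {
    tt <- wins[[w]]$time
    yy <- wins[[w]]$do_conc
    n <- length(tt)
    if (n < n_sub) next
    found <- TRUE
    # vectorized rolling OLS slope over fixed-length sub-windows
    cs_t <- cumsum(tt); cs_y <- cumsum(yy)
    cs_tt <- cumsum(tt * tt); cs_ty <- cumsum(tt * yy)
    i <- seq_len(n - n_sub + 1)
    j <- i + n_sub - 1
    s_t <- cs_t[j] - c(0, cs_t)[i]
    s_y <- cs_y[j] - c(0, cs_y)[i]
    s_tt <- cs_tt[j] - c(0, cs_tt)[i]
    s_ty <- cs_ty[j] - c(0, cs_ty)[i]
    slope <- (n_sub * s_ty - s_t * s_y) / (n_sub * s_tt - s_t^2)
    m <- which.min(slope)
    if (slope[m] < best) {
      best <- slope[m]; best_w <- w; best_t <- tt[m]
    }
  }
  if (!found) stop("no complete ", window_span, "-s sub-window in the horizon")
  v_eff <- trace$chamber_volume - trace$body_mass
  out <- -best * v_eff * 3600 / trace$body_mass^b
  structure(out, window_index = best_w, sub_start = best_t)
}

#' Absolute aerobic scope
#'
#' AAS is the difference between the maximum and minimum oxygen-uptake
#' determinations of a trial, both on the mass-scaled basis.
#'
#' @param mo2_min,mo2_max Scaled uptake rates, mg O2 h^-1 kg^-0.89.
#' @param temperature Trial temperature, deg C.
#' @param n_windows_used Number of uptake determinations behind `mo2_min`.
#' @return One-row data.frame: `mo2_min`, `mo2_max`, `aas`, `flag_negative`,
#'   `temperature`, `n_windows_used`. A negative scope is flagged, never
#'   silently dropped.
#' @export
aerobic_scope <- function(mo2_min, mo2_max, temperature = NA_real_,
                          n_windows_used = NA_integer_) {
  aas <- as.numeric(mo2_max) - as.numeric(mo2_min)
  if (aas < 0) warning("negative aerobic scope (mo2_max < mo2_min); flagged")
  data.frame(mo2_min = as.numeric(mo2_min), mo2_max = as.numeric(mo2_max),
             aas = aas, flag_negative = aas < 0,
             temperature = temperature, n_windows_used = n_windows_used)
}

#' Apply the respirometry exclusion filter
#'
#' Removes sharks flagged for bent posture in the chamber, loss of
#' equilibrium, or death during respirometry, and reports retained counts
#' per temperature group.
#'
#' @param ledger data.frame with columns `shark_id`, `group` and logical
#'   flags `bent_posture`, `equilibrium_loss`, `died`.
#' @return List with `retained` (the filtered ledger), `counts` (retained n
#'   per group) and `excluded` (n excluded per group).
#' @export
exclusion_filter <- function(ledger) {
  need <- c("shark_id", "group", "bent_posture", "equilibrium_loss", "died")
  if (!all(need %in% names(ledger))) {
    stop("ledger must have columns: ", paste(need, collapse = ", "))
  }
  flagged <- ledger$bent_posture | ledger$equilibrium_loss | ledger$died
  retained <- ledger[!flagged, , drop = FALSE]
  groups <- sort(unique(ledger$group))
  counts <- vapply(groups, function(g) sum(retained$group == g), integer(1))
  excluded <- vapply(groups, function(g)
    sum(ledger$group == g & flagged), integer(1))
  names(counts) <- names(excluded) <- as.character(groups)
  if (nrow(retained) == 0) warning("all sharks excluded")
  list(retained = retained, counts = counts, excluded = excluded)
}
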
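## Fast-start escape kinematics.
##
## Five performance variables are extracted from frame-indexed tracks:
## responsiveness, escape latency (frame-quantized), maximum Stage 1 turning
## rate, maximum speed and maximum acceleration of the centre of mass.
## Derivatives are taken by local quadratic (Savitzky-Golay) smoothing over
## a 5-frame window; raw finite differences amplify tracking noise in the
## acceleration estimate.

#' Detect an escape response and its onset frame
#'
#' The onset is the first post-stimulus frame where the head has moved more
#' than `threshold` from its pre-stimulus baseline position. When
#' `threshold` is `NULL` it adapts to the track: 3 times the pre-stimulus
#' jitter SD, floored at 1 mm.
#'
#' @param track An `escape_track` (see [gen_escape_track()]).
#' @param threshold Displacement threshold in metres, or `NULL` for the
#'   adaptive default.
#' @return List with `responded` (logical) and `onset_frame` (NA when no
#'   response).
#' @export
detect_response <- function(track, threshold = NULL) {
  d <- track$track
  stim <- track$stimulus_frame
  pre <- d[d$frame < stim, , drop = FALSE]
  if (nrow(pre) == 0) stop("no pre-stimulus frames in track")
  bx <- mean(pre$head_x); by <- mean(pre$head_y)
  if (is.null(threshold)) {
    jitter <- stats::sd(sqrt((pre$head_x - bx)^2 + (pre$head_y - by)^2))
    if (!is.finite(jitter)) jitter <- 0
    threshold <- max(3 * jitter, 0.001)
  }
  post <- d[d$frame >= stim, , drop = FALSE]
  disp <- sqrt((post$head_x - bx)^2 + (post$head_y - by)^2)
  hit <- which(disp > threshold)
  if (length(hit) == 0) {
    return(list(responded = FALSE, onset_frame = NA_integer_))
  }
  list(responded = TRUE, onset_frame = post$frame[hit[1]])
}

#' Escape latency in milliseconds
#'
#' Latency is the frame count between stimulus and movement onset divided by
#' the frame rate; it is therefore always an integer multiple of
#' `1000 / fps`. Reported values are truncated (not rounded) to two decimal
#' places, so one frame at 240 fps reads 4.16 ms.
#'
#' @param onset_frame,stimulus_frame Frame indices, onset >= stimulus.
#' @param fps Frame rate, frames s^-1.
#' @param digits Decimal places for the truncated report (default 2).
#' @return Latency in ms (truncated).
#' @export
latency_ms <- function(onset_frame, stimulus_frame, fps, digits = 2) {
  if (any(onset_frame < stimulus_frame)) stop("onset precedes stimulus")
  trunc_dp((onset_frame - stimulus_frame) * 1000 / fps, digits)
}

#' Segment a response into Stage 1 and (optional) Stage 2
#'
#' Stage 1 runs from onset to the first zero-crossing of the smoothed
#' angular velocity sustained for at least two frames. The response is
#' classified double-bend when a contralateral bend with angular excursion
#' greater than `min_excursion` follows; otherwise single-bend.
#'
#' @param track An `escape_track`.
#' @param onset_frame Movement onset from [detect_response()].
#' @param min_excursion Minimum contralateral excursion (degrees) to count
#'   as Stage 2.
#' @param window Smoothing window (frames) for the angular velocity.
#' @return List: `response_type` (`"single_bend"`/`"double_bend"`),
#'   `stage1` (frame range), `stage2` (frame range or NULL), `truncated`
#'   (TRUE when the track ends mid-Stage 1).
#' @export
stage_segment <- function(track, onset_frame, min_excursion = 10,
                          window = 5) {
  d <- track$track
  dt <- 1 / track$fps
  omega <- sg_deriv(d$body_angle_deg, dt, order = 1, window = window)
  idx0 <- which(d$frame == onset_frame)
  if (length(idx0) != 1) stop("onset_frame not in track")
  n <- nrow(d)
  dir1 <- sign(omega[min(idx0 + 1, n)])
  if (dir1 == 0) dir1 <- sign(omega[min(idx0 + 2, n)])
  # first sustained (>= 2 frames) sign reversal of angular velocity
  end1 <- NA_integer_
  i <- idx0 + 1
  while (i <= n - 1) {
    if (sign(omega[i]) == -dir1 && sign(omega[i + 1]) == -dir1) {
      end1 <- i - 1
      break
    }
    i <- i + 1
  }
  truncated <- is.na(end1)
  if (truncated) end1 <- n
  stage1 <- c(d$frame[idx0], d$frame[end1])
  stage2 <- NULL
  response_type <- "single_bend"
  if (!truncated && end1 < n) {
    ang_rev <- d$body_angle_deg[end1:n]
    excursion <- dir1 * (ang_rev[1] - ang_rev)   # positive = contralateral
    if (max(excursion) > min_excursion) {
      response_type <- "double_bend"
      end2 <- end1 - 1 + which.max(excursion)
      stage2 <- c(d$frame[min(end1 + 1, n)], d$frame[end2])
    }
  }
  list(response_type = response_type, stage1 = stage1, stage2 = stage2,
       truncated = truncated)
}

#' Maximum Stage 1 turning rate
#'
#' The maximum magnitude of the smoothed angular velocity of the body
#' midline within Stage 1, in degrees per second.
#'
#' @param track An `escape_track`.
#' @param stage1 Two-element frame range from [stage_segment()].
#' @param window Smoothing window (frames).
#' @return Turning rate, degrees s^-1.
#' @export
omega_s1 <- function(track, stage1, window = 5) {
  d <- track$track
  dt <- 1 / track$fps
  omega <- sg_deriv(d$body_angle_deg, dt, order = 1, window = window)
  sel <- d$frame >= stage1[1] & d$frame <= stage1[2]
  if (!any(sel)) stop("empty Stage 1 range")
  max(abs(omega[sel]))
}

#' Maximum speed and acceleration of the centre of mass
#'
#' Speed is the magnitude of the smoothed first derivative of the
#' centre-of-mass position; acceleration the magnitude of the smoothed
#' second derivative. Maxima are taken over the escape (onset to the end of
#' Stage 2, or the track end).
#'
#' @param track An `escape_track`.
#' @param onset_frame Movement onset.
#' @param end_frame Last frame of the escape (default: track end).
#' @param window Smoothing window (frames).
#' @return Named numeric: `u_max` (m s^-1), `a_max` (m s^-2).
#' @export
umax_amax <- function(track, onset_frame, end_frame = NULL, window = 5) {
  d <- track$track
  dt <- 1 / track$fps
  if (is.null(end_frame)) end_frame <- max(d$frame)
  if (sum(d$frame >= onset_frame) < window + 2) {
    stop("need >= ", window + 2, " frames after onset")
  }
  vx <- sg_deriv(d$com_x, dt, order = 1, window = window)
  vy <- sg_deriv(d$com_y, dt, order = 1, window = window)
  ax <- sg_deriv(d$com_x, dt, order = 2, window = window)
  ay <- sg_deriv(d$com_y, dt, order = 2, window = window)
  sel <- d$frame >= onset_frame & d$frame <= end_frame
  c(u_max = max(sqrt(vx[sel]^2 + vy[sel]^2)),
    a_max = max(sqrt(ax[sel]^2 + ay[sel]^2)))
}

#' Extract all escape metrics from one track
#'
#' Convenience wrapper running response detection, latency, stage
#' segmentation, turning rate and speed/acceleration extraction.
#'
#' @param track An `escape_track`.
#' @param threshold Displacement threshold passed to [detect_response()].
#' @return One-row data.frame: `responded`, `response_type`, `latency_ms`,
#'   `omega_s1`, `u_max`, `a_max`.
#' @export
escape_metrics <- function(track, threshold = NULL) {
  det <- detect_response(track, threshold)
  if (!det$responded) {
    return(data.frame(responded = FALSE, response_type = NA_character_,
                      latency_ms = NA_real_, omega_s1 = NA_real_,
                      u_max = NA_real_, a_max = NA_real_))
  }
  seg <- stage_segment(track, det$onset_frame)
  end_frame <- if (!is.null(seg$stage2)) seg$stage2[2] else seg$stage1[2]
  ua <- umax_amax(track, det$onset_frame, end_frame = end_frame)
  data.frame(responded = TRUE, response_type = seg$response_type,
             latency_ms = latency_ms(det$onset_frame, track$stimulus_frame,
                                     track$fps),
             omega_s1 = omega_s1(track, seg$stage1),
             u_max = unname(ua["u_max"]), a_max = unname(ua["a_max"]))
}

#' Maximal performance across an individual's three startle trials
#'
#' Per-variable extremum over the responding trials: minimum latency (the
#' fastest response), maximum turning rate, speed and acceleration. The
#' variables may come from different trials.
#'
#' @param trials data.frame of per-trial metrics (as from
#'   [escape_metrics()], row-bound), including a `responded` column.
#' @return One-row data.frame with the maximal-performance estimate and
#'   `n_trials` (number of responding trials).
#' @export
maximal_performance <- function(trials) {
  r <- trials[trials$responded %in% TRUE, , drop = FALSE]
  if (nrow(r) == 0) stop("no responding trial")
  data.frame(latency_ms = min(r$latency_ms),
             omega_s1 = max(r$omega_s1),
             u_max = max(r$u_max),
             a_max = max(r$a_max),
             n_trials = nrow(r))
}

#' Regress an escape variable on temperature
#'
#' Ordinary least squares of a (optionally natural-log-transformed)
#' performance variable on temperature as a continuous predictor, using
#' double-bend responses only.
#'
#' @param metrics data.frame with a `temperature` column, the response
#'   variable, and (if present) `response_type` used to drop single-bends.
#' @param variable Column name of the response.
#' @param log_transform Natural-log-transform the response first?
#' @return data.frame: `slope`, `intercept`, `F`, `df1`, `df2`, `p`, `n`.
#' @export
temperature_regression <- function(metrics, variable, log_transform = FALSE) {
  d <- metrics
  if ("response_type" %in% names(d)) {
    d <- d[is.na(d$response_type) | d$response_type == "double_bend", ,
           drop = FALSE]
    d <- d[!is.na(d[[variable]]), , drop = FALSE]
  }
  if (length(unique(d$temperature)) < 3) {
    stop("need >= 3 distinct temperatures")
  }
  y <- d[[variable]]
  if (log_transform) y <- log(y)
  fit <- stats::lm(y ~ temperature, data = d)
  an <- stats::anova(fit)
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
             p = an$`Pr(>F)`[1], n = nrow(d))
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs statistic `G = max|x - mean| / sd` against the t-based
#' critical value; flags at most one observation per call.
#'
#' @param values Numeric vector, n >= 3, approximately normal.
#' @param alpha Significance level.
#' @return List: `outlier_index` (or `NA`), `G`, `critical`, `p_like`
#'   (logical: G exceeded the critical value).
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop("Grubbs test needs n >= 3")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: Grubbs statistic undefined")
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tcrit <- stats::qt(1 - alpha / (2 * n), n - 2)
  critical <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  list(outlier_index = if (G > critical) which.max(dev) else NA_integer_,
       G = G, critical = critical, exceeded = G > critical)
}

#' Bartlett test of homogeneity of variances
#'
#' Thin wrapper over the standard Bartlett chi-squared test.
#'
#' @param values Numeric response values.
#' @param groups Group labels.
#' @return data.frame: `chi2`, `df`, `p`.
#' @export
bartlett_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  bt <- stats::bartlett.test(values, groups)
  data.frame(chi2 = unname(bt$statistic), df = unname(bt$parameter),
             p = bt$p.value)
}
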
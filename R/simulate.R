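## Synthetic-data generators.
##
## Every downstream module is exercised against seeded stand-ins for the
## four raw data streams of the study: post-exercise dissolved-oxygen
## traces, fast-start escape tracks, caudal-fin-height tables, and hourly
## temperature-logger records, plus aerobic-scope observations drawn from a
## known thermal-performance curve.

#' Simulate a 24-h post-exercise dissolved-oxygen trace
#'
#' Emulates intermittent-flow respirometry on a single shark recovering from
#' exhaustive exercise. Whole-animal oxygen uptake decays exponentially from
#' `mo2_max_true` to `mo2_min_true` with time constant `recovery_tau`
#' (hours). Within each measurement window DO declines linearly at the rate
#' implied by the window-averaged uptake (uptake varies slowly relative to a
#' 5-min window); each flush resets DO to the ambient value. Only
#' measurement-phase samples are recorded, matching the logger output of the
#' instrument: on the default 2-s / 5-min / 10-min / 24-h schedule that is
#' 14,400 DO readings in 96 windows.
#'
#' @param mo2_min_true Recovered (minimum) whole-animal uptake, mg O2 h^-1.
#' @param mo2_max_true Immediately post-exercise uptake, mg O2 h^-1; must
#'   not be below `mo2_min_true`.
#' @param recovery_tau Exponential recovery time constant, hours.
#' @param chamber_volume Respirometry chamber volume, litres.
#' @param body_mass Shark body mass, kg (body volume at density 1 kg l^-1 is
#'   subtracted from the chamber volume).
#' @param sample_interval DO sampling interval, seconds.
#' @param measure_duration Length of each measurement phase, seconds.
#' @param flush_duration Length of each flush phase, seconds.
#' @param total_duration Trial length, hours.
#' @param ambient_do Ambient (post-flush) DO, mg l^-1.
#' @param noise_sd SD of additive Gaussian sensor noise, mg l^-1.
#' @param temperature Water temperature, deg C (metadata only).
#' @param seed Integer seed; identical seeds give identical traces.
#'
#' @return An object of class `do_trace`: a list with `time` (s), `do_conc`
#'   (mg l^-1), chamber metadata and the schedule.
#' @export
#' @examples
#' tr <- gen_do_trace(mo2_min_true = 50, mo2_max_true = 180,
#'                    recovery_tau = 0.8, chamber_volume = 10,
#'                    body_mass = 0.9, seed = 1)
#' length(tr$time)  # 14400
gen_do_trace <- function(mo2_min_true, mo2_max_true, recovery_tau = 0.8,
                         chamber_volume = 10, body_mass = 0.9,
                         sample_interval = 2, measure_duration = 300,
                         flush_duration = 600, total_duration = 24,
                         ambient_do = 6.8, noise_sd = 0.01,
                         temperature = 29, seed = 1) {
  if (chamber_volume <= 0) stop("chamber_volume must be positive")
  if (body_mass <= 0) stop("body_mass must be positive")
  if (mo2_min_true <= 0 || mo2_max_true < mo2_min_true) {
    stop("need mo2_max_true >= mo2_min_true > 0")
  }
  if (recovery_tau <= 0 || sample_interval <= 0 || measure_duration <= 0 ||
      flush_duration <= 0 || total_duration <= 0) {
    stop("durations and time constants must be positive")
  }
  if (chamber_volume <= body_mass) {
    stop("chamber_volume must exceed the body-volume estimate (", body_mass,
         " l)")
  }
  set.seed(as.integer(seed))
  period <- measure_duration + flush_duration
  n_windows <- floor(total_duration * 3600 / period)
  n_per_window <- measure_duration / sample_interval
  v_eff <- chamber_volume - body_mass

  window_starts <- (seq_len(n_windows) - 1) * period
  time <- numeric(0)
  do <- numeric(0)
  for (w in seq_len(n_windows)) {
    t0 <- window_starts[w]
    ts <- t0 + sample_interval * (seq_len(n_per_window) - 1)
    # window-mean uptake (mg O2/h): analytic integral of the decay
    t0h <- t0 / 3600
    t1h <- (t0 + measure_duration) / 3600
    mbar <- mo2_min_true + (mo2_max_true - mo2_min_true) * recovery_tau /
      (t1h - t0h) * (exp(-t0h / recovery_tau) - exp(-t1h / recovery_tau))
    slope <- -mbar / (3600 * v_eff)          # mg l^-1 s^-1
    do_w <- ambient_do + slope * (ts - t0)
    time <- c(time, ts)
    do <- c(do, do_w)
  }
  if (noise_sd > 0) do <- do + stats::rnorm(length(do), 0, noise_sd)
  structure(list(
    time = time, do_conc = do, chamber_volume = chamber_volume,
    body_mass = body_mass, temperature = temperature,
    schedule = list(measure_duration = measure_duration,
                    flush_duration = flush_duration,
                    sample_interval = sample_interval),
    params = list(mo2_min_true = mo2_min_true, mo2_max_true = mo2_max_true,
                  recovery_tau = recovery_tau, ambient_do = ambient_do,
                  noise_sd = noise_sd, seed = seed)
  ), class = "do_trace")
}

#' Simulate a fast-start escape track
#'
#' Builds a frame-indexed track as recorded by an overhead high-speed camera
#' (default 240 fps), in corrected planar coordinates. The shark is
#' stationary (plus optional tracking jitter) until `latency_frames` frames
#' after the stimulus; it then performs a C-start: the body angle rotates at
#' `stage1_turn_rate` for `stage1_duration` (Stage 1), optionally followed
#' by a contralateral bend (Stage 2). The centre of mass translates along a
#' fixed escape heading with a speed profile that ramps at constant
#' acceleration `accel` for `accel_duration` and then cruises, so the
#' generating maximum speed and acceleration are known exactly.
#'
#' @param fps Frame rate, frames s^-1.
#' @param n_frames Total frames in the track.
#' @param stimulus_frame Frame index (1-based) of stimulus onset.
#' @param latency_frames Whole frames between stimulus and first movement.
#' @param stage1_duration Stage 1 duration, s.
#' @param stage1_turn_rate Stage 1 turning rate, degrees s^-1.
#' @param stage2 Logical; append a contralateral second bend?
#' @param stage2_duration Stage 2 duration, s.
#' @param stage2_turn_rate Stage 2 turning rate (opposite sign), deg s^-1.
#' @param accel Constant acceleration of the ramp, m s^-2.
#' @param accel_duration Ramp length, s; peak speed = `accel * accel_duration`.
#' @param speed_profile Optional numeric vector of per-frame speeds (m s^-1)
#'   for frames after movement onset; overrides the ramp.
#' @param escape_heading Direction of centre-of-mass travel, degrees.
#' @param head_offset Head-to-centre-of-mass distance, m.
#' @param jitter_sd SD of Gaussian positional jitter, m.
#' @param seed Integer seed.
#'
#' @return An object of class `escape_track`: data.frame of `frame`,
#'   `head_x`, `head_y`, `com_x`, `com_y`, `body_angle_deg` plus `fps` and
#'   `stimulus_frame` attributes and the generating parameters.
#' @export
gen_escape_track <- function(fps = 240, n_frames = 240, stimulus_frame = 60,
                             latency_frames = 2, stage1_duration = 0.05,
                             stage1_turn_rate = 1800, stage2 = TRUE,
                             stage2_duration = 0.04, stage2_turn_rate = 1200,
                             accel = 40, accel_duration = 0.05,
                             speed_profile = NULL, escape_heading = 30,
                             head_offset = 0.1, jitter_sd = 0, seed = 1) {
  if (fps <= 0) stop("fps must be positive")
  if (latency_frames < 0) stop("latency_frames must be >= 0")
  if (stage1_duration <= 0) stop("stage1_duration must be positive")
  if (stimulus_frame < 2 || stimulus_frame > n_frames) {
    stop("stimulus_frame must lie inside the track with >= 1 frame before it")
  }
  set.seed(as.integer(seed))
  dt <- 1 / fps
  onset <- stimulus_frame + latency_frames   # first frame showing movement
  frames <- seq_len(n_frames)

  # body angle: rotation begins so that the onset frame is already displaced
  angle <- numeric(n_frames)
  s1_frames <- max(1L, round(stage1_duration * fps))
  s2_frames <- if (stage2) max(1L, round(stage2_duration * fps)) else 0L
  for (f in frames) {
    if (f < onset) {
      angle[f] <- 0
    } else {
      k <- f - onset + 1                     # motion steps completed
      k1 <- min(k, s1_frames)
      angle[f] <- stage1_turn_rate * k1 * dt
      if (k > s1_frames && s2_frames > 0) {
        k2 <- min(k - s1_frames, s2_frames)
        angle[f] <- angle[f] - stage2_turn_rate * k2 * dt
      }
    }
  }

  # per-frame speed after onset
  n_post <- n_frames - onset + 1
  if (n_post > 0) {
    if (is.null(speed_profile)) {
      tpost <- (seq_len(n_post)) * dt
      v <- pmin(accel * tpost, accel * accel_duration)
    } else {
      v <- rep_len(speed_profile, n_post)
    }
  } else {
    v <- numeric(0)
  }
  step <- c(rep(0, onset - 1), v * dt)
  hd <- escape_heading * pi / 180
  com_x <- cumsum(step * cos(hd))
  com_y <- cumsum(step * sin(hd))
  head_x <- com_x + head_offset * cos(angle * pi / 180)
  head_y <- com_y + head_offset * sin(angle * pi / 180)
  if (jitter_sd > 0) {
    head_x <- head_x + stats::rnorm(n_frames, 0, jitter_sd)
    head_y <- head_y + stats::rnorm(n_frames, 0, jitter_sd)
    com_x <- com_x + stats::rnorm(n_frames, 0, jitter_sd)
    com_y <- com_y + stats::rnorm(n_frames, 0, jitter_sd)
  }
  out <- data.frame(frame = frames, head_x = head_x, head_y = head_y,
                    com_x = com_x, com_y = com_y, body_angle_deg = angle)
  structure(list(
    track = out, fps = fps, stimulus_frame = stimulus_frame,
    params = list(latency_frames = latency_frames,
                  stage1_turn_rate = stage1_turn_rate,
                  stage1_frames = s1_frames, stage2 = stage2,
                  stage2_frames = s2_frames,
                  u_max_true = if (length(v)) max(v) else 0,
                  a_max_true = if (is.null(speed_profile)) accel else NA_real_,
                  jitter_sd = jitter_sd, seed = seed)
  ), class = "escape_track")
}

#' Simulate caudal-fin-height measurements
#'
#' Draws `n` fin heights from a Gaussian truncated at zero. Defaults follow
#' the measured cohorts: newborn mean 11.66 cm, adult mean 31.11 cm.
#'
#' @param stage `"newborn"` or `"adult"`.
#' @param n Number of individuals (defaults to the measured subset size).
#' @param mean,sd Fin height mean and SD in metres (defaults per stage).
#' @param seed Integer seed.
#' @return data.frame with `individual_id`, `life_stage`, `fin_height_m`.
#' @export
gen_fin_heights <- function(stage = c("newborn", "adult"), n = NULL,
                            mean = NULL, sd = NULL, seed = 1) {
  stage <- match.arg(stage)
  k <- study_constants()
  if (is.null(n)) n <- if (stage == "newborn") k$fin_newborn_n else k$fin_adult_n
  if (is.null(mean)) {
    mean <- if (stage == "newborn") k$fin_newborn_mean else k$fin_adult_mean
  }
  if (is.null(sd)) {
    sd <- if (stage == "newborn") k$fin_newborn_sd else k$fin_adult_sd
  }
  if (mean <= 0) stop("mean fin height must be positive")
  if (sd < 0) stop("sd must be >= 0")
  set.seed(as.integer(seed))
  h <- stats::rnorm(n, mean, sd)
  # redraw non-positive heights (truncation at zero)
  while (any(h <= 0)) h[h <= 0] <- stats::rnorm(sum(h <= 0), mean, sd)
  data.frame(individual_id = sprintf("%s_%02d", stage, seq_len(n)),
             life_stage = stage, fin_height_m = h,
             stringsAsFactors = FALSE)
}

#' Simulate hourly temperature-logger records
#'
#' Generates hourly records for `loggers` co-located loggers over `n_days`:
#' a diel sinusoid `mean_temp + amplitude * cos(2*pi*(h - peak_hour)/24)`
#' plus hour-specific Gaussian noise and occasional warm spikes emulating
#' the extreme heating events observed on reef flats.
#'
#' @param mean_temp Cycle mean, deg C.
#' @param amplitude Half the noiseless daily range, deg C.
#' @param peak_hour Hour of day of the cycle maximum (0-23).
#' @param volatility_sd Noise SD, deg C; scalar or length-24 vector by hour.
#' @param spike_prob Per-record probability of a warm spike.
#' @param spike_mag Mean spike magnitude, deg C (exponentially distributed).
#' @param n_days Days of record.
#' @param loggers Number of loggers.
#' @param site Site label.
#' @param month Month label.
#' @param seed Integer seed.
#' @return data.frame with `site`, `month`, `logger_id`, `day`, `hour`,
#'   `temp_c` (class `temperature_log`).
#' @export
gen_temperature_log <- function(mean_temp = 28.21, amplitude = 2.41,
                                peak_hour = 14, volatility_sd = 0.5,
                                spike_prob = 0.005, spike_mag = 6,
                                n_days = 120, loggers = 2,
                                site = "Papetoai", month = "November",
                                seed = 1) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (peak_hour < 0 || peak_hour >= 24) stop("peak_hour must be in [0, 24)")
  if (spike_prob < 0 || spike_prob > 1) stop("spike_prob must be in [0, 1]")
  if (length(volatility_sd) == 1) volatility_sd <- rep(volatility_sd, 24)
  if (length(volatility_sd) != 24) stop("volatility_sd must be length 1 or 24")
  set.seed(as.integer(seed))
  grid <- expand.grid(hour = 0:23, day = seq_len(n_days),
                      logger_id = seq_len(loggers))
  base <- mean_temp + amplitude * cos(2 * pi * (grid$hour - peak_hour) / 24)
  noise <- stats::rnorm(nrow(grid), 0, volatility_sd[grid$hour + 1])
  spikes <- stats::rbinom(nrow(grid), 1, spike_prob) *
    stats::rexp(nrow(grid), 1 / spike_mag)
  out <- data.frame(site = site, month = month,
                    logger_id = grid$logger_id, day = grid$day,
                    hour = grid$hour, temp_c = base + noise + spikes,
                    stringsAsFactors = FALSE)
  class(out) <- c("temperature_log", "data.frame")
  out
}

#' Simulate aerobic-scope observations from a Gaussian performance curve
#'
#' Draws absolute aerobic scope (AAS) values at the requested temperatures
#' from the Gaussian thermal-performance curve
#' `a * exp(-0.5 * ((T - t_opt)/sigma)^2)` where `sigma` is derived from the
#' 80%-of-peak performance breadth: `sigma = breadth80 / (2 * sqrt(2 * log(1.25)))`.
#' Additive Gaussian noise, truncated at zero.
#'
#' @param peak Peak AAS, mg O2 h^-1 kg^-0.89.
#' @param t_opt Temperature of peak AAS, deg C.
#' @param breadth80 Width of the temperature interval where AAS >= 80% of
#'   the peak, deg C.
#' @param temps Temperatures to sample at, deg C.
#' @param n_per_temp Number of sharks per temperature (recycled).
#' @param noise_sd SD of additive noise, AAS units.
#' @param seed Integer seed.
#' @return data.frame with `shark_id`, `temperature`, `aas`.
#' @export
gen_aas_dataset <- function(peak = 317.10, t_opt = 29.15, breadth80 = 3.30,
                            temps = c(27, 29, 31), n_per_temp = c(9, 8, 8),
                            noise_sd = 40, seed = 1) {
  if (peak <= 0) stop("peak must be positive")
  if (breadth80 <= 0) stop("breadth80 must be positive")
  set.seed(as.integer(seed))
  n_per_temp <- rep_len(n_per_temp, length(temps))
  sigma <- breadth80 / (2 * sqrt(2 * log(1.25)))
  temperature <- rep(temps, n_per_temp)
  mu <- peak * exp(-0.5 * ((temperature - t_opt) / sigma)^2)
  aas <- mu + if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
  aas <- pmax(aas, 0)
  data.frame(shark_id = sprintf("shark_%02d", seq_along(aas)),
             temperature = temperature, aas = aas,
             stringsAsFactors = FALSE)
}
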
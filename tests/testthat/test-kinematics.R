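test_that("response detection finds the generated onset frame", {
  trk <- gen_escape_track(latency_frames = 3, jitter_sd = 0, seed = 1)
  det <- detect_response(trk)
  expect_true(det$responded)
  expect_equal(det$onset_frame, trk$stimulus_frame + 3)
  # a stationary track never responds
  still <- gen_escape_track(jitter_sd = 1e-5, seed = 2)
  still$track$head_x[] <- still$track$head_x[1]
  still$track$head_y[] <- still$track$head_y[1]
  still$track$com_x[] <- 0; still$track$com_y[] <- 0
  expect_false(detect_response(still)$responded)
})

test_that("latency is frame-quantized and truncated to two decimals", {
  expect_equal(latency_ms(61, 60, 240), 4.16)    # one frame at 240 fps
  expect_equal(latency_ms(72, 60, 240), 50.00)   # twelve frames
  expect_equal(latency_ms(60, 60, 240), 0)
  expect_error(latency_ms(59, 60, 240), "precedes")
  # quantization property: raw latency is a multiple of 1000/fps
  for (k in 0:12) {
    raw <- (k * 1000 / 240)
    expect_equal(latency_ms(60 + k, 60, 240), trunc(raw * 100) / 100)
  }
  # the extracted latency of a generated track honours latency_frames
  for (lf in c(0L, 1L, 5L)) {
    trk <- gen_escape_track(latency_frames = lf, jitter_sd = 0, seed = 3)
    m <- escape_metrics(trk)
    expect_equal(m$latency_ms, trunc(lf * 1000 / 240 * 100) / 100)
  }
})

test_that("stage segmentation classifies single- and double-bend responses", {
  db <- gen_escape_track(stage2 = TRUE, jitter_sd = 0, seed = 1)
  onset <- detect_response(db)$onset_frame
  seg <- stage_segment(db, onset)
  expect_equal(seg$response_type, "double_bend")
  # stage 1 ends near the generated stage-1 boundary
  expect_equal(seg$stage1[2] - onset + 1, db$params$stage1_frames,
               tolerance = 3)
  sb <- gen_escape_track(stage2 = FALSE, jitter_sd = 0, seed = 1)
  expect_equal(stage_segment(sb, detect_response(sb)$onset_frame)$response_type,
               "single_bend")
})

test_that("turning rate recovers constant and sinusoidal angular velocity", {
  trk <- gen_escape_track(stage1_turn_rate = 1800, jitter_sd = 0, seed = 1)
  onset <- detect_response(trk)$onset_frame
  seg <- stage_segment(trk, onset)
  expect_equal(omega_s1(trk, seg$stage1), 1800, tolerance = 0.02 * 1800)
  # realistic magnitude: 2038 deg/s
  trk2 <- gen_escape_track(stage1_turn_rate = 2038, jitter_sd = 0, seed = 2)
  seg2 <- stage_segment(trk2, detect_response(trk2)$onset_frame)
  expect_equal(omega_s1(trk2, seg2$stage1), 2038, tolerance = 0.02 * 2038)
  # sinusoidal bend: max angular velocity is 2*pi*f*A
  fps <- 240; A <- 30; fr <- 10
  n <- 120
  th <- A * sin(2 * pi * fr * (0:(n - 1)) / fps)
  synth <- gen_escape_track(n_frames = n, stimulus_frame = 2,
                            latency_frames = 0, jitter_sd = 0, seed = 1)
  synth$track <- synth$track[1:n, ]
  synth$track$body_angle_deg <- th
  expect_equal(omega_s1(synth, c(1, n)), 2 * pi * fr * A,
               tolerance = 0.02 * 2 * pi * fr * A)
})

test_that("speed and acceleration maxima recover kinematic ground truth", {
  # uniform motion throughout (no rest-to-speed kink): u_max = v, a_max ~ 0
  v <- 1.5
  trk <- gen_escape_track(latency_frames = 0, speed_profile = v,
                          stage1_turn_rate = 0, stage2 = FALSE,
                          jitter_sd = 0, seed = 1)
  tt <- (trk$track$frame - 1) / trk$fps
  trk$track$com_x <- v * tt * cos(pi / 6)
  trk$track$com_y <- v * tt * sin(pi / 6)
  ua <- umax_amax(trk, onset_frame = 10)
  expect_equal(unname(ua["u_max"]), v, tolerance = 1e-8)
  expect_lt(unname(ua["a_max"]), 1e-6)
  # constant acceleration from rest
  a0 <- 40; t_acc <- 0.05
  trk2 <- gen_escape_track(accel = a0, accel_duration = t_acc,
                           jitter_sd = 0, seed = 2)
  ua2 <- umax_amax(trk2, detect_response(trk2)$onset_frame)
  expect_equal(unname(ua2["a_max"]), a0, tolerance = 0.05 * a0)
  expect_equal(unname(ua2["u_max"]), a0 * t_acc, tolerance = 0.05 * a0 * t_acc)
  expect_error(umax_amax(trk2, max(trk2$track$frame) - 2), "frames after onset")
})

test_that("kinematic metrics are invariant to rigid motions of the track", {
  trk <- gen_escape_track(jitter_sd = 0, seed = 7)
  m0 <- escape_metrics(trk)
  for (tf in list(c(90, 0, 0), c(37, 1.2, -3.4), c(-120, -0.5, 0.8))) {
    mt <- escape_metrics(transform_track(trk, tf[1], tf[2], tf[3]))
    expect_equal(mt$latency_ms, m0$latency_ms)
    expect_equal(mt$omega_s1, m0$omega_s1, tolerance = 1e-9)
    expect_equal(mt$u_max, m0$u_max, tolerance = 1e-9)
    expect_equal(mt$a_max, m0$a_max, tolerance = 1e-6)
  }
})

test_that("maximal performance is the per-variable extremum and is idempotent", {
  trials <- data.frame(
    responded = TRUE,
    latency_ms = c(26.4, 30, 33),
    omega_s1 = c(1500, 1900, 1700),
    u_max = c(1.2, 1.1, 1.4),
    a_max = c(35, 42, 30))
  best <- maximal_performance(trials)
  expect_equal(best$latency_ms, 26.4)
  expect_equal(best$omega_s1, 1900)
  expect_equal(best$u_max, 1.4)
  expect_equal(best$a_max, 42)
  expect_equal(best$n_trials, 3)
  # order invariance and idempotence
  perm <- maximal_performance(trials[c(3, 1, 2), ])
  expect_equal(perm, best)
  again <- maximal_performance(cbind(responded = TRUE,
                                     best[names(best) != "n_trials"]))
  expect_equal(again$latency_ms, best$latency_ms)
  # identical trials return themselves; single responder is flagged
  one <- trials[2, ]
  expect_equal(maximal_performance(one)$n_trials, 1)
  expect_error(maximal_performance(transform(trials, responded = FALSE)),
               "no responding trial")
})

test_that("temperature regression matches a permutation oracle on small data", {
  set.seed(11)
  d <- data.frame(temperature = rep(c(25, 27, 29, 31), each = 5),
                  u_max = rnorm(20, 1.2, 0.1) +
                    0.03 * rep(c(25, 27, 29, 31), each = 5))
  fit <- temperature_regression(d, "u_max")
  # permutation null of the F statistic
  f_perm <- replicate(4000, {
    dd <- d; dd$u_max <- sample(dd$u_max)
    temperature_regression(dd, "u_max")$F
  })
  p_perm <- mean(f_perm >= fit$F)
  expect_equal(fit$p, p_perm, tolerance = 0.03)
  # an exactly linear response has an exact slope and p -> 0
  d2 <- data.frame(temperature = rep(c(25, 27, 29, 31), each = 3))
  d2$a_max <- 2 + 1.5 * d2$temperature
  # a perfect fit makes summary.lm warn about its F-test; that is the point
  fit2 <- suppressWarnings(temperature_regression(d2, "a_max"))
  expect_equal(fit2$slope, 1.5, tolerance = 1e-9)
  expect_lt(fit2$p, 1e-12)
})

test_that("latency declines significantly with temperature in a printed-means cohort", {
  k <- study_constants()
  set.seed(21)
  rows <- list()
  for (temp in k$escape_temps) {
    mu_f <- k$latency_means_ms[[as.character(temp)]] * k$fps / 1000
    for (s in 1:9) {
      lf <- max(0L, round(rnorm(1, mu_f, 1.2)))
      trk <- gen_escape_track(latency_frames = lf, jitter_sd = 0,
                              seed = 100 * temp + s)
      rows[[length(rows) + 1]] <- cbind(temperature = temp,
                                        escape_metrics(trk))
    }
  }
  kin <- do.call(rbind, rows)
  kin <- kin[kin$latency_ms > 0, ]   # log transform needs positive latencies
  fit <- temperature_regression(kin, "latency_ms", log_transform = TRUE)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p, 0.05)
})

test_that("Grubbs and Bartlett checks behave on canonical inputs", {
  g <- grubbs_test(c(1, 1.1, 0.9, 10))
  expect_equal(g$outlier_index, 4L)
  expect_true(g$exceeded)
  expect_true(is.na(grubbs_test(c(1, 1.1, 0.9, 1.05, 0.95))$outlier_index))
  expect_error(grubbs_test(rep(2, 3)), "zero variance")
  # Bartlett: identical groups give chi2 = 0, p = 1
  x <- rnorm(10)
  b0 <- bartlett_groups(c(x, x), rep(1:2, each = 10))
  expect_equal(b0$chi2, 0, tolerance = 1e-12)
  expect_equal(b0$p, 1, tolerance = 1e-12)
  # gross variance inequality is detected
  set.seed(8)
  b1 <- bartlett_groups(c(rnorm(20, 0, 1), rnorm(20, 0, 10)),
                        rep(1:2, each = 20))
  expect_lt(b1$p, 0.01)
  # under the null, p is not systematically small
  set.seed(9)
  ps <- replicate(100, bartlett_groups(rnorm(30), rep(1:3, each = 10))$p)
  expect_gt(mean(ps), 0.3)
})
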
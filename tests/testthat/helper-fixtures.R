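# Shared fixtures: small, fast synthetic inputs built in code.

# Short DO trace (1 h = 4 windows) for quick respirometry tests.
short_trace <- function(..., total_duration = 1, seed = 1) {
  gen_do_trace(mo2_min_true = 60, mo2_max_true = 220, recovery_tau = 0.5,
               chamber_volume = 10, body_mass = 0.9,
               total_duration = total_duration, seed = seed, ...)
}

# Brute-force rolling-regression maximum uptake, independent of mo2_max():
# fits lm() on every admissible sub-window.
brute_force_mo2max <- function(trace, horizon = 1, window_span = 30,
                               b = 0.89) {
  wins <- segment_cycles(trace)
  starts <- attr(wins, "window_starts")
  wins <- wins[starts < horizon * 3600]
  n_sub <- round(window_span / trace$schedule$sample_interval)
  best <- Inf
  for (w in wins) {
    n <- nrow(w)
    if (n < n_sub) next
    for (i in seq_len(n - n_sub + 1)) {
      d <- w[i:(i + n_sub - 1), ]
      sl <- unname(coef(lm(do_conc ~ time, data = d))[2])
      if (sl < best) best <- sl
    }
  }
  v_eff <- trace$chamber_volume - trace$body_mass
  -best * v_eff * 3600 / trace$body_mass^b
}

# Rigid rotation + translation of an escape track (for invariance tests).
transform_track <- function(trk, angle_deg = 0, dx = 0, dy = 0) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  d <- trk$track
  for (pref in c("head", "com")) {
    xy <- cbind(d[[paste0(pref, "_x")]], d[[paste0(pref, "_y")]]) %*% t(R)
    d[[paste0(pref, "_x")]] <- xy[, 1] + dx
    d[[paste0(pref, "_y")]] <- xy[, 2] + dy
  }
  d$body_angle_deg <- d$body_angle_deg + angle_deg
  trk$track <- d
  trk
}
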
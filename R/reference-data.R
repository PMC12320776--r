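#' Reported diel thermal-regime parameters for Mo'orea reef-flat sites
#'
#' Published 24-h thermal-cycle parameters for the four nursery sites around
#' Mo'orea (Papetoai, Maharepa, Vaiare, Haapiti) in each of the four months
#' when newborn blacktip reef sharks occupy the flats. These rows
#' parameterize the synthetic temperature-log generator and serve as
#' recovery targets for the diel-cycle pipeline.
#'
#' @return A data.frame with columns `site`, `month`, `mean_c`, `min_c`,
#'   `time_min_h` (hour of day), `max_c`, `time_max_h`, `range_c`.
#' @export
moorea_diel_table <- function() {
  df <- read.csv(text = "site,month,mean_c,min_c,time_min_h,max_c,time_max_h,range_c
Papetoai,November,28.21,26.41,6,30.62,14,4.21
Papetoai,December,28.33,27.01,6,30.28,14,3.27
Papetoai,January,28.41,27.33,6,30.10,13,2.77
Papetoai,February,28.91,27.71,6,30.96,14,3.25
Maharepa,November,27.91,26.85,6,29.12,15,2.27
Maharepa,December,28.25,27.40,6,29.34,15,1.94
Maharepa,January,28.49,27.57,6,29.65,15,2.08
Maharepa,February,29.02,28.04,6,30.18,15,2.14
Vaiare,November,28.27,26.69,6,29.99,14,3.30
Vaiare,December,28.88,27.31,6,30.73,14,3.43
Vaiare,January,28.83,27.34,6,30.58,14,3.24
Vaiare,February,29.25,27.85,6,31.00,15,3.15
Haapiti,November,28.39,26.22,6,30.44,14,4.23
Haapiti,December,28.74,26.59,6,30.92,14,4.33
Haapiti,January,28.72,26.80,6,30.69,14,3.89
Haapiti,February,29.10,27.41,6,30.86,15,3.45", stringsAsFactors = FALSE)
  df
}

#' Study design constants for the newborn blacktip reef shark experiments
#'
#' Published design values and summary statistics used as defaults by the
#' synthetic-data generators: respirometry schedule, metabolic scaling
#' exponent, the fitted aerobic-scope curve (peak, optimum, 80% breadth),
#' escape-latency group means, caudal-fin-height means/SDs by life stage,
#' and the median reef-flat water depth.
#'
#' @return A named list of constants.
#' @export
study_constants <- function() {
  list(
    # respirometry schedule: DO every 2 s for 5 min, 10-min flush, 24 h
    sample_interval_s = 2,
    measure_duration_s = 300,
    flush_duration_s = 600,
    total_duration_h = 24,
    scaling_exponent = 0.89,
    # aerobic scope curve (Gaussian fit): peak AAS in mg O2 h^-1 kg^-0.89
    aas_peak = 317.10,
    aas_t_opt = 29.15,
    aas_breadth80 = 3.30,
    # escape trials: 240 fps video, latency group means (ms) by temperature
    fps = 240,
    latency_means_ms = c(`25` = 26.4, `27` = 17.9, `29` = 18.75, `31` = 14.3),
    # caudal fin heights (m): mean +/- SE with subset sizes n=18 / n=10;
    # SDs reconstructed as SE * sqrt(n)
    fin_newborn_mean = 0.1166,
    fin_newborn_sd = 0.0062 * sqrt(18),
    fin_newborn_n = 18,
    fin_adult_mean = 0.3111,
    fin_adult_sd = 0.0095 * sqrt(10),
    fin_adult_n = 10,
    # reported critical depths (m) where SDI crosses 3, and habitat depth
    critical_depth_newborn = 0.33,
    critical_depth_adult = 0.92,
    median_flat_depth = 0.74,
    # treatment design
    respiro_temps = c(27, 29, 31),
    respiro_n = c(9, 8, 8),
    escape_temps = c(25, 27, 29, 31),
    n_per_treatment = 12
  )
}
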
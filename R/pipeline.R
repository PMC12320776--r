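## End-to-end pipeline and CSV schemas.
##
## The package's interface is its functions; `run_pipeline()` wires the
## stages together (simulate -> respirometry -> TPC; simulate -> kinematics;
## simulate -> SDI; simulate -> thermal regime -> overlap with the aerobic
## 80% window), writes every stage output as CSV plus a JSON manifest, and
## fans one global seed out into deterministic per-stage sub-seeds.

# Registered CSV schemas: column names and types.
csv_schemas <- function() {
  list(
    do_trace = list(cols = c(time_s = "numeric", do_mg_per_l = "numeric"),
                    checks = list(do_mg_per_l = function(x) x >= 0,
                                  time_s = function(x) !is.unsorted(x, strictly = TRUE))),
    aas = list(cols = c(shark_id = "character", temperature = "numeric",
                        aas = "numeric"),
               checks = list(aas = function(x) x >= 0)),
    fins = list(cols = c(individual_id = "character",
                         life_stage = "character", fin_height_m = "numeric"),
                checks = list(fin_height_m = function(x) x > 0)),
    temperature_log = list(
      cols = c(site = "character", month = "character",
               logger_id = "integer", day = "integer", hour = "integer",
               temp_c = "numeric"),
      checks = list(hour = function(x) x == round(x) & x >= 0 & x <= 23))
  )
}

#' Validate a CSV file against a registered schema
#'
#' Checks column presence, type coercibility and row-level constraints
#' (e.g. non-negative DO, on-the-hour timestamps), reporting violations with
#' row numbers.
#'
#' @param path CSV file path.
#' @param schema_name One of `"do_trace"`, `"aas"`, `"fins"`,
#'   `"temperature_log"`.
#' @return List with `ok` (logical) and `violations` (character vector).
#' @export
validate_csv <- function(path, schema_name) {
  schemas <- csv_schemas()
  if (!schema_name %in% names(schemas)) {
    stop("unknown schema: ", schema_name, " (registered: ",
         paste(names(schemas), collapse = ", "), ")")
  }
  sch <- schemas[[schema_name]]
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("malformed CSV at ", path, ": ",
                                         conditionMessage(e)))
  v <- character(0)
  missing_cols <- setdiff(names(sch$cols), names(d))
  if (length(missing_cols)) {
    v <- c(v, paste("missing column:", missing_cols))
  }
  for (cn in intersect(names(sch$checks), names(d))) {
    bad <- which(!sch$checks[[cn]](d[[cn]]))
    if (length(bad)) {
      v <- c(v, paste0("column ", cn, ": constraint violated at rows ",
                       paste(utils::head(bad, 10), collapse = ", "),
                       if (length(bad) > 10) " ..." else ""))
    }
  }
  list(ok = length(v) == 0, violations = v)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates every input stream from one seed and runs all downstream
#' stages: respirometry uptake extraction and aerobic scope per shark, TPC
#' fitting with AICc selection, escape-track kinematics, SDI regressions
#' with critical depths, and diel-cycle fitting with the time spent inside
#' the aerobic 80% window. Outputs are written as CSV under `out_dir` along
#' with a JSON manifest recording the seed, parameters and per-stage row
#' counts.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param n_sharks_respiro Sharks per respirometry temperature group before
#'   exclusions.
#' @param n_boot Bootstrap replicates for the TPC intervals.
#' @param thermal_rows Rows of [moorea_diel_table()] to simulate (indices);
#'   default first 4 (one site).
#' @return List with per-stage results and the manifest.
#' @export
run_pipeline <- function(seed = 1, out_dir = NULL, n_sharks_respiro = 12,
                         n_boot = 199, thermal_rows = 1:4) {
  k <- study_constants()
  manifest <- list(seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   package_version = as.character(utils::packageVersion("sharkperf")),
                   stages = list())

  # --- respirometry + aerobic scope per shark -------------------------------
  set.seed(sub_seed(seed, "cohort"))
  groups <- rep(k$respiro_temps, each = n_sharks_respiro)
  # exclusion flags reproducing the study's per-group exclusion totals
  excl_tot <- c(`27` = 3L, `29` = 4L, `31` = 4L)
  ledger <- data.frame(shark_id = sprintf("s%02d", seq_along(groups)),
                       group = groups, bent_posture = FALSE,
                       equilibrium_loss = FALSE, died = FALSE)
  for (g in names(excl_tot)) {
    idx <- sample(which(ledger$group == as.numeric(g)), excl_tot[[g]])
    ledger$bent_posture[idx] <- TRUE
  }
  filt <- exclusion_filter(ledger)
  cohort <- filt$retained
  summaries <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    temp <- cohort$group[i]
    # uptake scales weakly with temperature around the optimum
    tr <- gen_do_trace(
      mo2_min_true = 60 + 4 * (temp - 27),
      mo2_max_true = 220 + 10 * (temp - 27),
      recovery_tau = 0.8, chamber_volume = 10, body_mass = 0.9,
      noise_sd = 0.005, temperature = temp,
      seed = sub_seed(seed, paste0("do_", cohort$shark_id[i])))
    ser <- mo2_series(tr)
    aerobic_scope(mo2_min(ser), mo2_max(tr), temperature = temp,
                  n_windows_used = nrow(ser))
  }))
  summaries$shark_id <- cohort$shark_id
  manifest$stages$respirometry <- list(
    n_sharks = nrow(cohort), retained = as.list(filt$counts),
    windows_per_shark = summaries$n_windows_used[1])

  # --- TPC on synthetic AAS at the study design -----------------------------
  aas <- gen_aas_dataset(seed = sub_seed(seed, "aas"))
  fits <- list(
    suppressWarnings(fit_tpc(aas, "gaussian", seed = sub_seed(seed, "fitg"))),
    suppressWarnings(fit_tpc(aas, "quadratic")))
  sel <- aicc_select(fits)
  der <- derive_params(sel$best)
  boot <- bootstrap_bca(sel$best, n_boot = n_boot,
                        seed = sub_seed(seed, "boot"))
  hs <- holm_sidak_pairwise(aas$aas, aas$temperature)
  manifest$stages$tpc <- list(
    best_shape = sel$best$shape, delta_aicc = sel$table$delta_aicc[2],
    n_temperatures = length(unique(aas$temperature)),
    three_temperature_design = length(unique(aas$temperature)) == 3,
    boot_failed = boot$n_failed)

  # --- kinematics on synthetic tracks ---------------------------------------
  lat_means <- k$latency_means_ms
  kin <- do.call(rbind, lapply(seq_along(k$escape_temps), function(gi) {
    temp <- k$escape_temps[gi]
    do.call(rbind, lapply(1:6, function(sid) {
      lat_f <- max(0L, round(lat_means[[as.character(temp)]] * k$fps / 1000 +
                               sample(-2:2, 1)))
      trk <- gen_escape_track(
        latency_frames = lat_f,
        stage1_turn_rate = 1500 + 60 * (temp - 25),
        accel = 30 + 2 * (temp - 25),
        seed = sub_seed(seed, paste0("trk", temp, "_", sid)))
      cbind(temperature = temp, shark = sid, escape_metrics(trk))
    }))
  }))
  reg_latency <- temperature_regression(kin, "latency_ms", log_transform = TRUE)
  manifest$stages$kinematics <- list(n_tracks = nrow(kin),
                                     responsiveness = mean(kin$responded))

  # --- SDI ------------------------------------------------------------------
  fins <- rbind(gen_fin_heights("newborn", seed = sub_seed(seed, "finN")),
                gen_fin_heights("adult", seed = sub_seed(seed, "finA")))
  sdi_fit <- sdi_regression(fins)
  zstar <- critical_depth(sdi_fit)
  band <- advantage_band(zstar[["newborn"]], zstar[["adult"]])
  manifest$stages$sdi <- list(critical_depths = as.list(zstar),
                              band_width = band[["width"]])

  # --- thermal regime + overlap with the aerobic 80% window -----------------
  tab <- moorea_diel_table()[thermal_rows, , drop = FALSE]
  cycles <- lapply(seq_len(nrow(tab)), function(i) {
    logs <- gen_temperature_log(
      mean_temp = tab$mean_c[i], amplitude = tab$max_c[i] - tab$mean_c[i],
      peak_hour = tab$time_max_h[i], site = tab$site[i], month = tab$month[i],
      seed = sub_seed(seed, paste0("log", i)))
    agg <- hourly_aggregate(logs)
    fit_diel_loess(agg, seed = sub_seed(seed, paste0("cv", i)))
  })
  cycle_params <- do.call(rbind, lapply(cycles, derive_cycle_params))
  overlap <- do.call(rbind, lapply(cycles, function(cy) {
    ti <- time_in_breadth(cy, der$lower, der$upper)
    data.frame(site = cy$site, month = cy$month, hours = ti[["hours"]],
               fraction = ti[["fraction"]])
  }))
  manifest$stages$thermal <- list(n_cycles = length(cycles))

  results <- list(
    exclusions = filt, metabolic = summaries, aas = aas, tpc = sel,
    derived = der, bootstrap = boot, holm_sidak = hs, kinematics = kin,
    latency_regression = reg_latency, fins = fins, sdi = sdi_fit,
    critical_depths = zstar, advantage_band = band,
    cycle_params = cycle_params, breadth_overlap = overlap,
    manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "metabolic_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(aas, file.path(out_dir, "aas.csv"), row.names = FALSE)
    utils::write.csv(kin, file.path(out_dir, "escape_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(fins, file.path(out_dir, "fins.csv"), row.names = FALSE)
    utils::write.csv(cycle_params, file.path(out_dir, "diel_cycle.csv"),
                     row.names = FALSE)
    utils::write.csv(overlap, file.path(out_dir, "breadth_overlap.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  results
}

#' Write a dissolved-oxygen trace as CSV with a sidecar parameter file
#'
#' @param trace A `do_trace`.
#' @param path Output CSV path (`time_s`, `do_mg_per_l`); parameters go to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_do_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time,
                              do_mg_per_l = trace$do_conc),
                   path, row.names = FALSE)
  meta <- c(trace$params,
            list(chamber_volume = trace$chamber_volume,
                 body_mass = trace$body_mass,
                 temperature = trace$temperature),
            trace$schedule)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dissolved-oxygen trace from CSV
#'
#' @param path CSV with columns `time_s`, `do_mg_per_l`.
#' @param chamber_volume,body_mass,temperature Chamber metadata (overridden
#'   by a `<path>.json` sidecar when present).
#' @param measure_duration,flush_duration,sample_interval Schedule, seconds.
#' @return A `do_trace`.
#' @export
read_do_trace <- function(path, chamber_volume = NA, body_mass = NA,
                          temperature = NA, measure_duration = 300,
                          flush_duration = 600, sample_interval = 2) {
  d <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    chamber_volume <- meta$chamber_volume %||% chamber_volume
    body_mass <- meta$body_mass %||% body_mass
    temperature <- meta$temperature %||% temperature
    measure_duration <- meta$measure_duration %||% measure_duration
    flush_duration <- meta$flush_duration %||% flush_duration
    sample_interval <- meta$sample_interval %||% sample_interval
  }
  structure(list(time = d$time_s, do_conc = d$do_mg_per_l,
                 chamber_volume = chamber_volume, body_mass = body_mass,
                 temperature = temperature,
                 schedule = list(measure_duration = measure_duration,
                                 flush_duration = flush_duration,
                                 sample_interval = sample_interval)),
            class = "do_trace")
}
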
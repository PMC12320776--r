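## Submergence depth index.
##
## SDI = z / B: habitat water depth over caudal-fin height. Below SDI = 3
## surface-proximity drag is significant and fast-start thrust is lost.
## Per-life-stage regressions of SDI on depth give the critical depth where
## each stage crosses SDI = 3; depths between the newborn and adult critical
## depths form the newborn propulsive-advantage band.

#' Submergence depth index
#'
#' @param depth_z Habitat water depth, m (> 0).
#' @param fin_height_B Caudal fin height, m (> 0).
#' @return SDI = `depth_z / fin_height_B` (unitless).
#' @export
sdi_value <- function(depth_z, fin_height_B) {
  if (any(depth_z <= 0)) stop("depth_z must be positive")
  if (any(fin_height_B <= 0)) stop("fin_height_B must be positive")
  depth_z / fin_height_B
}

#' Fit SDI-versus-depth regressions by life stage
#'
#' Evaluates each individual's SDI across a grid of habitat water depths and
#' fits a linear regression per life stage. With the intercept constrained
#' to zero (SDI is exactly 0 at z = 0 by construction) the fitted slope
#' equals the cohort mean of `1/B`. The slope difference between stages is
#' tested by the depth-by-stage interaction F-test (ANCOVA).
#'
#' @param fins data.frame with `individual_id`, `life_stage`,
#'   `fin_height_m` (see [gen_fin_heights()]).
#' @param depth_grid Depths at which SDI is evaluated, m (default 0.1-1.5 m
#'   in 0.01-m steps).
#' @param intercept Fit an unconstrained intercept instead of forcing it
#'   through the origin?
#' @return An object of class `sdi_model`: list with `stages` (per-stage
#'   slope, intercept, n), `ancova` (`F`, `df1`, `df2`, `p`, or NULL when a
#'   single stage is present), `points` (the stacked grid evaluations), and
#'   the call parameters.
#' @export
sdi_regression <- function(fins, depth_grid = seq(0.1, 1.5, by = 0.01),
                           intercept = FALSE) {
  if (length(depth_grid) < 3) stop("depth grid needs >= 3 depths")
  if (any(fins$fin_height_m <= 0)) stop("fin heights must be positive")
  stages <- unique(fins$life_stage)
  pts <- do.call(rbind, lapply(seq_len(nrow(fins)), function(i) {
    data.frame(individual_id = fins$individual_id[i],
               life_stage = fins$life_stage[i],
               depth = depth_grid,
               sdi = sdi_value(depth_grid, fins$fin_height_m[i]))
  }))
  per_stage <- do.call(rbind, lapply(stages, function(s) {
    d <- pts[pts$life_stage == s, ]
    f <- if (intercept) stats::lm(sdi ~ depth, data = d)
         else stats::lm(sdi ~ depth + 0, data = d)
    cf <- stats::coef(f)
    data.frame(life_stage = s,
               slope = unname(cf[["depth"]]),
               intercept = if (intercept) unname(cf[["(Intercept)"]]) else 0,
               n_individuals = sum(fins$life_stage == s))
  }))
  ancova <- NULL
  if (length(stages) >= 2) {
    full <- if (intercept) stats::lm(sdi ~ depth * life_stage, data = pts)
            else stats::lm(sdi ~ depth + depth:life_stage + 0, data = pts)
    red <- if (intercept) stats::lm(sdi ~ depth + life_stage, data = pts)
           else stats::lm(sdi ~ depth + 0, data = pts)
    an <- stats::anova(red, full)
    ancova <- data.frame(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                         p = an$`Pr(>F)`[2])
  } else {
    warning("single life stage present; slope-difference test skipped")
  }
  structure(list(stages = per_stage, ancova = ancova, points = pts,
                 depth_grid = depth_grid, intercept = intercept),
            class = "sdi_model")
}

#' Critical depth where the fitted SDI line crosses a threshold
#'
#' The depth at which a life stage's fitted SDI equals `threshold`
#' (default 3, the drag-significance limit): `z* = (threshold - intercept) / slope`.
#' With a zero intercept and a single individual this is exactly `3 * B`.
#'
#' @param model An `sdi_model`.
#' @param threshold SDI threshold (default 3).
#' @return Named numeric vector of critical depths (m) by life stage.
#' @export
critical_depth <- function(model, threshold = 3) {
  st <- model$stages
  if (any(st$slope <= 0)) stop("non-positive SDI slope")
  stats::setNames((threshold - st$intercept) / st$slope, st$life_stage)
}

#' Newborn propulsive-advantage depth band
#'
#' Depths between the newborn and adult critical depths, where newborns keep
#' SDI >= 3 (negligible drag) while adults fall below 3 (significant drag).
#'
#' @param newborn_zstar,adult_zstar Critical depths, m.
#' @return Named numeric: `lower`, `upper`, `width` (m).
#' @export
advantage_band <- function(newborn_zstar, adult_zstar) {
  if (newborn_zstar >= adult_zstar) {
    stop("no advantage zone: newborn critical depth (", newborn_zstar,
         ") is not below the adult's (", adult_zstar, ")")
  }
  c(lower = unname(newborn_zstar), upper = unname(adult_zstar),
    width = unname(adult_zstar - newborn_zstar))
}
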
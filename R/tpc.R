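## Thermal-performance-curve fitting for absolute aerobic scope.
##
## Two candidate shapes: a Gaussian, f(T) = a * exp(-0.5 ((T - t_opt)/sigma)^2),
## and a quadratic, f(T) = c0 + c1 T + c2 T^2. The Gaussian is fitted by
## Levenberg-Marquardt nonlinear least squares from 64 random starts; the
## quadratic is linear in its coefficients and solved exactly by OLS. Models
## are compared by AICc; uncertainty comes from a residual bootstrap with
## bias-corrected and accelerated (BCa) intervals.

gaussian_tpc <- function(temp, a, t_opt, sigma) {
  a * exp(-0.5 * ((temp - t_opt) / sigma)^2)
}

#' Convert between Gaussian width and 80%-of-peak performance breadth
#'
#' For a Gaussian curve the interval where performance stays at or above a
#' fraction `q` of the peak has width `2 * sigma * sqrt(2 * log(1/q))`; at
#' the 80% level that is `2 * sigma * sqrt(2 * log(1.25))`.
#'
#' @param sigma Gaussian width, deg C.
#' @param breadth Breadth at fraction `q`, deg C.
#' @param q Fraction of peak (default 0.8).
#' @return The corresponding breadth or sigma.
#' @export
breadth_from_sigma <- function(sigma, q = 0.8) 2 * sigma * sqrt(2 * log(1 / q))

#' @rdname breadth_from_sigma
#' @export
sigma_from_breadth <- function(breadth, q = 0.8) breadth / (2 * sqrt(2 * log(1 / q)))

# Internal Gaussian fit from one start via Levenberg-Marquardt.
fit_gaussian_once <- function(temp, y, start) {
  resid_fn <- function(p) y - gaussian_tpc(temp, p[1], p[2], p[3])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = c(0, -Inf, 1e-6), upper = c(Inf, Inf, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4) return(NULL)
  list(par = unname(fit$par), rss = sum(fit$fvec^2))
}

#' Fit a thermal-performance curve
#'
#' Gaussian fits use nonlinear least squares from `n_starts` starting
#' vectors drawn uniformly from data-informed bounds (peak within 0.5-1.5
#' times the observed maximum, optimum within the observed temperature range
#' +/- 2 deg C, width in (0.1, 10]); the converged fit with the lowest
#' residual sum of squares wins. Quadratic fits are exact OLS. A warning is
#' raised when the data contain three or fewer distinct temperatures, since
#' the optimum is then informed by very few levels.
#'
#' @param data data.frame with columns `temperature` and `aas`.
#' @param shape `"gaussian"` or `"quadratic"`.
#' @param n_starts Number of random starts for the Gaussian fit.
#' @param seed Integer seed controlling the start draws.
#' @return An object of class `tpc_fit`: list with `shape`, `params`
#'   (named vector), `fitted`, `residuals`, `rss`, `n_obs`, `aicc`, `data`.
#' @export
fit_tpc <- function(data, shape = c("gaussian", "quadratic"),
                    n_starts = 64, seed = 1) {
  shape <- match.arg(shape)
  temp <- data$temperature
  y <- data$aas
  ok <- is.finite(temp) & is.finite(y)
  temp <- temp[ok]; y <- y[ok]
  n <- length(y)
  if (n < 4 || length(unique(temp)) < 2) {
    stop("need >= 4 observations spanning >= 2 distinct temperatures")
  }
  if (length(unique(temp)) <= 3) {
    warning("optimum is informed by only ", length(unique(temp)),
            " measured temperatures; interpret with caution")
  }
  if (shape == "quadratic") {
    fit <- stats::lm(y ~ temp + I(temp^2))
    params <- stats::setNames(stats::coef(fit), c("c0", "c1", "c2"))
    fitted <- unname(stats::fitted(fit))
    rss <- sum(stats::resid(fit)^2)
  } else {
    set.seed(as.integer(seed))
    lo <- c(0.5 * max(y), min(temp) - 2, 0.1)
    hi <- c(1.5 * max(y), max(temp) + 2, 10)
    starts <- cbind(stats::runif(n_starts, lo[1], hi[1]),
                    stats::runif(n_starts, lo[2], hi[2]),
                    stats::runif(n_starts, lo[3], hi[3]))
    best <- NULL
    for (s in seq_len(n_starts)) {
      cand <- fit_gaussian_once(temp, y, starts[s, ])
      if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) best <- cand
    }
    if (is.null(best)) {
      stop("no Gaussian start converged; bounds tried: a in [",
           signif(lo[1], 4), ", ", signif(hi[1], 4), "], t_opt in [",
           lo[2], ", ", hi[2], "], sigma in (", lo[3], ", ", hi[3], "]")
    }
    params <- stats::setNames(best$par, c("a", "t_opt", "sigma"))
    fitted <- gaussian_tpc(temp, params[1], params[2], params[3])
    rss <- best$rss
  }
  k <- length(params) + 1   # +1 for the error variance
  structure(list(shape = shape, params = params, fitted = fitted,
                 residuals = y - fitted, rss = rss, n_obs = n,
                 aicc = aicc_value(rss, n, k),
                 data = data.frame(temperature = temp, aas = y)),
            class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("Thermal performance curve (", x$shape, ")\n", sep = "")
  print(round(x$params, 4))
  cat("n =", x$n_obs, " RSS =", signif(x$rss, 6),
      " AICc =", signif(x$aicc, 6), "\n")
  invisible(x)
}

# Least-squares AICc: n*log(RSS/n) + 2k + 2k(k+1)/(n-k-1), k counting the
# error variance as a parameter.
aicc_value <- function(rss, n, k) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select among fitted curves by AICc
#'
#' @param fits List of `tpc_fit` objects fitted to the same data.
#' @return List with `best` (the winning fit; ties go to the first listed)
#'   and `table` (shape, aicc, delta_aicc sorted ascending).
#' @export
aicc_select <- function(fits) {
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1) stop("fits must be on identical data")
  aicc <- vapply(fits, function(f) f$aicc, numeric(1))
  shapes <- vapply(fits, function(f) f$shape, character(1))
  ord <- order(aicc)   # stable: ties keep list order
  tab <- data.frame(shape = shapes[ord], aicc = aicc[ord],
                    delta_aicc = aicc[ord] - min(aicc))
  list(best = fits[[ord[1]]], table = tab)
}

#' Derived curve parameters: peak, optimum and performance breadth
#'
#' For a Gaussian fit the optimum is `t_opt` and the breadth at fraction
#' `level` of the peak has the closed form `2 * sigma * sqrt(2 * log(1/level))`.
#' For a quadratic, the optimum is `-c1/(2 c2)` (requiring `c2 < 0`) and the
#' crossings are found by root-finding on the fitted curve.
#'
#' @param model A `tpc_fit`.
#' @param level Fraction of peak defining the breadth (default 0.8).
#' @param use_roots Force numeric root-finding even for the Gaussian
#'   (the closed form and the root-finder agree to < 1e-8 deg C).
#' @return data.frame: `aas_max`, `t_peak`, `lower`, `upper`, `breadth`.
#' @export
derive_params <- function(model, level = 0.8, use_roots = FALSE) {
  p <- model$params
  if (model$shape == "gaussian") {
    t_peak <- unname(p["t_opt"])
    aas_max <- unname(p["a"])
    f <- function(T) gaussian_tpc(T, p["a"], p["t_opt"], p["sigma"])
    half <- breadth_from_sigma(unname(p["sigma"]), q = level) / 2
    lower <- t_peak - half; upper <- t_peak + half
    if (use_roots) {
      g <- function(T) f(T) - level * aas_max
      lower <- stats::uniroot(g, c(t_peak - 20 * p["sigma"], t_peak),
                              tol = 1e-12)$root
      upper <- stats::uniroot(g, c(t_peak, t_peak + 20 * p["sigma"]),
                              tol = 1e-12)$root
    }
  } else {
    if (p["c2"] >= 0) stop("quadratic has no interior maximum (c2 >= 0)")
    t_peak <- unname(-p["c1"] / (2 * p["c2"]))
    f <- function(T) p["c0"] + p["c1"] * T + p["c2"] * T^2
    aas_max <- unname(f(t_peak))
    g <- function(T) f(T) - level * aas_max
    # crossings of a parabola: quadratic formula
    cc <- c(unname(p["c0"]) - level * aas_max, unname(p["c1"]), unname(p["c2"]))
    disc <- cc[2]^2 - 4 * cc[3] * cc[1]
    roots <- sort((-cc[2] + c(-1, 1) * sqrt(disc)) / (2 * cc[3]))
    lower <- roots[1]; upper <- roots[2]
  }
  data.frame(aas_max = aas_max, t_peak = t_peak, lower = lower,
             upper = upper, breadth = upper - lower)
}

# Fast single-start refit used by the bootstrap and jackknife: reuses the
# point estimate as the start.
refit_tpc <- function(model, y_new) {
  temp <- model$data$temperature
  if (model$shape == "quadratic") {
    X <- cbind(1, temp, temp^2)
    beta <- stats::.lm.fit(X, y_new)$coefficients
    params <- stats::setNames(beta, c("c0", "c1", "c2"))
    fitted <- drop(X %*% beta)
  } else {
    cand <- fit_gaussian_once(temp, y_new, unname(model$params))
    if (is.null(cand)) return(NULL)
    params <- stats::setNames(cand$par, c("a", "t_opt", "sigma"))
    fitted <- gaussian_tpc(temp, params[1], params[2], params[3])
  }
  out <- model
  out$params <- params
  out$fitted <- fitted
  out$residuals <- y_new - fitted
  out$rss <- sum(out$residuals^2)
  out$data$aas <- y_new
  out
}

# BCa interval from bootstrap draws, a point estimate, and jackknife values.
bca_interval <- function(draws, estimate, jack, conf = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0) return(c(NA_real_, NA_real_))
  if (stats::sd(draws) == 0) return(c(draws[1], draws[1]))
  alpha <- (1 - conf) / 2
  z0 <- stats::qnorm(mean(draws < estimate))
  if (!is.finite(z0)) z0 <- 0
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  a <- if (den == 0) 0 else num / den
  zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  unname(stats::quantile(draws, c(a1, a2), type = 7))
}

#' Residual-bootstrap BCa intervals for a thermal-performance curve
#'
#' Builds replicate datasets `y* = fitted + resampled residuals` (with
#' replacement), refits each from the point estimate, and computes 95%
#' bias-corrected and accelerated intervals for the curve parameters and the
#' derived quantities (peak, optimum, breadth and its endpoints). The
#' acceleration constant comes from a jackknife over observations.
#'
#' @param model A `tpc_fit`.
#' @param n_boot Number of bootstrap replicates (default 999).
#' @param level Fraction of peak defining the breadth (default 0.8).
#' @param conf Interval coverage (default 0.95).
#' @param seed Integer seed.
#' @param max_fail Maximum tolerated fraction of non-converged replicates.
#' @return List with `draws` (data.frame of per-replicate derived values),
#'   `intervals` (derived-parameter table with `bca_low`/`bca_high`),
#'   `n_boot`, `n_failed`, `seed`.
#' @export
bootstrap_bca <- function(model, n_boot = 999, level = 0.8, conf = 0.95,
                          seed = 1, max_fail = 0.2) {
  set.seed(as.integer(seed))
  y_hat <- model$fitted
  n <- model$n_obs
  # residuals from a p-parameter fit underestimate the error variance by a
  # factor (n - p)/n; inflate before resampling so replicate noise has the
  # right scale at small n
  p_model <- length(model$params)
  res <- model$residuals * sqrt(n / (n - p_model))
  derive1 <- function(m) unlist(derive_params(m, level = level))
  est <- derive1(model)
  draws <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, names(est)))
  n_failed <- 0L
  for (bidx in seq_len(n_boot)) {
    y_star <- y_hat + sample(res, n, replace = TRUE)
    m_star <- refit_tpc(model, y_star)
    d <- tryCatch(if (is.null(m_star)) NULL else derive1(m_star),
                  error = function(e) NULL)
    if (is.null(d)) n_failed <- n_failed + 1L else draws[bidx, ] <- d
  }
  if (n_failed > max_fail * n_boot) {
    stop(n_failed, "/", n_boot, " bootstrap replicates failed to converge")
  }
  # jackknife over observations for the acceleration constant
  jack <- matrix(NA_real_, n, length(est), dimnames = list(NULL, names(est)))
  temp <- model$data$temperature
  y <- model$data$aas
  for (i in seq_len(n)) {
    sub <- model
    sub$data <- data.frame(temperature = temp[-i], aas = y[-i])
    m_i <- refit_tpc_data(sub)
    d <- tryCatch(if (is.null(m_i)) NULL else derive1(m_i),
                  error = function(e) NULL)
    if (!is.null(d)) jack[i, ] <- d
  }
  intervals <- do.call(rbind, lapply(names(est), function(q) {
    ci <- bca_interval(draws[, q], est[[q]], jack[is.finite(jack[, q]), q],
                       conf = conf)
    data.frame(quantity = q, estimate = est[[q]],
               bca_low = ci[1], bca_high = ci[2])
  }))
  list(draws = as.data.frame(draws), intervals = intervals,
       n_boot = n_boot, n_failed = n_failed, seed = seed)
}

# Refit a model on the (possibly subsetted) data stored in the object.
refit_tpc_data <- function(model) {
  temp <- model$data$temperature
  y <- model$data$aas
  if (model$shape == "quadratic") {
    X <- cbind(1, temp, temp^2)
    beta <- stats::.lm.fit(X, y)$coefficients
    model$params <- stats::setNames(beta, c("c0", "c1", "c2"))
    model$fitted <- drop(X %*% beta)
  } else {
    cand <- fit_gaussian_once(temp, y, unname(model$params))
    if (is.null(cand)) return(NULL)
    model$params <- stats::setNames(cand$par, c("a", "t_opt", "sigma"))
    model$fitted <- gaussian_tpc(temp, model$params[1], model$params[2],
                                 model$params[3])
  }
  model$residuals <- y - model$fitted
  model$rss <- sum(model$residuals^2)
  model$n_obs <- length(y)
  model
}

#' Pairwise Holm-Sidak comparisons of group means
#'
#' Runs all pairwise Welch t-tests between groups, orders raw p-values
#' ascending and applies the Holm-Sidak step-down adjustment
#' `p_adj(i) = 1 - (1 - p(i))^(m - i + 1)` with monotonicity enforced, then
#' builds a compact letter display (groups sharing a letter do not differ at
#' `alpha`).
#'
#' @param values Numeric response values.
#' @param groups Group labels (factor or vector), same length as `values`.
#' @param alpha Significance level for the letter display.
#' @return List with `comparisons` (group pair, t, raw and adjusted p) and
#'   `letters` (named character vector of significance letters).
#' @export
holm_sidak_pairwise <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2) stop("need >= 2 groups")
  split_vals <- split(values, groups)
  if (any(vapply(split_vals, length, integer(1)) < 2)) {
    stop("every group needs n >= 2")
  }
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  comp <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     t = NA_real_, p_raw = NA_real_)
  for (i in seq_len(m)) {
    x <- split_vals[[pairs[1, i]]]; y <- split_vals[[pairs[2, i]]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stop("zero within-group variance in both groups of pair ",
           pairs[1, i], "-", pairs[2, i])
    }
    tt <- stats::t.test(x, y)   # Welch
    comp$t[i] <- unname(tt$statistic)
    comp$p_raw[i] <- tt$p.value
  }
  ord <- order(comp$p_raw)
  adj <- 1 - (1 - comp$p_raw[ord])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  comp$p_adj <- NA_real_
  comp$p_adj[ord] <- adj
  list(comparisons = comp,
       letters = compact_letters(comp, lev, alpha = alpha))
}

# Compact letter display from a pairwise table via insert-and-absorb.
compact_letters <- function(comp, lev, alpha = 0.05) {
  k <- length(lev)
  differ <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(nrow(comp))) {
    if (comp$p_adj[i] < alpha) {
      differ[comp$group1[i], comp$group2[i]] <- TRUE
      differ[comp$group2[i], comp$group1[i]] <- TRUE
    }
  }
  sets <- list(lev)   # candidate letter groups, split until conflict-free
  repeat {
    conflict <- NULL
    for (s in seq_along(sets)) {
      g <- sets[[s]]
      if (length(g) > 1) {
        prs <- utils::combn(g, 2)
        bad <- which(apply(prs, 2, function(p) differ[p[1], p[2]]))
        if (length(bad)) { conflict <- list(s = s, pair = prs[, bad[1]]); break }
      }
    }
    if (is.null(conflict)) break
    g <- sets[[conflict$s]]
    sets[[conflict$s]] <- setdiff(g, conflict$pair[1])
    sets[[length(sets) + 1]] <- setdiff(g, conflict$pair[2])
    # absorb duplicates/subsets (of equal sets, keep the earlier one)
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]]) &&
          (length(sets[[a]]) < length(sets[[b]]) || a > b)) {
        keep[a] <- FALSE
      }
    }
    sets <- sets[keep]
  }
  letters_out <- stats::setNames(rep("", k), lev)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) {
      letters_out[g] <- paste0(letters_out[g], letters[s])
    }
  }
  letters_out
}
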
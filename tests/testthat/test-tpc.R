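test_that("the multistart Gaussian fit recovers noiseless parameters", {
  temps <- seq(25, 33, by = 0.5)
  d <- gen_aas_dataset(peak = 317.10, t_opt = 29.15, breadth80 = 3.30,
                       temps = temps, n_per_temp = 1, noise_sd = 0, seed = 1)
  f <- fit_tpc(d, "gaussian", seed = 2)
  sigma <- sigma_from_breadth(3.30)
  expect_equal(unname(f$params["a"]), 317.10, tolerance = 1e-6)
  expect_equal(unname(f$params["t_opt"]), 29.15, tolerance = 1e-6)
  expect_equal(unname(f$params["sigma"]), sigma, tolerance = 1e-6)
})

test_that("a quadratic fit of exact parabolic data has zero residuals", {
  temps <- seq(25, 33, by = 1)
  d <- data.frame(temperature = temps,
                  aas = 300 - 5 * (temps - 29)^2)
  f <- fit_tpc(d, "quadratic")
  expect_lt(f$rss, 1e-18 * 300^2)
  expect_equal(derive_params(f)$t_peak, 29, tolerance = 1e-9)
})

test_that("a three-temperature design fits with a caution warning", {
  d <- gen_aas_dataset(seed = 4)   # 27/29/31, n = 9/8/8
  expect_warning(f <- fit_tpc(d, "gaussian", seed = 1),
                 "only 3 measured temperatures")
  expect_s3_class(f, "tpc_fit")
  expect_error(fit_tpc(d[1:3, ], "gaussian"), ">= 4 observations")
})

test_that("AICc follows the least-squares formula and selects the lowest", {
  # delta for equal k, n=25, RSS 100 vs 200 is 25*ln(2)
  mk <- function(shape, rss) {
    structure(list(shape = shape, rss = rss, n_obs = 25,
                   aicc = sharkperf:::aicc_value(rss, 25, 4)),
              class = "tpc_fit")
  }
  sel <- aicc_select(list(mk("gaussian", 100), mk("quadratic", 200)))
  expect_equal(sel$table$delta_aicc[2], 25 * log(2), tolerance = 1e-12)
  expect_equal(sel$best$shape, "gaussian")
  # equal RSS and k: delta 0 and the first-listed fit wins
  tie <- aicc_select(list(mk("gaussian", 100), mk("quadratic", 100)))
  expect_equal(tie$table$delta_aicc[2], 0)
  expect_equal(tie$best$shape, "gaussian")
  # order invariance of the ranking itself
  sel_r <- aicc_select(list(mk("quadratic", 200), mk("gaussian", 100)))
  expect_equal(sel_r$best$shape, "gaussian")
  expect_error(sharkperf:::aicc_value(10, 5, 4), "undefined")
})

test_that("derived breadth crossings match the closed form and root-finder", {
  sigma <- sigma_from_breadth(3.30)
  f <- structure(list(shape = "gaussian",
                      params = c(a = 317.10, t_opt = 29.15, sigma = sigma)),
                 class = "tpc_fit")
  d_closed <- derive_params(f)
  d_roots <- derive_params(f, use_roots = TRUE)
  expect_equal(d_closed$lower, 27.5, tolerance = 1e-9)
  expect_equal(d_closed$upper, 30.8, tolerance = 1e-9)
  expect_lt(abs(d_closed$lower - d_roots$lower), 1e-8)
  expect_lt(abs(d_closed$upper - d_roots$upper), 1e-8)
  # property: agreement on random Gaussians
  set.seed(42)
  for (i in 1:20) {
    fr <- structure(list(shape = "gaussian",
                         params = c(a = runif(1, 50, 500),
                                    t_opt = runif(1, 20, 35),
                                    sigma = runif(1, 0.5, 6))),
                    class = "tpc_fit")
    expect_lt(abs(derive_params(fr)$lower -
                    derive_params(fr, use_roots = TRUE)$lower), 1e-8)
    expect_lt(abs(derive_params(fr)$upper -
                    derive_params(fr, use_roots = TRUE)$upper), 1e-8)
  }
  # quadratic without an interior maximum errors
  fq <- structure(list(shape = "quadratic",
                       params = c(c0 = 1, c1 = 1, c2 = 0.5)),
                  class = "tpc_fit")
  expect_error(derive_params(fq), "no interior maximum")
})

test_that("BCa machinery reduces to expected special cases", {
  # zero residuals: every draw equals the point estimate, interval collapses
  temps <- seq(26, 32, by = 0.5)
  sigma <- sigma_from_breadth(3.3)
  d <- data.frame(temperature = temps,
                  aas = 317.1 * exp(-0.5 * ((temps - 29.15) / sigma)^2))
  f <- fit_tpc(d, "gaussian", seed = 1)
  b <- bootstrap_bca(f, n_boot = 50, seed = 1)
  iv <- b$intervals[b$intervals$quantity == "t_peak", ]
  expect_equal(iv$bca_low, iv$estimate, tolerance = 1e-6)
  expect_equal(iv$bca_high, iv$estimate, tolerance = 1e-6)
  # symmetric draws with z0 = 0, a = 0: BCa equals the percentile interval
  draws <- seq(-1, 1, length.out = 2001)   # median = 0 = estimate
  jack <- seq(-1, 1, length.out = 11)      # symmetric -> a = 0
  ci <- sharkperf:::bca_interval(draws, 0, jack)
  # z0 estimated from a finite grid is near but not exactly 0, so the
  # adjusted quantile levels wobble at ~1e-4
  expect_equal(ci, unname(quantile(draws, c(0.025, 0.975))),
               tolerance = 1e-3)
})

test_that("bootstrap intervals bracket the point estimate on noisy fits", {
  d <- gen_aas_dataset(seed = 10)
  f <- suppressWarnings(fit_tpc(d, "gaussian", seed = 1))
  b <- bootstrap_bca(f, n_boot = 299, seed = 2)
  iv <- b$intervals
  expect_true(all(iv$bca_low <= iv$estimate + 1e-9))
  expect_true(all(iv$bca_high >= iv$estimate - 1e-9))
  expect_lte(b$n_failed, 0.2 * 299)
})

test_that("Holm-Sidak adjustment is monotone, conservative and identity at m=1", {
  set.seed(3)
  v <- c(rnorm(9, 250, 30), rnorm(8, 320, 30), rnorm(8, 255, 30))
  g <- rep(c(27, 29, 31), c(9, 8, 8))
  hs <- holm_sidak_pairwise(v, g)
  cmp <- hs$comparisons
  expect_true(all(cmp$p_adj >= cmp$p_raw - 1e-12))
  ord <- order(cmp$p_raw)
  expect_true(all(diff(cmp$p_adj[ord]) >= -1e-12))
  # m = 1: adjustment is the identity
  hs1 <- holm_sidak_pairwise(v[g != 31], g[g != 31])
  # 1 - (1 - p)^1 loses a few ulps relative to p itself
  expect_equal(hs1$comparisons$p_adj, hs1$comparisons$p_raw, tolerance = 1e-9)
  # identical groups share a single letter with p ~ 1
  x <- rnorm(6)
  hs0 <- holm_sidak_pairwise(c(x, x, x), rep(1:3, each = 6))
  expect_true(all(hs0$comparisons$p_adj > 0.999))
  expect_length(unique(hs0$letters), 1)
  expect_error(
    holm_sidak_pairwise(c(1, 1, 2, 2), c("a", "a", "b", "b")),
    "zero within-group variance")
})

test_that("groups built to differ 27-29 and 29-31 but not 27-31 get letters a/b/a", {
  set.seed(5)
  v <- c(rnorm(9, 240, 25), rnorm(8, 320, 25), rnorm(8, 245, 25))
  g <- rep(c("27", "29", "31"), c(9, 8, 8))
  hs <- holm_sidak_pairwise(v, g)
  expect_equal(unname(hs$letters["27"]), unname(hs$letters["31"]))
  expect_false(hs$letters["27"] == hs$letters["29"])
})
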
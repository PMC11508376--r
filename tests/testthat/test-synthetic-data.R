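# The synthetic landscape generator: distributional contracts, determinism,
# and the CSV round-trip through the register readers.

test_that("fire counts follow the register-scale Poisson and areas respect the cut-off", {
  cfg <- synthetic_config(fire_rate = 118, n_years = 12, seed = 101)
  fires <- simulate_fires(cfg)
  lambda <- 118 * 12
  expect_lt(abs(nrow(fires) - lambda), 3 * sqrt(lambda))
  expect_true(all(fires$area_m2 >= 100))
  expect_true(all(fires$year %in% 2000:2011))
  expect_true(all(fires$x_m >= 0 & fires$x_m <= 150000))
  # reproducible, and a different seed gives a different register
  expect_identical(fires, simulate_fires(cfg))
  cfg2 <- cfg; cfg2$seed <- 102
  expect_false(identical(fires, simulate_fires(cfg2)))
})

test_that("uniform landscapes show no quadrat signal, clustered ones do", {
  cfg <- synthetic_config(fire_rate = 200, n_years = 12, cluster_sd_km = 0,
                          seed = 103)
  fires <- simulate_fires(cfg)
  quadrat_p <- function(f, extent_m = 150000, k = 4) {
    qx <- cut(f$x_m, seq(0, extent_m, length.out = k + 1),
              include.lowest = TRUE)
    qy <- cut(f$y_m, seq(0, extent_m, length.out = k + 1),
              include.lowest = TRUE)
    counts <- as.vector(table(qx, qy))
    suppressWarnings(
      chisq.test(counts, p = rep(1 / length(counts), length(counts)))$p.value)
  }
  expect_gt(quadrat_p(fires), 0.01)
  cfg_cl <- synthetic_config(fire_rate = 200, n_years = 12,
                             cluster_sd_km = 5, n_clusters = 6, seed = 103)
  expect_lt(quadrat_p(simulate_fires(cfg_cl)), 1e-6)
})

test_that("site layouts respect the minimum separation or fail loudly", {
  cfg <- synthetic_config(n_sites = 21, extent_km = 100,
                          min_site_separation_km = 7, seed = 104)
  sites <- simulate_sites(cfg)
  expect_equal(nrow(sites), 21)
  d <- as.matrix(dist(sites[, c("x_m", "y_m")])) / 1000
  expect_true(all(d[upper.tri(d)] >= 7 - 1e-3))  # metre rounding slack
  expect_equal(unique(sites$sampling_year), 2012)
  expect_identical(sites, simulate_sites(cfg))

  tiny <- synthetic_config(n_sites = 3, extent_km = 1,
                           min_site_separation_km = 7, seed = 104)
  expect_error(simulate_sites(tiny), "increase extent_km")
})

test_that("with no connectivity effect the pooled pyrophilic fraction matches the baseline", {
  cfg <- synthetic_config(n_sites = 50, beta = 0, baseline_logit = -3.58,
                          seed = 105)
  sim <- simulate_dataset(cfg)
  frac <- sum(sim$sites$n_ind_pyro) / sum(sim$sites$n_ind_total)
  p0 <- plogis(-3.58)  # 0.0271
  n_tot <- sum(sim$sites$n_ind_total)
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / n_tot))
  expect_silent(validate_catches(sim$sites))
})

test_that("strong effects make the fitted slope positive essentially always", {
  cfg <- synthetic_config(n_sites = 40, beta = 2, true_alpha_s = 1,
                          true_alpha_t = 1)
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg$seed <- 200 + s
    sim <- simulate_dataset(cfg)
    resp <- build_responses(sim$sites)
    st <- connectivity(sim$sites, sim$fires,
                       connectivity_params(1, 1))$st_value
    if (fit_glm(resp$ln_odds, standardize(st))$slope > 0) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("a written synthetic dataset round-trips through the readers unchanged", {
  cfg <- synthetic_config(n_sites = 10, fire_rate = 30, seed = 106)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_synthetic(sim, dir)
  fires_back <- suppressMessages(
    load_fires(file.path(dir, "fires.csv"), min_area_m2 = cfg$min_area_m2))
  catches_back <- load_catches(file.path(dir, "catches.csv"))
  expect_equal(fires_back, sim$fires)
  expect_equal(catches_back, sim$sites, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$true_alpha_s, cfg$true_alpha_s)
  expect_equal(truth$seed, 106)
})
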
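# Standardization, the gaussian GLM, and the deviance-profile grid search.

test_that("standardize gives mean 0, sample sd 1, and rejects constants", {
  expect_equal(standardize(c(0, 1, 2)), c(-1, 0, 1))
  set.seed(8)
  x <- rexp(50)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(standardize(rep(3, 10)), "constant")
})

test_that("fit_glm reproduces exact and degenerate-correlation lines", {
  fit <- fit_glm(c(1, 3, 5), standardize(c(0, 1, 2)))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$deviance, 0, tolerance = 1e-20)

  # y orthogonal to x (Gram-Schmidt): slope 0, deviance = total SS
  set.seed(9)
  x <- standardize(rnorm(30))
  y0 <- rnorm(30)
  y <- y0 - mean(y0) - sum((y0 - mean(y0)) * x) / sum(x^2) * x
  fit0 <- fit_glm(y, x)
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_equal(fit0$deviance, sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("fit_glm agrees with the closed-form OLS oracle and centred-predictor identities", {
  set.seed(10)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    x <- standardize(rnorm(n) + rexp(n))
    y <- rnorm(n, sd = runif(1, 0.1, 5)) + runif(1, -2, 2) * x
    fit <- fit_glm(y, x)
    want <- ols_closed_form(y, x)
    for (f in c("intercept", "slope", "se_intercept", "se_slope",
                "p_intercept", "p_slope", "deviance")) {
      expect_equal(fit[[f]], want[[f]], tolerance = 1e-10)
    }
    expect_equal(fit$intercept, mean(y), tolerance = 1e-12)
  }
})

test_that("fit_glm validates its inputs", {
  expect_error(fit_glm(1:2, standardize(c(1, 2))), "at least 3")
  expect_error(fit_glm(1:5, 1:5), "not standardized")
  expect_error(fit_glm(1:4, standardize(1:5)), "equal length")
})

make_profile_case <- function(seed = 12, n_sites = 15, n_fires = 60) {
  set.seed(seed)
  traps <- random_traps(n_sites)
  fires <- random_fires(n_fires)
  st <- connectivity(traps, fires, connectivity_params(1, 1))$st_value
  resp <- data.frame(site_id = traps$site_id,
                     ln_odds = -3 + 0.8 * standardize(st) + rnorm(n_sites, 0, 0.4))
  list(traps = traps, fires = fires, resp = resp)
}

test_that("profile covers the grid and its optimum dominates every entry", {
  case <- make_profile_case()
  prof <- deviance_profile(case$traps, case$fires, case$resp, grid_step = 0.5)
  expect_equal(nrow(prof$grid), 81)  # 9 x 9
  expect_true(all(min(prof$grid$deviance) <= prof$grid$deviance))
  at_origin <- prof$grid$deviance[prof$grid$alpha_s == 0 &
                                  prof$grid$alpha_t == 0]
  expect_lte(min(prof$grid$deviance), at_origin)
  best_dev <- min(prof$grid$deviance)
  b <- prof$best
  expect_equal(
    prof$grid$deviance[prof$grid$alpha_s == b$alpha_s &
                       prof$grid$alpha_t == b$alpha_t], best_dev)
  # the refit at the optimum reproduces the recorded deviance, and the
  # intercept is the response mean (centred predictor)
  expect_equal(prof$best_fit$deviance, best_dev, tolerance = 1e-10)
  expect_equal(prof$best_fit$intercept, mean(case$resp$ln_odds),
               tolerance = 1e-10)
})

test_that("refining the grid never worsens the minimum deviance", {
  case <- make_profile_case(13)
  coarse <- deviance_profile(case$traps, case$fires, case$resp, grid_step = 1)
  fine <- deviance_profile(case$traps, case$fires, case$resp, grid_step = 0.5)
  expect_lte(min(fine$grid$deviance), min(coarse$grid$deviance))
})

test_that("degenerate profiles fall back to the intercept-only deviance and tie-break low", {
  case <- make_profile_case(14, n_sites = 8)
  # push every fire beyond the truncation radius: constant (zero) ST
  far_fires <- case$fires
  far_fires$x_m <- far_fires$x_m + 1e6
  prof <- deviance_profile(case$traps, far_fires, case$resp, grid_step = 1)
  y <- case$resp$ln_odds
  expect_true(all(prof$grid$deviance == sum((y - mean(y))^2)))
  expect_true(prof$degenerate)
  # all-tie grid resolves to the lexicographically smallest pair
  expect_equal(prof$best$alpha_s, 0)
  expect_equal(prof$best$alpha_t, 0)

  expect_error(deviance_profile(case$traps, case$fires[0, ], case$resp),
               "empty fire register")
  expect_error(deviance_profile(case$traps, case$fires, case$resp,
                                grid_step = 0.3), "divide")
})

test_that("fit_all_groups profiles each group/level independently", {
  cfg <- synthetic_config(n_sites = 15, extent_km = 60, fire_rate = 40,
                          beta = 1, seed = 15)
  sim <- simulate_dataset(cfg)
  fits <- fit_all_groups(sim$sites, sim$fires, grid_step = 0.5)
  expect_equal(nrow(fits$report), 6)
  expect_setequal(unique(fits$report$group),
                  c("pyrophilic", "non_pyrophilic", "saproxylic"))
  expect_setequal(unique(fits$report$level), c("individuals", "species"))
  expect_length(fits$profiles, 6)
  expect_true(all(fits$report$deviance >= 0))
  expect_true(all(fits$report$n_obs >= 3))
})
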
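# Independent oracles and fixture builders shared across the suite.

# Naive double-loop evaluation of the connectivity sum, kept deliberately
# scalar so it cannot share code paths with the vectorized implementation.
naive_st <- function(traps, fires, alpha_s, alpha_t, max_distance_km = 20,
                     log_base = "ln") {
  out <- numeric(nrow(traps))
  for (i in seq_len(nrow(traps))) {
    acc <- 0
    for (j in seq_len(nrow(fires))) {
      d <- sqrt((traps$x_m[i] - fires$x_m[j])^2 +
                (traps$y_m[i] - fires$y_m[j])^2) / 1000
      if (d > max_distance_km) next
      t_j <- traps$sampling_year[i] - fires$year[j]
      fa <- if (log_base == "ln") log(fires$area_m2[j]) else
        log10(fires$area_m2[j])
      acc <- acc + exp(-d * alpha_s) * fa * exp(-t_j * alpha_t)
    }
    out[i] <- acc
  }
  out
}

# Closed-form two-parameter OLS with t-based p-values (n - 2 df).
ols_closed_form <- function(y, x) {
  n <- length(y)
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  rss <- sum((y - intercept - slope * x)^2)
  s2 <- rss / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  se_intercept <- sqrt(s2 * (1 / n + xbar^2 / sxx))
  list(intercept = intercept, slope = slope,
       se_intercept = se_intercept, se_slope = se_slope,
       p_intercept = 2 * pt(-abs(intercept / se_intercept), n - 2),
       p_slope = 2 * pt(-abs(slope / se_slope), n - 2),
       deviance = rss)
}

random_fires <- function(m, extent_m = 40000, year_range = c(1999, 2010)) {
  data.frame(fire_id = sprintf("f%03d", seq_len(m)),
             x_m = runif(m, 0, extent_m), y_m = runif(m, 0, extent_m),
             area_m2 = exp(runif(m, log(100), log(1e6))),
             year = sample(year_range[1]:year_range[2], m, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_traps <- function(n, extent_m = 40000, sampling_year = 2011) {
  data.frame(site_id = sprintf("s%03d", seq_len(n)),
             x_m = runif(n, 0, extent_m), y_m = runif(n, 0, extent_m),
             sampling_year = sampling_year, stringsAsFactors = FALSE)
}

# Pooled single-site catch table carrying study-scale totals (60 of 2220
# individuals and 13 of 169 species pyrophilic, plus the control groups).
pooled_catch_fixture <- function() {
  data.frame(site_id = "pooled", x_m = 0, y_m = 0, sampling_year = 2011,
             n_ind_total = 2220, n_ind_pyro = 60, n_ind_nonpyro = 227,
             n_ind_sapro = 67, n_sp_total = 169, n_sp_pyro = 13,
             n_sp_nonpyro = 22, n_sp_sapro = 34, stringsAsFactors = FALSE)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}
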
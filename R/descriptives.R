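# Descriptive summaries of the catch table and the fire register.

#' Pooled catch composition across sites
#'
#' Pools counts over all sites and reports, for each classification group
#' and level, the count, the pooled total and the percentage of the total.
#'
#' @param sites Catch `data.frame` (see [load_catches()]).
#' @return `data.frame` with columns `group`, `level`, `count`, `total`,
#'   `pct` (percent of the pooled total).
#' @examples
#' pooled <- data.frame(site_id = "all", x_m = 0, y_m = 0,
#'   sampling_year = 2011,
#'   n_ind_total = 2220, n_ind_pyro = 60, n_ind_nonpyro = 227,
#'   n_ind_sapro = 67, n_sp_total = 169, n_sp_pyro = 13,
#'   n_sp_nonpyro = 22, n_sp_sapro = 34)
#' catch_summary(pooled)
#' @export
catch_summary <- function(sites) {
  validate_catches(sites)
  rows <- list()
  for (level in .valid_levels) {
    lev <- if (level == "individuals") "ind" else "sp"
    total <- sum(sites[[paste0("n_", lev, "_total")]])
    for (group in .valid_groups) {
      g <- switch(group, pyrophilic = "pyro", non_pyrophilic = "nonpyro",
                  saproxylic = "sapro")
      count <- sum(sites[[paste0("n_", lev, "_", g)]])
      rows[[paste(group, level)]] <- data.frame(
        group = group, level = level, count = count, total = total,
        pct = if (total > 0) 100 * count / total else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Fraction of forested area burned
#'
#' Register-level arithmetic: total burned area as a percentage of the
#' forested area of the study region.
#'
#' @param burned_km2 Total burned area over the register window, km2.
#' @param forested_km2 Forested area of the study region, km2.
#' @return Percentage (`100 * burned / forested`).
#' @examples
#' burned_fraction_pct(20.54, 14394)  # ~0.14
#' @export
burned_fraction_pct <- function(burned_km2, forested_km2) {
  stopifnot(burned_km2 >= 0, forested_km2 > 0)
  100 * burned_km2 / forested_km2
}

#' Summary statistics of a fire register
#'
#' @param fires Fire register `data.frame` (see [load_fires()]).
#' @return `data.frame` with one row: `n_fires`, `total_burned_km2`,
#'   `min_year`, `max_year`, `min_fires_per_year`, `max_fires_per_year`.
#' @export
register_summary <- function(fires) {
  per_year <- table(factor(fires$year, levels = min(fires$year):max(fires$year)))
  data.frame(n_fires = nrow(fires),
             total_burned_km2 = sum(fires$area_m2) / 1e6,
             min_year = min(fires$year), max_year = max(fires$year),
             min_fires_per_year = as.integer(min(per_year)),
             max_fires_per_year = as.integer(max(per_year)))
}
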
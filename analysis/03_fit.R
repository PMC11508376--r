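#!/usr/bin/env Rscript
# Step 3: the main analysis — for each classification group (pyrophilic,
# non-pyrophilic, saproxylic) and level (individuals, species), build the
# ln-odds response, select the decay scales on the deviance profile, and
# refit the gaussian GLM at the optimum. Writes the estimates table, the
# long-format deviance surfaces, the selected weight curves and the
# response-vs-connectivity scatter data.
# Usage: Rscript analysis/03_fit.R [--grid-step S]

suppressPackageStartupMessages({
  library(optparse)
  library(fireconn)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--in-dir", type = "character", default = "results/synthetic"),
  make_option("--out", type = "character", default = "results/fit"),
  make_option("--grid-step", type = "double", default = 0.1)
)))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

fires <- load_fires(file.path(opts$`in-dir`, "fires.csv"))
traps <- load_catches(file.path(opts$`in-dir`, "catches.csv"))

fits <- fit_all_groups(traps, fires, grid_step = opts$`grid-step`)
utils::write.csv(fits$report, file.path(opts$out, "report.csv"),
                 row.names = FALSE)

profiles <- do.call(rbind, lapply(names(fits$profiles), function(key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  cbind(group = parts[1], level = parts[2], fits$profiles[[key]]$grid)
}))
utils::write.csv(profiles, file.path(opts$out, "profile.csv"),
                 row.names = FALSE)

# weight curves at each combination's selected scales
curves <- do.call(rbind, lapply(names(fits$profiles), function(key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  best <- fits$profiles[[key]]$best
  d_grid <- seq(0, 10, by = 0.1)
  t_grid <- 0:12
  rbind(
    data.frame(group = parts[1], level = parts[2], dimension = "spatial",
               x = d_grid, alpha = best$alpha_s,
               weight = weight_curve_spatial(best$alpha_s, d_grid)),
    data.frame(group = parts[1], level = parts[2], dimension = "temporal",
               x = t_grid, alpha = best$alpha_t,
               weight = weight_curve_temporal(best$alpha_t, t_grid)))
}))
utils::write.csv(curves, file.path(opts$out, "weight_curves.csv"),
                 row.names = FALSE)

# scatter data: standardized connectivity at the selected scales vs ln-odds
scatter <- do.call(rbind, lapply(names(fits$profiles), function(key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  prof <- fits$profiles[[key]]
  if (prof$degenerate) return(NULL)
  resp <- build_responses(traps, group = parts[1], level = parts[2])
  st <- connectivity(traps[match(resp$site_id, traps$site_id), , drop = FALSE],
                     fires, prof$best)$st_value
  data.frame(group = parts[1], level = parts[2], site_id = resp$site_id,
             st_std = standardize(st), ln_odds = resp$ln_odds)
}))
utils::write.csv(scatter, file.path(opts$out, "scatter.csv"),
                 row.names = FALSE)
jsonlite::write_json(
  list(package_version = as.character(utils::packageVersion("fireconn")),
       grid_step = opts$`grid-step`, in_dir = opts$`in-dir`),
  file.path(opts$out, "run_info.json"), auto_unbox = TRUE, digits = NA)

print(fits)
cat("wrote", file.path(opts$out, c("report.csv", "profile.csv",
                                   "weight_curves.csv", "scatter.csv")),
    sep = "\n  ")
cat("\n")
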
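# Fire-history register and trap-catch I/O, with the register's filtering
# rules (minimum burned area, register year window).

.fire_cols <- c("fire_id", "x_m", "y_m", "area_m2", "year")

.catch_count_cols <- c(
  "n_ind_total", "n_ind_pyro", "n_ind_nonpyro", "n_ind_sapro",
  "n_sp_total", "n_sp_pyro", "n_sp_nonpyro", "n_sp_sapro"
)

.catch_cols <- c("site_id", "x_m", "y_m", "sampling_year", .catch_count_cols)

# coerce a column to numeric; error names the column and first offending row
.coerce_numeric <- function(df, cols, what) {
  for (col in cols) {
    v <- df[[col]]
    if (is.numeric(v)) next
    vn <- suppressWarnings(as.numeric(as.character(v)))
    bad <- which(is.na(vn) & !(is.na(v) | trimws(as.character(v)) == ""))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric value '%s' in column '%s' at data row %d",
                   what, as.character(v[bad[1]]), col, bad[1]), call. = FALSE)
    }
    df[[col]] <- vn
  }
  df
}

#' Load a fire-history register
#'
#' Reads a CSV fire register (columns `fire_id`, `x_m`, `y_m`, `area_m2`,
#' `year`) and applies the register's filtering rules: fires below the
#' minimum burned area or outside the register year window are dropped, as
#' are fires without coordinates (national registers often contain events
#' that were never geocoded). Drop counts are reported via [message()].
#'
#' Coordinates must already be in a projected planar CRS in metres (for
#' example a national grid); no reprojection is performed. The area
#' threshold is inclusive (`area_m2 >= min_area_m2`): registers round areas,
#' so records at exactly the cut-off are common and are kept.
#'
#' @param path Path to the register CSV.
#' @param min_area_m2 Minimum burned area kept, in square metres
#'   (default 100, the usual register cut-off). Inclusive.
#' @param year_range Length-2 integer vector `c(first, last)` of calendar
#'   years kept (inclusive), or `NULL` to keep all years.
#' @return A `data.frame` with columns `fire_id`, `x_m`, `y_m`, `area_m2`,
#'   `year`, one row per surviving fire, input order preserved.
#' @seealso [load_catches()], [connectivity()]
#' @export
load_fires <- function(path, min_area_m2 = 100, year_range = NULL) {
  if (!file.exists(path)) {
    stop("fire register not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.fire_cols, names(df))
  if (length(missing) > 0) {
    stop("fire register missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, .fire_cols, drop = FALSE]
  if (nrow(df) == 0) {
    warning("fire register '", basename(path), "' has no data rows",
            call. = FALSE)
    return(df)
  }
  df <- .coerce_numeric(df, c("x_m", "y_m", "area_m2", "year"), "fire register")
  df$fire_id <- as.character(df$fire_id)

  no_coord <- is.na(df$x_m) | is.na(df$y_m)
  if (any(no_coord)) {
    message(sum(no_coord), " fire(s) dropped: missing coordinates")
    df <- df[!no_coord, , drop = FALSE]
  }
  if (anyNA(df$area_m2) || any(df$area_m2 <= 0)) {
    stop("fire register: area_m2 must be positive for all fires",
         call. = FALSE)
  }
  small <- df$area_m2 < min_area_m2
  if (any(small)) {
    message(sum(small), " fire(s) dropped: area below ", min_area_m2, " m2")
    df <- df[!small, , drop = FALSE]
  }
  if (!is.null(year_range)) {
    stopifnot(length(year_range) == 2, year_range[1] <= year_range[2])
    out_year <- df$year < year_range[1] | df$year > year_range[2]
    if (any(out_year)) {
      message(sum(out_year), " fire(s) dropped: year outside [",
              year_range[1], ", ", year_range[2], "]")
      df <- df[!out_year, , drop = FALSE]
    }
  }
  if (any(df$year != round(df$year))) {
    stop("fire register: year must be an integer calendar year", call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("no fires remain after filtering", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write a fire register CSV
#'
#' Inverse of [load_fires()] (same column dialect).
#'
#' @param fires A fire `data.frame` as returned by [load_fires()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fires <- function(fires, path) {
  stopifnot(all(.fire_cols %in% names(fires)))
  utils::write.csv(fires[, .fire_cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Load a per-site trap-catch table
#'
#' Reads a CSV of sampling sites with their catch counts: per site, total
#' individuals and species, and individuals/species in each classification
#' group (pyrophilic, non-pyrophilic, obligate saproxylic). Group labels are
#' not mutually exclusive — a pyrophilic species can also be saproxylic — so
#' group counts need not sum to the total, but each group count must not
#' exceed its total.
#'
#' @param path Path to the catches CSV (columns `site_id`, `x_m`, `y_m`,
#'   `sampling_year`, `n_ind_total`, `n_ind_pyro`, `n_ind_nonpyro`,
#'   `n_ind_sapro`, `n_sp_total`, `n_sp_pyro`, `n_sp_nonpyro`, `n_sp_sapro`).
#' @return A `data.frame`, one row per site, in file order.
#' @seealso [build_responses()]
#' @export
load_catches <- function(path) {
  if (!file.exists(path)) {
    stop("catch table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.catch_cols, names(df))
  if (length(missing) > 0) {
    stop("catch table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, .catch_cols, drop = FALSE]
  if (nrow(df) == 0) {
    return(df)
  }
  df <- .coerce_numeric(df, c("x_m", "y_m", "sampling_year", .catch_count_cols),
                        "catch table")
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) {
    stop("catch table: duplicate site_id '",
         df$site_id[duplicated(df$site_id)][1], "'", call. = FALSE)
  }
  validate_catches(df)
  rownames(df) <- NULL
  df
}

#' Validate catch-count invariants
#'
#' Checks that every count is a non-negative integer and that no group count
#' exceeds the corresponding total; errors name the offending site and
#' column.
#'
#' @param sites A catch `data.frame` (see [load_catches()]).
#' @return `sites`, invisibly, if valid.
#' @export
validate_catches <- function(sites) {
  for (col in .catch_count_cols) {
    v <- sites[[col]]
    if (anyNA(v) || any(v < 0) || any(v != round(v))) {
      bad <- which(is.na(v) | v < 0 | v != round(v))[1]
      stop(sprintf("site '%s': column '%s' must be a non-negative integer",
                   sites$site_id[bad], col), call. = FALSE)
    }
  }
  groups <- c("pyro", "nonpyro", "sapro")
  for (lev in c("ind", "sp")) {
    total <- sites[[paste0("n_", lev, "_total")]]
    for (g in groups) {
      col <- paste0("n_", lev, "_", g)
      over <- sites[[col]] > total
      if (any(over)) {
        stop(sprintf("site '%s': %s exceeds %s", sites$site_id[which(over)[1]],
                     col, paste0("n_", lev, "_total")), call. = FALSE)
      }
    }
  }
  invisible(sites)
}

#' Write a trap-catch CSV
#'
#' Inverse of [load_catches()] (same column dialect).
#'
#' @param sites A catch `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catches <- function(sites, path) {
  stopifnot(all(.catch_cols %in% names(sites)))
  utils::write.csv(sites[, .catch_cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Years elapsed between a fire and sampling
#'
#' The temporal covariate of the connectivity kernel: integer calendar-year
#' difference, with the convention that a fire in the year before sampling is
#' 1 year prior. Fires must strictly precede sampling.
#'
#' @param sampling_year Sampling calendar year(s).
#' @param fire_year Fire calendar year(s).
#' @return Integer years elapsed, `>= 1`. Vectorized with recycling.
#' @examples
#' time_since_fire(2011, 2010)  # 1
#' time_since_fire(2011, 1999)  # 12
#' @export
time_since_fire <- function(sampling_year, fire_year) {
  if (any(fire_year >= sampling_year)) {
    stop("fire_year must be strictly before sampling_year ",
         "(fires must be prior to sampling)", call. = FALSE)
  }
  as.integer(sampling_year - fire_year)
}
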
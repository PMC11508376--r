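# The spatiotemporal connectivity kernel: for sampling site i,
#   ST_i = sum_j exp(-d_ij * alpha_s) * FA_j * exp(-T_j * alpha_t)
# over all register fires j within the truncation radius, where d_ij is the
# planar distance in km, FA_j the log-transformed burned area (m2) and T_j
# the integer years since fire j at the time of sampling.

#' Connectivity kernel parameters
#'
#' Bundles the two exponential decay scales and the truncation radius.
#' `alpha_s` (per km) and `alpha_t` (per year) are restricted to the
#' optimization range `[0, 4]` unless `allow_outside_range = TRUE`.
#'
#' @param alpha_s Spatial decay scale, per kilometre.
#' @param alpha_t Temporal decay scale, per year.
#' @param max_distance_km Truncation radius in km (default 20): fires beyond
#'   it contribute exactly zero. The boundary is inclusive.
#' @param log_base Log transform for burned area: `"ln"` (default, natural
#'   log) or `"log10"`. The choice rescales ST by a constant and is absorbed
#'   by the standardized GLM slope.
#' @param allow_outside_range Permit decay scales outside `[0, 4]`.
#' @return A list of class `"connectivity_params"`.
#' @export
connectivity_params <- function(alpha_s, alpha_t, max_distance_km = 20,
                                log_base = c("ln", "log10"),
                                allow_outside_range = FALSE) {
  log_base <- match.arg(log_base)
  stopifnot(is.numeric(alpha_s), length(alpha_s) == 1, is.finite(alpha_s),
            is.numeric(alpha_t), length(alpha_t) == 1, is.finite(alpha_t),
            is.numeric(max_distance_km), length(max_distance_km) == 1,
            max_distance_km > 0)
  if (!allow_outside_range &&
      (alpha_s < 0 || alpha_s > 4 || alpha_t < 0 || alpha_t > 4)) {
    stop("decay scales must lie in [0, 4] (the optimization range); ",
         "set allow_outside_range = TRUE to override", call. = FALSE)
  }
  structure(list(alpha_s = alpha_s, alpha_t = alpha_t,
                 max_distance_km = max_distance_km, log_base = log_base),
            class = "connectivity_params")
}

#' @export
print.connectivity_params <- function(x, ...) {
  cat(sprintf(
    "connectivity kernel: alpha_s = %g /km, alpha_t = %g /yr, radius %g km, log area base %s\n",
    x$alpha_s, x$alpha_t, x$max_distance_km, x$log_base))
  invisible(x)
}

#' Pairwise site-fire distances in kilometres
#'
#' Planar Euclidean distances between sites and fires whose coordinates are
#' in metres (projected CRS), returned in kilometres.
#'
#' @param traps `data.frame` with columns `x_m`, `y_m` (sites, n rows).
#' @param fires `data.frame` with columns `x_m`, `y_m` (fires, m rows).
#' @return An `n x m` numeric matrix of distances in km.
#' @export
pairwise_distance_km <- function(traps, fires) {
  if (anyNA(traps$x_m) || anyNA(traps$y_m) ||
      anyNA(fires$x_m) || anyNA(fires$y_m)) {
    stop("missing coordinates", call. = FALSE)
  }
  dx <- outer(traps$x_m, fires$x_m, "-")
  dy <- outer(traps$y_m, fires$y_m, "-")
  sqrt(dx^2 + dy^2) / 1000
}

.log_area <- function(area_m2, log_base) {
  if (any(area_m2 < 1)) {
    stop("burned area below 1 m2: log-transformed area would be negative; ",
         "apply the register area filter first", call. = FALSE)
  }
  if (log_base == "ln") log(area_m2) else log10(area_m2)
}

#' Spatiotemporal connectivity of sampling sites to past fires
#'
#' For each site, sums the log burned area of every register fire within the
#' truncation radius, discounted by `exp(-d * alpha_s)` in distance and
#' `exp(-T * alpha_t)` in years since fire. Every fire must predate every
#' site's sampling year.
#'
#' @param traps Sites `data.frame` (`site_id`, `x_m`, `y_m`,
#'   `sampling_year`).
#' @param fires Fire register `data.frame` (see [load_fires()]).
#' @param params A [connectivity_params()] object.
#' @return `data.frame` with one row per site: `site_id`, `st_value`
#'   (dimensionless, `>= 0`), `n_contributing_fires` (fires within the
#'   radius).
#' @examples
#' trap <- data.frame(site_id = "t1", x_m = 0, y_m = 0, sampling_year = 2011)
#' fire <- data.frame(fire_id = "f1", x_m = 2000, y_m = 0,
#'                    area_m2 = 10000, year = 2010)
#' connectivity(trap, fire, connectivity_params(1.7, 1.4))
#' @export
connectivity <- function(traps, fires, params) {
  stopifnot(inherits(params, "connectivity_params"))
  n <- nrow(traps)
  if (is.null(fires) || nrow(fires) == 0) {
    warning("empty fire register: connectivity is 0 at every site",
            call. = FALSE)
    return(data.frame(site_id = as.character(traps$site_id),
                      st_value = numeric(n),
                      n_contributing_fires = integer(n),
                      stringsAsFactors = FALSE))
  }
  d_km <- pairwise_distance_km(traps, fires)
  # errors if any fire is not strictly prior to sampling
  t_yr <- outer(traps$sampling_year, fires$year,
                function(s, f) time_since_fire(s, f))
  fa <- .log_area(fires$area_m2, params$log_base)
  within <- d_km <= params$max_distance_km
  w <- exp(-d_km * params$alpha_s - t_yr * params$alpha_t)
  w[!within] <- 0
  data.frame(site_id = as.character(traps$site_id),
             st_value = as.vector(w %*% fa),
             n_contributing_fires = as.integer(rowSums(within)),
             stringsAsFactors = FALSE)
}

#' Spatial weight curve of the connectivity kernel
#'
#' The weight `exp(-d * alpha_s)` a fire at distance `d` receives,
#' evaluated over a distance grid; 1 at the site, strictly decreasing for
#' `alpha_s > 0`.
#'
#' @param alpha_s Spatial decay scale, per km (`>= 0`).
#' @param d_grid Non-negative distances in km.
#' @return Numeric vector of weights in `(0, 1]`.
#' @export
weight_curve_spatial <- function(alpha_s, d_grid) {
  stopifnot(is.numeric(alpha_s), length(alpha_s) == 1, alpha_s >= 0)
  if (any(d_grid < 0)) stop("distances must be non-negative", call. = FALSE)
  exp(-d_grid * alpha_s)
}

#' Temporal weight curve of the connectivity kernel
#'
#' The weight `exp(-t * alpha_t)` a fire `t` years before sampling receives.
#'
#' @param alpha_t Temporal decay scale, per year (`>= 0`).
#' @param t_grid Non-negative times in years.
#' @return Numeric vector of weights in `(0, 1]`.
#' @export
weight_curve_temporal <- function(alpha_t, t_grid) {
  stopifnot(is.numeric(alpha_t), length(alpha_t) == 1, alpha_t >= 0)
  if (any(t_grid < 0)) stop("times must be non-negative", call. = FALSE)
  exp(-t_grid * alpha_t)
}

# Connectivity for every (alpha_s, alpha_t) pair on a grid, in one pass.
# Returns an n_sites x (n_as * n_at) matrix with columns ordered alpha_s-major
# (alpha_s ascending in blocks, alpha_t ascending within a block), matching
# the deviance-profile grid ordering. Exploits the kernel's separability:
# when all sites share one sampling year the temporal weights factor out of
# the site dimension and each alpha_s block is a single matrix product.
.st_grid <- function(traps, fires, alpha_s_vec, alpha_t_vec,
                     max_distance_km = 20, log_base = "ln") {
  n <- nrow(traps)
  m <- nrow(fires)
  n_as <- length(alpha_s_vec)
  n_at <- length(alpha_t_vec)
  out <- matrix(0, n, n_as * n_at)
  if (m == 0) return(out)
  d_km <- pairwise_distance_km(traps, fires)
  within <- d_km <= max_distance_km
  fa <- .log_area(fires$area_m2, log_base)
  years <- unique(traps$sampling_year)
  if (length(years) == 1) {
    t_j <- time_since_fire(years, fires$year)
    # m x n_at matrix of FA_j * exp(-T_j * alpha_t)
    fa_t <- fa * exp(-outer(t_j, alpha_t_vec))
    for (i in seq_len(n_as)) {
      e_s <- exp(-d_km * alpha_s_vec[i])
      e_s[!within] <- 0
      out[, ((i - 1) * n_at + 1):(i * n_at)] <- e_s %*% fa_t
    }
  } else {
    t_yr <- outer(traps$sampling_year, fires$year,
                  function(s, f) time_since_fire(s, f))
    for (i in seq_len(n_as)) {
      e_s <- exp(-d_km * alpha_s_vec[i])
      e_s[!within] <- 0
      for (j in seq_len(n_at)) {
        out[, (i - 1) * n_at + j] <- (e_s * exp(-t_yr * alpha_t_vec[j])) %*% fa
      }
    }
  }
  out
}
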
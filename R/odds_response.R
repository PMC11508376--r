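# Response construction: the ln-transformed odds that a random caught
# individual (or species) at a site belongs to a focal classification group.

.valid_groups <- c("pyrophilic", "non_pyrophilic", "saproxylic")
.valid_levels <- c("individuals", "species")

# map (group, level) to the catch-table count columns
.count_col <- function(group, level) {
  lev <- if (level == "individuals") "ind" else "sp"
  g <- switch(group,
              pyrophilic = "pyro",
              non_pyrophilic = "nonpyro",
              saproxylic = "sapro")
  c(k = paste0("n_", lev, "_", g), n = paste0("n_", lev, "_total"))
}

#' Natural-log odds of a focal group with zero-cell handling
#'
#' `ln(k / (n - k))` for focal count `k` out of total `n`. When a cell is
#' zero (`k = 0` or `k = n`) a Haldane-style continuity constant is added to
#' both cells, `ln((k + c) / (n - k + c))`, keeping the log-odds finite.
#'
#' @param k Focal count(s), `0 <= k <= n`.
#' @param n Total count(s), `>= 1`.
#' @param correction Continuity constant `c >= 0` (default 0.5), applied
#'   only when a cell is zero.
#' @return Numeric vector of ln-odds.
#' @examples
#' ln_odds(60, 2220)   # -3.584: pooled odds of a pyrophilic individual
#' ln_odds(13, 169)    # -2.485: pooled odds of a pyrophilic species
#' ln_odds(0, 100)     # -5.303 with the default 0.5 correction
#' @export
ln_odds <- function(k, n, correction = 0.5) {
  stopifnot(is.numeric(k), is.numeric(n), length(correction) == 1,
            correction >= 0)
  if (any(n < 1)) stop("total count n must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > n)) {
    stop("focal count k must satisfy 0 <= k <= n", call. = FALSE)
  }
  zero_cell <- (k == 0) | (k == n)
  ifelse(zero_cell,
         log((k + correction) / (n - k + correction)),
         log(k / (n - k)))
}

#' Per-site ln-odds responses for one group and level
#'
#' Builds the modelling response: one ln-odds value per site for the odds
#' that a random caught individual (or species) belongs to `group`. Sites
#' with a zero total at the requested level carry no information and are
#' excluded with a message. Group labels overlap (a pyrophilic species may
#' also be saproxylic), so runs for different groups on the same sites are
#' independent.
#'
#' @param sites Catch `data.frame` (see [load_catches()]).
#' @param group One of `"pyrophilic"`, `"non_pyrophilic"`, `"saproxylic"`.
#' @param level One of `"individuals"`, `"species"`.
#' @param correction Continuity constant passed to [ln_odds()].
#' @return `data.frame` with columns `site_id`, `group`, `level`, `k`, `n`,
#'   `correction_applied`, `ln_odds`, in input site order.
#' @export
build_responses <- function(sites, group = "pyrophilic",
                            level = "individuals", correction = 0.5) {
  if (!group %in% .valid_groups) {
    stop("unknown group '", group, "'; valid groups: ",
         paste(.valid_groups, collapse = ", "), call. = FALSE)
  }
  if (!level %in% .valid_levels) {
    stop("unknown level '", level, "'; valid levels: ",
         paste(.valid_levels, collapse = ", "), call. = FALSE)
  }
  cols <- .count_col(group, level)
  k <- sites[[cols["k"]]]
  n <- sites[[cols["n"]]]
  keep <- n >= 1
  if (any(!keep)) {
    message(sum(!keep), " site(s) excluded from '", group, "'/", level,
            " responses: zero total catch (no information)")
  }
  k <- k[keep]
  n <- n[keep]
  data.frame(site_id = as.character(sites$site_id[keep]),
             group = group,
             level = level,
             k = as.integer(k),
             n = as.integer(n),
             correction_applied = ((k == 0) | (k == n)) & correction > 0,
             ln_odds = ln_odds(k, n, correction),
             stringsAsFactors = FALSE)
}
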
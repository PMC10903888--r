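#' The 8-month climate window of a growth year
#'
#' The growing season is taken to end at the end of August in the
#' northern hemisphere and at the end of February in the southern
#' hemisphere; the window is the 8 consecutive months ending at (and
#' including) that month. For the north this is January-August of the
#' growth year; for the south, July of the previous calendar year through
#' February of the growth year (the growth year is labelled by the
#' calendar year containing the season's end, the usual convention for
#' southern-hemisphere dendrochronology).
#'
#' @param growth_year Integer calendar year labelling the growth season.
#' @param hemisphere `"N"` or `"S"`.
#' @return A tibble with 8 rows: `lag` (1 = oldest month), `year`,
#'   `month`.
#' @examples
#' window_months(1950, "N")  # Jan..Aug 1950
#' window_months(1950, "S")  # Jul 1949 .. Feb 1950
#' @export
window_months <- function(growth_year, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  end_month <- if (hemisphere == "N") 8L else 2L
  m <- (end_month - 7L):end_month          # may dip below 1
  tibble(
    lag = 1:8,
    year = as.integer(growth_year + ifelse(m < 1L, -1L, 0L)),
    month = as.integer(ifelse(m < 1L, m + 12L, m))
  )
}

## lag-month offsets relative to growth_year * 12, oldest first
window_offsets <- function(hemisphere) {
  wm <- window_months(0L, hemisphere)
  wm$year * 12L + wm$month
}

#' Assemble a lagged regression design for one site and product
#'
#' One row per growth year whose full 8-month precipitation window is
#' present in the climate table and whose response is non-missing; years
#' with any missing window month are dropped, not imputed.
#'
#' @param growth Tibble with columns `year` and `value` (annual growth or
#'   greenness response) for one site.
#' @param climate Climate tibble for the same site (may hold several
#'   products).
#' @param product_id Which product's precipitation to use.
#' @param hemisphere `"N"` or `"S"`.
#' @return A design tibble: `product_id`, `year`, `response`,
#'   `lag_1`..`lag_8` (lag 1 = oldest window month, precipitation in mm).
#'   Zero usable rows yield an empty (0-row) design.
#' @export
build_design <- function(growth, climate, product_id,
                         hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(is.data.frame(growth), is.data.frame(climate))
  clim <- climate[climate$product_id == product_id, ]
  growth <- growth[!is.na(growth$value), ]
  empty <- tibble(
    product_id = character(), year = integer(), response = numeric()
  )
  for (j in 1:8) empty[[paste0("lag_", j)]] <- numeric()
  if (nrow(growth) == 0 || nrow(clim) == 0) return(empty)

  off <- window_offsets(hemisphere)
  keys <- outer(growth$year * 12L, off, "+")            # n x 8
  clim_key <- clim$year * 12L + clim$month
  P <- matrix(clim$precip_mm[match(keys, clim_key)], nrow = nrow(growth))
  ok <- rowSums(is.na(P)) == 0
  out <- tibble(
    product_id = product_id,
    year = as.integer(growth$year[ok]),
    response = growth$value[ok]
  )
  Pm <- P[ok, , drop = FALSE]
  for (j in 1:8) out[[paste0("lag_", j)]] <- Pm[, j]
  out
}

#' Restrict designs of one site to pairwise-complete years
#'
#' Every product's design is trimmed to the intersection of usable years
#' across all products, so all products are scored on identical data. An
#' empty intersection yields all-empty designs.
#'
#' @param designs A list of design tibbles (one per product) for the same
#'   site.
#' @return The list with every design restricted to the common years.
#' @export
pairwise_complete <- function(designs) {
  if (length(designs) < 2) {
    abort("pairwise_complete() needs designs for at least two products.")
  }
  common <- Reduce(intersect, lapply(designs, function(d) d$year))
  lapply(designs, function(d) d[d$year %in% common, , drop = FALSE])
}
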
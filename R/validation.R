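#' Un-adjusted R-squared of a lagged design
#'
#' Ordinary least squares of the response on an intercept plus the 8
#' monthly precipitation predictors; reports the un-adjusted variance
#' explained `R^2 = 1 - SSE/SST`. Rank-deficient designs are handled by
#' pivoted QR elimination of dependent columns (tolerance 1e-10) with a
#' warning; a constant response makes R^2 undefined and is reported as
#' `NA`.
#'
#' @param design A design tibble from [build_design()] with at least 10
#'   rows (8 predictors + intercept + 1).
#' @param warn_rank Warn when predictors are collinear (default `TRUE`).
#' @return A one-row tibble: `r_squared`, `n_obs`.
#' @export
r_squared <- function(design, warn_rank = TRUE) {
  lag_cols <- grep("^lag_", names(design), value = TRUE)
  stopifnot(length(lag_cols) == 8, "response" %in% names(design))
  n <- nrow(design)
  if (n < 10) {
    abort("At least 10 observations are required (8 predictors + intercept + 1).")
  }
  y <- design$response
  X <- cbind(1, as.matrix(design[lag_cols]))
  tibble(r_squared = ols_r2(y, X, warn_rank = warn_rank), n_obs = n)
}

## pivoted-QR least squares R^2; tolerance per design choice
ols_r2 <- function(y, X, tol = 1e-10, warn_rank = TRUE) {
  qx <- qr(X, tol = tol)
  if (qx$rank < ncol(X) && warn_rank) {
    warn(sprintf("Design is rank-deficient (rank %d of %d); dependent columns dropped",
                 qx$rank, ncol(X)))
  }
  sst <- sum((y - mean(y))^2)
  if (sst <= .Machine$double.eps * max(1, sum(y^2))) return(NA_real_)
  sse <- sum((y - qr.fitted(qx, y))^2)
  max(0, min(1, 1 - sse / sst))
}

#' Full-period validation of every site against every product
#'
#' For each site: assembles one lagged design per product, restricts them
#' to pairwise-complete years, and — if every product retains at least
#' `min_obs_full` usable years — scores each with un-adjusted R-squared.
#' A site failing the threshold for any product is excluded for all
#' products, so every product is evaluated on an identical set of sites
#' and years.
#'
#' @param growth Tibble `site_id`, `year`, `value` (a chronology table's
#'   `index` column is accepted as the response and used as `value`).
#' @param climate Climate tibble across products (no `"truth"` rows
#'   unless truth should compete).
#' @param regions Tibble `site_id`, `region`, `hemisphere`.
#' @param min_obs_full Minimum pairwise-complete years per fit
#'   (default 20).
#' @return A fit-results tibble: `site_id`, `product_id`, `scope`
#'   (`"full"`), `midpoint` (`NA`), `r_squared`, `n_obs`.
#' @export
validate_full <- function(growth, climate, regions, min_obs_full = 20) {
  prep <- prepare_site_designs(growth, climate, regions)
  rows <- purrr::map(prep, function(site) {
    ns <- vapply(site$designs, nrow, integer(1))
    if (any(ns < min_obs_full)) return(NULL)
    dplyr::bind_rows(lapply(site$designs, function(d) {
      dplyr::bind_cols(
        tibble(site_id = site$site_id, product_id = d$product_id[1],
               scope = "full", midpoint = NA_integer_),
        r_squared(d)
      )
    }))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(site_id = character(), product_id = character(),
                  scope = character(), midpoint = integer(),
                  r_squared = numeric(), n_obs = integer())
  }
  out
}

#' Moving-window validation
#'
#' Applies the full-period scoring inside moving windows of
#' `window_length` years stepping by `window_step`, anchored to the
#' calendar years of `eval_span` so midpoints align across sites. Each
#' window is reported at its midpoint year,
#' `first_year + (window_length - 1) / 2`. With
#' `require_complete_window` (the default) a window with any missing year
#' in a site's pairwise-complete design is skipped — identically for all
#' products, since the designs share year sets.
#'
#' @inheritParams validate_full
#' @param window_length Window width in years, odd (default 21).
#' @param window_step Step between window starts (default 1).
#' @param eval_span Length-2 inclusive year range to cover
#'   (default `c(1901, 2000)`).
#' @param require_complete_window Skip windows with missing years
#'   (default `TRUE`).
#' @return A fit-results tibble with `scope = "window"` and the window
#'   `midpoint`.
#' @export
validate_windows <- function(growth, climate, regions,
                             window_length = 21, window_step = 1,
                             eval_span = c(1901, 2000),
                             require_complete_window = TRUE,
                             min_obs_full = 20) {
  if (window_length %% 2 != 1) {
    abort("`window_length` must be odd so the midpoint year is well-defined.")
  }
  starts <- window_starts(eval_span, window_length, window_step)
  prep <- prepare_site_designs(growth, climate, regions)
  rows <- purrr::map(prep, function(site) {
    ns <- vapply(site$designs, nrow, integer(1))
    if (any(ns < min_obs_full)) return(NULL)
    yrs <- site$designs[[1]]$year
    per_window <- purrr::map(starts, function(w0) {
      wyrs <- w0:(w0 + window_length - 1L)
      inside <- yrs %in% wyrs
      n_in <- sum(inside)
      if (require_complete_window && n_in < window_length) return(NULL)
      if (n_in < 10) return(NULL)
      mid <- as.integer(w0 + (window_length - 1L) %/% 2L)
      dplyr::bind_rows(lapply(site$designs, function(d) {
        dplyr::bind_cols(
          tibble(site_id = site$site_id, product_id = d$product_id[1],
                 scope = "window", midpoint = mid),
          r_squared(d[inside, , drop = FALSE])
        )
      }))
    })
    dplyr::bind_rows(per_window)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(site_id = character(), product_id = character(),
                  scope = character(), midpoint = integer(),
                  r_squared = numeric(), n_obs = integer())
  }
  out
}

#' Midpoint years of the moving-window layout
#'
#' @param eval_span Inclusive year range, length 2.
#' @param window_length Odd window width (default 21).
#' @param window_step Step (default 1).
#' @return Integer vector of midpoint years (empty when the window
#'   exceeds the span).
#' @examples
#' range(window_midpoints(c(1901, 2000)))  # 1911 .. 1990
#' @export
window_midpoints <- function(eval_span, window_length = 21,
                             window_step = 1) {
  as.integer(window_starts(eval_span, window_length, window_step) +
               (window_length - 1L) %/% 2L)
}

window_starts <- function(eval_span, window_length, window_step) {
  stopifnot(length(eval_span) == 2, eval_span[2] >= eval_span[1])
  last_start <- eval_span[2] - window_length + 1L
  if (last_start < eval_span[1]) return(integer())
  seq.int(eval_span[1], last_start, by = window_step)
}

## shared site preparation: hemisphere lookup, per-product designs,
## pairwise-complete trimming
prepare_site_designs <- function(growth, climate, regions) {
  stopifnot(is.data.frame(growth), is.data.frame(climate),
            is.data.frame(regions))
  if (!"value" %in% names(growth) && "index" %in% names(growth)) {
    growth$value <- growth$index
  }
  req <- c("site_id", "year", "value")
  miss <- setdiff(req, names(growth))
  if (length(miss) > 0) {
    abort(sprintf("`growth` lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  products <- sort(unique(climate$product_id))
  if (length(products) < 2) {
    abort("At least two products are required for validation.")
  }
  g_by_site <- split(dplyr::select(growth, "year", "value"), growth$site_id)
  c_by_site <- split(climate, climate$site_id)
  sites <- names(g_by_site)
  unknown <- setdiff(sites, regions$site_id)
  if (length(unknown) > 0) {
    abort(sprintf("Site '%s' has no region/hemisphere entry", unknown[1]))
  }
  hemi <- setNames(regions$hemisphere, regions$site_id)
  lapply(sites, function(sid) {
    clim <- c_by_site[[sid]]
    if (is.null(clim)) clim <- climate[0, ]
    designs <- lapply(products, function(p) {
      build_design(g_by_site[[sid]], clim, p, hemisphere = hemi[[sid]])
    })
    list(site_id = sid, designs = pairwise_complete(designs))
  })
}
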
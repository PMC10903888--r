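#' Simulate the latent "true" monthly precipitation field
#'
#' Monthly precipitation at each site is drawn independently as
#' `seasonal_mean[month] * exp(sigma * Z - sigma^2/2)` with
#' `sigma^2 = log(1 + seasonal_cv^2)`, i.e. a lognormal deviate whose mean
#' equals the seasonal mean and whose coefficient of variation equals
#' `seasonal_cv`. With `seasonal_cv = 0` every site-year repeats the
#' seasonal means exactly. Values are strictly positive.
#'
#' @param config A [sim_config()].
#' @return A climate tibble with columns `site_id`, `product_id`
#'   (`"truth"`), `year`, `month`, `precip_mm`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sites <- site_table(config)
  grid <- tidyr::expand_grid(
    site_id = sites$site_id,
    year = config$years,
    month = 1:12
  )
  sigma <- sqrt(log(1 + config$seasonal_cv^2))
  mu <- config$seasonal_mean[grid$month]
  z <- withr::with_seed(stage_seed(config, "truth"), rnorm(nrow(grid)))
  grid$precip_mm <- mu * exp(sigma * z - sigma^2 / 2)
  grid$product_id <- "truth"
  dplyr::select(grid, "site_id", "product_id", "year", "month", "precip_mm")
}

#' Derive K candidate products from the true precipitation field
#'
#' Each product perturbs truth multiplicatively:
#' `product = truth * exp(eps)` with `eps ~ N(0, sd[product, region])`,
#' independent across products, sites and months. Multiplicative lognormal
#' error keeps products positive and scales error with precipitation
#' magnitude, emulating divergent interpolation quality among gridded
#' products.
#'
#' @param truth Climate tibble from [simulate_truth()].
#' @param config A [sim_config()] (supplies `product_noise_sd`, possibly
#'   region-specific, and the region assignment).
#' @return A climate tibble over products `product_01` ... `product_K`
#'   covering exactly the same (site, year, month) keys as `truth`.
#' @export
derive_products <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_products < 2) {
    abort("At least 2 products are required.")
  }
  sites <- site_table(config)
  region_idx <- match(
    sites$region[match(truth$site_id, sites$site_id)],
    sprintf("region_%02d", seq_len(config$n_regions))
  )
  n <- nrow(truth)
  out <- withr::with_seed(stage_seed(config, "products"), {
    purrr::map(seq_len(config$n_products), function(k) {
      sd_row <- config$product_noise_sd[k, region_idx]
      eps <- rnorm(n) * sd_row
      tibble(
        site_id = truth$site_id,
        product_id = sprintf("product_%02d", k),
        year = truth$year,
        month = truth$month,
        precip_mm = truth$precip_mm * exp(eps)
      )
    })
  })
  dplyr::bind_rows(out)
}

## Per-site list of z-score matrices (years x 12) of the true field.
## Standardization is per calendar month across years, so the planted
## growth response is scale-free.
truth_zscores <- function(truth, config) {
  key <- order(truth$site_id, truth$year, truth$month)
  p <- truth$precip_mm[key]
  n_years <- length(config$years)
  arr <- array(p, dim = c(12, n_years, config$n_sites))
  site_ids <- sort(unique(truth$site_id))
  lapply(seq_len(config$n_sites), function(s) {
    m <- t(arr[, , s])                      # years x 12
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    sd[sd == 0] <- 1
    sweep(sweep(m, 2, mu), 2, sd, "/")
  }) |> setNames(site_ids)
}

## 8-column lag matrix of z-scores for each growth year of one site.
## N hemisphere: Jan..Aug of the growth year.
## S hemisphere: Jul of the prior year .. Feb of the growth year.
lagged_z <- function(z, years, hemisphere) {
  if (hemisphere == "N") {
    gy <- years
    X <- z[, 1:8, drop = FALSE]
  } else {
    gy <- years[-1]
    X <- cbind(z[-nrow(z), 7:12, drop = FALSE], z[-1, 1:2, drop = FALSE])
  }
  list(growth_years = gy, X = X)
}

## Annual growth signal g_t = X beta + AR(1) noise (innovation sd given).
growth_signal <- function(X, beta, ar1, innov_sd) {
  eta <- rnorm(nrow(X)) * innov_sd
  if (ar1 > 0) eta <- as.numeric(stats::filter(eta, ar1, "recursive"))
  drop(X %*% beta) + eta
}

#' Simulate multi-core ring-width series with a planted climate response
#'
#' Each site carries an annual growth signal: the 8 response weights
#' applied to the site's standardized true precipitation over its 8-month
#' growing-season window, plus AR(1) noise. Each core multiplies a
#' negative-exponential juvenile trend (in cambial age) by
#' `exp(signal + white noise)`, so widths are strictly positive. Core
#' start years are staggered uniformly over the first third of the
#' simulated span to exercise ragged-edge chronology averaging.
#'
#' @param truth Climate tibble from [simulate_truth()].
#' @param config A [sim_config()].
#' @return A tibble with columns `site_id`, `series_id`, `year`,
#'   `width_mm`.
#' @export
simulate_ring_widths <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  sites <- site_table(config)
  zs <- truth_zscores(truth, config)
  years <- config$years
  n_years <- length(years)
  start_pool <- years[seq_len(max(1L, n_years %/% 3L))]
  beta <- config$response_weights
  a0 <- config$age_trend[1]
  k <- config$age_trend[2]

  withr::with_seed(stage_seed(config, "rings"), {
    res <- purrr::map(seq_len(config$n_sites), function(s) {
      sid <- sites$site_id[s]
      lz <- lagged_z(zs[[sid]], years, sites$hemisphere[s])
      g <- growth_signal(lz$X, beta, config$ar1_coef, config$growth_noise_sd)
      starts <- start_pool[sample.int(length(start_pool),
                                      config$n_cores_per_site,
                                      replace = TRUE)]
      cores <- purrr::map(seq_len(config$n_cores_per_site), function(ci) {
        first <- max(starts[ci], lz$growth_years[1])
        yrs <- seq(first, max(years))
        age <- yrs - starts[ci] + 1L
        gi <- g[match(yrs, lz$growth_years)]
        noise <- rnorm(length(yrs)) * config$core_noise_sd
        tibble(
          site_id = sid,
          series_id = sprintf("s%03dc%02d", s, ci),
          year = as.integer(yrs),
          width_mm = a0 * exp(-k * age) * exp(gi + noise)
        )
      })
      dplyr::bind_rows(cores)
    })
    dplyr::bind_rows(res)
  })
}

#' Simulate annual greenness (EVI-like) series
#'
#' Uses the same lagged response model as the site growth signal, without
#' age trend or core replication. A fraction `evi_missing_frac` of
#' (site, year) cells is set missing completely at random; a site's series
#' is retained only if at least 50% of its years are non-missing,
#' mirroring the completeness filter applied to remotely sensed
#' vegetation-index pixels.
#'
#' @param truth Climate tibble from [simulate_truth()].
#' @param config A [sim_config()].
#' @return A tibble with columns `site_id`, `year`, `value`; missing cells
#'   of retained sites carry `NA`.
#' @export
simulate_evi <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  sites <- site_table(config)
  zs <- truth_zscores(truth, config)
  years <- config$years
  beta <- config$response_weights

  withr::with_seed(stage_seed(config, "evi"), {
    res <- purrr::map(seq_len(config$n_sites), function(s) {
      sid <- sites$site_id[s]
      lz <- lagged_z(zs[[sid]], years, sites$hemisphere[s])
      g <- growth_signal(lz$X, beta, config$ar1_coef, config$growth_noise_sd)
      miss <- runif(length(g)) < config$evi_missing_frac
      g[miss] <- NA_real_
      tibble(site_id = sid, year = as.integer(lz$growth_years), value = g)
    })
    dplyr::bind_rows(res)
  }) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::filter(mean(!is.na(.data$value)) >= 0.5) |>
    dplyr::ungroup()
}

#' Simulate a complete synthetic validation study
#'
#' Runs every generator stage under seeds derived from `config$seed` (one
#' fixed offset per stage), so identical configurations produce
#' bit-identical studies and each stage is also reproducible on its own.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_study`: a list with elements
#'   `truth`, `products` (climate tibbles), `ring_widths`, `evi`, `sites`
#'   (region/hemisphere table) and `config`.
#' @examples
#' study <- simulate_study(sim_config(n_sites = 4, years = 1961:2000,
#'                                    n_cores_per_site = 3, seed = 7))
#' names(study)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_truth(config)
  structure(
    list(
      truth = truth,
      products = derive_products(truth, config),
      ring_widths = simulate_ring_widths(truth, config),
      evi = simulate_evi(truth, config),
      sites = site_table(config),
      config = config
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  cat(sprintf("  %d sites, years %d-%d, %d products\n",
              x$config$n_sites, min(x$config$years), max(x$config$years),
              x$config$n_products))
  cat(sprintf("  ring series: %d, greenness sites retained: %d\n",
              dplyr::n_distinct(x$ring_widths$series_id),
              dplyr::n_distinct(x$evi$site_id)))
  invisible(x)
}
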
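#' Read a monthly climate table
#'
#' Tab-delimited text with a mandatory header and columns `site_id`,
#' `product_id`, `year`, `month`, `precip_mm`. The schema is validated
#' strictly: missing columns, months outside 1-12, negative precipitation
#' or duplicate (site, product, year, month) keys raise an error naming
#' the offending key. A header-only file yields an empty table.
#'
#' @param path Path to a TSV file.
#' @return A climate tibble.
#' @export
read_climate_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ## columns come in as text and are converted with base R's
  ## correctly-rounded as.numeric so decimal round-trips are bit-exact
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  req <- c("site_id", "product_id", "year", "month", "precip_mm")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s lacks required column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  x <- dplyr::select(x, dplyr::all_of(req))
  x$year <- as.integer(x$year)
  x$month <- as.integer(x$month)
  x$precip_mm <- as.numeric(x$precip_mm)
  validate_climate_table(x, path)
  x
}

validate_climate_table <- function(x, label = "climate table") {
  if (nrow(x) == 0) return(invisible(x))
  bad_m <- which(x$month < 1 | x$month > 12 | is.na(x$month))
  if (length(bad_m) > 0) {
    abort(sprintf("%s: month out of range for key (%s, %s, %d, %s)",
                  label, x$site_id[bad_m[1]], x$product_id[bad_m[1]],
                  x$year[bad_m[1]], as.character(x$month[bad_m[1]])))
  }
  bad_p <- which(is.na(x$precip_mm) | x$precip_mm < 0)
  if (length(bad_p) > 0) {
    abort(sprintf("%s: negative or missing precipitation for key (%s, %s, %d, %d)",
                  label, x$site_id[bad_p[1]], x$product_id[bad_p[1]],
                  x$year[bad_p[1]], x$month[bad_p[1]]))
  }
  key <- paste(x$site_id, x$product_id, x$year, x$month, sep = "\r")
  d <- anyDuplicated(key)
  if (d > 0) {
    abort(sprintf("%s: duplicate key (%s, %s, %d, %d)",
                  label, x$site_id[d], x$product_id[d], x$year[d], x$month[d]))
  }
  invisible(x)
}

#' Write a monthly climate table
#'
#' @param climate A climate tibble (`site_id`, `product_id`, `year`,
#'   `month`, `precip_mm`).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_climate_table <- function(climate, path) {
  req <- c("site_id", "product_id", "year", "month", "precip_mm")
  miss <- setdiff(req, names(climate))
  if (length(miss) > 0) {
    abort(sprintf("Climate table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  readr::write_tsv(dplyr::select(climate, dplyr::all_of(req)), path,
                   progress = FALSE)
  invisible(path)
}

#' Write / read validation results
#'
#' Results files carry one row per site x product x scope with columns
#' `site_id`, `product_id`, `scope` (`"full"` or the moving-window
#' midpoint year), `r_squared`, `n_obs`.
#'
#' @param results A fit-results tibble as produced by
#'   [validate_full()] / [validate_windows()] (columns `site_id`,
#'   `product_id`, `scope`, `midpoint`, `r_squared`, `n_obs`).
#' @param path Path to a TSV file.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the results tibble with `scope`/`midpoint` reconstructed.
#' @export
write_results <- function(results, path) {
  req <- c("site_id", "product_id", "scope", "r_squared", "n_obs")
  miss <- setdiff(req, names(results))
  if (length(miss) > 0) {
    abort(sprintf("Results lack column(s): %s", paste(miss, collapse = ", ")))
  }
  out <- tibble(
    site_id = results$site_id,
    product_id = results$product_id,
    scope = ifelse(results$scope == "full", "full",
                   as.character(results$midpoint)),
    r_squared = results$r_squared,
    n_obs = results$n_obs
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  req <- c("site_id", "product_id", "scope", "r_squared", "n_obs")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s lacks required column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  x$r_squared <- as.numeric(x$r_squared)
  x$n_obs <- as.integer(x$n_obs)
  if (nrow(x) > 0 && any(!is.na(x$r_squared) &
                         (x$r_squared < 0 | x$r_squared > 1))) {
    abort(sprintf("%s: r_squared outside [0, 1]", path))
  }
  tibble(
    site_id = as.character(x$site_id),
    product_id = as.character(x$product_id),
    scope = ifelse(x$scope == "full", "full", "window"),
    midpoint = ifelse(x$scope == "full", NA_integer_,
                      suppressWarnings(as.integer(x$scope))),
    r_squared = as.numeric(x$r_squared),
    n_obs = as.integer(x$n_obs)
  )
}

#' Read a site regions table
#'
#' Columns `site_id`, `region`, `hemisphere` (`"N"` or `"S"`).
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("site_id", "region", "hemisphere")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s lacks required column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  x$site_id <- as.character(x$site_id)
  bad <- which(!x$hemisphere %in% c("N", "S"))
  if (length(bad) > 0) {
    abort(sprintf("%s: hemisphere must be 'N' or 'S' (site %s)",
                  path, x$site_id[bad[1]]))
  }
  if (anyDuplicated(x$site_id) > 0) {
    abort(sprintf("%s: duplicate site_id '%s'", path,
                  x$site_id[anyDuplicated(x$site_id)]))
  }
  dplyr::select(x, dplyr::all_of(req))
}

#' Write a synthetic study to a directory of standard files
#'
#' Emits one RWL file per site (`rwl/<site_id>.rwl`), `truth.tsv` and
#' `products.tsv` climate tables, `greenness.tsv` (site_id, year, value)
#' and `regions.tsv` (site_id, region, hemisphere). Ring widths are
#' quantized to the requested RWL dialect, so the directory round-trips
#' exactly.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @param precision RWL dialect, `"0.01"` or `"0.001"`.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, precision = c("0.01", "0.001")) {
  stopifnot(inherits(study, "synthetic_study"))
  precision <- match.arg(precision)
  dir.create(file.path(dir, "rwl"), recursive = TRUE, showWarnings = FALSE)
  rw <- quantize_widths(study$ring_widths, precision)
  for (sid in unique(rw$site_id)) {
    write_rwl(rw[rw$site_id == sid, ],
              file.path(dir, "rwl", paste0(sid, ".rwl")),
              precision = precision)
  }
  write_climate_table(study$truth, file.path(dir, "truth.tsv"))
  write_climate_table(study$products, file.path(dir, "products.tsv"))
  readr::write_tsv(study$evi, file.path(dir, "greenness.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$sites, file.path(dir, "regions.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read ring-width series for many sites from a directory of RWL files
#'
#' Each file `<site_id>.rwl` contributes its series under that site id.
#'
#' @param dir Directory containing `.rwl` files.
#' @return A tibble `site_id`, `series_id`, `year`, `width_mm`.
#' @export
read_rwl_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.rwl$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("No .rwl files under %s", dir))
  purrr::map(files, function(f) {
    x <- read_rwl(f)
    x$site_id <- sub("\\.rwl$", "", basename(f))
    dplyr::select(x, "site_id", "series_id", "year", "width_mm")
  }) |> dplyr::bind_rows()
}
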
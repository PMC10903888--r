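#' Read a Tucson decadal ring-width (RWL) file
#'
#' Parses the decadal layout used by the International Tree Ring Data
#' Bank: each line carries a series identifier (columns 1-8), the calendar
#' year of the line's first value, and up to ten integer measurements; a
#' series ends with a terminator value. The measurement precision dialect
#' is auto-detected from the terminator: `999` marks 0.01 mm units,
#' `-9999` marks 0.001 mm units. Structurally invalid files are rejected,
#' never silently repaired.
#'
#' @param path Path to an RWL file.
#' @param precision Optional override: `"0.01"` or `"0.001"`. By default
#'   the dialect is detected from the terminator.
#' @return A tibble with columns `series_id`, `year`, `width_mm`, with the
#'   detected precision (mm per stored unit) in attribute `"precision"`.
#'   An empty file yields an empty tibble.
#' @export
read_rwl <- function(path, precision = NULL) {
  if (!file.exists(path)) abort(sprintf("RWL file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  empty <- tibble(series_id = character(), year = integer(),
                  width_mm = numeric())
  if (length(lines) == 0) {
    attr(empty, "precision") <- if (is.null(precision)) NA_real_ else
      as.numeric(precision)
    return(empty)
  }

  ids <- trimws(substr(lines, 1, 8))
  rest <- trimws(substring(lines, 9))
  toks <- strsplit(rest, "\\s+")
  vals <- lapply(seq_along(toks), function(i) {
    v <- suppressWarnings(as.integer(toks[[i]]))
    if (length(v) < 2 || anyNA(v)) {
      abort(sprintf("Malformed decade line %d in %s: '%s'",
                    lineno[i], path, lines[i]))
    }
    v
  })
  if (any(ids == "")) {
    i <- which(ids == "")[1]
    abort(sprintf("Missing series id on line %d in %s", lineno[i], path))
  }

  ## consecutive lines with the same id form one series block
  block <- cumsum(c(TRUE, ids[-1] != ids[-length(ids)]))
  block_ids <- ids[!duplicated(block)]
  if (anyDuplicated(block_ids)) {
    dup <- block_ids[duplicated(block_ids)][1]
    abort(sprintf(
      "Series '%s' appears in non-contiguous blocks in %s (overlapping or duplicated series)",
      dup, path))
  }

  detected <- NULL
  out <- vector("list", length(block_ids))
  for (b in seq_along(block_ids)) {
    sel <- which(block == b)
    yr0 <- vapply(vals[sel], function(v) v[1], integer(1))
    vlist <- lapply(vals[sel], function(v) v[-1])
    last <- vlist[[length(vlist)]]
    term <- last[length(last)]
    if (!term %in% c(999L, -9999L)) {
      abort(sprintf(
        "Series '%s' in %s lacks a terminator (999 or -9999) on line %d",
        block_ids[b], path, lineno[sel[length(sel)]]))
    }
    prec <- if (term == 999L) 0.01 else 0.001
    if (is.null(detected)) detected <- prec
    if (prec != detected) {
      abort(sprintf("Mixed precision dialects in %s (series '%s')",
                    path, block_ids[b]))
    }
    vlist[[length(vlist)]] <- last[-length(last)]

    ## continuation check: each line starts right after the previous one
    n_per <- lengths(vlist)
    for (j in seq_along(sel)[-1]) {
      expected <- yr0[j - 1] + n_per[j - 1]
      if (yr0[j] < expected) {
        abort(sprintf(
          "Overlapping decades in series '%s' at line %d in %s",
          block_ids[b], lineno[sel[j]], path))
      }
      if (yr0[j] > expected) {
        abort(sprintf(
          "Gap before line %d in series '%s' in %s (years must be consecutive)",
          lineno[sel[j]], block_ids[b], path))
      }
    }
    units <- unlist(vlist)
    if (length(units) == 0) {
      abort(sprintf("Series '%s' in %s holds no measurements",
                    block_ids[b], path))
    }
    if (any(units < 0)) {
      abort(sprintf("Negative measurement in series '%s' in %s",
                    block_ids[b], path))
    }
    out[[b]] <- tibble(
      series_id = block_ids[b],
      year = seq.int(yr0[1], length.out = length(units)),
      width_mm = units * prec
    )
  }
  res <- dplyr::bind_rows(out)
  if (!is.null(precision)) {
    precision <- as.numeric(precision)
    if (precision != detected) {
      abort(sprintf(
        "Requested precision %g does not match terminator-detected %g in %s",
        precision, detected, path))
    }
  }
  attr(res, "precision") <- detected
  res
}

#' Write ring-width series to a Tucson decadal RWL file
#'
#' The inverse of [read_rwl()]: emits the requested precision dialect
#' (`"0.01"` mm with terminator 999, `"0.001"` mm with terminator -9999)
#' so that reading the file back reproduces the input exactly, provided
#' widths are already multiples of the dialect precision.
#'
#' @param rings A tibble with columns `series_id`, `year`, `width_mm`
#'   (years consecutive within each series).
#' @param path Output path.
#' @param precision `"0.01"` (default) or `"0.001"`.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rings, path, precision = c("0.01", "0.001")) {
  precision <- match.arg(precision)
  prec <- as.numeric(precision)
  term <- if (prec == 0.01) 999L else -9999L
  stopifnot(is.data.frame(rings))
  if (nrow(rings) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  req <- c("series_id", "year", "width_mm")
  miss <- setdiff(req, names(rings))
  if (length(miss) > 0) {
    abort(sprintf("`rings` lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(nchar(rings$series_id) > 8)) {
    bad <- unique(rings$series_id[nchar(rings$series_id) > 8])[1]
    abort(sprintf("series_id '%s' exceeds the 8-character Tucson limit", bad))
  }
  if (any(rings$year < 0)) {
    abort("Negative (BCE) years are not representable in Tucson format.")
  }
  if (any(rings$width_mm < 0)) abort("Ring widths must be non-negative.")

  con <- file(path, "w")
  on.exit(close(con))
  for (sid in unique(rings$series_id)) {
    s <- rings[rings$series_id == sid, ]
    s <- s[order(s$year), ]
    if (anyDuplicated(s$year)) {
      abort(sprintf("Duplicate year in series '%s'", sid))
    }
    if (any(diff(s$year) != 1)) {
      abort(sprintf("Years of series '%s' must be consecutive", sid))
    }
    units <- as.integer(round(s$width_mm / prec))
    yrs <- s$year
    first <- yrs[1]
    ## decade chunks: first line runs to the end of its decade
    pos <- 1L
    n <- length(units)
    while (pos <= n) {
      yr <- yrs[pos]
      take <- min(10L - (yr %% 10L), n - pos + 1L)
      chunk <- units[pos:(pos + take - 1L)]
      pos <- pos + take
      line_vals <- chunk
      if (pos > n && take < 10L) line_vals <- c(chunk, term)
      cat(sprintf("%-8s%4d%s\n", sid, yr,
                  paste(sprintf("%6d", line_vals), collapse = "")),
          file = con)
      if (pos > n && take == 10L) {
        cat(sprintf("%-8s%4d%6d\n", sid, yrs[n] + 1L, term), file = con)
      }
    }
  }
  invisible(path)
}

#' Quantize ring widths to an RWL precision dialect
#'
#' Convenience for exact round-trips: snaps widths to multiples of the
#' dialect precision before writing.
#'
#' @param rings Ring-width tibble with `width_mm`.
#' @param precision `"0.01"` or `"0.001"`.
#' @return The tibble with quantized `width_mm`.
#' @export
quantize_widths <- function(rings, precision = c("0.01", "0.001")) {
  precision <- match.arg(precision)
  prec <- as.numeric(precision)
  rings$width_mm <- round(rings$width_mm / prec) * prec
  rings
}
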
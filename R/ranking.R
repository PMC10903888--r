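#' Ranked ballot from per-product skill scores
#'
#' Products are ranked by descending R-squared; exact ties share a rank
#' (no jitter, so results stay deterministic). Any missing score
#' invalidates the ballot — the caller must exclude that site.
#'
#' @param scores Named numeric vector of R-squared values, one per
#'   product.
#' @return Named integer ranks (1 = best; tied products share the
#'   smallest rank of their group).
#' @examples
#' ballots_from_scores(c(A = 0.4, B = 0.3, C = 0.2))
#' ballots_from_scores(c(A = 0.4, B = 0.4, C = 0.2))  # A and B tied
#' @export
ballots_from_scores <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    abort("`scores` must be named by product.")
  }
  if (anyNA(scores)) {
    abort("Missing score: ballot rejected (exclude this site).")
  }
  r <- rank(-scores, ties.method = "min")
  storage.mode(r) <- "integer"
  r
}

#' Pairwise strict-preference tally of a ballot profile
#'
#' `tally[a, b]` counts ballots that strictly prefer product `a` over
#' product `b`; a ballot on which the two are tied counts for neither
#' side.
#'
#' @param ballots A matrix of ranks (one row per ballot, one column per
#'   product, 1 = best) or a list of rank vectors from
#'   [ballots_from_scores()].
#' @return A K x K integer matrix with product names on both dimensions.
#' @export
pairwise_tally <- function(ballots) {
  if (is.list(ballots)) ballots <- do.call(rbind, ballots)
  stopifnot(is.matrix(ballots), nrow(ballots) >= 1)
  if (is.null(colnames(ballots))) {
    abort("Ballots must carry product names.")
  }
  K <- ncol(ballots)
  tally <- matrix(0L, K, K, dimnames = list(colnames(ballots),
                                            colnames(ballots)))
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      if (a != b) tally[a, b] <- sum(ballots[, a] < ballots[, b])
    }
  }
  tally
}

#' Condorcet outcome of a pairwise tally
#'
#' The Condorcet winner is the product that beats every other product in
#' head-to-head majority comparison; the loser is beaten by every other.
#' When a majority cycle leaves no winner, the outcome reports
#' `winner = NA` with `used_fallback = TRUE` and Copeland scores
#' (pairwise wins minus losses) for downstream tie-breaking, rather than
#' silently electing a fallback.
#'
#' @param tally A K x K tally from [pairwise_tally()].
#' @param n_ballots Number of ballots behind the tally.
#' @return An object of class `condorcet_outcome`: a list with `winner`,
#'   `loser` (product id or `NA`), `copeland` (named numeric),
#'   `margins` (K x K win fractions), `n_ballots`, `used_fallback`.
#' @export
condorcet_outcome <- function(tally, n_ballots) {
  stopifnot(is.matrix(tally), nrow(tally) == ncol(tally),
            nrow(tally) >= 2, n_ballots >= 1)
  prods <- rownames(tally)
  K <- nrow(tally)
  beats <- tally > t(tally)
  wins <- rowSums(beats)
  losses <- colSums(beats)
  copeland <- setNames(as.numeric(wins - losses), prods)
  winner <- prods[wins == K - 1]
  loser <- prods[losses == K - 1]
  structure(
    list(
      winner = if (length(winner) == 1) winner else NA_character_,
      loser = if (length(loser) == 1) loser else NA_character_,
      copeland = copeland,
      margins = tally / n_ballots,
      n_ballots = as.integer(n_ballots),
      used_fallback = length(winner) != 1
    ),
    class = "condorcet_outcome"
  )
}

#' @export
print.condorcet_outcome <- function(x, ...) {
  cat("<condorcet_outcome>", x$n_ballots, "ballots\n")
  cat("  winner:", ifelse(is.na(x$winner), "none (majority cycle)", x$winner),
      " loser:", ifelse(is.na(x$loser), "none", x$loser), "\n")
  cat("  Copeland:", paste(names(x$copeland), x$copeland, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Per-region Condorcet report from validation results
#'
#' Groups full-period fit results by region, turns each site's per-product
#' R-squared values into a ranked ballot (sites missing any product's
#' score are excluded), and elects a Condorcet winner and loser per
#' region. Also reports the per-region, per-product mean (or median)
#' R-squared used in continental-scale summaries.
#'
#' @param fit_results Fit-results tibble (rows with `scope == "full"` are
#'   used).
#' @param regions Tibble `site_id`, `region` (and optionally
#'   `hemisphere`). Every site in `fit_results` must be present.
#' @param min_ballots Regions with fewer ballots are flagged
#'   (default 5); their outcome is still reported.
#' @param summary_fn Aggregator for regional R-squared summaries, `mean`
#'   (default) or `median`.
#' @return An object of class `condorcet_report`: list with `regions`
#'   (one row per region: `region`, `n_ballots`, `winner`, `loser`,
#'   `used_fallback`, `flagged`), `products` (per region x product:
#'   `mean_r2`, `copeland`), and `tallies` (named list of tally
#'   matrices).
#' @export
regional_report <- function(fit_results, regions, min_ballots = 5,
                            summary_fn = mean) {
  stopifnot(is.data.frame(fit_results), is.data.frame(regions))
  fr <- fit_results[fit_results$scope == "full", ]
  if (nrow(fr) == 0) abort("No full-period results to rank.")
  unknown <- setdiff(unique(fr$site_id), regions$site_id)
  if (length(unknown) > 0) {
    abort(sprintf("Site '%s' has no region label", unknown[1]))
  }
  fr$region <- regions$region[match(fr$site_id, regions$site_id)]
  products <- sort(unique(fr$product_id))

  region_rows <- list()
  product_rows <- list()
  tallies <- list()
  for (reg in sort(unique(fr$region))) {
    sub <- fr[fr$region == reg, ]
    wide <- tidyr::pivot_wider(sub[c("site_id", "product_id", "r_squared")],
                               names_from = "product_id",
                               values_from = "r_squared")
    score_mat <- as.matrix(wide[products])
    complete <- rowSums(is.na(score_mat)) == 0
    score_mat <- score_mat[complete, , drop = FALSE]
    n_ballots <- nrow(score_mat)
    if (n_ballots == 0) {
      region_rows[[reg]] <- tibble(
        region = reg, n_ballots = 0L, winner = NA_character_,
        loser = NA_character_, used_fallback = NA, flagged = TRUE
      )
      next
    }
    ballots <- t(apply(score_mat, 1, ballots_from_scores))
    colnames(ballots) <- products
    tally <- pairwise_tally(ballots)
    out <- condorcet_outcome(tally, n_ballots)
    tallies[[reg]] <- tally
    region_rows[[reg]] <- tibble(
      region = reg, n_ballots = as.integer(n_ballots),
      winner = out$winner, loser = out$loser,
      used_fallback = out$used_fallback,
      flagged = n_ballots < min_ballots
    )
    product_rows[[reg]] <- tibble(
      region = reg, product_id = products,
      mean_r2 = unname(apply(score_mat, 2, summary_fn)),
      copeland = as.numeric(out$copeland[products])
    )
  }
  structure(
    list(
      regions = dplyr::bind_rows(region_rows),
      products = dplyr::bind_rows(product_rows),
      tallies = tallies
    ),
    class = "condorcet_report"
  )
}

#' @export
print.condorcet_report <- function(x, ...) {
  cat("<condorcet_report>", nrow(x$regions), "region(s)\n")
  print(x$regions, ...)
  invisible(x)
}

#' @describeIn regional_report One row per region x product with the
#'   regional summary R-squared, Copeland score and winner/loser flags.
#' @param x A `condorcet_report`.
#' @param ... Unused.
#' @export
tidy.condorcet_report <- function(x, ...) {
  dplyr::left_join(x$products,
                   x$regions[c("region", "winner", "loser", "n_ballots")],
                   by = "region") |>
    dplyr::mutate(
      is_winner = !is.na(.data$winner) & .data$product_id == .data$winner,
      is_loser = !is.na(.data$loser) & .data$product_id == .data$loser
    ) |>
    dplyr::select(-"winner", -"loser")
}

#' @describeIn regional_report One-row summary: regions ranked, regions
#'   with a winner, cycles encountered.
#' @export
glance.condorcet_report <- function(x, ...) {
  tibble(
    n_regions = nrow(x$regions),
    n_with_winner = sum(!is.na(x$regions$winner)),
    n_cycles = sum(x$regions$used_fallback %in% TRUE),
    n_flagged = sum(x$regions$flagged),
    total_ballots = sum(x$regions$n_ballots)
  )
}

#' Write a per-region Condorcet report to a delimited file
#'
#' One row per region x product (long form): region, n_ballots, winner,
#' loser, used_fallback, product_id, copeland, mean_r2.
#'
#' @param report A `condorcet_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "condorcet_report"))
  readr::write_tsv(tidy(report), path, progress = FALSE)
  invisible(path)
}
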
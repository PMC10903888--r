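# Independent oracles, deliberately coded from first principles and kept
# structurally different from the package implementations they check.

# Fixed-span local linear smoother: symmetric nearest-neighbour window,
# plain lm() at each point.
oracle_local_linear <- function(x, y, span) {
  n <- length(y)
  h <- max(1L, floor(span * n / 2))
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    d <- data.frame(x = x[lo:hi], y = y[lo:hi])
    unname(predict(lm(y ~ x, data = d), newdata = data.frame(x = x[i])))
  }, numeric(1))
}

# Tukey biweight location by explicit elementwise loops.
oracle_biweight <- function(v, c_const = 9, tol = 1e-8, iter_cap = 50) {
  v <- v[is.finite(v)]
  if (length(v) < 4) return(median(v))
  est <- median(v)
  for (it in seq_len(iter_cap)) {
    scale <- median(abs(v - est))
    if (scale == 0) return(est)
    num <- 0; den <- 0
    for (vi in v) {
      u <- (vi - est) / (c_const * scale)
      if (abs(u) < 1) {
        w <- (1 - u * u)^2
        num <- num + w * vi
        den <- den + w
      }
    }
    nxt <- num / den
    if (abs(nxt - est) < tol) return(nxt)
    est <- nxt
  }
  est
}

# Un-adjusted R^2 by direct normal equations.
oracle_r2 <- function(y, X) {
  Xi <- cbind(1, X)
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  fitted <- Xi %*% beta
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

# Adjusted R^2 for the unadjusted-vs-adjusted regression check.
oracle_adj_r2 <- function(y, X) {
  r2 <- oracle_r2(y, X)
  n <- length(y); p <- ncol(X)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# Condorcet winner by exhaustive pairwise majority over all pairs
# (double loop over ballots). Returns NA when no candidate beats all.
oracle_condorcet_winner <- function(ballots) {
  K <- ncol(ballots)
  prods <- colnames(ballots)
  for (a in seq_len(K)) {
    beats_all <- TRUE
    for (b in seq_len(K)) {
      if (a == b) next
      a_over_b <- 0; b_over_a <- 0
      for (i in seq_len(nrow(ballots))) {
        if (ballots[i, a] < ballots[i, b]) a_over_b <- a_over_b + 1
        if (ballots[i, b] < ballots[i, a]) b_over_a <- b_over_a + 1
      }
      if (!(a_over_b > b_over_a)) { beats_all <- FALSE; break }
    }
    if (beats_all) return(prods[a])
  }
  NA_character_
}

# Yule-Walker AR coefficients from sample autocovariances (biased
# normalization, as in standard chronology pre-whitening).
oracle_yule_walker <- function(x, p) {
  n <- length(x)
  xc <- x - mean(x)
  gamma <- vapply(0:p, function(k) {
    sum(xc[1:(n - k)] * xc[(1 + k):n]) / n
  }, numeric(1))
  solve(toeplitz(gamma[1:p]), gamma[2:(p + 1)])
}

# Random strict/tied ballot profile over K products.
random_ballots <- function(n, K, tie_prob = 0.2) {
  prods <- LETTERS[seq_len(K)]
  b <- t(replicate(n, {
    sc <- sample(seq_len(K), K, replace = runif(1) < tie_prob)
    as.integer(rank(sc, ties.method = "min"))
  }))
  colnames(b) <- prods
  b
}

# Small complete synthetic climate + growth pair for alignment tests.
toy_climate <- function(site = "s1", products = "p1", years = 1901:2000,
                        fun = function(y, m) {
                          50 + 3 * m + 15 * abs(sin(y * 0.71 + m)) +
                            8 * abs(cos(y * 1.37 + 2 * m))
                        }) {
  g <- expand.grid(site_id = site, product_id = products, year = years,
                   month = 1:12, stringsAsFactors = FALSE)
  g$precip_mm <- fun(g$year, g$month)
  tibble::as_tibble(g[order(g$site_id, g$product_id, g$year, g$month), ])
}

toy_regions <- function(sites = "s1", region = "r1", hemisphere = "N") {
  tibble::tibble(site_id = sites, region = region, hemisphere = hemisphere)
}

small_config <- function(...) {
  args <- list(n_sites = 6, n_regions = 2, years = 1961:2000,
               n_products = 2, product_noise_sd = c(0.2, 0.8),
               n_cores_per_site = 3, seed = 99)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
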
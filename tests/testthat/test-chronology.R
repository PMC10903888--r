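test_that("the detrending smoother reproduces lines and constants", {
  x <- 1:80
  y <- 3 + 0.25 * x
  expect_equal(supersmooth(x, y), y, tolerance = 1e-6)
  expect_equal(supersmooth(x, y, span = 0.3), y, tolerance = 1e-6)
  expect_equal(supersmooth(x, rep(2.5, 80)), rep(2.5, 80), tolerance = 1e-12)
  expect_error(supersmooth(1:5, rnorm(5)), "shorter than 10")
  expect_error(supersmooth(c(1, 1, 2:78), rnorm(79)), "strictly increasing")
})

test_that("variable-span smoothing tracks a noisy sine about as well as a fixed-span oracle", {
  set.seed(404)
  n <- 200
  x <- seq_len(n)
  signal <- sin(2 * pi * x / 50)
  y <- signal + rnorm(n, 0, 0.1)
  fit <- supersmooth(x, y)
  rmse <- sqrt(mean((fit - signal)^2))
  oracle_fit <- oracle_local_linear(x, y, 0.2)
  oracle_rmse <- sqrt(mean((oracle_fit - signal)^2))
  expect_lt(rmse, 0.12)
  expect_lt(rmse, 1.2 * oracle_rmse)
})

test_that("smoother fits stay within the padded data range", {
  set.seed(11)
  for (i in 1:5) {
    y <- cumsum(rnorm(60))
    fit <- supersmooth(seq_along(y), y)
    pad <- 0.1 * diff(range(y))
    inner <- 4:57
    expect_true(all(fit[inner] >= min(y) - pad))
    expect_true(all(fit[inner] <= max(y) + pad))
  }
})

test_that("ratio detrending behaves as stated", {
  w <- c(2, 3, 4, 3, 2)
  expect_equal(detrend_series(w, w), rep(1, 5))
  expect_equal(detrend_series(2 * w, w), rep(2, 5))
  expect_warning(out <- detrend_series(c(1, 1), c(1, -1)), "floored")
  expect_true(all(out > 0))

  # negative-exponential growth with multiplicative noise: index mean ~ 1
  set.seed(9)
  age <- 1:120
  raw <- 2 * exp(-0.02 * age) * exp(rnorm(120, 0, 0.15))
  idx <- detrend_series(raw, supersmooth(age, raw))
  expect_lt(abs(mean(idx) - 1), 0.05)
})

test_that("biweight mean matches an independent brute-force iteration", {
  expect_equal(biweight_mean(rep(1, 6)), 1)
  expect_equal(biweight_mean(c(0.9, 1.0, 1.1)), 1)  # < 4 values: median

  v <- c(1.00, 1.02, 0.98, 0.97, 1.03, 5.0)
  bw <- biweight_mean(v)
  expect_lt(abs(bw - oracle_biweight(v)), 1e-6)
  expect_lt(abs(bw - 1.0), abs(mean(v) - 1.0))  # outlier down-weighted

  set.seed(77)
  for (i in 1:200) {
    vv <- rnorm(sample(4:30, 1), sd = runif(1, 0.1, 3)) +
      c(rep(0, 5), 50)[sample.int(6, 1)]
    expect_lt(abs(biweight_mean(vv) - oracle_biweight(vv)), 1e-6)
  }
})

test_that("biweight mean stays inside the data range and equals the mean for tight symmetric data", {
  set.seed(3)
  for (i in 1:50) {
    v <- rnorm(12)
    m <- biweight_mean(v)
    expect_gte(m, min(v))
    expect_lte(m, max(v))
  }
  # symmetric values well inside the biweight window: exact arithmetic mean
  v <- c(0.98, 0.99, 1.0, 1.0, 1.01, 1.02)
  expect_equal(biweight_mean(v), mean(v), tolerance = 1e-7)
})

test_that("pre-whitening selects order 0 on most white-noise series and is then a no-op", {
  zero_orders <- 0L
  for (s in 1:50) {
    x <- withr::with_seed(1000 + s, rnorm(500))
    out <- prewhiten(x)
    if (attr(out, "order") == 0) {
      zero_orders <- zero_orders + 1L
      expect_identical(as.numeric(out), x)
    }
  }
  expect_gte(zero_orders, 30)  # AIC admits some spurious structure
})

test_that("pre-whitening an AR(1) series recovers the coefficient and whitens residuals", {
  x <- withr::with_seed(52, as.numeric(arima.sim(list(ar = 0.7), 500)))
  out <- prewhiten(x)
  p <- attr(out, "order")
  expect_gte(p, 1)
  # oracle: Yule-Walker solve on hand-computed autocovariances
  phi <- oracle_yule_walker(x, p)
  expect_lt(abs(phi[1] - 0.7), 0.1)
  res <- out[!is.na(out)]
  r1 <- cor(res[-1], res[-length(res)])
  expect_lt(abs(r1), 0.1)
  # mean re-added: output mean equals input mean
  expect_lt(abs(mean(res) - mean(x)), 1e-9)
})

test_that("pre-whitening is idempotent in distribution", {
  zero_after <- 0L
  for (s in 1:50) {
    x <- withr::with_seed(2000 + s, as.numeric(arima.sim(list(ar = 0.5), 300)))
    once <- prewhiten(x)
    once <- once[!is.na(once)]
    twice <- prewhiten(as.numeric(once))
    if (attr(twice, "order") == 0) zero_after <- zero_after + 1L
  }
  expect_gte(zero_after, 45)  # >= 90% of trials
})

test_that("constant series is returned unchanged with a warning", {
  expect_warning(out <- prewhiten(rep(2, 50)), "Constant")
  expect_equal(as.numeric(out), rep(2, 50))
})

test_that("chronologies of one or two identical cores equal the core index", {
  cfg <- small_config(hemisphere_split = 0)
  rings <- simulate_ring_widths(simulate_truth(cfg), cfg)
  one <- rings[rings$series_id == rings$series_id[1], ]
  chron1 <- build_chronology(one, prewhiten = FALSE)
  idx <- detrend_series(one$width_mm, supersmooth(one$year, one$width_mm))
  expect_equal(chron1$index, idx)
  expect_true(all(chron1$sample_depth == 1))

  two <- dplyr::bind_rows(one, dplyr::mutate(one, series_id = "twin"))
  chron2 <- build_chronology(two, prewhiten = FALSE)
  expect_equal(chron2$index, idx)
  expect_true(all(chron2$sample_depth == 2))
})

test_that("averaging cores improves correlation with the planted signal", {
  cfg <- sim_config(n_sites = 1, years = 1941:2000, n_products = 2,
                    product_noise_sd = c(0.2, 0.5), growth_noise_sd = 0.1,
                    ar1_coef = 0, core_noise_sd = 0.4, n_cores_per_site = 5,
                    hemisphere_split = 0, seed = 61)
  truth <- simulate_truth(cfg)
  rings <- simulate_ring_widths(truth, cfg)
  z <- precipval:::truth_zscores(truth, cfg)[[1]]
  lz <- precipval:::lagged_z(z, cfg$years, "N")
  signal <- drop(lz$X %*% cfg$response_weights)
  sig_at <- function(yrs) signal[match(yrs, lz$growth_years)]

  chron <- suppressWarnings(build_chronology(rings, prewhiten = FALSE))
  r_chron <- cor(chron$index, sig_at(chron$year))
  r_cores <- vapply(split(rings, rings$series_id), function(s) {
    idx <- detrend_series(s$width_mm, supersmooth(s$year, s$width_mm))
    cor(idx, sig_at(s$year))
  }, numeric(1))
  expect_gt(r_chron, max(r_cores))
})

test_that("the full chain on signal-free data leaves little autocorrelation", {
  cfg <- sim_config(n_sites = 4, years = 1921:2000, n_products = 2,
                    product_noise_sd = c(0.2, 0.5),
                    response_weights = rep(0, 8), ar1_coef = 0.5,
                    growth_noise_sd = 0.3, n_cores_per_site = 5,
                    hemisphere_split = 0, seed = 71)
  rings <- simulate_ring_widths(simulate_truth(cfg), cfg)
  chrons <- suppressWarnings(build_chronologies(rings, prewhiten = TRUE))
  r1 <- vapply(unique(chrons$site_id), function(sid) {
    idx <- chrons$index[chrons$site_id == sid]
    cor(idx[-1], idx[-length(idx)])
  }, numeric(1))
  # |r1| of a whitened ~80-year series has sd ~ 0.11, so individual sites
  # may drift; the persistence (phi = 0.5) must be gone on average
  expect_lt(mean(abs(r1)), 0.15)
  expect_lt(max(abs(r1)), 0.25)
})

test_that("cores shorter than the smoother minimum are mean-detrended with a warning", {
  short <- tibble::tibble(site_id = "s", series_id = "c1",
                          year = 1991:1998,
                          width_mm = c(1, 1.1, 0.9, 1, 1.2, 0.8, 1, 1))
  expect_warning(chron <- build_chronology(short, prewhiten = FALSE),
                 "shorter than 10")
  expect_equal(mean(chron$index), 1, tolerance = 1e-10)
})
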
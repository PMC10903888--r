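test_that("identical configs give bit-identical studies", {
  cfg <- small_config()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$products, s2$products)
  expect_identical(s1$ring_widths, s2$ring_widths)
  expect_identical(s1$evi, s2$evi)
  expect_identical(serialize(unclass(s1)[1:5], NULL),
                   serialize(unclass(s2)[1:5], NULL))
})

test_that("zero seasonal variability repeats the seasonal means exactly", {
  cfg <- small_config(seasonal_cv = 0)
  truth <- simulate_truth(cfg)
  by_month <- tapply(truth$precip_mm, truth$month, unique)
  expect_true(all(lengths(by_month) == 1))
  expect_equal(as.numeric(unlist(by_month)), cfg$seasonal_mean)
})

test_that("truth precipitation matches closed-form lognormal moments", {
  cfg <- sim_config(n_sites = 10, years = 1951:2000, seasonal_cv = 0.3,
                    seasonal_mean = rep(100, 12), seed = 11)
  truth <- simulate_truth(cfg)
  # oracle: lognormal with E[X] = m requires mu = log(m) - s^2/2,
  # s^2 = log(1 + cv^2); then E[X] = exp(mu + s^2/2) = m
  s2 <- log(1 + 0.3^2)
  expected_mean <- exp((log(100) - s2 / 2) + s2 / 2)
  expect_gt(nrow(truth), 1000)
  expect_lt(abs(mean(truth$precip_mm) - expected_mean) / expected_mean, 0.03)
  # and CV should be near 0.3
  expect_lt(abs(sd(truth$precip_mm) / mean(truth$precip_mm) - 0.3), 0.03)
})

test_that("zero product noise reproduces truth; fewer than 2 products rejected", {
  cfg <- small_config(product_noise_sd = c(0, 0.5))
  truth <- simulate_truth(cfg)
  prods <- derive_products(truth, cfg)
  p1 <- prods[prods$product_id == "product_01", ]
  expect_equal(p1$precip_mm, truth$precip_mm)
  expect_error(sim_config(n_products = 1, product_noise_sd = 0.1),
               "At least 2 products")
})

test_that("lower product noise means higher per-site correlation with truth", {
  cfg <- sim_config(n_sites = 100, years = 1901:2000, n_products = 2,
                    product_noise_sd = c(0.1, 1.0), seed = 5)
  truth <- simulate_truth(cfg)
  prods <- derive_products(truth, cfg)
  key <- function(d) order(d$site_id, d$year, d$month)
  tr <- truth[key(truth), ]
  wins <- vapply(unique(tr$site_id), function(sid) {
    tv <- tr$precip_mm[tr$site_id == sid]
    p1 <- prods[prods$product_id == "product_01" & prods$site_id == sid, ]
    p2 <- prods[prods$product_id == "product_02" & prods$site_id == sid, ]
    cor(tv, p1$precip_mm[key(p1)]) > cor(tv, p2$precip_mm[key(p2)])
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("region-specific noise shows up as larger log error in the noisy region", {
  sd_mat <- matrix(c(0.3, 0.3,   # product 1: same everywhere
                     0.1, 1.0),  # product 2: low in region 1, high in region 2
                   nrow = 2, byrow = TRUE)
  cfg <- sim_config(n_sites = 40, n_regions = 2, years = 1961:2000,
                    n_products = 2, product_noise_sd = sd_mat, seed = 8)
  truth <- simulate_truth(cfg)
  prods <- derive_products(truth, cfg)
  sites <- site_table(cfg)
  p2 <- prods[prods$product_id == "product_02", ]
  tr <- truth[order(truth$site_id, truth$year, truth$month), ]
  p2 <- p2[order(p2$site_id, p2$year, p2$month), ]
  err <- abs(log(p2$precip_mm) - log(tr$precip_mm))
  reg <- sites$region[match(p2$site_id, sites$site_id)]
  expect_gt(mean(err[reg == "region_02"]), mean(err[reg == "region_01"]))
})

test_that("noise-free ring widths trace the age-trend curve exactly", {
  cfg <- small_config(response_weights = rep(0, 8), ar1_coef = 0,
                      growth_noise_sd = 0, core_noise_sd = 0,
                      age_trend = c(2, 0.03), hemisphere_split = 0)
  rings <- simulate_ring_widths(simulate_truth(cfg), cfg)
  for (sid in unique(rings$series_id)) {
    one <- rings[rings$series_id == sid, ]
    ages <- one$year - one$year[1] + 1  # cores start at their first year
    expect_equal(one$width_mm, 2 * exp(-0.03 * ages), tolerance = 1e-10)
  }
})

test_that("strong signal and weak noise give a chronology tracking the planted signal", {
  cfg <- sim_config(n_sites = 1, years = 1941:2000, n_products = 2,
                    product_noise_sd = c(0.2, 0.5),
                    growth_noise_sd = 0.05, ar1_coef = 0,
                    core_noise_sd = 0.05, n_cores_per_site = 5,
                    hemisphere_split = 0, seed = 21)
  truth <- simulate_truth(cfg)
  rings <- simulate_ring_widths(truth, cfg)
  chron <- suppressWarnings(build_chronology(rings, prewhiten = FALSE))
  # planted signal: beta-weighted standardized truth precipitation
  z <- precipval:::truth_zscores(truth, cfg)[[1]]
  lz <- precipval:::lagged_z(z, cfg$years, "N")
  signal <- drop(lz$X %*% cfg$response_weights)
  shared <- intersect(chron$year, lz$growth_years)
  r <- cor(chron$index[match(shared, chron$year)],
           signal[match(shared, lz$growth_years)])
  expect_gt(r, 0.9)
})

test_that("greenness missingness filter matches the binomial retention oracle", {
  cfg <- sim_config(n_sites = 200, years = 1961:2000, evi_missing_frac = 0,
                    seed = 31)
  expect_equal(dplyr::n_distinct(simulate_evi(simulate_truth(cfg), cfg)$site_id),
               200)
  cfg6 <- sim_config(n_sites = 400, years = 1971:2000,
                     evi_missing_frac = 0.6, hemisphere_split = 0, seed = 32)
  evi <- simulate_evi(simulate_truth(cfg6), cfg6)
  n_years <- length(precipval:::lagged_z(
    matrix(0, 30, 12), cfg6$years, "N")$growth_years)
  # oracle: P(Binomial(n_years, 0.4) >= n_years / 2), exact binomial tail
  p_keep <- 1 - pbinom(ceiling(n_years / 2) - 1, n_years, 0.4)
  kept <- dplyr::n_distinct(evi$site_id)
  se <- sqrt(400 * p_keep * (1 - p_keep))
  expect_lt(abs(kept - 400 * p_keep), 4 * se + 1)
})

test_that("zero response and zero noise give constant greenness", {
  cfg <- small_config(response_weights = rep(0, 8), growth_noise_sd = 0,
                      ar1_coef = 0, evi_missing_frac = 0)
  evi <- simulate_evi(simulate_truth(cfg), cfg)
  expect_true(all(evi$value == 0))
})

test_that("generated precipitation and ring widths are strictly positive", {
  for (seed in c(3, 14)) {
    s <- simulate_study(small_config(seed = seed))
    expect_true(all(s$truth$precip_mm > 0))
    expect_true(all(s$products$precip_mm > 0))
    expect_true(all(s$ring_widths$width_mm > 0))
  }
})
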
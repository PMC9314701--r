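# SSD curves and hazardous-concentration posteriors.

test_that("fraction affected is the log-normal CDF", {
  expect_equal(ssd_fraction_affected(10^2.46, 2.46, 0.72), 0.5)
  hc5_conc <- 10^(2.46 + qnorm(0.05) * 0.72)
  expect_equal(ssd_fraction_affected(hc5_conc, 2.46, 0.72), 0.05)
  expect_lt(ssd_fraction_affected(1e-12, 2.46, 0.72), 1e-10)
  # strictly increasing in concentration
  grid <- 10^seq(-2, 5, length.out = 50)
  fa <- ssd_fraction_affected(grid, 2.46, 0.72)
  expect_true(all(diff(fa) > 0))
  expect_error(ssd_fraction_affected(0, 2.46, 0.72), "positive")
  expect_error(ssd_fraction_affected(-1, 2.46, 0.72), "positive")
  expect_error(ssd_fraction_affected(1, 2.46, 0), "sigma")
})

test_that("single-draw HC5 is the deterministic plug-in value", {
  # posterior medians of a size+media SSD fit to chronic NMP data
  fit <- make_fit(list(alpha = rep(3.20, 2), beta_size = rep(-0.21, 2),
                       beta_media = rep(-0.95, 2), sigma = rep(0.72, 2),
                       sigma_ref = rep(0, 2), `r[1]` = rep(0, 2)))
  marine <- hc5(fit, size_um = 0.1, medium = "marine")
  expect_equal(marine$median, 10^(2.46 + qnorm(0.05) * 0.72))
  expect_equal(marine$median, 18.86, tolerance = 1e-3)
  fresh <- hc5(fit, size_um = 0.1, medium = "freshwater")
  expect_equal(fresh$median, 10^(3.41 + qnorm(0.05) * 0.72))
  expect_equal(fresh$median, 168.2, tolerance = 1e-3)
  # marine SSD sits an order of magnitude lower here
  expect_equal(fresh$median / marine$median, 10^0.95, tolerance = 1e-9)
})

test_that("the fraction affected at every HC5 draw is exactly the protected fraction", {
  dat <- make_dataset(n_refs = 6, obs_per_ref = 4, seed = 21)
  fit <- suppressWarnings(
    fit_hssd(dat, hssd_spec(size = TRUE, media = TRUE),
             sampler_config_fast(seed = 21)))
  sigma <- as.vector(fit$draws[, , "sigma"])
  for (hcp in c(0.01, 0.05, 0.10)) {
    h <- hc5(fit, size_um = 1, medium = "marine", hcp = hcp)
    mu <- hssd:::scenario_mu(fit, 1, "marine")
    fa <- ssd_fraction_affected(h$draws, mu, sigma)
    expect_lt(max(abs(fa - hcp)), 1e-12)
  }
})

test_that("HC5 summaries are ordered and positive", {
  dat <- make_dataset(n_refs = 6, obs_per_ref = 4, seed = 22)
  fit <- suppressWarnings(
    fit_hssd(dat, hssd_spec(size = TRUE, media = TRUE),
             sampler_config_fast(seed = 22)))
  h <- hc5(fit, size_um = 10, medium = "freshwater")
  expect_true(all(h$draws > 0))
  expect_lte(h$ci_low, h$median)
  expect_lte(h$median, h$ci_high)
  expect_error(hc5(fit, size_um = -1, medium = "marine"), "positive")
  expect_error(hc5(fit, size_um = 1, medium = "marine", hcp = 1.2), "hcp")
  # polymer contrast requires a polymer term in the model
  expect_error(hc5(fit, size_um = 1, medium = "marine", polymer_is_ps = TRUE),
               "polymer")
})

test_that("a zero random-effect spread makes inclusive and exclusive HC5 identical", {
  dat <- make_dataset(n_refs = 6, obs_per_ref = 4, sigma_ref = 0, seed = 23)
  fit <- suppressWarnings(
    fit_hssd(dat, hssd_spec(size = TRUE), sampler_config_fast(seed = 23),
             sigma_ref_fixed = 0))
  h_off <- hc5(fit, size_um = 1, medium = "marine", seed = 7)
  h_on <- hc5(fit, size_um = 1, medium = "marine",
              include_random_effects = TRUE, seed = 7)
  expect_equal(h_on$draws, h_off$draws)
})

test_that("random-effect-inclusive intervals contain the exclusive ones", {
  dat <- make_dataset(n_refs = 10, obs_per_ref = 3, seed = 24)
  fit <- suppressWarnings(
    fit_hssd(dat, hssd_spec(size = TRUE, media = TRUE),
             sampler_config_fast(seed = 24)))
  h_ex <- hc5(fit, size_um = 0.1, medium = "marine", seed = 7)
  h_in <- hc5(fit, size_um = 0.1, medium = "marine",
              include_random_effects = TRUE, seed = 7)
  expect_lt(h_in$ci_low, h_ex$ci_low)
  expect_gt(h_in$ci_high, h_ex$ci_high)
})

test_that("HC5 tables cover the scenario grid and flag extrapolated sizes", {
  dat <- make_dataset(n_refs = 8, obs_per_ref = 4, seed = 25)
  fit <- suppressWarnings(
    fit_hssd(dat, hssd_spec(size = TRUE, media = TRUE),
             sampler_config_fast(seed = 25)))
  tab <- hc5_table(fit)
  expect_equal(nrow(tab), 10) # 5 sizes x 2 media
  expect_named(tab, c("medium", "size_um", "polymer_is_ps", "hc5_median",
                      "hc5_ci_low", "hc5_ci_high", "extrapolated"))
  rng <- attr(fit$data, "size_range_um")
  expect_equal(tab$extrapolated, tab$size_um < rng[1] | tab$size_um > rng[2])
  # sizes 1000 and 5000 um lie beyond any fit to <= 315 um particles
  expect_true(all(tab$extrapolated[tab$size_um >= 1000]))
  expect_error(hc5_table(fit, tibble::tibble()), "empty|columns")
})

test_that("SSD curves are monotone with ordered bands and shift with size", {
  dat <- make_dataset(n_refs = 8, obs_per_ref = 4, seed = 26)
  fit <- suppressWarnings(
    fit_hssd(dat, hssd_spec(size = TRUE, media = TRUE),
             sampler_config_fast(seed = 26)))
  curve <- ssd_curve(fit, size_um = 0.1, medium = "marine")
  expect_true(all(diff(curve$median) >= 0))
  expect_true(all(curve$ci_low <= curve$median & curve$median <= curve$ci_high))
  # one-point grid at the posterior-median SSD centre: fraction about 0.5
  mu_med <- median(hssd:::scenario_mu(fit, 0.1, "marine"))
  one <- ssd_curve(fit, 0.1, "marine", conc_grid = 10^mu_med)
  expect_equal(one$median, 0.5, tolerance = 0.05)
  # negative size effect: larger particles shift the curve to lower
  # concentrations (higher affected fraction at a fixed concentration)
  if (median(fit$draws[, , "beta_size"]) < 0) {
    small <- ssd_curve(fit, 0.1, "marine", conc_grid = 10^mu_med)
    large <- ssd_curve(fit, 100, "marine", conc_grid = 10^mu_med)
    expect_gt(large$median, small$median)
  }
  expect_error(ssd_curve(fit, 0.1, "marine", conc_grid = numeric(0)), "empty")
  expect_error(ssd_curve(fit, 0.1, "marine", conc_grid = c(2, 1)), "ascending")
})

test_that("result types render through autoplot", {
  dat <- make_dataset(n_refs = 6, obs_per_ref = 4, seed = 27)
  fit <- suppressWarnings(
    fit_hssd(dat, hssd_spec(size = TRUE), sampler_config_fast(seed = 27)))
  expect_s3_class(autoplot(ssd_curve(fit, 1, "marine")), "ggplot")
  expect_s3_class(autoplot(hc5(fit, 1, "marine")), "ggplot")
  cfg <- sampler_config(chains = 2, burnin = 100, draws = 100, thin = 1,
                        seed = 27)
  tab <- rank_models(suppressWarnings(fit_all_models(dat, cfg)))
  expect_s3_class(autoplot(tab), "ggplot")
})
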
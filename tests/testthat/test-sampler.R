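# Gibbs sampler: reproducibility, convergence diagnostics, posterior
# summaries, and agreement with independent fitters.

test_that("identical seed, config and data give bit-identical draws", {
  dat <- make_dataset(n_refs = 6, obs_per_ref = 3, seed = 1)
  cfg <- sampler_config(chains = 2, burnin = 100, draws = 100, thin = 1,
                        seed = 123)
  f1 <- suppressWarnings(fit_hssd(dat, hssd_spec(size = TRUE), cfg))
  f2 <- suppressWarnings(fit_hssd(dat, hssd_spec(size = TRUE), cfg))
  expect_identical(f1$draws, f2$draws)
})

test_that("retained-draw accounting follows chains x draws / thin", {
  dat <- make_dataset(n_refs = 5, obs_per_ref = 4, seed = 2)
  cfg <- sampler_config(chains = 3, burnin = 50, draws = 100, thin = 10,
                        seed = 1)
  fit <- suppressWarnings(fit_hssd(dat, hssd_spec(), cfg))
  expect_equal(dim(fit$draws)[1:2], c(10L, 3L))
  # default profile: 3 x 10,000 / 10 = 3,000 retained
  dflt <- sampler_config()
  expect_equal(dflt$chains * dflt$draws / dflt$thin, 3000)
  expect_error(sampler_config(draws = 100, thin = 3), "divide")
})

test_that("degenerate inputs are rejected", {
  dat <- make_dataset(n_refs = 4, obs_per_ref = 4, seed = 3)
  empty <- dat[0, ]
  expect_error(fit_hssd(empty, hssd_spec()), "empty|hssd_data")
  bad <- dat
  bad$y[1] <- NA_real_
  expect_error(fit_hssd(bad, hssd_spec(), sampler_config_fast()),
               "non-finite")
  # more parameters than a 4-observation dataset supports
  tiny <- make_dataset(n_refs = 2, obs_per_ref = 2, seed = 4)
  expect_error(
    fit_hssd(tiny, hssd_spec(size = TRUE, media = TRUE, polymer = TRUE)),
    "too few")
})

test_that("all retained scale draws respect their support", {
  dat <- make_dataset(n_refs = 6, obs_per_ref = 3, seed = 5)
  fit <- suppressWarnings(
    fit_hssd(dat, hssd_spec(size = TRUE), sampler_config_fast(seed = 5)))
  expect_true(all(fit$draws[, , "sigma"] > 0))
  expect_true(all(fit$draws[, , "sigma_ref"] > 0))
  expect_true(all(is.finite(fit$rhat)))
})

test_that("split-chain R-hat matches a direct evaluation of the B/W formula", {
  draws <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  # independent hand computation: split each chain in half
  halves <- list(c(1, 2), c(3, 4), c(2, 3), c(4, 5))
  W <- mean(vapply(halves, var, 1))
  B_over_m <- var(vapply(halves, mean, 1))
  m <- 2
  expected <- sqrt(((m - 1) / m * W + B_over_m) / W)
  expect_equal(gelman_rubin(draws), expected)
  expect_equal(expected, 1.9578900, tolerance = 1e-6)
})

test_that("R-hat separates mixed from divergent chains", {
  withr::with_seed(7, {
    same <- cbind(rnorm(2000), rnorm(2000))
    apart <- cbind(rnorm(2000), rnorm(2000) + 10)
  })
  expect_lt(gelman_rubin(same), 1.02)
  expect_gt(gelman_rubin(apart), 5)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "chain")
  expect_error(gelman_rubin(cbind(1:2, 3:4)), "draws")
})

test_that("posterior summaries use interpolated percentiles", {
  fit <- make_fit(list(alpha = as.numeric(1:100), sigma = rep(2, 100),
                       sigma_ref = rep(0.5, 100), `r[1]` = rep(0, 100)),
                  spec = hssd_spec())
  s <- posterior_summary(fit)
  expect_equal(s$median[s$parameter == "alpha"], 50.5)
  expect_equal(s$ci_low[s$parameter == "alpha"],
               unname(quantile(1:100, 0.025)))
  # constant draws collapse to a point
  expect_equal(unlist(s[s$parameter == "sigma", c("median", "ci_low", "ci_high")],
                      use.names = FALSE),
               c(2, 2, 2))
})

test_that("tidy and glance expose broom-shaped summaries", {
  dat <- make_dataset(n_refs = 6, obs_per_ref = 3, seed = 6)
  fit <- suppressWarnings(
    fit_hssd(dat, hssd_spec(size = TRUE), sampler_config_fast(seed = 6)))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high", "rhat"))
  expect_setequal(td$term, c("alpha", "beta_size", "sigma", "sigma_ref"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(dat))
  expect_equal(gl$n_draws, 6000)
  expect_equal(gl$model, "size")
})

test_that("row order of the data does not change the posterior", {
  rec <- simulate_hssd_records(n_refs = 8, obs_per_ref = 5, seed = 8)
  dat <- encode_predictors(rec)
  perm <- withr::with_seed(1, sample(nrow(dat)))
  dat_perm <- dat[perm, ]
  attr(dat_perm, "ref_levels") <- attr(dat, "ref_levels")
  attr(dat_perm, "size_range_um") <- attr(dat, "size_range_um")
  class(dat_perm) <- class(dat)
  cfg <- sampler_config_fast(seed = 21)
  s1 <- posterior_summary(suppressWarnings(fit_hssd(dat, hssd_spec(size = TRUE), cfg)))
  s2 <- posterior_summary(suppressWarnings(fit_hssd(dat_perm, hssd_spec(size = TRUE), cfg)))
  expect_lt(max(abs(s1$median - s2$median)), 0.1)
})

test_that("with sigma_ref fixed at zero the posterior mean matches least squares", {
  rec <- simulate_hssd_records(n_refs = 10, obs_per_ref = 12, sigma_ref = 0,
                               seed = 31)
  dat <- encode_predictors(rec)
  fit <- suppressWarnings(fit_hssd(dat, hssd_spec(size = TRUE, media = TRUE),
                                   sampler_config_fast(seed = 31),
                                   sigma_ref_fixed = 0))
  ols <- coef(lm(y ~ x_size + x_media, data = dat))
  post_mean <- c(mean(fit$draws[, , "alpha"]),
                 mean(fit$draws[, , "beta_size"]),
                 mean(fit$draws[, , "beta_media"]))
  # flat-prior conjugate limit: posterior centred on the OLS solution
  expect_lt(max(abs(post_mean - ols)), 0.02)
  expect_true(all(fit$draws[, , "sigma_ref"] == 0))
  expect_true(all(fit$draws[, , "r[1]"] == 0))
})

test_that("the Gibbs sampler agrees with an independent JAGS fit", {
  rec <- simulate_hssd_records(n_refs = 8, obs_per_ref = 5, seed = 13)
  dat <- encode_predictors(rec)
  fit <- suppressWarnings(fit_hssd(dat, hssd_spec(size = TRUE, media = TRUE),
                                   sampler_config_fast(seed = 13)))
  mine <- posterior_summary(fit)

  model_string <- "
  model {
    for (i in 1:n) {
      y[i] ~ dnorm(alpha + bs * xs[i] + bm * xm[i] + r[ref[i]],
                   1 / (sigma * sigma))
    }
    for (j in 1:J) { r[j] ~ dnorm(0, 1 / (sref * sref)) }
    alpha ~ dunif(-50, 50)
    bs ~ dunif(-50, 50)
    bm ~ dunif(-50, 50)
    sigma ~ dunif(0, 50)
    sref ~ dunif(0, 50)
  }"
  jm <- rjags::jags.model(
    textConnection(model_string),
    data = list(y = dat$y, xs = dat$x_size, xm = dat$x_media,
                ref = dat$ref_index, n = nrow(dat), J = 8),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 13),
    n.chains = 1, quiet = TRUE)
  update(jm, 3000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("alpha", "bs", "bm", "sigma", "sref"),
                            n.iter = 8000, progress.bar = "none")
  jmed <- apply(as.matrix(js[[1]]), 2, median)

  get <- function(p) mine$median[mine$parameter == p]
  expect_lt(abs(get("alpha") - jmed["alpha"]), 0.15)
  expect_lt(abs(get("beta_size") - jmed["bs"]), 0.1)
  expect_lt(abs(get("beta_media") - jmed["bm"]), 0.15)
  expect_lt(abs(get("sigma") - jmed["sigma"]), 0.1)
  expect_lt(abs(get("sigma_ref") - jmed["sref"]), 0.15)
})
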
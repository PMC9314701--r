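# SSD curves and hazardous concentrations (HC5) from posterior draws.

#' Fraction of species affected at a concentration
#'
#' The cumulative probability of the log-normal SSD at `conc_ug_l`: the
#' expected proportion of species whose chronic effect concentration lies
#' below it, `pnorm((log10(conc) - mu) / sigma)`.
#'
#' @param conc_ug_l Concentration(s), ug/L, > 0.
#' @param mu,sigma SSD mean and standard deviation on the log10 scale.
#' @return Fractions in \[0, 1\], strictly increasing in `conc_ug_l`.
#' @export
#' @examples
#' ssd_fraction_affected(10^2.46, mu = 2.46, sigma = 0.72) # the SSD median
ssd_fraction_affected <- function(conc_ug_l, mu, sigma) {
  if (any(conc_ug_l <= 0)) rlang::abort("concentrations must be positive")
  if (any(sigma <= 0)) rlang::abort("sigma must be positive")
  stats::pnorm((log10(conc_ug_l) - mu) / sigma)
}

# scenario mu for each retained draw (no random effect). `polymer_is_ps`
# may be NULL = "not requested": an error only if the model includes the
# polymer predictor and the caller must choose.
scenario_mu <- function(fit, size_um, medium, polymer_is_ps = FALSE) {
  spec <- fit$spec
  medium <- match.arg(medium, c("freshwater", "marine"))
  if (size_um <= 0) rlang::abort("size_um must be positive")
  mu <- param_vector(fit, "alpha")
  if (spec$use_size) mu <- mu + param_vector(fit, "beta_size") * log10(size_um)
  if (spec$use_media) {
    mu <- mu + param_vector(fit, "beta_media") * (medium == "marine")
  }
  if (spec$use_polymer) {
    mu <- mu + param_vector(fit, "beta_polymer") * as.numeric(polymer_is_ps)
  } else if (isTRUE(polymer_is_ps)) {
    rlang::abort("scenario requests a polymer contrast but the fitted model has no polymer predictor")
  }
  mu
}

is_extrapolated <- function(fit, size_um) {
  rng <- attr(fit$data, "size_range_um")
  !is.null(rng) && (size_um < rng[1] || size_um > rng[2])
}

#' Posterior distribution of the hazardous concentration (HC5)
#'
#' For each retained draw the scenario SSD mean is assembled from the
#' sampled coefficients, and the hazardous concentration for a fraction
#' `hcp` of species is `10^(mu_s + qnorm(hcp) * sigma_s)` (ug/L). By
#' default the reference-level random effects are left out, so the HC5
#' describes a study free of reference-specific unmodeled factors; with
#' `include_random_effects = TRUE` one fresh perturbation
#' `r* ~ Normal(0, sigma_ref_s)` is added to each draw's mean, propagating
#' the between-reference uncertainty into the HC5.
#'
#' @param fit A [fit_hssd()] result.
#' @param size_um Particle size for the scenario, um. Sizes outside the
#'   fitted range are flagged as extrapolations.
#' @param medium `"freshwater"` or `"marine"` (ignored by models without
#'   the media predictor).
#' @param polymer_is_ps Scenario polymer is polystyrene? Only meaningful --
#'   and only allowed to be `TRUE` -- when the model includes the polymer
#'   predictor.
#' @param include_random_effects Add the reference-level perturbation?
#' @param hcp Protected fraction; 0.05 gives the conventional HC5.
#' @param seed Optional seed for the random-effect perturbation stream
#'   (ignored unless `include_random_effects`).
#' @return A `hssd_hc5` object: `draws` (ug/L), `median`, `ci_low`,
#'   `ci_high` (2.5th/97.5th percentiles), and the scenario description.
#' @export
#' @examples
#' rec <- simulate_hssd_records(seed = 3)
#' fit <- fit_hssd(encode_predictors(rec),
#'                 config = sampler_config_fast(seed = 3))
#' hc5(fit, size_um = 0.1, medium = "marine")
hc5 <- function(fit, size_um, medium, polymer_is_ps = FALSE,
                include_random_effects = FALSE, hcp = 0.05, seed = NULL) {
  if (hcp <= 0 || hcp >= 1) rlang::abort("hcp must lie in (0, 1)")
  mu <- scenario_mu(fit, size_um, medium, polymer_is_ps)
  sigma <- param_vector(fit, "sigma")
  if (include_random_effects) {
    sigma_ref <- param_vector(fit, "sigma_ref")
    if (!is.null(seed)) {
      mu <- mu + withr::with_seed(seed, rnorm(length(mu), 0, sigma_ref))
    } else {
      mu <- mu + rnorm(length(mu), 0, sigma_ref)
    }
  }
  draws <- 10^(mu + qnorm(hcp) * sigma)
  q <- quantile(draws, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  structure(
    list(draws = draws, median = q[2], ci_low = q[1], ci_high = q[3],
         hcp = hcp,
         scenario = list(size_um = size_um, medium = medium,
                         polymer_is_ps = polymer_is_ps,
                         include_random_effects = include_random_effects,
                         extrapolated = is_extrapolated(fit, size_um))),
    class = "hssd_hc5"
  )
}

#' @export
print.hssd_hc5 <- function(x, ...) {
  cat(sprintf(
    "<hssd_hc5> HC%d at %g um, %s%s: %.3g ug/L (95%% CrI %.3g-%.3g)%s\n",
    round(100 * x$hcp), x$scenario$size_um, x$scenario$medium,
    if (x$scenario$include_random_effects) ", random effects included" else "",
    x$median, x$ci_low, x$ci_high,
    if (x$scenario$extrapolated) " [extrapolated size]" else ""))
  invisible(x)
}

#' Scenario grids and HC5 tables
#'
#' `scenario_grid()` builds the full crossing of particle sizes and media;
#' `hc5_table()` evaluates [hc5()] for every row of a scenario table and
#' returns one summary row per scenario.
#'
#' @param size_um Particle sizes, um. The default grid spans the nanoplastic
#'   to large-microplastic range; sizes beyond the fitted data are flagged.
#' @param medium Media to cross with the sizes.
#' @param polymer_is_ps Scenario polymer indicator (recycled).
#' @return A tibble of scenarios.
#' @export
#' @examples
#' scenario_grid()
scenario_grid <- function(size_um = c(0.05, 0.1, 10, 1000, 5000),
                          medium = c("freshwater", "marine"),
                          polymer_is_ps = FALSE) {
  tidyr::crossing(medium = medium, size_um = size_um) |>
    dplyr::mutate(polymer_is_ps = polymer_is_ps) |>
    dplyr::arrange(match(medium, c("freshwater", "marine")), .data$size_um)
}

#' @rdname scenario_grid
#' @param fit A [fit_hssd()] result.
#' @param scenarios A tibble with columns `size_um`, `medium` and optionally
#'   `polymer_is_ps`.
#' @inheritParams hc5
#' @export
hc5_table <- function(fit, scenarios = scenario_grid(),
                      include_random_effects = FALSE, hcp = 0.05,
                      seed = NULL) {
  scenarios <- tibble::as_tibble(scenarios)
  if (nrow(scenarios) == 0) rlang::abort("empty scenario table")
  if (!all(c("size_um", "medium") %in% names(scenarios))) {
    rlang::abort("scenarios need columns size_um and medium")
  }
  if (!"polymer_is_ps" %in% names(scenarios)) scenarios$polymer_is_ps <- FALSE
  purrr::pmap_dfr(scenarios, function(size_um, medium, polymer_is_ps, ...) {
    h <- hc5(fit, size_um, medium, polymer_is_ps,
             include_random_effects = include_random_effects, hcp = hcp,
             seed = seed)
    tibble::tibble(
      medium = medium, size_um = size_um, polymer_is_ps = polymer_is_ps,
      hc5_median = h$median, hc5_ci_low = h$ci_low, hc5_ci_high = h$ci_high,
      extrapolated = h$scenario$extrapolated
    )
  })
}

#' SSD curve with credible band
#'
#' Pointwise posterior median and 95% band of the fraction of species
#' affected across a concentration grid, for one exposure scenario.
#'
#' @inheritParams hc5
#' @param conc_grid Positive, ascending concentrations (ug/L); the default
#'   spans 1e-3 to 1e6 log-uniformly.
#' @return A `hssd_ssd_curve` tibble: `conc_ug_l`, `median`, `ci_low`,
#'   `ci_high`.
#' @export
ssd_curve <- function(fit, size_um, medium, polymer_is_ps = FALSE,
                      conc_grid = 10^seq(-3, 6, length.out = 181)) {
  if (length(conc_grid) == 0) rlang::abort("empty concentration grid")
  if (any(conc_grid <= 0)) rlang::abort("concentrations must be positive")
  if (is.unsorted(conc_grid, strictly = FALSE)) {
    rlang::abort("concentration grid must be ascending")
  }
  mu <- scenario_mu(fit, size_um, medium, polymer_is_ps)
  sigma <- param_vector(fit, "sigma")
  out <- purrr::map_dfr(conc_grid, function(conc) {
    fa <- ssd_fraction_affected(conc, mu, sigma)
    q <- quantile(fa, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    tibble::tibble(conc_ug_l = conc, median = q[2], ci_low = q[1],
                   ci_high = q[3])
  })
  structure(out,
            scenario = list(size_um = size_um, medium = medium,
                            polymer_is_ps = polymer_is_ps),
            class = c("hssd_ssd_curve", class(out)))
}
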
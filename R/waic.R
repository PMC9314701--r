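# Model comparison by WAIC (widely applicable information criterion),
# computed from the pointwise posterior log densities and reported on the
# deviance scale, waic = -2 * (lppd - p_waic).

#' WAIC of a fitted model
#'
#' For each observation `i` and retained draw `s`, the log density
#' `log p(y_i | theta_s)` is evaluated conditional on the sampled reference
#' intercepts. Then `lppd_i = log mean_s exp(log p_is)` (computed by a
#' stable log-sum-exp), `p_waic_i = var_s(log p_is)`, and
#' `waic = -2 * (sum lppd_i - sum p_waic_i)`.
#'
#' With `marginal = TRUE` the reference intercepts are integrated out
#' analytically instead: `y_i ~ Normal(fixed part, sqrt(sigma^2 +
#' sigma_ref^2))`, which scores predictions for a new, unseen reference.
#'
#' @param fit A [fit_hssd()] result (>= 2 retained draws).
#' @param marginal Integrate over the reference random effect?
#' @return A `hssd_waic` object: `lppd`, `p_waic`, `waic`, and a
#'   `pointwise` tibble with per-observation contributions.
#' @export
#' @examples
#' rec <- simulate_hssd_records(n_refs = 6, obs_per_ref = 4, seed = 7)
#' fit <- fit_hssd(encode_predictors(rec), hssd_spec(size = TRUE),
#'                 sampler_config(chains = 2, burnin = 200, draws = 200,
#'                                thin = 1, seed = 7))
#' waic(fit)
waic <- function(fit, marginal = FALSE) {
  ll <- loglik_matrix(fit, marginal = marginal)
  waic_from_loglik(ll)
}

# draws x observations matrix of pointwise log densities
loglik_matrix <- function(fit, marginal = FALSE) {
  data <- fit$data
  X <- design_matrix(data, fit$spec)
  d <- dim(fit$draws)
  S <- d[1] * d[2]
  b <- matrix(fit$draws[, , fixed_names(fit$spec)], nrow = S)
  sigma <- param_vector(fit, "sigma")
  fixed <- b %*% t(X) # S x n
  if (marginal) {
    sigma_ref <- param_vector(fit, "sigma_ref")
    sd_tot <- sqrt(sigma^2 + sigma_ref^2)
    mu <- fixed
    sds <- sd_tot
  } else {
    r <- matrix(fit$draws[, , startsWith(fit$param_names, "r["), drop = FALSE],
                nrow = S)
    mu <- fixed + r[, data$ref_index, drop = FALSE]
    sds <- sigma
  }
  stats::dnorm(matrix(data$y, nrow = S, ncol = ncol(mu), byrow = TRUE),
               mean = mu, sd = sds, log = TRUE)
}

# WAIC from an S x n log-likelihood matrix
waic_from_loglik <- function(ll) {
  if (nrow(ll) < 2) rlang::abort("WAIC needs >= 2 posterior draws")
  S <- nrow(ll)
  # column-wise log-sum-exp
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx)))) # log mean exp
  p_waic_i <- apply(ll, 2, var)
  structure(
    list(
      lppd = sum(lppd_i), p_waic = sum(p_waic_i),
      waic = -2 * (sum(lppd_i) - sum(p_waic_i)),
      pointwise = tibble::tibble(observation = seq_len(ncol(ll)),
                                 lppd = lppd_i, p_waic = p_waic_i,
                                 waic = -2 * (lppd_i - p_waic_i))
    ),
    class = "hssd_waic"
  )
}

#' @export
print.hssd_waic <- function(x, ...) {
  cat(sprintf("<hssd_waic> waic = %.2f (lppd = %.2f, p_waic = %.2f)\n",
              x$waic, x$lppd, x$p_waic))
  invisible(x)
}

#' Fit all eight candidate models
#'
#' Runs [fit_hssd()] for every predictor subset from [enumerate_models()].
#' Each model gets the same sampler configuration (and therefore seed).
#'
#' @inheritParams fit_hssd
#' @return A named list of `hssd_fit` objects, one per model label.
#' @export
fit_all_models <- function(data, config = sampler_config()) {
  purrr::map(enumerate_models(), function(spec) {
    fit_hssd(data, spec, config)
  })
}

#' Rank candidate models by WAIC
#'
#' Orders models by ascending WAIC and reports the difference to the
#' minimum (delta WAIC). Exact ties are broken by fewer predictors, then by
#' label; when that happens a `tie_break` note is attached as an attribute.
#'
#' @param fits A named list of `hssd_fit` objects (e.g. from
#'   [fit_all_models()]), or a named list of `hssd_waic` objects.
#' @param marginal Passed to [waic()] when `fits` contains fits.
#' @return A `hssd_rank_table` tibble: `rank`, `model`, `size`, `media`,
#'   `polymer` (`"+"` marks), `waic`, `delta_waic`, `lppd`, `p_waic`.
#' @export
rank_models <- function(fits, marginal = FALSE) {
  if (length(fits) == 0) rlang::abort("no models to rank")
  if (inherits(fits[[1]], "hssd_fit")) {
    specs <- purrr::map(fits, "spec")
    waics <- purrr::map(fits, waic, marginal = marginal)
  } else {
    specs <- purrr::map(names(fits), parse_spec_label)
    waics <- fits
  }
  labels <- unname(purrr::map_chr(specs, "label"))
  tab <- tibble::tibble(
    model = labels,
    size = ifelse(unname(purrr::map_lgl(specs, "use_size")), "+", ""),
    media = ifelse(unname(purrr::map_lgl(specs, "use_media")), "+", ""),
    polymer = ifelse(unname(purrr::map_lgl(specs, "use_polymer")), "+", ""),
    n_predictors = unname(purrr::map_int(specs, ~ n_fixed(.x) - 1L)),
    waic = unname(purrr::map_dbl(waics, "waic")),
    lppd = unname(purrr::map_dbl(waics, "lppd")),
    p_waic = unname(purrr::map_dbl(waics, "p_waic"))
  )
  ord <- order(tab$waic, tab$n_predictors, tab$model)
  tab <- tab[ord, ]
  tied <- duplicated(tab$waic) | duplicated(tab$waic, fromLast = TRUE)
  tab <- tab |>
    dplyr::mutate(rank = dplyr::row_number(),
                  delta_waic = .data$waic - min(.data$waic)) |>
    dplyr::select("rank", "model", "size", "media", "polymer", "waic",
                  "delta_waic", "lppd", "p_waic")
  out <- tibble::new_tibble(tab, class = "hssd_rank_table")
  if (any(tied)) {
    attr(out, "tie_break") <-
      "exact WAIC ties broken by fewer predictors, then label order"
  }
  out
}

#' Write a model-ranking table to CSV
#'
#' @param rank_table A [rank_models()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(rank_table, path) {
  readr::write_csv(tibble::as_tibble(rank_table), path, progress = FALSE)
  invisible(path)
}
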
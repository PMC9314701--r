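# Shared fixtures: small record tables, hand-built posterior objects, and
# an independent brute-force WAIC used as the oracle.

# a minimal valid effect-record row, overridable field by field
make_record <- function(species_name = "Daphnia magna",
                        reported_value = 100,
                        effect_type = "chronic_LOEC",
                        exposure_duration = NA_real_,
                        chronic_loec = NA_real_,
                        size_um = 1, shape = "sphere",
                        polymer = "polystyrene", medium = "freshwater",
                        reference_id = "ref_a", ...) {
  tibble::tibble(
    species_name = species_name, reported_value = reported_value,
    effect_type = effect_type, exposure_duration = exposure_duration,
    chronic_loec = chronic_loec, size_um = size_um, shape = shape,
    polymer = polymer, medium = medium, reference_id = reference_id, ...
  )
}

# small encoded dataset from the generator (deterministic)
make_dataset <- function(n_refs = 8, obs_per_ref = 5, seed = 42, ...) {
  encode_predictors(simulate_hssd_records(
    n_refs = n_refs, obs_per_ref = obs_per_ref, seed = seed, ...))
}

# hand-built hssd_fit: each row of `draw_tbl` is one parameter, columns are
# the retained draws (single chain x >=2 draws), for plug-in HC5 checks
make_fit <- function(draws_by_param, spec = hssd_spec(size = TRUE, media = TRUE),
                     n_refs = 1, size_range_um = c(0.04, 315)) {
  par_names <- names(draws_by_param)
  n_draw <- length(draws_by_param[[1]])
  arr <- array(NA_real_, dim = c(n_draw, 1, length(par_names)),
               dimnames = list(NULL, NULL, par_names))
  for (k in seq_along(par_names)) arr[, 1, k] <- draws_by_param[[k]]
  data_stub <- structure(tibble::tibble(.rows = 0),
                         size_range_um = size_range_um,
                         ref_levels = character(n_refs))
  structure(
    list(draws = arr, spec = spec,
         config = sampler_config_fast(seed = 1), data = data_stub,
         rhat = stats::setNames(rep(NA_real_, length(par_names)), par_names),
         sigma_ref_fixed = NULL, param_names = par_names, n_refs = n_refs),
    class = "hssd_fit"
  )
}

# independent WAIC oracle: plain double loop, no log-sum-exp, no vectorised
# shortcuts shared with the implementation
brute_force_waic <- function(loglik) {
  S <- nrow(loglik)
  n <- ncol(loglik)
  lppd <- 0
  p_waic <- 0
  for (i in seq_len(n)) {
    dens <- 0
    for (s in seq_len(S)) dens <- dens + exp(loglik[s, i])
    lppd <- lppd + log(dens / S)
    m <- mean(loglik[, i])
    v <- 0
    for (s in seq_len(S)) v <- v + (loglik[s, i] - m)^2
    p_waic <- p_waic + v / (S - 1)
  }
  list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic))
}
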
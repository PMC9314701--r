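# File-based pipeline stages: preprocess -> fit/select -> hc5, with
# plain-text posterior stores and an append-only JSON-lines run manifest.

#' Persist and reload posterior draws
#'
#' A posterior store is a pair of plain-text files: `<prefix>.csv` holds the
#' draws in long format (`chain`, `draw`, `parameter`, `value`) and
#' `<prefix>.json` the model label, sampler configuration, per-parameter
#' R-hat and the fitted size range. A reloaded store supports [hc5()],
#' [hc5_table()] and [ssd_curve()]; WAIC needs the original data and is
#' computed at fit time.
#'
#' @param fit A [fit_hssd()] result.
#' @param prefix Path prefix (without extension).
#' @return `write_posterior()` returns `prefix` invisibly;
#'   `read_posterior()` returns a `hssd_fit`-like object.
#' @export
write_posterior <- function(fit, prefix) {
  readr::write_csv(posterior_draws(fit), paste0(prefix, ".csv"),
                   progress = FALSE)
  sidecar <- list(
    model = fit$spec$label,
    config = unclass(fit$config),
    rhat = as.list(fit$rhat),
    n_refs = fit$n_refs,
    size_range_um = attr(fit$data, "size_range_um"),
    package_version = as.character(packageVersion("hssd"))
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(prefix) {
  draws_long <- readr::read_csv(paste0(prefix, ".csv"),
                                col_types = "iicd", progress = FALSE,
                                show_col_types = FALSE)
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  par_names <- unique(draws_long$parameter)
  n_chain <- max(draws_long$chain)
  n_draw <- max(draws_long$draw)
  arr <- array(NA_real_, dim = c(n_draw, n_chain, length(par_names)),
               dimnames = list(NULL, NULL, par_names))
  arr[cbind(draws_long$draw, draws_long$chain,
            match(draws_long$parameter, par_names))] <- draws_long$value
  data_stub <- structure(
    tibble::tibble(.rows = 0),
    size_range_um = sidecar$size_range_um,
    ref_levels = character(sidecar$n_refs)
  )
  structure(
    list(draws = arr, spec = parse_spec_label(sidecar$model),
         config = sidecar$config, data = data_stub,
         rhat = unlist(sidecar$rhat), sigma_ref_fixed = NULL,
         param_names = par_names, n_refs = sidecar$n_refs),
    class = "hssd_fit"
  )
}

append_manifest <- function(dir, stage, entries) {
  manifest <- c(
    list(stage = stage,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         package_version = as.character(packageVersion("hssd"))),
    entries
  )
  path <- file.path(dir, "manifest.jsonl")
  line <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' Pipeline stage: preprocess raw effect records
#'
#' Reads a raw effect-record CSV, applies the full preprocessing chain
#' (conversion to chronic LOECs, spherical filter, brackish
#' recategorisation, geometric-mean aggregation), and writes the processed
#' records plus a manifest line to `out_dir`.
#'
#' @param records_csv Path to the raw record CSV.
#' @param out_dir Output directory (created if needed).
#' @param extrapolation_csv Optional path to a custom extrapolation-factor
#'   table.
#' @inheritParams prepare_hssd_data
#' @return Path of the processed-record CSV, invisibly.
#' @export
run_preprocess <- function(records_csv, out_dir,
                           extrapolation_csv = NULL,
                           chronic_threshold_days = 7,
                           freshwater_species = "Hyalella azteca",
                           ps_labels = default_ps_labels()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- if (is.null(extrapolation_csv)) {
    default_extrapolation_table()
  } else {
    read_extrapolation_table(extrapolation_csv)
  }
  records <- read_effect_records(records_csv)
  n_in <- nrow(records)
  processed <- records |>
    convert_to_chronic_loec(table, chronic_threshold_days) |>
    filter_and_recategorize(freshwater_species) |>
    aggregate_geometric_mean(ps_labels)
  out_csv <- file.path(out_dir, "records_processed.csv")
  write_effect_records(
    dplyr::select(processed, -dplyr::any_of("extrapolation_factor")), out_csv)
  n_refs_out <- if (nrow(processed) > 0) {
    n_refs(encode_predictors(processed, ps_labels))
  } else {
    0L
  }
  append_manifest(out_dir, "preprocess", list(
    input = records_csv, output = out_csv, n_input = n_in,
    n_output = nrow(processed), n_species = length(unique(processed$species_name)),
    n_refs = n_refs_out,
    n_freshwater = sum(processed$medium == "freshwater"),
    n_marine = sum(processed$medium == "marine")
  ))
  invisible(out_csv)
}

#' Pipeline stage: fit all candidate models and rank them
#'
#' Reads a processed record CSV, fits all eight candidate models, writes a
#' posterior store per model, the WAIC rank table, and a manifest line.
#'
#' @param prepared_csv Path to a processed record CSV (chronic LOECs
#'   populated, no brackish rows).
#' @param out_dir Output directory.
#' @param config A [sampler_config()].
#' @param ps_labels Polymer labels counted as PS when encoding.
#' @return The rank table (invisibly); files land in `out_dir`.
#' @export
run_fit_select <- function(prepared_csv, out_dir,
                           config = sampler_config(),
                           ps_labels = default_ps_labels()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_effect_records(prepared_csv)
  dat <- encode_predictors(records, ps_labels)
  fits <- fit_all_models(dat, config)
  for (label in names(fits)) {
    write_posterior(fits[[label]],
                    file.path(out_dir, paste0("posterior_", gsub("\\+", "_", label))))
  }
  ranks <- rank_models(fits)
  write_rank_table(ranks, file.path(out_dir, "rank_table.csv"))
  append_manifest(out_dir, "fit_select", list(
    input = prepared_csv, seed = config$seed,
    best_model = ranks$model[1],
    max_rhat = max(purrr::map_dbl(fits, ~ max(.x$rhat, na.rm = TRUE)))
  ))
  invisible(ranks)
}

#' Pipeline stage: HC5 table for a scenario grid
#'
#' Loads a posterior store, evaluates the HC5 for every scenario row, and
#' writes the result table plus a manifest line.
#'
#' @param posterior_prefix Prefix of a posterior store written by
#'   [run_fit_select()] or [write_posterior()].
#' @param out_dir Output directory.
#' @param scenarios_csv Optional CSV with columns `medium`, `size_um` and
#'   optionally `polymer_is_ps`; defaults to the standard grid of
#'   [scenario_grid()].
#' @inheritParams hc5
#' @return The HC5 tibble (invisibly); written to `out_dir/hc5_table.csv`.
#' @export
run_hc5 <- function(posterior_prefix, out_dir, scenarios_csv = NULL,
                    include_random_effects = FALSE, hcp = 0.05,
                    seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- read_posterior(posterior_prefix)
  scenarios <- if (is.null(scenarios_csv)) {
    scenario_grid()
  } else {
    tab <- readr::read_csv(scenarios_csv, show_col_types = FALSE,
                           progress = FALSE)
    if (nrow(tab) == 0) rlang::abort("empty scenario file")
    tab
  }
  out <- hc5_table(fit, scenarios,
                   include_random_effects = include_random_effects,
                   hcp = hcp, seed = seed)
  out_csv <- file.path(out_dir, "hc5_table.csv")
  readr::write_csv(out, out_csv, progress = FALSE)
  append_manifest(out_dir, "hc5", list(
    posterior = posterior_prefix, scenarios = scenarios_csv %||% "default",
    include_random_effects = include_random_effects, hcp = hcp, seed = seed
  ))
  invisible(out)
}

#' Pipeline stage: simulate a synthetic dataset to disk
#'
#' Writes a synthetic effect-record CSV and its latent-truth JSON.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_hssd_records()].
#' @return Path of the record CSV, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- simulate_hssd_records(seed = seed, ...)
  out_csv <- file.path(out_dir, "records_synthetic.csv")
  write_effect_records(records, out_csv)
  write_truth(records, file.path(out_dir, "truth_synthetic.json"))
  append_manifest(out_dir, "simulate", list(
    output = out_csv, seed = seed, n_records = nrow(records)
  ))
  invisible(out_csv)
}
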
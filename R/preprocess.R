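# Preprocessing: raw effect records -> model-ready dataset.
#
# Chain: convert_to_chronic_loec -> filter_and_recategorize ->
#        aggregate_geometric_mean -> encode_predictors.

#' Extrapolation-factor tables
#'
#' Reported effect concentrations (LC50, EC50, NOEC, LOEC) are standardised
#' to chronic LOECs by dividing by an extrapolation factor that depends on
#' the effect-concentration type and an exposure-duration class
#' (`acute`/`chronic`, split at `chronic_threshold_days`). All factors must
#' lie in \[1, 30\].
#'
#' The table shipped with the package
#' (`system.file("extdata", "extrapolation_factors.csv", package = "hssd")`)
#' is an illustrative default: regulatory applications should substitute the
#' factor table of their assessment framework via `read_extrapolation_table()`.
#'
#' @param path CSV with columns `effect_type`, `duration_class`
#'   (`acute`, `chronic` or `any`) and `factor`.
#' @return A tibble with those three columns.
#' @export
#' @examples
#' default_extrapolation_table()
read_extrapolation_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    effect_type = readr::col_character(),
    duration_class = readr::col_character(),
    factor = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  validate_extrapolation_table(tab)
}

#' @rdname read_extrapolation_table
#' @export
default_extrapolation_table <- function() {
  read_extrapolation_table(
    system.file("extdata", "extrapolation_factors.csv", package = "hssd",
                mustWork = TRUE)
  )
}

validate_extrapolation_table <- function(tab) {
  tab <- tibble::as_tibble(tab)
  needed <- c("effect_type", "duration_class", "factor")
  if (!all(needed %in% names(tab))) {
    rlang::abort("extrapolation table needs columns effect_type, duration_class, factor")
  }
  if (any(is.na(tab$factor)) || any(tab$factor < 1) || any(tab$factor > 30)) {
    rlang::abort("extrapolation factors must lie in [1, 30]")
  }
  if (anyDuplicated(tab[, c("effect_type", "duration_class")])) {
    rlang::abort("duplicate (effect_type, duration_class) rows in extrapolation table")
  }
  tab
}

#' Convert reported effect concentrations to chronic LOECs
#'
#' Each record's reported concentration is divided by the extrapolation
#' factor resolved from `(effect_type, duration class)`; records already
#' typed `chronic_LOEC` pass through with factor 1. The applied factor is
#' recorded in an `extrapolation_factor` column for audit.
#'
#' @param records An effect-record table (see [validate_effect_records()]).
#' @param table An extrapolation table; defaults to the packaged one.
#' @param chronic_threshold_days Exposure durations at or above this many
#'   days are classed `chronic`, below it `acute`. Records without a
#'   duration fall back to a `duration_class` of `"any"` in the table.
#' @return The records with `chronic_loec` and `extrapolation_factor` filled.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   species_name = "Daphnia magna", reported_value = 200,
#'   effect_type = "EC50", exposure_duration = 2, size_um = 1,
#'   shape = "sphere", polymer = "polystyrene", medium = "freshwater",
#'   reference_id = "r1"
#' )
#' convert_to_chronic_loec(rec)$chronic_loec
convert_to_chronic_loec <- function(records, table = default_extrapolation_table(),
                                    chronic_threshold_days = 7) {
  records <- validate_effect_records(records)
  table <- validate_extrapolation_table(table)

  lookup <- function(effect_type, duration, i) {
    if (effect_type == "chronic_LOEC") return(1)
    cls <- if (is.na(duration)) "any" else if (duration >= chronic_threshold_days) "chronic" else "acute"
    hit <- table$factor[table$effect_type == effect_type &
                          table$duration_class == cls]
    if (length(hit) == 0) { # class-specific row absent: try the wildcard
      hit <- table$factor[table$effect_type == effect_type &
                            table$duration_class == "any"]
    }
    if (length(hit) == 0) {
      rlang::abort(sprintf(
        "no extrapolation factor for record %d (species %s, effect_type %s, duration class %s)",
        i, records$species_name[i], effect_type, cls))
    }
    hit[1]
  }
  factors <- purrr::map_dbl(seq_len(nrow(records)), function(i) {
    lookup(records$effect_type[i], records$exposure_duration[i], i)
  })
  if (any(is.na(records$reported_value) & records$effect_type != "chronic_LOEC")) {
    rlang::abort("reported_value required to convert non-chronic_LOEC records")
  }
  records$chronic_loec <- dplyr::if_else(
    records$effect_type == "chronic_LOEC" & !is.na(records$chronic_loec),
    records$chronic_loec,
    records$reported_value / factors
  )
  records$extrapolation_factor <- factors
  records
}

#' Midpoint of a particle-size range
#'
#' When only a size range is reported for an observation, the particle size
#' entering the model is the arithmetic mean of the range's minimum and
#' maximum. Vectorised.
#'
#' @param size_min_um,size_max_um Range bounds in micrometres;
#'   `0 < size_min_um <= size_max_um`.
#' @return `(size_min_um + size_max_um) / 2`.
#' @export
#' @examples
#' midpoint_size(0.04, 315)
midpoint_size <- function(size_min_um, size_max_um) {
  if (any(is.na(size_min_um)) || any(is.na(size_max_um))) {
    rlang::abort("size bounds must be non-missing")
  }
  if (any(size_min_um <= 0)) rlang::abort("size_min_um must be positive")
  if (any(size_min_um > size_max_um)) {
    rlang::abort("size_min_um must not exceed size_max_um")
  }
  (size_min_um + size_max_um) / 2
}

#' Restrict to spherical particles and resolve brackish media
#'
#' Keeps only records from tests with spherical particles (fibre and
#' irregular shapes are too sparse to model shape effects), then reassigns
#' brackish-medium records: species listed in `freshwater_species` become
#' freshwater, all others marine. Counts of dropped and reassigned records
#' are reported via `message()`.
#'
#' @param records An effect-record table.
#' @param freshwater_species Character vector of species whose brackish
#'   tests are recategorised as freshwater (default: *Hyalella azteca*, an
#'   epibenthic amphipod used in low-salinity assays).
#' @return The filtered, recategorised records; possibly zero rows (with a
#'   warning).
#' @export
filter_and_recategorize <- function(records,
                                    freshwater_species = "Hyalella azteca") {
  records <- validate_effect_records(records)
  keep <- records$shape == "sphere"
  n_dropped <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  brackish <- records$medium == "brackish"
  if (any(brackish)) {
    to_fresh <- brackish & records$species_name %in% freshwater_species
    records$medium[to_fresh] <- "freshwater"
    records$medium[brackish & !to_fresh] <- "marine"
    message(sprintf(
      "recategorised %d brackish record(s): %d to freshwater, %d to marine",
      sum(brackish), sum(to_fresh), sum(brackish & !to_fresh)))
  }
  if (n_dropped > 0) {
    message(sprintf("dropped %d non-spherical record(s)", n_dropped))
  }
  if (nrow(records) == 0) {
    rlang::warn("no records remain after the spherical-particle filter")
  }
  records
}

#' Aggregate replicate effect concentrations by geometric mean
#'
#' Observations of the same species under identical test conditions --
#' particle size, polymer category (PS vs non-PS), medium -- within one
#' reference are replaced by a single record whose chronic LOEC is their
#' geometric mean. Singleton groups pass through unchanged. Groups that
#' recur across references are kept separate (each aggregated record must
#' belong to exactly one reference for the random effect) and reported via
#' `message()`.
#'
#' @param records Effect records with `chronic_loec` populated.
#' @param ps_labels Polymer labels counted as polystyrene, matched
#'   case-insensitively (see [encode_predictors()]).
#' @return The aggregated records (row count is never larger than the input).
#' @export
aggregate_geometric_mean <- function(records, ps_labels = default_ps_labels()) {
  records <- validate_effect_records(records, require_chronic = TRUE)
  if (nrow(records) == 0) return(records)
  cond_key <- paste(records$species_name, sprintf("%.15g", records$size_um),
                    is_ps(records$polymer, ps_labels), records$medium,
                    sep = "\r")
  full_key <- paste(cond_key, records$reference_id, sep = "\r")
  # same conditions under different references: flag, aggregate within reference
  pairs <- !duplicated(full_key)
  n_cross <- sum(table(cond_key[pairs]) > 1)
  if (n_cross > 0) {
    message(sprintf(
      "%d condition group(s) recur across references; aggregated within reference only",
      n_cross))
  }
  gm <- tapply(log(records$chronic_loec), full_key, mean)
  out <- records[!duplicated(full_key), , drop = FALSE]
  out$chronic_loec <- as.numeric(exp(gm[full_key[!duplicated(full_key)]]))
  out
}

#' Default polystyrene label set
#'
#' Polymer labels treated as polystyrene (PS) when encoding the binary
#' polymer predictor: polystyrene itself and polystyrene--polyethyleneimine
#' mixtures. Matching is case-insensitive and whitespace-tolerant.
#' @return A character vector of labels.
#' @export
default_ps_labels <- function() {
  c("polystyrene", "ps",
    "polystyrene + polyethyleneimine", "polystyrene+polyethyleneimine",
    "ps + pei", "ps-pei", "ps+pei")
}

is_ps <- function(polymer, ps_labels = default_ps_labels()) {
  norm <- function(x) gsub("\\s+", " ", trimws(tolower(x)))
  norm(polymer) %in% norm(ps_labels)
}

#' Encode predictors into a model-ready dataset
#'
#' Builds the response and design columns of the hierarchical SSD from
#' preprocessed effect records: `y = log10(chronic_loec)`,
#' `x_size = log10(size_um)`, `x_media` (freshwater 0, marine 1),
#' `x_polymer` (non-PS 0, PS 1), and `ref_index`, consecutive integers
#' assigned by first appearance of `reference_id`.
#'
#' @param records Effect records after filtering (no brackish media) with
#'   `chronic_loec` populated.
#' @param ps_labels Polymer labels counted as PS (case-insensitive).
#' @return A `hssd_data` tibble with columns `y`, `x_size`, `x_media`,
#'   `x_polymer`, `ref_index`, `species_name`, `reference_id`, and
#'   attributes `ref_levels` (reference ids in index order) and
#'   `size_range_um` (fitted size range, used to flag extrapolation).
#' @export
#' @examples
#' rec <- simulate_hssd_records(n_refs = 4, obs_per_ref = 3, seed = 1)
#' dat <- encode_predictors(rec)
#' dplyr::glimpse(dat)
encode_predictors <- function(records, ps_labels = default_ps_labels()) {
  records <- validate_effect_records(records, require_chronic = TRUE)
  if (any(records$medium == "brackish")) {
    rlang::abort("brackish records must be recategorised (run filter_and_recategorize) before encoding")
  }
  if (nrow(records) == 0) rlang::abort("no records to encode")
  ref_levels <- unique(records$reference_id)
  dat <- tibble::tibble(
    y = log10(records$chronic_loec),
    x_size = log10(records$size_um),
    x_media = as.integer(records$medium == "marine"),
    x_polymer = as.integer(is_ps(records$polymer, ps_labels)),
    ref_index = match(records$reference_id, ref_levels),
    species_name = records$species_name,
    reference_id = records$reference_id
  )
  new_hssd_data(dat, ref_levels = ref_levels,
                size_range_um = range(records$size_um))
}

new_hssd_data <- function(dat, ref_levels, size_range_um) {
  structure(
    dat,
    ref_levels = ref_levels,
    size_range_um = size_range_um,
    class = c("hssd_data", class(dat))
  )
}

#' @export
print.hssd_data <- function(x, ...) {
  cat(sprintf("<hssd_data> %d observations, %d references, sizes %.3g-%.3g um\n",
              nrow(x), n_refs(x), attr(x, "size_range_um")[1],
              attr(x, "size_range_um")[2]))
  NextMethod()
}

n_refs <- function(data) length(attr(data, "ref_levels"))

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying, in order, [convert_to_chronic_loec()],
#' [filter_and_recategorize()], [aggregate_geometric_mean()] and
#' [encode_predictors()].
#'
#' @inheritParams convert_to_chronic_loec
#' @inheritParams filter_and_recategorize
#' @inheritParams encode_predictors
#' @return A `hssd_data` tibble (see [encode_predictors()]).
#' @export
prepare_hssd_data <- function(records, table = default_extrapolation_table(),
                              chronic_threshold_days = 7,
                              freshwater_species = "Hyalella azteca",
                              ps_labels = default_ps_labels()) {
  records |>
    convert_to_chronic_loec(table, chronic_threshold_days) |>
    filter_and_recategorize(freshwater_species) |>
    aggregate_geometric_mean(ps_labels) |>
    encode_predictors(ps_labels)
}
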
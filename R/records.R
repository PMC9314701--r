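#' @importFrom rlang .data
#' @importFrom stats median qnorm quantile rnorm runif rgamma sd var setNames
#' @importFrom utils packageVersion head
NULL

# Canonical column order for effect-record tables. Optional columns may be NA
# but must be present so CSV round-trips are lossless.
record_columns <- c(
  "species_name", "phylum", "reported_value", "effect_type",
  "exposure_duration", "chronic_loec", "size_min_um", "size_max_um",
  "size_um", "shape", "polymer", "medium", "salinity_permil", "reference_id"
)

effect_types <- c("LC50", "EC50", "NOEC", "LOEC", "chronic_LOEC", "other")
shape_levels <- c("sphere", "fiber", "irregular")
medium_levels <- c("freshwater", "marine", "brackish")

#' Effect-record tables
#'
#' An effect-record table holds one toxicity observation per row: the species
#' tested, the reported effect concentration and its type, the nano- or
#' microplastic particle's size (point value or min--max range, micrometres),
#' shape and polymer, the test medium, and the identifier of the study
#' (reference) the observation came from. Concentrations are in micrograms
#' per litre throughout.
#'
#' `validate_effect_records()` checks the table against the schema and
#' returns it invisibly, erroring on the first violation.
#'
#' @param records A data frame with the columns listed in Details.
#' @param require_chronic If `TRUE`, every row must carry a positive
#'   `chronic_loec` (i.e. conversion has already run).
#'
#' @details Required columns: `species_name`, `reported_value` (ug/L, > 0),
#' `effect_type` (one of LC50, EC50, NOEC, LOEC, chronic_LOEC, other),
#' `size_um` (um, > 0), `shape` (sphere, fiber, irregular), `polymer`,
#' `medium` (freshwater, marine, brackish), `reference_id`. Optional:
#' `phylum`, `exposure_duration` (days, > 0), `chronic_loec` (ug/L, > 0 when
#' populated), `size_min_um`/`size_max_um` (with
#' `size_min_um <= size_um <= size_max_um` when both are present),
#' `salinity_permil`.
#'
#' @return `records`, invisibly, with columns in canonical order.
#' @export
#' @examples
#' rec <- simulate_hssd_records(n_refs = 3, obs_per_ref = 2, seed = 1)
#' validate_effect_records(rec, require_chronic = TRUE)
validate_effect_records <- function(records, require_chronic = FALSE) {
  records <- as_record_tibble(records)
  n <- nrow(records)
  stop_if <- function(bad, msg) {
    idx <- which(bad)
    if (length(idx) > 0) {
      rlang::abort(sprintf("%s (first offending row: %d)", msg, idx[1]))
    }
  }
  stop_if(is.na(records$species_name) | records$species_name == "",
          "species_name must be non-empty")
  stop_if(is.na(records$reference_id) | records$reference_id == "",
          "reference_id must be non-empty")
  stop_if(!records$effect_type %in% effect_types,
          paste0("effect_type must be one of ", paste(effect_types, collapse = ", ")))
  stop_if(!records$shape %in% shape_levels,
          paste0("shape must be one of ", paste(shape_levels, collapse = ", ")))
  stop_if(!records$medium %in% medium_levels,
          paste0("medium must be one of ", paste(medium_levels, collapse = ", ")))
  stop_if(!is.na(records$reported_value) & records$reported_value <= 0,
          "reported_value must be positive (ug/L)")
  stop_if(is.na(records$size_um) | records$size_um <= 0,
          "size_um must be positive (um)")
  stop_if(!is.na(records$exposure_duration) & records$exposure_duration <= 0,
          "exposure_duration must be positive (days)")
  stop_if(!is.na(records$chronic_loec) & records$chronic_loec <= 0,
          "chronic_loec must be positive (ug/L) when populated")
  both <- !is.na(records$size_min_um) & !is.na(records$size_max_um)
  stop_if(both & records$size_min_um > records$size_max_um,
          "size_min_um must not exceed size_max_um")
  stop_if(both &
            (records$size_um < records$size_min_um - 1e-9 |
               records$size_um > records$size_max_um + 1e-9),
          "size_um must lie within [size_min_um, size_max_um]")
  if (require_chronic) {
    stop_if(is.na(records$chronic_loec), "chronic_loec must be populated")
  }
  invisible(records)
}

# Coerce to a tibble with the full canonical column set, filling optional
# columns with NA. Extra columns are preserved after the canonical ones.
as_record_tibble <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("species_name", "reported_value", "effect_type", "size_um",
                "shape", "polymer", "medium", "reference_id")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  for (col in setdiff(record_columns, names(records))) {
    records[[col]] <- if (col %in% c("phylum", "reference_id")) NA_character_ else NA_real_
  }
  dplyr::relocate(records, dplyr::all_of(record_columns))
}

#' Read and write effect-record CSV files
#'
#' The on-disk dialect is plain UTF-8 CSV with a header row, decimal points,
#' and the canonical column set of [validate_effect_records()]. Units are
#' fixed at micrograms per litre (concentrations) and micrometres (sizes);
#' a `units` column, if present, must declare `ug/L` and `um` or the file is
#' rejected.
#'
#' @param path Path to a CSV file.
#' @param records An effect-record table.
#' @return `read_effect_records()` returns a validated tibble;
#'   `write_effect_records()` returns `path` invisibly.
#' @export
read_effect_records <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("input file not found: ", path))
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      species_name = readr::col_character(),
      phylum = readr::col_character(),
      effect_type = readr::col_character(),
      shape = readr::col_character(),
      polymer = readr::col_character(),
      medium = readr::col_character(),
      reference_id = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if ("units" %in% names(records)) {
    ok <- records$units %in% c("ug/L,um", "ug/L um", "ug/L;um")
    if (!all(ok)) {
      rlang::abort("declared units must be ug/L (concentrations) and um (sizes)")
    }
    records$units <- NULL
  }
  validate_effect_records(records)
}

#' @rdname read_effect_records
#' @export
write_effect_records <- function(records, path) {
  records <- validate_effect_records(records)
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
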
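#' Occurrence record set
#'
#' Container for presence records of one species (or a pooled "combined"
#' set): coordinates in decimal degrees, an optional known positional error
#' in km, a free-text source, and a cleaning log counting records removed by
#' each filter that has been applied.
#'
#' @param records Data frame with columns `species`, `lon`, `lat` and
#'   optionally `error_km`, `source`.
#' @param species Set label; defaults to the single species present, or
#'   `"combined"` when records mix species.
#' @param cleaning_log Named integer vector of removal counts per filter.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(records, species = NULL, cleaning_log = integer(0)) {
  records <- as.data.frame(records)
  for (col in c("species", "lon", "lat"))
    if (!col %in% names(records)) stop("missing required column: ", col)
  if (!"error_km" %in% names(records)) records$error_km <- NA_real_
  if (!"source" %in% names(records)) records$source <- NA_character_
  records$lon <- as.numeric(records$lon)
  records$lat <- as.numeric(records$lat)
  records$error_km <- as.numeric(records$error_km)
  bad <- is.na(records$lon) | is.na(records$lat) |
    records$lat < -90 | records$lat > 90 |
    records$lon < -180 | records$lon > 180
  if (any(bad)) stop("records with invalid coordinates; drop them before construction")
  if (any(records$error_km < 0, na.rm = TRUE))
    stop("positional error must be non-negative")
  if (is.null(species)) {
    sp <- unique(records$species)
    species <- if (length(sp) == 1L) sp else "combined"
  }
  rownames(records) <- NULL
  structure(list(species = species, records = records,
                 cleaning_log = cleaning_log),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d record(s)\n", x$species, nrow(x$records)))
  if (length(x$cleaning_log)) {
    cat("  removed by filter:\n")
    for (nm in names(x$cleaning_log))
      cat(sprintf("    %s: %d\n", nm, x$cleaning_log[[nm]]))
  }
  invisible(x)
}

#' Number of records in a set
#' @param occ An [occurrence_set].
#' @return Integer count.
#' @export
n_records <- function(occ) nrow(occ$records)

#' Load occurrence records from CSV
#'
#' Expects a UTF-8 CSV with header columns `species`, `lon`, `lat` and
#' optionally `error_km` and `source`. Rows whose coordinates do not parse
#' or fall outside valid lon/lat ranges are dropped and counted in the
#' cleaning log under `"invalid_coordinates"`.
#'
#' @param path CSV file path.
#' @param species Optional label override for the set.
#' @return An [occurrence_set].
#' @export
load_occurrences <- function(path, species = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("species", "lon", "lat"))
    if (!col %in% names(df)) stop("missing required column: ", col)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad <- is.na(lon) | is.na(lat) | lat < -90 | lat > 90 | lon < -180 | lon > 180
  df$lon <- lon; df$lat <- lat
  occurrence_set(df[!bad, , drop = FALSE], species = species,
                 cleaning_log = c(invalid_coordinates = sum(bad)))
}

#' Build the study-area mask
#'
#' The analysis region excludes high-elevation cells (above the species'
#' documented elevational ceiling), everything south of a latitude floor,
#' and cells with no elevation data.
#'
#' @param elevation An [env_grid] of elevation in metres.
#' @param max_elev_m Elevation ceiling; cells at exactly this value are kept.
#' @param lat_floor Southernmost latitude retained (cell centers below it are
#'   dropped). A floor outside the grid's extent yields an all-false mask
#'   with a warning.
#' @return An [env_grid] named `"mask"` with values 1 (in study area) / 0.
#' @export
build_study_mask <- function(elevation, max_elev_m = 2500, lat_floor = -Inf) {
  stopifnot(is_env_grid(elevation))
  if (is.finite(lat_floor) &&
      (lat_floor > elevation$extent[4] || lat_floor < elevation$extent[3] - elevation$cell_size)) {
    warning("lat_floor outside grid extent; mask is all-false")
    m <- elevation$values * 0
    m[] <- 0
    return(env_grid(m, elevation$extent, elevation$cell_size, name = "mask"))
  }
  lat_center <- elevation$extent[4] - (seq_len(nrow(elevation$values)) - 0.5) *
    elevation$cell_size
  keep <- !is.na(elevation$values) & elevation$values <= max_elev_m
  keep <- keep & (lat_center >= lat_floor)  # recycles down columns
  env_grid(keep + 0, elevation$extent, elevation$cell_size, name = "mask")
}

# logical matrix view of a 0/1 mask grid
mask_matrix <- function(mask) {
  stopifnot(is_env_grid(mask))
  !is.na(mask$values) & mask$values > 0
}

#' Clean occurrence records
#'
#' Applies the rule-based filters in a fixed order: (1) drop records with a
#' known positional error greater than `max_error_km` (unknown errors are
#' retained); (2) drop records whose cell falls outside the study mask
#' (including outside the grid extent); (3) deduplicate to one record per
#' grid cell, keeping the first record in input order. The cleaning log
#' gains counts `positional_error`, `outside_mask`, `duplicate_cell`.
#'
#' @param occ An [occurrence_set].
#' @param mask Study mask grid from [build_study_mask()].
#' @param max_error_km Positional-error cutoff in km (strict `>` removal).
#' @return A cleaned [occurrence_set]; cleaning is idempotent.
#' @export
clean_occurrences <- function(occ, mask, max_error_km = 50) {
  stopifnot(inherits(occ, "occurrence_set"), is_env_grid(mask))
  df <- occ$records
  log <- occ$cleaning_log

  err_bad <- !is.na(df$error_km) & df$error_km > max_error_km
  log["positional_error"] <- sum(err_bad)
  df <- df[!err_bad, , drop = FALSE]

  mm <- mask_matrix(mask)
  idx <- cell_index(mask, df$lon, df$lat)
  inside <- !is.na(idx$row)
  flat <- ifelse(inside, (idx$col - 1L) * nrow(mm) + idx$row, NA_integer_)
  in_mask <- inside & mm[ifelse(inside, flat, 1L)]
  in_mask[!inside] <- FALSE
  log["outside_mask"] <- sum(!in_mask)
  df <- df[in_mask, , drop = FALSE]
  flat <- flat[in_mask]

  dup <- duplicated(flat)
  log["duplicate_cell"] <- sum(dup)
  df <- df[!dup, , drop = FALSE]

  occurrence_set(df, species = occ$species, cleaning_log = log)
}

#' Write an occurrence set (with its cleaning log) to CSV
#'
#' @param occ An [occurrence_set].
#' @param path Records CSV path.
#' @param log_path Optional path for the cleaning-log CSV.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path, log_path = NULL) {
  utils::write.csv(occ$records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(log_path))
    utils::write.csv(
      data.frame(filter = names(occ$cleaning_log),
                 removed = as.integer(occ$cleaning_log)),
      log_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
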
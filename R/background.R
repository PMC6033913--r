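#' Background point set
#'
#' Background ("pseudo-absence") points characterize the available
#' environment that presences are contrasted against. Two schemes are
#' supported: `"random"` (uniform sample of study-area cells, used with
#' spatially thinned presences) and `"targeted"` (occurrence records of a
#' broader target group sharing the presences' sampling bias, used with
#' un-thinned presences).
#'
#' @param points Data frame with columns `lon`, `lat`.
#' @param method `"random"` or `"targeted"`.
#' @param seed Generation seed (random method; `NA` for targeted).
#' @return An object of class `background_set`.
#' @export
background_set <- function(points, method = c("random", "targeted"), seed = NA) {
  method <- match.arg(method)
  points <- as.data.frame(points)[, c("lon", "lat")]
  rownames(points) <- NULL
  structure(list(method = method, points = points,
                 n = nrow(points), seed = seed),
            class = "background_set")
}

#' @export
print.background_set <- function(x, ...) {
  cat(sprintf("<background_set> %s: %d point(s)%s\n", x$method, x$n,
              if (!is.na(x$seed)) sprintf(" (seed %s)", format(x$seed)) else ""))
  invisible(x)
}

#' Sample a uniform random background
#'
#' Draws `n` distinct study-area cells uniformly without replacement and
#' returns their centers. Identical `(mask, n, seed)` always yields the
#' identical set, so several species modelled over one study area can share
#' one background.
#'
#' @param mask Study mask grid ([build_study_mask()]).
#' @param n Number of background cells.
#' @param seed Integer seed.
#' @param exclude Optional [occurrence_set] whose occupied cells are removed
#'   from the sampling frame (off by default: a presence-background design
#'   does not require presence-free background).
#' @return A [background_set] with `method = "random"`.
#' @export
sample_random_background <- function(mask, n = 10000, seed = 1, exclude = NULL) {
  stopifnot(is_env_grid(mask))
  mm <- mask_matrix(mask)
  avail <- which(mm)
  if (!is.null(exclude)) {
    idx <- cell_index(mask, exclude$records$lon, exclude$records$lat)
    occ_flat <- (idx$col - 1L) * nrow(mm) + idx$row
    avail <- setdiff(avail, occ_flat[!is.na(occ_flat)])
  }
  if (length(avail) < n)
    stop(sprintf("mask has %d available cells, fewer than n = %d",
                 length(avail), n))
  chosen <- withr::with_seed(seed, sort(sample(avail, n)))
  nr <- nrow(mm)
  row <- (chosen - 1L) %% nr + 1L
  col <- (chosen - 1L) %/% nr + 1L
  lon <- mask$extent[1] + (col - 0.5) * mask$cell_size
  lat <- mask$extent[4] - (row - 0.5) * mask$cell_size
  background_set(data.frame(lon = lon, lat = lat), "random", seed = seed)
}

#' Build a target-group background
#'
#' Pools target-group occurrence records (related taxa collected by similar
#' methods, hence sharing sampling bias) with the modelled species'
#' records, restricts the union to the study mask, and reduces it to one
#' point per grid cell (cell centers). Used with un-thinned presences.
#'
#' @param target_records An [occurrence_set] of target-group records (may be
#'   empty).
#' @param species_records A list of [occurrence_set]s for the modelled
#'   species, all merged into the background.
#' @param mask Study mask grid.
#' @return A [background_set] with `method = "targeted"`, one point per
#'   occupied pixel.
#' @export
build_target_background <- function(target_records, species_records, mask) {
  stopifnot(is_env_grid(mask))
  if (inherits(species_records, "occurrence_set"))
    species_records <- list(species_records)
  all_df <- do.call(rbind, c(
    list(target_records$records[, c("lon", "lat")]),
    lapply(species_records, function(o) o$records[, c("lon", "lat")])))
  mm <- mask_matrix(mask)
  idx <- cell_index(mask, all_df$lon, all_df$lat)
  inside <- !is.na(idx$row)
  flat <- (idx$col - 1L) * nrow(mm) + idx$row
  keep <- inside & mm[ifelse(inside, flat, 1L)]
  keep[!inside] <- FALSE
  flat <- unique(flat[keep])
  if (!length(flat)) stop("no target-group background points fall in the study area")
  nr <- nrow(mm)
  row <- (flat - 1L) %% nr + 1L
  col <- (flat - 1L) %/% nr + 1L
  background_set(
    data.frame(lon = mask$extent[1] + (col - 0.5) * mask$cell_size,
               lat = mask$extent[4] - (row - 0.5) * mask$cell_size),
    "targeted")
}

#' Write a background set to CSV
#' @param bg A [background_set].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_background <- function(bg, path) {
  df <- bg$points
  df$method <- bg$method
  df$seed <- bg$seed
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
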
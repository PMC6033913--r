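#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param a,b Points as `c(lon, lat)` vectors or two-column (lon, lat)
#'   matrices; the usual recycling between one point and many applies.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(a, b) {
  geosphere::distHaversine(a, b, r = 6371.0)
}

# full pairwise distance matrix (km) for lon/lat data frame
pairwise_dist_km <- function(df) {
  m <- as.matrix(df[, c("lon", "lat")])
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    d[i, ] <- haversine_km(m[i, , drop = FALSE], m)
  d
}

#' Spatial thinning of occurrence records
#'
#' Seeks the largest subset of records in which every pair is at least
#' `min_dist_km` apart (great-circle). The heuristic mirrors the spThin
#' family: within each repetition, repeatedly delete one record chosen
#' uniformly at random among those with the greatest number of neighbours
#' closer than `min_dist_km`, until no violating pair remains; across
#' repetitions the largest surviving set wins (first found on ties). The
#' returned set always satisfies the pairwise constraint; optimality of its
#' size is heuristic.
#'
#' @param occ An [occurrence_set].
#' @param min_dist_km Minimum pairwise distance in km.
#' @param reps Number of randomized repetitions.
#' @param seed Integer seed; same seed gives the identical retained set.
#' @return A thinned [occurrence_set]; the cleaning log gains a
#'   `"thinned"` count.
#' @export
thin_occurrences <- function(occ, min_dist_km = 50, reps = 100, seed = 1) {
  stopifnot(inherits(occ, "occurrence_set"), min_dist_km > 0, reps >= 1)
  n <- n_records(occ)
  if (n == 0L) return(occ)
  d <- pairwise_dist_km(occ$records)
  conflict <- d < min_dist_km
  diag(conflict) <- FALSE
  if (!any(conflict)) {
    out <- occ
    out$cleaning_log["thinned"] <- 0L
    return(out)
  }
  best <- integer(0)
  withr::with_seed(seed, {
    for (rep in seq_len(reps)) {
      alive <- rep.int(TRUE, n)
      deg <- rowSums(conflict)
      while (any(deg[alive] > 0L)) {
        worst <- which(alive & deg == max(deg[alive]))
        drop <- if (length(worst) == 1L) worst else sample(worst, 1L)
        alive[drop] <- FALSE
        nb <- which(conflict[drop, ] & alive)
        deg[nb] <- deg[nb] - 1L
        deg[drop] <- 0L
      }
      if (sum(alive) > length(best)) best <- which(alive)
    }
  })
  removed <- n - length(best)
  out <- occurrence_set(occ$records[best, , drop = FALSE],
                        species = occ$species,
                        cleaning_log = occ$cleaning_log)
  out$cleaning_log["thinned"] <- removed
  out
}

#' Exact maximum thinned-subset size (test oracle)
#'
#' Exhaustive search over all subsets for the maximum number of records
#' with pairwise distance at least `min_dist_km`. Exponential in n; refuses
#' more than 15 records.
#'
#' @param occ An [occurrence_set] (or data frame with `lon`, `lat`).
#' @param min_dist_km Minimum pairwise distance in km.
#' @return Integer: the maximum attainable subset size.
#' @export
exhaustive_thin_oracle <- function(occ, min_dist_km = 50) {
  df <- if (inherits(occ, "occurrence_set")) occ$records else as.data.frame(occ)
  n <- nrow(df)
  if (n > 15L) stop("exhaustive oracle limited to 15 records (got ", n, ")")
  if (n == 0L) return(0L)
  ok <- pairwise_dist_km(df) >= min_dist_km
  diag(ok) <- TRUE
  best <- 1L
  for (code in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(code, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(members) <= best) next
    if (all(ok[members, members])) best <- length(members)
  }
  best
}
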
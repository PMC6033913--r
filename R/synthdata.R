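#' Virtual landscape specification
#'
#' Describes a stack of synthetic environmental surfaces on a lon/lat grid.
#' Each layer is a planar gradient in normalized coordinates plus spatially
#' autocorrelated noise (white noise smoothed by a moving-average box filter
#' and rescaled to the stated marginal standard deviation), optionally with
#' a Gaussian ridge (used for an elevation layer with a mountain chain).
#' Normalized coordinates `u` (west → east) and `v` (south → north) run 0–1
#' across the extent, so two regions generated from the same layer specs on
#' different extents are statistically exchangeable.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @param cell_size Cell edge in decimal degrees.
#' @param layers Named list; each element a list with fields `g0`
#'   (intercept), `gu`, `gv` (gradient per unit u / v), `noise_sd`
#'   (marginal sd of the smoothed noise), `smooth` (box half-width in
#'   cells), optional `ridge = list(center_u, width_u, height)`, optional
#'   `units`.
#' @param seed Integer seed; `(spec, seed)` reproduces the stack exactly.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(extent, cell_size, layers, seed = 1) {
  stopifnot(length(extent) == 4L, extent[1] < extent[2], extent[3] < extent[4],
            cell_size > 0, length(layers) >= 1L, !is.null(names(layers)))
  structure(list(extent = as.numeric(extent), cell_size = cell_size,
                 layers = layers, seed = as.integer(seed)),
            class = "landscape_spec")
}

# moving-average box smoother, edge-truncated, via cumulative sums
box_smooth <- function(m, radius) {
  if (radius <= 0) return(m)
  smooth_1d <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - radius, 1L)
    hi <- pmin(seq_len(n) + radius, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  m <- apply(m, 2L, smooth_1d)
  t(apply(m, 1L, smooth_1d))
}

#' Generate a virtual landscape
#'
#' @param spec A [landscape_spec()].
#' @return A [grid_stack][align_stack] with one layer per spec entry;
#'   deterministic given `(spec, seed)`.
#' @export
make_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  ext <- spec$extent; cs <- spec$cell_size
  nr <- round((ext[4] - ext[3]) / cs)
  nc <- round((ext[2] - ext[1]) / cs)
  if (nr < 1 || nc < 1) stop("non-positive extent")
  lon <- ext[1] + (seq_len(nc) - 0.5) * cs
  lat <- ext[4] - (seq_len(nr) - 0.5) * cs
  u <- matrix((lon - ext[1]) / (ext[2] - ext[1]), nr, nc, byrow = TRUE)
  v <- matrix((lat - ext[3]) / (ext[4] - ext[3]), nr, nc)
  grids <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    vals <- (ly$g0 %||% 0) + (ly$gu %||% 0) * u + (ly$gv %||% 0) * v
    if (!is.null(ly$ridge))
      vals <- vals + ly$ridge$height *
        exp(-(u - ly$ridge$center_u)^2 / (2 * ly$ridge$width_u^2))
    sd_target <- ly$noise_sd %||% 0
    if (sd_target > 0) {
      eps <- withr::with_seed(child_seed(spec$seed, i), {
        box_smooth(matrix(stats::rnorm(nr * nc), nr, nc), ly$smooth %||% 0L)
      })
      vals <- vals + eps * (sd_target / stats::sd(as.vector(eps)))
    }
    grids[[i]] <- env_grid(vals, ext, cs, name = names(spec$layers)[i],
                           units = ly$units %||% "")
  }
  align_stack(grids)
}

#' Virtual species with known response curves
#'
#' Suitability is the product over layers of univariate responses:
#' * `resp_plateau(lower_rise, plateau_lo, plateau_hi, upper_fall)` — a
#'   trapezoid: 0 below `lower_rise`, linear rise to 1 at `plateau_lo`,
#'   flat top to `plateau_hi`, linear fall to 0 at `upper_fall`;
#' * `resp_logistic(midpoint, slope)` — `1 / (1 + exp(-slope (x - mid)))`;
#' * `resp_flat()` — constant 1 (the layer is ecologically inert).
#'
#' @param responses Named list (layer name → response descriptor).
#' @param prevalence_target Nominal fraction of the landscape intended to be
#'   occupied; recorded for documentation (sampling intensity, not the
#'   response product, controls realized prevalence).
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(responses, prevalence_target = NA_real_) {
  stopifnot(is.list(responses), !is.null(names(responses)))
  structure(list(responses = responses, prevalence_target = prevalence_target),
            class = "virtual_species")
}

#' @rdname virtual_species
#' @param lower_rise,plateau_lo,plateau_hi,upper_fall Trapezoid breakpoints
#'   (must be non-decreasing).
#' @export
resp_plateau <- function(lower_rise, plateau_lo, plateau_hi, upper_fall) {
  stopifnot(lower_rise <= plateau_lo, plateau_lo <= plateau_hi,
            plateau_hi <= upper_fall)
  list(type = "plateau", lower_rise = lower_rise, plateau_lo = plateau_lo,
       plateau_hi = plateau_hi, upper_fall = upper_fall)
}

#' @rdname virtual_species
#' @param midpoint,slope Logistic location and rate (slope may be negative
#'   for a declining response).
#' @export
resp_logistic <- function(midpoint, slope) {
  list(type = "logistic", midpoint = midpoint, slope = slope)
}

#' @rdname virtual_species
#' @export
resp_flat <- function() list(type = "flat")

response_value <- function(desc, x) {
  switch(desc$type,
    flat = rep(1, length(x)),
    logistic = 1 / (1 + exp(-desc$slope * (x - desc$midpoint))),
    plateau = {
      out <- numeric(length(x))
      rise <- x > desc$lower_rise & x < desc$plateau_lo
      if (desc$plateau_lo > desc$lower_rise)
        out[rise] <- (x[rise] - desc$lower_rise) /
          (desc$plateau_lo - desc$lower_rise)
      out[x >= desc$plateau_lo & x <= desc$plateau_hi] <- 1
      fall <- x > desc$plateau_hi & x < desc$upper_fall
      if (desc$upper_fall > desc$plateau_hi)
        out[fall] <- (desc$upper_fall - x[fall]) /
          (desc$upper_fall - desc$plateau_hi)
      out
    },
    stop("unknown response type: ", desc$type))
}

#' True suitability surface of a virtual species
#'
#' @param vs A [virtual_species()].
#' @param stack A [grid_stack][align_stack] containing every layer the
#'   species responds to.
#' @return An [env_grid] of true suitability in \[0, 1\].
#' @export
true_suitability <- function(vs, stack) {
  stopifnot(inherits(vs, "virtual_species"), is_grid_stack(stack))
  miss <- setdiff(names(vs$responses), stack_names(stack))
  if (length(miss))
    stop("stack is missing layer(s): ", paste(miss, collapse = ", "))
  ref <- stack$layers[[1]]
  suit <- matrix(1, nrow(ref$values), ncol(ref$values))
  for (v in names(vs$responses))
    suit <- suit * matrix(
      response_value(vs$responses[[v]], as.vector(stack$layers[[v]]$values)),
      nrow(ref$values), ncol(ref$values))
  suit[!stack$mask] <- NA_real_
  env_grid(suit, ref$extent, ref$cell_size, name = "true_suitability",
           units = "suitability")
}

#' Sample presence records from a virtual species
#'
#' Draws presence cells without replacement with probability proportional to
#' true suitability times an optional sampling-bias surface (emulating the
#' uneven collection effort of aggregated occurrence databases); records are
#' placed at cell centers.
#'
#' @param vs A [virtual_species()] (or an [env_grid] already holding the
#'   suitability/weight surface).
#' @param stack Landscape [grid_stack][align_stack].
#' @param n_presence Number of records.
#' @param bias Optional aligned [env_grid] of relative sampling effort.
#' @param seed Integer seed.
#' @param species Species label for the records.
#' @return An [occurrence_set] with `source = "simulated"`.
#' @export
sample_occurrences <- function(vs, stack, n_presence, bias = NULL, seed = 1,
                               species = "virtual_species") {
  suit <- if (is_env_grid(vs)) vs else true_suitability(vs, stack)
  w <- as.vector(suit$values)
  if (!is.null(bias)) {
    stopifnot(is_env_grid(bias))
    if (!identical(dim(bias$values), dim(suit$values)))
      stop("bias grid is not aligned with the landscape")
    w <- w * as.vector(bias$values)
  }
  w[is.na(w)] <- 0
  if (sum(w > 0) < n_presence)
    stop(sprintf("only %d cells have positive sampling weight (need %d)",
                 sum(w > 0), n_presence))
  cells <- withr::with_seed(seed, sample(length(w), n_presence, prob = w))
  nr <- nrow(suit$values)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  occurrence_set(data.frame(
    species = species,
    lon = suit$extent[1] + (col - 0.5) * suit$cell_size,
    lat = suit$extent[4] - (row - 0.5) * suit$cell_size,
    error_km = 0, source = "simulated"))
}

#' Bias surface concentrated toward one corner
#'
#' Relative sampling effort ramping multiplicatively from 1 in the far
#' corner to `ratio` in the chosen corner, emulating roadside/urban
#' collection bias.
#'
#' @param grid Template [env_grid].
#' @param ratio Effort ratio between the favoured corner and its opposite.
#' @param corner One of `"ne"`, `"nw"`, `"se"`, `"sw"`.
#' @return An [env_grid] named `"bias"`.
#' @export
make_bias_grid <- function(grid, ratio = 10, corner = c("ne", "nw", "se", "sw")) {
  corner <- match.arg(corner)
  stopifnot(is_env_grid(grid), ratio >= 1)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  u <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
  v <- matrix(seq(1, 0, length.out = nr), nr, nc)  # row 1 = north
  if (corner %in% c("nw", "sw")) u <- 1 - u
  if (corner %in% c("se", "sw")) v <- 1 - v
  env_grid(1 + (ratio - 1) * u * v, grid$extent, grid$cell_size, name = "bias")
}

#' Generate a projection region, optionally with injected novel conditions
#'
#' Builds a second landscape from the same layer generators on a
#' longitudinally shifted extent with an independent noise realization —
#' statistically exchangeable with the training region — and optionally
#' shifts a rectangular block of one layer by a fixed offset to create
#' environments outside the training range.
#'
#' @param spec The training-region [landscape_spec()].
#' @param lon_shift Degrees to shift the extent eastward (default: one
#'   extent width, making the region disjoint).
#' @param novel_block Optional
#'   `list(layer =, offset =, rows = c(r1, r2), cols = c(c1, c2))`.
#' @param seed_offset Added to the spec seed for the new noise realization.
#' @return A [grid_stack][align_stack].
#' @export
make_projection_region <- function(spec, lon_shift = NULL, novel_block = NULL,
                                   seed_offset = 5000L) {
  stopifnot(inherits(spec, "landscape_spec"))
  width <- spec$extent[2] - spec$extent[1]
  if (is.null(lon_shift)) lon_shift <- width
  spec2 <- spec
  spec2$extent <- spec$extent + c(lon_shift, lon_shift, 0, 0)
  spec2$seed <- child_seed(spec$seed, seed_offset)
  stack <- make_landscape(spec2)
  if (!is.null(novel_block)) {
    g <- stack$layers[[novel_block$layer]]
    if (is.null(g)) stop("unknown layer: ", novel_block$layer)
    r <- novel_block$rows; cl <- novel_block$cols
    if (r[1] < 1 || r[2] > nrow(g$values) || cl[1] < 1 || cl[2] > ncol(g$values))
      stop("novel block rectangle lies outside the region extent")
    if (r[1] <= r[2] && cl[1] <= cl[2]) {
      g$values[r[1]:r[2], cl[1]:cl[2]] <-
        g$values[r[1]:r[2], cl[1]:cl[2]] + novel_block$offset
      stack$layers[[novel_block$layer]] <- g
    }
  }
  stack
}

#' Default synthetic study system
#'
#' A 100 x 100 cell landscape (0.1 degree cells) with three signal layers
#' and one inert layer, a virtual species combining a temperature plateau
#' (rise above 5 degC, maximal 5–15 degC), a precipitation rise around
#' 1000 mm, and a weak evapotranspiration response, an elevation surface
#' with a western mountain ridge for study-area masking, corner-biased
#' sampling effort, and a disjoint projection region with an injected
#' out-of-range temperature block.
#'
#' @param seed Integer seed controlling every stochastic element.
#' @param n_presence Presence records sampled for the focal species.
#' @param n_target Target-group records (related taxa, same sampling bias).
#' @param bias_ratio Corner sampling-effort ratio.
#' @return List: `spec`, `stack` (covariates), `elevation`, `mask`,
#'   `vs`, `truth`, `bias`, `occ`, `target`, `projection` (stack),
#'   `novel_block`.
#' @export
default_fixture <- function(seed = 1, n_presence = 300, n_target = 400,
                            bias_ratio = 5) {
  spec <- landscape_spec(
    extent = c(-65, -55, -35, -25), cell_size = 0.1,
    layers = list(
      bio11 = list(g0 = 0, gv = 20, noise_sd = 2, smooth = 8, units = "degC"),
      bio12 = list(g0 = 400, gu = 1600, noise_sd = 150, smooth = 8, units = "mm"),
      pet   = list(g0 = 600, gu = 300, gv = 400, noise_sd = 150, smooth = 8,
                   units = "mm"),
      bio5  = list(g0 = 26, noise_sd = 2.5, smooth = 8, units = "degC")),
    seed = seed)
  stack <- make_landscape(spec)
  elev_spec <- landscape_spec(
    extent = spec$extent, cell_size = spec$cell_size,
    layers = list(elev = list(
      g0 = 200, noise_sd = 120, smooth = 4,
      ridge = list(center_u = 0.12, width_u = 0.05, height = 3200),
      units = "m")),
    seed = child_seed(seed, 77))
  elevation <- make_landscape(elev_spec)$layers$elev
  mask <- build_study_mask(elevation, max_elev_m = 2500, lat_floor = -34.5)
  vs <- virtual_species(list(
    bio11 = resp_plateau(-2, 6, 9, 13),
    bio12 = resp_logistic(1350, 0.008),
    pet   = resp_logistic(1000, 0.005),
    bio5  = resp_flat()))
  truth <- true_suitability(vs, stack)
  # suppress truth (and sampling) outside the study area
  masked_truth <- truth
  masked_truth$values[!mask_matrix(mask)] <- NA_real_
  bias <- make_bias_grid(stack$layers[[1]], ratio = bias_ratio, corner = "ne")
  occ <- sample_occurrences(masked_truth, stack, n_presence, bias = bias,
                            seed = child_seed(seed, 11),
                            species = "virtual_species")
  flat_weight <- masked_truth
  flat_weight$values[!is.na(flat_weight$values)] <- 1
  target <- sample_occurrences(flat_weight, stack, n_target, bias = bias,
                               seed = child_seed(seed, 12),
                               species = "target_group")
  novel_block <- list(layer = "bio11", offset = 40,
                      rows = c(6, 25), cols = c(6, 25))
  projection <- make_projection_region(spec, novel_block = novel_block)
  list(spec = spec, stack = stack, elevation = elevation, mask = mask,
       vs = vs, truth = truth, bias = bias, occ = occ, target = target,
       projection = projection, novel_block = novel_block)
}
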
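#' Project a fitted model onto a grid stack
#'
#' Predicts suitability for every cell of a (possibly disjoint) region's
#' stack. Nodata cells propagate to nodata.
#'
#' @param model An [sdm_fit][fit_sdm].
#' @param stack A [grid_stack][align_stack] whose layer names include all
#'   training covariates.
#' @param name Output layer name.
#' @return An [env_grid] of suitability in \[0, 1\].
#' @export
predict_map <- function(model, stack, name = model$algorithm) {
  stopifnot(inherits(model, "sdm_fit"), is_grid_stack(stack))
  miss <- setdiff(model$covariates, stack_names(stack))
  if (length(miss))
    stop("stack is missing layer(s): ", paste(miss, collapse = ", "))
  ref <- stack$layers[[1]]
  newdata <- as.data.frame(lapply(stack$layers[model$covariates],
                                  function(g) as.vector(g$values)))
  names(newdata) <- model$covariates
  newdata[!as.vector(stack$mask), ] <- NA_real_
  pred <- predict(model, newdata)
  env_grid(matrix(pred, nrow(ref$values), ncol(ref$values)),
           ref$extent, ref$cell_size, name = name, units = "suitability")
}

#' Ensemble mean of suitability maps
#'
#' Per-cell arithmetic mean over the input maps; a cell that is nodata in
#' any input is nodata in the ensemble.
#'
#' @param maps List of aligned suitability [env_grid]s (typically the five
#'   learners' maps).
#' @param name Output layer name.
#' @return An [env_grid] named `name`.
#' @export
ensemble_mean <- function(maps, name = "ensemble") {
  if (is_env_grid(maps)) maps <- list(maps)
  stopifnot(length(maps) >= 1L, all(vapply(maps, is_env_grid, logical(1))))
  ref <- maps[[1]]
  for (m in maps[-1])
    if (any(abs(m$extent - ref$extent) > 1e-9) ||
        abs(m$cell_size - ref$cell_size) > 1e-9 ||
        !identical(dim(m$values), dim(ref$values)))
      stop(sprintf("maps '%s' and '%s' are not aligned", ref$name, m$name))
  acc <- Reduce(`+`, lapply(maps, function(m) m$values))
  env_grid(acc / length(maps), ref$extent, ref$cell_size,
           name = name, units = "suitability")
}

# sentinel for similarity against a zero-width (constant) reference when the
# point does not equal the constant: "infinitely novel"
MESS_SENTINEL <- -9999

#' Multivariate environmental similarity of one point
#'
#' For each variable, the similarity follows the piecewise percentile rule:
#' with `f` the percentage of reference values strictly below the point
#' value, `min`/`max` the reference range,
#' * `f = 0`:  `S = 100 * (p - min) / (max - min)` (negative below the range)
#' * `0 < f <= 50`:  `S = 2 f`
#' * `50 < f < 100`:  `S = 2 (100 - f)`
#' * `f = 100`:  `S = 100 * (max - p) / (max - min)` (negative above the range)
#'
#' The overall similarity is the minimum over variables; it is negative
#' exactly when at least one variable lies outside the reference range. A
#' constant reference variable yields 100 when the point equals the constant
#' and the sentinel value -9999 otherwise.
#'
#' @param reference Data frame (or named list of numeric vectors) of
#'   training-point values, one element per variable.
#' @param point Named numeric vector of the same variables.
#' @return List with `per_variable` (named numeric) and `min` (overall S).
#' @export
mess_similarity <- function(reference, point) {
  reference <- as.list(as.data.frame(reference))
  vars <- names(reference)
  if (!all(vars %in% names(point)))
    stop("point is missing variable(s): ",
         paste(setdiff(vars, names(point)), collapse = ", "))
  s <- vapply(vars, function(v) {
    ref <- reference[[v]]; p <- as.numeric(point[[v]])
    mess_one(sort(ref), p)
  }, numeric(1))
  list(per_variable = s, min = min(s))
}

# similarity of scalar p against a sorted reference vector
mess_one <- function(sorted_ref, p) {
  n <- length(sorted_ref)
  lo <- sorted_ref[1]; hi <- sorted_ref[n]
  if (hi == lo) return(if (p == lo) 100 else MESS_SENTINEL)
  f <- 100 * findInterval(p, sorted_ref, left.open = TRUE) / n  # strict <
  if (f == 0) 100 * (p - lo) / (hi - lo)
  else if (f <= 50) 2 * f
  else if (f < 100) 2 * (100 - f)
  else 100 * (hi - p) / (hi - lo)
}

#' MESS map over a grid stack
#'
#' Applies [mess_similarity()] cell-wise: for every valid cell of the
#' projection stack, the minimum over layers of the percentile similarity to
#' the reference (training) values. Cells with negative similarity are
#' environmentally novel — at least one layer falls outside the training
#' range there.
#'
#' @param reference Data frame of training-point values whose columns match
#'   the stack's layer names.
#' @param stack Projection-region [grid_stack][align_stack].
#' @return List of class `mess_map`: `similarity` ([env_grid], `S <= 100`),
#'   `novelty` ([env_grid] with 1 where `S < 0`, else 0), and `per_variable`
#'   (named list of per-layer similarity grids).
#' @export
mess_map <- function(reference, stack) {
  stopifnot(is_grid_stack(stack))
  reference <- as.data.frame(reference)
  vars <- stack_names(stack)
  miss <- setdiff(vars, names(reference))
  if (length(miss))
    stop("reference table is missing column(s): ", paste(miss, collapse = ", "))
  ref <- stack$layers[[1]]
  valid <- as.vector(stack$mask)
  per_var <- list()
  smin <- rep(Inf, length(valid))
  for (v in vars) {
    rv <- sort(reference[[v]])
    n <- length(rv)
    lo <- rv[1]; hi <- rv[n]
    p <- as.vector(stack$layers[[v]]$values)
    s <- rep(NA_real_, length(p))
    if (hi == lo) {
      s[valid] <- ifelse(p[valid] == lo, 100, MESS_SENTINEL)
    } else {
      pv <- p[valid]
      f <- 100 * findInterval(pv, rv, left.open = TRUE) / n
      sv <- numeric(length(pv))
      b1 <- f == 0
      b2 <- f > 0 & f <= 50
      b3 <- f > 50 & f < 100
      b4 <- f == 100
      sv[b1] <- 100 * (pv[b1] - lo) / (hi - lo)
      sv[b2] <- 2 * f[b2]
      sv[b3] <- 2 * (100 - f[b3])
      sv[b4] <- 100 * (hi - pv[b4]) / (hi - lo)
      s[valid] <- sv
    }
    per_var[[v]] <- env_grid(matrix(s, nrow(ref$values), ncol(ref$values)),
                             ref$extent, ref$cell_size,
                             name = paste0("mess_", v))
    smin <- pmin(smin, ifelse(is.na(s), Inf, s))
  }
  smin[!valid] <- NA_real_
  sim <- env_grid(matrix(smin, nrow(ref$values), ncol(ref$values)),
                  ref$extent, ref$cell_size, name = "mess")
  nov <- env_grid(matrix(ifelse(is.na(smin), NA_real_, as.numeric(smin < 0)),
                         nrow(ref$values), ncol(ref$values)),
                  ref$extent, ref$cell_size, name = "novelty")
  structure(list(similarity = sim, novelty = nov, per_variable = per_var),
            class = "mess_map")
}

#' @export
print.mess_map <- function(x, ...) {
  v <- x$similarity$values
  nov <- x$novelty$values
  cat(sprintf("<mess_map> %d valid cells, %d novel (S < 0)\n",
              sum(!is.na(v)), sum(nov > 0, na.rm = TRUE)))
  invisible(x)
}
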
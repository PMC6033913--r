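#' Assemble a presence-background training table
#'
#' Extracts the stack's layer values at presence and background points,
#' drops rows falling on nodata cells or outside the extent (counted in
#' attributes), and returns the modelling table.
#'
#' @param stack A [grid_stack][align_stack] of the retained predictors.
#' @param presences An [occurrence_set].
#' @param background A [background_set].
#' @return Data frame with columns `lon`, `lat`, `pb` (1 = presence,
#'   0 = background) and one column per layer; attribute `"n_dropped"`
#'   counts rows lost to nodata.
#' @export
make_training_table <- function(stack, presences, background) {
  stopifnot(is_grid_stack(stack))
  pres <- extract_values(stack, presences$records[, c("lon", "lat")])
  bg <- extract_values(stack, background$points)
  pres$pb <- 1L
  bg$pb <- 0L
  tab <- rbind(pres, bg)
  dropped <- sum(!tab$valid)
  tab <- tab[tab$valid, setdiff(names(tab), "valid"), drop = FALSE]
  if (!sum(tab$pb == 1L)) stop("no valid presence rows")
  if (!sum(tab$pb == 0L)) stop("no valid background rows")
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- dropped
  attr(tab, "layers") <- stack_names(stack)
  tab
}

covariate_names <- function(table) {
  lyr <- attr(table, "layers")
  if (!is.null(lyr)) lyr else setdiff(names(table), c("lon", "lat", "pb", "fold"))
}

#' Class-stratified cross-validation folds
#'
#' Assigns each row of the table to one of `k` folds so that presences and
#' backgrounds are each split into near-equal parts (sizes within a class
#' differ by at most 1), guaranteeing both classes in every fold.
#'
#' @param table Training table from [make_training_table()].
#' @param k Number of folds.
#' @param seed Integer seed; identical seed gives identical assignment.
#' @return Integer vector of fold ids in `1:k`, one per row.
#' @export
make_folds <- function(table, k = 10, seed = 1) {
  pb <- table$pb
  if (sum(pb == 1L) < k || sum(pb == 0L) < k)
    stop(sprintf("need at least k = %d rows of each class (have %d presences, %d backgrounds)",
                 k, sum(pb == 1L), sum(pb == 0L)))
  fold <- integer(length(pb))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      ix <- which(pb == cls)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  fold
}

sdm_algorithms <- c("glm_stepwise", "mars", "brt", "rf", "maxent_like")

algo_fitters <- list(
  glm_stepwise = list(fit = fit_glm_stepwise, predict = predict_glm_stepwise),
  mars = list(fit = fit_mars, predict = predict_mars),
  brt = list(fit = fit_brt, predict = predict_brt),
  rf = list(fit = fit_rf, predict = predict_rf),
  maxent_like = list(fit = fit_maxent_like, predict = predict_maxent_like))

#' Fit a presence-background suitability model
#'
#' Fits one of five learners to a presence-background table and returns a
#' fitted-model object with a [predict][predict.sdm_fit] method producing
#' relative habitat suitability in \[0, 1\]:
#'
#' * `glm_stepwise` — logistic regression over main effects, squares and
#'   pairwise products, bidirectional stepwise by AIC with a marginality
#'   (hierarchy) rule; variables absent from all surviving terms are
#'   recorded as dropped.
#' * `mars` — additive (degree-1) piecewise-linear regression splines,
#'   forward hinge growth and backward prune by generalized cross-validation
#'   with penalty 2.0, refit as a binomial GLM.
#' * `brt` — stochastic gradient-boosted trees, bag fraction 0.5, learning
#'   rate 0.01, depth 3; tree count by held-out deviance.
#' * `rf` — probability random forest with `mtry` tuned to minimize
#'   out-of-bag error.
#' * `maxent_like` — L1-penalized logistic regression on Maxent-style
#'   features (linear, quadratic, product, hinge).
#'
#' @param table Training table ([make_training_table()]).
#' @param algorithm One of `"glm_stepwise"`, `"mars"`, `"brt"`, `"rf"`,
#'   `"maxent_like"`.
#' @param hyperparams Named list of algorithm-specific settings; unset
#'   entries use the defaults above.
#' @param seed Integer seed governing all stochastic components of the fit.
#' @return An object of class `sdm_fit`.
#' @export
fit_sdm <- function(table, algorithm = sdm_algorithms, hyperparams = list(),
                    seed = 1) {
  algorithm <- match.arg(algorithm)
  vars <- covariate_names(table)
  x <- as.data.frame(table)[, vars, drop = FALSE]
  y <- table$pb
  if (anyNA(x)) stop("training table contains missing covariate values")
  if (length(unique(y)) < 2L) stop("degenerate table: only one class present")
  const <- vapply(x, function(v) max(v) == min(v), logical(1))
  if (any(const))
    stop("degenerate table: constant covariate(s): ",
         paste(vars[const], collapse = ", "))
  fitter <- algo_fitters[[algorithm]]
  state <- fitter$fit(x, y, hyperparams, seed)
  structure(
    list(algorithm = algorithm, state = state, covariates = vars,
         retained = state$retained, dropped = state$dropped,
         hyperparams = hyperparams, seed = seed,
         n_presence = sum(y == 1L), n_background = sum(y == 0L)),
    class = "sdm_fit")
}

#' Predict relative habitat suitability
#'
#' @param object An [sdm_fit][fit_sdm].
#' @param newdata Data frame containing all training covariate columns.
#'   Rows with any missing covariate yield `NA` (nodata in, nodata out).
#' @param ... Unused.
#' @return Numeric vector of suitabilities in \[0, 1\] (`NA` for nodata rows).
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  x <- newdata[, object$covariates, drop = FALSE]
  ok <- stats::complete.cases(x)
  out <- rep(NA_real_, nrow(x))
  if (any(ok)) {
    p <- algo_fitters[[object$algorithm]]$predict(object$state, x[ok, , drop = FALSE])
    out[ok] <- pmin(1, pmax(0, p))
  }
  out
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s on %d presences vs %d background points\n",
              x$algorithm, x$n_presence, x$n_background))
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sdm_fit <- function(object, ...) {
  cat(sprintf("Suitability model: %s\n", object$algorithm))
  cat(sprintf("Training data: %d presences, %d background points\n",
              object$n_presence, object$n_background))
  cat("Covariates retained:",
      paste(if (length(object$retained)) object$retained else "(none)",
            collapse = ", "), "\n")
  if (length(object$dropped))
    cat("Covariates dropped:", paste(object$dropped, collapse = ", "), "\n")
  if (object$algorithm == "glm_stepwise")
    cat("Model terms:", paste(object$state$terms, collapse = " + "), "\n")
  if (object$algorithm == "mars")
    cat(sprintf("Hinge basis functions: %d (GCV %.4g)\n",
                length(object$state$basis), object$state$gcv))
  if (object$algorithm == "brt")
    cat(sprintf("Boosted trees: %d\n", object$state$n_trees))
  if (object$algorithm == "rf")
    cat(sprintf("Forest mtry: %d\n", object$state$mtry))
  invisible(object)
}

# deterministic derived seed, kept within 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1009 * as.double(offset)) %% 2147483647)
}

#' Cross-validate a suitability model
#'
#' Class-stratified k-fold cross-validation: each row receives exactly one
#' out-of-fold prediction; the per-fold fitted models are retained for
#' permutation importance.
#'
#' @inheritParams fit_sdm
#' @param k Number of folds.
#' @return An object of class `sdm_cv`: `oof` (out-of-fold predictions),
#'   `fold` (assignments), `models` (per-fold `sdm_fit`s), `auc_folds`
#'   (per-fold validation AUC), and the training `table`.
#' @export
crossvalidate <- function(table, algorithm = sdm_algorithms, k = 10,
                          hyperparams = list(), seed = 1) {
  algorithm <- match.arg(algorithm)
  fold <- make_folds(table, k = k, seed = child_seed(seed, 999))
  oof <- rep(NA_real_, nrow(table))
  models <- vector("list", k)
  auc_folds <- numeric(k)
  vars <- covariate_names(table)
  for (f in seq_len(k)) {
    train <- table[fold != f, , drop = FALSE]
    attr(train, "layers") <- vars
    val <- table[fold == f, , drop = FALSE]
    fitted <- tryCatch(
      fit_sdm(train, algorithm, hyperparams, seed = child_seed(seed, f)),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e), call. = FALSE))
    p <- predict(fitted, val)
    oof[fold == f] <- p
    models[[f]] <- fitted
    auc_folds[f] <- roc_auc(p[val$pb == 1L], p[val$pb == 0L])
  }
  structure(
    list(algorithm = algorithm, oof = oof, fold = fold, models = models,
         auc_folds = auc_folds, table = table, k = k, seed = seed,
         hyperparams = hyperparams),
    class = "sdm_cv")
}

#' @export
print.sdm_cv <- function(x, ...) {
  cat(sprintf("<sdm_cv> %s, %d-fold: mean validation AUC %.3f\n",
              x$algorithm, x$k, mean(x$auc_folds)))
  invisible(x)
}
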
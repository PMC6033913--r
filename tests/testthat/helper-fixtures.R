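# Shared fixtures. Heavy objects are computed lazily and cached for the whole
# test run so several test files can reuse one expensive model run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small 4x5 grid with one nodata cell, deterministic values
small_grid <- function(name = "g1", seed = 1) {
  vals <- matrix(withr::with_seed(seed, stats::rnorm(20)), 4, 5)
  vals[2, 3] <- NA
  env_grid(vals, extent = c(0, 5, 0, 4), cell_size = 1, name = name)
}

# all-true study mask matching a grid
full_mask <- function(grid) {
  env_grid(matrix(1, nrow(grid$values), ncol(grid$values)),
           grid$extent, grid$cell_size, name = "mask")
}

# occurrence set at given lon/lat
occ_at <- function(lon, lat, species = "sp", error_km = 0) {
  occurrence_set(data.frame(species = species, lon = lon, lat = lat,
                            error_km = error_km, source = "test"))
}

# two-covariate separable training table: presences at x1 > 0
separable_table <- function(n_per_class = 60, seed = 1) {
  withr::with_seed(seed, {
    x1 <- c(stats::runif(n_per_class, 0.5, 2), stats::runif(n_per_class, -2, -0.5))
    x2 <- stats::rnorm(2 * n_per_class)
    tab <- data.frame(lon = 0, lat = 0, x1 = x1, x2 = x2,
                      pb = rep(c(1L, 0L), each = n_per_class))
    attr(tab, "layers") <- c("x1", "x2")
    tab
  })
}

# table with covariates independent of class
noise_table <- function(n_per_class = 1000, seed = 1) {
  withr::with_seed(seed, {
    tab <- data.frame(lon = 0, lat = 0,
                      x1 = stats::rnorm(2 * n_per_class),
                      x2 = stats::rnorm(2 * n_per_class),
                      pb = rep(c(1L, 0L), each = n_per_class))
    attr(tab, "layers") <- c("x1", "x2")
    tab
  })
}

all_algorithms <- c("glm_stepwise", "mars", "brt", "rf", "maxent_like")

child_seed_t <- sdmensemble:::child_seed

# fast hyperparameters used by property tests where the check is about
# direction/shape, not the production defaults
fast_hp <- list(
  brt = list(max_trees = 400L),
  rf = list(ntree = 200L),
  maxent_like = list(lambda_nfolds = 4L))

# ---- cached heavy objects -------------------------------------------------

# the default synthetic study system
get_fixture <- function() memo("fixture", default_fixture(seed = 404))

# full random-scheme model run on the default fixture: table, per-algorithm
# cross-validations, full fits, projection maps, ensemble, MESS, importance
get_recovery <- function() memo("recovery", {
  fx <- get_fixture()
  bg <- sample_random_background(fx$mask, n = 1000, seed = 405)
  tab <- make_training_table(fx$stack, fx$occ, bg)
  cvs <- list(); fits <- list(); maps <- list()
  for (alg in all_algorithms) {
    cvs[[alg]] <- crossvalidate(tab, alg, k = 10, seed = 406)
    fits[[alg]] <- fit_sdm(tab, alg, seed = 407)
    maps[[alg]] <- predict_map(fits[[alg]], fx$projection)
  }
  layers <- stack_names(fx$stack)
  imp <- importance_table(cvs, n_perm = 10, seed = 408)
  mess <- mess_map(tab[, layers, drop = FALSE], fx$projection)
  report <- evaluation_report(cvs, fits, background_method = "random")
  list(fx = fx, table = tab, cvs = cvs, fits = fits, maps = maps,
       ensemble = ensemble_mean(maps), imp = imp, mess = mess,
       report = report)
})

# a compact pipeline configuration for determinism/structure checks
small_pipeline_config <- function(out_dir, seed = 11) {
  fx <- memo("small_fx", default_fixture(seed = 390, n_presence = 120,
                                         n_target = 200))
  run_config(
    stack = fx$stack, occurrences = fx$occ, elevation = fx$elevation,
    target_group = fx$target, out_dir = out_dir,
    lat_floor = -34.5, n_background = 600,
    thin_min_km = 25, thin_reps = 20, k = 5, n_perm = 5,
    hyperparams = fast_hp, seed = seed)
}

run_small_pipeline <- function(dir_key) {
  out <- file.path(tempdir(), dir_key)
  res <- run_pipeline(small_pipeline_config(out), quiet = TRUE)
  list(out = out, res = res)
}

get_pipeline_run <- function() memo("pipe1", run_small_pipeline("pipe_run_a"))
get_pipeline_rerun <- function() memo("pipe2", run_small_pipeline("pipe_run_b"))
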
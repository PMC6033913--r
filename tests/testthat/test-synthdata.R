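grad_spec <- function(layers, seed = 1, n = 50) {
  landscape_spec(extent = c(0, n / 10, 0, n / 10), cell_size = 0.1,
                 layers = layers, seed = seed)
}

test_that("zero-noise layers are exact planar gradients", {
  st <- make_landscape(grad_spec(list(
    a = list(g0 = 10, gu = 4, gv = -2, noise_sd = 0))))
  g <- st$layers$a
  # cell (1,1) is the NW corner: u small, v near 1
  u <- (0.05 - 0) / 5; v <- (5 - 0.05 - 0) / 5
  expect_equal(g$values[1, 1], 10 + 4 * u - 2 * v)
  expect_equal(g$values[50, 50], 10 + 4 * (1 - u) - 2 * (1 - v))
})

test_that("landscapes regenerate bit-identically from spec and seed", {
  spec <- grad_spec(list(a = list(g0 = 0, gu = 1, noise_sd = 1, smooth = 2),
                         b = list(g0 = 5, gv = 3, noise_sd = 0.5, smooth = 1)),
                    seed = 33)
  s1 <- make_landscape(spec)
  s2 <- make_landscape(spec)
  expect_identical(s1$layers$a$values, s2$layers$a$values)
  expect_identical(s1$layers$b$values, s2$layers$b$values)
  s3 <- make_landscape(grad_spec(spec$layers, seed = 34))
  expect_false(identical(s1$layers$a$values, s3$layers$a$values))
})

test_that("shared gradients induce the analytically expected correlation", {
  sd_n <- 1.5
  spec <- grad_spec(list(
    g = list(g0 = 0, gu = 10, noise_sd = 0),
    a = list(g0 = 0, gu = 10, noise_sd = sd_n, smooth = 2),
    b = list(g0 = 0, gu = 10, noise_sd = sd_n, smooth = 2)),
    seed = 5, n = 100)
  st <- make_landscape(spec)
  var_g <- stats::var(as.vector(st$layers$g$values))
  target <- var_g / (var_g + sd_n^2)
  got <- stats::cor(as.vector(st$layers$a$values),
                    as.vector(st$layers$b$values))
  expect_equal(got, target, tolerance = 0.1)
})

test_that("response curves take their defining shapes", {
  pl <- resp_plateau(0, 5, 15, 25)
  x <- c(-1, 0, 2.5, 5, 10, 15, 20, 25, 30)
  expect_equal(sdmensemble:::response_value(pl, x),
               c(0, 0, 0.5, 1, 1, 1, 0.5, 0, 0))
  lg <- resp_logistic(1000, 0.01)
  expect_equal(sdmensemble:::response_value(lg, 1000), 0.5)
  expect_gt(sdmensemble:::response_value(lg, 1500), 0.99)
  expect_equal(sdmensemble:::response_value(resp_flat(), c(1, 99)), c(1, 1))
  expect_error(resp_plateau(5, 4, 10, 12))
})

test_that("true suitability is the product of responses, bounded in [0,1]", {
  st <- make_landscape(grad_spec(list(
    t = list(g0 = 10, noise_sd = 0),   # constant 10, inside the plateau
    p = list(g0 = 2000, noise_sd = 0), # saturated precipitation response
    n = list(g0 = 0, noise_sd = 1))))
  vs <- virtual_species(list(t = resp_plateau(0, 5, 15, 25),
                             p = resp_logistic(1000, 0.05),
                             n = resp_flat()))
  suit <- true_suitability(vs, st)
  expect_true(all(abs(suit$values - 1) < 1e-6))
  # temperature below the rise zeroes the product
  st$layers$t$values[] <- -5
  expect_true(all(true_suitability(vs, st)$values == 0))
  flat_only <- virtual_species(list(n = resp_flat()))
  expect_true(all(true_suitability(flat_only, st)$values == 1))
  expect_error(true_suitability(virtual_species(list(zz = resp_flat())), st),
               "missing layer")
})

test_that("occurrence sampling follows the suitability weights", {
  g <- env_grid(matrix(0, 5, 5), c(0, 5, 0, 5), 1, "t")
  st <- align_stack(list(g))
  suit <- env_grid(matrix(c(rep(1, 5), rep(0, 20)), 5, 5),
                   c(0, 5, 0, 5), 1, "s")
  occ <- sample_occurrences(suit, st, 5, seed = 2)
  # exactly the 5 positive-weight cells (first matrix column = western col)
  expect_equal(n_records(occ), 5L)
  expect_true(all(occ$records$lon == 0.5))
  expect_error(sample_occurrences(suit, st, 6, seed = 2), "positive sampling weight")
  expect_identical(sample_occurrences(suit, st, 3, seed = 9)$records,
                   sample_occurrences(suit, st, 3, seed = 9)$records)
})

test_that("sampling bias concentrates records as its ratio dictates", {
  g <- env_grid(matrix(1, 40, 40), c(0, 40, 0, 40), 1, "t")
  st <- align_stack(list(g))
  uniform_suit <- env_grid(matrix(1, 40, 40), c(0, 40, 0, 40), 1, "s")
  bias <- make_bias_grid(g, ratio = 10, corner = "ne")
  occ <- sample_occurrences(uniform_suit, st, 500, bias = bias, seed = 3)
  ne <- occ$records$lon > 20 & occ$records$lat > 20
  # multinomial expectation: NE-quadrant share of the total bias mass
  ne_mass <- sum(bias$values[1:20, 21:40]) / sum(bias$values)
  expect_gt(mean(ne), 0.25 + 0.1)             # clearly above unbiased
  expect_equal(mean(ne), ne_mass, tolerance = 0.12)  # near expectation
  corner_bias <- env_grid(matrix(0, 40, 40), c(0, 40, 0, 40), 1, "b")
  corner_bias$values[1:20, 21:40] <- 1  # NE quadrant only
  corner_bias$values[21:40, 1:20] <- 0.1 / 9  # trace effort elsewhere
  occ2 <- sample_occurrences(uniform_suit, st, 400, bias = corner_bias, seed = 4)
  expect_gte(mean(occ2$records$lon > 20 & occ2$records$lat > 20), 0.7)
})

test_that("projection regions are exchangeable unless a block is injected", {
  spec <- grad_spec(list(a = list(g0 = 0, gu = 10, noise_sd = 1, smooth = 2)),
                    seed = 21)
  base <- make_landscape(spec)
  # zero shift + zero seed offset + no block: identical to the base landscape
  same <- make_projection_region(spec, lon_shift = 0, seed_offset = 0)
  expect_equal(same$layers$a$values, base$layers$a$values)
  # injected block shifted far outside the training range
  blk <- list(layer = "a", offset = 100, rows = c(2, 6), cols = c(3, 9))
  nov <- make_projection_region(spec, lon_shift = 0, novel_block = blk,
                                seed_offset = 0)
  ref <- data.frame(a = as.vector(base$layers$a$values))
  mm <- mess_map(ref, nov)
  inblock <- matrix(FALSE, 50, 50); inblock[2:6, 3:9] <- TRUE
  expect_true(all(mm$novelty$values[inblock] == 1))
  expect_true(all(mm$novelty$values[!inblock] == 0))
  expect_error(make_projection_region(spec, novel_block = list(
    layer = "a", offset = 1, rows = c(0, 2), cols = c(1, 2))), "outside")
  expect_error(make_projection_region(spec, novel_block = list(
    layer = "zz", offset = 1, rows = c(1, 2), cols = c(1, 2))), "unknown layer")
})

test_that("the default study system has its designed structure", {
  fx <- get_fixture()
  expect_identical(stack_names(fx$stack), c("bio11", "bio12", "pet", "bio5"))
  expect_equal(dim(fx$stack$layers[[1]]$values), c(100L, 100L))
  expect_equal(n_records(fx$occ), 300L)
  # the mountain ridge and latitude floor remove part of the landscape
  expect_lt(sum(fx$mask$values), 10000)
  expect_gt(sum(fx$mask$values), 7000)
  # all sampled occurrences lie inside the study mask
  idx <- sdmensemble:::cell_index(fx$mask, fx$occ$records$lon, fx$occ$records$lat)
  expect_true(all(fx$mask$values[cbind(idx$row, idx$col)] == 1))
  # screening keeps all four layers: none of the designed pairs exceed 0.70
  cc <- extract_values(fx$stack, cell_centers(fx$stack$layers[[1]]))
  cc <- cc[cc$valid, stack_names(fx$stack)]
  cm <- pairwise_max_correlation(cc[withr::with_seed(1, sample(nrow(cc), 1500)), ])
  expect_identical(screen_predictors(cm, stack_names(fx$stack)),
                   stack_names(fx$stack))
})

test_that("target-group correction outperforms random background under bias", {
  # scaled-down replicate study: 60x60 cells, 150 presences, strong corner
  # bias; compare ensemble-truth Spearman under both background schemes
  wins <- logical(20)
  for (r in seq_len(20)) {
    seed <- 7000 + r
    spec <- landscape_spec(
      extent = c(0, 6, 0, 6), cell_size = 0.1,
      layers = list(
        t = list(g0 = 0, gv = 20, noise_sd = 2, smooth = 4),
        p = list(g0 = 400, gu = 1600, noise_sd = 150, smooth = 4)),
      seed = seed)
    st <- make_landscape(spec)
    vs <- virtual_species(list(t = resp_plateau(-2, 6, 10, 18),
                               p = resp_logistic(1400, 0.02)))
    truth <- true_suitability(vs, st)
    mask <- build_study_mask(env_grid(matrix(0, 60, 60), spec$extent, 0.1, "e"))
    bias <- make_bias_grid(st$layers$t, ratio = 12, corner = "ne")
    occ <- sample_occurrences(truth, st, 150, bias = bias,
                              seed = child_seed_t(seed, 1), species = "v")
    flat <- truth; flat$values[] <- 1
    tg <- sample_occurrences(flat, st, 400, bias = bias,
                             seed = child_seed_t(seed, 2), species = "tg")
    rb <- sample_random_background(mask, 600, seed = child_seed_t(seed, 3))
    tb <- build_target_background(tg, list(occ), mask)
    rho <- sapply(list(random = rb, targeted = tb), function(bg) {
      tab <- make_training_table(st, occ, bg)
      maps <- lapply(c("glm_stepwise", "mars", "maxent_like"), function(alg)
        predict_map(fit_sdm(tab, alg, hyperparams = fast_hp[[alg]],
                            seed = child_seed_t(seed, 4)), st))
      ens <- ensemble_mean(maps)
      ok <- !is.na(ens$values) & !is.na(truth$values)
      cor(ens$values[ok], truth$values[ok], method = "spearman")
    })
    wins[r] <- rho["targeted"] > rho["random"]
  }
  expect_gte(mean(wins), 0.7)
})
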
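# brute-force AUC: count all presence/background pairs
auc_bruteforce <- function(p, b) {
  wins <- 0
  for (x in p) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(p) * length(b))
}

test_that("roc_auc matches hand-enumerable cases", {
  expect_equal(roc_auc(c(2, 3), c(0, 1)), 1)
  expect_equal(roc_auc(c(1, 2), c(1, 2)), 0.5)
  # pairs: 3>2, 3>0, 1<2, 1>0 -> (2 + 1)/4... enumerate: wins 3v2,3v0,1v0 = 3/4
  expect_equal(roc_auc(c(3, 1), c(2, 0)), 0.75)
  expect_error(roc_auc(numeric(0), 1), "nonempty")
})

test_that("roc_auc equals brute-force pair counting on random instances", {
  withr::with_seed(8, {
    for (i in 1:100) {
      p <- sample(0:10, sample(1:8, 1), replace = TRUE) / 10
      b <- sample(0:10, sample(1:8, 1), replace = TRUE) / 10
      expect_equal(roc_auc(p, b), auc_bruteforce(p, b))
    }
  })
})

test_that("threshold choice maximizes mean sensitivity/specificity, ties low", {
  expect_equal(optimal_threshold(c(0.8, 0.9), c(0.1, 0.2)), 0.8)
  expect_equal(optimal_threshold(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  # tie between 0.4 (sens 1, spec .5) and 0.9 (sens .5, spec 1): smallest wins
  expect_equal(optimal_threshold(c(0.9, 0.4), c(0.5, 0.1)), 0.4)
})

test_that("threshold scan equals exhaustive candidate evaluation", {
  withr::with_seed(12, {
    for (i in 1:50) {
      p <- round(runif(sample(2:10, 1)), 2)
      b <- round(runif(sample(2:10, 1)), 2)
      t_star <- optimal_threshold(p, b)
      cand <- sort(unique(c(p, b)))
      obj <- sapply(cand, function(t) mean(p >= t) + mean(b < t))
      expect_equal(t_star, cand[which.max(obj)])
      best <- sdmensemble::confusion_metrics(p, b, t_star)
      expect_equal((best$sensitivity + best$specificity),
                   max(obj))
    }
  })
})

test_that("confusion metrics follow their defining identities", {
  m <- confusion_metrics(c(0.9, 0.8, 0.3), c(0.1, 0.2, 0.85), 0.8)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$pcc, 100 * 4 / 6)
  expect_equal(m$tss, m$sensitivity + m$specificity - 1)
  perfect <- confusion_metrics(c(0.9, 0.8), c(0.1, 0.2), 0.5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$pcc, 100)
  expect_equal(perfect$tss, 1)
})

# score set with exact sensitivity/specificity at threshold 0.5
scores_for <- function(sens, spec, n = 100) {
  list(p = c(rep(0.9, round(sens * n)), rep(0.1, n - round(sens * n))),
       b = c(rep(0.1, round(spec * n)), rep(0.9, n - round(spec * n))))
}

test_that("TSS reproduces published sensitivity/specificity worked examples", {
  # exact-rounding rows from a published ensemble-SDM evaluation table
  cases <- list(
    c(0.83, 0.79, 0.62), c(0.85, 0.76, 0.61), c(0.85, 0.77, 0.62),
    c(0.71, 0.85, 0.56), c(0.80, 0.81, 0.61), c(0.89, 0.87, 0.76),
    c(0.92, 0.84, 0.76), c(0.74, 0.75, 0.49), c(0.74, 0.91, 0.65))
  for (cs in cases) {
    s <- scores_for(cs[1], cs[2])
    m <- confusion_metrics(s$p, s$b, 0.5)
    expect_equal(m$sensitivity, cs[1])
    expect_equal(m$specificity, cs[2])
    expect_equal(round(m$tss, 2), cs[3])
  }
})

test_that("permutation importance finds signal and flags dropped layers", {
  withr::with_seed(44, {
    n <- 120
    x1 <- c(runif(n, 0.5, 2), runif(n, -2, -0.5))
    tab <- data.frame(lon = 0, lat = 0, x1 = x1, x2 = rnorm(2 * n),
                      pb = rep(c(1L, 0L), each = n))
  })
  attr(tab, "layers") <- c("x1", "x2")
  cv <- crossvalidate(tab, "glm_stepwise", k = 5, seed = 3)
  d1 <- permutation_importance(cv, "x1", n_perm = 20, seed = 5)
  auc_cv <- mean(cv$auc_folds)
  # permuting the only informative variable destroys essentially all signal
  expect_equal(d1, auc_cv - 0.5, tolerance = 0.05)
  # the noise covariate is dropped by the stepwise search in this fit
  if (all(sapply(cv$models, function(m) "x2" %in% m$dropped))) {
    expect_true(is.na(permutation_importance(cv, "x2", n_perm = 5, seed = 5)))
  } else {
    expect_lt(abs(permutation_importance(cv, "x2", n_perm = 20, seed = 5)), 0.05)
  }
  expect_error(permutation_importance(cv, "nope", 5, 1), "unknown layer")
})

test_that("importance table ranks within algorithm and preserves na", {
  tab <- separable_table(50)
  cvs <- list(glm_stepwise = crossvalidate(tab, "glm_stepwise", k = 5, seed = 2),
              rf = crossvalidate(tab, "rf", k = 5, seed = 2))
  imp <- importance_table(cvs, n_perm = 5, seed = 6)
  expect_equal(nrow(imp), 4L)
  for (alg in names(cvs)) {
    sub <- imp[imp$algorithm == alg, ]
    ranked <- sub$rank[!is.na(sub$rank)]
    expect_setequal(ranked, seq_along(ranked))
    expect_equal(sub$layer[which(sub$rank == 1)], "x1")
  }
})

test_that("evaluation report rows satisfy the metric identities", {
  tab <- separable_table(30)
  cvs <- list(); fits <- list()
  for (alg in c("glm_stepwise", "mars")) {
    cvs[[alg]] <- crossvalidate(tab, alg, k = 5, seed = 4)
    fits[[alg]] <- fit_sdm(tab, alg, seed = 4)
  }
  rep <- evaluation_report(cvs, fits, background_method = "random")
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$tss, rep$sensitivity + rep$specificity - 1, tolerance = 1e-12)
  expect_true(all(rep$pcc >= 0 & rep$pcc <= 100))
  expect_true(all(rep$auc_train >= 0 & rep$auc_train <= 1))
  expect_identical(rep$background_method, rep("random", 2))
  # separable construction: these models must be acceptable
  expect_true(all(rep$acceptable))
})

test_that("adding a separating covariate never lowers training AUC for GLM", {
  withr::with_seed(50, {
    for (i in 1:5) {
      n <- 40
      tab1 <- data.frame(lon = 0, lat = 0, x1 = rnorm(2 * n),
                         pb = rep(c(1L, 0L), each = n))
      attr(tab1, "layers") <- "x1"
      sep <- c(runif(n, 0.1, 1), runif(n, -1, -0.1))
      tab2 <- tab1; tab2$x2 <- sep
      attr(tab2, "layers") <- c("x1", "x2")
      auc1 <- {
        m <- fit_sdm(tab1, "glm_stepwise", seed = i)
        p <- predict(m, tab1); roc_auc(p[tab1$pb == 1], p[tab1$pb == 0])
      }
      auc2 <- {
        m <- fit_sdm(tab2, "glm_stepwise", seed = i)
        p <- predict(m, tab2); roc_auc(p[tab2$pb == 1], p[tab2$pb == 0])
      }
      expect_gte(auc2, auc1)
    }
  })
})
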
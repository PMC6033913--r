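# The five presence-background learners. Each internal fitter takes a
# data.frame of covariates `x`, a 0/1 response `y`, a hyperparameter list and
# a seed, and returns a list with everything predict_*() needs. All fitters
# produce suitability in [0, 1].

## ---- stepwise logistic regression --------------------------------------

# Candidate term vocabulary: main effects, squares, all pairwise products.
glm_term_vocabulary <- function(vars) {
  mains <- vars
  squares <- paste0("I(", vars, "^2)")
  prods <- if (length(vars) > 1L)
    utils::combn(vars, 2L, function(p) paste(p, collapse = ":")) else character(0)
  list(mains = mains, squares = squares, prods = prods,
       all = c(mains, squares, prods))
}

# variables a term depends on
glm_term_parents <- function(term, vars) {
  if (term %in% vars) return(character(0))       # main effect: no parent term
  if (startsWith(term, "I(")) return(sub("^I\\((.*)\\^2\\)$", "\\1", term))
  strsplit(term, ":", fixed = TRUE)[[1]]
}

glm_formula <- function(terms) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  stats::as.formula(paste("y ~", rhs))
}

# Bidirectional stepwise minimizing AIC, honouring marginality: a square or
# product term may enter only while its main effect(s) are in the model, and
# a main effect may leave only when no higher-order term depends on it.
fit_glm_stepwise <- function(x, y, params = list(), seed = 1) {
  vars <- colnames(x)
  voc <- glm_term_vocabulary(vars)
  dat <- cbind(y = y, x)
  fit_terms <- function(terms) {
    suppressWarnings(stats::glm(glm_formula(terms), data = dat,
                                family = stats::binomial()))
  }
  current <- voc$mains
  fit <- fit_terms(current)
  best_aic <- stats::AIC(fit)
  max_steps <- as.integer(params$max_steps %||% 100L)
  for (step in seq_len(max_steps)) {
    moves <- list()
    for (tm in setdiff(voc$all, current))
      if (all(glm_term_parents(tm, vars) %in% current))
        moves[[length(moves) + 1L]] <- c(current, tm)
    for (tm in current) {
      parents_used <- any(vapply(setdiff(current, tm), function(other)
        tm %in% glm_term_parents(other, vars), logical(1)))
      if (!parents_used)
        moves[[length(moves) + 1L]] <- setdiff(current, tm)
    }
    if (!length(moves)) break
    aics <- vapply(moves, function(tms) stats::AIC(fit_terms(tms)), numeric(1))
    if (min(aics) >= best_aic - 1e-8) break
    current <- moves[[which.min(aics)]]
    best_aic <- min(aics)
  }
  fit <- fit_terms(current)
  used <- unique(unlist(c(
    intersect(current, vars),
    lapply(current, glm_term_parents, vars = vars))))
  list(glm = fit, terms = current, vars = vars,
       retained = intersect(vars, used),
       dropped = setdiff(vars, used))
}

predict_glm_stepwise <- function(state, x) {
  as.numeric(stats::predict(state$glm, newdata = as.data.frame(x),
                            type = "response"))
}

## ---- multivariate adaptive regression splines (degree 1) ----------------

# Forward pass grows reflected hinge pairs max(0, x - t) / max(0, t - x) by
# greatest RSS reduction (least squares); the backward pass prunes by GCV
# with smoothing penalty d (effective parameters M + d * (M - 1) / 2). The
# pruned basis is refit as a binomial GLM so predictions are probabilities.
fit_mars <- function(x, y, params = list(), seed = 1) {
  degree <- params$degree %||% 1
  if (degree != 1) stop("only degree-1 (additive) MARS is supported")
  penalty <- params$gcv_penalty %||% 2.0
  n <- length(y)
  vars <- colnames(x)
  max_terms <- as.integer(params$max_terms %||% min(21L, n - 1L, 2L * length(vars) * 10L + 1L))
  n_knots <- as.integer(params$n_knots %||% 20L)
  xm <- as.matrix(x)

  knots <- lapply(vars, function(v) {
    u <- sort(unique(xm[, v]))
    if (length(u) <= 2L) return(numeric(0))
    u <- u[-c(1L, length(u))]
    if (length(u) > n_knots)
      u <- stats::quantile(u, probs = seq(0, 1, length.out = n_knots),
                           names = FALSE, type = 1L)
    unique(u)
  })
  names(knots) <- vars

  B <- matrix(1, n, 1)
  terms <- list()   # each: list(var, knot); expands to a reflected pair
  rss <- sum((y - mean(y))^2)
  while (ncol(B) + 2L <= max_terms) {
    best <- NULL
    for (v in vars) for (t in knots[[v]]) {
      h1 <- pmax(0, xm[, v] - t); h2 <- pmax(0, t - xm[, v])
      f <- stats::lm.fit(cbind(B, h1, h2), y)
      cand_rss <- sum(f$residuals^2)
      if (is.null(best) || cand_rss < best$rss - 1e-12)
        best <- list(var = v, knot = t, rss = cand_rss, h1 = h1, h2 = h2)
    }
    if (is.null(best) || best$rss >= rss * (1 - 1e-6)) break
    B <- cbind(B, best$h1, best$h2)
    terms[[length(terms) + 1L]] <- list(var = best$var, knot = best$knot)
    rss <- best$rss
  }

  # backward prune over individual hinge columns by GCV
  gcv <- function(rss, m) (rss / n) / (1 - min(m + penalty * (m - 1) / 2, n - 1) / n)^2
  col_terms <- c(0L, rep(seq_along(terms), each = 2L))  # 0 = intercept
  active <- seq_len(ncol(B))
  fit0 <- stats::lm.fit(B, y)
  best_set <- active
  best_gcv <- gcv(sum(fit0$residuals^2), length(active))
  set <- active
  while (length(set) > 1L) {
    cand <- set[col_terms[set] != 0L]
    scores <- vapply(cand, function(drop_col) {
      s <- setdiff(set, drop_col)
      gcv(sum(stats::lm.fit(B[, s, drop = FALSE], y)$residuals^2), length(s))
    }, numeric(1))
    set <- setdiff(set, cand[which.min(scores)])
    if (min(scores) < best_gcv) {
      best_gcv <- min(scores)
      best_set <- set
    }
  }

  keep <- sort(best_set)
  basis_info <- lapply(keep[keep != 1L], function(cl) {
    tm <- terms[[col_terms[cl]]]
    dir <- if (cl %% 2L == 0L) 1 else -1   # even col = (x - t)+, odd = (t - x)+
    list(var = tm$var, knot = tm$knot, dir = dir)
  })
  Bk <- B[, keep, drop = FALSE]
  gfit <- suppressWarnings(stats::glm.fit(Bk, y, family = stats::binomial()))
  gfit$coefficients[is.na(gfit$coefficients)] <- 0
  used <- unique(vapply(basis_info, function(b) b$var, character(1)))
  list(coef = gfit$coefficients, basis = basis_info, vars = vars,
       retained = intersect(vars, used), dropped = setdiff(vars, used),
       gcv = best_gcv)
}

mars_basis <- function(state, x) {
  xm <- as.matrix(x)
  B <- matrix(1, nrow(xm), 1)
  for (b in state$basis) {
    col <- if (b$dir > 0) pmax(0, xm[, b$var] - b$knot) else pmax(0, b$knot - xm[, b$var])
    B <- cbind(B, col)
  }
  B
}

predict_mars <- function(state, x) {
  eta <- drop(mars_basis(state, x) %*% state$coef)
  1 / (1 + exp(-eta))
}

## ---- boosted regression trees ------------------------------------------

# Stochastic gradient boosting via xgboost: bernoulli deviance, bag
# fraction = subsample, tree count selected by held-out deviance (stratified
# 80/20 split within the training data, early stopping), then refit on all
# rows at the selected tree count.
fit_brt <- function(x, y, params = list(), seed = 1) {
  eta <- params$learning_rate %||% 0.01
  depth <- as.integer(params$interaction_depth %||% 3L)
  bag <- params$bag_fraction %||% 0.5
  max_trees <- as.integer(params$max_trees %||% 2000L)
  xm <- as.matrix(x)
  withr::with_seed(seed, {
    hold <- unlist(lapply(split(seq_along(y), y), function(ix)
      sample(ix, max(1L, round(0.2 * length(ix))))))
    xgb_params <- list(objective = "binary:logistic", eta = eta,
                       max_depth = depth, subsample = bag, nthread = 1)
    dtrain <- xgboost::xgb.DMatrix(xm[-hold, , drop = FALSE], label = y[-hold])
    dhold <- xgboost::xgb.DMatrix(xm[hold, , drop = FALSE], label = y[hold])
    tuner <- xgboost::xgb.train(
      params = c(xgb_params, list(eval_metric = "logloss")),
      data = dtrain, nrounds = max_trees,
      evals = list(holdout = dhold),
      early_stopping_rounds = 50L, verbose = 0)
    n_trees <- as.integer(xgboost::xgb.attributes(tuner)$best_iteration)
    if (!length(n_trees) || is.na(n_trees) || n_trees < 1L) n_trees <- max_trees
    fit <- xgboost::xgb.train(
      params = xgb_params,
      data = xgboost::xgb.DMatrix(xm, label = y),
      nrounds = n_trees, verbose = 0)
  })
  list(booster = fit, n_trees = n_trees, vars = colnames(x),
       retained = colnames(x), dropped = character(0))
}

predict_brt <- function(state, x) {
  xm <- as.matrix(x)[, state$vars, drop = FALSE]
  as.numeric(stats::predict(state$booster, xgboost::xgb.DMatrix(xm)))
}

## ---- random forest -------------------------------------------------------

# Classification forest with probability (vote-fraction) output; variables
# tried per split (mtry) tuned to minimize out-of-bag error, as tuneRF does.
# Terminal nodes hold >= 10 cases — the usual probability-forest leaf size,
# which keeps vote fractions from degenerating to memorized 0/1 votes.
fit_rf <- function(x, y, params = list(), seed = 1) {
  ntree <- as.integer(params$ntree %||% 500L)
  nodesize <- as.integer(params$nodesize %||% 10L)
  yf <- factor(y, levels = c(0, 1))
  withr::with_seed(seed, {
    mtry <- if (ncol(x) <= 1L) 1L else {
      tr <- try(suppressMessages(utils::capture.output(
        tune <- randomForest::tuneRF(x, yf, ntreeTry = min(ntree, 250L),
                                     stepFactor = 2, improve = 0.02,
                                     trace = FALSE, plot = FALSE,
                                     nodesize = nodesize))),
        silent = TRUE)
      if (inherits(tr, "try-error")) max(1L, floor(sqrt(ncol(x))))
      else tune[which.min(tune[, "OOBError"]), "mtry"]
    }
    fit <- randomForest::randomForest(x, yf, mtry = mtry, ntree = ntree,
                                      nodesize = nodesize)
  })
  list(forest = fit, mtry = as.integer(mtry), vars = colnames(x),
       retained = colnames(x), dropped = character(0))
}

predict_rf <- function(state, x) {
  as.numeric(stats::predict(state$forest, newdata = as.data.frame(x),
                            type = "prob")[, "1"])
}

## ---- maximum-entropy-style penalized logistic ---------------------------

# L1-penalized logistic regression on the Maxent feature vocabulary:
# linear, quadratic, pairwise-product, and reflected hinge features (8
# knots per direction per variable). The lasso path plays the role of
# Maxent's l1 regularization; lambda is chosen by internal cross-validated
# deviance. Logistic output is already a [0, 1] suitability.
fit_maxent_like <- function(x, y, params = list(), seed = 1) {
  n_hinge <- as.integer(params$hinge_knots %||% 8L)
  nfolds <- as.integer(params$lambda_nfolds %||% 5L)
  vars <- colnames(x)
  knots <- lapply(vars, function(v) {
    q <- stats::quantile(x[[v]], probs = seq(0.05, 0.95, length.out = n_hinge),
                         names = FALSE)
    unique(q)
  })
  names(knots) <- vars
  spec <- list(vars = vars, knots = knots)
  feats <- maxent_features(spec, x)
  withr::with_seed(seed, {
    # small-lambda tail convergence warnings are benign for lambda.min use
    cvfit <- suppressWarnings(
      glmnet::cv.glmnet(feats, y, family = "binomial", alpha = 1,
                        nfolds = nfolds, standardize = TRUE))
  })
  list(cvfit = cvfit, spec = spec, vars = vars,
       retained = vars, dropped = character(0))
}

maxent_features <- function(spec, x) {
  xm <- as.matrix(as.data.frame(x)[, spec$vars, drop = FALSE])
  out <- list(xm, xm^2)
  nm <- c(spec$vars, paste0(spec$vars, "_sq"))
  if (length(spec$vars) > 1L) {
    pr <- utils::combn(spec$vars, 2L)
    prod_m <- apply(pr, 2L, function(p) xm[, p[1]] * xm[, p[2]])
    if (is.null(dim(prod_m))) prod_m <- matrix(prod_m, nrow = nrow(xm))
    out <- c(out, list(prod_m))
    nm <- c(nm, apply(pr, 2L, paste, collapse = "_x_"))
  }
  for (v in spec$vars) for (t in spec$knots[[v]]) {
    out <- c(out, list(cbind(pmax(0, xm[, v] - t), pmax(0, t - xm[, v]))))
    nm <- c(nm, paste0(v, "_hf_", format(t)), paste0(v, "_hr_", format(t)))
  }
  m <- do.call(cbind, out)
  colnames(m) <- nm
  m
}

predict_maxent_like <- function(state, x) {
  feats <- maxent_features(state$spec, x)
  as.numeric(stats::predict(state$cvfit, newx = feats, s = "lambda.min",
                            type = "response"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
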
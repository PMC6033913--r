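#' Area under the ROC curve
#'
#' Mann–Whitney formulation: the probability that a random presence scores
#' above a random background point, ties counting one half.
#'
#' @param presence_scores,background_scores Numeric score vectors (both
#'   nonempty; `NA` scores are not allowed).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("both score vectors must be nonempty")
  if (anyNA(presence_scores) || anyNA(background_scores))
    stop("scores contain NA")
  np <- length(presence_scores); nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))  # midranks handle ties
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Threshold maximizing mean sensitivity and specificity
#'
#' Scans every unique observed score as a candidate cut-off (classification
#' rule: score >= threshold predicts presence) and returns the candidate
#' maximizing (sensitivity + specificity) / 2; ties break to the smallest
#' threshold.
#'
#' @inheritParams roc_auc
#' @return The selected threshold.
#' @export
optimal_threshold <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("both score vectors must be nonempty")
  cand <- sort(unique(c(presence_scores, background_scores)))
  obj <- vapply(cand, function(t) {
    (mean(presence_scores >= t) + mean(background_scores < t)) / 2
  }, numeric(1))
  cand[which.max(obj)]   # which.max returns first (= smallest) on ties
}

#' Threshold-dependent accuracy metrics
#'
#' At the rule score >= threshold -> presence: sensitivity = TP / n_presence,
#' specificity = TN / n_background, PCC = percent of all points correctly
#' classified, TSS = sensitivity + specificity - 1.
#'
#' @inheritParams roc_auc
#' @param threshold Classification threshold.
#' @return Named list: `sensitivity`, `specificity`, `pcc` (0–100 scale),
#'   `tss`.
#' @export
confusion_metrics <- function(presence_scores, background_scores, threshold) {
  stopifnot(is.finite(threshold))
  np <- length(presence_scores); nb <- length(background_scores)
  tp <- sum(presence_scores >= threshold)
  tn <- sum(background_scores < threshold)
  sens <- tp / np
  spec <- tn / nb
  list(sensitivity = sens, specificity = spec,
       pcc = 100 * (tp + tn) / (np + nb),
       tss = sens + spec - 1)
}

#' Permutation variable importance (delta AUC)
#'
#' For each cross-validation fold: the fold model's validation AUC minus the
#' mean validation AUC over `n_perm` random permutations of one layer's
#' column (presence and background rows pooled into a single shuffled
#' column). The per-fold differences are averaged. A layer the learner
#' dropped entirely (possible for the stepwise GLM and MARS) is
#' not-applicable and yields `NA` rather than 0.
#'
#' @param cv An [sdm_cv][crossvalidate].
#' @param layer Layer (covariate) name.
#' @param n_perm Permutations per fold.
#' @param seed Integer seed.
#' @return Mean delta AUC over folds (positive = the variable carries
#'   discriminating signal), or `NA` if the layer was dropped from the model.
#' @export
permutation_importance <- function(cv, layer, n_perm = 10, seed = 1) {
  stopifnot(inherits(cv, "sdm_cv"))
  vars <- covariate_names(cv$table)
  if (!layer %in% vars) stop("unknown layer: ", layer)
  if (all(vapply(cv$models, function(m) layer %in% m$dropped, logical(1))))
    return(NA_real_)
  deltas <- numeric(cv$k)
  for (f in seq_len(cv$k)) {
    val <- cv$table[cv$fold == f, , drop = FALSE]
    model <- cv$models[[f]]
    base_pred <- cv$oof[cv$fold == f]
    auc0 <- roc_auc(base_pred[val$pb == 1L], base_pred[val$pb == 0L])
    perm_auc <- withr::with_seed(child_seed(seed, f), {
      vapply(seq_len(n_perm), function(i) {
        shuffled <- val
        shuffled[[layer]] <- sample(val[[layer]])
        p <- predict(model, shuffled)
        roc_auc(p[val$pb == 1L], p[val$pb == 0L])
      }, numeric(1))
    })
    deltas[f] <- auc0 - mean(perm_auc)
  }
  mean(deltas)
}

#' Permutation-importance table across algorithms
#'
#' @param cv_list Named list of [sdm_cv][crossvalidate] objects (one per
#'   algorithm).
#' @param n_perm Permutations per fold.
#' @param seed Integer seed.
#' @return Data frame with columns `algorithm`, `layer`, `delta_auc`
#'   (`NA` = not applicable) and `rank` (1 = most important within
#'   algorithm; dropped layers unranked).
#' @export
importance_table <- function(cv_list, n_perm = 10, seed = 1) {
  rows <- list()
  for (alg in names(cv_list)) {
    cv <- cv_list[[alg]]
    layers <- covariate_names(cv$table)
    d <- vapply(seq_along(layers), function(i)
      permutation_importance(cv, layers[i], n_perm = n_perm,
                             seed = child_seed(seed, i * 131)),
      numeric(1))
    rk <- rep(NA_integer_, length(d))
    rk[!is.na(d)] <- rank(-d[!is.na(d)], ties.method = "first")
    rows[[alg]] <- data.frame(algorithm = alg, layer = layers,
                              delta_auc = d, rank = rk)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluation report for a set of cross-validated models
#'
#' One row per (algorithm, background method): training AUC (model fit on
#' the full table, scored on its own training rows), mean cross-validation
#' AUC over folds, and threshold-dependent metrics computed on the pooled
#' out-of-fold predictions at the threshold maximizing mean sensitivity and
#' specificity on those same pooled scores. An acceptability flag marks rows
#' clearing AUC > `auc_min` and TSS > `tss_min`.
#'
#' @param cv_list Named list of [sdm_cv][crossvalidate] objects.
#' @param full_models Named list of [sdm_fit][fit_sdm] objects fit on the
#'   full table (same names as `cv_list`).
#' @param background_method Label for the background scheme (`"random"` or
#'   `"targeted"`).
#' @param threshold_on `"cv"` (default: pooled out-of-fold scores) or
#'   `"train"` (training-split scores).
#' @param auc_min,tss_min Acceptability cut-offs.
#' @return Data frame with columns `algorithm`, `background_method`,
#'   `auc_train`, `auc_cv`, `threshold`, `sensitivity`, `specificity`,
#'   `pcc`, `tss`, `acceptable`.
#' @export
evaluation_report <- function(cv_list, full_models,
                              background_method = "random",
                              threshold_on = c("cv", "train"),
                              auc_min = 0.7, tss_min = 0.4) {
  threshold_on <- match.arg(threshold_on)
  rows <- lapply(names(cv_list), function(alg) {
    cv <- cv_list[[alg]]
    tab <- cv$table
    pres <- tab$pb == 1L
    train_pred <- predict(full_models[[alg]], tab)
    auc_train <- roc_auc(train_pred[pres], train_pred[!pres])
    auc_cv <- mean(cv$auc_folds)
    scores <- if (threshold_on == "cv") cv$oof else train_pred
    thr <- optimal_threshold(scores[pres], scores[!pres])
    m <- confusion_metrics(scores[pres], scores[!pres], thr)
    data.frame(algorithm = alg, background_method = background_method,
               auc_train = auc_train, auc_cv = auc_cv, threshold = thr,
               sensitivity = m$sensitivity, specificity = m$specificity,
               pcc = m$pcc, tss = m$tss,
               acceptable = auc_cv > auc_min & m$tss > tss_min)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
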
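#' Pairwise maximum correlation among candidate predictors
#'
#' For every pair of columns, computes absolute Pearson, Spearman, and
#' Kendall correlation on pairwise-complete cases and keeps the largest of
#' the three. This deliberately over-detects association: rank-based
#' coefficients catch monotone nonlinear dependence that Pearson misses.
#' Constant columns have undefined correlations; these are reported as 0
#' for screening purposes, with a warning.
#'
#' @param table Data frame or matrix of per-point predictor values, one
#'   column per candidate layer.
#' @return Symmetric matrix with unit diagonal; entry `[i, j]` is
#'   `max(|pearson|, |spearman|, |kendall|)` for columns i and j. Columns
#'   found constant are listed in attribute `"constant"`.
#' @export
pairwise_max_correlation <- function(table) {
  x <- as.matrix(as.data.frame(table))
  storage.mode(x) <- "double"
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  const <- apply(x, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2L || max(v) == min(v)
  })
  if (any(const))
    warning("constant column(s) treated as uncorrelated: ",
            paste(colnames(x)[const], collapse = ", "))
  out <- diag(1, p)
  dimnames(out) <- list(colnames(x), colnames(x))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    ok <- stats::complete.cases(x[, c(i, j)])
    if (sum(ok) < 3L || const[i] || const[j]) {
      out[i, j] <- out[j, i] <- 0
      next
    }
    xi <- x[ok, i]; xj <- x[ok, j]
    r <- max(abs(stats::cor(xi, xj, method = "pearson")),
             abs(stats::cor(xi, xj, method = "spearman")),
             abs(stats::cor(xi, xj, method = "kendall")))
    out[i, j] <- out[j, i] <- r
  }
  attr(out, "constant") <- colnames(x)[const]
  out
}

#' Screen predictors by pairwise correlation
#'
#' Greedy elimination: walk the candidate layers in priority order (most
#' biologically relevant first) and accept a layer only if its screening
#' correlation with every already-accepted layer is at or below the
#' threshold. From each highly correlated pair, the higher-priority member
#' survives.
#'
#' @param cor_matrix Matrix from [pairwise_max_correlation()].
#' @param priority Character vector ordering all candidate layers, most
#'   relevant first.
#' @param threshold Correlation cutoff; pairs with correlation strictly
#'   above it conflict (a pair at exactly the threshold is kept).
#' @return Character vector of retained layer names, in priority order.
#' @export
screen_predictors <- function(cor_matrix, priority, threshold = 0.70) {
  stopifnot(is.matrix(cor_matrix), threshold > 0, threshold < 1)
  nm <- rownames(cor_matrix)
  miss <- setdiff(nm, priority)
  if (length(miss))
    stop("priority list does not cover: ", paste(miss, collapse = ", "))
  priority <- priority[priority %in% nm]
  kept <- character(0)
  for (cand in priority) {
    if (!length(kept) || all(cor_matrix[cand, kept] <= threshold))
      kept <- c(kept, cand)
  }
  kept
}
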
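# Feature selection: mutual-information filter and Lasso (L1-penalised
# multinomial logistic regression) embedded selection. Both are always
# fitted on training rows only; cross-validation wiring lives in
# crossvalidate().

#' Selection method specification
#'
#' @param method `"none"`, `"mutual_information"` or `"lasso"`.
#' @param k_top number of features kept by the MI filter.
#' @param lambda_grid penalty grid for the Lasso path (20 log-spaced values
#'   over \[1e-3, 10\] by default).
#' @param inner_folds folds of the inner CV used to pick the Lasso penalty.
#' @param mi_bins quantile bins used to discretize features for MI.
#' @return A list of class `selection_spec`.
#' @export
selection_spec <- function(method = c("none", "mutual_information", "lasso"),
                           k_top = 20L,
                           lambda_grid = 10^seq(-3, 1, length.out = 20),
                           inner_folds = 3L, mi_bins = 4L) {
  method <- match.arg(method)
  if (method == "mutual_information" && k_top < 1) stop("k_top must be >= 1")
  if (method == "lasso" && length(lambda_grid) == 0) {
    stop("lambda_grid must be nonempty")
  }
  structure(list(method = method, k_top = as.integer(k_top),
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 inner_folds = as.integer(inner_folds),
                 mi_bins = as.integer(mi_bins)),
            class = "selection_spec")
}

# Plug-in mutual information (bits) between a discretized feature and the
# class label, from the joint contingency table.
mi_bits <- function(xf, y) {
  tab <- table(xf, y)
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Mutual-information feature filter
#'
#' Discretizes each feature into quantile bins, estimates the mutual
#' information with the class label from the joint table, and returns the
#' `k_top` highest-MI feature names. Ties break deterministically by column
#' order; constant columns have MI 0 and rank last.
#'
#' @param x numeric training feature matrix/data frame (rows = samples).
#' @param y class label factor (training rows).
#' @param k_top number of features to keep.
#' @param bins number of quantile bins.
#' @return Character vector of selected feature names (length `k_top`), with
#'   the per-feature MI values attached as attribute `mi`.
#' @export
select_mi <- function(x, y, k_top = 20L, bins = 4L) {
  x <- as.matrix(x)
  if (k_top > ncol(x)) stop("k_top exceeds number of features")
  mi <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                                 na.rm = TRUE))
    if (length(br) < 2) return(0) # constant column
    xf <- cut(v, breaks = br, include.lowest = TRUE)
    mi_bits(xf, y)
  }, numeric(1))
  ord <- order(-mi, seq_along(mi)) # ties -> column order
  sel <- colnames(x)[ord[seq_len(k_top)]]
  attr(sel, "mi") <- stats::setNames(mi, colnames(x))
  sel
}

#' Lasso embedded feature selection
#'
#' Fits an L1-penalised multinomial logistic regression over a penalty grid
#' on standardized training features, picks the penalty by inner
#' cross-validated accuracy under a one-standard-error rule (the sparsest
#' penalty within one SE of the best), and returns the features with any
#' nonzero coefficient at that penalty. If the chosen penalty zeroes every coefficient, the single
#' feature with the largest absolute coefficient anywhere on the path is
#' returned with a warning.
#'
#' @param x numeric training feature matrix/data frame (already imputed;
#'   standardization is done internally from these training rows).
#' @param y class label factor with >= 2 observed classes.
#' @param lambda_grid decreasing penalty grid.
#' @param inner_folds folds for the inner CV.
#' @param seed seed for the inner fold assignment.
#' @return Character vector of selected feature names, with the chosen
#'   penalty attached as attribute `lambda`.
#' @export
select_lasso <- function(x, y,
                         lambda_grid = 10^seq(-3, 1, length.out = 20),
                         inner_folds = 3L, seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("degenerate single-class training fold")
  # glmnet needs >= 2 observations per class; singleton classes carry no
  # usable signal for selection and are dropped from the selection fit
  counts <- table(y)
  if (any(counts < 2)) {
    keep <- y %in% names(counts)[counts >= 2]
    x <- x[keep, , drop = FALSE]
    y <- droplevels(y[keep])
    if (nlevels(y) < 2) stop("degenerate single-class training fold")
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  fold <- with_seed(seed, stratified_folds(y, inner_folds))
  acc <- matrix(NA_real_, nrow = inner_folds, ncol = length(lambda_grid))
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
    if (any(table(droplevels(y[tr])) < 2)) next # glmnet cannot fit this fold
    # small-class warnings are expected at these fold sizes
    fit_f <- tryCatch(
      suppressWarnings(
        glmnet::glmnet(xs[tr, , drop = FALSE], y[tr], family = fam,
                       alpha = 1, lambda = lambda_grid, standardize = FALSE)),
      error = function(e) NULL)
    if (is.null(fit_f)) next
    pred <- predict(fit_f, xs[!tr, , drop = FALSE], s = lambda_grid,
                    type = "class")
    acc[f, seq_len(ncol(pred))] <- colMeans(pred == as.character(y[!tr]))
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  mean_acc[is.nan(mean_acc)] <- -Inf
  # one-standard-error rule on the inner accuracy: among penalties within
  # one SE of the best, keep the strongest (sparsest); stabilises the
  # choice at the small fold sizes this design runs at
  best <- which.max(mean_acc)
  se <- stats::sd(acc[, best], na.rm = TRUE) / sqrt(sum(!is.na(acc[, best])))
  if (is.na(se)) se <- 0
  best <- which(mean_acc >= mean_acc[best] - se)[1]
  lam <- lambda_grid[best]
  fit <- suppressWarnings(
    glmnet::glmnet(xs, y, family = fam, alpha = 1, lambda = lambda_grid,
                   standardize = FALSE))
  cf <- glmnet::coef.glmnet(fit, s = lam)
  if (!is.list(cf)) cf <- list(cf)
  nz <- Reduce(`|`, lapply(cf, function(m) as.vector(m[-1, 1]) != 0))
  sel <- colnames(x)[nz]
  if (length(sel) == 0) {
    warning("Lasso selected no features at the chosen penalty; ",
            "falling back to the strongest coefficient on the path")
    cfs <- glmnet::coef.glmnet(fit, s = lambda_grid)
    if (!is.list(cfs)) cfs <- list(cfs)
    path_max <- Reduce(pmax, lapply(cfs, function(m) {
      apply(abs(as.matrix(m[-1, , drop = FALSE])), 1, max)
    }))
    sel <- colnames(x)[which.max(path_max)]
  }
  attr(sel, "lambda") <- lam
  sel
}
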
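# Per-trait classification benchmark: five classifiers x three selection
# settings under stratified five-fold cross-validation, with all
# preprocessing (imputation, scaling, selection) fitted inside the training
# fold only.

classifier_names <- c("DT", "KNN", "LR", "NB", "SVM")

# Each classifier is a fit/predict_prob pair returning a probability matrix
# with one column per label level. Hyperparameters are fixed documented
# defaults (the tunable grid of the source protocol is unspecified):
# DT depth 5; KNN k = 5 distance-weighted; LR multinomial with ridge decay
# 0.1 (light enough that separable data is fit exactly); Gaussian NB; SVM
# RBF cost 1 with probability estimates.
make_classifier <- function(name) {
  switch(
    name,
    DT = list(
      fit = function(x, y) {
        df <- data.frame(x, check.names = FALSE)
        df$.y <- y
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(maxdepth = 5, cp = 0.01,
                                                    xval = 0))
      },
      prob = function(model, x) {
        predict(model, data.frame(x, check.names = FALSE), type = "prob")
      }
    ),
    KNN = list(
      fit = function(x, y) list(x = as.matrix(x), y = y, k = 5L),
      prob = function(model, x) {
        x <- as.matrix(x)
        lev <- levels(model$y)
        out <- matrix(0, nrow(x), length(lev), dimnames = list(NULL, lev))
        for (i in seq_len(nrow(x))) {
          d <- sqrt(colSums((t(model$x) - x[i, ])^2))
          nn <- order(d)[seq_len(min(model$k, length(d)))]
          w <- 1 / (d[nn] + 1e-6)
          for (j in seq_along(nn)) {
            cl <- as.character(model$y[nn[j]])
            out[i, cl] <- out[i, cl] + w[j]
          }
          out[i, ] <- out[i, ] / sum(out[i, ])
        }
        out
      }
    ),
    LR = list(
      fit = function(x, y) {
        df <- data.frame(x, check.names = FALSE)
        df$.y <- y
        nnet::multinom(.y ~ ., data = df, decay = 0.1, trace = FALSE,
                       MaxNWts = 10000, maxit = 1000)
      },
      prob = function(model, x) {
        p <- predict(model, data.frame(x, check.names = FALSE), type = "probs")
        if (is.null(dim(p))) { # two-class multinom returns a vector
          p <- cbind(1 - p, p)
          colnames(p) <- model$lev
        }
        p
      }
    ),
    NB = list(
      fit = function(x, y) e1071::naiveBayes(as.matrix(x), y),
      prob = function(model, x) predict(model, as.matrix(x), type = "raw")
    ),
    SVM = list(
      fit = function(x, y) {
        e1071::svm(as.matrix(x), y, kernel = "radial", cost = 1,
                   probability = TRUE)
      },
      prob = function(model, x) {
        p <- predict(model, as.matrix(x), probability = TRUE)
        attr(p, "probabilities")
      }
    ),
    stop("unknown classifier: ", name)
  )
}

macro_f1 <- function(truth, pred, levels) {
  f1 <- vapply(levels, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1, na.rm = TRUE)
}

# Macro one-vs-rest AUC from a class-probability matrix; classes absent from
# the test fold (or present in every row) are skipped.
macro_auc <- function(truth, prob, levels) {
  aucs <- vapply(levels, function(cl) {
    pos <- truth == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    r <- pROC::roc(response = pos, predictor = prob[, cl], quiet = TRUE,
                   levels = c(FALSE, TRUE), direction = "<")
    as.numeric(pROC::auc(r))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

ci_normal <- function(v) {
  m <- mean(v, na.rm = TRUE)
  se <- stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
  if (is.na(se)) se <- 0
  c(point = m, lower = m - 1.96 * se, upper = m + 1.96 * se)
}

apply_selection <- function(xtr, ytr, selection, seed) {
  switch(
    selection$method,
    none = colnames(xtr),
    mutual_information = as.character(
      select_mi(xtr, ytr, k_top = selection$k_top, bins = selection$mi_bins)),
    lasso = as.character(
      select_lasso(xtr, ytr, lambda_grid = selection$lambda_grid,
                   inner_folds = selection$inner_folds, seed = seed))
  )
}

#' Cross-validated trait classification
#'
#' Stratified k-fold cross-validation with strictly in-fold preprocessing:
#' within each training fold, missing values are imputed by the training
#' medians, features are standardized with training statistics, the
#' selection method is fitted, and the classifier is trained on the selected
#' columns; the held-out fold only ever passes through those frozen
#' transforms. Accuracy, macro F1 and macro one-vs-rest AUC are averaged
#' over folds with normal-approximation 95% confidence intervals.
#'
#' @param features a `feature_table` (or plain data frame); an attached
#'   `missing_mask` attribute is honoured so imputation stays in-fold.
#' @param labels factor of class labels, one per feature row.
#' @param classifier one of `"DT"`, `"KNN"`, `"LR"`, `"NB"`, `"SVM"`.
#' @param selection a [selection_spec()].
#' @param n_folds number of outer folds.
#' @param seed integer seed controlling fold assignment and any classifier
#'   randomness; identical seeds give identical reports.
#' @param trait optional trait name recorded in the report.
#' @return A list of class `model_report`: metric summaries (`accuracy`,
#'   `f1`, `auc`, each `point`/`lower`/`upper`), `per_fold` data frame and a
#'   `selected_freq` table of how often each feature was selected across
#'   folds.
#' @export
crossvalidate <- function(features, labels,
                          classifier = "LR",
                          selection = selection_spec("none"),
                          n_folds = 5L, seed = 1L, trait = NULL) {
  classifier <- match.arg(classifier, classifier_names)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("single-class label vector")
  x <- as.matrix(as.data.frame(features))
  mask <- attr(features, "missing_mask")
  if (!is.null(mask)) x[mask] <- NA_real_
  if (nrow(x) != length(labels)) stop("features/labels length mismatch")
  min_class <- min(table(labels))
  if (min_class < n_folds) {
    warning("fewest class has ", min_class, " rows; stratification degrades ",
            "to at most one row per fold for that class")
  }
  clf <- make_classifier(classifier)
  lev <- levels(labels)

  fold <- with_seed(seed, stratified_folds(labels, n_folds))
  per_fold <- vector("list", n_folds)
  selected_by_fold <- vector("list", n_folds)
  sel_all <- character(0)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- !tr
    xtr <- x[tr, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    med <- apply(xtr, 2, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (j in which(colSums(is.na(xtr)) > 0)) xtr[is.na(xtr[, j]), j] <- med[j]
    for (j in which(colSums(is.na(xte)) > 0)) xte[is.na(xte[, j]), j] <- med[j]
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    ytr <- droplevels(labels[tr])
    sel <- apply_selection(xtr, ytr, selection, derive_seed(seed, f))
    selected_by_fold[[f]] <- sel
    sel_all <- c(sel_all, sel)
    prob <- if (nlevels(ytr) < 2) {
      # degenerate training fold: predict the only observed class
      matrix(as.numeric(lev == levels(ytr)), sum(te), length(lev),
             byrow = TRUE, dimnames = list(NULL, lev))
    } else {
      p <- with_seed(derive_seed(seed, f, 99), {
        model <- clf$fit(xtr[, sel, drop = FALSE], ytr)
        clf$prob(model, xte[, sel, drop = FALSE])
      })
      # classes absent from the training fold get probability zero
      full <- matrix(0, nrow(p), length(lev), dimnames = list(NULL, lev))
      full[, colnames(p)] <- p
      full
    }
    # degenerate fits (e.g. Gaussian NB with a singleton class) can emit
    # non-finite scores; fall back to uniform over the trained classes
    prob[!is.finite(prob)] <- 0
    zero <- rowSums(prob) == 0
    if (any(zero)) {
      trained <- lev %in% levels(ytr)
      prob[zero, trained] <- 1 / sum(trained)
    }
    pred <- lev[max.col(prob, ties.method = "first")]
    truth <- as.character(labels[te])
    per_fold[[f]] <- data.frame(
      fold = f,
      accuracy = mean(pred == truth),
      f1 = macro_f1(truth, pred, lev),
      auc = macro_auc(truth, prob, lev),
      n_test = sum(te),
      n_selected = length(sel)
    )
  }
  per_fold <- do.call(rbind, per_fold)
  structure(
    list(trait = trait, classifier = classifier, selection = selection,
         n_folds = n_folds, seed = seed,
         accuracy = ci_normal(per_fold$accuracy),
         f1 = ci_normal(per_fold$f1),
         auc = ci_normal(per_fold$auc),
         per_fold = per_fold,
         selected_by_fold = selected_by_fold,
         selected_freq = sort(table(sel_all), decreasing = TRUE)),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "<model_report> %s%s, selection = %s, %d-fold CV\n  accuracy %.3f (%.3f, %.3f)  F1 %.3f  AUC %.3f\n",
    if (!is.null(x$trait)) paste0(x$trait, ": ") else "", x$classifier,
    x$selection$method, x$n_folds,
    x$accuracy["point"], x$accuracy["lower"], x$accuracy["upper"],
    x$f1["point"], x$auc["point"]
  ))
  invisible(x)
}

#' Full trait x classifier x selection benchmark
#'
#' Runs [crossvalidate()] for every combination of trait, classifier and
#' selection method (5 x 5 x 3 = 75 cells under defaults) and tabulates the
#' results, including per-(classifier, selection) averages across traits.
#' Per-cell failures are recorded as `NA` rows, never aborting the grid.
#'
#' @param features a `feature_table` with participant rownames.
#' @param labels_by_trait data frame of label factors, one column per trait,
#'   rows aligned with `features`.
#' @param classifiers character vector of classifier names.
#' @param selections named list of [selection_spec()]s.
#' @param n_folds outer folds.
#' @param seed integer seed.
#' @return A list of class `benchmark_grid`: `grid` (one row per cell with
#'   point estimates and CIs), `by_method` (averages over traits) and
#'   `reports` (nested list of `model_report`s).
#' @export
run_benchmark <- function(features, labels_by_trait,
                          classifiers = classifier_names,
                          selections = list(
                            none = selection_spec("none"),
                            mutual_information = selection_spec("mutual_information"),
                            lasso = selection_spec("lasso")),
                          n_folds = 5L, seed = 1L) {
  rows <- list()
  reports <- list()
  for (tr in colnames(labels_by_trait)) {
    for (cl in classifiers) {
      for (sn in names(selections)) {
        rep <- tryCatch(
          crossvalidate(features, labels_by_trait[[tr]], classifier = cl,
                        selection = selections[[sn]], n_folds = n_folds,
                        seed = derive_seed(seed, match(tr, colnames(labels_by_trait)),
                                           match(cl, classifiers)),
                        trait = tr),
          error = function(e) e
        )
        failed <- inherits(rep, "error")
        if (failed) {
          warning(sprintf("benchmark cell (%s, %s, %s) failed: %s",
                          tr, cl, sn, conditionMessage(rep)))
        } else {
          reports[[paste(tr, cl, sn, sep = ".")]] <- rep
        }
        num <- function(field, q) if (failed) NA_real_ else rep[[field]][[q]]
        rows[[length(rows) + 1]] <- data.frame(
          trait = tr, classifier = cl, selection = sn,
          accuracy = num("accuracy", "point"),
          accuracy_lo = num("accuracy", "lower"),
          accuracy_hi = num("accuracy", "upper"),
          f1 = num("f1", "point"), f1_lo = num("f1", "lower"),
          f1_hi = num("f1", "upper"),
          auc = num("auc", "point"), auc_lo = num("auc", "lower"),
          auc_hi = num("auc", "upper"),
          failed = failed
        )
      }
    }
  }
  grid <- do.call(rbind, rows)
  by_method <- stats::aggregate(
    grid[, c("accuracy", "f1", "auc")],
    by = list(classifier = grid$classifier, selection = grid$selection),
    FUN = mean, na.rm = TRUE
  )
  structure(list(grid = grid, by_method = by_method, reports = reports,
                 seed = seed),
            class = "benchmark_grid")
}

#' @export
print.benchmark_grid <- function(x, ...) {
  cat(sprintf("<benchmark_grid> %d cells (%d failed)\n",
              nrow(x$grid), sum(x$grid$failed)))
  print(x$by_method)
  invisible(x)
}
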
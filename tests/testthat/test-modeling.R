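# Shared small modeling fixture: separable 3-class data.
separable_data <- function(n = 60, p_noise = 6, sd = 0.15, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("low", "medium", "high"), length.out = n),
              levels = c("low", "medium", "high"))
  x <- matrix(rnorm(n * p_noise), n, p_noise,
              dimnames = list(NULL, paste0("n", seq_len(p_noise))))
  x <- cbind(x, sig1 = as.integer(y) + rnorm(n, 0, sd),
             sig2 = -as.integer(y) + rnorm(n, 0, sd))
  list(x = as.data.frame(x), y = y)
}

test_that("perfectly separable data gives accuracy and AUC of 1 with LR", {
  d <- separable_data(sd = 0.05)
  r <- crossvalidate(d$x, d$y, classifier = "LR",
                     selection = selection_spec("none"), seed = 1)
  expect_equal(unname(r$accuracy["point"]), 1)
  expect_equal(unname(r$auc["point"]), 1)
  expect_equal(unname(r$f1["point"]), 1)
})

test_that("cross-validation reports are deterministic given the seed", {
  d <- separable_data(sd = 0.6)
  for (clf in c("LR", "NB", "DT", "KNN")) {
    r1 <- crossvalidate(d$x, d$y, classifier = clf,
                        selection = selection_spec("mutual_information",
                                                   k_top = 4), seed = 7)
    r2 <- crossvalidate(d$x, d$y, classifier = clf,
                        selection = selection_spec("mutual_information",
                                                   k_top = 4), seed = 7)
    expect_identical(r1$per_fold, r2$per_fold, label = clf)
    expect_identical(r1$accuracy, r2$accuracy, label = clf)
  }
})

test_that("every classifier produces valid metrics and CI ordering", {
  d <- separable_data(sd = 0.8, seed = 3)
  for (clf in c("DT", "KNN", "LR", "NB", "SVM")) {
    r <- crossvalidate(d$x, d$y, classifier = clf,
                       selection = selection_spec("none"), seed = 2)
    for (m in c("accuracy", "f1", "auc")) {
      v <- r[[m]]
      expect_true(v["lower"] <= v["point"] && v["point"] <= v["upper"],
                  label = paste(clf, m, "CI ordering"))
      expect_true(v["point"] >= 0 && v["point"] <= 1,
                  label = paste(clf, m, "bounds"))
    }
    expect_identical(nrow(r$per_fold), 5L)
  }
})

test_that("fold assignment is a stratified partition", {
  d <- separable_data(n = 47, sd = 1)
  fold <- fivegaze:::with_seed(5, fivegaze:::stratified_folds(d$y, 5))
  expect_identical(length(fold), 47L)
  expect_true(all(fold %in% 1:5)) # every row in exactly one fold
  glob <- table(d$y) / length(d$y)
  for (f in 1:5) {
    tab <- table(d$y[fold == f])
    expected <- glob * sum(fold == f)
    expect_true(all(abs(tab - expected) <= 1)) # within one sample
  }
})

test_that("preprocessing and selection never leak the held-out fold", {
  d <- separable_data(n = 50, sd = 0.4, seed = 8)
  fold <- fivegaze:::with_seed(11, fivegaze:::stratified_folds(d$y, 5))
  xc <- d$x
  xc[fold == 1, ] <- xc[fold == 1, ] + 1e6 # wild shift of fold 1's rows
  for (sel in list(selection_spec("mutual_information", k_top = 3),
                   selection_spec("lasso"))) {
    r0 <- suppressWarnings(
      crossvalidate(d$x, d$y, classifier = "LR", selection = sel, seed = 11))
    rc <- suppressWarnings(
      crossvalidate(xc, d$y, classifier = "LR", selection = sel, seed = 11))
    # fold 1 fits on untouched rows: had imputation medians, scaling or the
    # selection statistics seen the corrupted held-out rows, the quantile
    # bins / penalty path would pick different features
    expect_identical(rc$selected_by_fold[[1]], r0$selected_by_fold[[1]],
                     label = sel$method)
  }
})

test_that("single-class labels and degenerate inputs error cleanly", {
  d <- separable_data()
  expect_error(crossvalidate(d$x, factor(rep("low", 60)), seed = 1),
               "single-class")
  expect_warning(
    crossvalidate(d$x[1:12, ], d$y[1:12], classifier = "NB",
                  selection = selection_spec("none"), n_folds = 5, seed = 1),
    "stratification")
})

test_that("the benchmark grid covers every cell and averages per method", {
  coh <- generate_cohort(18, 1, seed = 6,
                         protocol = stimulus_protocol(n_trials = 2))
  feat <- extract_features(coh)
  lab <- label_table(coh$inventory)
  labels_by_trait <- as.data.frame(lapply(trait_names(), function(tr) {
    lab$level[lab$trait == tr][match(rownames(feat), coh$inventory$participant_id)]
  }))
  names(labels_by_trait) <- trait_names()
  bench <- suppressWarnings(run_benchmark(
    feat, labels_by_trait[, c("TYa", "Yy")],
    classifiers = c("LR", "NB"),
    selections = list(none = selection_spec("none"),
                      mutual_information = selection_spec("mutual_information",
                                                          k_top = 5)),
    n_folds = 3, seed = 2))
  expect_identical(nrow(bench$grid), 2L * 2L * 2L)
  expect_identical(nrow(bench$by_method), 4L)
  expect_true(all(!bench$grid$failed))
  expect_true(all(bench$grid$accuracy >= 0 & bench$grid$accuracy <= 1))
  # restricting the grid restricts the rows
  bench2 <- suppressWarnings(run_benchmark(
    feat, labels_by_trait["TYa"], classifiers = "LR",
    selections = list(lasso = selection_spec("lasso")), n_folds = 3, seed = 2))
  expect_identical(nrow(bench2$grid), 1L)
})
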
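# Paired comparison of pipeline variants: Friedman's rank test with tie
# correction and Dunn / Bonferroni-paired post-hoc tables. The rank
# machinery is authored here from the formulas; tests cross-check it against
# an exact within-block permutation enumeration and stats::friedman.test.

#' Validate a paired score matrix
#'
#' Rows are blocks (e.g. classifiers), columns treatments (e.g. selection
#' methods); every cell must be observed.
#'
#' @param m numeric matrix, >= 2 rows and >= 2 columns, no missing cells.
#' @return the matrix, invisibly validated.
#' @export
paired_score_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 blocks and >= 2 treatments")
  if (anyNA(m)) stop("missing cells in paired score matrix")
  m
}

#' Friedman rank test
#'
#' Within-block midranks; the chi-square statistic
#' `12n/(k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2` with the standard tie
#' correction (divide by `1 - sum(t^3 - t) / (n k (k^2 - 1))`), `df = k - 1`.
#'
#' The p-value comes from the exact permutation distribution (all `(k!)^n`
#' within-block orderings of the observed scores) when that enumeration is
#' small, and from the upper chi-square tail otherwise; the chi-square
#' approximation is visibly conservative at the matrix sizes where the exact
#' path takes over.
#'
#' @param m a [paired_score_matrix()] (blocks x treatments).
#' @param p_method `"auto"` (exact when `(k!)^n <= 20000`, else asymptotic),
#'   `"exact"` or `"asymptotic"`.
#' @return List with `statistic`, `df`, `p_value`, `p_method` and
#'   `mean_ranks`.
#' @export
friedman_test <- function(m, p_method = c("auto", "exact", "asymptotic")) {
  p_method <- match.arg(p_method)
  m <- paired_score_matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  stat_of <- function(mat) {
    ranks <- t(apply(mat, 1, rank)) # midranks for ties
    rbar <- colMeans(ranks)
    s <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
    tie_sum <- sum(apply(mat, 1, function(row) {
      tt <- table(row)
      sum(tt^3 - tt)
    }))
    corr <- 1 - tie_sum / (n * k * (k^2 - 1))
    list(stat = if (corr > 0) s / corr else 0, rbar = rbar)
  }
  obs <- stat_of(m)
  df <- k - 1
  n_perm <- factorial(k)^n
  if (p_method == "auto") {
    p_method <- if (n_perm <= 20000) "exact" else "asymptotic"
  }
  if (p_method == "exact") {
    if (n_perm > 5e6) stop("exact enumeration infeasible for this matrix size")
    pk <- perm_list(k)
    count <- 0
    idx <- rep(1L, n)
    repeat {
      mm <- m
      for (b in seq_len(n)) mm[b, ] <- m[b, pk[[idx[b]]]]
      if (stat_of(mm)$stat >= obs$stat - 1e-12) count <- count + 1
      # odometer increment over the n-digit base-(k!) counter
      b <- 1L
      while (b <= n) {
        idx[b] <- idx[b] + 1L
        if (idx[b] <= length(pk)) break
        idx[b] <- 1L
        b <- b + 1L
      }
      if (b > n) break
    }
    p <- count / n_perm
  } else {
    p <- stats::pchisq(obs$stat, df = df, lower.tail = FALSE)
  }
  list(statistic = obs$stat, df = df, p_value = p, p_method = p_method,
       mean_ranks = stats::setNames(obs$rbar, colnames(m)))
}

# All permutations of 1..k (k small).
perm_list <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in perm_list(k - 1L)) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1]] <- append(p, k, after = pos)
    }
  }
  out
}

#' Post-hoc pairwise comparisons after a Friedman test
#'
#' Two flavours: `"dunn"` compares treatments by mean-rank differences,
#' `z = (Rbar_i - Rbar_j) / sqrt(k(k+1)/(6n))`, two-sided normal p-values
#' with Bonferroni multiplicity adjustment; `"bonferroni_paired"` runs
#' paired t-tests on the raw scores with p multiplied by the number of
#' comparisons (capped at 1).
#'
#' @param m a [paired_score_matrix()].
#' @param method `"dunn"` or `"bonferroni_paired"`.
#' @return Data frame with one row per treatment pair: `treatment_i`,
#'   `treatment_j`, the test statistic (`z` or `t`), `p_unadjusted`,
#'   `p_adjusted`.
#' @export
posthoc_pairwise <- function(m, method = c("dunn", "bonferroni_paired")) {
  method <- match.arg(method)
  m <- paired_score_matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  cn <- colnames(m) %||% paste0("T", seq_len(k))
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  rows <- vector("list", n_comp)
  if (method == "dunn") {
    rbar <- colMeans(t(apply(m, 1, rank)))
    se <- sqrt(k * (k + 1) / (6 * n))
    for (q in seq_len(n_comp)) {
      i <- pairs[1, q]; j <- pairs[2, q]
      z <- (rbar[i] - rbar[j]) / se
      p <- 2 * stats::pnorm(-abs(z))
      rows[[q]] <- data.frame(treatment_i = cn[i], treatment_j = cn[j],
                              statistic = z, p_unadjusted = p,
                              p_adjusted = min(1, p * n_comp))
    }
  } else {
    for (q in seq_len(n_comp)) {
      i <- pairs[1, q]; j <- pairs[2, q]
      d <- m[, i] - m[, j]
      if (stats::sd(d) == 0) {
        tt <- list(statistic = c(t = 0), p.value = 1)
      } else {
        tt <- stats::t.test(m[, i], m[, j], paired = TRUE)
      }
      rows[[q]] <- data.frame(treatment_i = cn[i], treatment_j = cn[j],
                              statistic = unname(tt$statistic),
                              p_unadjusted = tt$p.value,
                              p_adjusted = min(1, tt$p.value * n_comp))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Comparison report for a paired score matrix
#'
#' Bundles the Friedman test and a post-hoc table, optionally written as
#' JSON.
#'
#' @param m a [paired_score_matrix()].
#' @param posthoc post-hoc method, see [posthoc_pairwise()].
#' @param path optional JSON output path.
#' @return List with `friedman`, `posthoc` and the input `matrix`.
#' @export
comparison_report <- function(m, posthoc = "dunn", path = NULL) {
  m <- paired_score_matrix(m)
  out <- list(friedman = friedman_test(m),
              posthoc = posthoc_pairwise(m, posthoc),
              matrix = m)
  if (!is.null(path)) {
    jsonlite::write_json(
      list(friedman = out$friedman[c("statistic", "df", "p_value")],
           posthoc = out$posthoc,
           matrix = as.data.frame(m)),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
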
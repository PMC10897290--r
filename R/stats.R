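# Group-comparison statistics policy: two-sided Mann-Whitney by default,
# Welch's t only when both samples pass a Shapiro-Wilk normality gate, with
# pairwise comparisons against a reference (wild-type) group and no multiple
# testing correction by default (a Holm adjustment is optional).

#' Choose the two-sample test by a normality gate
#'
#' Welch's t test is used only when both samples pass the Shapiro-Wilk test at
#' `alpha_normality`; otherwise the Mann-Whitney test.
#'
#' @param sample_a,sample_b numeric samples with at least 3 values each.
#' @param alpha_normality normality significance level (default 0.05).
#' @return `"welch_t"` or `"mann_whitney"`.
#' @export
choose_test <- function(sample_a, sample_b, alpha_normality = 0.05) {
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stopf("the normality gate needs at least 3 values per sample")
  pa <- shapiro_p(sample_a)
  pb <- shapiro_p(sample_b)
  if (pa > alpha_normality && pb > alpha_normality) "welch_t" else "mann_whitney"
}

shapiro_p <- function(x) {
  if (stats::sd(x) == 0) return(0)   # degenerate sample is not Gaussian
  if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
  stats::shapiro.test(x)$p.value
}

#' Two-sided Mann-Whitney test
#'
#' Exact p-value (full enumeration over rank assignments) when both samples
#' have at most `exact_threshold` observations and there are no ties;
#' otherwise the normal approximation with tie and continuity corrections.
#' The branch used is recorded in the result.
#'
#' @param sample_a,sample_b nonempty numeric samples.
#' @param exact_threshold maximum per-sample size for the exact branch
#'   (default 8).
#' @return an object of class `crista_test` with the U statistic, p-value,
#'   sample sizes and the branch used.
#' @export
mann_whitney <- function(sample_a, sample_b, exact_threshold = 8L) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stopf("samples must be nonempty")
  pooled <- c(sample_a, sample_b)
  if (length(unique(pooled)) == 1L) {
    # every observation tied: no evidence against the null
    return(structure(list(test_name = "mann_whitney",
                          statistic = length(sample_a) * length(sample_b) / 2,
                          p_value = 1, n_a = length(sample_a),
                          n_b = length(sample_b), exact = FALSE,
                          normality_p_a = NA_real_, normality_p_b = NA_real_),
                     class = "crista_test"))
  }
  ties <- any(duplicated(pooled))
  use_exact <- !ties && length(sample_a) <= exact_threshold &&
    length(sample_b) <= exact_threshold
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            alternative = "two.sided",
                                            exact = use_exact, correct = TRUE))
  structure(list(
    test_name = "mann_whitney",
    statistic = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    n_a = length(sample_a), n_b = length(sample_b),
    exact = use_exact,
    normality_p_a = NA_real_, normality_p_b = NA_real_
  ), class = "crista_test")
}

#' Welch's two-sample t test
#'
#' Two-sided, with Welch-Satterthwaite degrees of freedom.  Two samples that
#' are both constant at the same value return p = 1 by contract; constant at
#' different values is degenerate and errors.
#'
#' @param sample_a,sample_b numeric samples with at least 2 values each.
#' @return an object of class `crista_test`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stopf("Welch's t needs at least 2 values per sample")
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(structure(list(test_name = "welch_t", statistic = 0, p_value = 1,
                            n_a = length(sample_a), n_b = length(sample_b),
                            df = NA_real_, exact = FALSE,
                            normality_p_a = NA_real_, normality_p_b = NA_real_),
                       class = "crista_test"))
    }
    stopf("both samples are constant with different means: t is degenerate")
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  structure(list(
    test_name = "welch_t",
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    n_a = length(sample_a), n_b = length(sample_b),
    df = unname(tt$parameter), exact = FALSE,
    normality_p_a = NA_real_, normality_p_b = NA_real_
  ), class = "crista_test")
}

#' @export
print.crista_test <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4g, p = %.4g (n = %d vs %d%s)\n",
              x$test_name, x$statistic, x$p_value, x$n_a, x$n_b,
              if (isTRUE(x$exact)) ", exact" else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Group tables

#' Assemble a long-format group table
#'
#' @param group character vector of group labels.
#' @param unit_id per-row measurement unit identifier.
#' @param metric metric name.
#' @param value numeric value.
#' @return a data.frame with those four columns.
#' @export
group_table <- function(group, unit_id, metric, value) {
  if (any(!is.finite(value))) stopf("group table values must be finite")
  data.frame(group = as.character(group), unit_id = unit_id,
             metric = as.character(metric), value = value,
             stringsAsFactors = FALSE)
}

#' Per-group summary (mean, SD, n)
#'
#' @param table a [group_table()].
#' @return a data.frame with one row per group x metric: mean, sd, n.
#' @export
summarize_groups <- function(table) {
  stopifnot(all(c("group", "metric", "value") %in% names(table)))
  agg <- stats::aggregate(value ~ group + metric, data = table,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(group = agg$group, metric = agg$metric,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$metric, out$group), , drop = FALSE]
}

#' Pairwise group comparisons against a reference
#'
#' For every metric and every non-reference group, gates the test choice on
#' Shapiro-Wilk normality of both samples, runs the chosen test, and reports
#' one row per comparison.  No multiple-testing correction is applied by
#' default; `adjust = "holm"` adds Holm-adjusted p-values.
#'
#' @param table a [group_table()].
#' @param reference reference group label (default `"WT"`).
#' @param alpha_normality normality gate level (default 0.05).
#' @param adjust `"none"` (default) or `"holm"`.
#' @param drop_outliers optionally re-run after removing per-sample values
#'   outside 1.5 IQR of the quartiles (sensitivity check, default FALSE).
#' @return a data.frame: metric, groups, test name and branch, statistic,
#'   p-value, sample sizes and normality p-values.
#' @export
compare_groups <- function(table, reference = "WT", alpha_normality = 0.05,
                           adjust = c("none", "holm"), drop_outliers = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("group", "metric", "value") %in% names(table)))
  if (!reference %in% table$group)
    stopf("reference group '%s' not present in the table", reference)
  trim <- function(v) {
    if (!drop_outliers || length(v) < 4L) return(v)
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    v[v >= q[1] - 1.5 * iqr & v <= q[2] + 1.5 * iqr]
  }
  rows <- list()
  for (m in unique(table$metric)) {
    sub <- table[table$metric == m, ]
    ref_v <- trim(sub$value[sub$group == reference])
    for (grp in setdiff(unique(sub$group), reference)) {
      v <- trim(sub$value[sub$group == grp])
      if (length(ref_v) < 3L || length(v) < 3L) next
      pa <- shapiro_p(ref_v); pb <- shapiro_p(v)
      tn <- if (pa > alpha_normality && pb > alpha_normality) "welch_t" else "mann_whitney"
      res <- if (tn == "welch_t") welch_t(ref_v, v) else mann_whitney(ref_v, v)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group_a = reference, group_b = grp,
        test_name = res$test_name, exact = isTRUE(res$exact),
        statistic = res$statistic, p_value = res$p_value,
        n_a = res$n_a, n_b = res$n_b,
        normality_p_a = pa, normality_p_b = pb,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no comparable groups (need >= 3 values per sample)")
  if (adjust == "holm") out$p_adjusted <- stats::p.adjust(out$p_value, "holm")
  rownames(out) <- NULL
  out
}
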
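# Cohort pooling and group comparison of per-mitochondrion metrics.

#' Per-group summary of a metric
#'
#' n, mean and s.e.m. (sample SD / sqrt(n)) of one metric per group.
#' Missing values (e.g. the undefined average distance of zero-contact
#' mitochondria) are excluded and counted.
#'
#' @param table data.frame of per-mitochondrion metrics (e.g.
#'   `measure_scene()$metrics` rows bound across scenes).
#' @param metric name of the numeric column to summarise.
#' @param group_col name of the grouping column.
#' @return `data.frame` with columns `group`, `n`, `n_missing`, `mean`,
#'   `sem`.
#' @export
summarize_groups <- function(table, metric, group_col = "group") {
  stopifnot(is.data.frame(table), metric %in% names(table),
            group_col %in% names(table))
  v <- table[[metric]]
  if (!is.numeric(v)) stop("metric '", metric, "' is not numeric")
  out <- lapply(split(v, table[[group_col]]), function(g) {
    ok <- g[!is.na(g)]
    if (length(ok) < 2L)
      stop("group has fewer than 2 non-missing values for '", metric, "'")
    data.frame(n = length(ok), n_missing = sum(is.na(g)),
               mean = mean(ok), sem = stats::sd(ok) / sqrt(length(ok)))
  })
  res <- cbind(data.frame(group = names(out)), do.call(rbind, out))
  rownames(res) <- NULL
  if (any(res$n_missing > 0))
    message(sum(res$n_missing), " missing value(s) excluded from '",
            metric, "' summaries")
  res
}

#' Two-sample comparison of a metric between groups
#'
#' Two-tailed unpaired t-test on a per-mitochondrion metric with every data
#' point included (the mitochondrion, not the cell, is the experimental
#' unit by default).  The default is Student's pooled-variance test;
#' Welch's is available.  Degenerate zero-variance inputs: equal means give
#' t = 0, p = 1 by convention; unequal means are an error.
#'
#' @inheritParams summarize_groups
#' @param group_a,group_b the two group labels; default the two groups
#'   present in the table.
#' @param test `"student"` (pooled variance) or `"welch"`.
#' @param unit `"mitochondrion"` (all data points) or `"cell"` (average per
#'   cell first, requires `cell_col`).
#' @param cell_col column identifying cells for `unit = "cell"`.
#' @return object of class `contact_test`: a list with group labels and
#'   sizes, means, s.e.m.s, `t`, `df`, `p_value`, `test` and the number of
#'   excluded missing values.
#' @export
compare_groups <- function(table, metric, group_a = NULL, group_b = NULL,
                           group_col = "group",
                           test = c("student", "welch"),
                           unit = c("mitochondrion", "cell"),
                           cell_col = "cell_id") {
  test <- match.arg(test)
  unit <- match.arg(unit)
  stopifnot(is.data.frame(table), metric %in% names(table),
            group_col %in% names(table))
  if (is.null(group_a) || is.null(group_b)) {
    groups <- unique(as.character(table[[group_col]]))
    if (length(groups) != 2L)
      stop("table has ", length(groups),
           " groups; specify group_a and group_b")
    group_a <- groups[1L]; group_b <- groups[2L]
  }
  pick <- function(g) {
    sub <- table[table[[group_col]] == g, , drop = FALSE]
    if (!nrow(sub)) stop("group '", g, "' not found")
    v <- sub[[metric]]
    if (unit == "cell") {
      if (!cell_col %in% names(sub)) stop("missing cell column '", cell_col, "'")
      v <- tapply(v, sub[[cell_col]], mean, na.rm = TRUE)
    }
    v
  }
  va <- pick(group_a); vb <- pick(group_b)
  n_excluded <- sum(is.na(va)) + sum(is.na(vb))
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) < 2L || length(vb) < 2L)
    stop("each group needs at least 2 non-missing values")
  if (stats::var(va) == 0 && stats::var(vb) == 0) {
    if (mean(va) != mean(vb))
      stop("zero variance in both groups with unequal means; ",
           "t statistic undefined")
    tt <- list(statistic = c(t = 0),
               parameter = c(df = length(va) + length(vb) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(va, vb, var.equal = test == "student")
  }
  structure(list(metric = metric, test = test, unit = unit,
                 group_a = group_a, group_b = group_b,
                 n_a = length(va), n_b = length(vb),
                 mean_a = mean(va), mean_b = mean(vb),
                 sem_a = stats::sd(va) / sqrt(length(va)),
                 sem_b = stats::sd(vb) / sqrt(length(vb)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n_excluded = n_excluded),
            class = "contact_test")
}

#' @export
print.contact_test <- function(x, ...) {
  cat(sprintf("Two-tailed unpaired t-test (%s) on %s, unit = %s\n",
              x$test, x$metric, x$unit))
  cat(sprintf("  %s: n = %d, mean = %.5g +/- %.3g (s.e.m.)\n",
              x$group_a, x$n_a, x$mean_a, x$sem_a))
  cat(sprintf("  %s: n = %d, mean = %.5g +/- %.3g (s.e.m.)\n",
              x$group_b, x$n_b, x$mean_b, x$sem_b))
  cat(sprintf("  t = %.4f, df = %.4g, p = %.4g\n", x$t, x$df, x$p_value))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d missing value(s) excluded)\n", x$n_excluded))
  invisible(x)
}
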
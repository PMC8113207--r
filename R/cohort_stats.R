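# Cohort statistics: Pearson correlations with two-tailed t tests,
# Kruskal-Wallis across visual grades, apical-sparing prevalence, and the
# assembled correlation report.
#
# No multiple-testing adjustment is applied anywhere: every p value is
# reported raw, and the 0.05 threshold is a reporting convention, never a
# row filter.

#' Pearson correlation with a two-tailed t test
#'
#' Complete-case product-moment correlation; the p value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-tailed. Perfect correlations get `p = 0`.
#'
#' @param x,y numeric vectors of equal length; pairs with a missing member
#'   are dropped first.
#' @param label optional pair label carried into the result.
#' @return list with `label`, `r`, `p`, `n_used`.
#' @examples
#' pearson(1:5, c(2, 1, 4, 3, 5))  # r = 0.8, p ~ 0.104
#' @export
pearson <- function(x, y, label = "") {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete pairs (", label, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (zero-variance) input (", label, ")")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(label = label, r = r, p = p, n_used = n)
}

#' Base-10 logarithm of a positive biomarker vector
#'
#' Summaries of log-transformed biomarkers are means of per-subject logs,
#' not logs of means. Missing values pass through.
#'
#' @param values numeric vector, strictly positive where non-missing.
#' @return elementwise `log10(values)`.
#' @export
log10_transform <- function(values) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad))
    stop("non-positive value(s) at position(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  log10(values)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H with mid-ranks for ties and the standard tie-correction
#' factor; p from a chi-square with `k - 1` degrees of freedom. When every
#' observation is identical the statistic is defined as 0 (`p = 1`).
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return list with `H`, `p`, `df`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))  # H = 7.2, p ~ 0.027
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of >= 2 vectors")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("empty group at position ",
                             which(sizes == 0L)[1])
  pooled <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(pooled))) stop("non-finite values in groups")
  N <- length(pooled)
  rk <- rank(pooled)  # mid-ranks for ties
  grp <- rep(seq_along(groups), sizes)
  rank_sums <- tapply(rk, grp, sum)
  H <- 12 / (N * (N + 1)) * sum(rank_sums^2 / sizes) - 3 * (N + 1)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (C > 0) H / C else 0
  df <- length(groups) - 1L
  p <- if (C > 0) stats::pchisq(H, df = df, lower.tail = FALSE) else 1
  list(H = H, p = p, df = df)
}

#' Assemble the full uptake-vs-strain / biomarker correlation report
#'
#' For each uptake metric (`dpd_load`, `dpd_mean`, `dpd_max`): the metric in
#' each of the five strain regions against the matched regional strain, then
#' the ventricles metric against troponin T, NT-ProBNP, and log10
#' NT-ProBNP. Complete-case per pair, so `n_used` varies across rows
#' exactly as the measurement availability dictates.
#'
#' @param cohort a `cohort_table` (see [make_cohort()] / [read_cohort()]).
#' @return `data.frame` with columns `metric`, `pair`, `region`, `r`, `p`,
#'   `n_used`.
#' @export
build_correlation_report <- function(cohort) {
  rows <- list()
  add <- function(metric, pair, region, x, y) {
    res <- pearson(x, y, label = paste(metric, pair))
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, pair = pair, region = region,
      r = res$r, p = res$p, n_used = res$n_used, stringsAsFactors = FALSE)
  }
  lognt <- if ("log10_nt_probnp" %in% names(cohort)) cohort$log10_nt_probnp
           else log10_transform(cohort$nt_probnp)
  for (m in c("dpd_load", "dpd_mean", "dpd_max")) {
    for (reg in .strain_regions)
      add(m, paste0("strain_", reg), reg,
          cohort[[paste0(m, "_", reg)]], cohort[[paste0("strain_", reg)]])
    vent <- cohort[[paste0(m, "_VENTRICLES")]]
    add(m, "troponin_t", "VENTRICLES", vent, cohort$troponin_t)
    add(m, "nt_probnp", "VENTRICLES", vent, cohort$nt_probnp)
    add(m, "log10_nt_probnp", "VENTRICLES", vent, lognt)
  }
  do.call(rbind, rows)
}

#' Fraction of subjects with relative apical sparing
#'
#' @param cohort a `cohort_table` with an `echo_sparing_ratio` column, or a
#'   numeric vector of per-subject ratios.
#' @return fraction of (non-missing) ratios strictly above 1.
#' @export
sparing_prevalence <- function(cohort) {
  ratios <- if (is.numeric(cohort)) cohort else cohort$echo_sparing_ratio
  if (is.null(ratios)) stop("no echo sparing ratios available")
  mean(ratios > 1, na.rm = TRUE)
}

#' Burden-vs-grade comparisons
#'
#' Kruskal-Wallis of a burden column across visual grades: the omnibus test
#' over all grades plus each pairwise two-group comparison.
#'
#' @param cohort a `cohort_table`.
#' @param column burden column, default `"dpd_load_LV"`.
#' @return list with `omnibus` (H, p, df) and `pairwise`, a `data.frame`
#'   with one row per grade pair.
#' @export
grade_burden_tests <- function(cohort, column = "dpd_load_LV") {
  if (!column %in% names(cohort)) stop("no column '", column, "' in cohort")
  ok <- is.finite(cohort[[column]]) & !is.na(cohort$perugini_grade)
  vals <- cohort[[column]][ok]
  grades <- cohort$perugini_grade[ok]
  lv <- sort(unique(grades))
  if (length(lv) < 2L) stop("need at least two grades present")
  groups <- lapply(lv, function(g) vals[grades == g])
  omnibus <- kruskal_wallis(groups)
  pairs <- utils::combn(seq_along(lv), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    res <- kruskal_wallis(groups[c(i, j)])
    data.frame(grade_a = lv[i], grade_b = lv[j], H = res$H, p = res$p)
  }))
  list(omnibus = omnibus, pairwise = pw)
}
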
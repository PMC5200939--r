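#' Per-group median and range
#'
#' @param values numeric vector.
#' @param labels group label per value.
#' @return tibble with `group`, `n`, `median` (midpoint convention for even
#'   n), `min`, `max`.
#' @export
group_summary <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  bind_rows(lapply(split(values, labels), function(v)
    tibble(n = length(v), median = median(v), min = min(v), max = max(v))),
    .id = "group")
}

#' Unpaired two-tailed t-test
#'
#' Classical two-sample Student t-test with pooled variance (the default
#' here, since the reference analysis names only "unpaired 2-tailed t-test";
#' note that plain `t.test()` in R defaults to the Welch form — set
#' `var_equal = FALSE` for that). When both groups are constant, equal means
#' return `t = 0, p = 1` by convention; otherwise degenerate variance is an
#' error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance Student test (`TRUE`, default) or Welch.
#' @return list with `t`, `p` (two-tailed), `df`, `mean_a`, `mean_b`.
#' @export
ttest_unpaired <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("degenerate variance in both groups with unequal means")
  }
  fit <- stats::t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  list(t = unname(fit$statistic), p = fit$p.value, df = unname(fit$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' Compare diversity statistics between cohort arms
#'
#' Runs the unpaired two-tailed t-test for each requested statistic and group
#' pair over a cohort diversity table, reporting medians and ranges alongside
#' the test. All raw p-values are printed together; no multiplicity
#' correction is applied (users may correct downstream).
#'
#' @param diversity tibble from [cohort_diversity()].
#' @param statistics which columns to compare.
#' @param pairs list of 2-vectors of group labels; default: all pairs present.
#' @param var_equal see [ttest_unpaired()].
#' @return tibble with one row per (statistic, subset, pair): group medians,
#'   ranges, `t` and `p`.
#' @export
compare_groups <- function(diversity,
                           statistics = c("entropy", "hec_count", "hec_ratio"),
                           pairs = NULL, var_equal = TRUE) {
  groups <- unique(diversity$group)
  if (is.null(pairs)) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  }
  rows <- list()
  for (sub in unique(diversity$subset)) {
    d <- diversity[diversity$subset == sub, ]
    for (stat in statistics) for (pr in pairs) {
      va <- d[[stat]][d$group == pr[1]]
      vb <- d[[stat]][d$group == pr[2]]
      if (length(va) < 2 || length(vb) < 2) next
      tt <- ttest_unpaired(va, vb, var_equal = var_equal)
      rows[[length(rows) + 1L]] <- tibble(
        statistic = stat, subset = sub, group_a = pr[1], group_b = pr[2],
        median_a = median(va), min_a = min(va), max_a = max(va),
        median_b = median(vb), min_b = min(vb), max_b = max(vb),
        t = tt$t, p = tt$p)
    }
  }
  bind_rows(rows)
}
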
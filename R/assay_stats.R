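#' Summarise per-cell calls into per-field percent-positive values
#'
#' Percentages use the evaluable-cell count as denominator (cells with an
#' empty ring mask are excluded and reported in `n_excluded`). The
#' conditional percentage `pct_gh2ax_of_which_bleb` -- the fraction of
#' gamma-H2AX-positive cells that are also CC3(bleb)-positive -- uses the
#' gamma-H2AX-positive count as denominator and is `NA` when that count is
#' zero.
#'
#' @param calls Per-cell data frame from [call_cells()].
#' @param field_id Field identifier.
#' @param group_label Treatment-group label.
#' @return One-row data frame of class `field_summary`.
#' @export
summarize_field <- function(calls, field_id, group_label = NA_character_) {
  ev <- calls[which(calls$evaluable), , drop = FALSE]
  n <- nrow(ev)
  if (n == 0L)
    stop("zero evaluable cells in field ", field_id,
         ": refusing to report a silent 0%")
  pct <- function(x) 100 * sum(x) / n
  n_gh <- sum(ev$gh2ax_pos)
  out <- data.frame(
    field_id = field_id,
    group_label = group_label,
    n_cells = n,
    n_excluded = nrow(calls) - n,
    pct_cyto_cc3 = pct(ev$cyto_cc3_pos),
    pct_bleb = pct(ev$cc3_bleb_pos),
    pct_gh2ax = pct(ev$gh2ax_pos),
    pct_coloc = pct(ev$coloc_pos),
    pct_gh2ax_of_which_bleb =
      if (n_gh > 0) 100 * sum(ev$coloc_pos) / n_gh else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("field_summary", class(out))
  out
}

#' Two-sample Mann-Whitney U test
#'
#' Rank-based nonparametric comparison of per-field percentages between two
#' treatment groups. The exact permutation null is used when the smaller
#' group has at most 8 observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. The test is two-sided and symmetric in its arguments.
#'
#' @param a,b Numeric vectors of per-field values (each nonempty).
#' @param metric Optional name of the compared percentage.
#' @param group_a,group_b Optional group labels carried into the result.
#' @param exact_max_n Largest min-group size for which the exact null is
#'   enumerated (default 8).
#' @return One-row data frame of class `group_comparison`: `u_statistic`
#'   (U of the first sample), `p_value`, `method` (`"exact"` or
#'   `"normal-approximation"`) and significance `stars`.
#' @export
mann_whitney <- function(a, b, metric = NA_character_,
                         group_a = "A", group_b = "B", exact_max_n = 8L) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (anyNA(a) || anyNA(b)) stop("missing values in group data")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= exact_max_n && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  out <- data.frame(
    group_a = group_a, group_b = group_b, metric = metric,
    n_a = length(a), n_b = length(b),
    u_statistic = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    method = if (exact) "exact" else "normal-approximation",
    stars = significance_stars(min(wt$p.value, 1)),
    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Significance stars at conventional strict thresholds
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001 and `****` for p < 0.0001 (all strict inequalities).
#'
#' @param p A p-value in (0, 1].
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    stop("p must be a single value in (0, 1]")
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Compare groups across per-field summaries
#'
#' Runs [mann_whitney()] for each configured contrast on a table of
#' per-field summaries.
#'
#' @param summaries Data frame of stacked [summarize_field()] rows.
#' @param comparisons List of lists with elements `group_a`, `group_b`,
#'   `metric` (a percentage column of the summaries).
#' @return Data frame with one row per contrast.
#' @export
compare_groups <- function(summaries, comparisons) {
  rows <- lapply(comparisons, function(cmp) {
    a <- summaries[summaries$group_label == cmp$group_a, cmp$metric]
    b <- summaries[summaries$group_label == cmp$group_b, cmp$metric]
    if (!length(a) || !length(b))
      stop("no fields found for contrast ", cmp$group_a, " vs ",
           cmp$group_b)
    mann_whitney(a, b, metric = cmp$metric, group_a = cmp$group_a,
                 group_b = cmp$group_b)
  })
  do.call(rbind, rows)
}
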
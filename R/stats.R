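# Reporting layer: per-genotype summaries (mean +/- SD, n) and pairwise
# Student's t-tests with NS / * / ** significance labels.

#' Summarise one genotype group
#'
#' @param values Numeric metric values (PN or SE), one per animal; `NA`s are
#'   dropped. At least 2 values required.
#' @param genotype Group label.
#' @param metric Metric name, `"pn"` or `"se"`.
#' @return One-row data.frame: `genotype`, `metric`, `n`, `mean`, `sd`
#'   (sample SD, n - 1 denominator).
#' @export
summarize_group <- function(values, genotype = NA_character_,
                            metric = c("se", "pn")) {
  metric <- match.arg(metric)
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("at least 2 values are required for a group summary", call. = FALSE)
  }
  data.frame(genotype = genotype, metric = metric, n = length(values),
             mean = mean(values), sd = stats::sd(values))
}

# p-value -> significance label, thresholds fixed at 0.05 and 0.01.
significance_label <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS"))
}

#' Two-group Student's t-test with significance label
#'
#' Two-sided t-test between two groups of per-animal metric values. The
#' default is the classical pooled-variance Student's t; Welch's unequal
#' variance variant is available as an option. Degenerate inputs where both
#' groups are constant are handled explicitly: identical constants give
#' t = 0, p = 1; distinct constants give infinite t and p = 0.
#'
#' Labels: `**` for p < 0.01, `*` for p < 0.05, `NS` otherwise.
#'
#' @param a,b Numeric vectors (n >= 2 each after `NA` removal).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param group_a,group_b Labels recorded in the output row.
#' @return One-row data.frame: `group_a`, `group_b`, `t_stat`, `df`,
#'   `p_value`, `label`.
#' @export
compare_groups <- function(a, b, variant = c("pooled", "welch"),
                           group_a = "a", group_b = "b") {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                 parameter = length(a) + length(b) - 2, p.value = 0)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = (variant == "pooled"),
                        alternative = "two.sided")
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  data.frame(group_a = group_a, group_b = group_b,
             t_stat = tt$statistic, df = tt$parameter,
             p_value = tt$p.value, label = significance_label(tt$p.value))
}

#' Summaries and pairwise comparisons for a per-animal quantification table
#'
#' Convenience wrappers over [summarize_group()] and [compare_groups()] for
#' the per-animal CSV produced by the pipeline (one row per animal with a
#' genotype column and `pn` / `se` metric columns).
#'
#' @param quant Data.frame with at least columns `genotype` and the metric.
#' @param metric `"se"` or `"pn"`.
#' @param group_col Name of the grouping column.
#' @return `summarize_groups()`: one row per genotype.
#' @export
summarize_groups <- function(quant, metric = c("se", "pn"),
                             group_col = "genotype") {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(quant), metric %in% names(quant),
            group_col %in% names(quant))
  groups <- unique(quant[[group_col]])
  do.call(rbind, lapply(groups, function(g) {
    summarize_group(quant[[metric]][quant[[group_col]] == g], g, metric)
  }))
}

#' @rdname summarize_groups
#' @param ref Reference genotype each other group is tested against.
#' @param variant Passed to [compare_groups()].
#' @return `compare_to_reference()`: one row per non-reference genotype.
#' @export
compare_to_reference <- function(quant, metric = c("se", "pn"),
                                 group_col = "genotype", ref,
                                 variant = "pooled") {
  metric <- match.arg(metric)
  stopifnot(ref %in% quant[[group_col]])
  others <- setdiff(unique(quant[[group_col]]), ref)
  a <- quant[[metric]][quant[[group_col]] == ref]
  do.call(rbind, lapply(others, function(g) {
    compare_groups(a, quant[[metric]][quant[[group_col]] == g],
                   variant = variant, group_a = ref, group_b = g)
  }))
}
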
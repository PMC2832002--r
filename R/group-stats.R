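#' Group summary: mean, SEM, n
#'
#' @param values Numeric vector (n >= 1).
#' @param label Group label.
#' @return Object of class `group_summary` with `group`, `mean`, `sem`
#'   (sample SD / sqrt(n); 0 when n = 1) and `n`.
#' @export
#' @examples
#' group_summary(c(1, 2, 3), "demo")  # mean 2, sem 0.577
group_summary <- function(values, label = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) < 1)
    stop("group_summary: need at least one value", call. = FALSE)
  n <- length(values)
  sem <- if (n == 1) 0 else stats::sd(values) / sqrt(n)
  structure(list(group = label, mean = mean(values), sem = sem, n = n),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.3g (SEM), n = %d\n",
              if (is.na(x$group)) "group" else x$group, x$mean, x$sem, x$n))
  invisible(x)
}

#' Two-sample t-test with Bonferroni-adjusted significance
#'
#' Student's (pooled-variance) t-test by default, matching the reporting
#' convention for three-group pairwise comparisons where significance is
#' declared at alpha / m (e.g. P < 0.05/3 = 0.0167); Welch's test is
#' available via `welch = TRUE`. Tests are two-sided.
#'
#' @param a,b Numeric vectors, each with n >= 2.
#' @param m_comparisons Number of pairwise comparisons in the family.
#' @param base_alpha Family-wise alpha (default 0.05).
#' @param welch Use Welch's unequal-variance test instead of pooled.
#' @param labels Optional length-2 character vector naming the groups.
#' @return Object of class `comparison_result`: `p_value`,
#'   `adjusted_alpha` (= base_alpha / m_comparisons), `significant`,
#'   `groups`, `statistic`, `df`.
#' @export
compare_groups <- function(a, b, m_comparisons = 1, base_alpha = 0.05,
                           welch = FALSE, labels = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("compare_groups: each group needs n >= 2", call. = FALSE)
  if (m_comparisons < 1)
    stop("compare_groups: m_comparisons must be >= 1", call. = FALSE)
  p <- if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    # identical constant samples: no evidence of difference
    tt <- list(statistic = 0, parameter = length(a) + length(b) - 2)
    1
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
    unname(tt$p.value)
  }
  adj <- base_alpha / m_comparisons
  structure(list(p_value = p, adjusted_alpha = adj,
                 significant = p < adj,
                 groups = labels,
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 welch = welch, m_comparisons = m_comparisons),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s: p = %.4g (%s t-test), alpha_adj = %.4g -> %s\n",
              x$groups[1], x$groups[2], x$p_value,
              if (x$welch) "Welch" else "Student",
              x$adjusted_alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Phosphoform percentages from band/spot signals
#'
#' Expresses each signal (e.g. mono- and diphosphorylated band
#' intensities P1, P2) as a percentage of the summed signal; percentages
#' sum to 100.
#'
#' @param signals Named non-negative numeric vector of intensities.
#' @return Named percentages.
#' @export
#' @examples
#' phosphoform_percentages(c(P1 = 221, P2 = 779))  # 22.1 / 77.9
phosphoform_percentages <- function(signals) {
  if (any(!is.finite(signals)) || any(signals < 0))
    stop("phosphoform_percentages: signals must be finite and >= 0",
         call. = FALSE)
  tot <- sum(signals)
  if (tot <= 0)
    stop("phosphoform_percentages: all signals are zero", call. = FALSE)
  100 * signals / tot
}

#' Phospho/total ratios scaled to a reference group
#'
#' Computes the phospho-specific signal divided by the total signal for
#' each sample, then rescales so the reference-group mean equals 100
#' percent (the convention for reporting relative phosphorylation of,
#' e.g., TnI Ser23/24 or MYBP-C against perfused controls). The result is
#' invariant to any global rescaling of intensities.
#'
#' @param records Data frame with columns `sample_id`, `group`, `phospho`,
#'   `total`.
#' @param reference_group Group whose mean ratio defines 100 percent.
#' @return `records` with added columns `ratio` and `percent_of_reference`.
#' @export
relative_phosphorylation <- function(records, reference_group) {
  need_cols(records, c("sample_id", "group", "phospho", "total"),
            "relative_phosphorylation")
  if (any(records$total <= 0))
    stop("relative_phosphorylation: zero or negative total signal",
         call. = FALSE)
  if (!reference_group %in% records$group)
    stop("relative_phosphorylation: reference group not present",
         call. = FALSE)
  records$ratio <- records$phospho / records$total
  ref_mean <- mean(records$ratio[records$group == reference_group])
  if (ref_mean <= 0)
    stop("relative_phosphorylation: reference-group mean ratio is zero",
         call. = FALSE)
  records$percent_of_reference <- 100 * records$ratio / ref_mean
  records
}
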
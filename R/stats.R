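#' Recovery rate of a hemodynamic value relative to the pre-VF baseline
#'
#' @param epoch_value mean channel value over the epoch window.
#' @param baseline_value mean channel value in the pre-VF state (> 0).
#' @return recovery rate in percent of baseline.
#' @export
compute_recovery_rate <- function(epoch_value, baseline_value) {
  if (any(baseline_value <= 0)) stop("baseline_value must be positive")
  100 * epoch_value / baseline_value
}

#' Quartile-group and median-split labels for recovery rates
#'
#' Groups: 1 (< 25%), 2 (25-50%), 3 (50-75%), 4 (> 75%); a value exactly
#' on a boundary is assigned to the upper group. `above_median` is
#' `value > median` where the median is computed over the analyzed set
#' (override with `median_value`, e.g. a fixed 30% threshold).
#'
#' @param value_pct recovery rates in percent.
#' @param edges group boundaries in percent.
#' @param median_value optional fixed median-split threshold (percent).
#' @return data.frame `value_pct`, `quartile_group`, `above_median` with
#'   attribute `median_pct`.
#' @export
assign_recovery_groups <- function(value_pct, edges = c(25, 50, 75),
                                   median_value = NULL) {
  if (any(value_pct < 0)) stop("recovery rates must be nonnegative")
  med <- median_value %||% stats::median(value_pct)
  out <- data.frame(
    value_pct = value_pct,
    quartile_group = findInterval(value_pct, edges) + 1L,
    above_median = value_pct > med
  )
  attr(out, "median_pct") <- med
  out
}

#' Pearson correlation between a feature and the recovery rates
#'
#' Standard Pearson r with a two-sided p-value from the t transform;
#' pairs with an undefined feature are removed pairwise.
#'
#' @param feature numeric feature values.
#' @param recovery paired recovery rates.
#' @return list `r`, `p_value`, `n`, `n_dropped`.
#' @export
pearson_assoc <- function(feature, recovery) {
  stopifnot(length(feature) == length(recovery))
  ok <- stats::complete.cases(feature, recovery)
  x <- feature[ok]; y <- recovery[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       n_dropped = sum(!ok))
}

#' One-way ANOVA across recovery groups
#'
#' Classical fixed-effects between/within decomposition via `stats::lm`.
#'
#' @param groups list of numeric vectors (one per group), or a numeric
#'   vector with `g` a grouping factor.
#' @param g optional grouping factor when `groups` is a vector.
#' @return list `F`, `p_value`, `df`, `group_means`, `group_n`,
#'   `ss_between`, `ss_within`, `ss_total`.
#' @export
one_way_anova <- function(groups, g = NULL) {
  if (is.null(g)) {
    stopifnot(is.list(groups))
    if (any(vapply(groups, length, integer(1)) == 0))
      stop("every group must be non-empty")
    g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
    v <- unlist(groups)
  } else {
    v <- groups; g <- factor(g)
  }
  ok <- stats::complete.cases(v, g)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups")
  if (any(table(g) < 2)) stop("every group needs n >= 2")
  if (sum((v - stats::ave(v, g))^2) <= 1e-12 * (sum(v^2) + .Machine$double.xmin))
    stop("degenerate ANOVA: zero within-group variability")
  fit <- stats::lm(v ~ g)
  an <- stats::anova(fit)
  ss_b <- an$`Sum Sq`[1]; ss_w <- an$`Sum Sq`[2]
  list(F = an$`F value`[1], p_value = an$`Pr(>F)`[1],
       df = unname(an$Df), group_means = tapply(v, g, mean),
       group_n = as.vector(table(g)),
       ss_between = ss_b, ss_within = ss_w, ss_total = ss_b + ss_w)
}
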
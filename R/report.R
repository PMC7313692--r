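#' Association report: correlations, quartile ANOVA + Dunnett T3, ROC
#'
#' Pairs the epoch feature table with the epoch recovery rates and runs
#' the three association analyses:
#' \enumerate{
#'   \item Pearson correlation of each of the eleven parameters with the
#'     CBF recovery rate (undefined feature values removed pairwise and
#'     counted);
#'   \item one-way ANOVA of selected parameters across the four
#'     recovery-rate quartile groups, with Dunnett T3 post hoc pairwise
#'     comparisons;
#'   \item ROC analysis of selected parameters against the median-split
#'     recovery class, with Youden-index cut-offs.
#' }
#' By default the parameters carried into the ANOVA and ROC stages are
#' the three with the largest |r|.
#'
#' @param features data.frame from [feature_table()].
#' @param recovery data.frame from [assign_recovery_groups()], one row
#'   per epoch in the same order as `features`.
#' @param select_features character vector of parameters for the
#'   ANOVA/ROC stages, or `"top3"` (default).
#' @param alpha significance level recorded in the log.
#' @param out_dir optional directory; when given, writes
#'   `correlations.csv`, `anova_posthoc.csv`, `roc.csv`.
#' @return a `stats_report`: list `correlations`, `anova`, `posthoc`,
#'   `roc` (data.frames) and `log` (settings, counts, median split).
#' @export
build_report <- function(features, recovery, select_features = "top3",
                         alpha = 0.05, out_dir = NULL) {
  fn <- intersect(feature_names(), names(features))
  if (nrow(features) == 0 || length(fn) == 0)
    stop("empty feature table")
  stopifnot(nrow(features) == nrow(recovery))

  undef_counts <- vapply(features[fn], function(v) sum(is.na(v)), integer(1))
  cors <- do.call(rbind, lapply(fn, function(nm) {
    res <- pearson_assoc(features[[nm]], recovery$value_pct)
    data.frame(feature = nm, r = res$r, p_value = res$p_value, n = res$n)
  }))

  if (identical(select_features, "top3"))
    select_features <- cors$feature[order(-abs(cors$r))][1:3]

  anova_rows <- list(); posthoc_rows <- list(); roc_rows <- list()
  for (nm in select_features) {
    v <- features[[nm]]
    ok <- !is.na(v)
    grp <- split(v[ok], recovery$quartile_group[ok])
    grp <- grp[vapply(grp, length, integer(1)) >= 2]
    if (length(grp) >= 2) {
      an <- one_way_anova(grp)
      anova_rows[[nm]] <- data.frame(feature = nm, F = an$F,
                                     p_value = an$p_value,
                                     df_between = an$df[1], df_within = an$df[2])
      ph <- dunnett_t3(grp, group_names = names(grp))
      ph <- cbind(feature = nm, ph)
      posthoc_rows[[nm]] <- ph
    }
    roc <- roc_analysis(v, recovery$above_median)
    roc_rows[[nm]] <- data.frame(feature = nm, auc = roc$auc,
                                 standard_error = roc$standard_error,
                                 sensitivity = roc$sensitivity,
                                 one_minus_specificity = roc$one_minus_specificity,
                                 cut_off = roc$cut_off)
  }

  report <- list(
    correlations = cors,
    anova = if (length(anova_rows)) do.call(rbind, anova_rows) else NULL,
    posthoc = if (length(posthoc_rows)) do.call(rbind, posthoc_rows) else NULL,
    roc = do.call(rbind, roc_rows),
    log = list(alpha = alpha,
               n_epochs = nrow(features),
               undefined_feature_values = as.list(undef_counts),
               median_split_pct = attr(recovery, "median_pct"),
               selected_features = select_features,
               group_sizes = as.list(table(recovery$quartile_group)))
  )
  class(report) <- "stats_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$correlations,
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
    ap <- merge(report$anova, report$posthoc, by = "feature", sort = FALSE)
    utils::write.csv(ap, file.path(out_dir, "anova_posthoc.csv"),
                     row.names = FALSE)
    utils::write.csv(report$roc, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Pearson correlations with CBF recovery rate:\n")
  print(x$correlations[order(-abs(x$correlations$r)), ], row.names = FALSE)
  if (!is.null(x$anova)) {
    cat("\nQuartile-group ANOVA:\n"); print(x$anova, row.names = FALSE)
  }
  cat("\nROC (median split at", sprintf("%.1f%%", x$log$median_split_pct), "):\n")
  print(x$roc, row.names = FALSE)
  invisible(x)
}
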
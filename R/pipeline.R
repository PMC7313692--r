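#' Pre-VF baseline value of a hemodynamic channel
#'
#' Mean of the channel over the pre-VF baseline interval, excluding a
#' guard margin at both ends.
#'
#' @param rec a `recording` with a `vf_onset` event.
#' @param channel channel name.
#' @param guard_s margin excluded at the start of the recording and
#'   before VF onset (s).
#' @return mean channel value in the pre-VF state.
#' @export
baseline_value <- function(rec, channel = "cbf", guard_s = 5) {
  ch <- rec$channels[[channel]]
  if (is.null(ch)) stop("missing channel: ", channel)
  t_vf <- rec$events$time_s[rec$events$label == "vf_onset"]
  if (length(t_vf) == 0) stop("recording has no vf_onset event")
  i0 <- max(1, floor(guard_s * ch$fs))
  i1 <- floor((t_vf[1] - guard_s) * ch$fs)
  if (i1 <= i0) stop("baseline interval too short for guard margins")
  mean(ch$data[i0:i1])
}

#' Full-run configuration
#'
#' @param mode `"simulate"` (generate a cohort) or `"load"` (read
#'   recordings from `paths`).
#' @param n_subjects cohort size in simulate mode.
#' @param scenario a [scenario_config()].
#' @param coupling a [coupling_model()].
#' @param features a [feature_config()].
#' @param r_distribution per-session recovery-rate distribution.
#' @param alpha significance level for the report log.
#' @param group_edges quartile-group boundaries (percent).
#' @param median_value optional fixed median-split threshold (percent).
#' @param select_features parameters carried to the ANOVA/ROC stages
#'   (`"top3"` or names).
#' @param out_dir output directory (`NULL`: nothing written).
#' @param write_data also write the simulated raw data as CSV.
#' @param paths load mode: list of per-subject `list(data=, events=)`.
#' @param seed master seed; overrides `scenario$seed`.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       n_subjects = 8,
                       scenario = scenario_config(),
                       coupling = coupling_model(),
                       features = feature_config(),
                       r_distribution = default_r_distribution,
                       alpha = 0.05,
                       group_edges = c(25, 50, 75),
                       median_value = NULL,
                       select_features = "top3",
                       out_dir = NULL,
                       write_data = FALSE,
                       paths = NULL,
                       seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "load" && is.null(paths))
    stop("load mode requires paths")
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  cfg <- list(mode = mode, n_subjects = n_subjects, scenario = scenario,
              coupling = coupling, features = features,
              r_distribution = r_distribution, alpha = alpha,
              group_edges = group_edges, median_value = median_value,
              select_features = select_features, out_dir = out_dir,
              write_data = write_data, paths = paths,
              seed = scenario$seed)
  class(cfg) <- "run_config"
  cfg
}

.config_hash <- function(cfg) {
  txt <- paste(deparse(cfg, control = "all"), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) the cohort, extract the pre-defibrillation epochs,
#' compute the eleven-parameter feature table, pair it with the CBF
#' recovery rates, and build the association report. When `out_dir` is
#' set, writes `epochs.csv`, `features.csv`, the three report tables and
#' `run_log.json` (seed, config hash, every estimator setting in force,
#' dropped-epoch counts).
#'
#' @param cfg a [run_config()].
#' @return list with `report` (a `stats_report`), `features`,
#'   `recovery`, `epochs` (per-epoch table), `records` (simulate mode),
#'   `log`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  dropped <- 0

  if (cfg$mode == "simulate") {
    records <- simulate_cohort(cfg$n_subjects, cfg$scenario, cfg$coupling,
                               cfg$r_distribution)
    recs <- lapply(records, as_recording)
    if (cfg$write_data && !is.null(cfg$out_dir)) {
      for (rec in recs)
        write_recording_csv(rec, file.path(cfg$out_dir, "data"))
    }
  } else {
    records <- NULL
    recs <- lapply(cfg$paths, function(p) read_recording(p, format = "csv"))
  }

  epoch_rows <- list(); all_epochs <- list()
  for (rec in recs) {
    base <- baseline_value(rec, "cbf")
    eps <- withCallingHandlers(
      extract_preshock_epochs(rec),
      warning = function(w) { dropped <<- dropped + 1; invokeRestart("muffleWarning") }
    )
    for (ep in eps) {
      cbf_val <- epoch_hemodynamic_value(rec, ep, "cbf")
      epoch_rows[[length(epoch_rows) + 1]] <- data.frame(
        subject = ep$subject, session = ep$session,
        epoch_time_s = ep$linked_event,
        cbf = cbf_val, cbf_baseline = base,
        value_pct = compute_recovery_rate(cbf_val, base))
      all_epochs[[length(all_epochs) + 1]] <- ep
    }
  }
  if (length(all_epochs) == 0) stop("pipeline error at epoch extraction: no epochs")
  epochs_df <- do.call(rbind, epoch_rows)

  features <- feature_table(all_epochs, cfg$features)
  recovery <- assign_recovery_groups(epochs_df$value_pct,
                                     edges = cfg$group_edges,
                                     median_value = cfg$median_value)
  recovery$subject <- epochs_df$subject

  report <- build_report(features, recovery,
                         select_features = cfg$select_features,
                         alpha = cfg$alpha, out_dir = cfg$out_dir)

  log <- list(
    seed = cfg$seed,
    config_hash = .config_hash(cfg[setdiff(names(cfg), "out_dir")]),
    mode = cfg$mode,
    n_subjects = length(recs),
    n_epochs = nrow(features),
    dropped_epochs = dropped,
    probability_source = cfg$features$probability_source,
    log_base = cfg$features$log_base,
    renyi_alpha = cfg$features$renyi_alpha,
    window = cfg$features$window,
    band_hz = c(cfg$features$low_hz, cfg$features$high_hz),
    group_edges = cfg$group_edges,
    median_split_pct = attr(recovery, "median_pct"),
    alpha = cfg$alpha,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(epochs_df, file.path(cfg$out_dir, "epochs.csv"),
                     row.names = FALSE)
    utils::write.csv(features, file.path(cfg$out_dir, "features.csv"),
                     row.names = FALSE)
    log_out <- log; log_out$elapsed_s <- NULL   # keep run_log reproducible
    jsonlite::write_json(log_out, file.path(cfg$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(report = report, features = features, recovery = recovery,
       epochs = epochs_df, records = records, log = log)
}
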
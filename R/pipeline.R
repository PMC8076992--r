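# One-command orchestration: (simulate ->) nights -> features -> filter
# -> models -> reports, with a manifest for deterministic re-runs.

#' Pipeline configuration
#'
#' Either simulation mode (`simulate = TRUE` with a [sim_config()]) or
#' file mode (paths to sessions, PHQ-8 and demographics inputs).
#' Validated up front, before any compute: in file mode all paths must
#' exist; the inclusion configuration is checked against the feature
#' window (so `min_sleep_days` cannot exceed `window_days`).
#'
#' @param simulate Logical; generate the cohort instead of reading it.
#' @param sim A [sim_config()] (simulation mode).
#' @param sessions_path,phq8_path,demographics_path Input files (file
#'   mode).
#' @param dialect Sessions dialect, `"segments_csv"` or `"jsonl"`.
#' @param inclusion An [inclusion_config()].
#' @param outcomes Outcomes to model (default both).
#' @param window_days Feature window (default 14).
#' @param boxcox `"never"` or `"auto"` residual-normality fallback.
#' @param outdir Output directory for artifacts.
#' @param seed Seed recorded in the manifest; overrides `sim$seed` in
#'   simulation mode.
#' @param trajectory_features Features exported in the per-participant
#'   trajectory table.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE,
                            sim = sim_config(),
                            sessions_path = NULL,
                            phq8_path = NULL,
                            demographics_path = NULL,
                            dialect = "segments_csv",
                            inclusion = inclusion_config(),
                            outcomes = c("phq8_total", "sleep_subscore"),
                            window_days = 14L,
                            boxcox = "never",
                            outdir = "sleepdep_out",
                            seed = NULL,
                            trajectory_features = c("Av_tst", "Awake_pct",
                                                    "Efficiency")) {
  if (!simulate) {
    for (p in c(sessions_path, phq8_path, demographics_path))
      if (is.null(p) || !file.exists(p))
        stop("input path missing or not found: ", p %||% "<NULL>",
             call. = FALSE)
  } else if (!is.null(seed)) {
    sim$seed <- as.integer(seed)
  }
  if (inclusion$min_sleep_days > window_days)
    stop("inclusion min_sleep_days (", inclusion$min_sleep_days,
         ") exceeds the feature window (", window_days, " days)",
         call. = FALSE)
  outcomes <- match.arg(outcomes, c("phq8_total", "sleep_subscore"),
                        several.ok = TRUE)
  structure(list(simulate = isTRUE(simulate), sim = sim,
                 sessions_path = sessions_path, phq8_path = phq8_path,
                 demographics_path = demographics_path, dialect = dialect,
                 inclusion = inclusion, outcomes = outcomes,
                 window_days = as.integer(window_days),
                 boxcox = boxcox, outdir = outdir,
                 seed = seed %||% (if (simulate) sim$seed else 0L),
                 trajectory_features = trajectory_features),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `sim:` and
#' `inclusion:` sub-maps are passed to [sim_config()] and
#' [inclusion_config()].
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (e.g. `seed`, `outdir`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$inclusion))
    args$inclusion <- do.call(inclusion_config, y$inclusion)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Stages: obtain the cohort (simulate or read), score nights, extract
#' windowed features per PHQ-8 record, join with outcomes and
#' demographics, apply the inclusion criteria, fit the association
#' models (pooled dataset with the three-level model when several sites
#' are present; each site separately with the two-level model), compute
#' Spearman correlations between the PHQ-8 total and sleep subscore
#' overall and per site, and export per-participant trajectories. All
#' artifacts are CSV (plus a JSON manifest recording the seed and a
#' configuration hash); a failing stage aborts with the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the artifact paths and the main
#'   in-memory objects (`nights`, `features`, `records`, `results`,
#'   `spearman`).
#' @export
run_pipeline <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  if (cfg$simulate) {
    cohort <- stage("simulate", simulate_cohort(cfg$sim, "sessions"))
    sessions <- cohort$sessions
    phq8 <- cohort$phq8
    demographics <- cohort$demographics
  } else {
    sessions <- stage("read_sessions",
                      read_sessions(cfg$sessions_path, cfg$dialect))
    phq8 <- stage("read_phq8", read_phq8(cfg$phq8_path))
    demographics <- stage("read_demographics",
                          read_demographics(cfg$demographics_path))
  }

  nights <- stage("night_metrics", compute_nights(sessions))
  paths$nights <- file.path(cfg$outdir, "nights.csv")
  write_table(nights, paths$nights)

  features <- stage("windowed_features",
                    extract_all_features(nights, phq8, cfg$window_days))
  paths$features <- file.path(cfg$outdir, "features.csv")
  write_table(features, paths$features)

  records <- stage("join", join_records(features, phq8, demographics))
  filtered <- stage("inclusion_filter",
                    filter_records(records, cfg$inclusion))
  paths$exclusions <- file.path(cfg$outdir, "exclusion_report.csv")
  write_table(exclusion_report(filtered), paths$exclusions)

  sites <- sort(unique(as.character(filtered$site_id)))
  datasets <- c(list(all = filtered),
                stats::setNames(
                  lapply(sites, function(s)
                    filtered[filtered$site_id == s, , drop = FALSE]),
                  sites))
  results <- list()
  for (ds in names(datasets)) {
    lev <- if (ds == "all" &&
               length(unique(datasets[[ds]]$site_id)) > 1L)
      "three_level" else "two_level"
    for (oc in cfg$outcomes) {
      res <- stage(paste0("models_", ds, "_", oc),
                   fit_all_models(datasets[[ds]], oc, lev,
                                  boxcox = cfg$boxcox))
      res$dataset <- ds
      results[[paste(ds, oc, sep = "_")]] <- res
      p <- file.path(cfg$outdir, paste0("results_", ds, "_", oc, ".csv"))
      write_table(res, p)
      paths[[paste0("results_", ds, "_", oc)]] <- p
    }
  }

  spearman <- stage("spearman", dplyr::bind_rows(lapply(
    names(datasets), function(ds) {
      d <- datasets[[ds]]
      out <- spearman_corr(d$phq8_total, d$sleep_subscore)
      out$dataset <- ds
      out
    })))
  paths$spearman <- file.path(cfg$outdir, "spearman.csv")
  write_table(spearman, paths$spearman)

  traj_cols <- c("participant_id", "site_id", "phq8_ts", "phq8_total",
                 "sleep_subscore",
                 intersect(cfg$trajectory_features, names(filtered)))
  traj <- filtered[order(filtered$participant_id, filtered$phq8_ts),
                   traj_cols]
  paths$trajectories <- file.path(cfg$outdir, "trajectories.csv")
  write_table(traj, paths$trajectories)

  manifest <- list(
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "outdir")]),
    n_records_in = nrow(records),
    n_records_retained = nrow(filtered),
    n_participants = length(unique(filtered$participant_id)),
    artifacts = vapply(paths, basename, character(1L)))
  paths$manifest <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(paths = paths, nights = nights, features = features,
                 records = filtered, results = dplyr::bind_rows(results),
                 spearman = spearman))
}

#' Plot one participant's PHQ-8 and feature trajectories
#'
#' Convenience plot of the trajectory export: PHQ-8 total and selected
#' sleep features over time for one participant. Requires \pkg{ggplot2}.
#'
#' @param records Filtered analysis records (or the `records` element
#'   of [run_pipeline()] output).
#' @param participant_id Which participant to plot.
#' @param features Feature columns to include.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(records, participant_id,
                            features = c("Av_tst", "Awake_pct")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- records[records$participant_id == participant_id, , drop = FALSE]
  if (!nrow(d)) stop("no records for participant ", participant_id,
                     call. = FALSE)
  long <- dplyr::bind_rows(lapply(c("phq8_total", features), function(v)
    tibble::tibble(phq8_ts = d$phq8_ts, series = v, value = d[[v]])))
  ggplot2::ggplot(long, ggplot2::aes(.data$phq8_ts, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Participant", participant_id))
}
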
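#' Step plot of the return CDF with its confidence band
#'
#' @param table A filled weekly table ([weekly_table()]).
#' @param cutoff Optional [select_cutoff()] result; when it carries a
#'   recommendation a vertical marker is drawn at that week.
#' @return A ggplot object.
#' @export
plot_cdf <- function(table, cutoff = NULL) {
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$week, y = .data$cdf)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_step(colour = "steelblue", linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Weeks late", y = "Proportion returned",
      title = "Cumulative distribution of return among late patients",
      subtitle = "Shaded band: 95% Greenwood confidence interval"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff) && !is.na(cutoff$recommended_week)) {
    p <- p + ggplot2::geom_vline(
      xintercept = cutoff$recommended_week,
      linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

#' Bar plot of the weekly return hazard
#'
#' @inheritParams plot_cdf
#' @return A ggplot object.
#' @export
plot_hazard <- function(table, cutoff = NULL) {
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$week, y = .data$hazard)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.8) +
    ggplot2::labs(
      x = "Weeks late", y = "Proportion returning, of those yet to return",
      title = "Weekly hazard of return among late patients"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff) && !is.na(cutoff$recommended_week)) {
    p <- p + ggplot2::geom_vline(
      xintercept = cutoff$recommended_week,
      linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

save_plot_quietly <- function(plot, path_base) {
  for (ext in c("png", "svg")) {
    path <- paste0(path_base, ".", ext)
    dev <- if (ext == "svg") grDevices::svg else NULL
    ok <- tryCatch(
      {
        suppressMessages(suppressWarnings(ggplot2::ggsave(path, plot,
          device = dev, width = 7, height = 4.5, dpi = 150
        )))
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      warning(sprintf("could not render %s (graphics device unavailable)", path),
        call. = FALSE
      )
    }
  }
}

cutoff_to_json <- function(cutoff, path) {
  jsonlite::write_json(
    list(
      recommended_week = cutoff$recommended_week,
      rule = cutoff$rule[c("hazard_threshold", "run_length", "min_week", "method")],
      by_method = cutoff$by_method,
      stable = cutoff$stable,
      evidence = cutoff$evidence
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
}

render_report <- function(out_dir) {
  wt <- read_weekly_table(file.path(out_dir, "weekly_table.csv"))
  fl <- readr::read_csv(file.path(out_dir, "filter_log.csv"),
    col_types = "ci", progress = FALSE
  )
  co <- jsonlite::read_json(file.path(out_dir, "cutoff.json"))
  meta <- jsonlite::read_json(file.path(out_dir, "run_meta.json"))

  rec <- co$recommended_week
  lines <- c(
    "# Late-return analysis report",
    "",
    sprintf("- Patients analyzed: %s", meta$n_patients),
    sprintf("- Candidate follow-up visits: %s", meta$n_candidate_visits),
    sprintf("- Late episodes analyzed: %s", meta$n_episodes),
    sprintf("- Patients contributing episodes: %s", meta$n_patients_with_episodes),
    sprintf(
      "- Episodes per contributing patient: median %s (range %s-%s)",
      meta$median_episodes_per_patient,
      meta$min_episodes_per_patient, meta$max_episodes_per_patient
    ),
    "",
    "## Recommended cut-off",
    "",
    if (is.null(rec)) {
      "No weeks-late cut-off satisfied the selection rule."
    } else {
      sprintf(
        "**Tracing should begin at >= %s weeks late** (%s rule; %s under a +/-20%% change of the hazard threshold). By method: hazard_drop = %s, cdf_plateau = %s.",
        rec, co$rule$method,
        if (isTRUE(co$stable)) "stable" else "not stable",
        ifelse(is.null(co$by_method$hazard_drop), "none", co$by_method$hazard_drop),
        ifelse(is.null(co$by_method$cdf_plateau), "none", co$by_method$cdf_plateau)
      )
    },
    "",
    "## Weekly estimates (excerpt)",
    "",
    "| week | at risk | returned | hazard | CDF | 95% CI |",
    "|-----:|--------:|---------:|-------:|----:|:-------|",
    sprintf(
      "| %d | %d | %d | %.4f | %.4f | [%.4f, %.4f] |",
      wt$week, wt$n_at_risk, wt$n_returned, wt$hazard, wt$cdf,
      wt$ci_low, wt$ci_high
    ),
    "",
    "## Visits removed by each filter",
    "",
    "| filter | removed |",
    "|:-------|--------:|",
    sprintf("| %s | %d |", fl$filter, fl$n_removed),
    "",
    sprintf(
      "_Generated by latereturn %s; mode: %s%s._",
      as.character(utils::packageVersion("latereturn")),
      meta$mode,
      if (!is.null(meta$seed)) sprintf(", seed %s", meta$seed) else ""
    )
  )
  writeLines(lines, file.path(out_dir, "report.md"))
}

#' Run the full late-return analysis
#'
#' One call from raw tables (or the simulator) to the artifact set: the
#' weekly estimates table, the filter log, the cut-off recommendation,
#' both plots and a human-readable report. The report is rendered from the
#' written artifacts, not recomputed, so its numbers always equal the
#' CSV/JSON values. Given the same inputs, configuration and seed the
#' artifacts are identical across runs.
#'
#' @param patients,visits Cohort tables (file mode). Ignored when `params`
#'   is supplied.
#' @param params A [sim_params()] to generate the cohort (simulate mode).
#' @param config A [lateness_config()].
#' @param rule A [cutoff_rule()].
#' @param level Confidence level for the Greenwood band.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `weekly`, `cutoff`, `episodes`,
#'   `filter_log`, `validation` and the artifact paths.
#' @export
run_pipeline <- function(patients = NULL, visits = NULL, params = NULL,
                         config = lateness_config(), rule = cutoff_rule(),
                         level = 0.95, out_dir) {
  mode <- if (!is.null(params)) "simulate" else "files"
  if (mode == "simulate") {
    cohort <- simulate_cohort(params)
    patients <- cohort$patients
    visits <- cohort$visits
  } else if (is.null(patients) || is.null(visits)) {
    stop("either supply `patients` and `visits` tables or simulation `params`",
      call. = FALSE
    )
  }

  validation <- validate_cohort(patients, visits)
  built <- build_late_episodes(patients, visits, config)
  wt <- weekly_table(built$episodes, max_week = config$max_week, level = level)
  cutoff <- select_cutoff(wt, rule)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_weekly_table(wt, file.path(out_dir, "weekly_table.csv"))
  readr::write_csv(built$filter_log, file.path(out_dir, "filter_log.csv"),
    progress = FALSE
  )
  cutoff_to_json(cutoff, file.path(out_dir, "cutoff.json"))

  per_patient <- table(built$episodes$patient_id)
  meta <- list(
    mode = mode,
    seed = if (mode == "simulate") params$seed else NULL,
    n_patients = nrow(patients),
    n_candidate_visits = built$n_candidate_visits,
    n_episodes = nrow(built$episodes),
    n_patients_with_episodes = length(per_patient),
    median_episodes_per_patient = if (length(per_patient)) stats::median(as.integer(per_patient)) else NA,
    min_episodes_per_patient = if (length(per_patient)) min(per_patient) else NA,
    max_episodes_per_patient = if (length(per_patient)) max(per_patient) else NA,
    max_week = config$max_week,
    conf_level = level
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )

  save_plot_quietly(plot_cdf(wt, cutoff), file.path(out_dir, "cdf"))
  save_plot_quietly(plot_hazard(wt, cutoff), file.path(out_dir, "hazard"))
  render_report(out_dir)

  invisible(list(
    weekly = wt, cutoff = cutoff, episodes = built$episodes,
    filter_log = built$filter_log, validation = validation,
    meta = meta, out_dir = out_dir
  ))
}

#' Read a run configuration from YAML
#'
#' Maps a YAML file with (all optional) blocks `io.patient_columns`,
#' `io.visit_columns`, `lateness.*`, `cutoff.*` and `sim.*` onto the
#' package's configuration objects; omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A list with `patient_columns`, `visit_columns`, `lateness`
#'   ([lateness_config()]), `cutoff` ([cutoff_rule()]) and `sim`
#'   ([sim_params()] or `NULL` when no `sim` block is present).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  take <- function(block, fn) do.call(fn, as.list(block))
  list(
    patient_columns = take(raw$io$patient_columns, patient_columns),
    visit_columns = take(raw$io$visit_columns, visit_columns),
    lateness = take(raw$lateness, lateness_config),
    cutoff = take(raw$cutoff, cutoff_rule),
    sim = if (!is.null(raw$sim)) take(raw$sim, sim_params) else NULL
  )
}
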
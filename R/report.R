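#' Long-format results of a simulation
#'
#' Flattens an `rt_sim` into the long results table written by
#' [write_results()]: one row per day, metric and group (`"ALL"` for
#' department totals), deterministically ordered by day, metric, group.
#'
#' @param sim An `rt_sim`.
#' @return Tibble with columns `day`, `week`, `metric`, `group_id`, `value`.
#' @export
as_long_results <- function(sim) {
  sim$steps |>
    pivot_longer(-c("day", "week"), names_to = "metric") |>
    mutate(group_id = "ALL") |>
    select("day", "week", "metric", "group_id", "value") |>
    arrange(.data$day, .data$metric, .data$group_id)
}

#' @rdname as_long_results
#' @param path Output CSV path.
#' @export
write_results <- function(sim, path) {
  readr::write_csv(as_long_results(sim), path)
  invisible(path)
}

#' Run manifest
#'
#' A small JSON-serialisable record sufficient to re-run a simulation:
#' the department configuration, scenario, schedule provenance (totals,
#' scaling factor, horizon), seed, package version, and a content hash of
#' the configuration. Timestamps are deliberately excluded so manifests of
#' identical runs are byte-identical.
#'
#' @param sim An `rt_sim`.
#' @param seed The seed used upstream (if any).
#' @param schedule The input schedule (optional, for provenance totals).
#' @return A list; serialise with [jsonlite::write_json()].
#' @export
run_manifest <- function(sim, seed = NULL, schedule = NULL) {
  cfg <- unclass(sim$config)
  man <- list(
    package = "rtflow",
    version = as.character(utils::packageVersion("rtflow")),
    seed = seed,
    config = cfg,
    scenario = if (!is.null(sim$scenario)) unclass(sim$scenario),
    horizon_weeks = sim$horizon_weeks,
    schedule = if (!is.null(schedule)) list(
      total = schedule_total(schedule),
      n_groups = dplyr::n_distinct(schedule$group_id),
      horizon_weeks = attr(schedule, "horizon_weeks"),
      scaling_factor = attr(schedule, "scaling_factor")))
  man$config_hash <- rlang::hash(man[c("config", "scenario", "horizon_weeks")])
  man
}

#' Render a report for a suite run
#'
#' Writes, under `out_dir`: `metrics.csv` (the suite metrics),
#' `comparison.md` and `comparison.json` (the ranking report), per-scenario
#' trajectory CSVs, and — if `plots` — one PNG figure per scenario plus a
#' suite comparison figure.
#'
#' @param suite An `rt_suite` from [run_suite()].
#' @param out_dir Output directory (created if needed).
#' @param plots Render PNG figures (default TRUE)?
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(suite, out_dir, plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- as_tibble(suite) |>
    select(-"overtime_by_week", -"idle_by_week")
  readr::write_csv(flat, file.path(out_dir, "metrics.csv"))
  cmp <- compare_scenarios(suite)
  writeLines(cmp$markdown, file.path(out_dir, "comparison.md"))
  jsonlite::write_json(cmp$ranking, file.path(out_dir, "comparison.json"),
                       dataframe = "rows", digits = NA)
  sims <- suite_sims(suite)
  for (id in names(sims)) {
    safe <- gsub("[^A-Za-z0-9]", "", id)
    write_results(sims[[id]], file.path(out_dir, sprintf("trajectory_%s.csv", safe)))
    if (plots) {
      suppressMessages(ggplot2::ggsave(
        file.path(out_dir, sprintf("scenario_%s.png", safe)),
        autoplot(sims[[id]]), width = 8, height = 7, dpi = 120))
    }
  }
  if (plots) {
    suppressMessages(ggplot2::ggsave(
      file.path(out_dir, "suite_comparison.png"), autoplot(suite),
      width = 9, height = 4, dpi = 120))
  }
  invisible(out_dir)
}
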
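#' Built-in suite of nine summer-vacation scenarios
#'
#' The nine capacity-reduction policies evaluated in the study the model
#' supports: three period lengths (eight, six, four weeks) crossed with
#' reduction depths (30/30, 50/30, 50/50, 70/70 percent for
#' preparation/treatment) and timing offsets of the preparation vacation
#' (simultaneous, or one/two/four weeks earlier).
#'
#' @param treat_start_week First week of the treatment vacation window
#'   (default 27 of a 70-week horizon starting in January, i.e. summer).
#' @return A `scenario_set` tibble with one row per scenario: columns
#'   `scenario_id`, `prep_offset_weeks`, `length_weeks`, `prep_reduction`,
#'   `treat_reduction`, `treat_start_week`.
#' @export
#' @examples
#' table1_scenarios()
table1_scenarios <- function(treat_start_week = 27L) {
  suite <- tibble(
    scenario_id = paste0("#", 1:9),
    prep_offset_weeks = c(0L, 0L, 4L, 2L, 1L, 0L, 1L, 1L, 4L),
    length_weeks = c(8L, 8L, 8L, 8L, 8L, 6L, 6L, 4L, 4L),
    prep_reduction = c(.30, .50, .30, .30, .30, .50, .50, .70, .70),
    treat_reduction = c(.30, .30, .30, .30, .30, .50, .50, .70, .70),
    treat_start_week = as.integer(treat_start_week))
  class(suite) <- c("scenario_set", class(suite))
  suite
}

#' Read a scenario suite from JSON
#'
#' A suite file is a JSON array of objects whose keys mirror the
#' [vacation_scenario()] fields. The built-in nine-scenario suite is
#' shipped at `system.file("extdata", "table1_scenarios.json",
#' package = "rtflow")`.
#'
#' @param path Path to the JSON suite.
#' @return A `scenario_set` tibble.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- as_tibble(jsonlite::fromJSON(path))
  required <- c("scenario_id", "prep_offset_weeks", "length_weeks",
                "prep_reduction", "treat_reduction")
  miss <- setdiff(required, names(df))
  if (length(miss)) abort(sprintf("Scenario suite lacks field(s): %s",
                                  paste(miss, collapse = ", ")))
  if (!"treat_start_week" %in% names(df)) df$treat_start_week <- 27L
  df <- df |> mutate(across(c("prep_offset_weeks", "length_weeks",
                              "treat_start_week"), as.integer))
  class(df) <- c("scenario_set", class(tibble()))
  df
}

#' Scenario metrics from a simulation run
#'
#' Summarises one run against its vacation scenario: the peak of the
#' ready-to-start queue (patients with completed preparations waiting for a
#' linac slot) and the week it occurs; total and weekly overtime and idle
#' fraction-units; and mean treatment utilization (delivered units over
#' capacity units) before, during, and after the treatment vacation window.
#' Utilization can exceed 1 when overtime is worked.
#'
#' @param sim An `rt_sim` from [simulate_flow()].
#' @param scenario The scenario to evaluate against; defaults to the one
#'   recorded in `sim`. `NULL` (a no-vacation run with no recorded
#'   scenario) evaluates global metrics with empty window utilizations.
#' @param window_weeks Width of the pre-/post-vacation comparison windows
#'   in weeks (default 4).
#' @return A one-row tibble: `scenario_id`, `peak_ready_queue`,
#'   `week_of_peak`, `total_overtime`, `total_idle`, `overtime_vacation_week1`,
#'   `util_pre`, `util_during`, `util_post`, plus list-columns
#'   `overtime_by_week` and `idle_by_week`.
#' @export
compute_metrics <- function(sim, scenario = sim$scenario, window_weeks = 4L) {
  st <- sim$steps
  if (!is.null(scenario)) {
    scenario <- as_vacation_scenario(scenario)
    vac <- seq(scenario$treat_start_week, length.out = scenario$length_weeks)
    if (max(vac) > sim$horizon_weeks) {
      abort("Scenario window lies outside the simulated horizon.")
    }
    pre <- seq(max(1L, scenario$treat_start_week - window_weeks),
               scenario$treat_start_week - 1L)
    post <- seq(max(vac) + 1L,
                min(sim$horizon_weeks, max(vac) + window_weeks))
  } else {
    vac <- pre <- post <- integer(0)
  }

  weekly <- st |>
    group_by(week = .data$week) |>
    summarise(overtime = sum(.data$overtime_units),
              idle = sum(.data$idle_units),
              delivered = sum(.data$fractions_delivered),
              capacity = sum(.data$treat_capacity), .groups = "drop")
  util <- function(weeks) {
    w <- weekly |> filter(.data$week %in% weeks)
    if (nrow(w) == 0 || sum(w$capacity) == 0) return(NA_real_)
    sum(w$delivered) / sum(w$capacity)
  }
  peak_i <- which.max(st$ready_to_start)

  tibble(
    scenario_id = if (is.null(scenario)) "baseline" else scenario$scenario_id,
    peak_ready_queue = st$ready_to_start[peak_i],
    week_of_peak = st$week[peak_i],
    total_overtime = sum(st$overtime_units),
    total_idle = sum(st$idle_units),
    overtime_vacation_week1 = if (length(vac)) {
      weekly$overtime[match(vac[1], weekly$week)]
    } else NA_real_,
    util_pre = util(pre),
    util_during = util(vac),
    util_post = util(post),
    overtime_by_week = list(weekly |> select("week", "overtime")),
    idle_by_week = list(weekly |> select("week", "idle")))
}

#' Calibrate a baseline capacity
#'
#' Finds, by bisection, the lowest capacity (at the given resolution) for
#' one part of the department such that a no-vacation run does not build a
#' persistent queue: the queue level the system returns to at the end of
#' the horizon must not exceed the level it returns to at mid-horizon by
#' more than `tolerance` patients. Levels are low-water marks — the
#' minimum of the daily queue over the final and the middle four weeks —
#' so that the weekly arrival pulse and transient spikes, which drain
#' again, do not count as persistent, while a queue that ratchets upward
#' does. The relevant queue is the awaiting-preparation stock when
#' calibrating the preparation part and the ready-to-start queue when
#' calibrating the treatment part.
#'
#' @param schedule A `referral_schedule` with positive inflow.
#' @param config A [department_config()] template; the non-calibrated
#'   part keeps its template capacity.
#' @param part `"prep"` (patients/week) or `"treat"` (fraction-units/day).
#' @param tolerance Permitted terminal-minus-mid queue growth in patients
#'   (default 1).
#' @param resolution Capacity step of the returned value (default 1 unit).
#' @param upper Optional upper search bound; defaults to a generous load
#'   bound derived from the schedule.
#' @return The calibrated capacity (a multiple of `resolution`).
#' @export
#' @examples
#' sched <- generate_constant_schedule(10, weeks = 40, n_fractions = 4)
#' cfg <- department_config(prep_capacity_per_week = 1000,
#'                          treat_capacity_per_day = 1000)
#' calibrate_baseline(sched, cfg, part = "treat")
calibrate_baseline <- function(schedule, config, part = c("prep", "treat"),
                               tolerance = 1, resolution = 1, upper = NULL) {
  part <- match.arg(part)
  if (schedule_total(schedule) == 0) return(0)
  dpw <- config$treatment_days_per_week
  hz <- attr(schedule, "horizon_weeks")
  if (is.null(upper)) {
    per_week <- schedule_total(schedule) / hz
    mean_nf <- sum(schedule$count * schedule$n_fractions) /
      schedule_total(schedule)
    upper <- if (part == "prep") {
      4 * max(per_week, 1)
    } else {
      4 * max(per_week * (mean_nf + config$first_fraction_weight - 1) / dpw, 1)
    }
  }
  upper <- ceiling(upper / resolution) * resolution

  queue_of <- function(sim) {
    st <- sim$steps
    q <- if (part == "prep") st$awaiting_prep else st$ready_to_start
    win <- 4L * dpw                      # four-week low-water windows
    mid_end <- (hz %/% 2) * dpw
    c(mid = min(q[seq(max(1L, mid_end - win + 1L), mid_end)]),
      terminal = min(q[seq(nrow(st) - win + 1L, nrow(st))]))
  }
  passes <- function(cap) {
    cfg <- config
    if (part == "prep") cfg$prep_capacity_per_week <- cap
    else cfg$treat_capacity_per_day <- cap
    q <- queue_of(simulate_flow(schedule, cfg))
    q["terminal"] <= q["mid"] + tolerance
  }

  if (passes(0)) return(0)
  lo <- 0
  hi <- upper
  tries <- 0
  while (!passes(hi)) {
    lo <- hi
    hi <- hi * 2
    tries <- tries + 1
    if (tries > 8) {
      abort(sprintf(
        "calibrate_baseline(%s): no capacity up to %.1f clears the queue; inflow may exceed any finite steady capacity within the horizon.",
        part, hi))
    }
  }
  while (hi - lo > resolution + 1e-9) {
    mid <- lo + floor((hi - lo) / (2 * resolution)) * resolution
    if (mid <= lo) mid <- lo + resolution
    if (passes(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Run a suite of vacation scenarios
#'
#' Simulates every scenario of a suite on the same referral schedule and
#' department configuration and collects their metrics, ranked by peak
#' ready queue, total overtime, and total idle capacity. Rows are ordered
#' by `scenario_id`, so the result is invariant to the ordering of the
#' input suite.
#'
#' @param schedule A `referral_schedule`.
#' @param config A [department_config()].
#' @param scenarios A `scenario_set` tibble (default [table1_scenarios()]).
#' @param window_weeks Pre/post utilization window (see
#'   [compute_metrics()]).
#' @return An `rt_suite` tibble: one metrics row per scenario with rank
#'   columns `rank_peak`, `rank_overtime`, `rank_idle` (1 = smallest), and
#'   the simulations in attribute `sims`.
#' @export
run_suite <- function(schedule, config, scenarios = table1_scenarios(),
                      window_weeks = 4L) {
  rows <- split(as_tibble(scenarios), seq_len(nrow(scenarios)))
  sims <- map(rows, function(r) simulate_flow(schedule, config, r))
  metrics <- map2(sims, rows, function(s, r) {
    compute_metrics(s, r, window_weeks = window_weeks)
  }) |> list_rbind()
  ord <- order(metrics$scenario_id)
  metrics <- metrics[ord, ]
  sims <- sims[ord]
  names(sims) <- metrics$scenario_id
  metrics <- metrics |>
    mutate(rank_peak = rank(.data$peak_ready_queue, ties.method = "min"),
           rank_overtime = rank(.data$total_overtime, ties.method = "min"),
           rank_idle = rank(.data$total_idle, ties.method = "min"))
  structure(metrics, sims = sims,
            class = c("rt_suite", class(tibble())))
}

#' Simulations backing a suite result
#' @param suite An `rt_suite` from [run_suite()].
#' @return Named list of `rt_sim` objects, one per scenario.
#' @export
suite_sims <- function(suite) attr(suite, "sims")

#' Comparison report of a scenario suite
#'
#' @param suite An `rt_suite` from [run_suite()].
#' @return A list with `ranking` (tibble sorted by peak ready queue) and
#'   `markdown` (a rendered Markdown table as a character vector).
#' @export
compare_scenarios <- function(suite) {
  ranking <- as_tibble(suite) |>
    select("scenario_id", "peak_ready_queue", "week_of_peak",
           "total_overtime", "total_idle", "util_pre", "util_during",
           "util_post", "rank_peak", "rank_overtime", "rank_idle") |>
    arrange(.data$rank_peak)
  fmt <- function(x) formatC(x, format = "f", digits = 1)
  md <- c(
    "| scenario | peak ready queue | week | overtime | idle | util pre/during/post |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %s | %d | %s | %s | %.2f / %.2f / %.2f |",
            ranking$scenario_id, fmt(ranking$peak_ready_queue),
            ranking$week_of_peak, fmt(ranking$total_overtime),
            fmt(ranking$total_idle), ranking$util_pre,
            ranking$util_during, ranking$util_post))
  list(ranking = ranking, markdown = md)
}
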
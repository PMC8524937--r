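#' Department configuration
#'
#' Capacities and structural constants of the radiotherapy department: the
#' preparation stage (mould, imaging, contouring, planning, QA combined) is
#' a capacity-limited fixed-delay pipeline in patients per week; the
#' treatment stage is a linac pool in fraction-units per working day. The
#' first treatment fraction consumes `first_fraction_weight` fraction-units
#' (default 2: extra time for patient information and technical
#' verification); subsequent fractions consume 1.
#'
#' @param prep_capacity_per_week Baseline preparation capacity, patients
#'   per week (default 100).
#' @param treat_capacity_per_day Baseline treatment capacity, fraction-units
#'   per working day (default 330).
#' @param treatment_days_per_week Working days per week (default 5;
#'   weekends carry no fractions).
#' @param prep_lead_working_days Fixed preparation lead time in working
#'   days (default 8, i.e. about 1.5 five-day weeks from mould to QA).
#' @param first_fraction_weight Linac capacity multiple consumed by a
#'   course's first fraction (default 2).
#' @return A `department_config` list.
#' @export
department_config <- function(prep_capacity_per_week = 100,
                              treat_capacity_per_day = 330,
                              treatment_days_per_week = 5L,
                              prep_lead_working_days = 8L,
                              first_fraction_weight = 2) {
  stopifnot_scalar_number(prep_capacity_per_week, "prep_capacity_per_week", lower = 0)
  stopifnot_scalar_number(treat_capacity_per_day, "treat_capacity_per_day", lower = 0)
  stopifnot_scalar_number(treatment_days_per_week, "treatment_days_per_week", lower = 1)
  if (treatment_days_per_week > 7) abort("`treatment_days_per_week` must be in 1..7.")
  stopifnot_scalar_number(prep_lead_working_days, "prep_lead_working_days", lower = 1)
  stopifnot_scalar_number(first_fraction_weight, "first_fraction_weight", lower = 1)
  structure(
    list(prep_capacity_per_week = prep_capacity_per_week,
         treat_capacity_per_day = treat_capacity_per_day,
         treatment_days_per_week = as.integer(treatment_days_per_week),
         prep_lead_working_days = as.integer(prep_lead_working_days),
         first_fraction_weight = first_fraction_weight),
    class = "department_config")
}

#' Vacation scenario
#'
#' One capacity-reduction policy: for `length_weeks` weeks the treatment
#' capacity is reduced by `treat_reduction` starting at `treat_start_week`,
#' and the preparation capacity is reduced by `prep_reduction` over an
#' equally long window starting `prep_offset_weeks` weeks earlier.
#'
#' @param scenario_id Identifier string.
#' @param length_weeks Vacation window length in whole weeks.
#' @param prep_reduction,treat_reduction Fractional capacity reductions in
#'   `[0, 1]` (0.3 means 30% less capacity).
#' @param prep_offset_weeks How many weeks before the treatment vacation
#'   the preparation vacation starts (0 = simultaneous).
#' @param treat_start_week First week of the treatment vacation window
#'   (default 27, i.e. early summer of a horizon starting in January).
#' @return A `vacation_scenario` list.
#' @seealso [table1_scenarios()] for the built-in nine-scenario suite.
#' @export
vacation_scenario <- function(scenario_id, length_weeks,
                              prep_reduction, treat_reduction,
                              prep_offset_weeks = 0L, treat_start_week = 27L) {
  stopifnot_scalar_number(length_weeks, "length_weeks", lower = 1)
  stopifnot_scalar_number(prep_offset_weeks, "prep_offset_weeks", lower = 0)
  stopifnot_scalar_number(treat_start_week, "treat_start_week", lower = 1)
  for (r in c(prep_reduction, treat_reduction)) {
    if (r < 0 || r > 1) abort("Capacity reductions must lie in [0, 1].")
  }
  structure(
    list(scenario_id = as.character(scenario_id),
         length_weeks = as.integer(length_weeks),
         prep_reduction = prep_reduction,
         treat_reduction = treat_reduction,
         prep_offset_weeks = as.integer(prep_offset_weeks),
         treat_start_week = as.integer(treat_start_week)),
    class = "vacation_scenario")
}

as_vacation_scenario <- function(x) {
  if (inherits(x, "vacation_scenario")) return(x)
  if (is.data.frame(x) && nrow(x) == 1) {
    return(vacation_scenario(
      x$scenario_id, x$length_weeks, x$prep_reduction, x$treat_reduction,
      x$prep_offset_weeks, x$treat_start_week))
  }
  abort("Cannot interpret `scenario`: give a vacation_scenario or a one-row tibble.")
}

#' Daily capacity profile under a vacation scenario
#'
#' Expands baseline capacities into per-working-day series over the
#' horizon, applying the scenario's reductions inside the vacation windows.
#' Preparation capacity is spread evenly over the working days of each
#' week. Windows cover whole weeks: the preparation window is
#' `[treat_start_week - prep_offset_weeks, + length_weeks)` and the
#' treatment window `[treat_start_week, + length_weeks)`.
#'
#' @param config A [department_config()].
#' @param scenario A [vacation_scenario()] or `NULL` for flat baseline
#'   capacity.
#' @param horizon_weeks Simulation horizon in weeks.
#' @return Tibble with one row per working day: `day`, `week`,
#'   `prep_capacity`, `treat_capacity`.
#' @export
build_capacity_profile <- function(config, scenario = NULL, horizon_weeks = 70L) {
  stopifnot_scalar_number(horizon_weeks, "horizon_weeks", lower = 1)
  dpw <- config$treatment_days_per_week
  days <- seq_len(horizon_weeks * dpw)
  week <- (days - 1L) %/% dpw + 1L
  prep <- rep(config$prep_capacity_per_week / dpw, length(days))
  treat <- rep(config$treat_capacity_per_day, length(days))
  if (!is.null(scenario)) {
    scenario <- as_vacation_scenario(scenario)
    treat_weeks <- seq(scenario$treat_start_week,
                       length.out = scenario$length_weeks)
    prep_weeks <- treat_weeks - scenario$prep_offset_weeks
    if (min(prep_weeks) < 1 || max(treat_weeks) > horizon_weeks) {
      abort(sprintf(
        "Scenario %s: vacation windows (weeks %d-%d) fall outside the %d-week horizon.",
        scenario$scenario_id, min(prep_weeks), max(treat_weeks), horizon_weeks))
    }
    prep[week %in% prep_weeks] <- prep[week %in% prep_weeks] * (1 - scenario$prep_reduction)
    treat[week %in% treat_weeks] <- treat[week %in% treat_weeks] * (1 - scenario$treat_reduction)
  }
  tibble(day = days, week = week, prep_capacity = prep, treat_capacity = treat)
}

# Arrival matrix (weeks x groups) and group table from a referral_schedule.
schedule_matrices <- function(schedule, horizon_weeks) {
  groups <- schedule |>
    distinct(.data$group_id, .data$n_fractions) |>
    arrange(.data$group_id)
  if (anyDuplicated(groups$group_id)) {
    abort("Each group_id must have a single n_fractions value.")
  }
  arr <- matrix(0, nrow = horizon_weeks, ncol = nrow(groups),
                dimnames = list(NULL, groups$group_id))
  idx <- cbind(schedule$week, match(schedule$group_id, groups$group_id))
  in_h <- schedule$week <= horizon_weeks
  arr[idx[in_h, , drop = FALSE]] <- schedule$count[in_h]
  list(groups = groups, arrivals = arr)
}

#' Run the patient-flow simulation
#'
#' Deterministic continuous (stock-and-flow) simulation on a working-day
#' clock. Each week's referrals arrive on its first working day and join
#' the awaiting-preparation stock. Each day:
#' \enumerate{
#'   \item preparation starts are limited by that day's preparation
#'     capacity and allocated across groups in proportion to their awaiting
#'     stock; started patients enter a fixed-lead-time conveyor;
#'   \item conveyor completions join the ready-to-start queue (FIFO by
#'     completion day);
#'   \item ongoing treatments are always served — each patient consumes one
#'     fraction-unit (or their remaining fraction, if less) and demand above
#'     capacity becomes overtime: treatments are never interrupted;
#'   \item residual capacity admits new starts from the ready queue, each
#'     consuming `first_fraction_weight` units; admission is FIFO by
#'     preparation-completion day, proportional across groups within a day;
#'   \item unutilised capacity is recorded as idle; the treatment aging
#'     chain advances and patients whose prescribed fractions are all
#'     delivered move to completed.
#' }
#' All stocks are real-valued.
#'
#' @param schedule A `referral_schedule` (see [pareto_aggregate()],
#'   [generate_constant_schedule()]).
#' @param config A [department_config()].
#' @param scenario A [vacation_scenario()], one row of a scenario set, or
#'   `NULL` for a no-vacation baseline run.
#' @param horizon_weeks Horizon; defaults to the schedule's.
#' @param capacity_profile Optional pre-built capacity profile tibble
#'   (overrides `scenario`).
#' @return An `rt_sim` object: list with `steps` (one tibble row per
#'   working day: flows, overtime/idle units, stock snapshots), `groups`
#'   (per-group totals and conservation bookkeeping), `config`, `scenario`,
#'   `horizon_weeks`, and `conservation` (maximum absolute patient- and
#'   fraction-conservation residuals over the run). Use [tidy()] /
#'   [glance()] / [autoplot()] on it.
#' @export
#' @examples
#' sched <- generate_constant_schedule(10, weeks = 20, n_fractions = 5)
#' cfg <- department_config(prep_capacity_per_week = 50,
#'                          treat_capacity_per_day = 30)
#' sim <- simulate_flow(sched, cfg)
#' glance(sim)
simulate_flow <- function(schedule, config, scenario = NULL,
                          horizon_weeks = NULL, capacity_profile = NULL) {
  horizon_weeks <- as.integer(horizon_weeks %||% attr(schedule, "horizon_weeks"))
  if (is.na(horizon_weeks) || horizon_weeks < 1) {
    abort("`horizon_weeks` must be a positive integer.")
  }
  if (!is.null(scenario)) scenario <- as_vacation_scenario(scenario)
  profile <- capacity_profile %||%
    build_capacity_profile(config, scenario, horizon_weeks)

  sm <- schedule_matrices(schedule, horizon_weeks)
  G <- nrow(sm$groups)
  nf <- sm$groups$n_fractions
  dpw <- config$treatment_days_per_week
  L <- config$prep_lead_working_days
  w1 <- config$first_fraction_weight
  H <- horizon_weeks * dpw

  # aging chain: slot j holds patients with ceil(remaining fractions) == j
  # after their first fraction; entry slot and last-day (slot-1) demand per
  # patient are fixed per group
  entry_slot <- ceiling(pmax(nf - 1, 0))
  S <- max(entry_slot, 1L)
  r1 <- ifelse(entry_slot >= 1, nf - 1 - (entry_slot - 1), 0)
  r1[entry_slot >= 1 & r1 == 0] <- 1  # integer remaining: full final fraction

  awaiting <- numeric(G)
  conveyor <- matrix(0, nrow = L, ncol = G)
  ready_days <- integer(0)
  ready_mat <- matrix(0, nrow = 0, ncol = G)
  chain <- matrix(0, nrow = S, ncol = G)
  completed <- numeric(G)
  frac_given <- numeric(G)     # fractions (counts) delivered per group
  arrivals_cum <- 0

  steps <- vector("list", H)
  max_pat_resid <- 0
  max_frac_resid <- 0
  # fractions already given to a chain patient in slot j of group g:
  # n_fractions - remaining, with remaining = (j - 1) + r1
  given_by_slot <- matrix(nf, nrow = S, ncol = G, byrow = TRUE) -
    ((seq_len(S) - 1) + rep(1, S) %o% r1)

  for (d in seq_len(H)) {
    wk <- (d - 1L) %/% dpw + 1L
    arrived <- 0
    if ((d - 1L) %% dpw == 0L) {           # first working day of the week
      awaiting <- awaiting + sm$arrivals[wk, ]
      arrived <- sum(sm$arrivals[wk, ])
      arrivals_cum <- arrivals_cum + arrived
    }

    pc <- profile$prep_capacity[d]
    tc <- profile$treat_capacity[d]

    # preparation starts, proportional across groups
    aw_tot <- sum(awaiting)
    prep_starts <- min(aw_tot, pc)
    started <- if (aw_tot > 0) awaiting * (prep_starts / aw_tot) else numeric(G)
    awaiting <- awaiting - started

    # conveyor advance: row 1 completes, new starts enter at row L
    completions <- conveyor[1L, ]
    if (L > 1) conveyor[seq_len(L - 1L), ] <- conveyor[seq(2L, L), ]
    conveyor[L, ] <- started
    if (sum(completions) > 0) {
      ready_days <- c(ready_days, d)
      ready_mat <- rbind(ready_mat, completions)
    }

    # ongoing demand: slot-1 patients need r1 units, others 1; always served
    ongoing_by_group <- colSums(chain) - chain[1L, ] * (1 - r1)
    ongoing <- sum(ongoing_by_group)
    overtime <- max(0, ongoing - tc)
    residual <- max(0, tc - ongoing)

    # admissions: FIFO by completion day, proportional within a day
    ready_tot <- sum(ready_mat)
    starts_tot <- min(ready_tot, residual / w1)
    starters <- numeric(G)
    if (starts_tot > 0) {
      left <- starts_tot
      drop_rows <- 0L
      for (i in seq_along(ready_days)) {
        row_tot <- sum(ready_mat[i, ])
        if (row_tot <= left + 1e-15) {
          starters <- starters + ready_mat[i, ]
          left <- left - row_tot
          drop_rows <- i
        } else {
          take <- ready_mat[i, ] * (left / row_tot)
          starters <- starters + take
          ready_mat[i, ] <- ready_mat[i, ] - take
          left <- 0
          break
        }
      }
      if (drop_rows > 0L) {
        keep <- seq_along(ready_days) > drop_rows
        ready_days <- ready_days[keep]
        ready_mat <- ready_mat[keep, , drop = FALSE]
      }
    }

    delivered <- ongoing + w1 * starts_tot
    idle <- max(0, tc - delivered)
    frac_given <- frac_given + ongoing_by_group + starters

    # chain advance: slot-1 cohorts complete, survivors shift down,
    # starters enter (same-day completion for single-fraction courses)
    done_now <- chain[1L, ]
    if (S > 1) chain[seq_len(S - 1L), ] <- chain[seq(2L, S), ]
    chain[S, ] <- 0
    enter <- entry_slot >= 1L
    if (any(enter)) {
      chain[cbind(entry_slot[enter], which(enter))] <-
        chain[cbind(entry_slot[enter], which(enter))] + starters[enter]
    }
    done_now[!enter] <- done_now[!enter] + starters[!enter]
    completed <- completed + done_now

    in_treatment <- ongoing_by_group + starters   # receiving a fraction today
    chain_stock <- sum(chain)

    # conservation residuals (two independent bookkeeping routes)
    pat_resid <- abs(arrivals_cum -
      (sum(awaiting) + sum(conveyor) + sum(ready_mat) + chain_stock + sum(completed)))
    frac_resid <- max(abs(frac_given -
      (completed * nf + colSums(chain * given_by_slot))))
    max_pat_resid <- max(max_pat_resid, pat_resid)
    max_frac_resid <- max(max_frac_resid, frac_resid)

    steps[[d]] <- c(
      day = d, week = wk, arrivals = arrived,
      prep_starts = prep_starts, prep_completions = sum(completions),
      treatment_starts = starts_tot,
      fractions_delivered = delivered, overtime_units = overtime,
      idle_units = idle, prep_capacity = pc, treat_capacity = tc,
      awaiting_prep = sum(awaiting), in_prep = sum(conveyor),
      ready_to_start = sum(ready_mat),
      in_treatment = sum(in_treatment),
      treatment_completions = sum(done_now),
      completed_cum = sum(completed))
  }

  steps <- as_tibble(do.call(rbind, steps))
  groups <- sm$groups |>
    mutate(arrivals_total = colSums(sm$arrivals),
           completed = completed,
           fractions_delivered = frac_given,
           still_in_system = .data$arrivals_total - completed)

  structure(
    list(steps = steps, groups = groups, config = config,
         scenario = scenario, horizon_weeks = horizon_weeks,
         capacity_profile = profile,
         conservation = list(max_patient_residual = max_pat_resid,
                             max_fraction_residual = max_frac_resid)),
    class = "rt_sim")
}

#' @export
print.rt_sim <- function(x, ...) {
  cat(sprintf("<rt_sim> %d weeks (%d working days), %d workflow group(s)\n",
              x$horizon_weeks, nrow(x$steps), nrow(x$groups)))
  if (!is.null(x$scenario)) {
    s <- x$scenario
    cat(sprintf("  scenario %s: %dw vacation, prep -%.0f%% / treat -%.0f%%, prep offset %dw\n",
                s$scenario_id, s$length_weeks, 100 * s$prep_reduction,
                100 * s$treat_reduction, s$prep_offset_weeks))
  }
  g <- glance(x)
  cat(sprintf("  arrivals %.1f, completed %.1f, peak ready queue %.1f (week %d)\n",
              g$arrivals_total, g$completed_total, g$peak_ready_queue,
              g$week_of_peak))
  cat(sprintf("  overtime %.1f and idle %.1f fraction-units\n",
              g$total_overtime, g$total_idle))
  invisible(x)
}

#' Tidy a simulation result
#'
#' `tidy()` returns the per-working-day step records (flows, overtime and
#' idle units, and end-of-day stock snapshots); `glance()` a one-row run
#' summary.
#'
#' @param x An `rt_sim` object from [simulate_flow()].
#' @param weekly Aggregate to one row per week (flows summed, stocks taken
#'   at each week's last working day)?
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.rt_sim <- function(x, weekly = FALSE, ...) {
  if (!weekly) return(x$steps)
  x$steps |>
    group_by(week = .data$week) |>
    summarise(
      across(c("arrivals", "prep_starts", "prep_completions",
               "treatment_starts", "fractions_delivered", "overtime_units",
               "idle_units", "prep_capacity", "treat_capacity"), sum),
      across(c("awaiting_prep", "in_prep", "ready_to_start", "in_treatment",
               "completed_cum"), last),
      .groups = "drop")
}

#' @rdname tidy.rt_sim
#' @exportS3Method generics::glance
glance.rt_sim <- function(x, ...) {
  st <- x$steps
  peak_i <- which.max(st$ready_to_start)
  tibble(
    horizon_weeks = x$horizon_weeks,
    arrivals_total = sum(st$arrivals),
    completed_total = st$completed_cum[nrow(st)],
    peak_ready_queue = st$ready_to_start[peak_i],
    week_of_peak = st$week[peak_i],
    total_overtime = sum(st$overtime_units),
    total_idle = sum(st$idle_units),
    mean_utilization = sum(st$fractions_delivered) / sum(st$treat_capacity),
    max_patient_residual = x$conservation$max_patient_residual,
    max_fraction_residual = x$conservation$max_fraction_residual)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
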
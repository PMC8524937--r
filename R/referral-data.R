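#' Read a booking extract from CSV
#'
#' Reads one row per scheduled treatment course and converts referral dates
#' to 1-based week indices relative to the ISO week (Monday start) of the
#' earliest referral. Rows whose date cannot be parsed or whose fraction
#' count is missing or non-positive are rejected and collected, with their
#' row numbers, in a `problems` attribute; structural problems (a missing
#' required column) are an error.
#'
#' @param path Path to a CSV file with columns `patient_id`, `course_id`,
#'   `referral_date` (ISO 8601), `diagnosis`, `intent`, `n_fractions`.
#'   Lines starting with `#` are treated as comments.
#' @param col_map Optional named character vector mapping the canonical
#'   column names (names) to the file's column names (values), e.g.
#'   `c(referral_date = "ref_dt")`.
#' @return A booking tibble (`patient_id`, `course_id`, `referral_week`,
#'   `diagnosis`, `intent`, `n_fractions`) with attribute `problems`: a
#'   tibble of rejected rows (`row`, `reason`).
#' @seealso [clean_bookings()], [write_bookings()]
#' @export
read_bookings <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "course_id", "referral_date", "diagnosis",
                "intent", "n_fractions")
  lookup <- stats::setNames(required, required)
  if (!is.null(col_map)) lookup[names(col_map)] <- col_map
  missing <- lookup[!lookup %in% names(raw)]
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  raw <- raw |>
    select(all_of(unname(lookup))) |>
    stats::setNames(names(lookup)) |>
    mutate(.row = dplyr::row_number())

  dates <- suppressWarnings(lubridate::ymd(raw$referral_date))
  nfrac <- suppressWarnings(as.numeric(raw$n_fractions))
  bad_date <- is.na(dates)
  bad_frac <- !bad_date & (is.na(nfrac) | nfrac < 1)
  problems <- bind_rows(
    tibble(row = raw$.row[bad_date], reason = "unparseable referral_date"),
    tibble(row = raw$.row[bad_frac], reason = "non-positive n_fractions")
  ) |> arrange(.data$row)

  keep <- !bad_date & !bad_frac
  dates <- dates[keep]
  week0 <- if (length(dates) > 0) {
    lubridate::floor_date(min(dates), unit = "week", week_start = 1)
  } else lubridate::today()
  bookings <- tibble(
    patient_id = raw$patient_id[keep],
    course_id = raw$course_id[keep],
    referral_week = as.integer(
      (lubridate::floor_date(dates, "week", week_start = 1) - week0) / 7) + 1L,
    diagnosis = raw$diagnosis[keep],
    intent = raw$intent[keep],
    n_fractions = nfrac[keep]
  )
  attr(bookings, "problems") <- problems
  bookings
}

#' Rejected-row report of a booking read
#'
#' @param bookings Tibble returned by [read_bookings()].
#' @return Tibble of rejected rows (`row`, `reason`); empty if none.
#' @export
read_problems <- function(bookings) {
  attr(bookings, "problems") %||% tibble(row = integer(), reason = character())
}

#' Clean a booking extract
#'
#' Removes exact duplicates on the deduplication keys (the first occurrence
#' is kept, in input order) and then removes "non-logical" rows under
#' explicit rules: fraction count missing or below 1, missing referral
#' week, or an intent outside \{curative, palliative\}. Cleaning is total —
#' nothing errors; every removal is counted by reason in a cleaning report
#' attached as an attribute (see [cleaning_report()]).
#'
#' @param bookings Booking tibble (from [read_bookings()] or
#'   [generate_bookings()]).
#' @param dedupe_keys Columns defining a duplicate (default
#'   `c("patient_id", "course_id")`).
#' @return The kept rows, with attribute `cleaning_report`.
#' @export
#' @examples
#' b <- generate_bookings(seed = 7, weeks = 4, mean_weekly_referrals = 20,
#'                        dup_rate = 0.05, invalid_rate = 0.05)
#' cleaned <- clean_bookings(b)
#' cleaning_report(cleaned)$removed_by_reason
clean_bookings <- function(bookings, dedupe_keys = c("patient_id", "course_id")) {
  n_in <- nrow(bookings)
  if (!all(dedupe_keys %in% names(bookings))) {
    abort("All `dedupe_keys` must be columns of `bookings`.")
  }
  row0 <- seq_len(n_in)
  dup <- duplicated(bookings[dedupe_keys])
  bad_frac <- !dup & (is.na(bookings$n_fractions) | bookings$n_fractions < 1)
  bad_week <- !dup & !bad_frac &
    (is.na(bookings$referral_week) | bookings$referral_week < 1)
  bad_intent <- !dup & !bad_frac & !bad_week &
    !bookings$intent %in% c("curative", "palliative")
  keep <- !(dup | bad_frac | bad_week | bad_intent)

  kept <- bookings[keep, ]
  attr(kept, "injection") <- NULL
  attr(kept, "problems") <- NULL
  attr(kept, "cleaning_report") <- list(
    input_rows = n_in,
    kept = sum(keep),
    removed_by_reason = list(
      duplicate = sum(dup),
      `non-logical: fractions` = sum(bad_frac),
      `non-logical: week` = sum(bad_week),
      `non-logical: intent` = sum(bad_intent)
    ),
    row_numbers = list(
      duplicate = row0[dup],
      `non-logical: fractions` = row0[bad_frac],
      `non-logical: week` = row0[bad_week],
      `non-logical: intent` = row0[bad_intent]
    )
  )
  kept
}

#' Cleaning report of a cleaned booking extract
#'
#' @param bookings Tibble returned by [clean_bookings()].
#' @return A list: `input_rows`, `kept`, `removed_by_reason`, `row_numbers`.
#' @export
cleaning_report <- function(bookings) {
  rep <- attr(bookings, "cleaning_report")
  if (is.null(rep)) abort("`bookings` carries no cleaning report; run clean_bookings() first.")
  rep
}

new_referral_schedule <- function(df, horizon_weeks, scaling_factor = 1) {
  structure(
    df,
    horizon_weeks = as.integer(horizon_weeks),
    scaling_factor = scaling_factor,
    class = c("referral_schedule", class(tibble())))
}

#' Pareto-aggregate bookings into a weekly referral schedule
#'
#' Groups cleaned bookings by diagnosis and intent, orders groups by patient
#' count (descending, ties broken lexicographically by group label), keeps
#' groups until the cumulative patient share first reaches `pareto_share`
#' (the 80/20 principle by default), and pools the remaining records into
#' one `other` group per intent with a patient-weighted mean fraction count.
#' Each group's referrals are batched into weekly counts, producing the
#' engine's input: a long-format referral schedule.
#'
#' @param bookings Cleaned booking tibble.
#' @param pareto_share Cumulative patient share retained before pooling,
#'   in `(0, 1]` (default 0.8). At 1 every diagnosis-by-intent pair is kept.
#' @param pool_by_intent Pool the tail per intent (default) rather than
#'   into one combined group.
#' @param horizon_weeks Horizon length; defaults to the largest referral
#'   week observed.
#' @return A `referral_schedule`: a tibble with one row per group and week
#'   (`group_id`, `diagnosis`, `intent`, `n_fractions`, `week`, `count`),
#'   complete over the horizon, with attributes `horizon_weeks` and
#'   `scaling_factor` (1 until [scale_schedule()] is applied).
#' @export
#' @examples
#' b <- clean_bookings(generate_bookings(seed = 3, weeks = 10,
#'                                       mean_weekly_referrals = 30))
#' sched <- pareto_aggregate(b)
#' dplyr::n_distinct(sched$group_id)
pareto_aggregate <- function(bookings, pareto_share = 0.8,
                             pool_by_intent = TRUE, horizon_weeks = NULL) {
  if (pareto_share <= 0 || pareto_share > 1) {
    abort("`pareto_share` must lie in (0, 1].")
  }
  if (nrow(bookings) == 0) {
    return(new_referral_schedule(
      tibble(group_id = character(), diagnosis = character(),
             intent = character(), n_fractions = numeric(),
             week = integer(), count = numeric()),
      horizon_weeks = horizon_weeks %||% 0L))
  }
  horizon_weeks <- horizon_weeks %||% max(bookings$referral_week)

  sizes <- bookings |>
    count(.data$diagnosis, .data$intent, name = "n_patients") |>
    mutate(label = paste(.data$diagnosis, .data$intent)) |>
    arrange(desc(.data$n_patients), .data$label) |>
    mutate(cum_share = cumsum(.data$n_patients) / sum(.data$n_patients))

  # keep groups until cumulative share first reaches the threshold
  # (the crossing group is included)
  n_keep <- which(sizes$cum_share >= pareto_share - 1e-12)[1]
  kept_groups <- sizes[seq_len(n_keep), c("diagnosis", "intent")]

  tagged <- bookings |>
    left_join(kept_groups |> mutate(.kept = TRUE),
              by = c("diagnosis", "intent")) |>
    mutate(
      .kept = !is.na(.data$.kept),
      group_diag = if_else(.data$.kept, .data$diagnosis, "other"),
      group_intent = if (pool_by_intent) .data$intent else
        if_else(.data$.kept, .data$intent, "mixed")
    )

  groups <- tagged |>
    group_by(diagnosis = .data$group_diag, intent = .data$group_intent) |>
    summarise(n_fractions = mean(.data$n_fractions), .groups = "drop") |>
    mutate(group_id = paste(.data$diagnosis, .data$intent, sep = "_"))

  weekly <- tagged |>
    count(diagnosis = .data$group_diag, intent = .data$group_intent,
          week = .data$referral_week, name = "count") |>
    mutate(count = as.numeric(.data$count))

  out <- groups |>
    left_join(weekly, by = c("diagnosis", "intent")) |>
    complete(tidyr::nesting(group_id, diagnosis, intent, n_fractions),
             week = seq_len(horizon_weeks), fill = list(count = 0)) |>
    filter(!is.na(.data$week), .data$week <= horizon_weeks) |>
    arrange(.data$group_id, .data$week) |>
    select("group_id", "diagnosis", "intent", "n_fractions", "week", "count")

  new_referral_schedule(out, horizon_weeks = horizon_weeks)
}

#' Coerce a long table to a referral schedule
#'
#' Validates and completes a long-format table of weekly referral counts
#' into the `referral_schedule` container the engine consumes. Missing
#' group-week combinations are filled with zero counts.
#'
#' @param df Data frame with columns `group_id`, `n_fractions`, `week`,
#'   `count`; `diagnosis` and `intent` are optional (defaults: the group id
#'   and `"curative"`).
#' @param horizon_weeks Horizon; defaults to the largest week present.
#' @param scaling_factor Scaling already applied to the counts (default 1).
#' @return A `referral_schedule` tibble.
#' @export
#' @examples
#' as_referral_schedule(tibble::tibble(
#'   group_id = "breast", n_fractions = 16, week = 1:4, count = 12))
as_referral_schedule <- function(df, horizon_weeks = NULL, scaling_factor = 1) {
  required <- c("group_id", "n_fractions", "week", "count")
  miss <- setdiff(required, names(df))
  if (length(miss)) abort(sprintf("Missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(df$count < 0) || any(df$n_fractions < 1) || any(df$week < 1)) {
    abort("Counts must be >= 0, n_fractions >= 1 and weeks >= 1.")
  }
  df <- as_tibble(df)
  if (!"diagnosis" %in% names(df)) df$diagnosis <- df$group_id
  if (!"intent" %in% names(df)) df$intent <- "curative"
  horizon_weeks <- horizon_weeks %||% max(df$week)
  out <- df |>
    complete(tidyr::nesting(group_id, diagnosis, intent, n_fractions),
             week = seq_len(horizon_weeks), fill = list(count = 0)) |>
    filter(.data$week <= horizon_weeks) |>
    arrange(.data$group_id, .data$week) |>
    select("group_id", "diagnosis", "intent", "n_fractions", "week", "count")
  new_referral_schedule(out, horizon_weeks = horizon_weeks,
                        scaling_factor = scaling_factor)
}

#' Scale a referral schedule
#'
#' Multiplies every weekly referral count by a constant factor, as when a
#' historical extract is scaled up to a later year's patient volumes.
#' Counts stay real-valued: the flow engine is a continuous model and
#' rounding would distort low-volume groups.
#'
#' @param schedule A `referral_schedule`.
#' @param factor Positive scaling factor; see [compute_scaling_factor()].
#' @return The scaled schedule; its `scaling_factor` attribute accumulates
#'   the applied factor.
#' @export
scale_schedule <- function(schedule, factor) {
  stopifnot_scalar_number(factor, "factor", lower = 0, strict = TRUE)
  out <- schedule
  out$count <- out$count * factor
  attr(out, "scaling_factor") <- attr(schedule, "scaling_factor") * factor
  out
}

#' Scaling factor between two referral volumes
#'
#' Ratio of the target weekly rate to the historical weekly rate:
#' `(target_total / target_weeks) / (historical_total / historical_weeks)`.
#' Used to scale a historical extract to a later year's volumes, e.g.
#' 3666 courses over 70 weeks scaled to 4610 over 53 weeks gives 1.66,
#' i.e. 1.7 at one decimal.
#'
#' @param historical_total,historical_weeks Historical course count and
#'   span in weeks.
#' @param target_total,target_weeks Target course count and span in weeks.
#' @return The positive scaling factor.
#' @export
#' @examples
#' compute_scaling_factor(3666, 70, 4610, 53)
compute_scaling_factor <- function(historical_total, historical_weeks,
                                   target_total, target_weeks) {
  args <- list(historical_total = historical_total,
               historical_weeks = historical_weeks,
               target_total = target_total, target_weeks = target_weeks)
  for (nm in names(args)) {
    stopifnot_scalar_number(args[[nm]], nm, lower = 0, strict = TRUE)
  }
  (target_total / target_weeks) / (historical_total / historical_weeks)
}

#' Total referrals in a schedule
#' @param schedule A `referral_schedule`.
#' @return Sum of weekly counts over all groups.
#' @export
schedule_total <- function(schedule) sum(schedule$count)

#' Write / read a referral schedule (long CSV)
#'
#' Long format: `group_id, diagnosis, intent, n_fractions, week, count`.
#' The horizon and accumulated scaling factor travel in `#`-comment header
#' lines.
#'
#' @param schedule A `referral_schedule`.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns the `referral_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# horizon_weeks=%d scaling_factor=%.12g",
                     attr(schedule, "horizon_weeks"),
                     attr(schedule, "scaling_factor")), con)
  utils::write.csv(as.data.frame(schedule), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1L)
  meta <- list(horizon_weeks = NA_integer_, scaling_factor = 1)
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("horizon_weeks=(\\d+) scaling_factor=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 3) {
      meta$horizon_weeks <- as.integer(m[2])
      meta$scaling_factor <- as.numeric(m[3])
    }
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          group_id = readr::col_character(),
                          diagnosis = readr::col_character(),
                          intent = readr::col_character(),
                          n_fractions = readr::col_double(),
                          week = readr::col_integer(),
                          count = readr::col_double()))
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  hz <- if (is.na(meta$horizon_weeks)) max(df$week) else meta$horizon_weeks
  new_referral_schedule(df, horizon_weeks = hz, scaling_factor = meta$scaling_factor)
}
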
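#' Generate a synthetic radiotherapy booking extract
#'
#' Draws a seeded synthetic table of scheduled treatment courses with the
#' statistical structure a departmental booking-system extract exhibits:
#' weekly Poisson referral arrivals, a curative/palliative intent split, a
#' long-tailed (Zipf-like) distribution of diagnosis-group sizes, and
#' intent-dependent fraction counts. Optionally injects duplicate and
#' invalid rows at known rates so that downstream cleaning can be audited.
#'
#' The defaults emulate a department booking about 52 treatment courses per
#' week over 70 weeks (roughly 3670 courses), 65% of them curative, spread
#' over 128 raw diagnosis-by-intent workflow groups whose sizes decay with
#' Zipf exponent 1.4 — calibrated so that an 80/20 Pareto aggregation of a
#' generated extract retains on the order of 21 workflow groups. The
#' fraction-count ranges are set so that, after scaling the extract by 1.7,
#' baseline capacities of 100 patients/week (preparation) and 330
#' fraction-units/day (treatment) are the lowest round levels that do not
#' build persistent queues.
#'
#' @param seed Integer seed; the output is fully reproducible given the seed.
#' @param weeks Number of referral weeks in the horizon (default 70).
#' @param mean_weekly_referrals Mean of the weekly Poisson referral count.
#' @param curative_share Probability a course is curative (default 0.65).
#' @param n_raw_groups Total number of raw diagnosis-by-intent workflow
#'   groups, split between intents in proportion to `curative_share`.
#' @param tail_exponent Zipf exponent of the group-size decay (default 1.4).
#' @param curative_fractions,palliative_fractions Integer range (length-2
#'   vector) of fraction counts per intent; draws are uniform over the range.
#' @param dup_rate Rate in `[0, 1)` of injected exact duplicate rows
#'   (appended copies of sampled valid rows).
#' @param invalid_rate Rate in `[0, 1)` of injected invalid rows (zero
#'   fraction counts or unknown intent labels).
#' @param seasonal_amplitude Optional relative amplitude in `[0, 1)` of a
#'   sinusoidal yearly modulation of the weekly referral mean (default 0,
#'   i.e. a homogeneous process).
#'
#' @return A tibble of bookings with columns `patient_id`, `course_id`,
#'   `referral_week`, `diagnosis`, `intent`, `n_fractions`, carrying an
#'   `injection` attribute listing how many duplicate/invalid rows were
#'   injected (see [injection_report()]).
#' @seealso [clean_bookings()], [pareto_aggregate()], [write_bookings()]
#' @export
#' @examples
#' b <- generate_bookings(seed = 1, weeks = 4, mean_weekly_referrals = 10)
#' nrow(b)
generate_bookings <- function(seed,
                              weeks = 70,
                              mean_weekly_referrals = 52.4,
                              curative_share = 0.65,
                              n_raw_groups = 128,
                              tail_exponent = 1.4,
                              curative_fractions = c(15L, 29L),
                              palliative_fractions = c(1L, 10L),
                              dup_rate = 0,
                              invalid_rate = 0,
                              seasonal_amplitude = 0) {
  stopifnot_scalar_number(seed, "seed")
  stopifnot_scalar_number(weeks, "weeks", lower = 1)
  stopifnot_scalar_number(mean_weekly_referrals, "mean_weekly_referrals",
                          lower = 0, strict = TRUE)
  stopifnot_scalar_number(n_raw_groups, "n_raw_groups", lower = 1)
  stopifnot_scalar_number(tail_exponent, "tail_exponent", lower = 0, strict = TRUE)
  if (curative_share < 0 || curative_share > 1) {
    abort("`curative_share` must lie in [0, 1].")
  }
  for (r in list(dup_rate = dup_rate, invalid_rate = invalid_rate,
                 seasonal_amplitude = seasonal_amplitude)) {
    if (r < 0 || r >= 1) abort("injection/seasonality rates must lie in [0, 1).")
  }

  n_cur <- max(1L, round(n_raw_groups * curative_share))
  n_pal <- max(1L, n_raw_groups - n_cur)
  zipf <- function(k) {
    p <- seq_len(k)^(-tail_exponent)
    p / sum(p)
  }

  with_seed(seed, {
    week_mean <- mean_weekly_referrals *
      (1 + seasonal_amplitude * sin(2 * pi * (seq_len(weeks) - 1) / 52))
    n_by_week <- stats::rpois(weeks, week_mean)
    n <- sum(n_by_week)

    referral_week <- rep(seq_len(weeks), n_by_week)
    curative <- stats::rbinom(n, 1L, curative_share) == 1L
    diagnosis <- character(n)
    diagnosis[curative] <- sprintf(
      "dxC%02d", sample.int(n_cur, sum(curative), replace = TRUE, prob = zipf(n_cur)))
    diagnosis[!curative] <- sprintf(
      "dxP%02d", sample.int(n_pal, sum(!curative), replace = TRUE, prob = zipf(n_pal)))
    n_fractions <- integer(n)
    n_fractions[curative] <- sample(
      seq(curative_fractions[1], curative_fractions[2]), sum(curative), replace = TRUE)
    n_fractions[!curative] <- sample(
      seq(palliative_fractions[1], palliative_fractions[2]), sum(!curative), replace = TRUE)

    bookings <- tibble(
      patient_id = sprintf("pt%05d", seq_len(n)),
      course_id = sprintf("crs%05d", seq_len(n)),
      referral_week = referral_week,
      diagnosis = diagnosis,
      intent = ifelse(curative, "curative", "palliative"),
      n_fractions = n_fractions
    )

    n_dup <- if (dup_rate > 0) stats::rbinom(1L, n, dup_rate) else 0L
    n_inv <- if (invalid_rate > 0) stats::rbinom(1L, n, invalid_rate) else 0L
    if (n_dup > 0) {
      bookings <- bind_rows(bookings, bookings[sample.int(n, n_dup, replace = FALSE), ])
    }
    if (n_inv > 0) {
      bad_kind <- sample(c("fractions", "intent"), n_inv, replace = TRUE)
      invalid <- tibble(
        patient_id = sprintf("ptX%04d", seq_len(n_inv)),
        course_id = sprintf("crsX%04d", seq_len(n_inv)),
        referral_week = sample.int(weeks, n_inv, replace = TRUE),
        diagnosis = "dxC01",
        intent = ifelse(bad_kind == "intent", "unknown", "curative"),
        n_fractions = ifelse(bad_kind == "fractions", 0L, 5L)
      )
      bookings <- bind_rows(bookings, invalid)
    }

    attr(bookings, "injection") <- list(
      n_valid = n, n_duplicates = n_dup, n_invalid = n_inv, seed = seed
    )
    bookings
  })
}

#' Injection bookkeeping of a synthetic booking extract
#'
#' @param bookings A tibble from [generate_bookings()].
#' @return A list with `n_valid`, `n_duplicates`, `n_invalid` and `seed`.
#' @export
injection_report <- function(bookings) {
  rep <- attr(bookings, "injection")
  if (is.null(rep)) abort("`bookings` carries no injection bookkeeping.")
  rep
}

#' Deterministic constant-rate referral schedule
#'
#' Builds a single-group referral schedule with the same (possibly
#' fractional) number of referrals every week — the simplest input for
#' closed-form checks of the flow engine (steady states, conservation,
#' capacity calibration).
#'
#' @param rate Referrals per week (positive real; flows are continuous).
#' @param weeks Horizon length in weeks.
#' @param n_fractions Fractions per course for the single group.
#' @param intent Intent label attached to the group (cosmetic).
#' @return A `referral_schedule` tibble (see [pareto_aggregate()]).
#' @export
#' @examples
#' generate_constant_schedule(10, weeks = 4, n_fractions = 5)
generate_constant_schedule <- function(rate, weeks, n_fractions,
                                       intent = "curative") {
  stopifnot_scalar_number(rate, "rate", lower = 0, strict = TRUE)
  stopifnot_scalar_number(weeks, "weeks", lower = 1)
  stopifnot_scalar_number(n_fractions, "n_fractions", lower = 1)
  new_referral_schedule(
    tibble(
      group_id = "constant",
      diagnosis = "constant",
      intent = intent,
      n_fractions = as.numeric(n_fractions),
      week = seq_len(weeks),
      count = as.numeric(rate)
    ),
    horizon_weeks = as.integer(weeks),
    scaling_factor = 1
  )
}

#' Write a booking extract to CSV
#'
#' Writes the bookings CSV dialect that [read_bookings()] reads: columns
#' `patient_id`, `course_id`, `referral_date` (ISO 8601), `diagnosis`,
#' `intent`, `n_fractions`. Week indices are mapped to the Monday of each
#' week counted from `week1_monday`. If the extract came from
#' [generate_bookings()] its seed is recorded in a `#` comment header line.
#'
#' @param bookings Booking tibble with a `referral_week` column.
#' @param path Output file path.
#' @param week1_monday Date of the Monday of week 1 (default `"2015-01-05"`).
#' @return `path`, invisibly.
#' @export
write_bookings <- function(bookings, path, week1_monday = as.Date("2015-01-05")) {
  out <- bookings |>
    mutate(referral_date = week1_monday + 7L * (.data$referral_week - 1L)) |>
    select("patient_id", "course_id", "referral_date", "diagnosis",
           "intent", "n_fractions")
  inj <- attr(bookings, "injection")
  header <- if (!is.null(inj)) sprintf("# rtflow synthetic extract, seed=%d", inj$seed)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
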
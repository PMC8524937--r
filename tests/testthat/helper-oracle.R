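# Independent per-patient event-list simulator used as an oracle for the
# continuous flow engine on integer-valued instances. Patients are atomic:
# FIFO queues, whole-patient preparation starts and treatment admissions.
# Exact equivalence with the engine holds when allocations never split a
# patient: single-group instances (any capacities with unit first-fraction
# weight, or finite prep with ample treatment), or multi-group instances
# with ample capacity everywhere.
oracle_sim <- function(arrivals, nf, prep_cap_day, treat_cap_day,
                       lead_days, w1, dpw = 5) {
  weeks <- nrow(arrivals)
  G <- ncol(arrivals)
  H <- weeks * dpw

  pt_week <- integer(0)
  pt_group <- integer(0)
  for (w in seq_len(weeks)) {
    for (g in seq_len(G)) {
      k <- arrivals[w, g]
      pt_week <- c(pt_week, rep(w, k))
      pt_group <- c(pt_group, rep(g, k))
    }
  }
  n <- length(pt_week)
  ready_day <- rep(NA_integer_, n)
  frac_given <- numeric(n)
  awaiting <- integer(0)
  in_prep <- integer(0)
  ready <- integer(0)
  active <- integer(0)
  n_completed <- 0

  rec <- vector("list", H)
  for (d in seq_len(H)) {
    wk <- (d - 1L) %/% dpw + 1L
    if ((d - 1L) %% dpw == 0L) awaiting <- c(awaiting, which(pt_week == wk))

    k <- min(length(awaiting), prep_cap_day)
    started <- utils::head(awaiting, k)
    awaiting <- utils::tail(awaiting, length(awaiting) - k)
    ready_day[started] <- d + lead_days
    in_prep <- c(in_prep, started)

    completing <- in_prep[ready_day[in_prep] == d]
    in_prep <- in_prep[ready_day[in_prep] != d]
    ready <- c(ready, completing)      # arrival (hence FIFO) order preserved

    D <- length(active)                # each ongoing patient needs 1 unit
    overtime <- max(0, D - treat_cap_day)
    residual <- max(0, treat_cap_day - D)
    s <- min(length(ready), floor(residual / w1 + 1e-9))
    starters <- utils::head(ready, s)
    ready <- utils::tail(ready, length(ready) - s)

    frac_given[active] <- frac_given[active] + 1
    frac_given[starters] <- frac_given[starters] + 1
    delivered <- D + w1 * s
    idle <- max(0, treat_cap_day - delivered)

    served <- c(active, starters)
    done <- served[frac_given[served] >= nf[pt_group[served]]]
    active <- setdiff(served, done)
    n_completed <- n_completed + length(done)

    rec[[d]] <- c(day = d, week = wk,
                  prep_starts = k, prep_completions = length(completing),
                  treatment_starts = s, fractions_delivered = delivered,
                  overtime_units = overtime,
                  awaiting_prep = length(awaiting), in_prep = length(in_prep),
                  ready_to_start = length(ready),
                  in_treatment = length(served),
                  treatment_completions = length(done),
                  completed_cum = n_completed)
  }
  tibble::as_tibble(do.call(rbind, rec))
}

# random small integer instance for oracle-equivalence tests; `kind` picks
# which capacity may bind so that the engine never splits a patient
random_oracle_instance <- function(kind = c("single_w1", "single_ample_treat",
                                            "multi_ample")) {
  kind <- match.arg(kind)
  weeks <- sample(4:20, 1)
  if (kind == "multi_ample") {
    G <- sample(2:5, 1)
    arrivals <- matrix(rpois(weeks * G, sample(1:4, 1)), nrow = weeks)
    list(arrivals = arrivals, nf = sample(1:8, G, replace = TRUE),
         prep_cap = 1e6, treat_cap = 1e6,
         lead = sample(1:8, 1), w1 = sample(1:3, 1), weeks = weeks)
  } else {
    arrivals <- matrix(rpois(weeks, sample(2:8, 1)), ncol = 1)
    if (kind == "single_w1") {
      list(arrivals = arrivals, nf = sample(1:8, 1),
           prep_cap = sample(1:3, 1), treat_cap = sample(2:10, 1),
           lead = sample(1:8, 1), w1 = 1, weeks = weeks)
    } else {
      list(arrivals = arrivals, nf = sample(1:8, 1),
           prep_cap = sample(1:3, 1), treat_cap = 1e6,
           lead = sample(1:8, 1), w1 = sample(2:3, 1), weeks = weeks)
    }
  }
}

# run the engine on an oracle instance
engine_on_instance <- function(inst) {
  G <- ncol(inst$arrivals)
  long <- do.call(rbind, lapply(seq_len(G), function(g) {
    data.frame(group_id = sprintf("g%02d", g),
               n_fractions = inst$nf[g],
               week = seq_len(inst$weeks),
               count = inst$arrivals[, g])
  }))
  sched <- as_referral_schedule(long, horizon_weeks = inst$weeks)
  cfg <- department_config(
    prep_capacity_per_week = inst$prep_cap * 5,
    treat_capacity_per_day = inst$treat_cap,
    prep_lead_working_days = inst$lead,
    first_fraction_weight = inst$w1)
  simulate_flow(sched, cfg)
}

# paper-scale schedule used across tests: default synthetic extract,
# cleaned, 80/20-aggregated and scaled by 1.7
paper_scale_schedule <- function(seed) {
  scale_schedule(pareto_aggregate(clean_bookings(generate_bookings(seed = seed))), 1.7)
}
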
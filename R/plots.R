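#' Plot a simulation run
#'
#' Panels in the style of the study's scenario figures: treatment capacity
#' versus delivered fraction-units, the ready-to-start queue, and overtime
#' and idle units, aggregated by week, with the vacation windows shaded
#' (preparation window light, treatment window darker).
#'
#' @param object An `rt_sim` from [simulate_flow()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rt_sim <- function(object, ...) {
  wk <- tidy(object, weekly = TRUE)
  long <- wk |>
    transmute(.data$week,
              `delivered units` = .data$fractions_delivered,
              `treatment capacity` = .data$treat_capacity,
              `ready-to-start queue` = .data$ready_to_start,
              `overtime units` = .data$overtime_units,
              `idle units` = .data$idle_units) |>
    pivot_longer(-"week", names_to = "series") |>
    mutate(panel = case_when(
      .data$series %in% c("delivered units", "treatment capacity") ~ "treatment stage",
      .data$series == "ready-to-start queue" ~ "ready queue [patients]",
      TRUE ~ "overtime / idle [units]"))

  p <- ggplot2::ggplot(long, ggplot2::aes(.data$week, .data$value,
                                          colour = .data$series))
  if (!is.null(object$scenario)) {
    s <- object$scenario
    shade <- tibble(
      xmin = c(s$treat_start_week - s$prep_offset_weeks, s$treat_start_week),
      xmax = c(s$treat_start_week - s$prep_offset_weeks + s$length_weeks,
               s$treat_start_week + s$length_weeks),
      part = c("preparation vacation", "treatment vacation"))
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, alpha = .data$part),
      fill = "grey40") +
      ggplot2::scale_alpha_manual(values = c("preparation vacation" = 0.10,
                                             "treatment vacation" = 0.22))
  }
  p +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "week", y = NULL, colour = NULL, alpha = NULL,
      title = if (!is.null(object$scenario)) {
        sprintf("Scenario %s: %d-week vacation, prep -%.0f%% / treat -%.0f%%, offset %dw",
                object$scenario$scenario_id, object$scenario$length_weeks,
                100 * object$scenario$prep_reduction,
                100 * object$scenario$treat_reduction,
                object$scenario$prep_offset_weeks)
      } else "Baseline (no vacation)") +
    ggplot2::theme_minimal()
}

#' Plot a scenario-suite comparison
#'
#' Dot plot of peak ready queue, total overtime and total idle per
#' scenario, each metric on its own panel, scenarios ordered by peak ready
#' queue.
#'
#' @param object An `rt_suite` from [run_suite()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rt_suite <- function(object, ...) {
  df <- as_tibble(object) |>
    select("scenario_id", `peak ready queue [patients]` = "peak_ready_queue",
           `total overtime [units]` = "total_overtime",
           `total idle [units]` = "total_idle") |>
    pivot_longer(-"scenario_id", names_to = "metric") |>
    mutate(scenario_id = stats::reorder(.data$scenario_id, .data$value,
                                        FUN = max))
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$scenario_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "scenario",
                  title = "Vacation scenario comparison") +
    ggplot2::theme_minimal()
}

#' Plot a capacity profile
#'
#' @param profile Tibble from [build_capacity_profile()].
#' @return A ggplot of daily preparation and treatment capacity.
#' @export
plot_capacity_profile <- function(profile) {
  profile |>
    pivot_longer(c("prep_capacity", "treat_capacity"), names_to = "part") |>
    mutate(part = dplyr::recode(.data$part,
                                prep_capacity = "preparation [patients/day]",
                                treat_capacity = "treatment [units/day]")) |>
    ggplot2::ggplot(ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~part, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "working day", y = NULL) +
    ggplot2::theme_minimal()
}
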
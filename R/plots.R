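#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated session's six distance channels
#'
#' One facet per channel, distance (tenths of mm) against time. Injected
#' limb-movement dips show up as downward spikes on the LLL/LLR facets.
#'
#' @param object A `plm_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plm_session
#' @export
autoplot.plm_session <- function(object, ...) {
  long <- object$frames |>
    tidyr::pivot_longer(dplyr::all_of(sensor_channels()),
                        names_to = "channel", values_to = "distance_tmm") |>
    dplyr::mutate(channel = factor(.data$channel, levels = sensor_channels()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s,
                                     y = .data$distance_tmm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "distance (0.1 mm)",
                  title = "Simulated ultrasonic sleep session") +
    ggplot2::theme_minimal()
}

#' Plot per-second limb motion flags
#'
#' Logic-level view of the two lower-limb channels: each limb drawn as a
#' 0/1 step trace over the session seconds.
#'
#' @param object A [limb_flags()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plm_limb_flags
#' @export
autoplot.plm_limb_flags <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("flag_LLL", "flag_LLR"), names_to = "limb",
                        values_to = "flag") |>
    dplyr::mutate(limb = sub("flag_", "", .data$limb))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$flag)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~limb, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("static", "motion")) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Per-second lower-limb motion flags") +
    ggplot2::theme_minimal()
}

#' Plot the event-type unit-count report
#'
#' Bar chart of movement units per event type (static, left, right, both).
#'
#' @param object A `plm_result`.
#' @param confirmed_only Count only confirmed events.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plm_result
#' @export
autoplot.plm_result <- function(object, confirmed_only = FALSE, ...) {
  rep_tbl <- event_report(object, confirmed_only = confirmed_only) |>
    dplyr::mutate(event_type = factor(.data$event_type,
                                      levels = c("static", "left", "right",
                                                 "both")))
  ggplot2::ggplot(rep_tbl, ggplot2::aes(x = .data$event_type,
                                        y = .data$count_units)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "event type", y = "movement units",
                  title = paste0("Limb-movement units by event type (status: ",
                                 object$status, ")")) +
    ggplot2::theme_minimal()
}
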
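#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Q10 fit
#'
#' Per-temperature mean frequencies with the fitted exponential
#' `f_ref * Q10^((T - T_ref)/10)` overlaid.
#'
#' @param object A `"q10_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.q10_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(temp_c = seq(min(d$temp_c), max(d$temp_c),
                                      length.out = 100))
  grid$freq_hz <- object$f_ref *
    object$q10^((grid$temp_c - object$t_ref) / 10)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temp_c, y = .data$freq_hz)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Temperature (°C)", y = "Pyloric frequency (Hz)",
      title = sprintf("Q10 = %.2f, f(%g °C) = %.2f Hz",
                      object$q10, object$t_ref, object$f_ref)
    ) +
    ggplot2::theme_minimal()
}

#' Frequency and temperature trajectory of a classified cycle table
#'
#' Cycle frequency over time coloured by the per-cycle frequency state
#' (increasing / stable / decreasing), with the cycle temperature as a
#' second panel; the visual signature of a "jag" is blue (decreasing)
#' frequency under red (rising) temperature.
#'
#' @param cycles Classified cycle tibble (see [classify_cycles()]).
#' @return A ggplot (two stacked facets).
#' @export
plot_frequency_trace <- function(cycles) {
  stopifnot(all(c("start_s", "freq_hz", "temp_c", "freq_state")
                %in% names(cycles)))
  long <- tidyr::pivot_longer(
    cycles[c("start_s", "freq_hz", "temp_c", "freq_state", "temp_state")],
    cols = c("freq_hz", "temp_c"),
    names_to = "measure", values_to = "value"
  )
  long$measure <- factor(long$measure, levels = c("temp_c", "freq_hz"),
                         labels = c("Temperature (°C)",
                                    "Frequency (Hz)"))
  long$state <- ifelse(long$measure == "Frequency (Hz)",
                       long$freq_state, long$temp_state)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start_s, y = .data$value,
                                     colour = .data$state)) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$measure),
                        scales = "free_y", switch = "y") +
    ggplot2::scale_colour_manual(
      values = c(increasing = "#c0392b", stable = "#e6b800",
                 decreasing = "#2c6fbb"),
      na.value = "grey70"
    ) +
    ggplot2::labs(x = "Time (s)", y = NULL, colour = "state") +
    ggplot2::theme_minimal()
}

#' Phase-versus-temperature summary plot
#'
#' Mean phase of each pyloric event across holding temperatures, one line
#' per event; flat lines indicate phase constancy.
#'
#' @param steady Steady-state table from [steady_state_means()].
#' @return A ggplot.
#' @export
plot_phase_temperature <- function(steady) {
  cols <- grep("^mean_(pd|lp|py)_(on|off)_phase$", names(steady),
               value = TRUE)
  if (length(cols) == 0) rlang::abort("no phase columns in `steady`")
  long <- tidyr::pivot_longer(steady[c("target_temp", cols)],
                              cols = dplyr::all_of(cols),
                              names_to = "event", values_to = "phase")
  long$event <- toupper(gsub("mean_|_phase", "", long$event))
  long$event <- gsub("_", " ", long$event)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target_temp,
                                     y = .data$phase,
                                     colour = .data$event)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (°C)", y = "Phase (fraction of period)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
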
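#' Moving-average smoothing of a per-cycle series
#'
#' Centered moving average with edge truncation: near the ends the window
#' simply shrinks to the available samples, so the output has the length of
#' the input. For even windows the extra sample is taken on the trailing
#' (earlier) side. A purely trailing window is available via
#' `align = "right"` for sensitivity checks.
#'
#' @param values Numeric per-cycle series.
#' @param window Window length in cycles (>= 1).
#' @param align `"center"` (default) or `"right"` (trailing window).
#' @return Smoothed numeric vector of the same length.
#' @export
#' @examples
#' smooth_series(0:4, 3)  # c(0.5, 1, 2, 3, 3.5)
smooth_series <- function(values, window, align = c("center", "right")) {
  align <- match.arg(align)
  if (!is.numeric(window) || length(window) != 1 || window < 1) {
    rlang::abort("`window` must be a single integer >= 1")
  }
  window <- as.integer(window)
  n <- length(values)
  if (n == 0) return(numeric(0))
  # index bounds of the window at each position
  if (align == "center") {
    left <- (window - 1L) %/% 2L + as.integer(window %% 2L == 0L)
    right <- (window - 1L) %/% 2L
  } else {
    left <- window - 1L
    right <- 0L
  }
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  cs <- cumsum(c(0, values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Classify per-cycle temperature and frequency changes
#'
#' Implements the jag-detection state labels: for each cycle after the
#' first, the change in the smoothed series from the previous cycle is
#' compared against thresholds with strict inequalities ("more than").
#' Temperature is `increasing` when the change exceeds `temp_thr`
#' (0.01 degC/cycle by default), otherwise `stable`; frequency is
#' `increasing`/`decreasing` when the change exceeds +/- `freq_thr`
#' (0.002 Hz/cycle), otherwise `stable`. The first cycle has no defined
#' change and is `NA`.
#'
#' @param smoothed_temp,smoothed_freq Equal-length smoothed per-cycle series
#'   (see [smooth_series()]).
#' @param temp_thr Temperature threshold, degC per cycle (default 0.01).
#' @param freq_thr Frequency threshold, Hz per cycle (default 0.002).
#' @return Tibble with character columns `temp_state` and `freq_state`, one
#'   row per cycle.
#' @export
classify_series <- function(smoothed_temp, smoothed_freq,
                            temp_thr = 0.01, freq_thr = 0.002) {
  if (length(smoothed_temp) != length(smoothed_freq)) {
    rlang::abort("temperature and frequency series differ in length")
  }
  if (length(smoothed_temp) < 2) {
    rlang::abort("need at least 2 cycles to classify changes")
  }
  stopifnot(temp_thr > 0, freq_thr > 0)
  dt <- c(NA_real_, diff(smoothed_temp))
  df <- c(NA_real_, diff(smoothed_freq))
  tibble::tibble(
    temp_state = dplyr::case_when(
      is.na(dt) ~ NA_character_,
      dt > temp_thr ~ "increasing",
      TRUE ~ "stable"
    ),
    freq_state = dplyr::case_when(
      is.na(df) ~ NA_character_,
      df > freq_thr ~ "increasing",
      df < -freq_thr ~ "decreasing",
      TRUE ~ "stable"
    )
  )
}

#' Smooth and classify a cycle table
#'
#' Convenience wrapper: smooths `freq_hz` and `temp_c` over the configured
#' windows, classifies per-cycle changes, and appends `temp_state` and
#' `freq_state` columns to the cycle table.
#'
#' @param cycles Cycle tibble with `freq_hz` and `temp_c` columns.
#' @param config A [run_config()] (windows and thresholds are read from it).
#' @param align Moving-average alignment, see [smooth_series()].
#' @return The cycle tibble with `temp_state` and `freq_state` appended.
#' @export
classify_cycles <- function(cycles, config = run_config(),
                            align = c("center", "right")) {
  align <- match.arg(align)
  stopifnot(all(c("freq_hz", "temp_c") %in% names(cycles)))
  sf <- smooth_series(cycles$freq_hz, config$freq_smooth_window, align)
  st <- smooth_series(cycles$temp_c, config$temp_smooth_window, align)
  cls <- classify_series(st, sf,
                         temp_thr = config$temp_increase_threshold,
                         freq_thr = config$freq_change_threshold)
  cycles$temp_state <- cls$temp_state
  cycles$freq_state <- cls$freq_state
  cycles
}

#' Jag conditional probabilities
#'
#' The non-monotonicity ("jag") statistic: among temperature-increasing
#' cycles, the proportion in which the smoothed frequency decreased; and
#' among temperature-stable cycles, the proportion in which it increased. A
#' smooth monotonic warming response gives both probabilities near zero once
#' steady state is reached; Ih-blocked preparations show markedly elevated
#' values of both.
#'
#' @param classes Tibble with `temp_state` and `freq_state` columns (from
#'   [classify_series()] or a classified cycle table).
#' @return One-row tibble: `p_dec_given_inc`, `p_inc_given_stable` (each
#'   `NA` when its conditioning set is empty), `n_inc`, `n_stable`,
#'   `n_dec_in_inc`, `n_inc_in_stable`.
#' @export
jag_probabilities <- function(classes) {
  stopifnot(all(c("temp_state", "freq_state") %in% names(classes)))
  ok <- !is.na(classes$temp_state)
  if (!any(ok)) rlang::abort("no classified cycles")
  ts <- classes$temp_state[ok]
  fs <- classes$freq_state[ok]
  n_inc <- sum(ts == "increasing")
  n_stable <- sum(ts == "stable")
  n_dec_in_inc <- sum(ts == "increasing" & fs == "decreasing")
  n_inc_in_stable <- sum(ts == "stable" & fs == "increasing")
  tibble::tibble(
    p_dec_given_inc = if (n_inc > 0) n_dec_in_inc / n_inc else NA_real_,
    p_inc_given_stable = if (n_stable > 0) n_inc_in_stable / n_stable else NA_real_,
    n_inc = n_inc,
    n_stable = n_stable,
    n_dec_in_inc = n_dec_in_inc,
    n_inc_in_stable = n_inc_in_stable
  )
}
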
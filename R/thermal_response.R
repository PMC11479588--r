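#' Attach bath temperature to cycles
#'
#' Each cycle's temperature is the time-average of the linearly interpolated
#' thermocouple trace over `[start_s, end_s)`: the trapezoidal integral over
#' the trace's native samples inside the cycle plus the interpolated
#' endpoints, divided by the period. Cycles outside the span of the trace
#' use nearest-sample extrapolation with a warning.
#'
#' @param cycles Cycle tibble from [build_cycles()].
#' @param trace Temperature tibble (`time_s`, `temp_c`) from
#'   [read_temperature()] or [make_protocol()].
#' @return `cycles` with a `temp_c` column.
#' @export
annotate_temperature <- function(cycles, trace) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "temp_c") %in% names(trace)))
  if (nrow(trace) == 0) rlang::abort("empty temperature trace")
  tt <- trace$time_s
  tv <- trace$temp_c
  if (min(cycles$start_s) < tt[1] || max(cycles$end_s) > tt[length(tt)]) {
    rlang::warn("cycles extend beyond the temperature trace; extrapolating nearest sample")
  }
  temp_at <- function(x) {
    stats::approx(tt, tv, xout = x, method = "linear", rule = 2)$y
  }
  cycles$temp_c <- vapply(seq_len(nrow(cycles)), function(i) {
    a <- cycles$start_s[i]
    b <- cycles$end_s[i]
    inner <- tt[tt > a & tt < b]
    knots <- c(a, inner, b)
    vals <- temp_at(knots)
    # trapezoid over the knots = exact integral of the piecewise-linear trace
    sum(diff(knots) * (vals[-1] + vals[-length(vals)]) / 2) / (b - a)
  }, numeric(1))
  cycles
}

#' Find holding windows
#'
#' A holding window is a maximal contiguous run of cycles whose temperature
#' stays within `tolerance` of a protocol target. A cycle eligible for two
#' targets is given to the nearer one; runs shorter than `min_cycles`
#' (grazing transits of the tolerance band during a ramp) are discarded.
#'
#' @param cycles Cycle tibble with a `temp_c` column
#'   (see [annotate_temperature()]).
#' @param targets Protocol target temperatures, degC (distinct).
#' @param tolerance Band half-width, degC (default 0.3).
#' @param min_cycles Minimum run length to keep (default 10).
#' @return Tibble with one row per window: `window`, `target_temp`,
#'   `first_cycle`, `last_cycle`, `n_cycles`, `mean_temp`.
#' @export
find_holding_windows <- function(cycles, targets, tolerance = 0.3,
                                 min_cycles = 10) {
  stopifnot("temp_c" %in% names(cycles), tolerance > 0)
  if (anyDuplicated(targets)) rlang::abort("`targets` must be distinct")
  d <- abs(outer(cycles$temp_c, targets, "-"))
  nearest <- max.col(-d, ties.method = "first")
  target <- targets[nearest]
  target[d[cbind(seq_len(nrow(cycles)), nearest)] > tolerance] <- NA_real_
  r <- rle(target)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values) & r$lengths >= min_cycles
  out <- tibble::tibble(
    window = seq_len(sum(keep)),
    target_temp = r$values[keep],
    first_cycle = cycles$cycle[starts[keep]],
    last_cycle = cycles$cycle[ends[keep]],
    n_cycles = r$lengths[keep],
    mean_temp = vapply(which(keep), function(i) {
      mean(cycles$temp_c[starts[i]:ends[i]])
    }, numeric(1))
  )
  missing <- setdiff(targets, out$target_temp)
  if (length(missing) > 0) {
    rlang::warn(paste0("no holding window found for target(s): ",
                       paste(missing, collapse = ", ")))
  }
  out
}

# SD with the single-observation convention: one value has zero spread.
sd_or_zero <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (length(x) == 1) return(0)
  stats::sd(x)
}

#' Per-target steady-state means
#'
#' Pools the cycles of all holding windows at each target temperature and
#' reports arithmetic mean, SD and n of cycle frequency and of every phase
#' column present.
#'
#' @param cycles Cycle tibble with `temp_c` (and optionally phase columns).
#' @param windows Window tibble from [find_holding_windows()].
#' @return Tibble keyed by `target_temp` with `n_cycles`, `mean_freq_hz`,
#'   `sd_freq_hz`, and `mean_`/`sd_` columns for each phase measure.
#' @export
steady_state_means <- function(cycles, windows) {
  if (nrow(windows) == 0) rlang::abort("no holding windows supplied")
  member <- purrr::map(seq_len(nrow(windows)), function(i) {
    rows <- cycles$cycle >= windows$first_cycle[i] &
      cycles$cycle <= windows$last_cycle[i]
    dplyr::mutate(cycles[rows, , drop = FALSE],
                  target_temp = windows$target_temp[i])
  }) |> purrr::list_rbind()
  meas <- intersect(
    c("freq_hz", "pd_off_phase", "lp_on_phase", "lp_off_phase",
      "py_on_phase", "py_off_phase", "lp_duty", "pd_duration_s",
      "delay_lp_on_pd_off"),
    names(member)
  )
  member |>
    dplyr::group_by(.data$target_temp) |>
    dplyr::summarise(
      n_cycles = dplyr::n(),
      mean_temp = mean(.data$temp_c),
      dplyr::across(dplyr::all_of(meas),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         sd = ~ sd_or_zero(.x)),
                    .names = "{.fn}_{.col}"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$target_temp)
}

#' Fit Q10 temperature sensitivity
#'
#' Fits the temperature-scaling law `f(T) = f_ref * Q10^((T - T_ref)/10)` to
#' per-temperature mean frequencies by ordinary least squares of `ln f` on
#' `(T - T_ref)/10`: `Q10 = exp(slope)`, `f_ref = exp(intercept)`. This uses
#' every holding temperature, not just the endpoints; the endpoint ratio
#' estimator is available as [q10_endpoint()].
#'
#' @param data Data frame of per-temperature means.
#' @param temp,freq Names of the temperature (degC) and frequency (Hz)
#'   columns (defaults `target_temp`, `mean_freq_hz`).
#' @param t_ref Reference temperature, degC (default 11).
#' @return An object of class `"q10_fit"` with elements `f_ref`, `q10`,
#'   `t_ref`, `residual_sd` (log space; 0 when n <= 2), `n`, `data`, and the
#'   underlying `lm` fit. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
#' @examples
#' fit_q10(data.frame(target_temp = c(11, 21), mean_freq_hz = c(1.2, 2.1)))
fit_q10 <- function(data, temp = "target_temp", freq = "mean_freq_hz",
                    t_ref = 11) {
  stopifnot(is.data.frame(data), temp %in% names(data), freq %in% names(data))
  d <- tibble::tibble(temp_c = data[[temp]], freq_hz = data[[freq]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 2) rlang::abort("fit_q10 needs at least 2 (T, f) points")
  if (any(d$freq_hz <= 0)) rlang::abort("fit_q10 requires all frequencies > 0")
  d$x <- (d$temp_c - t_ref) / 10
  fit <- stats::lm(log(freq_hz) ~ x, data = d)
  res_sd <- if (nrow(d) <= 2) 0 else stats::sd(stats::residuals(fit))
  structure(
    list(
      f_ref = unname(exp(stats::coef(fit)[1])),
      q10 = unname(exp(stats::coef(fit)[2])),
      t_ref = t_ref,
      residual_sd = res_sd,
      n = nrow(d),
      data = d[c("temp_c", "freq_hz")],
      fit = fit
    ),
    class = "q10_fit"
  )
}

#' @export
print.q10_fit <- function(x, ...) {
  cat(sprintf("<q10_fit> Q10 = %.4g, f_ref = %.4g Hz at %.3g degC (n = %d, log-residual SD = %.3g)\n",
              x$q10, x$f_ref, x$t_ref, x$n, x$residual_sd))
  invisible(x)
}

#' Endpoint Q10 estimator
#'
#' The classic two-point estimator `(f_high/f_low)^(10/(T_high - T_low))`,
#' provided alongside the log-linear fit of [fit_q10()] for comparison with
#' reports that use only the temperature extremes.
#'
#' @param f_low,f_high Frequencies (Hz) at the low and high temperature.
#' @param t_low,t_high Temperatures, degC.
#' @return The Q10 as a single number.
#' @export
#' @examples
#' q10_endpoint(1.2, 2.1, 11, 21)  # 1.75
q10_endpoint <- function(f_low, f_high, t_low = 11, t_high = 21) {
  stopifnot(f_low > 0, f_high > 0, t_high != t_low)
  (f_high / f_low)^(10 / (t_high - t_low))
}

#' Frequency differences between two conditions
#'
#' Aligns two per-temperature steady-state tables on their target grid and
#' returns the per-target difference in mean frequency (first minus second),
#' together with each condition's overall change from the lowest to the
#' highest target.
#'
#' @param means_a,means_b Tables from [steady_state_means()] sharing the
#'   target-temperature grid.
#' @param labels Condition labels, used in messages (default
#'   `c("a", "b")`).
#' @return Tibble with `target_temp`, `freq_a`, `freq_b`, `diff_hz`, and an
#'   attribute `"within_change"`: each condition's mean frequency at the
#'   highest target minus that at the lowest.
#' @export
condition_difference <- function(means_a, means_b, labels = c("a", "b")) {
  ga <- means_a$target_temp
  gb <- means_b$target_temp
  if (!setequal(ga, gb)) {
    rlang::abort(paste0(
      "target grids differ; missing from one table: ",
      paste(union(setdiff(ga, gb), setdiff(gb, ga)), collapse = ", ")
    ))
  }
  a <- means_a[order(ga), ]
  b <- means_b[order(gb), ]
  out <- tibble::tibble(
    target_temp = a$target_temp,
    freq_a = a$mean_freq_hz,
    freq_b = b$mean_freq_hz,
    diff_hz = a$mean_freq_hz - b$mean_freq_hz
  )
  chg <- function(f) f[length(f)] - f[1]
  wc <- c(chg(out$freq_a), chg(out$freq_b))
  names(wc) <- labels
  attr(out, "within_change") <- wc
  out
}
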
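#' Fit a phase-versus-temperature slope
#'
#' Ordinary least-squares line through per-temperature mean phases for one
#' event (PD OFF, LP ON, ...) in one experiment. The slope is reported both
#' per degC and per 10 degC; by the advance convention a negative slope is a
#' phase advance.
#'
#' @param data Data frame of per-temperature mean phases (typically the
#'   output of [steady_state_means()]).
#' @param phase Name of the phase column to fit (e.g. `"mean_lp_off_phase"`).
#' @param temp Name of the temperature column (default `"target_temp"`).
#' @param event Optional event label carried through to results.
#' @return Object of class `"phase_slope"` with `slope_per_c`,
#'   `slope_per_10c` (= 10 x `slope_per_c`), `intercept`, `n_temps`,
#'   `event`, `data`, and the underlying `lm` fit.
#' @export
#' @examples
#' d <- data.frame(target_temp = c(11, 13, 15, 17, 19, 21),
#'                 mean_lp_off_phase = 0.66 - 0.007 * (c(11, 13, 15, 17, 19, 21) - 11))
#' fit_phase_slope(d, "mean_lp_off_phase")
fit_phase_slope <- function(data, phase, temp = "target_temp", event = phase) {
  stopifnot(is.data.frame(data), phase %in% names(data), temp %in% names(data))
  d <- tibble::tibble(temp_c = data[[temp]], phase = data[[phase]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 2) rlang::abort("fit_phase_slope needs >= 2 temperatures")
  fit <- stats::lm(phase ~ temp_c, data = d)
  co <- stats::coef(fit)
  structure(
    list(
      event = event,
      slope_per_c = unname(co[2]),
      slope_per_10c = unname(10 * co[2]),
      intercept = unname(co[1]),
      n_temps = nrow(d),
      data = d,
      fit = fit
    ),
    class = "phase_slope"
  )
}

#' @export
print.phase_slope <- function(x, ...) {
  cat(sprintf("<phase_slope> %s: %+.4g per 10 degC (%s; n = %d temps)\n",
              x$event, x$slope_per_10c,
              if (x$slope_per_10c < 0) "advance" else "delay", x$n_temps))
  invisible(x)
}

#' Group-level test of phase constancy
#'
#' Tests whether per-experiment phase-versus-temperature slopes differ from
#' zero across animals. Normality of the slopes is assessed with a
#' Shapiro-Wilk test at `alpha`: normal slopes get a two-sided one-sample
#' t-test against zero, non-normal slopes a Wilcoxon signed-rank test.
#' p-values are Bonferroni-adjusted for the battery of tests run in a
#' session (by default 10: five phase events by two conditions).
#'
#' @param slopes Numeric vector of per-experiment slopes (one per animal;
#'   per degC or per 10 degC, as long as it is consistent).
#' @param n_tests Bonferroni multiplier (default 10).
#' @param alpha Significance level for the normality gate (default 0.05).
#' @param event Optional label carried into the result.
#' @return One-row tibble: `event`, `test_name`, `statistic`, `p_raw`,
#'   `p_adjusted` (`min(1, p_raw * n_tests)`), `n`, `normality_p`,
#'   `mean_slope`.
#' @export
group_slope_test <- function(slopes, n_tests = 10, alpha = 0.05,
                             event = NA_character_) {
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) < 3) rlang::abort("need >= 3 slopes for a group test")
  if (stats::sd(slopes) == 0) {
    rlang::abort("degenerate: zero-variance slopes")
  }
  norm_p <- tryCatch(stats::shapiro.test(slopes)$p.value,
                     error = function(e) 0)
  if (norm_p >= alpha) {
    ht <- stats::t.test(slopes, mu = 0)
    name <- "one-sample t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(slopes, mu = 0))
    name <- "Wilcoxon signed-rank"
  }
  tibble::tibble(
    event = event,
    test_name = name,
    statistic = unname(ht$statistic),
    p_raw = ht$p.value,
    p_adjusted = min(1, ht$p.value * n_tests),
    n = length(slopes),
    normality_p = norm_p,
    mean_slope = mean(slopes)
  )
}

#' Per-event phase slopes for one experiment
#'
#' Fits [fit_phase_slope()] for every phase event present in a steady-state
#' table, returning one tidy row per event.
#'
#' @param means Output of [steady_state_means()].
#' @param events Phase events to fit; defaults to the five canonical ones
#'   that are present.
#' @param temp Temperature column to regress on (default `"target_temp"`).
#' @return Tibble with columns `event`, `slope_per_c`, `slope_per_10c`,
#'   `intercept`, `n_temps`.
#' @export
phase_slopes <- function(means, events = NULL, temp = "target_temp") {
  canonical <- c("pd_off_phase", "lp_on_phase", "lp_off_phase",
                 "py_on_phase", "py_off_phase")
  if (is.null(events)) {
    events <- canonical[paste0("mean_", canonical) %in% names(means)]
  }
  purrr::map(events, function(ev) {
    col <- paste0("mean_", ev)
    if (sum(stats::complete.cases(means[c(temp, col)])) < 2) {
      return(NULL)
    }
    fs <- fit_phase_slope(means, col, temp = temp, event = ev)
    tibble::tibble(event = ev, slope_per_c = fs$slope_per_c,
                   slope_per_10c = fs$slope_per_10c,
                   intercept = fs$intercept, n_temps = fs$n_temps)
  }) |>
    purrr::compact() |>
    purrr::list_rbind()
}
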
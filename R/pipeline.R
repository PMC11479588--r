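#' Analyse one experiment end to end
#'
#' Runs the full per-experiment chain: burst detection, cycle construction,
#' follower-event assignment, phases, temperature annotation, holding
#' windows, steady-state means, Q10 fit, smoothing/classification, jag
#' probabilities and per-event phase slopes.
#'
#' @param experiment A `"pyloric_experiment"` (see [experiment_record()] or
#'   [simulate_experiment()]).
#' @param config A [run_config()].
#' @param targets Holding-window target temperatures; by default the
#'   rounded unique plateau values are inferred from the temperature trace
#'   are not guessed — pass them explicitly or leave `NULL` to use
#'   2-degC-rounded values covered by the trace.
#' @return A list: `id`, `condition`, `cycles` (fully annotated tibble),
#'   `windows`, `steady`, `q10` (a [fit_q10()] object), `jag` (one-row
#'   tibble), `slopes` (per-event tibble), `n_cycles`.
#' @export
analyse_experiment <- function(experiment, config = run_config(),
                               targets = NULL) {
  stopifnot(inherits(experiment, "pyloric_experiment"))
  bursts <- detect_bursts(experiment$trains,
                          min_spikes = config$burst_min_spikes,
                          min_gap = config$burst_min_gap)
  cycles <- build_cycles(bursts) |>
    assign_events(bursts) |>
    compute_phases() |>
    annotate_temperature(experiment$temperature) |>
    classify_cycles(config)
  if (is.null(targets)) {
    targets <- infer_targets(experiment$temperature)
  }
  windows <- find_holding_windows(cycles, targets,
                                  tolerance = config$holding_tolerance,
                                  min_cycles = config$min_window_cycles)
  steady <- steady_state_means(cycles, windows)
  # regress on the measured window-mean temperature, not the nominal
  # target: ramp-tail cycles inside the tolerance band then cancel
  q10 <- fit_q10(steady, temp = "mean_temp", t_ref = config$t_ref)
  jag <- jag_probabilities(cycles)
  slopes <- phase_slopes(steady, temp = "mean_temp")
  list(id = experiment$id, condition = experiment$condition,
       cycles = cycles, windows = windows, steady = steady, q10 = q10,
       jag = jag, slopes = slopes, n_cycles = nrow(cycles))
}

#' Infer protocol hold temperatures from a temperature trace
#'
#' Finds plateaus — stretches where the trace drifts more slowly than
#' `max_rate` for at least `min_duration` — and returns the median
#' temperature of each, merging plateaus closer than `merge_within`. Used
#' when the protocol targets are not given explicitly.
#'
#' @param trace Temperature tibble (`time_s`, `temp_c`).
#' @param max_rate Maximum |dT/dt| inside a plateau, degC/s
#'   (default 0.005).
#' @param min_duration Minimum plateau length, s (default 60).
#' @param merge_within Plateaus closer than this are one target, degC
#'   (default 0.5).
#' @return Ascending numeric vector of hold temperatures.
#' @export
infer_targets <- function(trace, max_rate = 0.005, min_duration = 60,
                          merge_within = 0.5) {
  stopifnot(nrow(trace) >= 3)
  n <- nrow(trace)
  dt_med <- stats::median(diff(trace$time_s))
  # smooth the trace and take a central difference over a few seconds so
  # thermocouple read-out noise does not break plateaus apart
  w <- max(3L, min(n, as.integer(round(15 / dt_med)) %/% 2L * 2L + 1L))
  tsm <- smooth_series(trace$temp_c, w)
  k <- max(1L, min((n - 1L) %/% 2L, as.integer(round(5 / dt_med))))
  idx <- seq_len(n)
  lo <- pmax(idx - k, 1L)
  hi <- pmin(idx + k, n)
  rate <- abs((tsm[hi] - tsm[lo]) / (trace$time_s[hi] - trace$time_s[lo]))
  flat <- rate < max_rate
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  targets <- numeric(0)
  for (i in which(r$values)) {
    span <- trace$time_s[ends[i]] - trace$time_s[starts[i]]
    if (span >= min_duration) {
      targets <- c(targets,
                   stats::median(trace$temp_c[starts[i]:ends[i]]))
    }
  }
  if (length(targets) == 0) {
    rlang::warn("no plateau found; using the trace median as single target")
    return(stats::median(trace$temp_c))
  }
  targets <- sort(targets)
  merged <- targets[1]
  for (tt in targets[-1]) {
    if (tt - merged[length(merged)] > merge_within) merged <- c(merged, tt)
  }
  merged
}

#' Run the full multi-experiment analysis
#'
#' Applies [analyse_experiment()] to every record, isolating failures (a
#' corrupt experiment is recorded under `errors` and the rest continue),
#' then computes the group-level statistics: per-event, per-condition
#' phase-constancy tests (Bonferroni multiplier = the number of tests
#' actually run), and paired condition comparisons of Q10 and jag
#' probabilities wherever at least three experiments have both conditions.
#'
#' @param experiments List of `"pyloric_experiment"` records.
#' @param config A [run_config()].
#' @return Object of class `"pyloric_report"`: `per_experiment` (named
#'   list), `errors` (named list of condition messages), `group` (list of
#'   tidy tibbles), `config`.
#' @export
run_full_analysis <- function(experiments, config = run_config()) {
  if (length(experiments) == 0) rlang::abort("no experiments supplied")
  results <- list()
  errors <- list()
  for (ex in experiments) {
    key <- paste(ex$id, ex$condition, sep = ":")
    res <- tryCatch(analyse_experiment(ex, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
    } else {
      results[[key]] <- res
    }
  }
  if (length(results) == 0) rlang::abort("zero analyzable experiments")

  slope_tbl <- purrr::imap(results, function(r, key) {
    dplyr::mutate(r$slopes, id = r$id, condition = r$condition)
  }) |> purrr::list_rbind()
  combos <- dplyr::distinct(slope_tbl, .data$event, .data$condition)
  eligible <- purrr::map_lgl(seq_len(nrow(combos)), function(i) {
    sum(slope_tbl$event == combos$event[i] &
          slope_tbl$condition == combos$condition[i]) >= 3
  })
  n_tests <- sum(eligible)
  slope_tests <- purrr::map(which(eligible), function(i) {
    sel <- slope_tbl$event == combos$event[i] &
      slope_tbl$condition == combos$condition[i]
    dplyr::mutate(
      group_slope_test(slope_tbl$slope_per_10c[sel],
                       n_tests = max(1, n_tests), alpha = config$alpha,
                       event = combos$event[i]),
      condition = combos$condition[i], .after = "event")
  }) |> purrr::list_rbind()

  q10_tbl <- purrr::map(results, function(r) {
    tibble::tibble(id = r$id, condition = r$condition, q10 = r$q10$q10,
                   f_ref = r$q10$f_ref)
  }) |> purrr::list_rbind()
  jag_tbl <- purrr::map(results, function(r) {
    dplyr::mutate(r$jag, id = r$id, condition = r$condition,
                  .before = 1)
  }) |> purrr::list_rbind()

  paired <- list()
  conds <- unique(q10_tbl$condition)
  if (length(conds) >= 2) {
    for (j in seq_len(length(conds) - 1)) {
      for (l in (j + 1):length(conds)) {
        wide <- tidyr::pivot_wider(q10_tbl[c("id", "condition", "q10")],
                                   names_from = "condition",
                                   values_from = "q10")
        a <- wide[[conds[j]]]
        b <- wide[[conds[l]]]
        ok <- stats::complete.cases(a, b)
        if (sum(ok) >= 3) {
          paired[[paste0("q10_", conds[j], "_vs_", conds[l])]] <-
            normality_gated_paired_test(a[ok], b[ok], alpha = config$alpha,
                                        labels = c(conds[j], conds[l]))
        }
      }
    }
  }

  structure(
    list(per_experiment = results, errors = errors,
         group = list(slope_tests = slope_tests, q10 = q10_tbl,
                      jag = jag_tbl, paired = paired),
         config = config),
    class = "pyloric_report"
  )
}

#' @export
print.pyloric_report <- function(x, ...) {
  cat(sprintf("<pyloric_report> %d experiment(s) analysed, %d failed\n",
              length(x$per_experiment), length(x$errors)))
  if (nrow(x$group$q10) > 0) {
    q <- x$group$q10 |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(mean_q10 = mean(.data$q10), n = dplyr::n(),
                       .groups = "drop")
    print(q)
  }
  invisible(x)
}

# Recursively convert report pieces to plain lists with stable ordering.
report_payload <- function(report) {
  num <- function(v) round(v, 12)
  tidy_tbl <- function(tb) {
    tb <- as.data.frame(tb)
    for (nm in names(tb)) if (is.numeric(tb[[nm]])) tb[[nm]] <- num(tb[[nm]])
    tb
  }
  per_exp <- purrr::map(report$per_experiment[
    order(names(report$per_experiment))], function(r) {
      list(
        id = r$id, condition = r$condition, n_cycles = r$n_cycles,
        q10 = list(q10 = num(r$q10$q10), f_ref = num(r$q10$f_ref),
                   t_ref = r$q10$t_ref, residual_sd = num(r$q10$residual_sd),
                   n = r$q10$n),
        windows = tidy_tbl(r$windows),
        steady = tidy_tbl(r$steady),
        jag = tidy_tbl(r$jag),
        slopes = tidy_tbl(r$slopes)
      )
    })
  list(
    config = purrr::compact(unclass(report$config)),
    n_experiments = length(report$per_experiment),
    errors = if (length(report$errors) == 0) list() else
      report$errors[order(names(report$errors))],
    per_experiment = per_exp,
    group = list(
      slope_tests = tidy_tbl(report$group$slope_tests),
      q10 = tidy_tbl(report$group$q10),
      jag = tidy_tbl(report$group$jag),
      paired = if (length(report$group$paired) == 0) list() else
        purrr::map(report$group$paired[
          order(names(report$group$paired))], tidy_tbl)
    )
  )
}

#' Serialise a report as deterministic JSON
#'
#' Fixed key order and 12-significant-digit floats, so identical inputs and
#' configuration give byte-identical files.
#'
#' @param report A `"pyloric_report"`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "pyloric_report"))
  js <- jsonlite::toJSON(report_payload(report), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
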
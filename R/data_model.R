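#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline in one validated list so a
#' whole analysis can be reproduced from a single JSON file. Defaults follow
#' standard practice for the pyloric rhythm: bursts are two or more spikes
#' separated by less than 200 ms, holding windows are cycles within 0.3 degC
#' of a protocol target, frequency and temperature are smoothed over 30 and
#' 10 cycles, and per-cycle changes count as real when they exceed
#' 0.01 degC (temperature) or 0.002 Hz (frequency).
#'
#' @param burst_min_spikes Minimum spikes per burst (count, default 2).
#' @param burst_min_gap Inter-burst interval in seconds; a gap of at least
#'   this length splits bursts (default 0.200).
#' @param holding_tolerance Half-width of a holding window in degC
#'   (default 0.3).
#' @param min_window_cycles Minimum contiguous cycles for a holding window;
#'   shorter grazes of the tolerance band during ramps are discarded
#'   (default 10).
#' @param freq_smooth_window Moving-average window for frequency, in cycles
#'   (default 30).
#' @param temp_smooth_window Moving-average window for temperature, in cycles
#'   (default 10).
#' @param temp_increase_threshold Per-cycle smoothed temperature change above
#'   which a cycle is "increasing", degC/cycle (default 0.01).
#' @param freq_change_threshold Per-cycle smoothed frequency change beyond
#'   which a cycle is "increasing"/"decreasing", Hz/cycle (default 0.002).
#' @param t_ref Reference temperature for Q10 fits, degC (default 11).
#' @param period_match_tolerance Maximum period difference for
#'   [match_periods()], seconds (default 0.02).
#' @param alpha Significance level for normality gates and tests
#'   (default 0.05).
#' @param n_phase_tests Bonferroni multiplier for the phase-constancy test
#'   battery; 5 phase events x 2 conditions by default (10).
#' @param rng_seed Optional integer seed recorded alongside results.
#'
#' @return A list of class `"run_config"`.
#' @export
#' @examples
#' cfg <- run_config(burst_min_gap = 0.25)
#' cfg$burst_min_gap
run_config <- function(burst_min_spikes = 2,
                       burst_min_gap = 0.200,
                       holding_tolerance = 0.3,
                       min_window_cycles = 10,
                       freq_smooth_window = 30,
                       temp_smooth_window = 10,
                       temp_increase_threshold = 0.01,
                       freq_change_threshold = 0.002,
                       t_ref = 11,
                       period_match_tolerance = 0.02,
                       alpha = 0.05,
                       n_phase_tests = 10,
                       rng_seed = NULL) {
  cfg <- list(
    burst_min_spikes = as.integer(burst_min_spikes),
    burst_min_gap = burst_min_gap,
    holding_tolerance = holding_tolerance,
    min_window_cycles = as.integer(min_window_cycles),
    freq_smooth_window = as.integer(freq_smooth_window),
    temp_smooth_window = as.integer(temp_smooth_window),
    temp_increase_threshold = temp_increase_threshold,
    freq_change_threshold = freq_change_threshold,
    t_ref = t_ref,
    period_match_tolerance = period_match_tolerance,
    alpha = alpha,
    n_phase_tests = as.integer(n_phase_tests),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  thresholds <- c(
    "burst_min_gap", "holding_tolerance", "temp_increase_threshold",
    "freq_change_threshold", "period_match_tolerance"
  )
  for (nm in thresholds) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L ||
        !is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      rlang::abort(paste0("`", nm, "` must be a single positive number"))
    }
  }
  for (nm in c("burst_min_spikes", "min_window_cycles",
               "freq_smooth_window", "temp_smooth_window",
               "n_phase_tests")) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      rlang::abort(paste0("`", nm, "` must be >= 1"))
    }
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    rlang::abort("`alpha` must lie in (0, 1)")
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  flat <- purrr::compact(unclass(x))
  for (nm in names(flat)) cat(sprintf("  %-24s %s\n", nm, format(flat[[nm]])))
  invisible(x)
}

#' Read and write a run configuration as JSON
#'
#' @param path File path of the JSON configuration.
#' @return `read_run_config()` returns a [run_config()] object;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config fields: ",
                        paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A [run_config()] object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(purrr::compact(unclass(config)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Internal: read a delimited file, erroring with a file line number on the
# first unparseable numeric field. `cols` names the expected header columns.
read_checked_csv <- function(path, cols, numeric_cols) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  )
  if (nrow(raw) == 0) {
    return(raw)
  }
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0(path, ": missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  raw <- raw[cols]
  for (nm in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[nm]]))
    # NaN/Inf strings parse as non-finite values; they are caught by the
    # finiteness checks downstream, not as parse errors
    bad <- which(is.na(parsed) & !is.nan(parsed) &
                   !(is.na(raw[[nm]]) | raw[[nm]] == ""))
    if (length(bad) > 0) {
      # +1 for the header row so the number matches the text file
      rlang::abort(sprintf("%s: unparseable value '%s' in column '%s' at line %d",
                           path, raw[[nm]][bad[1]], nm, bad[1] + 1L))
    }
    raw[[nm]] <- parsed
  }
  raw
}

#' Read labelled spike times
#'
#' Reads a two-column CSV (`time_s`, `unit`) of spike times for identified
#' units (typically PD, LP and PY), or a single-column CSV (`time_s`) for one
#' unit named via `unit`. Times are sorted within unit; exact duplicate
#' timestamps within a unit are collapsed with a warning (sorted real data
#' contain near-duplicates from merged recordings).
#'
#' @param path CSV file with a header row.
#' @param unit Unit label to apply when the file has only a `time_s` column.
#' @param units Time unit of the file, `"s"` (default) or `"ms"`; values are
#'   converted to seconds on ingest.
#' @return A tibble with columns `time_s` (seconds, ascending within unit)
#'   and `unit` (character).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time_s,unit", "0.10,PD", "0.05,PD", "0.20,LP"), f)
#' read_spike_trains(f)
read_spike_trains <- function(path, unit = NULL, units = c("s", "ms")) {
  units <- match.arg(units)
  header <- names(suppressWarnings(
    readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                    progress = FALSE)
  ))
  single <- !("unit" %in% header)
  raw <- read_checked_csv(path,
                          cols = if (single) "time_s" else c("time_s", "unit"),
                          numeric_cols = "time_s")
  if (nrow(raw) == 0) {
    rlang::warn(paste0(path, ": no spike rows; returning empty train set"))
    return(tibble::tibble(time_s = numeric(0), unit = character(0)))
  }
  if (single) {
    if (is.null(unit)) {
      rlang::abort("single-column spike file requires a `unit` label")
    }
    raw$unit <- unit
  }
  if (units == "ms") raw$time_s <- raw$time_s / 1000
  if (anyNA(raw$time_s)) rlang::abort(paste0(path, ": missing spike time"))
  if (any(raw$time_s < 0)) rlang::abort(paste0(path, ": negative spike time"))
  out <- dplyr::arrange(raw, .data$unit, .data$time_s)
  n_in <- nrow(out)
  out <- dplyr::distinct(out, .data$unit, .data$time_s)
  if (nrow(out) < n_in) {
    rlang::warn(sprintf("%s: collapsed %d duplicate spike timestamp(s)",
                        path, n_in - nrow(out)))
  }
  tibble::as_tibble(out[c("time_s", "unit")])
}

#' Read a temperature trace
#'
#' Reads a two-column CSV (`time_s`, `temp_c`) of thermocouple readings.
#' Timestamps must be strictly ascending and all values finite.
#'
#' @inheritParams read_spike_trains
#' @return A tibble with columns `time_s` and `temp_c`.
#' @export
read_temperature <- function(path, units = c("s", "ms")) {
  units <- match.arg(units)
  raw <- read_checked_csv(path, cols = c("time_s", "temp_c"),
                          numeric_cols = c("time_s", "temp_c"))
  if (nrow(raw) < 2) {
    rlang::abort(paste0(path, ": temperature trace needs at least 2 samples"))
  }
  if (units == "ms") raw$time_s <- raw$time_s / 1000
  if (anyNA(raw$time_s) || anyNA(raw$temp_c) ||
      any(!is.finite(raw$time_s)) || any(!is.finite(raw$temp_c))) {
    rlang::abort(paste0(path, ": non-finite time or temperature value"))
  }
  if (any(diff(raw$time_s) <= 0)) {
    rlang::abort(paste0(path, ": times not strictly ascending"))
  }
  tibble::as_tibble(raw)
}

# Canonical cycle-table columns, in serialization order. Extra columns are
# appended after these.
cycle_table_core <- c(
  "cycle", "start_s", "end_s", "period_s", "freq_hz", "temp_c",
  "pd_off_phase", "lp_on_phase", "lp_off_phase", "py_on_phase",
  "py_off_phase", "temp_state", "freq_state"
)

#' Write and read a per-cycle table
#'
#' Serialises a cycle table (one row per pyloric cycle) as CSV. Missing
#' measurements (e.g. no LP burst in a cycle) are written as empty fields,
#' never zeros, and the writer/reader pair round-trips numeric values to
#' better than 1e-9 s.
#'
#' @param cycles A cycle tibble as produced by [build_cycles()] and
#'   downstream annotators.
#' @param path Output CSV path.
#' @return `write_cycle_table()` returns `path` invisibly;
#'   `read_cycle_table()` returns the cycle tibble.
#' @export
write_cycle_table <- function(cycles, path) {
  stopifnot(is.data.frame(cycles))
  front <- intersect(cycle_table_core, names(cycles))
  out <- cycles[c(front, setdiff(names(cycles), front))]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_cycle_table
#' @export
read_cycle_table <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      cycle = readr::col_integer(),
      temp_state = readr::col_character(),
      freq_state = readr::col_character(),
      .default = readr::col_double()
    ),
    na = "", progress = FALSE
  )
  tibble::as_tibble(out)
}

#' Bundle one experiment's data
#'
#' Light-weight container pairing labelled spike trains with the simultaneous
#' temperature trace and a condition label (`saline`, `Cs`, or `Cs+PTX`).
#' Rhythm analysis requires a `PD` train, since PD burst onsets define the
#' pyloric cycle.
#'
#' @param trains Spike tibble (`time_s`, `unit`) as from
#'   [read_spike_trains()].
#' @param temperature Temperature tibble (`time_s`, `temp_c`) as from
#'   [read_temperature()].
#' @param condition One of `"saline"`, `"Cs"`, `"Cs+PTX"`.
#' @param id Experiment identifier (animal/preparation).
#' @param metadata Optional named list of free-form metadata.
#' @return A list of class `"pyloric_experiment"`.
#' @export
experiment_record <- function(trains, temperature,
                              condition = c("saline", "Cs", "Cs+PTX"),
                              id = "exp1", metadata = list()) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(trains), all(c("time_s", "unit") %in% names(trains)))
  stopifnot(is.data.frame(temperature),
            all(c("time_s", "temp_c") %in% names(temperature)))
  if (!"PD" %in% trains$unit) {
    rlang::abort("experiment needs a train labelled 'PD' for rhythm analysis")
  }
  structure(
    list(trains = tibble::as_tibble(trains),
         temperature = tibble::as_tibble(temperature),
         condition = condition, id = id, metadata = metadata),
    class = "pyloric_experiment"
  )
}

#' @export
print.pyloric_experiment <- function(x, ...) {
  cat(sprintf("<pyloric_experiment> id=%s condition=%s\n", x$id, x$condition))
  counts <- table(x$trains$unit)
  cat("  spikes:", paste(names(counts), as.integer(counts),
                         sep = "=", collapse = " "), "\n")
  cat(sprintf("  temperature: %d samples, %.1f-%.1f degC\n",
              nrow(x$temperature), min(x$temperature$temp_c),
              max(x$temperature$temp_c)))
  invisible(x)
}
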
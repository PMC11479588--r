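#' Read a voltage-clamp current trace
#'
#' Two-column CSV (`time_s`, `current_na`) of holding current during a long
#' hyperpolarizing step. Step timing and voltages travel as arguments or a
#' JSON side-car, not inside the CSV.
#'
#' @param path CSV file with a header row.
#' @return Tibble with `time_s` and `current_na`.
#' @export
read_clamp_trace <- function(path) {
  raw <- read_checked_csv(path, cols = c("time_s", "current_na"),
                          numeric_cols = c("time_s", "current_na"))
  if (nrow(raw) < 2) rlang::abort(paste0(path, ": clamp trace too short"))
  if (any(diff(raw$time_s) <= 0)) {
    rlang::abort(paste0(path, ": times not strictly ascending"))
  }
  tibble::as_tibble(raw)
}

#' Measure Ih amplitude from a hyperpolarizing step
#'
#' Because Ih activates slowly, its amplitude is taken as the difference
#' between the current needed to hold the hyperpolarization initially and
#' at steady state: both are window means, and `Ih = |I_steady - I_initial|`.
#' Window times are relative to the step onset. The default initial window
#' (50-150 ms post-onset) skips the capacitive transient of real
#' recordings; the default steady window is the last second of a 12 s step.
#' The measure is invariant to any constant current offset.
#'
#' @param trace Clamp tibble (`time_s`, `current_na`).
#' @param step_onset Step onset time in the trace, s (default 0).
#' @param step_duration Step length, s (default 12).
#' @param initial_window Numeric length-2, seconds after onset
#'   (default `c(0.05, 0.15)`).
#' @param steady_window Numeric length-2, seconds after onset (default the
#'   last 1 s of the step).
#' @return One-row tibble: `i_initial_na`, `i_steady_na`, `ih_na`
#'   (non-negative amplitude), `n_initial`, `n_steady`.
#' @export
measure_ih <- function(trace, step_onset = 0, step_duration = 12,
                       initial_window = c(0.05, 0.15),
                       steady_window = c(step_duration - 1, step_duration)) {
  stopifnot(all(c("time_s", "current_na") %in% names(trace)))
  for (w in list(initial_window, steady_window)) {
    if (length(w) != 2 || w[1] >= w[2] || w[1] < 0 || w[2] > step_duration) {
      rlang::abort("measurement windows must lie inside the step")
    }
  }
  t_rel <- trace$time_s - step_onset
  win_mean <- function(w, what) {
    sel <- t_rel >= w[1] & t_rel <= w[2]
    if (sum(sel) < 5) {
      rlang::abort(paste0("fewer than 5 samples in the ", what, " window"))
    }
    c(mean(trace$current_na[sel]), sum(sel))
  }
  ini <- win_mean(initial_window, "initial")
  ste <- win_mean(steady_window, "steady")
  tibble::tibble(
    i_initial_na = ini[1],
    i_steady_na = ste[1],
    ih_na = abs(ste[1] - ini[1]),
    n_initial = as.integer(ini[2]),
    n_steady = as.integer(ste[2])
  )
}

#' Percent block of Ih across paired cells
#'
#' Per-cell percent reduction `100 * (1 - blocked/control)`, then the group
#' mean and SD of those per-cell reductions. Note this is deliberately the
#' mean of per-cell ratios, not the ratio of group means; the two differ
#' whenever block fraction and control amplitude covary.
#'
#' @param ih_control,ih_blocked Paired per-cell Ih amplitudes (nA); all
#'   control amplitudes must be > 0.
#' @return Object of class `"ih_block"`: `per_cell` tibble (`cell`,
#'   `ih_control_na`, `ih_blocked_na`, `pct_block`), `mean_pct`, `sd_pct`,
#'   `n`.
#' @export
#' @examples
#' percent_block(c(1.5, 2.0), c(0.105, 0.2))
percent_block <- function(ih_control, ih_blocked) {
  if (length(ih_control) != length(ih_blocked)) {
    rlang::abort("control and blocked must be paired per cell")
  }
  bad <- which(!(ih_control > 0))
  if (length(bad) > 0) {
    rlang::abort(paste0("non-positive control Ih for cell(s): ",
                        paste(bad, collapse = ", ")))
  }
  pct <- 100 * (1 - ih_blocked / ih_control)
  structure(
    list(
      per_cell = tibble::tibble(
        cell = seq_along(pct),
        ih_control_na = ih_control,
        ih_blocked_na = ih_blocked,
        pct_block = pct
      ),
      mean_pct = mean(pct),
      sd_pct = stats::sd(pct),
      n = length(pct)
    ),
    class = "ih_block"
  )
}

#' @export
print.ih_block <- function(x, ...) {
  cat(sprintf("<ih_block> mean reduction %.1f +/- %.1f%% (n = %d cells)\n",
              x$mean_pct, if (is.na(x$sd_pct)) 0 else x$sd_pct, x$n))
  invisible(x)
}
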
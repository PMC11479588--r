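#' Detect bursts in labelled spike trains
#'
#' Partitions each unit's spikes into maximal groups whose internal
#' inter-spike gaps are all strictly less than `min_gap`; a gap of `min_gap`
#' or more ("an inter-burst interval of at least 200 ms") splits. Groups with
#' fewer than `min_spikes` spikes are discarded, not merged into neighbours:
#' stray spikes neither form bursts nor perturb cycle boundaries.
#'
#' @param spikes Tibble with columns `time_s` and `unit`, times ascending
#'   within unit (a bare numeric vector is accepted for a single unnamed
#'   unit).
#' @param min_spikes Minimum spikes per burst (default 2).
#' @param min_gap Splitting gap in seconds (default 0.200).
#' @return Tibble with one row per burst: `unit`, `burst` (index within
#'   unit), `onset_s` (first spike), `offset_s` (last spike), `n_spikes`,
#'   `duration_s`.
#' @export
#' @examples
#' detect_bursts(c(0, 0.05, 0.10, 0.50, 0.55, 1.00))
detect_bursts <- function(spikes, min_spikes = 2, min_gap = 0.200) {
  if (is.numeric(spikes)) {
    spikes <- tibble::tibble(time_s = spikes, unit = "PD")
  }
  stopifnot(all(c("time_s", "unit") %in% names(spikes)))
  if (min_spikes < 1) rlang::abort("`min_spikes` must be >= 1")
  if (!is.numeric(min_gap) || min_gap <= 0) {
    rlang::abort("`min_gap` must be > 0")
  }
  one_unit <- function(times, unit) {
    if (length(times) == 0) return(NULL)
    if (is.unsorted(times)) {
      rlang::abort(paste0("spike times for unit '", unit,
                          "' are not sorted ascending"))
    }
    # new group wherever the gap reaches min_gap
    grp <- cumsum(c(TRUE, diff(times) >= min_gap))
    sizes <- tabulate(grp)
    keep <- which(sizes >= min_spikes)
    if (length(keep) == 0) return(NULL)
    tibble::tibble(
      unit = unit,
      burst = seq_along(keep),
      onset_s = vapply(keep, function(g) times[grp == g][1], numeric(1)),
      offset_s = vapply(keep, function(g) {
        x <- times[grp == g]
        x[length(x)]
      }, numeric(1)),
      n_spikes = sizes[keep]
    )
  }
  out <- spikes |>
    dplyr::group_by(.data$unit) |>
    dplyr::group_map(~ one_unit(.x$time_s, .y$unit)) |>
    purrr::compact() |>
    purrr::list_rbind()
  if (nrow(out) == 0) {
    return(tibble::tibble(unit = character(0), burst = integer(0),
                          onset_s = numeric(0), offset_s = numeric(0),
                          n_spikes = integer(0), duration_s = numeric(0)))
  }
  out$duration_s <- out$offset_s - out$onset_s
  dplyr::arrange(out, .data$unit, .data$onset_s)
}

#' Build pyloric cycles from pacemaker bursts
#'
#' A cycle spans the interval between the first spikes of two consecutive PD
#' bursts; its period is that interval and its frequency the reciprocal.
#' The offset of the burst that opens a cycle is carried along as
#' `pd_off_s` so PD phase can be computed later.
#'
#' @param bursts Burst tibble from [detect_bursts()].
#' @param unit Pacemaker unit label whose bursts define cycles
#'   (default `"PD"`).
#' @return Tibble with columns `cycle`, `start_s`, `end_s`, `period_s`,
#'   `freq_hz`, `pd_off_s`.
#' @export
build_cycles <- function(bursts, unit = "PD") {
  pd <- bursts[bursts$unit == unit, , drop = FALSE]
  if (nrow(pd) < 2) {
    rlang::abort(paste0("insufficient bursts: need >= 2 '", unit,
                        "' bursts to form a cycle"))
  }
  on <- pd$onset_s
  tibble::tibble(
    cycle = seq_len(nrow(pd) - 1L),
    start_s = on[-length(on)],
    end_s = on[-1],
    period_s = diff(on),
    freq_hz = 1 / diff(on),
    pd_off_s = pd$offset_s[-nrow(pd)]
  )
}

#' Assign follower bursts to cycles
#'
#' Each follower (LP, PY, ...) burst is assigned to the unique cycle
#' containing its onset. If several bursts of one unit start within one
#' cycle, the first is kept and the extras are counted; bursts starting
#' before the first or after the last cycle are likewise counted, not
#' errors. Burst offsets may spill past the cycle end (flagged downstream as
#' phases > 1).
#'
#' @param cycles Cycle tibble from [build_cycles()].
#' @param bursts Burst tibble from [detect_bursts()]; rows whose `unit` is
#'   the pacemaker are ignored.
#' @param units Units to assign (default all non-PD units present).
#' @return `cycles` with two new columns per unit, `<unit>_on_s` and
#'   `<unit>_off_s` (lower-case), plus an attribute `"dropped"` counting
#'   unassigned or superfluous bursts per unit.
#' @export
assign_events <- function(cycles, bursts, units = NULL) {
  if (is.null(units)) units <- setdiff(unique(bursts$unit), "PD")
  dropped <- stats::setNames(integer(length(units)), units)
  for (u in units) {
    b <- bursts[bursts$unit == u, , drop = FALSE]
    on_col <- paste0(tolower(u), "_on_s")
    off_col <- paste0(tolower(u), "_off_s")
    cycles[[on_col]] <- NA_real_
    cycles[[off_col]] <- NA_real_
    if (nrow(b) == 0) next
    # cycle i covers [start_i, end_i); ends are the next starts
    idx <- findInterval(b$onset_s, c(cycles$start_s, cycles$end_s[nrow(cycles)]))
    inside <- idx >= 1 & idx <= nrow(cycles)
    dropped[u] <- dropped[u] + sum(!inside)
    b <- b[inside, , drop = FALSE]
    idx <- idx[inside]
    first <- !duplicated(idx)
    dropped[u] <- dropped[u] + sum(!first)
    cycles[[on_col]][idx[first]] <- b$onset_s[first]
    cycles[[off_col]][idx[first]] <- b$offset_s[first]
  }
  if (any(dropped > 0)) {
    rlang::inform(paste0(
      "assign_events: unassigned/extra bursts dropped: ",
      paste(names(dropped)[dropped > 0], dropped[dropped > 0],
            sep = "=", collapse = " ")
    ))
  }
  attr(cycles, "dropped") <- dropped
  cycles
}

#' Compute phases, duty cycles and delays
#'
#' Converts event times on each cycle into phases: the latency of an event
#' from the first PD spike of the cycle, normalised by the cycle period.
#' Adds, where the inputs exist, `pd_off_phase`, `<unit>_on_phase`,
#' `<unit>_off_phase`, `pd_duration_s` (PD burst duration in seconds),
#' `lp_duty` (LP duty cycle) and `delay_lp_on_pd_off`
#' (LP ON phase minus PD OFF phase). Events absent from a cycle yield `NA`,
#' never zero. Offsets that spill past the cycle end give phases > 1 and set
#' the logical `spill` column.
#'
#' @param cycles Cycle tibble with event-time columns (`pd_off_s`,
#'   `lp_on_s`, ...).
#' @return The cycle tibble with phase columns appended.
#' @export
compute_phases <- function(cycles) {
  stopifnot(all(c("start_s", "period_s") %in% names(cycles)))
  if (any(cycles$period_s <= 0)) rlang::abort("non-positive cycle period")
  ph <- function(t) (t - cycles$start_s) / cycles$period_s
  if ("pd_off_s" %in% names(cycles)) {
    cycles$pd_off_phase <- ph(cycles$pd_off_s)
    cycles$pd_duration_s <- cycles$pd_off_s - cycles$start_s
  }
  ev_cols <- grep("^(?!pd_)[a-z0-9]+_(on|off)_s$", names(cycles),
                  perl = TRUE, value = TRUE)
  for (cl in ev_cols) {
    cycles[[sub("_s$", "_phase", cl)]] <- ph(cycles[[cl]])
  }
  if (all(c("lp_on_phase", "lp_off_phase") %in% names(cycles))) {
    cycles$lp_duty <- cycles$lp_off_phase - cycles$lp_on_phase
  }
  if (all(c("lp_on_phase", "pd_off_phase") %in% names(cycles))) {
    cycles$delay_lp_on_pd_off <- cycles$lp_on_phase - cycles$pd_off_phase
  }
  off_ph <- grep("_off_phase$", names(cycles), value = TRUE)
  if (length(off_ph) > 0) {
    m <- as.matrix(cycles[off_ph])
    cycles$spill <- apply(m, 1, function(r) any(r > 1, na.rm = TRUE))
  }
  cycles
}

#' Match cycles of equal period across conditions
#'
#' Greedy one-to-one pairing used for period-matched latency comparisons
#' (e.g. control at 11 degC against Cs at whatever temperature gives the
#' same period): for each `a` cycle in order, the nearest still-unpaired `b`
#' cycle with period difference at most `tolerance` is taken.
#'
#' @param cycles_a,cycles_b Cycle tibbles (after [compute_phases()] if
#'   latency differences are wanted).
#' @param tolerance Maximum absolute period difference in seconds.
#' @return Tibble of pairs: `cycle_a`, `cycle_b`, `period_a`, `period_b`,
#'   and, for each of LP onset, PD offset and PY onset present in both
#'   inputs, the latency difference a minus b in milliseconds
#'   (`d_lp_on_ms`, `d_pd_off_ms`, `d_py_on_ms`).
#' @export
match_periods <- function(cycles_a, cycles_b, tolerance) {
  stopifnot(is.numeric(tolerance), tolerance > 0)
  pa <- cycles_a$period_s
  pb <- cycles_b$period_s
  used <- rep(FALSE, length(pb))
  ia <- integer(0)
  ib <- integer(0)
  for (i in seq_along(pa)) {
    d <- abs(pb - pa[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= tolerance) {
      used[j] <- TRUE
      ia <- c(ia, i)
      ib <- c(ib, j)
    }
  }
  if (length(ia) == 0) {
    rlang::warn("match_periods: no period-matched pairs found")
  }
  out <- tibble::tibble(
    cycle_a = cycles_a$cycle[ia], cycle_b = cycles_b$cycle[ib],
    period_a = pa[ia], period_b = pb[ib]
  )
  lat <- function(cy, col) (cy[[col]] - cy$start_s)
  for (spec in list(c("lp_on_s", "d_lp_on_ms"),
                    c("pd_off_s", "d_pd_off_ms"),
                    c("py_on_s", "d_py_on_ms"))) {
    if (spec[1] %in% names(cycles_a) && spec[1] %in% names(cycles_b)) {
      out[[spec[2]]] <-
        1000 * (lat(cycles_a, spec[1])[ia] - lat(cycles_b, spec[1])[ib])
    }
  }
  out
}
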
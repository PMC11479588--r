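#' Temperature step protocol
#'
#' Describes the stepped warming protocol: a baseline hold at the start
#' temperature, then `n_steps` repeats of a linear ramp (`step_size` degC
#' over `ramp_duration`) followed by a flat hold, with ramp + hold spanning
#' one stabilisation interval (240 s by default, i.e. 2 degC steps allowed
#' to stabilise over 4 min). Optionally the bath returns to the start
#' temperature at the end.
#'
#' @param start_temp Starting temperature, degC (default 11).
#' @param step_size Step height, degC (default 2).
#' @param n_steps Number of upward steps (default 5, i.e. to 21 degC).
#' @param ramp_duration Ramp length, s (default 40; the controller's ramp
#'   rate is not standardised, so this is configurable).
#' @param hold_duration Hold length, s (default 200 so ramp + hold = 240 s).
#' @param initial_hold Baseline hold before the first ramp, s (default
#'   `hold_duration`).
#' @param return_to_start Ramp back down and hold at `start_temp` at the end
#'   (default `FALSE`).
#' @param sample_interval Thermocouple sampling interval, s (default 0.5).
#' @param noise_sd SD of additive Gaussian measurement noise on the recorded
#'   trace, degC (default 0). The noise models thermocouple read-out error
#'   only; the true bath temperature driving a simulation is the noiseless
#'   template.
#' @return A list of class `"pyloric_protocol"`.
#' @export
pyloric_protocol <- function(start_temp = 11, step_size = 2, n_steps = 5,
                             ramp_duration = 40, hold_duration = 200,
                             initial_hold = hold_duration,
                             return_to_start = FALSE,
                             sample_interval = 0.5, noise_sd = 0) {
  stopifnot(ramp_duration > 0, hold_duration > 0, initial_hold > 0,
            sample_interval > 0, n_steps >= 0, noise_sd >= 0)
  structure(
    list(start_temp = start_temp, step_size = step_size,
         n_steps = as.integer(n_steps), ramp_duration = ramp_duration,
         hold_duration = hold_duration, initial_hold = initial_hold,
         return_to_start = isTRUE(return_to_start),
         sample_interval = sample_interval, noise_sd = noise_sd),
    class = "pyloric_protocol"
  )
}

# Piecewise-linear template breakpoints (time_s, temp_c) for a protocol.
protocol_template <- function(p) {
  t <- c(0, p$initial_hold)
  temp <- c(p$start_temp, p$start_temp)
  cur <- p$start_temp
  for (i in seq_len(p$n_steps)) {
    cur <- cur + p$step_size
    t <- c(t, t[length(t)] + p$ramp_duration, t[length(t)] + p$ramp_duration +
             p$hold_duration)
    temp <- c(temp, cur, cur)
  }
  if (p$return_to_start && p$n_steps > 0) {
    down <- p$ramp_duration * p$n_steps  # same ramp rate on the way down
    t <- c(t, t[length(t)] + down, t[length(t)] + down + p$hold_duration)
    temp <- c(temp, p$start_temp, p$start_temp)
  }
  list(time_s = t, temp_c = temp)
}

#' Protocol target temperatures
#'
#' @param p A [pyloric_protocol()].
#' @return Numeric vector of distinct hold temperatures, ascending.
#' @export
protocol_targets <- function(p) {
  sort(unique(p$start_temp + p$step_size * seq(0, p$n_steps)))
}

#' Generate a temperature trace from a protocol
#'
#' Samples the piecewise-linear protocol template at `sample_interval` and
#' adds optional Gaussian measurement noise. Deterministic given `seed`.
#'
#' @param p A [pyloric_protocol()].
#' @param seed Optional integer seed.
#' @return Tibble with `time_s` and `temp_c`.
#' @export
make_protocol <- function(p, seed = NULL) {
  stopifnot(inherits(p, "pyloric_protocol"))
  if (!is.null(seed)) set.seed(seed)
  tpl <- protocol_template(p)
  times <- seq(0, tpl$time_s[length(tpl$time_s)], by = p$sample_interval)
  temp <- stats::approx(tpl$time_s, tpl$temp_c, xout = times, rule = 2)$y
  if (p$noise_sd > 0) temp <- temp + stats::rnorm(length(temp), 0, p$noise_sd)
  tibble::tibble(time_s = times, temp_c = temp)
}

#' Ground-truth parameters for a simulated experiment
#'
#' The generative parameter set recovered by the analysis pipeline. The
#' steady-state frequency follows `f_ss(T) = f_ref * Q10^((T - t_ref)/10)`;
#' a first-order adaptation state `x` (a low-pass filtered warming rate,
#' `dx/dt = (dT/dt - x)/jag_tau`, clipped at zero) subtracts
#' `jag_gain * x` from the instantaneous frequency, producing the
#' non-monotonic "jag" during ramps and its ~`jag_tau` relaxation after the
#' bath stabilises. Follower bursts sit at their phase parameters (with
#' optional linear temperature drift); the PD burst spans
#' `pd_burst_duration` seconds (set it `NULL` to use the `pd_off` phase
#' instead). Every spike gets independent Gaussian timing jitter.
#'
#' @param f_ref Frequency at `t_ref`, Hz (default 1.2).
#' @param q10 Temperature sensitivity (default 1.7).
#' @param jag_gain Frequency drop per unit filtered warming rate,
#'   Hz/(degC/s) (default 0: smooth, control-like transitions).
#' @param jag_tau Adaptation time constant, s (default 30).
#' @param phases Named onset/offset phases at `t_ref`:
#'   `pd_off`, `lp_on`, `lp_off`, `py_on`, `py_off` (defaults are typical
#'   saline values at 11 degC).
#' @param phase_slopes Linear phase drift per degC for the same events
#'   (default: only `lp_off` drifts, -0.007 per degC).
#' @param spikes_per_burst Named counts for `PD`, `LP`, `PY`; a unit may be
#'   omitted by leaving it out.
#' @param pd_burst_duration PD burst span, s (default 0.164), or `NULL`.
#' @param spike_jitter_sd Per-spike Gaussian jitter SD, s (default 0.005).
#' @param t_ref Reference temperature, degC (default 11).
#' @param condition Condition label for the generated record.
#' @return A list of class `"ground_truth"`.
#' @export
ground_truth <- function(f_ref = 1.2, q10 = 1.7, jag_gain = 0, jag_tau = 30,
                         phases = c(pd_off = 0.19, lp_on = 0.40,
                                    lp_off = 0.66, py_on = 0.58,
                                    py_off = 0.87),
                         phase_slopes = c(pd_off = 0, lp_on = 0,
                                          lp_off = -0.007, py_on = 0,
                                          py_off = 0),
                         spikes_per_burst = c(PD = 5, LP = 4, PY = 4),
                         pd_burst_duration = 0.164,
                         spike_jitter_sd = 0.005,
                         t_ref = 11,
                         condition = c("saline", "Cs", "Cs+PTX")) {
  condition <- match.arg(condition)
  stopifnot(f_ref > 0, q10 > 0, jag_tau > 0, jag_gain >= 0,
            spike_jitter_sd >= 0)
  need <- c("pd_off", "lp_on", "lp_off", "py_on", "py_off")
  full <- c(pd_off = 0.19, lp_on = 0.40, lp_off = 0.66, py_on = 0.58,
            py_off = 0.87)
  full[names(phases)] <- phases
  sl <- stats::setNames(numeric(5), need)
  sl[names(phase_slopes)] <- phase_slopes
  if (any(full <= 0)) rlang::abort("phases must be > 0")
  if (!(full["pd_off"] < full["lp_on"] && full["lp_on"] < full["lp_off"])) {
    rlang::abort("phase ordering violated: need pd_off < lp_on < lp_off")
  }
  if (!is.null(pd_burst_duration)) stopifnot(pd_burst_duration > 0)
  structure(
    list(f_ref = f_ref, q10 = q10, jag_gain = jag_gain, jag_tau = jag_tau,
         phases = full, phase_slopes = sl,
         spikes_per_burst = spikes_per_burst,
         pd_burst_duration = pd_burst_duration,
         spike_jitter_sd = spike_jitter_sd, t_ref = t_ref,
         condition = condition),
    class = "ground_truth"
  )
}

# Drifted phase of one event at temperature temp.
drifted_phase <- function(gt, event, temp) {
  gt$phases[[event]] + gt$phase_slopes[[event]] * (temp - gt$t_ref)
}

#' Simulate a temperature-step experiment
#'
#' Integrates the generative model of [ground_truth()] over the protocol
#' template: the instantaneous frequency is
#' `f(t) = f_ss(T(t)) - jag_gain * x(t)` (floored at 0.05 Hz), cycle starts
#' are the integer crossings of the integrated frequency, and spikes are
#' placed evenly within each unit's burst window on every cycle, then
#' jittered. A single RNG stream is used, in draw order: thermocouple
#' noise, then PD, LP, PY spike jitter. Byte-identical output for a fixed
#' seed.
#'
#' @param gt A [ground_truth()] parameter set.
#' @param p A [pyloric_protocol()].
#' @param seed Optional integer seed.
#' @param id Experiment identifier (default `"sim1"`).
#' @param dt Integration step for the frequency dynamics, s (default 0.05).
#' @return A `"pyloric_experiment"` (see [experiment_record()]) with the
#'   generating `ground_truth` attached as `$ground_truth`.
#' @export
#' @examples
#' ex <- simulate_experiment(ground_truth(spike_jitter_sd = 0),
#'                           pyloric_protocol(n_steps = 1), seed = 1)
#' nrow(ex$trains)
simulate_experiment <- function(gt, p = pyloric_protocol(), seed = NULL,
                                id = "sim1", dt = 0.05) {
  stopifnot(inherits(gt, "ground_truth"), inherits(p, "pyloric_protocol"))
  if (!is.null(seed)) set.seed(seed)
  tpl <- protocol_template(p)

  # phase ordering must hold across the whole temperature range
  for (temp in range(tpl$temp_c)) {
    phs <- vapply(c("pd_off", "lp_on", "lp_off"), drifted_phase,
                  numeric(1), gt = gt, temp = temp)
    if (any(phs <= 0) || is.unsorted(phs, strictly = TRUE)) {
      rlang::abort(sprintf(
        "phase ordering violated after drift at %.1f degC", temp))
    }
  }

  # recorded (possibly noisy) thermocouple trace; draws come first
  trace <- make_protocol(p)
  if (p$noise_sd > 0) {
    trace$temp_c <- trace$temp_c + stats::rnorm(nrow(trace), 0, p$noise_sd)
  }

  # frequency dynamics on a fine grid over the noiseless template
  tgrid <- seq(0, tpl$time_s[length(tpl$time_s)], by = dt)
  temp <- stats::approx(tpl$time_s, tpl$temp_c, xout = tgrid, rule = 2)$y
  rate <- c(diff(temp) / dt, 0)                  # true warming rate, degC/s
  a <- exp(-dt / gt$jag_tau)
  x <- numeric(length(tgrid))
  for (i in seq_len(length(tgrid) - 1L)) {
    # exact update of dx/dt = (rate - x)/tau with rate held over the step
    x[i + 1L] <- max(0, a * x[i] + (1 - a) * rate[i])
  }
  f_ss <- gt$f_ref * gt$q10^((temp - gt$t_ref) / 10)
  f <- pmax(f_ss - gt$jag_gain * x, 0.05)

  # cycle starts where the integrated frequency crosses whole numbers
  phi <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * dt))
  n_cycles <- floor(phi[length(phi)])
  starts <- stats::approx(phi, tgrid, xout = 0:n_cycles)$y
  periods <- diff(starts)
  periods <- c(periods, periods[length(periods)])  # for the final burst
  temp_at_start <- stats::approx(tgrid, temp, xout = starts)$y

  spb <- gt$spikes_per_burst
  burst_spikes <- function(onset, offset, n) {
    if (n <= 1) return(onset)
    seq(onset, offset, length.out = n)
  }
  place_unit <- function(unit) {
    n <- spb[[unit]]
    times <- switch(
      unit,
      PD = {
        dur <- if (is.null(gt$pd_burst_duration)) {
          drifted_phase(gt, "pd_off", temp_at_start) * periods
        } else {
          rep(gt$pd_burst_duration, length(starts))
        }
        unlist(purrr::map(seq_along(starts), function(k) {
          burst_spikes(starts[k], starts[k] + dur[k], n)
        }))
      },
      LP = ,
      PY = {
        ev <- tolower(unit)
        on_ph <- drifted_phase(gt, paste0(ev, "_on"), temp_at_start)
        off_ph <- drifted_phase(gt, paste0(ev, "_off"), temp_at_start)
        unlist(purrr::map(seq_along(starts), function(k) {
          burst_spikes(starts[k] + on_ph[k] * periods[k],
                       starts[k] + off_ph[k] * periods[k], n)
        }))
      }
    )
    if (gt$spike_jitter_sd > 0) {
      times <- times + stats::rnorm(length(times), 0, gt$spike_jitter_sd)
    }
    tibble::tibble(time_s = pmax(sort(times), 0), unit = unit)
  }

  units <- intersect(c("PD", "LP", "PY"), names(spb))
  trains <- purrr::map(units, place_unit) |> purrr::list_rbind()
  trains <- dplyr::distinct(trains, .data$unit, .data$time_s)
  trains <- dplyr::arrange(trains, .data$unit, .data$time_s)[
    c("time_s", "unit")]

  out <- experiment_record(trains, trace, condition = gt$condition, id = id,
                           metadata = list(seed = seed, n_cycles = n_cycles))
  out$ground_truth <- gt
  out
}

#' Simulate a voltage-clamp Ih trace
#'
#' Mono-exponential Ih activation during a hyperpolarizing step:
#' `I(t) = i_hold - ih_amplitude * (1 - exp(-t/tau)) + noise`, sampled
#' uniformly over the step. Time is relative to step onset.
#'
#' @param i_hold Instantaneous holding current at step onset, nA
#'   (default -2).
#' @param ih_amplitude Asymptotic Ih amplitude, nA (default 1.5).
#' @param tau Activation time constant, s (default 2).
#' @param duration Step length, s (default 12).
#' @param sample_interval Sampling interval, s (default 0.001).
#' @param noise_sd Additive Gaussian noise SD, nA (default 0).
#' @param seed Optional integer seed.
#' @return Tibble with `time_s` and `current_na`.
#' @export
simulate_clamp_trace <- function(i_hold = -2, ih_amplitude = 1.5, tau = 2,
                                 duration = 12, sample_interval = 0.001,
                                 noise_sd = 0, seed = NULL) {
  stopifnot(duration > 0, tau > 0, sample_interval > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = sample_interval)
  i <- i_hold - ih_amplitude * (1 - exp(-t / tau))
  if (noise_sd > 0) i <- i + stats::rnorm(length(t), 0, noise_sd)
  tibble::tibble(time_s = t, current_na = i)
}

#' Write a simulated experiment to disk
#'
#' Emits the standard file set: `spikes.csv` (`time_s`, `unit`),
#' `temperature.csv` (`time_s`, `temp_c`) and, when the record carries one,
#' `ground_truth.json`.
#'
#' @param experiment A `"pyloric_experiment"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "pyloric_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(experiment$trains, file.path(dir, "spikes.csv"),
                   progress = FALSE)
  readr::write_csv(experiment$temperature, file.path(dir, "temperature.csv"),
                   progress = FALSE)
  if (!is.null(experiment$ground_truth)) {
    gt <- experiment$ground_truth
    jsonlite::write_json(
      purrr::compact(unclass(gt)), file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
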
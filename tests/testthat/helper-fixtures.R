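# Shared fixtures for the suite. Simulations reused across files are cached
# in this environment so each is generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Cs-like printed parameter set: lower frequency and Q10, advanced phases,
# steeper LP phase drift, shorter PD burst, pronounced jag.
cs_ground_truth <- function(jag_gain = 5, spike_jitter_sd = 0.005) {
  ground_truth(
    f_ref = 0.9, q10 = 1.3, jag_gain = jag_gain,
    phases = c(pd_off = 0.12, lp_on = 0.29, lp_off = 0.56,
               py_on = 0.60, py_off = 0.90),
    phase_slopes = c(lp_on = -0.005, lp_off = -0.014),
    pd_burst_duration = 0.144,
    spike_jitter_sd = spike_jitter_sd,
    condition = "Cs"
  )
}

# Shortened protocol (3 holds) for tests that only need structure, not the
# full five-step experiment.
small_protocol <- function(...) {
  pyloric_protocol(n_steps = 2, ramp_duration = 20, hold_duration = 100,
                   initial_hold = 100, ...)
}

# Family-wise error rate of the Bonferroni-adjusted phase-slope battery
# under a zero-mean normal null: 1000 simulated families of 10 tests.
fwer_rate <- function() {
  cached("fwer_rate", {
    set.seed(2024)
    n_rep <- 1000
    rejections <- 0
    for (r in seq_len(n_rep)) {
      ps <- replicate(10, {
        group_slope_test(rnorm(21, 0, 0.007), n_tests = 10)$p_adjusted
      })
      if (any(ps < 0.05)) rejections <- rejections + 1
    }
    rejections / n_rep
  })
}

# Seed-matched jag-probability ladder over increasing jag gains.
jag_ladder <- function(gains = c(0, 2, 5, 8)) {
  cached("jag_ladder", {
    p <- small_protocol()
    purrr::map_dbl(gains, function(g) {
      mean(purrr::map_dbl(c(61, 62), function(s) {
        ex <- simulate_experiment(cs_ground_truth(jag_gain = g), p, seed = s)
        suppressMessages(analyse_experiment(ex))$jag$p_dec_given_inc
      }))
    })
  })
}

# Brute-force burst grouping oracle: scan the sorted spike vector, starting a
# new group whenever the gap to the previous spike is >= min_gap, then drop
# small groups. Independent of the vectorised implementation.
oracle_bursts <- function(times, min_spikes, min_gap) {
  if (length(times) == 0) return(data.frame())
  groups <- list(times[1])
  for (t in times[-1]) {
    last <- groups[[length(groups)]]
    if (t - last[length(last)] >= min_gap) {
      groups[[length(groups) + 1]] <- t
    } else {
      groups[[length(groups)]] <- c(last, t)
    }
  }
  keep <- Filter(function(g) length(g) >= min_spikes, groups)
  data.frame(
    onset_s = vapply(keep, min, numeric(1)),
    offset_s = vapply(keep, max, numeric(1)),
    n_spikes = vapply(keep, length, numeric(1))
  )
}

# Brute-force windowed mean for smooth_series (center alignment).
oracle_smooth <- function(x, w) {
  n <- length(x)
  left <- (w - 1) %/% 2 + as.integer(w %% 2 == 0)
  right <- (w - 1) %/% 2
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - left):min(n, i + right)])
  }, numeric(1))
}
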
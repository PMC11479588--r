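test_that("burst detection follows the interburst-interval rule", {
  b <- detect_bursts(c(0.00, 0.05, 0.10, 0.50, 0.55, 1.00),
                     min_spikes = 2, min_gap = 0.2)
  expect_equal(b$onset_s, c(0.00, 0.50))
  expect_equal(b$offset_s, c(0.10, 0.55))
  expect_equal(b$n_spikes, c(3L, 2L))

  # a gap of exactly the criterion ("at least 200 ms") splits
  expect_equal(nrow(detect_bursts(c(0, 0.2), min_gap = 0.2)), 0)
  # just under the criterion does not
  expect_equal(nrow(detect_bursts(c(0, 0.19999), min_gap = 0.2)), 1)

  expect_equal(nrow(detect_bursts(numeric(0))), 0)
  expect_error(
    detect_bursts(tibble::tibble(time_s = c(1, 0), unit = "PD")),
    "sorted"
  )
})

test_that("burst detection matches a brute-force grouping oracle", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(0:40, 1)
    times <- sort(round(cumsum(rexp(n, rate = 8)), 4))
    times <- times[!duplicated(times)]
    min_spikes <- sample(1:3, 1)
    min_gap <- runif(1, 0.05, 0.4)
    got <- detect_bursts(times, min_spikes, min_gap)
    want <- oracle_bursts(times, min_spikes, min_gap)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$onset_s, want$onset_s)
      expect_equal(got$offset_s, want$offset_s)
      expect_equal(got$n_spikes, as.integer(want$n_spikes))
    }
  }
})

test_that("burst partition is idempotent", {
  set.seed(7)
  times <- sort(cumsum(rexp(200, 6)))
  b1 <- detect_bursts(times, 2, 0.2)
  spikes_back <- unlist(lapply(seq_len(nrow(b1)), function(i) {
    times[times >= b1$onset_s[i] & times <= b1$offset_s[i]]
  }))
  b2 <- detect_bursts(spikes_back, 2, 0.2)
  expect_equal(b2$onset_s, b1$onset_s)
  expect_equal(b2$offset_s, b1$offset_s)
  expect_equal(b2$n_spikes, b1$n_spikes)
})

test_that("cycles come from consecutive PD burst onsets", {
  b <- tibble::tibble(unit = "PD", burst = 1:3, onset_s = c(0, 1, 2.1),
                      offset_s = c(0.2, 1.2, 2.3), n_spikes = 3L,
                      duration_s = 0.2)
  cy <- build_cycles(b)
  expect_equal(cy$period_s, c(1.0, 1.1))
  expect_equal(cy$freq_hz, c(1.0, 1 / 1.1))
  expect_error(build_cycles(b[1, ]), "insufficient bursts")

  # conservation: periods sum to the onset span
  set.seed(3)
  on <- sort(runif(50, 0, 100))
  b2 <- tibble::tibble(unit = "PD", burst = seq_along(on), onset_s = on,
                       offset_s = on + 0.1, n_spikes = 3L, duration_s = 0.1)
  cy2 <- build_cycles(b2)
  expect_equal(sum(cy2$period_s), max(on) - min(on))

  # a fixed 1.25 Hz oscillator gives constant frequency
  on3 <- seq(0, by = 0.8, length.out = 100)
  b3 <- tibble::tibble(unit = "PD", burst = seq_along(on3), onset_s = on3,
                       offset_s = on3 + 0.1, n_spikes = 2L, duration_s = 0.1)
  expect_equal(build_cycles(b3)$freq_hz, rep(1.25, 99))
})

test_that("follower bursts are assigned by onset containment", {
  cycles <- build_cycles(tibble::tibble(
    unit = "PD", burst = 1:4, onset_s = c(0, 1, 2, 3),
    offset_s = c(0.2, 1.2, 2.2, 3.2), n_spikes = 3L, duration_s = 0.2
  ))
  lp <- tibble::tibble(unit = "LP", burst = 1:3,
                       onset_s = c(0.3, 0.7, 1.99),
                       offset_s = c(0.6, 0.9, 2.10),
                       n_spikes = 4L, duration_s = 0.2)
  expect_message(out <- assign_events(cycles, lp), "LP=1")
  # first burst wins in cycle 1; the 0.7 burst is the counted extra
  expect_equal(out$lp_on_s, c(0.3, 1.99, NA))
  expect_equal(attr(out, "dropped")[["LP"]], 1L)
  # offset 2.10 spills past cycle 2 end (2.0): flagged after phase step
  ph <- compute_phases(out)
  expect_true(ph$spill[2])
  expect_false(ph$spill[1])
})

test_that("phases reproduce typical saline means and are invariant", {
  cycles <- tibble::tibble(
    cycle = 1L, start_s = 0, end_s = 1, period_s = 1, freq_hz = 1,
    pd_off_s = 0.19, lp_on_s = 0.40, lp_off_s = 0.66
  )
  ph <- compute_phases(cycles)
  expect_equal(ph$pd_off_phase, 0.19)
  expect_equal(ph$lp_on_phase, 0.40)
  expect_equal(ph$lp_off_phase, 0.66)
  expect_equal(ph$delay_lp_on_pd_off, 0.21)
  expect_equal(ph$lp_duty, 0.26)

  # translation and scale invariance
  for (shift in c(5, 100)) {
    for (scale in c(1, 2, 0.5)) {
      tcy <- dplyr::mutate(cycles,
        start_s = start_s * scale + shift, end_s = end_s * scale + shift,
        period_s = period_s * scale, freq_hz = 1 / period_s,
        pd_off_s = pd_off_s * scale + shift,
        lp_on_s = lp_on_s * scale + shift,
        lp_off_s = lp_off_s * scale + shift)
      tph <- compute_phases(tcy)
      expect_equal(tph$lp_on_phase, 0.40, tolerance = 1e-12)
      expect_equal(tph$pd_off_phase, 0.19, tolerance = 1e-12)
    }
  }

  # absent unit gives absent fields, not zeros
  expect_false("py_on_phase" %in% names(ph))
  cycles$py_on_s <- NA_real_
  cycles$py_off_s <- NA_real_
  ph2 <- compute_phases(cycles)
  expect_true(is.na(ph2$py_on_phase))
})

test_that("period matching is greedy one-to-one within tolerance", {
  mk <- function(periods) {
    tibble::tibble(cycle = seq_along(periods),
                   start_s = cumsum(c(0, periods[-length(periods)])),
                   period_s = periods)
  }
  m <- match_periods(mk(1.00), mk(c(1.01, 1.30)), tolerance = 0.02)
  expect_equal(nrow(m), 1)
  expect_equal(m$period_b, 1.01)

  # identical sequences pair fully with zero latency differences
  a <- mk(c(1, 1.1, 0.9))
  a$lp_on_s <- a$start_s + 0.4
  m2 <- match_periods(a, a, tolerance = 0.01)
  expect_equal(nrow(m2), 3)
  expect_equal(m2$d_lp_on_ms, rep(0, 3))

  expect_warning(match_periods(mk(1), mk(2), tolerance = 0.1), "no period")
})

test_that("greedy matching agrees with exhaustive search on separable data", {
  # periods spaced more than 2*tolerance apart make the maximal matching
  # unique, so greedy must find exactly it; verify against brute force
  oracle_pairs <- function(pa, pb, tol) {
    best <- 0
    # enumerate all injective assignments (n <= 8)
    idx <- seq_along(pb)
    rec <- function(i, used) {
      if (i > length(pa)) return(0)
      top <- rec(i + 1, used)  # leave pa[i] unmatched
      for (j in setdiff(idx, used)) {
        if (abs(pa[i] - pb[j]) <= tol) {
          top <- max(top, 1 + rec(i + 1, c(used, j)))
        }
      }
      top
    }
    rec(1, integer(0))
  }
  set.seed(11)
  for (rep in 1:20) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    grid <- seq(0.5, 3, by = 0.11)  # spacing 0.11 > 2 * 0.05
    pa <- sample(grid, na)
    pb <- sample(grid, nb)
    tol <- 0.05
    mk <- function(p) tibble::tibble(cycle = seq_along(p),
                                     start_s = seq_along(p), period_s = p)
    got <- suppressWarnings(match_periods(mk(pa), mk(pb), tol))
    expect_equal(nrow(got), oracle_pairs(pa, pb, tol))
  }
})
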
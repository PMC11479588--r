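test_that("protocol traces follow the piecewise-linear template", {
  p <- pyloric_protocol()
  tr <- make_protocol(p)
  expect_true(all(c(11, 13, 15, 17, 19, 21) %in% tr$temp_c))
  expect_equal(protocol_targets(p), c(11, 13, 15, 17, 19, 21))
  expect_equal(max(tr$temp_c), 21)
  expect_equal(tr$temp_c[1], 11)

  # zero steps: constant trace
  flat <- make_protocol(pyloric_protocol(n_steps = 0))
  expect_equal(unique(flat$temp_c), 11)

  # no noise: exact match to the template at every sample
  tpl <- approx(c(0, 200, 240, 440), c(11, 11, 13, 13),
                xout = make_protocol(pyloric_protocol(n_steps = 1))$time_s)$y
  expect_equal(make_protocol(pyloric_protocol(n_steps = 1))$temp_c, tpl)

  # measurement noise is reproducible given the seed
  pn <- pyloric_protocol(noise_sd = 0.05)
  expect_identical(make_protocol(pn, seed = 2), make_protocol(pn, seed = 2))
})

test_that("ground truth validates phase ordering", {
  expect_error(ground_truth(phases = c(pd_off = 0.4, lp_on = 0.3)),
               "ordering")
  expect_error(ground_truth(phases = c(pd_off = -0.1)), "> 0")
  # drift that breaks ordering at high temperature is caught pre-generation
  gt <- ground_truth(phase_slopes = c(lp_on = -0.03))
  expect_error(simulate_experiment(gt, pyloric_protocol(n_steps = 5)),
               "ordering violated after drift")
})

test_that("simulated experiments are deterministic and conserve cycles", {
  gt <- ground_truth()
  p <- small_protocol()
  a <- simulate_experiment(gt, p, seed = 5)
  b <- simulate_experiment(gt, p, seed = 5)
  expect_identical(a$trains, b$trains)
  expect_identical(a$temperature, b$temperature)

  # PD bursts = integrated-frequency cycle count + 1
  bursts <- detect_bursts(a$trains)
  n_pd <- sum(bursts$unit == "PD")
  expect_equal(n_pd, a$metadata$n_cycles + 1)
  expect_equal(nrow(build_cycles(bursts)), a$metadata$n_cycles)
})

test_that("noiseless simulation returns exactly the generative parameters", {
  gt <- ground_truth(spike_jitter_sd = 0, q10 = 2.0, f_ref = 1.0,
                     phase_slopes = c(lp_off = 0))
  ex <- simulate_experiment(gt, small_protocol(), seed = 1)
  res <- suppressMessages(analyse_experiment(ex))
  expect_equal(res$q10$q10, 2.0, tolerance = 1e-6)
  expect_equal(res$q10$f_ref, 1.0, tolerance = 1e-5)
  # per-cycle follower phases equal the parameters to high precision
  inner <- res$cycles[!is.na(res$cycles$lp_on_phase), ]
  expect_lt(max(abs(inner$lp_on_phase - 0.40)), 1e-9)
  expect_lt(max(abs(inner$lp_off_phase - 0.66)), 1e-9)
  py <- res$cycles[!is.na(res$cycles$py_on_phase), ]
  expect_lt(max(abs(py$py_on_phase - 0.58)), 1e-9)
})

test_that("Q10 recovery is exact across the noiseless parameter grid", {
  # phase-proportional PD bursts and a tighter burst gap keep burst
  # detection valid at the fastest (4.6 Hz) corner of the grid
  cfg <- run_config(burst_min_gap = 0.08)
  p <- small_protocol()
  for (f_ref in c(0.8, 1.2, 2.0)) {
    for (q10 in c(1.0, 1.35, 1.75, 2.3)) {
      gt <- ground_truth(f_ref = f_ref, q10 = q10, spike_jitter_sd = 0,
                         pd_burst_duration = NULL,
                         phase_slopes = c(lp_off = 0))
      ex <- simulate_experiment(gt, p, seed = 17)
      res <- suppressMessages(analyse_experiment(ex, cfg))
      expect_lt(abs(res$q10$q10 - q10), 1e-3)
      expect_lt(abs(res$q10$f_ref - f_ref), 1e-3)
    }
  }
})

test_that("jitter leaves Q10 and phase estimates essentially unbiased", {
  p <- small_protocol()
  q10_err <- numeric(0)
  lp_on_err <- numeric(0)
  for (s in 1:24) {
    gt <- ground_truth(spike_jitter_sd = 0.005, phase_slopes = c(lp_off = 0))
    ex <- simulate_experiment(gt, p, seed = 1000 + s)
    res <- suppressMessages(analyse_experiment(ex))
    q10_err <- c(q10_err, res$q10$q10 - 1.7)
    lp_on_err <- c(lp_on_err,
                   mean(res$steady$mean_lp_on_phase, na.rm = TRUE) - 0.40)
  }
  expect_lt(abs(mean(q10_err)), 0.02)
  expect_lt(abs(mean(lp_on_err)), 0.005)
})

test_that("jag probability rises monotonically with jag gain", {
  probs <- jag_ladder()
  expect_true(all(diff(probs) >= 0))
  expect_equal(probs[1], 0, tolerance = 0.02)
})

test_that("jag separation between conditions is reliable across seeds", {
  # seed-matched control-like vs Cs-like pairs
  p <- small_protocol()
  wins <- purrr::map_lgl(1:12, function(s) {
    ctl <- simulate_experiment(ground_truth(), p, seed = 300 + s)
    cs <- simulate_experiment(cs_ground_truth(), p, seed = 300 + s)
    pc <- suppressMessages(analyse_experiment(ctl))$jag$p_dec_given_inc
    ps <- suppressMessages(analyse_experiment(cs))$jag$p_dec_given_inc
    ps > pc
  })
  expect_gte(mean(wins), 0.95)
})

test_that("experiment writer emits the standard readable file set", {
  ex <- cached("small_sal", simulate_experiment(
    ground_truth(spike_jitter_sd = 0.005), small_protocol(), seed = 31))
  dir <- withr::local_tempdir()
  write_experiment(ex, dir)
  expect_setequal(list.files(dir),
                  c("spikes.csv", "temperature.csv", "ground_truth.json"))
  back <- read_spike_trains(file.path(dir, "spikes.csv"))
  expect_equal(nrow(back), nrow(ex$trains))
  temp <- read_temperature(file.path(dir, "temperature.csv"))
  expect_equal(temp$temp_c, ex$temperature$temp_c, tolerance = 1e-9)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$q10, 1.7)
})
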
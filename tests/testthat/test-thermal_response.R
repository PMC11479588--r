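mk_cycles <- function(starts, period = NULL) {
  if (is.null(period)) period <- diff(starts)
  n <- length(starts) - 1
  tibble::tibble(cycle = seq_len(n), start_s = starts[-length(starts)],
                 end_s = starts[-1], period_s = diff(starts),
                 freq_hz = 1 / diff(starts))
}

test_that("cycle temperature is the time-average of the trace", {
  cy <- mk_cycles(c(0, 10))
  flat <- tibble::tibble(time_s = seq(0, 10), temp_c = 11)
  expect_equal(annotate_temperature(cy, flat)$temp_c, 11)

  ramp <- tibble::tibble(time_s = c(0, 10), temp_c = c(11, 13))
  expect_equal(annotate_temperature(cy, ramp)$temp_c, 12)

  # random piecewise-linear trace vs dense quadrature oracle
  set.seed(5)
  tt <- sort(runif(40, 0, 10))
  tt <- c(0, tt, 10)
  tv <- 11 + cumsum(rnorm(length(tt), 0, 0.3))
  trace <- tibble::tibble(time_s = tt, temp_c = tv)
  cy2 <- mk_cycles(c(0, 2.3, 4.1, 7.7, 10))
  got <- annotate_temperature(cy2, trace)$temp_c
  dense <- function(a, b) {
    x <- seq(a, b, length.out = 200001)
    y <- approx(tt, tv, xout = x)$y
    mean((y[-1] + y[-length(y)]) / 2)
  }
  want <- mapply(dense, cy2$start_s, cy2$end_s)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("annotation warns on extrapolation and rejects empty traces", {
  cy <- mk_cycles(c(-1, 11))
  trace <- tibble::tibble(time_s = c(0, 10), temp_c = c(11, 13))
  expect_warning(annotate_temperature(cy, trace), "extrapolat")
  expect_error(annotate_temperature(cy, trace[0, ]), "empty|at least")
})

test_that("holding windows are maximal in-band runs at the nearer target", {
  temps <- c(rep(11.0, 20), seq(11.35, 12.65, by = 0.1), rep(13.05, 20))
  cy <- tibble::tibble(cycle = seq_along(temps), temp_c = temps)
  w <- find_holding_windows(cy, targets = c(11, 13), tolerance = 0.3,
                            min_cycles = 10)
  expect_equal(nrow(w), 2)
  expect_equal(w$n_cycles, c(20, 20))  # ramp cycles fall outside both bands
  expect_equal(w$target_temp, c(11, 13))

  cy2 <- tibble::tibble(cycle = 1:30, temp_c = rep(12, 30))
  expect_warning(w2 <- find_holding_windows(cy2, c(11, 13), 0.3, 10),
                 "no holding window")
  expect_equal(nrow(w2), 0)

  # a cycle eligible for two targets goes to the nearer one
  cy3 <- tibble::tibble(cycle = 1:20, temp_c = rep(c(11.1, 11.4), each = 10))
  w3 <- find_holding_windows(cy3, c(11, 11.5), tolerance = 0.4,
                             min_cycles = 5)
  expect_equal(w3$target_temp, c(11, 11.5))
  expect_equal(w3$n_cycles, c(10, 10))
})

test_that("every cycle joins at most one window and windows do not overlap", {
  set.seed(9)
  ex <- cached("small_sal", simulate_experiment(
    ground_truth(spike_jitter_sd = 0.005), small_protocol(), seed = 31))
  res <- suppressMessages(analyse_experiment(ex))
  w <- res$windows
  covered <- unlist(mapply(seq, w$first_cycle, w$last_cycle))
  expect_false(any(duplicated(covered)))
  expect_equal(nrow(w), 3)  # one window per protocol hold
})

test_that("steady-state means pool window cycles with plain statistics", {
  cy <- tibble::tibble(cycle = 1:4, temp_c = c(11, 11, 11, 11),
                       freq_hz = c(1.0, 1.2, 1.1, 9))
  w <- tibble::tibble(window = 1:2, target_temp = c(11, 11),
                      first_cycle = c(1L, 3L), last_cycle = c(2L, 3L),
                      n_cycles = c(2L, 1L), mean_temp = 11)
  s <- steady_state_means(cy, w)
  expect_equal(s$n_cycles, 3)
  expect_equal(s$mean_freq_hz, mean(c(1.0, 1.2, 1.1)))
  # two-point window SD
  s2 <- steady_state_means(cy, w[1, ])
  expect_equal(s2$sd_freq_hz, sd(c(1.0, 1.2)), tolerance = 1e-12)
  # single-cycle window has zero spread by convention
  s3 <- steady_state_means(cy, w[2, ])
  expect_equal(s3$sd_freq_hz, 0)
})

test_that("Q10 fitting matches the model and an independent OLS oracle", {
  # exact two-point data at the typical saline values
  fit2 <- fit_q10(data.frame(target_temp = c(11, 21),
                             mean_freq_hz = c(1.2, 2.1)))
  expect_equal(fit2$q10, 1.75, tolerance = 1e-12)
  expect_equal(fit2$f_ref, 1.2, tolerance = 1e-12)
  expect_equal(fit2$residual_sd, 0)

  # six points exactly on f = 1.0 * 2^((T-11)/10)
  temps <- seq(11, 21, by = 2)
  d <- data.frame(target_temp = temps,
                  mean_freq_hz = 2^((temps - 11) / 10))
  fit6 <- fit_q10(d)
  expect_equal(fit6$q10, 2, tolerance = 1e-12)
  expect_equal(fit6$residual_sd, 0, tolerance = 1e-12)

  # noisy points vs closed-form log-space OLS
  set.seed(21)
  for (i in 1:20) {
    f <- 2^((temps - 11) / 10) * exp(rnorm(6, 0, 0.05))
    fit <- fit_q10(data.frame(target_temp = temps, mean_freq_hz = f))
    x <- (temps - 11) / 10
    y <- log(f)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    expect_equal(fit$q10, exp(slope), tolerance = 1e-10)
    expect_equal(fit$f_ref, exp(intercept), tolerance = 1e-10)
  }

  expect_error(fit_q10(data.frame(target_temp = 11, mean_freq_hz = 1)),
               "at least 2")
  expect_error(fit_q10(data.frame(target_temp = c(11, 21),
                                  mean_freq_hz = c(1, -1))), "> 0")
})

test_that("Q10 fit is scale-equivariant and recovers under log-normal noise", {
  temps <- seq(11, 21, by = 2)
  f <- 1.2 * 1.7^((temps - 11) / 10)
  base <- fit_q10(data.frame(target_temp = temps, mean_freq_hz = f))
  scaled <- fit_q10(data.frame(target_temp = temps, mean_freq_hz = 3 * f))
  expect_equal(scaled$q10, base$q10, tolerance = 1e-12)
  expect_equal(scaled$f_ref, 3 * base$f_ref, tolerance = 1e-12)

  # parameter recovery: mean estimate within 3 SE of truth over replicates
  set.seed(33)
  sigma <- 0.05
  ests <- replicate(1000, {
    fn <- f * exp(rnorm(6, 0, sigma))
    fit_q10(data.frame(target_temp = temps, mean_freq_hz = fn))$q10
  })
  se_mean <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1.7), 3 * se_mean + 1e-3)
})

test_that("condition differences align grids and report within-changes", {
  mk <- function(freqs) tibble::tibble(target_temp = c(11, 21),
                                       mean_freq_hz = freqs)
  same <- condition_difference(mk(c(1, 2)), mk(c(1, 2)))
  expect_equal(same$diff_hz, c(0, 0))

  d <- condition_difference(mk(c(1.2, 2.1)), mk(c(0.9, 1.215)),
                            labels = c("saline", "Cs"))
  expect_equal(d$diff_hz, c(0.3, 0.885))
  expect_equal(attr(d, "within_change"),
               c(saline = 0.9, Cs = 0.315))

  expect_error(
    condition_difference(mk(c(1, 2)),
                         tibble::tibble(target_temp = c(11, 19),
                                        mean_freq_hz = c(1, 2))),
    "grids differ"
  )
})

test_that("endpoint Q10 estimator matches its closed form", {
  expect_equal(q10_endpoint(1.2, 2.1, 11, 21), 1.75)
  expect_equal(q10_endpoint(1, 2, 11, 16), 2^(10 / 5))
  expect_error(q10_endpoint(-1, 2), "f_low")
})
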
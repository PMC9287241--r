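test_that("landmarks of a constructed damped cosine are recovered", {
  # single mode exp(gamma t) cos(omega t + phi): extrema where
  # tan(omega t + phi) = gamma / omega
  gamma <- -10; nu <- 5; omega <- 2 * pi * nu
  phi <- -omega * 0.1 + atan(gamma / omega) + pi   # minimum exactly at 100 ms
  t <- seq(0, 0.6, 1e-4)
  wave <- list(time = t, R = -exp(gamma * t) * cos(omega * t + phi))
  # the 100-ms extremum is a positive deflection: opposite to a negative P1m
  pk <- extract_peaks(wave, polarity = -1)
  n1 <- pk[pk$landmark == "N1m", ]
  expect_true(n1$found)
  expect_equal(n1$latency_s, 0.1, tolerance = 1e-3)
  amp_exact <- -exp(gamma * 0.1) * cos(omega * 0.1 + phi)
  expect_equal(n1$amplitude, abs(amp_exact), tolerance = 1e-4)
  # a window with no extremum of the required polarity is flagged, not zeroed
  flat <- list(time = t, R = rep(-1, length(t)))
  pk2 <- extract_peaks(flat, polarity = 1)
  expect_false(any(pk2$found[pk2$landmark == "P1m"]))
  expect_true(is.na(pk2$amplitude[pk2$landmark == "P1m"]))
})

test_that("landmark latencies are ordered P1m < N1m < P2m", {
  for (soi in c(1, 10)) {
    pk <- extract_peaks(erf_waveform(adapted_run(soi), "adapted"))
    expect_true(all(pk$found))
    expect_true(all(diff(pk$latency_s) > 0))
  }
})

test_that("noiseless saturating-exponential data are recovered exactly", {
  soi <- c(0.5, 1, 2.5, 5, 10)
  y <- 1 * (1 - exp(-(soi - (-1)) / 2.5))
  fit <- fit_recovery(soi, y)
  expect_true(fit$converged)
  expect_equal(fit$A, 1, tolerance = 1e-6)
  expect_equal(fit$t0, -1, tolerance = 1e-6)
  expect_equal(fit$tau_soi, 2.5, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-8)
  expect_error(fit_recovery(soi[1:3], y[1:3]))
  expect_error(fit_recovery(rev(soi), y))
})

test_that("noisy recovery stays within 10 % over 200 seeded replicates", {
  soi <- c(0.5, 1, 2.5, 5, 10)
  errs <- vapply(seq_len(200), function(seed) {
    d <- make_fixture("exp_recovery",
                      list(soi = soi, A = 1, t0 = -1, tau = 2.5,
                           sigma = 0.02), seed = seed)
    abs(fit_recovery(d$soi_s, d$peak_amplitude)$tau_soi - 2.5) / 2.5
  }, 0)
  # with 3 free parameters on 5 points the lifetime is noise-sensitive
  # (about a four-fold amplification of the 2 % amplitude noise); typical
  # recovery stays within 10 %
  expect_lt(mean(errs), 0.10)
  expect_lt(stats::median(errs), 0.10)
})

test_that("local saturation rate is constant exactly for exponential data", {
  soi <- seq(0.5, 10, by = 0.5)
  A <- 2; t0 <- -1; tau <- 2.5
  y <- A * (1 - exp(-(soi - t0) / tau))
  sat <- local_saturation_rate(soi, y, F_inf = A)
  expect_equal(nrow(sat), length(soi) - 1)
  expect_lt(diff(range(sat$f)), 1e-10)
  # the constant equals (1 - exp(-delta/tau)) / delta on a grid of step delta
  expect_equal(sat$f[1], (1 - exp(-0.5 / tau)) / 0.5, tolerance = 1e-10)
  # minimal input: two points give one value
  expect_equal(nrow(local_saturation_rate(soi[1:2], y[1:2], A)), 1)
  # saturated points are dropped with a warning
  expect_warning(local_saturation_rate(c(1, 2, 3), c(2, 2, 1.9), 2),
                 "dropped")
})

test_that("lifetime report covers ERF plus three cortical areas", {
  rep <- suppressWarnings(
    adaptation_lifetime_report("DEF", sois = c(0.5, 1, 2.5, 5, 10)))
  expect_equal(nrow(rep), 4)
  expect_setequal(rep$signal, c("ERF", "core", "belt", "parabelt"))
  expect_true(all(rep$converged))
  expect_true(all(rep$tau_soi_s > 0))
  # the ERF saturation amplitude approximates the initial-state N1m peak
  curve <- attr(rep, "curves")$DEF
  A_init <- curve$initial$magnitude[curve$initial$signal == "ERF"]
  expect_equal(rep$A[rep$signal == "ERF"], A_init, tolerance = 0.1)
})

test_that("fixtures are exact, seeded and reproducible", {
  d <- make_fixture("exp_recovery", list(soi = c(0.5, 1, 2.5, 5, 10),
                                         A = 1, t0 = -1, tau = 2.5))
  expect_equal(d$peak_amplitude, 1 - exp(-(d$soi_s + 1) / 2.5))
  n1 <- make_fixture("exp_recovery", list(sigma = 0.05), seed = 42)
  n2 <- make_fixture("exp_recovery", list(sigma = 0.05), seed = 42)
  expect_identical(n1, n2)
  expect_error(make_fixture("exp_recovery", list(sigma = 0.05)), "seed")
  # damped wave: extrema at (atan(gamma/omega) + k pi) / omega
  w <- make_fixture("damped_wave", list(gamma = -10, nu = 5, dt = 1e-4))
  omega <- 2 * pi * 5
  t1 <- (atan(-10 / omega) + pi) / omega
  i <- which(diff(sign(diff(w$R))) != 0) + 1L
  expect_equal(w$time_s[i[1]], t1, tolerance = 2e-4)
})
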
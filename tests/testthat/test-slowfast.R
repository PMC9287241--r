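test_that("slow recovery follows the closed form", {
  p <- default_params()
  expect_equal(slow_recovery(rep(1, 5), 2, p), rep(1, 5))
  # q = 0.5 over one replenishment time constant: 1 - 0.5/e
  expect_equal(slow_recovery(0.5, p$tau_rec, p), 1 - 0.5 * exp(-1),
               tolerance = 1e-12)
  expect_equal(slow_recovery(0.2, 1e6, p), 1)
  expect_equal(slow_recovery(c(0.5, 0.5), 1, p,
                             adapting = c(TRUE, FALSE))[2], 1)
  expect_error(slow_recovery(0.5, -1, p), "non-negative")
})

test_that("fast drop-off has the correct limits", {
  p <- default_params()
  dec <- default_spectrum()
  q <- c(1, 1, 0.9, 0.8, 0.7)
  # no activity: efficacy unchanged
  zero <- structure(rep(0 + 0i, 10), class = "ac_coefs")
  expect_equal(fast_dropoff(q, dec, zero, 0.5, p), q)
  # multiplicative form: zero efficacy stays zero
  co <- mode_coefficients(dec, jump_state())
  expect_equal(fast_dropoff(rep(0, 5), dec, co, 0.5, p), rep(0, 5))
  # released transmitter always reduces efficacy here (u >= 0 transient)
  f <- fast_dropoff(q, dec, co, 0.5, p)
  expect_true(all(f < q))
})

test_that("closed-form drop-off matches the quadrature oracle", {
  p <- default_params()
  net <- decoupled_net()
  u0 <- jump_state()                  # afferent jump on the isolated IC column
  dec <- spectral_decomposition(coefficient_matrix(net))
  co <- mode_coefficients(dec, u0)
  got <- fast_dropoff(rep(1, 5), dec, co, 0.5, p)
  # oracle: integrate g[u] = alpha * u on a fine numerically integrated grid
  tr <- integrate_full(net, p, stimulus_train(0.5, 1), "linear",
                       dt_out = 1e-4, fix_q = rep(1, 5), t_end = 0.5)
  for (i in seq_len(5)) {
    integral <- sum(diff(tr$time) *
                      (head(tr$u[, i], -1) + tail(tr$u[, i], -1)) / 2)
    expect_equal(got[i], exp(-p$alpha * integral / p$tau_o),
                 tolerance = 1e-6)
  }
})

test_that("lambda near zero uses the linear-in-time limit", {
  p <- default_params()
  dec <- default_spectrum()
  dec$values <- rep(0 + 0i, 10)   # degenerate spectrum: exponent -> c * delta
  co <- structure(rep(0.1 + 0i, 10), class = "ac_coefs")
  got <- fast_dropoff(rep(1, 5), dec, co, 0.3, p)
  X <- dec$right[1:5, ]
  expected <- exp(-p$alpha * Re(X %*% rep(0.1 * 0.3, 10)) / p$tau_o)
  expect_equal(got, as.vector(expected), tolerance = 1e-12)
})

test_that("a single stimulus leaves only the initial state", {
  ad <- suppressWarnings(run_stimulus_train(default_net(), default_params(),
                                            stimulus_train(0.5, 1)))
  expect_equal(nrow(ad$q), 1)
  expect_equal(unname(ad$q[1, ]), rep(1, 5))
  expect_equal(ad$n_used, 1)
})

test_that("efficacy decreases to a converged adapted state", {
  ad <- adapted_run(0.5)
  cortical <- ad$q[, c("core", "belt", "parabelt")]
  # the directly driven core depresses monotonically; downstream areas may
  # rebound marginally as weakening upstream transmission reduces their own
  # release, so only allow tiny upward steps there
  expect_true(all(diff(cortical[, "core"]) <= 1e-12))
  expect_true(all(diff(cortical) <= 1e-3))
  expect_true(all(cortical[nrow(cortical), ] < cortical[1, ] - 0.01))
  expect_true(ad$converged)
  expect_true(all(ad$q > 0 & ad$q <= 1))
  expect_true(all(ad$q[, c("IC", "thalamus")] == 1))
  expect_lt(max(abs(ad$q[nrow(ad$q), ] - ad$q[nrow(ad$q) - 1L, ])), 1e-4)
})

test_that("longer SOIs leave more efficacy in the adapted state", {
  q_ad <- sapply(c(0.5, 1, 2.5, 5, 10),
                 function(s) adapted_run(s)$q[adapted_run(s)$n_used, "core"])
  expect_true(all(diff(q_ad) > 0))
  expect_gt(q_ad[5], 0.98)   # SOI 10 s: nearly fully recovered
})

test_that("adapted modes sit higher on the dispersion curve", {
  for (soi in c(0.5, 10)) {
    ad <- adapted_run(soi)
    ini <- adaptation_state(ad, "initial")
    fin <- adaptation_state(ad, "adapted")
    dnu <- sort(fin$dec$nu[fin$dec$omega > 0]) -
      sort(ini$dec$nu[ini$dec$omega > 0])
    dga <- sort(abs(fin$dec$gamma[fin$dec$omega > 0])) -
      sort(abs(ini$dec$gamma[ini$dec$omega > 0]))
    expect_true(all(dnu >= -1e-12))
    expect_true(all(dga >= -1e-12))
    if (soi == 0.5) shift_small <- mean(dnu)
    if (soi == 10) {
      # at SOI 10 s the shift is minute on average (< 2 %); the lowest-
      # frequency mode is the most sensitive and stays below 5 %
      rel <- dnu / sort(ini$dec$nu[ini$dec$omega > 0])
      expect_lt(mean(rel), 0.02)
      expect_lt(max(rel), 0.05)
      expect_lt(mean(dnu), shift_small)
    }
  }
})

test_that("the slow-fast scheme reproduces the full model's efficacy", {
  net <- default_net(); p <- default_params()
  train <- stimulus_train(0.5, 10)
  ad <- suppressWarnings(run_stimulus_train(net, p, train, tol = 0))
  full <- suppressWarnings(integrate_full(net, p, train, "linear"))
  idx <- vapply(train$onsets, function(t0) which.min(abs(full$time - t0)), 0L)
  q_full <- full$q[idx, "core"]
  expect_lt(max(abs(ad$q[, "core"] - q_full)), 0.03)
})

test_that("per-stimulus peaks decrease and level off under fast stimulation", {
  rep <- suppressWarnings(validate_against_full_model(
    default_net(), default_params(), stimulus_train(0.5, 10)))
  core <- rep[rep$area == "core", ]
  expect_true(all(diff(core$peak_slowfast) < 0))
  # levelling off: late decrements are far smaller than the first
  expect_lt(abs(diff(tail(core$peak_slowfast, 2))),
            0.1 * abs(core$peak_slowfast[2] - core$peak_slowfast[1]))
  # adapted-state agreement with the linear full model is close
  late <- rep[rep$stimulus >= 5, ]
  expect_lt(max(late$rel_diff_linear), 0.05)
})

test_that("frozen efficacy limit: no depression accumulates", {
  p_frozen <- ac_params(tau_o = 4e5, tau_rec = 5e6)
  net <- build_network(p_frozen)
  ad <- suppressWarnings(run_stimulus_train(net, p_frozen,
                                            stimulus_train(0.5, 5), tol = 0))
  expect_true(all(abs(ad$q - 1) < 1e-4))
})

test_that("adaptation export is tidy", {
  ad <- adapted_run(0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_adaptation(ad, path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("stimulus_index", "area", "q", "d"))
  expect_equal(nrow(df), nrow(ad$q) * 5)
  expect_equal(df$q + df$d, rep(1, nrow(df)))
})
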
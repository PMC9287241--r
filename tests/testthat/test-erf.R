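test_that("the forward model is linear and null for silent sensors", {
  net <- default_net()
  tzero <- structure(list(time = seq(0, 0.1, 0.01),
                          u = matrix(0, 11, 5), v = matrix(0, 11, 5)),
                     class = "ac_trajectory")
  expect_equal(meg_signal(net, tzero)$R, rep(0, 11))
  # null topology: no signal regardless of activity
  net0 <- net; net0$K1[] <- 0; net0$K2[] <- 0
  dec <- default_spectrum()
  co <- mode_coefficients(dec, jump_state())
  tr <- evolve_modes(dec, co, seq(0, 0.3, 1e-3))
  expect_equal(max(abs(meg_signal(net0, tr)$R)), 0)
  # subcortical targets are magnetically silent (IC entirely; thalamic v);
  # only the thalamus' excitatory projection into the core reaches the sensor
  tr_sub <- tr
  tr_sub$u[] <- 0; tr_sub$v[] <- 0
  tr_sub$u[, "IC"] <- 1; tr_sub$v[, "IC"] <- 1; tr_sub$v[, "thalamus"] <- 1
  expect_equal(max(abs(meg_signal(net, tr_sub)$R)), 0)
  tr_sub$u[, "thalamus"] <- 1
  expect_equal(meg_signal(net, tr_sub)$R,
               rep(net$K1["core", "thalamus"] * net$W_ee["core", "thalamus"],
                   length(tr$time)))
})

test_that("mode contributions sum to the MEG signal", {
  net <- default_net()
  ad <- adapted_run(2.5)
  st <- adaptation_state(ad, "adapted")
  times <- seq(0, 0.5, 1e-3)
  mc <- mode_contributions(st$dec, st$coeffs, net, times = times)
  tr <- evolve_modes(st$dec, st$coeffs, times)
  R <- meg_signal(net, tr)$R
  R_modes <- Re(colSums(mc$r))
  expect_lt(max(abs(R_modes - R)), 1e-9 * max(abs(R)))
  # pair contribution is twice the real part of one member
  n <- 1; m <- st$dec$pair[n]
  pair_sum <- Re(mc$r[n, ] + mc$r[m, ])
  expect_equal(pair_sum, 2 * Re(mc$r[n, ]), tolerance = 1e-10)
})

test_that("total mode contribution is normalisation invariant", {
  net <- default_net()
  dec <- default_spectrum()
  co <- mode_coefficients(dec, jump_state())
  base <- mode_contributions(dec, co, net)$table$total
  # rescale each eigenvector by an arbitrary complex factor (conjugate
  #-consistent across pairs) and recompute coefficients and efficiencies
  dec2 <- dec
  set.seed(7)
  sc <- complex(modulus = runif(10, 0.2, 3), argument = runif(10, -pi, pi))
  for (n in 1:10) if (!is.na(dec$pair[n]) && dec$pair[n] < n)
    sc[n] <- Conj(sc[dec$pair[n]])
  dec2$right <- sweep(dec$right, 2, sc, "*")
  dec2$left <- sweep(dec$left, 1, sc, "/")
  co2 <- mode_coefficients(dec2, jump_state())
  tot2 <- mode_contributions(dec2, co2, net)$table$total
  expect_equal(tot2, base, tolerance = 1e-9)
})

test_that("low-frequency modes dominate the N1m and oppose at onset", {
  net <- default_net()
  ad <- adapted_run(2.5)
  st <- adaptation_state(ad, "adapted")
  erf <- erf_waveform(ad, "adapted")
  n1 <- extract_peaks(erf)
  lat <- n1$latency_s[n1$landmark == "N1m"]
  mc <- mode_contributions(st$dec, st$coeffs, net, times = lat)
  pos <- which(st$dec$omega > 0)           # one member per pair
  by_freq <- pos[order(st$dec$nu[pos])]
  # the two lowest-frequency pairs have the largest amplitude envelope at the
  # N1m latency ...
  env <- abs(2 * mc$r[, 1])
  expect_true(all(env[by_freq[1:2]] >= max(env[by_freq[3:5]])))
  # ... but the instantaneous N1m deflection is formed by the lowest mode:
  # the second mode's real part is minute there
  inst <- abs(2 * Re(mc$r[, 1]))
  expect_equal(which.max(inst[by_freq]), 1L)
  expect_lt(inst[by_freq[2]], 0.1 * inst[by_freq[1]])
  # at onset the two leading modes interfere destructively (phases ~ pi apart)
  mc0 <- mode_contributions(st$dec, st$coeffs, net, times = 0)
  dphi <- abs(Arg(mc0$r[by_freq[1], 1]) - Arg(mc0$r[by_freq[2], 1]))
  dphi <- min(dphi, 2 * pi - dphi)
  expect_lt(abs(dphi - pi), pi / 4)
})

test_that("connection decompositions partition the signal exactly", {
  net <- default_net()
  ad <- adapted_run(1)
  st <- adaptation_state(ad, "adapted")
  tr <- evolve_modes(st$dec, st$coeffs, seq(0, 0.5, 1e-3))
  R <- meg_signal(net, tr)$R
  for (scheme in c("incoming", "outgoing", "type")) {
    d <- decompose_by_connection(net, tr, scheme)
    expect_lt(max(abs(d$total - R)), 1e-12 * max(abs(R)))
  }
  expect_error(decompose_by_connection(net, tr, "sideways"))
  # incoming: subcortical rows are silent
  dinc <- decompose_by_connection(net, tr, "incoming")
  expect_equal(max(abs(dinc$groups[, c("IC", "thalamus")])), 0)
  # type groups are the four connection classes
  dtyp <- decompose_by_connection(net, tr, "type")
  expect_setequal(colnames(dtyp$groups),
                  c("feedforward", "feedback", "lateral", "inhibitory"))
})

test_that("the core's incoming contribution generates the P1m", {
  net <- default_net()
  ad <- adapted_run(1)
  st <- adaptation_state(ad, "adapted")
  erf <- erf_waveform(ad, "adapted")
  pk <- extract_peaks(erf)
  p1_lat <- pk$latency_s[pk$landmark == "P1m"]
  tr <- evolve_modes(st$dec, st$coeffs, seq(0, 0.5, 1e-3))
  dinc <- decompose_by_connection(net, tr, "incoming")
  i <- which.min(abs(dinc$time - p1_lat))
  core <- abs(dinc$groups[i, "core"])
  expect_lt(abs(dinc$groups[i, "belt"]), 0.25 * core)
  expect_lt(abs(dinc$groups[i, "parabelt"]), 0.1 * core)
})

test_that("display shift affects exports only", {
  ad <- adapted_run(1)
  erf <- erf_waveform(ad, "adapted", shift_ms = 30)
  pk <- extract_peaks(erf)          # analysis in model time
  expect_lt(pk$latency_s[pk$landmark == "P1m"], 0.04)
  path <- withr::local_tempfile(fileext = ".csv")
  write_erf(erf, path)
  df <- utils::read.csv(path)
  expect_equal(df$time_ms[1], 30)   # shift applied on export
  expect_equal(df$R, erf$R)
})
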
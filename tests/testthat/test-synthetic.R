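test_that("the integrate-and-fire generator fires at exact unit crossings", {
  ev <- simulate_ipfm(62, mean_hp = 1, lf = c(0.1, 0), hf = c(0.25, 0))
  expect_equal(ev$u[1:60], 1:60, tolerance = 1e-6)
  # constant modulation shortens every interval to T0 / (1 + m)
  ev2 <- simulate_ipfm(62, mean_hp = 1, lf = c(0.1, 0), hf = c(0.25, 0),
                       dc = 0.25)
  expect_equal(unique(round(ev2$hp[-1], 6)), 0.8, tolerance = 1e-5)
  # mean event rate
  ev3 <- simulate_ipfm(300, mean_hp = 0.9)
  expect_equal(length(ev3$u), 300 / 0.9, tolerance = 1.5 / (300 / 0.9))
})

test_that("the generator rejects saturating modulation and bad bands", {
  expect_error(simulate_ipfm(100, lf = c(0.1, 0.7), hf = c(0.25, 0.5)),
               "rate")
  expect_error(simulate_ipfm(100, lf = c(0.2, 0.1)), "LF")
  expect_error(simulate_ipfm(100, hf = c(0.1, 0.1)), "HF")
  expect_error(simulate_ipfm(5, mean_hp = 1), "duration")
})

test_that("HF modulation appears at the right spectral peak", {
  set.seed(3)
  ev <- simulate_ipfm(600, mean_hp = 0.9, lf = c(0.1, 0.02),
                      hf = c(0.25, 0.12), jitter_sd = 0.002)
  tt <- seq(10, 590, by = 0.25)
  hp_i <- approx(ev$u[-1], ev$hp[-1], xout = tt)$y
  sp <- stats::spec.pgram(stats::ts(hp_i, deltat = 0.25), plot = FALSE,
                          spans = 5)
  hot <- sp$freq[which.max(sp$spec)]
  expect_gte(hot, 0.2)
  expect_lte(hot, 0.3)
})

test_that("model-class simulation matches i.i.d. theory when g1 = 0", {
  b <- laguerre_basis()
  set.seed(10)
  ev <- simulate_from_model(0.8, rep(0, 10), 400, b, n_beats = 1000)
  hp <- ev$hp[-1]
  se_mean <- sqrt(0.8^3 / 400 / length(hp))
  expect_lt(abs(mean(hp) - 0.8), 3 * se_mean)
  expect_equal(var(hp), 0.8^3 / 400, tolerance = 0.2)
  # determinism under a fixed seed
  set.seed(77)
  a <- simulate_from_model(0.8, rep(0, 10), 400, b, n_beats = 50)
  set.seed(77)
  bb <- simulate_from_model(0.8, rep(0, 10), 400, b, n_beats = 50)
  expect_identical(a$u, bb$u)
  # infeasible parameters are rejected with context
  expect_error(simulate_from_model(-1, rep(0, 10), 400, b, 50),
               "stationary")
})

test_that("synthetic pulse waveforms round-trip through detection", {
  set.seed(20)
  ev <- simulate_ipfm(120, mean_hp = 0.9, jitter_sd = 0.003)
  x <- synth_ppg(ev, fs = 400)
  det <- detect_beats(x, fs = 400)
  expect_equal(length(det$u), length(ev$u))
  expect_lt(max(abs(det$u - ev$u)), 1 / 400)
  # doubling the amplitude moves no peak
  x2 <- synth_ppg(ev, fs = 400, amplitude = 2)
  det2 <- detect_beats(x2, fs = 400)
  expect_equal(det2$u, det$u)
  expect_error(synth_ppg(ev, fs = 400, pulse_width = 0.5), "overlap")
})

test_that("noisy round trip loses at most one beat per thousand", {
  set.seed(21)
  ev <- simulate_ipfm(900, mean_hp = 0.9, jitter_sd = 0.003)
  x <- synth_ppg(ev, fs = 400, noise_sd = 0.05)
  det <- correct_artifacts(detect_beats(x, fs = 400))
  expect_lte(abs(length(det$u) - length(ev$u)),
             max(1, length(ev$u) / 1000))
})

test_that("synthetic BOLD plants exactly what it reports", {
  reg <- convolve_regressor(regressor_series(rnorm(200), tr = 0.72))
  dims <- c(5, 5, 2)
  act <- array(FALSE, dims); act[2:3, 2:3, 1] <- TRUE
  set.seed(30)
  bold <- synth_bold(reg, dims = dims, active_mask = act, effect = 2,
                     noise_ar1 = 0, noise_sd = 1e-10)
  fl <- first_level(bold, reg)
  expect_equal(unname(fl$beta[match(which(act), which(bold$mask))]),
               rep(2, 4), tolerance = 1e-6)
  expect_lt(max(abs(fl$beta[-match(which(act), which(bold$mask))])), 1e-6)
  # reproducibility
  set.seed(31); b1 <- synth_bold(reg, dims = dims, effect = 0)
  set.seed(31); b2 <- synth_bold(reg, dims = dims, effect = 0)
  expect_identical(b1$data, b2$data)
  expect_error(synth_bold(reg, dims = dims, noise_ar1 = 1), "noise_ar1")
  expect_error(synth_bold(regressor_series(rnorm(10)), dims = dims),
               "convolved")
})

test_that("scenario presets are reproducible and correctly parameterized", {
  sc <- scenario("baseline", seed = 7, duration = 300, ppg = FALSE)
  expect_equal(sc$spec$mean_hp, 0.9)
  expect_equal(sc$spec$lf, c(0.1, 0.1))
  expect_equal(sc$spec$hf, c(0.25, 0.1))
  sc2 <- scenario("baseline", seed = 7, duration = 300, ppg = FALSE)
  expect_identical(sc$events$u, sc2$events$u)
  sa <- scenario("sympathetic_activation", seed = 1, duration = 900,
                 ppg = FALSE)
  expect_equal(sa$spec$epochs$start, 300)
  expect_equal(sa$spec$epochs$end, 600)
  expect_equal(sa$spec$epochs$lf_scale, 2)
  vw <- scenario("vagal_withdrawal", seed = 1, duration = 900, ppg = FALSE)
  expect_equal(vw$spec$epochs$hf_scale, 0.5)
  expect_error(scenario("nonsense"), "arg")
})
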
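test_that("index combination, normalization and floor follow the definitions", {
  psi <- psi_coefficients(psi_S0 = 0.4, psi_S = c(1, 0, 0),
                          psi_P0 = 1, psi_P = rep(0, 7))
  # zero coefficients: offset only
  expect_equal(compute_sai(rep(0, 10), 1, psi), 0.4)
  expect_equal(compute_pai(rep(0, 10), 1, psi), 1)
  # offset-only PAI with normalization
  expect_equal(compute_pai(rep(0, 10), 2, psi), 1 / 4)
  # arithmetic on the sympathetic block
  psi2 <- psi_coefficients(0, c(1, 0, 0), 0, rep(0, 7))
  expect_equal(compute_sai(c(2, rnorm(9)), 1, psi2), 2)
  # negative raw values are floored at zero
  psi3 <- psi_coefficients(-0.5, c(0, 0, 0), -0.5, rep(0, 7))
  expect_equal(compute_sai(rep(0, 10), 1, psi3), 0)
  expect_equal(compute_pai(rep(0, 10), 1, psi3), 0)
  # non-converged state yields a missing value
  expect_true(is.na(compute_sai(rep(0, 10), 1, psi, converged = FALSE)))
})

test_that("random psi and g1 match a brute-force dot product", {
  set.seed(12)
  for (i in 1:10) {
    g1 <- rnorm(10); mu <- runif(1, 0.5, 1.2)
    psi <- psi_coefficients(rnorm(1), rnorm(3), rnorm(1), rnorm(7))
    expect_equal(compute_sai(g1, mu, psi),
                 max((psi$psi_S0 + sum(psi$psi_S * g1[1:3])) / mu^2, 0))
    expect_equal(compute_pai(g1, mu, psi),
                 max((psi$psi_P0 + sum(psi$psi_P * g1[4:10])) / mu^2, 0))
  }
})

test_that("normalize_index divides by the squared mean heart period", {
  expect_equal(normalize_index(4, 2), 1)
  x <- rnorm(5)
  expect_equal(normalize_index(x, 1), x)
  expect_error(normalize_index(1, 0), "positive")
})

test_that("indices are invariant to coefficients outside their block", {
  set.seed(13)
  g1 <- rnorm(10); mu <- 0.9
  psi <- psi_default()
  g1_mod <- g1
  g1_mod[4:10] <- rnorm(7)             # parasympathetic block perturbed
  expect_equal(compute_sai(g1, mu, psi), compute_sai(g1_mod, mu, psi))
  g1_mod2 <- g1
  g1_mod2[1:3] <- rnorm(3)             # sympathetic block perturbed
  expect_equal(compute_pai(g1, mu, psi), compute_pai(g1_mod2, mu, psi))
})

test_that("index series preserves the grid and carries missingness", {
  p <- study_params()
  set.seed(14)
  ev <- simulate_from_model(p$g0, p$g1, p$xi0, p$basis, n_beats = 200)
  fit <- pphrv(ev, step = 0.5)
  idx <- index_series(fit)
  expect_equal(idx$time, fit$times)
  expect_true(all(idx$sai[idx$converged] >= 0))
  expect_true(all(is.na(idx$sai[!idx$converged])))
  # constant trajectory gives constant indices
  fit$g1[] <- rep(fit$g1[1, ], each = nrow(fit$g1))
  fit$g0[] <- fit$g0[1]; fit$mu_hp[] <- fit$mu_hp[1]
  fit$converged[] <- TRUE
  idx2 <- index_series(fit)
  expect_lt(diff(range(idx2$sai)), 1e-12)
  expect_lt(diff(range(idx2$pai)), 1e-12)
})

test_that("scaling all heart periods by c rescales mu_hp by c through the pipeline", {
  p <- study_params()
  set.seed(15)
  ev <- simulate_from_model(p$g0, p$g1, p$xi0, p$basis, n_beats = 180)
  cc <- 1.25
  ev_scaled <- event_series(ev$u * cc)
  f1 <- pphrv(ev, step = 1)
  f2 <- pphrv(ev_scaled, step = 1, duration = max(f1$times) * cc)
  m1 <- mean(f1$mu_hp[f1$converged])
  m2 <- mean(f2$mu_hp[f2$converged])
  expect_equal(m2 / m1, cc, tolerance = 0.02)
})

test_that("psi coefficients survive a JSON round trip", {
  psi <- psi_default()
  path <- tempfile(fileext = ".json")
  write_psi(psi, path)
  back <- read_psi(path)
  expect_equal(back$psi_S, psi$psi_S)
  expect_equal(back$psi_P, psi$psi_P)
  expect_equal(back$provenance, psi$provenance)
})
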
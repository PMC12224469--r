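test_that("mu_hp is the expansion's linear combination", {
  expect_equal(mu_hp(0.2, rep(0, 10), runif(10)), 0.2)
  expect_equal(mu_hp(0.2, c(0.5, rep(0, 9)), c(1, rnorm(9))), 0.7)
  set.seed(3)
  g1 <- rnorm(10); l <- rnorm(10)
  expect_equal(mu_hp(0.1, g1, l), 0.1 + sum(g1 * l))
  expect_error(mu_hp(0.1, g1[1:5], l), "length")
})

test_that("local log-likelihood matches a brute-force term-by-term oracle", {
  p <- study_params()
  set.seed(21)
  ev <- simulate_from_model(p$g0, p$g1, p$xi0, p$basis, n_beats = 120)
  t <- ev$u[110] + 0.2
  W <- 40
  ll <- local_loglik(ev, p$basis, p$g0, p$g1, p$xi0, t, W = W,
                     censor = FALSE)
  # brute force: log density of every interval fully inside the window,
  # with mu recomputed from each interval's own history
  u <- ev$u
  ks <- which(seq_along(u) >= 12 & u <= t)
  ks <- ks[u[ks - 1] >= t - W]
  brute <- sum(vapply(ks, function(k) {
    l <- laguerre_outputs(ev, p$basis, u[k] - 1e-12)
    ig_pdf(ev$hp[k], 0, mu_hp(p$g0, p$g1, l), p$xi0, log = TRUE)
  }, numeric(1)))
  expect_equal(ll, brute, tolerance = 1e-10)

  # censoring adds exactly the log-survival of the ongoing interval
  ll_c <- local_loglik(ev, p$basis, p$g0, p$g1, p$xi0, t, W = W)
  k_last <- max(ks)
  l_c <- laguerre_outputs(ev, p$basis, t)
  expect_equal(unname(ll_c - ll),
               unname(ig_cdf(t - u[k_last], mu_hp(p$g0, p$g1, l_c), p$xi0,
                             lower.tail = FALSE, log.p = TRUE)),
               tolerance = 1e-10)
})

test_that("a Newton step never decreases the likelihood and fixes stationary points", {
  p <- study_params()
  set.seed(31)
  ev <- simulate_from_model(p$g0, p$g1, p$xi0, p$basis, n_beats = 130)
  t <- ev$u[125] + 0.1
  # iterate single steps from a perturbed start: monotone ascent
  g0 <- p$g0 * 1.1; g1 <- p$g1 * 0.5; xi0 <- p$xi0 * 2
  ll_prev <- local_loglik(ev, p$basis, g0, g1, xi0, t)
  for (i in 1:60) {
    st <- pp_newton_step(ev, p$basis, g0, g1, xi0, t)
    expect_gte(st$loglik, ll_prev - 1e-8)
    ll_prev <- st$loglik
    g0 <- st$g0; g1 <- st$g1; xi0 <- st$xi0
    if (st$converged) break
  }
  expect_true(st$converged)
  # at the stationary point another step changes nothing
  st2 <- pp_newton_step(ev, p$basis, g0, g1, xi0, t)
  expect_true(st2$converged)
  expect_equal(st2$g0, g0, tolerance = 1e-9)
  expect_equal(st2$g1, g1, tolerance = 1e-7)
})

test_that("trajectory grid arithmetic, determinism and failure modes", {
  p <- study_params()
  set.seed(41)
  ev <- simulate_from_model(p$g0, p$g1, p$xi0, p$basis, n_beats = 150)
  fit <- pphrv(ev, step = 0.005, duration = 100)
  expect_equal(length(fit$times), floor((100 - 70) / 0.005) + 1)
  expect_gt(mean(fit$converged), 0.98)
  fit2 <- pphrv(ev, step = 0.005, duration = 100)
  expect_identical(fit$g0, fit2$g0)
  expect_identical(fit$mu_hp, fit2$mu_hp)
  expect_error(pphrv(event_series(seq(0, 50, by = 0.8))), "shorter")
})

test_that("compiled and reference engines agree", {
  p <- study_params()
  set.seed(51)
  ev <- simulate_from_model(p$g0, p$g1, p$xi0, p$basis, n_beats = 130)
  f_cpp <- pphrv(ev, step = 0.2, engine = "cpp")
  f_r <- pphrv(ev, step = 0.2, engine = "r")
  expect_equal(f_cpp$g0, f_r$g0, tolerance = 1e-7)
  expect_equal(f_cpp$mu_hp, f_r$mu_hp, tolerance = 1e-7)
  expect_equal(f_cpp$converged, f_r$converged)
  expect_equal(f_cpp$loglik, f_r$loglik, tolerance = 1e-8)
})

test_that("model methods expose the fit coherently", {
  p <- study_params()
  set.seed(61)
  ev <- simulate_from_model(p$g0, p$g1, p$xi0, p$basis, n_beats = 200)
  fit <- pphrv(ev, step = 0.5)
  cf <- coef(fit)
  expect_named(cf, c("g0", paste0("g1_", 0:9), "xi0"))
  expect_true(all(is.finite(cf)))
  pr <- predict(fit, times = fit$times[c(5, 10)])
  expect_true(all(pr > 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.pphrv")
  expect_equal(s$n_states, length(fit$times))
  sim <- simulate(fit, seed = 1, n_beats = 60)
  expect_s3_class(sim, "event_series")
  expect_equal(length(sim$u), 60)
})
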
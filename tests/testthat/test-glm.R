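toy_reg <- function(n = 300, seed = 1) {
  set.seed(seed)
  convolve_regressor(regressor_series(rnorm(n), tr = 0.72))
}

test_that("first level recovers noiseless effects exactly", {
  reg <- toy_reg()
  dims <- c(4, 4, 2)
  bold <- synth_bold(reg, dims = dims, active_mask = array(TRUE, dims),
                     effect = 3, noise_ar1 = 0, noise_sd = 1e-10)
  fl <- first_level(bold, reg)
  expect_equal(unname(fl$beta), rep(3, 32), tolerance = 1e-6)
  # scaling equivariance
  bold2 <- bold; bold2$data <- bold$data * 2
  expect_equal(first_level(bold2, reg)$beta, fl$beta * 2, tolerance = 1e-6)
  reg_half <- reg; reg_half$values <- reg$values * 0.5
  expect_equal(first_level(bold, reg_half)$beta, fl$beta * 2,
               tolerance = 1e-6)
})

test_that("first level returns zero beta for an orthogonal regressor", {
  reg <- toy_reg(seed = 2)
  dims <- c(3, 3, 1)
  bold <- synth_bold(reg, dims = dims, effect = 0, noise_ar1 = 0)
  # make every voxel exactly orthogonal to the regressor (and drift)
  X <- cbind(1, seq_len(reg$n_vols) / reg$n_vols, reg$values)
  Q <- qr.Q(qr(X))
  bold$data <- bold$data - Q %*% crossprod(Q, bold$data)
  fl <- first_level(bold, reg)
  expect_lt(max(abs(fl$beta)), 1e-10)
})

test_that("first level Z statistics are calibrated under the null", {
  reg <- toy_reg(n = 1200, seed = 3)
  set.seed(33)
  bold <- synth_bold(reg, dims = c(10, 10, 10), effect = 0, noise_ar1 = 0)
  fl <- first_level(bold, reg)
  expect_lt(abs(mean(fl$z)), 0.1)
  expect_gt(var(fl$z), 0.9)
  expect_lt(var(fl$z), 1.1)
})

test_that("rank-deficient designs fail loudly, naming the column", {
  reg <- toy_reg()
  bold <- synth_bold(reg, dims = c(2, 2, 1), effect = 0, noise_ar1 = 0)
  expect_error(first_level(bold, reg, confounds = cbind(dup = reg$values)),
               "collinear")
})

test_that("fixed-effects run combination weights by inverse variance", {
  reg <- toy_reg()
  dims <- c(3, 3, 2)
  mk <- function(seed, scale = 1) {
    set.seed(seed)
    fl <- first_level(synth_bold(reg, dims = dims, effect = 0.5,
                                 active_mask = array(TRUE, dims)), reg)
    fl$var <- fl$var * scale
    fl
  }
  a <- mk(1); b <- mk(2)
  b_eq <- b; b_eq$var <- a$var          # equal variances: simple mean
  comb <- second_level_fixed(a, b_eq)
  expect_equal(comb$beta, (a$beta + b_eq$beta) / 2, tolerance = 1e-12)
  # a run with infinite variance contributes nothing
  b_inf <- b; b_inf$var <- rep(Inf, length(b$var))
  comb2 <- second_level_fixed(a, b_inf)
  expect_equal(comb2$beta, a$beta, tolerance = 1e-12)
  # information adds
  comb3 <- second_level_fixed(a, b)
  expect_true(all(comb3$var <= pmin(a$var, b$var) + 1e-15))
})

test_that("group mixed effects is exchangeable and recovers common effects", {
  reg <- toy_reg()
  dims <- c(3, 3, 1)
  base <- first_level(synth_bold(reg, dims = dims, effect = 0,
                                 noise_ar1 = 0), reg)
  mk_const <- function(b, v) {
    out <- base
    out$beta <- rep(b, length(base$beta))
    out$var <- rep(v, length(base$var))
    out
  }
  subs <- lapply(c(0.7, 0.7, 0.7, 0.7), mk_const, v = 0.01)
  g <- group_mixed_effects(subs)
  expect_equal(unname(g$beta), rep(0.7, 9), tolerance = 1e-12)
  # permuting subjects changes nothing
  subs2 <- lapply(1:5, function(s) mk_const(rnorm(1, 0.5, 0.2), 0.02))
  g1 <- group_mixed_effects(subs2)
  g2 <- group_mixed_effects(subs2[c(3, 1, 5, 2, 4)])
  expect_equal(g1$beta, g2$beta)
  expect_equal(g1$z, g2$z)
  expect_error(group_mixed_effects(subs2[1:2]), "3 subjects")
})

test_that("group estimate covers the true mean across seeded replicates", {
  reg <- toy_reg()
  dims <- c(3, 3, 1)
  base <- first_level(synth_bold(reg, dims = dims, effect = 0,
                                 noise_ar1 = 0), reg)
  covered <- 0
  n_rep <- 40
  set.seed(55)
  for (r in seq_len(n_rep)) {
    subs <- lapply(1:8, function(s) {
      out <- base
      out$beta <- rep(rnorm(1, 0.5, 0.15), length(base$beta))
      out$var <- rep(0.01, length(base$var))
      out
    })
    g <- group_mixed_effects(subs)
    covered <- covered +
      (abs(g$beta[1] - 0.5) <= 2 * sqrt(g$var[1]))
  }
  expect_gte(covered / n_rep, 0.8)
})

test_that("cluster correction finds planted effects and nothing in flat maps", {
  reg <- toy_reg()
  dims <- c(10, 10, 5)
  active <- array(FALSE, dims); active[4:7, 4:7, 2:4] <- TRUE
  set.seed(77)
  subs <- lapply(1:6, function(s) {
    second_level_fixed(
      first_level(synth_bold(reg, dims = dims, active_mask = active,
                             effect = 0.6, noise_ar1 = 0.3), reg),
      first_level(synth_bold(reg, dims = dims, active_mask = active,
                             effect = 0.6, noise_ar1 = 0.3), reg))
  })
  g <- group_mixed_effects(subs)
  ct <- cluster_correct(g, n_perm = 199, seed = 5)
  expect_gte(sum(ct$significant), 1)
  best <- which(ct$significant)[1]
  expect_gte(dice_overlap(attr(ct, "voxels")[[best]], which(active)), 0.5)
  # flat map: empty table, not an error
  g0 <- g; g0$z[] <- 0
  ct0 <- cluster_correct(g0, n_perm = 100, seed = 5)
  expect_equal(nrow(ct0), 0)
})

test_that("cluster labelling reports overlap fractions", {
  dims <- c(6, 6, 2)
  labels <- array(0L, dims)
  labels[1:3, , ] <- 7L
  labels[4:6, , ] <- 2L
  # doctored cluster table: one cluster inside label 7, one straddling
  inside <- which(array(seq_len(prod(dims)), dims) > 0 &
                    slice.index(array(0, dims), 1) <= 2)
  straddle <- which(slice.index(array(0, dims), 1) %in% 3:4)
  ct <- structure(
    data.frame(id = 1:2, size = c(length(inside), length(straddle)),
               peak_z = c(5, 4), p_corrected = c(0.01, 0.02),
               significant = c(TRUE, TRUE)),
    voxels = list(inside, straddle), threshold = 2.3, alpha = 0.05,
    class = c("cluster_table", "data.frame"))
  lab <- label_clusters(ct, labels, names = c("A", "B", NA, NA, NA, NA, "G"))
  l1 <- lab[lab$cluster == 1, ]
  expect_equal(l1$name, "G")
  expect_equal(l1$fraction, 1)
  l2 <- lab[lab$cluster == 2, ]
  expect_equal(sort(l2$fraction), c(0.5, 0.5))
  # empty table gives empty output
  ct_empty <- structure(ct[0, ], voxels = list(),
                        class = c("cluster_table", "data.frame"))
  expect_equal(nrow(label_clusters(ct_empty, labels)), 0)
})
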
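test_that("three-indicator ML fit is exact for compound-symmetric input", {
  S <- matrix(1, 3, 3); diag(S) <- 1.8
  f <- fit_single_factor_ml(S, n = 1000)
  expect_equal(f$status, "converged")
  expect_equal(f$lambda, rep(1, 3), tolerance = 1e-12)
  expect_equal(f$psi, 1, tolerance = 1e-12)
  expect_equal(f$theta, rep(0.8, 3), tolerance = 1e-12)
  # just-identified: fitted covariance reproduces S, so the ML discrepancy is
  # minimal; in particular not larger than at any perturbed parameter value
  F_hat <- samcroon:::ml_discrepancy(S, f$lambda, f$psi, f$theta)
  F_pert <- samcroon:::ml_discrepancy(S, f$lambda * 1.05, f$psi, f$theta)
  expect_lt(F_hat, F_pert)
})

test_that("degenerate and non-PD inputs are flagged, not mis-fit", {
  expect_equal(fit_single_factor_ml(diag(3), n = 100)$status, "boundary")
  S <- matrix(c(1, .9, .9, .9, 1, .9, .9, .9, -0.5), 3, 3)
  S <- (S + t(S)) / 2
  expect_equal(fit_single_factor_ml(S, n = 100)$status, "non_PD")
  # sign-inconsistent covariances (PD matrix) admit no real factor solution
  S2 <- matrix(c(1.8, .3, -.3, .3, 1.8, .3, -.3, .3, 1.8), 3, 3)
  expect_gt(min(eigen(S2, only.values = TRUE)$values), 0)
  expect_equal(fit_single_factor_ml(S2, n = 100)$status, "boundary")
  expect_error(fit_single_factor_ml(matrix(1, 3, 3) + diag(3), n = 3))
})

test_that("negative uniquenesses are reported as Heywood but still score", {
  S <- matrix(1, 3, 3); diag(S) <- c(0.9, 1.8, 1.8)  # theta1 < 0
  f <- fit_single_factor_ml(S, n = 50)
  expect_equal(f$status, "heywood")
  expect_lt(f$theta[1], 0)
  expect_silent(regression_score_matrix(f))
})

test_that("optimizer route (4 indicators) recovers generating values", {
  lam <- c(1, 0.8, 1.2, 1)
  theta <- c(0.5, 0.6, 0.7, 0.5)
  S <- tcrossprod(lam) + diag(theta)
  f <- fit_single_factor_ml(S, n = 10000)
  expect_equal(f$status, "converged")
  expect_equal(f$lambda * sqrt(f$psi), lam, tolerance = 1e-3)
  expect_equal(f$theta, theta, tolerance = 1e-3)
})

test_that("regression score weights and validity match the closed form", {
  f8 <- pop_fit(1, 0.8)
  sm <- regression_score_matrix(f8)
  expect_equal(sm$A, rep(1 / 3.8, 3), tolerance = 1e-12)
  expect_equal(sm$validity, 3 / 3.8, tolerance = 1e-12)
  f2 <- pop_fit(1, 0.2)
  sm2 <- regression_score_matrix(f2)
  expect_equal(sm2$A, rep(1 / 3.2, 3), tolerance = 1e-12)
  expect_equal(sm2$validity, 3 / 3.2, tolerance = 1e-12)
  # error-free measurement: validity -> 1
  f0 <- pop_fit(1, 1e-10)
  expect_equal(regression_score_matrix(f0)$validity, 1, tolerance = 1e-6)
  f8$status <- "boundary"
  expect_error(regression_score_matrix(f8))
})

test_that("factor scores are centered, linear, and propagate missingness", {
  sm <- regression_score_matrix(pop_fit(1, 0.8))
  mu <- c(2, 2, 2)
  expect_equal(compute_scores(sm, matrix(2, 1, 3), mu), 0)
  expect_equal(compute_scores(sm, matrix(3, 1, 3), mu), 3 / 3.8,
               tolerance = 1e-12)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(compute_scores(sm, 2 * X, c(0, 0, 0)),
               2 * compute_scores(sm, X, c(0, 0, 0)), tolerance = 1e-12)
  X[3, 2] <- NA
  s <- compute_scores(sm, X, c(0, 0, 0))
  expect_true(is.na(s[3]) && !anyNA(s[-3]))
})

test_that("cluster decomposition is an exact additive decomposition", {
  d <- generate_mlsem(default_params, "within", n2 = 30, n1 = 50, seed = 2)
  dec <- cluster_decompose(d$data, c("x1", "x2", "x3"))
  expect_equal(nrow(dec$between), 30)
  expect_equal(unname(colSums(abs(rowsum(dec$within, d$data$cluster_id)))),
               rep(0, 3), tolerance = 1e-9)
  rebuilt <- as.matrix(dec$between[dec$cluster_id, c("x1", "x2", "x3")]) +
    dec$within
  expect_equal(unname(rebuilt), unname(as.matrix(d$data[, c("x1", "x2", "x3")])),
               tolerance = 1e-12)
  expect_error(cluster_decompose(d$data[0, ]))
})

test_that("cluster-mean reliability follows the stated formula", {
  expect_equal(rb_reliability(1, 1, 0.2, 1, 1, 0.8, 50), 1.2 / 1.236,
               tolerance = 1e-12)
  expect_equal(rb_reliability(1, 1, 0.2, 1, 1, 0.8, 20), 1.2 / 1.29,
               tolerance = 1e-12)
  expect_equal(rb_reliability(1, 1, 0.2, 1, 1, 0.8, 1e9), 1, tolerance = 1e-8)
  # from a fitted two-level model, the between part fitted on raw cluster
  # means is decontaminated before entering the formula
  d <- generate_mlsem(default_params, "within", n2 = 800, n1 = 50, seed = 21)
  fit <- fit_two_level_measurement(d$data, "x")
  expect_equal(unname(cluster_mean_reliability(fit, 50)), rep(1.2 / 1.236, 3),
               tolerance = 0.01)
  expect_equal(unname(cluster_mean_reliability(fit, 20)), rep(1.2 / 1.29, 3),
               tolerance = 0.01)
})

test_that("two-level measurement recovers the generating values", {
  d <- generate_mlsem(default_params, "within", n2 = 1000, n1 = 50, seed = 4)
  for (v in c("x", "z")) {
    fit <- fit_two_level_measurement(d$data, v)
    expect_equal(fit$status, "converged")
    expect_equal(fit$within$lambda, rep(1, 3), tolerance = 0.02)
    expect_equal(fit$within$psi, 1, tolerance = 0.03)
    expect_equal(fit$within$theta, rep(0.8, 3), tolerance = 0.03)
    # between fit on raw cluster means absorbs psi_W / n1
    expect_equal(fit$between$psi, 1 + 1 / 50, tolerance = 0.1)
    expect_equal(fit$between$theta, rep(0.2 + 0.8 / 50, 3), tolerance = 0.05)
    expect_equal(unname(fit$rb), rep(1.2 / 1.236, 3), tolerance = 0.01)
  }
  expect_error(fit_two_level_measurement(d$data[d$data$unit_id == 1, ], "x"))
})

test_that("collinear cluster means are flagged as non-PD at the between level", {
  d <- generate_mlsem(default_params, "within", n2 = 20, n1 = 10, seed = 6)
  dd <- d$data
  # make cluster means of x2 an exact copy of x1's: x2 = x1 + within noise
  # that cancels per cluster, so the between covariance is singular
  noise <- stats::ave(rnorm(nrow(dd)), dd$cluster_id,
                      FUN = function(u) u - mean(u))
  dd$x2 <- dd$x1 + noise
  fit <- fit_two_level_measurement(dd, "x")
  expect_equal(fit$between$status, "non_PD")
  expect_true(fit$status %in% c("boundary", "non_PD"))
})
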
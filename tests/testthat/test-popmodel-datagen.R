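test_that("generation is reproducible and has the stated shape", {
  d1 <- generate_mlsem(default_params, "within", n2 = 30, n1 = 50, seed = 5)
  d2 <- generate_mlsem(default_params, "within", n2 = 30, n1 = 50, seed = 5)
  expect_identical(d1, d2)
  expect_equal(nrow(d1$data), 1500)
  expect_equal(sum(grepl("^[xzy][0-9]$", names(d1$data))), 9)
  expect_equal(nrow(d1$latent), nrow(d1$data))
  expect_error(generate_mlsem(default_params, "within", n2 = 1, n1 = 50))
  expect_error(generate_mlsem(default_params, "sideways", 30, 50))
})

test_that("partially nested generation matches the 2/1 design contract", {
  d <- generate_pn(default_params, n2_t = 30, n1_t = 20, seed = 9)
  dt <- d$data[d$data$arm == "treatment", ]
  dc <- d$data[d$data$arm == "control", ]
  expect_equal(nrow(dt), 600)
  expect_equal(nrow(dc), 600)
  # control rows are singleton clusters with moderator absent (never zeros)
  expect_equal(max(table(dc$cluster_id)), 1L)
  expect_true(all(is.na(dc[, c("z1", "z2", "z3")])))
  expect_false(anyNA(dt[, c("z1", "z2", "z3")]))
  d2 <- generate_pn(default_params, n2_t = 30, n1_t = 20, seed = 9)
  expect_identical(d, d2)
})

test_that("sidecar latents follow the stated population model (large sample)", {
  d <- generate_mlsem(default_params, "within", n2 = 2000, n1 = 20, seed = 31)
  L <- d$latent
  cl1 <- !duplicated(L$cluster_id)
  # between-level predictor variance ~ psi_between (MC tolerance, n2 = 2000)
  expect_equal(stats::var(L$eta_x_b[cl1]), 1, tolerance = 0.1)
  expect_equal(stats::cor(L$eta_x_b[cl1], L$eta_z_b[cl1]), 0.25,
               tolerance = 0.08)
  # sidecar OLS recovers the generating structural coefficients (true model)
  tf <- true_empirical_fit(d)
  expect_equal(unname(tf$within), c(0.4, 0.4, 0.2), tolerance = 0.02)
  expect_equal(unname(tf$between), c(0.4, 0.4), tolerance = 0.05)
  # indicator covariance converges to Lambda psi Lambda' + Theta per level
  dec <- cluster_decompose(d$data, c("x1", "x2", "x3"))
  SW <- crossprod(dec$within) / (nrow(d$data) - 2000)
  expect_equal(unname(SW[1, 2]), 1, tolerance = 0.03)
  expect_equal(unname(diag(SW)), rep(1.8, 3), tolerance = 0.05)
})

test_that("treatment-control mediator mean contrast matches a_t", {
  d <- generate_pn(default_params, n2_t = 1500, n1_t = 10, seed = 13)
  L <- d$latent
  m_t <- mean(L$eta_m_b[L$arm == "treatment"] + L$eta_m_w[L$arm == "treatment"])
  m_c <- mean(L$eta_m_b[L$arm == "control"])
  expect_equal(m_t - m_c, 0.5, tolerance = 0.05)
})

test_that("analytic population moments match brute-force Monte Carlo", {
  mom <- population_moments(default_params, "within")
  expect_equal(mom$within$cov["x:z", "x:z"], 1.0625, tolerance = 1e-12)
  expect_equal(mom$within$cov["x:z", "x"], 0)
  expect_equal(mom$within$cov["x:z", "y"], 0.2 * 1.0625, tolerance = 1e-12)
  set.seed(77)
  X <- mc_latent_moments_within(default_params, 1e6)
  S <- stats::cov(X)
  # every entry within 4 MC standard errors (~4 * sqrt(2) * var / sqrt(n))
  for (g in colnames(S)) for (h in colnames(S)) {
    se <- sqrt((S[g, g] * S[h, h] + S[g, h]^2) / 1e6)
    expect_lt(abs(S[g, h] - mom$within$cov[g, h]), 4 * max(se, 1e-4))
  }
  # symmetry and PSD of every analytic matrix, all designs
  for (des in c("within", "cross", "between")) {
    mm <- population_moments(default_params, des)
    for (M in Filter(Negate(is.null), mm)) {
      expect_equal(M$cov, t(M$cov))
      expect_gte(min(eigen(M$cov, only.values = TRUE)$values), -1e-12)
    }
  }
})
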
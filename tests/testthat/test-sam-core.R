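test_that("variance-of-product rule matches substitution and Monte Carlo", {
  expect_equal(product_variance(1, 1, 0.25), 1.0625, tolerance = 1e-12)
  expect_equal(product_variance(1, 1, 0), 1)
  expect_error(product_variance(1, 1, 1.2))
  expect_error(product_variance(-1, 1, 0))
  set.seed(99)
  n <- 1e6
  a <- rnorm(n)
  b <- 0.25 * a + sqrt(1 - 0.25^2) * rnorm(n)
  v <- stats::var(a * b)
  se <- stats::sd((a * b - mean(a * b))^2) / sqrt(n)
  expect_lt(abs(v - 1.0625), 4 * se)
})

test_that("score moment assembly: plain covariance, centered products", {
  set.seed(1)
  S <- data.frame(x = rnorm(50), z = rnorm(50), y = rnorm(50))
  mm0 <- assemble_score_moments(S, level = "within")
  expect_equal(mm0$cov, stats::cov(as.matrix(S)))
  mm <- assemble_score_moments(S, products = list(c("x", "z")),
                               level = "within")
  expect_true("x:z" %in% colnames(mm$cov))
  expect_equal(unname(mm$means["x:z"]), 0)
  # squared-variable moment check on simulated normal scores
  set.seed(2)
  a <- rnorm(2e5)
  mm2 <- assemble_score_moments(data.frame(x = a),
                                products = list(c("x", "x")),
                                level = "within")
  expect_equal(mm2$cov["x:x", "x:x"], 2 * stats::var(a)^2, tolerance = 0.05)
  expect_error(assemble_score_moments(S, products = list(c("x", "w"))))
})

test_that("score covariances attenuate by the validity product", {
  # population-level score moments reproduce c_g c_h cov(eta_g, eta_h)
  pm <- population_score_moments(default_params, "within")
  c_w <- 3 / 3.8
  expect_equal(pm$within$cov["x", "z"], 0.25 * c_w^2, tolerance = 1e-12)
  expect_equal(pm$within$cov["x", "x"], c_w, tolerance = 1e-12)
  # simulation cross-check of the attenuation identity
  d <- generate_mlsem(default_params, "within", n2 = 1000, n1 = 50, seed = 8)
  f <- mlsam(d, estimator = "fs")
  expect_lt(abs(f$moments$within$cov["x", "z"] - 0.25 * c_w^2), 0.015)
})

test_that("Croon correction is the exact inverse of attenuation", {
  for (seed in 1:8) {
    M <- random_latent_moments(seed)
    set.seed(seed + 100)
    fits <- list(x = pop_fit(1, runif(1, 0.2, 1.5)),
                 z = pop_fit(1, runif(1, 0.2, 1.5)),
                 y = pop_fit(M$cov["y", "y"], runif(1, 0.2, 1.5)))
    att <- attenuate_moments(M, fits)
    rec <- croon_correct(att, fits)
    expect_equal(rec$status, "converged")
    expect_equal(rec$cov, M$cov, tolerance = 1e-10)
  }
})

test_that("perfect measurement leaves the moment matrix unchanged", {
  M <- random_latent_moments(3)
  fits <- list(x = pop_fit(1, 1e-12), z = pop_fit(1, 1e-12),
               y = pop_fit(M$cov["y", "y"], 1e-12))
  att <- attenuate_moments(M, fits)
  expect_equal(att$cov, M$cov, tolerance = 1e-8)
  rec <- croon_correct(att, fits)
  expect_equal(rec$cov, M$cov, tolerance = 1e-8)
})

test_that("denominator blow-up guard flags near-zero validities", {
  M <- random_latent_moments(4)
  fits <- list(x = pop_fit(1e-9, 1e3), z = pop_fit(1, 0.8),
               y = pop_fit(M$cov["y", "y"], 0.8))
  att <- attenuate_moments(M, fits)
  rec <- croon_correct(att, fits)
  expect_equal(rec$status, "non_convergence")
  expect_equal(estimate_paths(rec, "y", c("x", "z"))$status,
               "non_convergence")
})

test_that("normal-equations estimation matches the regression identities", {
  vars <- c("x", "y")
  M <- matrix(c(2, 0.6, 0.6, 1.5), 2, 2, dimnames = list(vars, vars))
  mm <- moment_matrix(M, c(x = 0.5, y = 1), "single")
  sf <- estimate_paths(mm, "y", "x")
  expect_equal(unname(sf$coefficients), 0.6 / 2, tolerance = 1e-12)
  expect_equal(sf$intercept, 1 - 0.3 * 0.5, tolerance = 1e-12)
  expect_equal(sf$residual_variance, 1.5 - 0.6^2 / 2, tolerance = 1e-12)
  # uncorrelated outcome: zero coefficients, residual = outcome variance
  M0 <- diag(c(1, 1, 2)); dimnames(M0) <- list(c("x", "z", "y"), c("x", "z", "y"))
  sf0 <- estimate_paths(moment_matrix(M0, c(x = 0, z = 0, y = 0), "single"),
                        "y", c("x", "z"))
  expect_equal(unname(sf0$coefficients), c(0, 0))
  expect_equal(sf0$residual_variance, 2)
  # singular predictor block
  Ms <- matrix(1, 3, 3); diag(Ms)[3] <- 2
  dimnames(Ms) <- dimnames(M0)
  expect_equal(estimate_paths(moment_matrix(Ms, c(x = 0, z = 0, y = 0), "single"),
                              "y", c("x", "z"))$status, "non_convergence")
})

test_that("end-to-end estimation is deterministic and design-consistent", {
  d <- generate_mlsem(default_params, "within", n2 = 60, n1 = 20, seed = 17)
  f1 <- mlsam(d, estimator = "croon")
  f2 <- mlsam(d, estimator = "croon")
  expect_identical(coef(f1), coef(f2))
  expect_null(mlsam(generate_mlsem(default_params, "between", 30, 20, seed = 1),
                    estimator = "fs")$within)
  expect_error(mlsam(d$data, estimator = "fs"))   # design required
})

test_that("Croon removes the attenuation SAM-FS leaves (large sample)", {
  d <- generate_mlsem(default_params, "within", n2 = 1000, n1 = 50, seed = 42)
  fc <- mlsam(d, estimator = "croon")
  ff <- mlsam(d, estimator = "fs")
  expect_equal(unname(fc$within$coefficients), c(0.4, 0.4, 0.2),
               tolerance = 0.03)
  expect_equal(unname(fc$between$coefficients), c(0.4, 0.4), tolerance = 0.06)
  expect_lt(ff$within$coefficients[["x:z"]], 0.18)
  expect_lt(ff$within$coefficients[["x"]], 0.37)
})

test_that("corrected interaction estimates dominate uncorrected on average", {
  # attenuation-removal ordering, checked across replications (scaled run)
  R <- 60
  b3 <- matrix(NA_real_, R, 2)
  for (r in 1:R) {
    d <- generate_mlsem(default_params, "within", n2 = 90, n1 = 50,
                        seed = 4000 + r)
    fc <- mlsam(d, estimator = "croon")
    ff <- mlsam(d, estimator = "fs")
    if (fc$status == "converged" && ff$status == "converged")
      b3[r, ] <- c(fc$within$coefficients[["x:z"]],
                   ff$within$coefficients[["x:z"]])
  }
  expect_gt(mean(abs(b3[, 1]), na.rm = TRUE), mean(abs(b3[, 2]), na.rm = TRUE))
})
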
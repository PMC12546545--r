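test_that("true-model benchmark is deterministic and unbiased", {
  d <- generate_mlsem(default_params, "within", n2 = 60, n1 = 20, seed = 71)
  expect_identical(true_empirical_fit(d), true_empirical_fit(d))
  # unbiasedness of OLS on exact latents across replications (scaled run)
  est <- t(vapply(1:80, function(r) {
    true_empirical_fit(generate_mlsem(default_params, "within", 60, 20,
                                      seed = 6000 + r))$within
  }, numeric(3)))
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - c(0.4, 0.4, 0.2)) < 3 * se + 1e-8))
  expect_error(true_empirical_fit(list(a = 1)))
})

test_that("condition runs are reproducible and internally consistent", {
  r1 <- run_condition(default_params, "within", n2 = 20, n1 = 10, R = 6,
                      seed = 5, keep_estimates = TRUE)
  r2 <- run_condition(default_params, "within", n2 = 20, n1 = 10, R = 6,
                      seed = 5, keep_estimates = TRUE)
  keep <- setdiff(names(r1$per_coef), "mean_time")  # timing is not data
  expect_identical(r1$per_coef[, keep], r2$per_coef[, keep])
  # RMSE cell equals sqrt(bias^2 + SD^2) recomputed from raw estimates
  E <- r1$estimates[["croon within"]]
  bias <- colMeans(E, na.rm = TRUE) - c(0.4, 0.4, 0.2)
  sds <- apply(E, 2, sd, na.rm = TRUE)
  pc <- subset(r1$per_coef, estimator == "croon" & level == "within")
  expect_equal(pc$rmse, unname(sqrt(bias^2 + sds^2)), tolerance = 1e-12)
  # any single replication is re-runnable in isolation from the seed scheme
  d3 <- generate_mlsem(default_params, "within", 20, 10,
                       seed = samcroon:::rep_seed(5, 3))
  f3 <- mlsam(d3, estimator = "croon")
  expect_equal(unname(E[3, ]), unname(f3$within$coefficients),
               tolerance = 1e-12)
})

test_that("study driver renders and persists the result tables", {
  out <- withr::local_tempdir()
  cfg <- list(designs = c("within", "pn"),
              grid = data.frame(n2 = 10, n1 = 5),
              R = 3, seed = 2, estimators = c("fs", "croon"),
              out_dir = out)
  tabs <- run_study(cfg)
  expect_true(all(c("convergence_failure", "interaction_bias", "average_bias",
                    "rmse", "pn_convergence_failure", "pn_effect_bias",
                    "pn_rmse") %in% names(tabs)))
  expect_true(file.exists(file.path(out, "interaction_bias.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)
  expect_true(all(file.exists(file.path(out, man$files))))
  # empty grid: empty tables, no error
  tabs0 <- run_study(list(designs = "within",
                          grid = data.frame(n2 = integer(), n1 = integer()),
                          R = 2, seed = 1))
  expect_null(tabs0$per_coef)
})

test_that("failure rates use all replications, metrics only converged ones", {
  res <- run_condition(default_params, "between", n2 = 30, n1 = 20, R = 40,
                       seed = 33, keep_estimates = TRUE)
  pc <- subset(res$per_coef, estimator == "croon")
  E <- res$estimates[["croon between"]]
  expect_equal(unique(pc$failure_rate), sum(is.na(E[, 1])) / 40)
  expect_equal(pc$n_converged[1], sum(!is.na(E[, 1])))
  expect_equal(pc$mean_est[1], mean(E[, 1], na.rm = TRUE), tolerance = 1e-12)
})

test_that("cluster bootstrap yields percentile intervals and degenerate width", {
  d <- generate_mlsem(default_params, "within", n2 = 30, n1 = 15, seed = 12)
  bs <- bootstrap_ci(d, estimator = "fs", B = 40, seed = 1)
  expect_equal(colnames(bs$ci), c("2.5%", "97.5%"))
  expect_true(all(bs$ci[, 1] <= bs$ci[, 2]))
  expect_gte(bs$prop_nonconverged, 0)
  # resampling is reproducible from the seed
  bs2 <- bootstrap_ci(d, estimator = "fs", B = 40, seed = 1)
  expect_identical(bs$ci, bs2$ci)
  # a dataset whose clusters are all copies of one pattern has zero between
  # variance: every replicate's between measurement model is degenerate and
  # the interval is reported as unavailable
  one <- d$data[d$data$cluster_id == 1, ]
  rep_dat <- do.call(rbind, lapply(1:12, function(j) {
    o <- one; o$cluster_id <- j; o
  }))
  dd <- structure(list(data = rep_dat, latent = NULL, design = "within",
                       n2 = 12, n1 = 15, params = default_params),
                  class = "mlsem_data")
  expect_error(bootstrap_ci(dd, estimator = "fs", B = 12, seed = 2),
               "failed to converge")
})
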
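pn_large <- generate_pn(default_params, n2_t = 1500, n1_t = 30, seed = 555)

test_that("arm-specific measurement respects the 2/1 structure", {
  meas <- fit_pn_measurement(pn_large)
  # moderator model is fitted to exactly n2_t cluster records
  expect_equal(meas$treatment$z$n, 1500)
  # control latent means are fixed at zero by construction
  expect_equal(meas$a_c, 0)
  # treatment mediator latent mean ~ a_t = 0.5
  expect_equal(meas$a_hat, 0.5, tolerance = 0.05)
  # outcome contrast ~ mu0_t + B_t * a_t = 0.9
  expect_equal(meas$y_contrast, 0.9, tolerance = 0.06)
  expect_error(fit_pn_measurement(
    pn_large$data[pn_large$data$arm == "treatment", ]))
})

test_that("large-sample Croon estimates recover the generating PN model", {
  fit <- pnsam(pn_large, estimator = "croon")
  expect_equal(fit$status, "converged")
  # ~3 MC SEs at n2_t = 1500 (slope SEs scaled from the measured SDs at
  # n2_t = 100; the b path and moderation slope carry the small
  # between-level mediator variance in their denominator, hence the wider
  # bands)
  expect_lt(abs(fit$effects$b_path - 0.4), 0.15)
  expect_lt(abs(fit$effects$b1_c - 0.4), 0.02)
  expect_lt(abs(fit$effects$b1_t - 0), 0.02)
  expect_lt(abs(fit$effects$moderation - 0.15), 0.15)
  expect_lt(abs(fit$effects$main - 0.7), 0.09)
  expect_lt(abs(fit$effects$mediation - 0.2), 0.07)
  # mediation factorizes exactly
  expect_equal(fit$effects$mediation,
               fit$effects$a_path * fit$effects$b_path, tolerance = 1e-12)
})

test_that("FS and Croon share the pipeline up to the correction step", {
  d <- generate_pn(default_params, n2_t = 40, n1_t = 20, seed = 77)
  ff <- pnsam(d, estimator = "fs")
  fc <- pnsam(d, estimator = "croon")
  # identical measurement stage (same latent mean contrasts)
  expect_identical(ff$measurement$a_hat, fc$measurement$a_hat)
  expect_identical(ff$measurement$y_contrast, fc$measurement$y_contrast)
  # FS attenuates the control slope; Croon corrects it
  expect_lt(ff$effects$b1_c, fc$effects$b1_c)
})

test_that("dropping the uncorrelated moderator leaves the b path consistent", {
  fit <- pnsam(pn_large, estimator = "croon")
  mm <- fit$moments$moments_treatment$between
  b_only <- estimate_paths(mm, "y", "m")
  expect_lt(abs(unname(b_only$coefficients["m"]) -
                  unname(fit$between$coefficients["m"])), 0.08)
})

test_that("non-converged ingredients yield unavailable effects", {
  d <- generate_pn(default_params, n2_t = 12, n1_t = 3, seed = 3)
  # force a measurement failure by wrecking the moderator indicators
  dd <- d$data
  dd[dd$arm == "treatment", c("z1", "z2", "z3")] <-
    matrix(rnorm(sum(dd$arm == "treatment") * 3), ncol = 3)
  dd$z2[dd$arm == "treatment"] <- -dd$z1[dd$arm == "treatment"] +
    0.01 * rnorm(sum(dd$arm == "treatment"))
  f <- tryCatch(pnsam(structure(list(data = dd, n2_t = 12, n1_t = 3,
                                     params = default_params),
                                class = "pn_data"), "croon"),
                error = function(e) NULL)
  if (!is.null(f) && f$status_treatment != "converged") {
    expect_true(is.na(f$effects$moderation))
  } else {
    succeed("degenerate moderator still produced an admissible fit")
  }
})
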
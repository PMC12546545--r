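# Shared fixtures and independent oracles for the test suite.

default_params <- sam_params()

# brute-force Monte Carlo latent moments for the within design: draws the
# latent variables directly from their stated distributions (independent of
# the package's moment algebra)
mc_latent_moments_within <- function(params, n) {
  rho <- params$latent_corr_within
  x <- stats::rnorm(n)
  z <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  y <- params$beta[2] * x + params$beta[3] * z + params$beta[4] * x * z +
    stats::rnorm(n, sd = sqrt(params$sigma2_y))
  cbind(x = x, z = z, "x:z" = x * z, y = y)
}

# explicit attenuation of a latent moment matrix by factor-score validities:
# the independent inverse of the Croon correction (variances become
# c * psi + a_theta on the score scale; covariances are multiplied by the
# validity product; product rows by the three validities)
attenuate_moments <- function(M, fits) {
  sm <- lapply(fits, regression_score_matrix)
  vars <- colnames(M$cov)
  pnames <- names(M$products)
  np <- setdiff(vars, pnames)
  S <- M$cov
  for (g in np) for (h in np) {
    S[g, h] <- if (g == h)
      sm[[g]]$validity^2 * fits[[g]]$psi + sm[[g]]$a_theta
    else sm[[g]]$validity * sm[[h]]$validity * M$cov[g, h]
  }
  for (p in pnames) {
    a <- M$products[[p]][1]; b <- M$products[[p]][2]
    S[p, p] <- S[a, a] * S[b, b] + S[a, b]^2
    for (g in np)
      S[p, g] <- S[g, p] <- sm[[a]]$validity * sm[[b]]$validity *
        sm[[g]]$validity * M$cov[p, g]
  }
  moment_matrix(S, M$means, M$level, corrected = FALSE, products = M$products)
}

# random admissible latent moment matrix over (x, z, y) with a product term,
# built from a random correlation structure (used by the inverse-property test)
random_latent_moments <- function(seed) {
  set.seed(seed)
  repeat {
    r_xz <- stats::runif(1, -0.6, 0.6)
    b <- stats::runif(3, -0.5, 0.5)
    vprod <- 1 + r_xz^2
    vars <- c("x", "z", "x:z", "y")
    M <- matrix(0, 4, 4, dimnames = list(vars, vars))
    M["x", "x"] <- M["z", "z"] <- 1
    M["x", "z"] <- M["z", "x"] <- r_xz
    M["x:z", "x:z"] <- vprod
    M["x", "y"] <- M["y", "x"] <- b[1] + b[2] * r_xz
    M["z", "y"] <- M["y", "z"] <- b[2] + b[1] * r_xz
    M["x:z", "y"] <- M["y", "x:z"] <- b[3] * vprod
    M["y", "y"] <- b[1] * M["x", "y"] + b[2] * M["z", "y"] +
      b[3] * M["x:z", "y"] + 0.5
    ev <- eigen(M[c("x", "z", "y"), c("x", "z", "y")], only.values = TRUE)$values
    if (min(ev) > 0.05) {
      return(moment_matrix(M, stats::setNames(rep(0, 4), vars), "within",
                           products = list("x:z" = c("x", "z"))))
    }
  }
}

pop_fit <- function(psi, theta, params = default_params) {
  samcroon:::new_factor_fit(lambda = rep(1, params$n_ind), psi = psi,
                            theta = rep(theta, params$n_ind),
                            mu = rep(0, params$n_ind), n = Inf,
                            status = "converged")
}
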
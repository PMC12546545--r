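# population-level factor fits and score moments: the idealized (no sampling,
# no cluster-mean contamination) moments of regression factor scores implied
# by the generating parameters; used by the population-consistency oracle
pop_factor_fit <- function(psi, theta, params) {
  new_factor_fit(lambda = params$loadings / params$loadings[1],
                 psi = psi * params$loadings[1]^2,
                 theta = theta, mu = params$intercepts, n = Inf,
                 status = "converged")
}

#' Analytic population moments of regression factor scores
#'
#' Converts the exact latent moments of [population_moments()] into the
#' moments of regression factor scores under the population measurement
#' model: latent covariances are attenuated by the validity product, score
#' variances equal validity times factor variance, and product terms follow
#' the normality of the first-order scores.  Cluster means are treated as
#' noiseless carriers of the between components (no finite-n1 contamination),
#' which is the idealization the population-consistency oracle tests.
#'
#' @param params a [sam_params()] object.
#' @param design `"within"`, `"cross"` or `"between"`.
#' @return A list with `within`/`between` `moment_matrix` objects (score
#'   scale) and `fits_within`/`fits_between` lists of population
#'   `factor_fit`s suitable for [croon_correct()].
#' @export
population_score_moments <- function(params = sam_params(),
                                     design = c("within", "cross", "between")) {
  design <- match.arg(design)
  lat <- population_moments(params, design)

  score_level <- function(L, fits, cross_parent = NULL) {
    if (is.null(L)) return(NULL)
    vars <- colnames(L$cov)
    pnames <- names(L$products)
    np <- setdiff(vars, pnames)
    infos <- lapply(fits, function(f) regression_score_matrix(f))
    S <- L$cov
    for (g in np) for (h in np) {
      S[g, h] <- if (g == h) infos[[g]]$validity * fits[[g]]$psi
      else infos[[g]]$validity * infos[[h]]$validity * L$cov[g, h]
    }
    for (p in pnames) {
      pa <- L$products[[p]]
      a <- pa[1]; b <- pa[2]
      if (!is.null(cross_parent) && b == cross_parent$latent) {
        vb <- cross_parent$score_var
        cb <- cross_parent$validity
        sab <- 0
      } else {
        vb <- S[b, b]; cb <- infos[[b]]$validity; sab <- S[a, b]
      }
      S[p, p] <- S[a, a] * vb + sab^2
      for (g in np)
        S[p, g] <- S[g, p] <-
          infos[[a]]$validity * cb * infos[[g]]$validity * L$cov[p, g]
    }
    moment_matrix(S, stats::setNames(rep(0, length(vars)), vars), L$level,
                  corrected = FALSE, products = L$products)
  }

  vw_y <- if (!is.null(lat$within)) lat$within$cov["y", "y"] else NA_real_
  vb_y <- lat$between$cov["y", "y"]

  if (design %in% c("within", "cross")) {
    fits_w <- list(
      x = pop_factor_fit(params$psi_within, params$theta_within, params),
      z = pop_factor_fit(params$psi_within, params$theta_within, params),
      y = pop_factor_fit(vw_y, params$theta_within, params))
    fits_b <- list(
      x = pop_factor_fit(params$psi_between, params$theta_between, params),
      z = pop_factor_fit(params$psi_between, params$theta_between, params),
      y = pop_factor_fit(vb_y, params$theta_between, params))
    cross_parent <- NULL
    if (design == "cross") {
      zb <- regression_score_matrix(fits_b$z)
      cross_parent <- list(latent = "z.between", validity = zb$validity,
                           score_var = zb$validity * fits_b$z$psi)
      lat$within$products[["x:z"]] <- c("x", "z.between")
      fits_w$z.between <- fits_b$z
    }
    within <- score_level(lat$within, fits_w, cross_parent)
    between <- score_level(lat$between, fits_b)
    list(within = within, between = between,
         fits_within = fits_w, fits_between = fits_b)
  } else {
    fits_b <- list(
      x = pop_factor_fit(params$psi_between, params$theta_between, params),
      z = pop_factor_fit(params$psi_between, params$theta_between, params),
      y = pop_factor_fit(vb_y, params$theta_between, params))
    list(within = NULL, between = score_level(lat$between, fits_b),
         fits_within = NULL, fits_between = fits_b)
  }
}
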
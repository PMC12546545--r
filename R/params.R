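#' Population parameters for the supported simulation designs
#'
#' Collects every generating quantity of the two simulation studies: the
#' measurement model (loadings, indicator intercepts, level-specific indicator
#' residual variances), the latent covariance structure (unit factor variances
#' per level for the exogenous predictors, latent correlation between the
#' focal predictor and moderator), the structural path coefficients at each
#' level, conditional outcome residual variances, and the arm-specific
#' quantities of the 2/1 partially nested moderated-mediation design.
#'
#' Defaults reproduce the fully crossed simulation conditions: three unit
#' loadings per factor, zero indicator intercepts, within/between indicator
#' residual variances 0.8/0.2, latent predictor correlation 0.25 at each
#' level, slopes 0.4 for first-order paths and 0.2 for the interaction,
#' conditional outcome residuals 0.8 (within) and 0.2 (between).  For the
#' partially nested design the mediator's latent variance decomposes 0.8/0.2
#' across levels in the treatment arm and is 1.0 in the (single-level)
#' control arm, with `a_t = 0.5`, `mu0_t = 0.7`, `B_t = 0.4`, `b1_t = 0`,
#' `b1_c = 0.4`, `xi1_t = 0.2`, `xi2_t = 0.15` and an uncorrelated moderator
#' (`cov_MZ = 0`).
#'
#' @param n_ind number of indicators per latent variable (default 3).
#' @param loadings per-indicator factor loading; recycled to `n_ind`.
#' @param intercepts per-indicator intercept; recycled to `n_ind`.
#' @param theta_within,theta_between within-/between-level indicator residual
#'   variances; recycled to `n_ind`.
#' @param psi_within,psi_between latent factor variance per level for the
#'   exogenous predictors (identification scale).
#' @param latent_corr_within,latent_corr_between correlation between the focal
#'   predictor and moderator at each level.
#' @param beta within-level structural coefficients `c(b0, b1, b2, b3)`.
#' @param gamma between-level structural coefficients `c(g0, g1, g2, g3)`.
#' @param sigma2_y,tau2_y conditional residual variance of the latent outcome
#'   at the within/between level.
#' @param sigma2_m_t,tau2_m_t latent mediator variance decomposition in the
#'   treatment arm of the partially nested design.
#' @param sigma2_m_c latent mediator variance in the control arm.
#' @param psi_z_t latent variance of the between-only moderator (treatment).
#' @param a_t,a_c latent mediator means by arm.
#' @param mu0_t,mu0_c latent outcome intercepts by arm.
#' @param B_t between-level mediator-outcome slope (treatment).
#' @param b1_t,b1_c within-level (treatment) and control mediator-outcome
#'   slopes.
#' @param xi1_t,xi2_t moderator main-effect and interaction slopes (treatment,
#'   between level).
#' @param sigma2_yt,tau2_yt conditional outcome residual variances in the
#'   treatment arm (within/between).
#' @param sigma2_yc conditional outcome residual variance in the control arm.
#' @param cov_MZ latent mediator-moderator covariance (between level,
#'   treatment arm).
#'
#' @return An object of class `sam_params` (a named list).
#' @examples
#' p <- sam_params()
#' implied_reliability(p)
#' @export
sam_params <- function(n_ind = 3L,
                       loadings = 1,
                       intercepts = 0,
                       theta_within = 0.8,
                       theta_between = 0.2,
                       psi_within = 1,
                       psi_between = 1,
                       latent_corr_within = 0.25,
                       latent_corr_between = 0.25,
                       beta = c(0, 0.4, 0.4, 0.2),
                       gamma = c(0, 0.4, 0.4, 0.2),
                       sigma2_y = 0.8,
                       tau2_y = 0.2,
                       sigma2_m_t = 0.8,
                       tau2_m_t = 0.2,
                       sigma2_m_c = 1,
                       psi_z_t = 1,
                       a_t = 0.5,
                       a_c = 0,
                       mu0_t = 0.7,
                       mu0_c = 0,
                       B_t = 0.4,
                       b1_t = 0,
                       b1_c = 0.4,
                       xi1_t = 0.2,
                       xi2_t = 0.15,
                       sigma2_yt = 0.8,
                       tau2_yt = 0.2,
                       sigma2_yc = 1,
                       cov_MZ = 0) {
  n_ind <- as.integer(n_ind)
  stopifnot(n_ind >= 2L)
  p <- list(
    n_ind = n_ind,
    loadings = rep_len(as.numeric(loadings), n_ind),
    intercepts = rep_len(as.numeric(intercepts), n_ind),
    theta_within = rep_len(as.numeric(theta_within), n_ind),
    theta_between = rep_len(as.numeric(theta_between), n_ind),
    psi_within = psi_within, psi_between = psi_between,
    latent_corr_within = latent_corr_within,
    latent_corr_between = latent_corr_between,
    beta = as.numeric(beta), gamma = as.numeric(gamma),
    sigma2_y = sigma2_y, tau2_y = tau2_y,
    sigma2_m_t = sigma2_m_t, tau2_m_t = tau2_m_t, sigma2_m_c = sigma2_m_c,
    psi_z_t = psi_z_t,
    a_t = a_t, a_c = a_c, mu0_t = mu0_t, mu0_c = mu0_c,
    B_t = B_t, b1_t = b1_t, b1_c = b1_c,
    xi1_t = xi1_t, xi2_t = xi2_t,
    sigma2_yt = sigma2_yt, tau2_yt = tau2_yt, sigma2_yc = sigma2_yc,
    cov_MZ = cov_MZ
  )
  stopifnot(
    all(p$theta_within > 0), all(p$theta_between > 0),
    p$psi_within > 0, p$psi_between > 0,
    abs(p$latent_corr_within) < 1, abs(p$latent_corr_between) < 1,
    length(p$beta) == 4L, length(p$gamma) == 4L,
    p$sigma2_y > 0, p$tau2_y > 0,
    p$sigma2_m_t > 0, p$tau2_m_t > 0, p$sigma2_m_c > 0, p$psi_z_t > 0,
    abs(p$cov_MZ) < sqrt(p$tau2_m_t * p$psi_z_t) + 1e-12 || p$cov_MZ == 0
  )
  class(p) <- "sam_params"
  p
}

#' @export
print.sam_params <- function(x, ...) {
  cat("Population parameters (SAM simulation designs)\n")
  cat(sprintf("  indicators per factor: %d, loadings: %s\n",
              x$n_ind, paste(format(x$loadings), collapse = ", ")))
  cat(sprintf("  indicator residuals: theta_W = %s, theta_B = %s\n",
              format(x$theta_within[1]), format(x$theta_between[1])))
  cat(sprintf("  latent predictor corr: %.2f (W), %.2f (B)\n",
              x$latent_corr_within, x$latent_corr_between))
  cat(sprintf("  beta = (%s); gamma = (%s)\n",
              paste(format(x$beta), collapse = ", "),
              paste(format(x$gamma), collapse = ", ")))
  cat(sprintf("  outcome residuals: sigma2 = %s (W), tau2 = %s (B)\n",
              format(x$sigma2_y), format(x$tau2_y)))
  cat(sprintf("  PN arm: a_t = %s, mu0_t = %s, B_t = %s, xi2_t = %s\n",
              format(x$a_t), format(x$mu0_t), format(x$B_t), format(x$xi2_t)))
  invisible(x)
}

#' Model-implied composite reliability (omega) per level
#'
#' Omega for a single-factor measurement block:
#' `(sum lambda)^2 psi / ((sum lambda)^2 psi + sum theta)`, evaluated with the
#' generating parameters at each level.  With the defaults this is
#' 9/9.6 = 0.9375 at the between level and 9/11.4 = 0.7895 within.
#'
#' @param params a [sam_params()] object.
#' @return Named numeric vector with elements `between` and `within`.
#' @export
implied_reliability <- function(params = sam_params()) {
  stopifnot(inherits(params, "sam_params"))
  lb <- sum(params$loadings)^2
  c(between = lb * params$psi_between / (lb * params$psi_between + sum(params$theta_between)),
    within  = lb * params$psi_within  / (lb * params$psi_within  + sum(params$theta_within)))
}

#' Model-implied outcome variance explained per level
#'
#' Computes, from the generating parameters, the marginal latent outcome
#' variance at each level of the requested design, the share of that variance
#' explained by the structural predictors, and the share owed to the latent
#' interaction term.  Exposed so the implied proportions are visible rather
#' than asserted; the product-term variance follows the variance-of-product
#' rule for centered bivariate normal variables.
#'
#' @param params a [sam_params()] object.
#' @param design one of `"within"`, `"cross"`, `"between"`.
#' @return A list with components `within` and `between`, each containing
#'   `var_total`, `r2` and `r2_interaction`.
#' @export
implied_r2 <- function(params = sam_params(), design = c("within", "cross", "between")) {
  design <- match.arg(design)
  mom <- population_moments(params, design)
  out <- list()
  for (lev in c("within", "between")) {
    M <- mom[[lev]]
    if (is.null(M)) { out[[lev]] <- NULL; next }
    vars <- colnames(M$cov)
    y <- "y"
    preds <- setdiff(vars, y)
    vy <- M$cov[y, y]
    if (length(preds)) {
      b <- solve(M$cov[preds, preds, drop = FALSE], M$cov[preds, y])
      expl <- sum(b * M$cov[preds, y])
      int <- grep(":", preds, value = TRUE)
      r2i <- if (length(int)) (b[int]^2 * M$cov[int, int]) / vy else 0
      out[[lev]] <- list(var_total = vy, r2 = expl / vy,
                         r2_interaction = unname(r2i))
    } else {
      out[[lev]] <- list(var_total = vy, r2 = 0, r2_interaction = 0)
    }
  }
  out
}
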
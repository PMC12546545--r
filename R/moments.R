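#' Variance of the product of two centered (bivariate normal) variables
#'
#' For jointly normal, mean-centered `a` and `b`,
#' `var(ab) = var(a) var(b) + cov(a, b)^2`.  This is the rule used to build
#' the model-implied variance of latent interaction terms.
#'
#' @param var_a,var_b marginal variances (non-negative).
#' @param cov_ab covariance; must satisfy the Cauchy-Schwarz bound.
#' @return The implied product variance (scalar).
#' @examples
#' product_variance(1, 1, 0.25) # 1.0625
#' @export
product_variance <- function(var_a, var_b, cov_ab) {
  if (var_a < 0 || var_b < 0)
    stop("variances must be non-negative")
  if (abs(cov_ab) > sqrt(var_a * var_b) + 1e-12)
    stop("covariance violates the Cauchy-Schwarz bound")
  var_a * var_b + cov_ab^2
}

moment_matrix <- function(cov, means, level, corrected = FALSE, n = NA_integer_,
                          products = list(), status = "converged") {
  structure(list(cov = cov, means = means, level = level,
                 corrected = corrected, n = n, products = products,
                 status = status),
            class = "moment_matrix")
}

#' @export
print.moment_matrix <- function(x, ...) {
  cat(sprintf("Moment matrix (%s level, %s, n = %s)\n", x$level,
              if (x$corrected) "corrected" else "uncorrected", x$n))
  print(round(x$cov, 4))
  invisible(x)
}

#' Exact population latent moments per level
#'
#' Builds the level-specific covariance matrices over the latent variables of
#' the requested design, including the interaction product term.  The product
#' variance follows [product_variance()]; covariances between a centered
#' normal product and its first-order parents are zero (odd moments vanish);
#' the product-outcome covariance is the interaction coefficient times the
#' product variance, as implied by the structural equation.
#'
#' @param params a [sam_params()] object.
#' @param design `"within"`, `"cross"` or `"between"`.
#' @return A list with elements `within` and `between` (each a
#'   `moment_matrix` over latent variables, or `NULL` when the level holds
#'   only a residual outcome term the design does not model).
#' @export
population_moments <- function(params = sam_params(),
                               design = c("within", "cross", "between")) {
  design <- match.arg(design)
  b <- params$beta; g <- params$gamma
  pw <- params$psi_within; pb <- params$psi_between
  cw <- params$latent_corr_within * pw
  cb <- params$latent_corr_between * pb

  within <- between <- NULL

  if (design %in% c("within", "cross")) {
    # within level: x, z first-order; product at within (within design) or
    # x(within) * z(between) (cross design); product variance identical when
    # psi and the cross-level covariance (0) are as generated
    vprod <- if (design == "within") product_variance(pw, pw, cw)
             else product_variance(pw, pb, 0)
    vars <- c("x", "z", "x:z", "y")
    M <- matrix(0, 4, 4, dimnames = list(vars, vars))
    M["x", "x"] <- pw; M["z", "z"] <- pw
    M["x", "z"] <- M["z", "x"] <- cw
    M["x:z", "x:z"] <- vprod
    M["x", "y"] <- M["y", "x"] <- b[2] * pw + b[3] * cw
    M["z", "y"] <- M["y", "z"] <- b[3] * pw + b[2] * cw
    M["x:z", "y"] <- M["y", "x:z"] <- b[4] * vprod
    M["y", "y"] <- b[2] * M["x", "y"] + b[3] * M["z", "y"] +
      b[4] * M["x:z", "y"] + params$sigma2_y
    within <- moment_matrix(M, stats::setNames(rep(0, 4), vars), "within",
                            products = list("x:z" = c("x", "z")))
    # between level: x, z, y, no interaction
    vars <- c("x", "z", "y")
    B <- matrix(0, 3, 3, dimnames = list(vars, vars))
    B["x", "x"] <- pb; B["z", "z"] <- pb
    B["x", "z"] <- B["z", "x"] <- cb
    B["x", "y"] <- B["y", "x"] <- g[2] * pb + g[3] * cb
    B["z", "y"] <- B["y", "z"] <- g[3] * pb + g[2] * cb
    B["y", "y"] <- g[2] * B["x", "y"] + g[3] * B["z", "y"] + params$tau2_y
    between <- moment_matrix(B, stats::setNames(rep(0, 3), vars), "between")
  } else {
    # between design: predictors and interaction live at the between level
    vprod <- product_variance(pb, pb, cb)
    vars <- c("x", "z", "x:z", "y")
    B <- matrix(0, 4, 4, dimnames = list(vars, vars))
    B["x", "x"] <- pb; B["z", "z"] <- pb
    B["x", "z"] <- B["z", "x"] <- cb
    B["x:z", "x:z"] <- vprod
    B["x", "y"] <- B["y", "x"] <- g[2] * pb + g[3] * cb
    B["z", "y"] <- B["y", "z"] <- g[3] * pb + g[2] * cb
    B["x:z", "y"] <- B["y", "x:z"] <- g[4] * vprod
    B["y", "y"] <- g[2] * B["x", "y"] + g[3] * B["z", "y"] +
      g[4] * B["x:z", "y"] + params$tau2_y
    between <- moment_matrix(B, stats::setNames(rep(0, 4), vars), "between",
                             products = list("x:z" = c("x", "z")))
    # within level: outcome is residual-only
    W <- matrix(params$sigma2_y, 1, 1, dimnames = list("y", "y"))
    within <- moment_matrix(W, c(y = 0), "within")
  }
  list(within = within, between = between)
}
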
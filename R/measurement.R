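#' Decompose indicators into cluster means and within-cluster deviations
#'
#' The univariate cluster-means route: the between-level indicator components
#' are estimated by the observed cluster means; the within components by the
#' deviations from the own-cluster mean.  The two tables reconstruct the
#' input additively.
#'
#' @param data a data frame with a `cluster_id` column, or an `mlsem_data`.
#' @param vars indicator column names; default: every column except
#'   `cluster_id`, `unit_id`, `arm`.
#' @return A list: `between` (one row per cluster, cluster means), `within`
#'   (input minus own-cluster mean), `cluster_id` (per-row cluster), `sizes`
#'   (per-cluster n), `n1_tilde` (harmonic mean cluster size).
#' @export
cluster_decompose <- function(data, vars = NULL) {
  if (inherits(data, "mlsem_data")) data <- data$data
  if (!nrow(data)) stop("empty dataset")
  if (is.null(vars))
    vars <- setdiff(names(data), c("cluster_id", "unit_id", "arm"))
  cl <- factor(data$cluster_id, levels = unique(data$cluster_id))
  X <- as.matrix(data[, vars, drop = FALSE])
  sizes <- as.integer(table(cl)[levels(cl)])
  means <- rowsum(X, cl, reorder = FALSE) / sizes
  within <- X - means[as.integer(cl), , drop = FALSE]
  list(between = data.frame(cluster_id = levels(cl), means,
                            check.names = FALSE, row.names = NULL),
       within = within,
       cluster_id = as.integer(cl),
       sizes = sizes,
       n1_tilde = length(sizes) / sum(1 / sizes))
}

new_factor_fit <- function(lambda, psi, theta, mu, n, status,
                           latent_mean = 0) {
  structure(list(lambda = lambda, psi = psi, theta = theta, mu = mu,
                 latent_mean = latent_mean, n = n, status = status),
            class = "factor_fit")
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("Single-factor fit (n = %s, status = %s)\n", x$n, x$status))
  cat("  loadings:", paste(format(round(x$lambda, 4)), collapse = " "), "\n")
  cat("  psi:", format(round(x$psi, 4)),
      " theta:", paste(format(round(x$theta, 4)), collapse = " "), "\n")
  invisible(x)
}

# admissible for scoring: a real, finite factor solution was produced
# (Heywood fits still produce results; boundary/non_PD do not)
fit_usable <- function(fit) fit$status %in% c("converged", "heywood")

ml_discrepancy <- function(S, lambda, psi, theta) {
  Sigma <- tcrossprod(lambda) * psi + diag(theta, length(lambda))
  ev <- determinant(Sigma, logarithm = TRUE)
  if (ev$sign <= 0) return(Inf)
  as.numeric(ev$modulus) + sum(diag(solve(Sigma, S)))
}

#' Fit a single-factor measurement model by maximum likelihood
#'
#' One common factor, `m` indicators.  With three indicators the model is
#' just-identified and the ML solution is closed form (the fitted covariance
#' reproduces the sample covariance exactly); with more indicators a
#' quasi-Newton optimizer on a log-variance parameterization is used, with a
#' second start on failure.  Fits are reported on the marker scale (first
#' loading 1, factor variance `psi` free), which for the unit-variance
#' generating models coincides with the psi = 1 identification.
#'
#' Admissibility statuses: `"converged"`; `"heywood"` (some residual variance
#' estimate is non-positive; estimates are still produced and usable for
#' scoring, mirroring how full SEM software reports such solutions);
#' `"boundary"` (no real/finite factor solution, e.g. sign-inconsistent
#' covariances or no common variance); `"non_PD"` (the input covariance
#' matrix is not positive definite).  `boundary` and `non_PD` are the
#' measurement-level convergence-failure events of the SAM pipeline.
#'
#' @param S sample covariance matrix of the indicators (symmetric).
#' @param means sample indicator means (defaults to zeros).
#' @param n number of observations behind `S` (must exceed the number of
#'   indicators).
#' @return A `factor_fit` with fields `lambda` (marker scale), `psi`,
#'   `theta`, `mu`, `n`, `status`.
#' @export
fit_single_factor_ml <- function(S, means = NULL, n = Inf) {
  m <- nrow(S)
  stopifnot(is.matrix(S), ncol(S) == m, m >= 3L)
  if (is.null(means)) means <- rep(0, m)
  if (is.finite(n) && n <= m) stop("need n > number of indicators")
  bad <- function(status) new_factor_fit(rep(NA_real_, m), NA_real_,
                                         rep(NA_real_, m), means, n, status)
  if (any(!is.finite(S))) return(bad("non_PD"))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(bad("non_PD"))

  if (m == 3L) {
    s12 <- S[1, 2]; s13 <- S[1, 3]; s23 <- S[2, 3]
    if (any(abs(c(s12, s13, s23)) < 1e-12) || s12 * s13 * s23 <= 0)
      return(bad("boundary"))
    l2 <- c(s12 * s13 / s23, s12 * s23 / s13, s13 * s23 / s12)
    if (any(l2 <= 0)) return(bad("boundary"))
    lam <- sqrt(l2) * sign(c(1, s12, s13))
    theta <- unname(diag(S)) - l2
    psi <- lam[1]^2
    lambda <- lam / lam[1]
    status <- if (any(theta <= 1e-6 * mean(diag(S)))) "heywood" else "converged"
    return(new_factor_fit(lambda, psi, theta, means, n, status))
  }

  # m > 3: optimize (lambda, log theta) under psi = 1, then rescale to marker
  obj <- function(par) {
    lam <- par[1:m]; th <- exp(par[(m + 1):(2 * m)])
    ml_discrepancy(S, lam, 1, th)
  }
  avg_off <- mean(S[upper.tri(S)])
  starts <- list(
    c(rep(sqrt(max(avg_off, 0.05 * mean(diag(S)))), m),
      log(pmax(diag(S) - avg_off, 0.05 * diag(S)))),
    c(sqrt(diag(S)) * 0.7, log(diag(S) * 0.5))
  )
  best <- NULL
  for (st in starts) {
    op <- tryCatch(stats::optim(st, obj, method = "L-BFGS-B",
                                control = list(maxit = 500)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best) || !is.finite(best$value)) return(bad("boundary"))
  lam <- best$par[1:m]; theta <- exp(best$par[(m + 1):(2 * m)])
  if (abs(lam[1]) < 1e-8) return(bad("boundary"))
  psi <- lam[1]^2
  lambda <- lam / lam[1]
  status <- if (any(theta <= 1e-6 * mean(diag(S)))) "heywood" else "converged"
  new_factor_fit(lambda, psi, theta, means, n, status)
}

#' Regression-method factor score weights
#'
#' `A = psi Lambda' (Lambda psi Lambda' + Theta)^-1`, with validity
#' `c = A Lambda` (the attenuation multiplier of factor-score covariances).
#'
#' @param fit an admissible `factor_fit`.
#' @return A `score_matrix`: weights `A`, validity `c`, and the noise
#'   quadratic form `a_theta = A' Theta A` used by the Croon variance
#'   correction.
#' @export
regression_score_matrix <- function(fit) {
  if (!inherits(fit, "factor_fit")) stop("need a factor_fit")
  if (!fit_usable(fit)) stop("fit is not admissible (status: ", fit$status, ")")
  Sigma <- tcrossprod(fit$lambda) * fit$psi + diag(fit$theta, length(fit$lambda))
  A <- drop(fit$psi * solve(Sigma, fit$lambda))
  structure(list(A = A, validity = sum(A * fit$lambda),
                 a_theta = sum(A^2 * fit$theta), psi = fit$psi),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Regression score weights:", paste(format(round(x$A, 4)), collapse = " "),
      "\n  validity:", format(round(x$validity, 4)), "\n")
  invisible(x)
}

#' Compute factor scores from indicators
#'
#' Weighted sum of mean-centered indicators; missing indicator values
#' propagate to a missing score.
#'
#' @param score_matrix a [regression_score_matrix()] result.
#' @param X matrix/data frame of indicator values (columns align with the
#'   weights).
#' @param means centering vector (defaults to the column means of `X`).
#' @return Numeric vector of factor scores.
#' @export
compute_scores <- function(score_matrix, X, means = NULL) {
  X <- as.matrix(X)
  if (is.null(means)) means <- colMeans(X, na.rm = TRUE)
  drop(sweep(X, 2, means) %*% score_matrix$A)
}

#' Reliability of a cluster mean for its between-level component
#'
#' For indicator `m`:
#' `R^B = (lambda_B^2 psi_B + theta_B) / (lambda_B^2 psi_B + theta_B +
#' (lambda_W^2 psi_W + theta_W) / n1)`.
#'
#' @param lambda_b,psi_b,theta_b between-level loading, factor variance and
#'   indicator residual variance (per indicator; recycled).
#' @param lambda_w,psi_w,theta_w within-level counterparts.
#' @param n1 cluster size (harmonic mean when unbalanced).
#' @return Per-indicator reliabilities in (0, 1].
#' @examples
#' rb_reliability(1, 1, 0.2, 1, 1, 0.8, 50) # 1.2 / 1.236
#' @export
rb_reliability <- function(lambda_b, psi_b, theta_b,
                           lambda_w, psi_w, theta_w, n1) {
  stopifnot(n1 >= 1)
  vb <- lambda_b^2 * psi_b + theta_b
  vw <- lambda_w^2 * psi_w + theta_w
  vb / (vb + vw / n1)
}

#' Two-level single-factor measurement model
#'
#' Fits the within-level factor model to the pooled within-cluster covariance
#' of the centered indicators and the between-level model to the covariance
#' of the raw cluster means (the cluster-means route; the between fit then
#' absorbs the within contamination of order 1/n1, which downstream
#' corrections remove).  Also computes the per-indicator cluster-mean
#' reliabilities `R^B`.
#'
#' @param data an `mlsem_data`, `pn_data` subset, or data frame with
#'   `cluster_id`.
#' @param variable indicator prefix (e.g. `"x"` for columns `x1..x3`).
#' @return A `two_level_fit`: `within` and `between` `factor_fit`s, `rb`
#'   (per-indicator cluster-mean reliabilities), `n1_tilde`, `status`
#'   (worst of the level statuses).
#' @export
fit_two_level_measurement <- function(data, variable) {
  if (inherits(data, c("mlsem_data", "pn_data"))) data <- data$data
  vars <- grep(paste0("^", variable, "[0-9]+$"), names(data), value = TRUE)
  if (length(vars) < 3L) stop("no indicator columns for '", variable, "'")
  dec <- cluster_decompose(data, vars)
  n2 <- length(dec$sizes)
  if (n2 < 2L) stop("need at least 2 clusters")
  if (max(dec$sizes) < 2L)
    stop("within-level model inestimable: all clusters are singletons")
  N <- nrow(dec$within)
  SW <- crossprod(dec$within) / (N - n2)
  MB <- as.matrix(dec$between[, vars, drop = FALSE])
  SB <- stats::cov(MB)
  wfit <- fit_single_factor_ml(SW, rep(0, length(vars)), N - n2)
  bfit <- fit_single_factor_ml(SB, colMeans(MB), n2)
  rb <- rep(NA_real_, length(vars))
  if (fit_usable(wfit) && fit_usable(bfit)) {
    v_mean <- bfit$lambda^2 * bfit$psi + bfit$theta    # fitted cluster-mean var
    vw <- wfit$lambda^2 * wfit$psi + wfit$theta
    rb <- pmin(pmax((v_mean - vw / dec$n1_tilde) / v_mean, 0), 1)
  }
  status <- if (!fit_usable(wfit) || !fit_usable(bfit)) {
    if (wfit$status == "non_PD" || bfit$status == "non_PD") "non_PD" else "boundary"
  } else if (wfit$status == "heywood" || bfit$status == "heywood") "heywood"
  else "converged"
  structure(list(within = wfit, between = bfit, rb = rb,
                 n1_tilde = dec$n1_tilde, n2 = n2, status = status),
            class = "two_level_fit")
}

#' @export
print.two_level_fit <- function(x, ...) {
  cat(sprintf("Two-level factor fit (%d clusters, n1~ = %.2f, status = %s)\n",
              x$n2, x$n1_tilde, x$status))
  cat("  within :"); print(x$within)
  cat("  between:"); print(x$between)
  cat("  R^B:", paste(format(round(x$rb, 4)), collapse = " "), "\n")
  invisible(x)
}

#' Cluster-mean reliabilities from a fitted two-level model
#'
#' Per-indicator `R^B` evaluated at the fitted loadings and variances; the
#' between-level quantities are decontaminated of the within-level sampling
#' component the raw cluster means carry, so at the population values this
#' reduces to [rb_reliability()] applied to the true between components.
#'
#' @param fit a `two_level_fit`.
#' @param n1 cluster size at which to evaluate (defaults to the harmonic mean
#'   cluster size of the fit).
#' @return Per-indicator reliabilities.
#' @export
cluster_mean_reliability <- function(fit, n1 = fit$n1_tilde) {
  stopifnot(inherits(fit, "two_level_fit"), n1 >= 1)
  if (!fit_usable(fit$within) || !fit_usable(fit$between))
    stop("both level fits must be admissible")
  v_mean_fit <- fit$between$lambda^2 * fit$between$psi + fit$between$theta
  vw <- fit$within$lambda^2 * fit$within$psi + fit$within$theta
  vb <- pmax(v_mean_fit - vw / fit$n1_tilde, 0)   # decontaminated between part
  rb_reliability(1, vb, 0, 1, vw, 0, n1)
}

# decontaminated between-level factor variance (marker scale)
psi_between_adj <- function(fit) {
  max(fit$between$psi - fit$within$psi / fit$n1_tilde, 0)
}
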
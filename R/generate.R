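# Multivariate normal draws via Cholesky; Sigma is small (2x2 here)
rmvn <- function(n, mu, Sigma) {
  p <- length(mu)
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% chol(Sigma), 2, mu, `+`)
}

# indicator block: lambda * eta + between residual (per cluster) + within
# residual (per row); eta_b indexed by cluster, eta_w per row
make_indicators <- function(eta_b, eta_w, cluster_index, params,
                            theta_b = params$theta_between,
                            theta_w = params$theta_within) {
  m <- params$n_ind
  n <- length(eta_w)
  n2 <- length(eta_b)
  eb <- matrix(stats::rnorm(n2 * m, sd = rep(sqrt(theta_b), each = n2)), n2, m)
  ew <- matrix(stats::rnorm(n * m, sd = rep(sqrt(theta_w), each = n)), n, m)
  common <- outer(eta_b[cluster_index] + eta_w, params$loadings)
  sweep(common + eb[cluster_index, , drop = FALSE] + ew, 2,
        params$intercepts, `+`)
}

ind_names <- function(prefix, m) paste0(prefix, seq_len(m))

#' Generate a two-level dataset from a stated population model
#'
#' Draws cluster- and individual-level latent variables from the multivariate
#' normal population model of the requested design, builds the latent outcome
#' from the design's structural equations, and attaches three indicators per
#' factor with level-specific residuals.  The exact generated latent values
#' are kept as a sidecar so true-model benchmark fits can be computed later.
#'
#' @param params a [sam_params()] object.
#' @param design `"within"`, `"cross"` or `"between"`: location of the latent
#'   interaction.
#' @param n2 number of clusters (>= 2).
#' @param n1 individuals per cluster (>= 2).
#' @param seed integer seed; the call is fully reproducible from it.
#' @return An object of class `mlsem_data`: a list with `data` (long-format
#'   data frame: `cluster_id`, `unit_id`, indicators `x1..x3`, `z1..z3`,
#'   `y1..y3`), `latent` (the sidecar of exact latent values), and the
#'   design/sizes/params used.  For the between design the `x`/`z` indicators
#'   are cluster-level measurements replicated across the cluster's rows.
#' @export
generate_mlsem <- function(params = sam_params(),
                           design = c("within", "cross", "between"),
                           n2, n1, seed = NULL) {
  design <- match.arg(design)
  n2 <- as.integer(n2); n1 <- as.integer(n1)
  if (n2 < 2L || n1 < 2L) stop("need n2 >= 2 and n1 >= 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- params$n_ind
  n <- n2 * n1
  cl <- rep(seq_len(n2), each = n1)
  b <- params$beta; g <- params$gamma

  Sw <- matrix(c(params$psi_within,
                 params$latent_corr_within * params$psi_within,
                 params$latent_corr_within * params$psi_within,
                 params$psi_within), 2, 2)
  Sb <- matrix(c(params$psi_between,
                 params$latent_corr_between * params$psi_between,
                 params$latent_corr_between * params$psi_between,
                 params$psi_between), 2, 2)

  EB <- rmvn(n2, c(0, 0), Sb)       # eta_x_b, eta_z_b
  eta_x_b <- EB[, 1]; eta_z_b <- EB[, 2]
  if (design %in% c("within", "cross")) {
    EW <- rmvn(n, c(0, 0), Sw)
    eta_x_w <- EW[, 1]; eta_z_w <- EW[, 2]
  } else {
    eta_x_w <- eta_z_w <- rep(0, n)
  }

  eps_w <- stats::rnorm(n, sd = sqrt(params$sigma2_y))
  u_b <- stats::rnorm(n2, sd = sqrt(params$tau2_y))

  if (design == "within") {
    eta_y_w <- b[1] + b[2] * eta_x_w + b[3] * eta_z_w +
      b[4] * eta_x_w * eta_z_w + eps_w
    eta_y_b <- g[1] + g[2] * eta_x_b + g[3] * eta_z_b + u_b
  } else if (design == "cross") {
    eta_y_w <- b[1] + b[2] * eta_x_w + b[3] * eta_z_w +
      b[4] * eta_x_w * eta_z_b[cl] + eps_w
    eta_y_b <- g[1] + g[2] * eta_x_b + g[3] * eta_z_b + u_b
  } else {
    eta_y_w <- b[1] + eps_w
    eta_y_b <- g[1] + g[2] * eta_x_b + g[3] * eta_z_b +
      g[4] * eta_x_b * eta_z_b + u_b
  }

  if (design == "between") {
    # cluster-level indicators for x and z (standard single-level factor
    # model at the cluster level), replicated over the cluster's rows
    X2 <- sweep(outer(eta_x_b, params$loadings) +
                  matrix(stats::rnorm(n2 * m, sd = rep(sqrt(params$theta_between), each = n2)), n2, m),
                2, params$intercepts, `+`)
    Z2 <- sweep(outer(eta_z_b, params$loadings) +
                  matrix(stats::rnorm(n2 * m, sd = rep(sqrt(params$theta_between), each = n2)), n2, m),
                2, params$intercepts, `+`)
    X <- X2[cl, , drop = FALSE]
    Z <- Z2[cl, , drop = FALSE]
  } else {
    X <- make_indicators(eta_x_b, eta_x_w, cl, params)
    Z <- make_indicators(eta_z_b, eta_z_w, cl, params)
  }
  Y <- make_indicators(eta_y_b, eta_y_w, cl, params)

  dat <- data.frame(cluster_id = cl, unit_id = sequence(rep(n1, n2)),
                    X, Z, Y)
  names(dat) <- c("cluster_id", "unit_id", ind_names("x", m),
                  ind_names("z", m), ind_names("y", m))
  latent <- data.frame(cluster_id = cl, unit_id = dat$unit_id,
                       eta_x_w = eta_x_w, eta_z_w = eta_z_w,
                       eta_y_w = eta_y_w,
                       eta_x_b = eta_x_b[cl], eta_z_b = eta_z_b[cl],
                       eta_y_b = eta_y_b[cl])
  structure(list(data = dat, latent = latent, design = design,
                 n2 = n2, n1 = n1, params = params),
            class = "mlsem_data")
}

#' @export
print.mlsem_data <- function(x, ...) {
  cat(sprintf("Two-level dataset (%s-interaction design): %d clusters x %d = %d rows\n",
              x$design, x$n2, x$n1, nrow(x$data)))
  invisible(x)
}

#' Generate a 2/1 partially nested moderated-mediation dataset
#'
#' The treatment arm is two-level (individuals in `n2_t` clusters of size
#' `n1_t`); the control arm holds `n2_t * n1_t` unclustered individuals
#' (singleton clusters).  Latent mediator means are `a_t` (treatment) and
#' `a_c` (control, fixed 0 by default); outcome intercepts `mu0_t` / `mu0_c`.
#' The between-only moderator `z` exists in the treatment arm only; its
#' indicator columns are missing (`NA`) for every control row.  The latent
#' interaction is formed from the moderator and the mediator's between
#' component centered at its arm mean, so `xi1_t` retains its stated value
#' under the centered-product estimation convention.
#'
#' @param params a [sam_params()] object.
#' @param n2_t treatment clusters (>= 2).
#' @param n1_t individuals per treatment cluster (>= 1).
#' @param seed integer seed.
#' @return An object of class `pn_data` with `data`, `latent`, sizes and
#'   params; `data` has an `arm` column (`"treatment"`/`"control"`).
#' @export
generate_pn <- function(params = sam_params(), n2_t, n1_t, seed = NULL) {
  n2_t <- as.integer(n2_t); n1_t <- as.integer(n1_t)
  if (n2_t < 2L || n1_t < 1L) stop("need n2_t >= 2 and n1_t >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- params$n_ind
  n_t <- n2_t * n1_t
  n_c <- n2_t * n1_t
  cl <- rep(seq_len(n2_t), each = n1_t)

  # treatment latents
  Sb <- matrix(c(params$tau2_m_t, params$cov_MZ,
                 params$cov_MZ, params$psi_z_t), 2, 2)
  EB <- rmvn(n2_t, c(0, 0), Sb)
  eta_m_b <- params$a_t + EB[, 1]
  eta_z_b <- EB[, 2]
  eta_m_w <- stats::rnorm(n_t, sd = sqrt(params$sigma2_m_t))
  eta_y_w <- params$b1_t * eta_m_w +
    stats::rnorm(n_t, sd = sqrt(params$sigma2_yt))
  eta_y_b <- params$mu0_t + params$B_t * eta_m_b + params$xi1_t * eta_z_b +
    params$xi2_t * (eta_m_b - params$a_t) * eta_z_b +
    stats::rnorm(n2_t, sd = sqrt(params$tau2_yt))

  Mt <- make_indicators(eta_m_b, eta_m_w, cl, params)
  Yt <- make_indicators(eta_y_b, eta_y_w, cl, params)
  Zt2 <- sweep(outer(eta_z_b, params$loadings) +
                 matrix(stats::rnorm(n2_t * m, sd = rep(sqrt(params$theta_between), each = n2_t)), n2_t, m),
               2, params$intercepts, `+`)
  Zt <- Zt2[cl, , drop = FALSE]

  # control latents: single level, total indicator residual matches the
  # stated sigma2(c) = 1 decomposition-free structure
  eta_m_c <- params$a_c + stats::rnorm(n_c, sd = sqrt(params$sigma2_m_c))
  eta_y_c <- params$mu0_c + params$b1_c * eta_m_c +
    stats::rnorm(n_c, sd = sqrt(params$sigma2_yc))
  theta_c <- params$theta_within + params$theta_between
  Mc <- sweep(outer(eta_m_c, params$loadings) +
                matrix(stats::rnorm(n_c * m, sd = rep(sqrt(theta_c), each = n_c)), n_c, m),
              2, params$intercepts, `+`)
  Yc <- sweep(outer(eta_y_c, params$loadings) +
                matrix(stats::rnorm(n_c * m, sd = rep(sqrt(theta_c), each = n_c)), n_c, m),
              2, params$intercepts, `+`)

  dt <- data.frame(arm = "treatment", cluster_id = paste0("t", cl),
                   unit_id = sequence(rep(n1_t, n2_t)), Mt, Zt, Yt)
  dc <- data.frame(arm = "control", cluster_id = paste0("c", seq_len(n_c)),
                   unit_id = 1L,
                   Mc, matrix(NA_real_, n_c, m), Yc)
  nm <- c("arm", "cluster_id", "unit_id", ind_names("m", m),
          ind_names("z", m), ind_names("y", m))
  names(dt) <- nm; names(dc) <- nm
  dat <- rbind(dt, dc)

  latent <- rbind(
    data.frame(arm = "treatment", cluster_id = paste0("t", cl),
               unit_id = dt$unit_id,
               eta_m_w = eta_m_w, eta_y_w = eta_y_w,
               eta_m_b = eta_m_b[cl], eta_z_b = eta_z_b[cl],
               eta_y_b = eta_y_b[cl]),
    data.frame(arm = "control", cluster_id = dc$cluster_id, unit_id = 1L,
               eta_m_w = 0, eta_y_w = 0,
               eta_m_b = eta_m_c, eta_z_b = NA_real_, eta_y_b = eta_y_c))
  structure(list(data = dat, latent = latent, n2_t = n2_t, n1_t = n1_t,
                 params = params),
            class = "pn_data")
}

#' @export
print.pn_data <- function(x, ...) {
  cat(sprintf("Partially nested 2/1 dataset: %d x %d treatment rows, %d control singletons\n",
              x$n2_t, x$n1_t, x$n2_t * x$n1_t))
  invisible(x)
}
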
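# pooled-loading GLS contrast of latent means across arms: loadings
# constrained equal across arms for the mean model only; Sigma is the pooled
# (within-arm centered) total indicator covariance used as the GLS weight
latent_mean_contrast <- function(Xt, Xc, lambda_t, lambda_c) {
  nt <- nrow(Xt); nc <- nrow(Xc)
  lam <- (nt * lambda_t + nc * lambda_c) / (nt + nc)
  St <- stats::cov(Xt); Sc <- stats::cov(Xc)
  Sp <- ((nt - 1) * St + (nc - 1) * Sc) / (nt + nc - 2)
  d <- colMeans(Xt) - colMeans(Xc)
  w <- solve(Sp, lam)
  sum(w * d) / sum(w * lam)
}

#' Arm-specific measurement models for a 2/1 partially nested SEM
#'
#' The treatment arm gets two-level factor models for the mediator `m` and
#' outcome `y` and a between-only model for the moderator `z` (fitted to the
#' cluster-level records); the control arm gets single-level models for `m`
#' and `y`.  Latent means are fixed to zero in the control arm; the treatment
#' latent means of the mediator (`a_hat`, the a path of the mediation effect)
#' and of the outcome (`y_contrast`) are estimated by a pooled-sample GLS
#' mean model with loadings constrained equal across arms.
#'
#' @param data a `pn_data` object or a data frame with `arm`, `cluster_id`
#'   and indicator columns `m1..`, `z1..`, `y1..` (z missing for control
#'   rows).
#' @return A `pn_measurement` list: `treatment` (`m`, `y` two-level fits, `z`
#'   factor fit), `control` (`m`, `y` factor fits), `a_hat`, `y_contrast`,
#'   `n1_tilde`, per-arm statuses.
#' @export
fit_pn_measurement <- function(data) {
  d <- if (inherits(data, "pn_data")) data$data else data
  if (!all(c("arm", "cluster_id") %in% names(d)))
    stop("need `arm` and `cluster_id` columns")
  dt <- d[d$arm == "treatment", , drop = FALSE]
  dc <- d[d$arm == "control", , drop = FALSE]
  if (!nrow(dt) || !nrow(dc)) stop("both study arms must be present")
  vars_of <- function(v) grep(paste0("^", v, "[0-9]+$"), names(d), value = TRUE)

  tr <- list(m = fit_two_level_measurement(dt, "m"),
             y = fit_two_level_measurement(dt, "y"))
  zdec <- cluster_decompose(dt, vars_of("z"))
  ZB <- as.matrix(zdec$between[, vars_of("z"), drop = FALSE])
  tr$z <- fit_single_factor_ml(stats::cov(ZB), colMeans(ZB), nrow(ZB))

  ctl <- list()
  for (v in c("m", "y")) {
    Xc <- as.matrix(dc[, vars_of(v), drop = FALSE])
    ctl[[v]] <- fit_single_factor_ml(stats::cov(Xc), colMeans(Xc), nrow(Xc))
  }

  status_arm <- function(fits) {
    st <- vapply(fits, function(f) f$status, "")
    if (any(st == "non_PD")) "non_PD"
    else if (any(st == "boundary")) "boundary"
    else if (any(st == "heywood")) "heywood" else "converged"
  }
  st_t <- status_arm(tr); st_c <- status_arm(ctl)

  a_hat <- y_contrast <- NA_real_
  if (!st_t %in% c("boundary", "non_PD") && !st_c %in% c("boundary", "non_PD")) {
    a_hat <- latent_mean_contrast(
      as.matrix(dt[, vars_of("m")]), as.matrix(dc[, vars_of("m")]),
      tr$m$between$lambda, ctl$m$lambda)
    y_contrast <- latent_mean_contrast(
      as.matrix(dt[, vars_of("y")]), as.matrix(dc[, vars_of("y")]),
      tr$y$between$lambda, ctl$y$lambda)
  }
  structure(list(treatment = tr, control = ctl,
                 a_hat = a_hat, a_c = 0, y_contrast = y_contrast,
                 n1_tilde = tr$m$n1_tilde,
                 status_treatment = st_t, status_control = st_c),
            class = "pn_measurement")
}

#' Arm-specific structural models for the partially nested SEM
#'
#' Estimates three structural models from factor-score moments: the
#' between-level treatment model (`y ~ m + z + m:z`, the model holding the
#' b path `B`, the moderator slope `xi1` and the moderation slope `xi2`),
#' the within-level treatment model (`y ~ m`) and the control model
#' (`y ~ m`).  The latent interaction is the product of the centered
#' cluster-level scores; under the Croon estimator every moment matrix is
#' corrected with the arm-specific measurement results, including the
#' cluster-mean decontamination of the treatment between level.
#'
#' @param data a `pn_data` object (or matching data frame).
#' @param estimator `"croon"` or `"fs"`.
#' @param measurement optionally, a precomputed [fit_pn_measurement()]
#'   result.
#' @return List with `between`, `within`, `control` `structural_fit`s and
#'   the `measurement` used.
#' @export
estimate_pn_structural <- function(data, estimator = c("croon", "fs"),
                                   measurement = NULL) {
  estimator <- match.arg(estimator)
  d <- if (inherits(data, "pn_data")) data$data else data
  meas <- if (is.null(measurement)) fit_pn_measurement(data) else measurement
  bad <- function(level) structure(
    list(outcome = "y", predictors = character(),
         coefficients = NULL, intercept = NA_real_,
         residual_variance = NA_real_, level = level,
         corrected = estimator == "croon", status = "non_convergence"),
    class = "structural_fit")
  out <- list(measurement = meas, between = NULL, within = NULL,
              control = NULL)
  vars_of <- function(v) grep(paste0("^", v, "[0-9]+$"), names(d), value = TRUE)
  dt <- d[d$arm == "treatment", , drop = FALSE]
  dc <- d[d$arm == "control", , drop = FALSE]

  if (!meas$status_treatment %in% c("boundary", "non_PD")) {
    dec <- cluster_decompose(dt, c(vars_of("m"), vars_of("y"), vars_of("z")))
    n1t <- dec$n1_tilde
    wsc <- data.frame(
      m = drop(dec$within[, vars_of("m")] %*%
                 regression_score_matrix(meas$treatment$m$within)$A),
      y = drop(dec$within[, vars_of("y")] %*%
                 regression_score_matrix(meas$treatment$y$within)$A))
    bsc <- data.frame(
      m = compute_scores(regression_score_matrix(meas$treatment$m$between),
                         dec$between[, vars_of("m")]),
      z = compute_scores(regression_score_matrix(meas$treatment$z),
                         dec$between[, vars_of("z")]),
      y = compute_scores(regression_score_matrix(meas$treatment$y$between),
                         dec$between[, vars_of("y")]))
    mm_w <- assemble_score_moments(wsc, level = "within")
    mm_b <- assemble_score_moments(bsc, products = list(c("m", "z")),
                                   level = "between")
    if (estimator == "croon") {
      mm_w <- croon_correct(mm_w, list(m = meas$treatment$m,
                                       y = meas$treatment$y))
      mm_b <- croon_correct(mm_b, list(m = meas$treatment$m,
                                       z = meas$treatment$z,
                                       y = meas$treatment$y),
                            within_corrected = mm_w, n1 = n1t)
    }
    out$within <- estimate_paths(mm_w, "y", "m")
    out$between <- estimate_paths(mm_b, "y", c("m", "z", "m:z"))
    out$moments_treatment <- list(within = mm_w, between = mm_b)
  } else {
    out$within <- bad("within"); out$between <- bad("between")
  }

  if (!meas$status_control %in% c("boundary", "non_PD")) {
    csc <- data.frame(
      m = compute_scores(regression_score_matrix(meas$control$m),
                         dc[, vars_of("m")]),
      y = compute_scores(regression_score_matrix(meas$control$y),
                         dc[, vars_of("y")]))
    mm_c <- assemble_score_moments(csc, level = "single")
    if (estimator == "croon")
      mm_c <- croon_correct(mm_c, list(m = meas$control$m,
                                       y = meas$control$y))
    out$control <- estimate_paths(mm_c, "y", "m")
    out$moments_control <- mm_c
  } else {
    out$control <- bad("single")
  }
  out
}

#' Main, mediation and moderation effects from the fitted arm models
#'
#' Main effect: the conditional latent outcome intercept contrast
#' `mu0(t) - mu0(c)`, recovered as the latent outcome mean contrast minus the
#' b-path coefficient times the latent mediator mean contrast (moderator and
#' interaction scores are centered, so their means drop).  Mediation effect:
#' `ME = a(t) * B(t)`, exactly the product of its stored factors.  Moderation
#' effect: the interaction slope `xi2(t)`.  The treatment-mediator
#' interaction on the b path (`B(t) - b1(c)`) is reported as a descriptive
#' contrast but not folded into `ME`.
#'
#' @param measurement a [fit_pn_measurement()] result.
#' @param structural an [estimate_pn_structural()] result.
#' @return Named list of effect estimates (`NA` when an ingredient did not
#'   converge) plus per-arm statuses.
#' @export
compute_effects <- function(measurement, structural) {
  B_t <- xi1 <- xi2 <- b1_t <- b1_c <- NA_real_
  sb <- structural$between; sw <- structural$within; sc <- structural$control
  if (sb$status == "converged") {
    B_t <- unname(sb$coefficients["m"])
    xi1 <- unname(sb$coefficients["z"])
    xi2 <- unname(sb$coefficients["m:z"])
  }
  if (sw$status == "converged") b1_t <- unname(sw$coefficients["m"])
  if (sc$status == "converged") b1_c <- unname(sc$coefficients["m"])
  a_hat <- measurement$a_hat
  main <- measurement$y_contrast - B_t * a_hat
  list(main = main, mediation = a_hat * B_t, moderation = xi2,
       a_path = a_hat, b_path = B_t, xi1 = xi1,
       b1_t = b1_t, b1_c = b1_c, b_contrast = B_t - b1_c)
}

#' SAM estimation of the 2/1 partially nested moderated-mediation SEM
#'
#' Full pipeline: arm-specific measurement models and latent mean contrasts
#' ([fit_pn_measurement()]), arm/level structural models
#' ([estimate_pn_structural()]) and derived main / mediation / moderation
#' effects ([compute_effects()]), using uncorrected (`"fs"`) or
#' Croon-corrected (`"croon"`) factor-score moments.
#'
#' @param data a `pn_data` object (see [generate_pn()]) or matching data
#'   frame.
#' @param estimator `"croon"` or `"fs"`.
#' @return An object of class `pnsam`: structural fits (`between`, `within`,
#'   `control`), `effects`, `measurement`, per-arm statuses and an overall
#'   `status`.
#' @examples
#' d <- generate_pn(sam_params(), n2_t = 40, n1_t = 20, seed = 2)
#' fit <- pnsam(d, estimator = "croon")
#' fit$effects[c("main", "mediation", "moderation")]
#' @export
pnsam <- function(data, estimator = c("croon", "fs")) {
  estimator <- match.arg(estimator)
  meas <- fit_pn_measurement(data)
  st <- estimate_pn_structural(data, estimator, measurement = meas)
  eff <- compute_effects(meas, st)
  status_t <- if (meas$status_treatment %in% c("boundary", "non_PD") ||
                  st$between$status != "converged" ||
                  st$within$status != "converged")
    "non_convergence" else "converged"
  status_c <- if (meas$status_control %in% c("boundary", "non_PD") ||
                  st$control$status != "converged")
    "non_convergence" else "converged"
  structure(list(estimator = estimator, measurement = meas,
                 between = st$between, within = st$within,
                 control = st$control,
                 moments = st[c("moments_treatment", "moments_control")],
                 effects = eff,
                 status_treatment = status_t, status_control = status_c,
                 status = if (status_t == "converged" && status_c == "converged")
                   "converged" else "non_convergence"),
            class = "pnsam")
}

#' @export
print.pnsam <- function(x, ...) {
  cat(sprintf("SAM-%s fit, 2/1 partially nested moderated mediation (status: %s)\n",
              toupper(x$estimator), x$status))
  e <- x$effects
  cat(sprintf("  main effect      : %s\n", format(round(e$main, 4))))
  cat(sprintf("  mediation  a*B   : %s = %s x %s\n",
              format(round(e$mediation, 4)), format(round(e$a_path, 4)),
              format(round(e$b_path, 4))))
  cat(sprintf("  moderation xi2(t): %s\n", format(round(e$moderation, 4))))
  cat(sprintf("  b1(t) = %s, b1(c) = %s\n",
              format(round(e$b1_t, 4)), format(round(e$b1_c, 4))))
  invisible(x)
}

#' @export
coef.pnsam <- function(object, ...) {
  e <- object$effects
  c(main = e$main, mediation = e$mediation, moderation = e$moderation,
    a_t = e$a_path, B_t = e$b_path, xi1_t = e$xi1,
    b1_t = e$b1_t, b1_c = e$b1_c)
}

#' @export
summary.pnsam <- function(object, ...) {
  structure(list(fit = object), class = "summary.pnsam")
}

#' @export
print.summary.pnsam <- function(x, ...) {
  print(x$fit)
  cat("\nTreatment between-level structural model:\n")
  print(x$fit$between)
  cat("Control model:\n")
  print(x$fit$control)
  invisible(x)
}
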
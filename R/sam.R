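#' Assemble a factor-score moment matrix
#'
#' Covariance matrix (and means) over factor-score columns plus, for each
#' requested pair, a product column formed from the mean-centered parents
#' (the factor-score operationalization of a latent interaction).
#'
#' @param scores data frame / matrix of aligned score columns (the matrix
#'   variables).
#' @param products list of product requests; each element either a character
#'   pair of parent names or a list with `name`, `parents` (parent names,
#'   looked up in `scores` then `extra`).
#' @param level `"within"`, `"between"` or `"single"`.
#' @param extra optional named columns usable only as product parents (e.g. a
#'   between-level score expanded to rows for a cross-level product).
#' @return An uncorrected `moment_matrix`.
#' @export
assemble_score_moments <- function(scores, products = list(),
                                   level = c("within", "between", "single"),
                                   extra = NULL) {
  level <- match.arg(level)
  S <- as.data.frame(scores)
  pool <- if (is.null(extra)) S else cbind(S, as.data.frame(extra))
  prod_meta <- list()
  for (p in products) {
    if (is.character(p)) p <- list(parents = p)
    if (is.null(p$name)) p$name <- paste(p$parents, collapse = ":")
    a <- pool[[p$parents[1]]]; b <- pool[[p$parents[2]]]
    if (is.null(a) || is.null(b)) stop("unknown product parent")
    if (length(a) != length(b) || length(a) != nrow(S))
      stop("mismatched score lengths")
    pr <- (a - mean(a, na.rm = TRUE)) * (b - mean(b, na.rm = TRUE))
    S[[p$name]] <- pr - mean(pr, na.rm = TRUE)   # centered product term
    prod_meta[[p$name]] <- p$parents
  }
  M <- as.matrix(S)
  moment_matrix(stats::cov(M, use = "complete.obs"),
                colMeans(M, na.rm = TRUE), level,
                corrected = FALSE, n = sum(stats::complete.cases(M)),
                products = prod_meta)
}

# normalize a fits entry to the correction info the Croon step needs
croon_info <- function(fit, level) {
  if (is.list(fit) && !is.null(fit$validity)) return(fit)  # already info
  if (inherits(fit, "two_level_fit")) {
    f <- if (level == "within") fit$within else fit$between
    sm <- regression_score_matrix(f)
    psi_adj <- if (level == "within") f$psi else psi_between_adj(fit)
    return(list(validity = sm$validity, a_theta = sm$a_theta,
                psi = f$psi, psi_adj = psi_adj))
  }
  if (inherits(fit, "factor_fit")) {
    sm <- regression_score_matrix(fit)
    return(list(validity = sm$validity, a_theta = sm$a_theta,
                psi = fit$psi, psi_adj = fit$psi))
  }
  stop("unsupported fit object in `fits`")
}

#' Croon method-of-moments correction of a score moment matrix
#'
#' Disattenuates a factor-score covariance matrix using the measurement-model
#' implied unreliability: covariances between two latent-variable scores are
#' divided by the product of their validities, interaction-outcome
#' covariances by the product of the three validities involved, and score
#' variances are replaced by the measurement-implied factor variances
#' (`(var(score) - A'Theta A) / c^2`).  The interaction variance is rebuilt
#' from corrected first-order moments with the variance-of-product rule.
#'
#' For a between-level matrix whose scores derive from cluster means, the
#' corrected within-level moments divided by the (harmonic mean) cluster size
#' are subtracted from the shared entries, removing the within-level sampling
#' contamination the cluster means carry (the latent-scale analogue of the
#' cluster-mean reliability adjustment; variables observed only at the
#' cluster level are left untouched).
#'
#' @param raw an uncorrected `moment_matrix`.
#' @param fits named list (one entry per matrix variable, plus one per
#'   cross-level product parent under the key used in the product metadata)
#'   of `factor_fit` / `two_level_fit` objects.
#' @param within_corrected corrected within-level `moment_matrix`, required
#'   for the cluster-mean decontamination of a between matrix with two-level
#'   variables.
#' @param n1 cluster size (harmonic mean) used in the decontamination.
#' @param zero_product_covariances force the covariance between a product and
#'   its first-order parents to the normal-theory value 0 instead of the
#'   corrected empirical value.
#' @return A corrected `moment_matrix`; its `status` is `"non_convergence"`
#'   when a validity falls below 1e-3, a corrected variance is non-positive,
#'   or a corrected product violates the Cauchy-Schwarz bound.
#' @export
croon_correct <- function(raw, fits, within_corrected = NULL, n1 = NULL,
                          zero_product_covariances = FALSE) {
  stopifnot(inherits(raw, "moment_matrix"))
  if (raw$corrected) stop("matrix is already corrected")
  vars <- colnames(raw$cov)
  pnames <- names(raw$products)
  np <- setdiff(vars, pnames)
  info <- lapply(stats::setNames(names(fits), names(fits)),
                 function(k) croon_info(fits[[k]], raw$level))
  fail <- function() {
    out <- raw; out$corrected <- TRUE; out$status <- "non_convergence"; out
  }
  cs <- vapply(np, function(g) info[[g]]$validity, 0)
  if (any(!is.finite(cs)) || any(cs < 1e-3)) return(fail())

  C <- raw$cov
  for (g in np) for (h in np) {
    C[g, h] <- if (g == h)
      (raw$cov[g, g] - info[[g]]$a_theta) / info[[g]]$validity^2
    else raw$cov[g, h] / (info[[g]]$validity * info[[h]]$validity)
  }
  # cluster-mean decontamination (between level, two-level variables only)
  if (!is.null(within_corrected)) {
    stopifnot(!is.null(n1))
    shared <- intersect(np, colnames(within_corrected$cov))
    if (length(shared))
      C[shared, shared] <- C[shared, shared] -
        within_corrected$cov[shared, shared, drop = FALSE] / n1
  }
  if (any(diag(C)[np] <= 0)) return(fail())

  for (p in pnames) {
    par <- raw$products[[p]]
    a <- par[1]; b <- par[2]
    pv <- function(key) {
      if (key %in% np) C[key, key] else info[[key]]$psi_adj
    }
    va <- pv(a); vb <- pv(b)
    cab <- if (a %in% np && b %in% np) C[a, b] else 0
    if (is.null(va) || is.null(vb) || va <= 0 || vb <= 0) return(fail())
    vp <- tryCatch(product_variance(va, vb, cab), error = function(e) NULL)
    if (is.null(vp)) return(fail())
    C[p, p] <- vp
    ca <- info[[a]]$validity; cb <- info[[b]]$validity
    if (!is.finite(ca) || !is.finite(cb) || ca < 1e-3 || cb < 1e-3)
      return(fail())
    for (g in np) {
      C[p, g] <- C[g, p] <- raw$cov[p, g] / (ca * cb * info[[g]]$validity)
    }
    if (zero_product_covariances) {
      base <- sub("\\..*$", "", c(a, b))
      for (g in intersect(base, np)) C[p, g] <- C[g, p] <- 0
    }
    for (q in setdiff(pnames, p)) {
      qq <- raw$products[[q]]
      cq <- prod(vapply(qq, function(k) info[[k]]$validity, 0))
      C[p, q] <- C[q, p] <- raw$cov[p, q] / (ca * cb * cq)
    }
  }
  moment_matrix(C, raw$means, raw$level, corrected = TRUE, n = raw$n,
                products = raw$products, status = "converged")
}

#' Estimate structural paths from a moment matrix
#'
#' Normal-equations solution: coefficients are the predictor-block inverse
#' times the predictor-outcome covariances; the conditional residual variance
#' is the outcome variance minus the explained part; the intercept follows
#' from the means.
#'
#' @param moments a `moment_matrix` (corrected or not).
#' @param outcome outcome variable label.
#' @param predictors predictor labels (order preserved in the output).
#' @return A `structural_fit` with `coefficients`, `intercept`,
#'   `residual_variance`, `level`, `status` (`"non_convergence"` when the
#'   predictor block is singular/non-PD or the implied residual variance is
#'   negative).
#' @export
estimate_paths <- function(moments, outcome, predictors) {
  stopifnot(inherits(moments, "moment_matrix"))
  bad <- function() structure(
    list(outcome = outcome, predictors = predictors,
         coefficients = stats::setNames(rep(NA_real_, length(predictors)), predictors),
         intercept = NA_real_, residual_variance = NA_real_,
         level = moments$level, corrected = moments$corrected,
         status = "non_convergence"),
    class = "structural_fit")
  if (!is.null(moments$status) && moments$status != "converged") return(bad())
  vy <- moments$cov[outcome, outcome]
  if (!length(predictors)) {
    return(structure(list(outcome = outcome, predictors = character(),
                          coefficients = numeric(0),
                          intercept = moments$means[[outcome]],
                          residual_variance = vy, level = moments$level,
                          corrected = moments$corrected, status = "converged"),
                     class = "structural_fit"))
  }
  P <- moments$cov[predictors, predictors, drop = FALSE]
  q <- moments$cov[predictors, outcome]
  ev <- tryCatch(eigen(P, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) -1)
  if (min(ev) <= 1e-10 * max(1, max(abs(diag(P))))) return(bad())
  b <- drop(solve(P, q))
  resid <- vy - sum(b * q)
  if (resid < 0) {
    if (resid > -1e-8 * max(1, vy)) resid <- 0 else return(bad())
  }
  intercept <- moments$means[[outcome]] -
    sum(b * moments$means[predictors])
  structure(list(outcome = outcome, predictors = predictors,
                 coefficients = stats::setNames(b, predictors),
                 intercept = unname(intercept), residual_variance = resid,
                 level = moments$level, corrected = moments$corrected,
                 status = "converged"),
            class = "structural_fit")
}

#' @export
print.structural_fit <- function(x, ...) {
  cat(sprintf("Structural fit (%s level%s, status = %s)\n", x$level,
              if (isTRUE(x$corrected)) ", Croon-corrected" else "", x$status))
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  cat("  residual variance:", format(round(x$residual_variance, 4)), "\n")
  invisible(x)
}

#' @export
coef.structural_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

# internal: per-variable scores and fits for the fully nested designs
mlsam_measurement <- function(data, design) {
  d <- if (inherits(data, "mlsem_data")) data$data else data
  two_level_vars <- switch(design,
                           within = c("x", "z", "y"),
                           cross  = c("x", "z", "y"),
                           between = "y")
  cluster_vars <- if (design == "between") c("x", "z") else character()
  fits <- list()
  for (v in two_level_vars) fits[[v]] <- fit_two_level_measurement(d, v)
  for (v in cluster_vars) {
    vars <- grep(paste0("^", v, "[0-9]+$"), names(d), value = TRUE)
    dec <- cluster_decompose(d, vars)
    MB <- as.matrix(dec$between[, vars, drop = FALSE])
    fits[[v]] <- fit_single_factor_ml(stats::cov(MB), colMeans(MB), nrow(MB))
  }
  fits
}

#' Structural-after-measurement estimation for a two-level SEM with a latent
#' interaction
#'
#' End-to-end SAM pipeline: level-specific single-factor measurement models
#' are fitted for the focal predictor `x`, moderator `z` and outcome `y`
#' (between-only models for `x`/`z` in the between design); regression factor
#' scores are computed per level; the latent interaction is the product of
#' the (centered) scores dictated by the design; the structural models are
#' estimated from the score moment matrices, after the Croon correction when
#' `estimator = "croon"`, or directly (`"fs"`).  Estimation is deterministic
#' given the data.
#'
#' Any measurement-level failure (no real factor solution, non-PD input) or,
#' for the Croon estimator, an inadmissible corrected moment matrix
#' (non-PD predictor block, non-positive corrected variance, validity below
#' 1e-3, negative residual variance) makes the overall `status`
#' `"non_convergence"` — the pipeline's convergence-failure event.
#'
#' @param data an `mlsem_data` (or a long-format data frame with
#'   `cluster_id` and indicator columns `x1..`, `z1..`, `y1..`).
#' @param design `"within"`, `"cross"` or `"between"`; defaults to the
#'   dataset's design when available.
#' @param estimator `"croon"` (corrected) or `"fs"` (uncorrected factor-score
#'   regression).
#' @return An object of class `mlsam` with components `within` and `between`
#'   (`structural_fit`s; `within` is `NULL` for the between design),
#'   `measurement`, `moments` (raw and, for Croon, corrected), `validities`,
#'   `status`.
#' @seealso [pnsam()] for the partially nested design, [bootstrap_ci()] for
#'   percentile intervals.
#' @examples
#' d <- generate_mlsem(sam_params(), "within", n2 = 30, n1 = 20, seed = 1)
#' fit <- mlsam(d, estimator = "croon")
#' coef(fit)
#' @export
mlsam <- function(data, design = NULL, estimator = c("croon", "fs")) {
  estimator <- match.arg(estimator)
  if (is.null(design)) {
    if (!inherits(data, "mlsem_data"))
      stop("`design` must be given for plain data frames")
    design <- data$design
  }
  design <- match.arg(design, c("within", "cross", "between"))
  d <- if (inherits(data, "mlsem_data")) data$data else data
  need <- c("x1", "z1", "y1")
  if (!all(need %in% names(d)))
    stop("dataset lacks required indicator columns for this design")

  out <- structure(list(design = design, estimator = estimator,
                        measurement = NULL, moments = list(),
                        within = NULL, between = NULL,
                        status = "non_convergence"),
                   class = "mlsam")
  fits <- mlsam_measurement(d, design)
  out$measurement <- fits
  statuses <- vapply(fits, function(f) f$status, "")
  if (any(statuses %in% c("boundary", "non_PD"))) return(out)

  dec <- cluster_decompose(d)
  n1t <- dec$n1_tilde
  vars_of <- function(v) grep(paste0("^", v, "[0-9]+$"), names(d), value = TRUE)
  w_score <- function(v) {
    sm <- regression_score_matrix(fits[[v]]$within)
    drop(dec$within[, vars_of(v), drop = FALSE] %*% sm$A)
  }
  b_score <- function(v) {
    f <- if (inherits(fits[[v]], "two_level_fit")) fits[[v]]$between else fits[[v]]
    sm <- regression_score_matrix(f)
    MB <- as.matrix(dec$between[, vars_of(v), drop = FALSE])
    compute_scores(sm, MB)
  }

  if (design %in% c("within", "cross")) {
    sw <- data.frame(x = w_score("x"), z = w_score("z"), y = w_score("y"))
    sb <- data.frame(x = b_score("x"), z = b_score("z"), y = b_score("y"))
    if (design == "within") {
      mm_w <- assemble_score_moments(sw, products = list(c("x", "z")),
                                     level = "within")
      w_fits <- list(x = fits$x, z = fits$z, y = fits$y)
    } else {
      zb_rows <- sb$z[dec$cluster_id]
      mm_w <- assemble_score_moments(
        sw, products = list(list(name = "x:z", parents = c("x", "z.between"))),
        level = "within", extra = data.frame(z.between = zb_rows))
      w_fits <- list(x = fits$x, z = fits$z, y = fits$y,
                     z.between = croon_info(fits$z, "between"))
    }
    mm_b <- assemble_score_moments(sb, level = "between")
    out$moments$within_raw <- mm_w
    out$moments$between_raw <- mm_b
    if (estimator == "croon") {
      mm_w_c <- croon_correct(mm_w, w_fits)
      mm_b_c <- croon_correct(mm_b, list(x = fits$x, z = fits$z, y = fits$y),
                              within_corrected = mm_w_c, n1 = n1t)
      out$moments$within <- mm_w_c
      out$moments$between <- mm_b_c
    } else {
      out$moments$within <- mm_w
      out$moments$between <- mm_b
    }
    out$within <- estimate_paths(out$moments$within, "y", c("x", "z", "x:z"))
    out$between <- estimate_paths(out$moments$between, "y", c("x", "z"))
  } else {
    sb <- data.frame(x = b_score("x"), z = b_score("z"), y = b_score("y"))
    mm_b <- assemble_score_moments(sb, products = list(c("x", "z")),
                                   level = "between")
    out$moments$between_raw <- mm_b
    if (estimator == "croon") {
      # only y carries cluster-mean contamination; x/z are cluster-level
      sw_y <- data.frame(y = w_score("y"))
      mm_wy <- assemble_score_moments(sw_y, level = "within")
      mm_wy_c <- croon_correct(mm_wy, list(y = fits$y))
      mm_b_c <- croon_correct(mm_b, list(x = fits$x, z = fits$z, y = fits$y),
                              within_corrected = mm_wy_c, n1 = n1t)
      out$moments$between <- mm_b_c
    } else {
      out$moments$between <- mm_b
    }
    out$between <- estimate_paths(out$moments$between, "y", c("x", "z", "x:z"))
  }

  ok <- function(f) is.null(f) || f$status == "converged"
  mom_ok <- all(vapply(out$moments, function(m)
    is.null(m$status) || m$status == "converged", TRUE))
  out$status <- if (ok(out$within) && ok(out$between) && mom_ok)
    "converged" else "non_convergence"
  out$validities <- vapply(fits, function(f) {
    f1 <- if (inherits(f, "two_level_fit")) f$between else f
    if (fit_usable(f1)) regression_score_matrix(f1)$validity else NA_real_
  }, 0)
  out
}

#' @export
print.mlsam <- function(x, ...) {
  cat(sprintf("SAM-%s fit, %s-interaction design (status: %s)\n",
              toupper(x$estimator), x$design, x$status))
  if (!is.null(x$within)) { cat("Within-level structural model:\n"); print(x$within) }
  if (!is.null(x$between)) { cat("Between-level structural model:\n"); print(x$between) }
  invisible(x)
}

#' @export
coef.mlsam <- function(object, level = c("both", "within", "between"), ...) {
  level <- match.arg(level)
  w <- if (!is.null(object$within)) coef(object$within) else NULL
  b <- if (!is.null(object$between)) coef(object$between) else NULL
  switch(level,
         within = w, between = b,
         both = c(if (!is.null(w)) stats::setNames(w, paste0("W.", names(w))),
                  if (!is.null(b)) stats::setNames(b, paste0("B.", names(b)))))
}

#' @export
summary.mlsam <- function(object, ...) {
  structure(list(fit = object), class = "summary.mlsam")
}

#' @export
print.summary.mlsam <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nMeasurement validities (between-level or single):\n")
  print(round(f$validities, 4))
  invisible(x)
}
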
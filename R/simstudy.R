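# deterministic per-replication seed scheme: any single replication can be
# re-run in isolation from (master seed, replication index)
rep_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 21474L * 100003 + i * 7919 + 1) %% 2147483647)
}

#' Population structural coefficients of a design
#'
#' The generating slope values the Monte Carlo metrics are computed against.
#'
#' @param params a [sam_params()] object.
#' @param design `"within"`, `"cross"`, `"between"` or `"pn"`.
#' @return Named list of per-level named coefficient vectors (and, for
#'   `"pn"`, the effect values).
#' @export
pop_coefficients <- function(params = sam_params(),
                             design = c("within", "cross", "between", "pn")) {
  design <- match.arg(design)
  b <- params$beta; g <- params$gamma
  switch(design,
    within = list(within = c(x = b[2], z = b[3], "x:z" = b[4]),
                  between = c(x = g[2], z = g[3])),
    cross = list(within = c(x = b[2], z = b[3], "x:z" = b[4]),
                 between = c(x = g[2], z = g[3])),
    between = list(within = NULL,
                   between = c(x = g[2], z = g[3], "x:z" = g[4])),
    pn = list(effects = c(main = params$mu0_t - params$mu0_c,
                          mediation = params$a_t * params$B_t,
                          moderation = params$xi2_t),
              treat_between = c(m = params$B_t, z = params$xi1_t,
                                "m:z" = params$xi2_t),
              treat_within = c(m = params$b1_t),
              control = c(m = params$b1_c)))
}

ols_coefs <- function(y, X) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  fit$coefficients[-1]
}

#' True-model benchmark fit on exact latent values
#'
#' OLS of the exact generated latent outcome on the exact latent predictors
#' (including the exact product term), per level - the benchmark the average
#' absolute bias metric is computed against.  Deterministic given the
#' dataset; requires the latent sidecar the generators attach.
#'
#' @param data an `mlsem_data` or `pn_data` with its latent sidecar.
#' @return For `mlsem_data`: list of named coefficient vectors `within` /
#'   `between`.  For `pn_data`: coefficient vectors per arm model plus the
#'   true effect estimates.
#' @export
true_empirical_fit <- function(data) {
  if (inherits(data, "mlsem_data")) {
    L <- data$latent
    cl1 <- !duplicated(L$cluster_id)
    if (data$design == "between") {
      Xb <- cbind(x = L$eta_x_b[cl1], z = L$eta_z_b[cl1],
                  "x:z" = (L$eta_x_b * L$eta_z_b)[cl1])
      return(list(within = NULL,
                  between = ols_coefs(L$eta_y_b[cl1], Xb)))
    }
    prod <- if (data$design == "within") L$eta_x_w * L$eta_z_w
            else L$eta_x_w * L$eta_z_b
    Xw <- cbind(x = L$eta_x_w, z = L$eta_z_w, "x:z" = prod)
    Xb <- cbind(x = L$eta_x_b[cl1], z = L$eta_z_b[cl1])
    return(list(within = ols_coefs(L$eta_y_w, Xw),
                between = ols_coefs(L$eta_y_b[cl1], Xb)))
  }
  if (inherits(data, "pn_data")) {
    L <- data$latent
    Lt <- L[L$arm == "treatment", ]
    Lc <- L[L$arm == "control", ]
    cl1 <- !duplicated(Lt$cluster_id)
    mb <- Lt$eta_m_b[cl1]; zb <- Lt$eta_z_b[cl1]; yb <- Lt$eta_y_b[cl1]
    Xb <- cbind(m = mb, z = zb, "m:z" = (mb - mean(mb)) * zb)
    tb <- ols_coefs(yb, Xb)
    tw <- ols_coefs(Lt$eta_y_w, cbind(m = Lt$eta_m_w))
    cc <- ols_coefs(Lc$eta_y_b, cbind(m = Lc$eta_m_b))
    a_true <- mean(Lt$eta_m_b + Lt$eta_m_w) - mean(Lc$eta_m_b)
    y_true <- mean(Lt$eta_y_b + Lt$eta_y_w) - mean(Lc$eta_y_b)
    return(list(treat_between = tb, treat_within = tw, control = cc,
                effects = c(main = y_true - tb[["m"]] * a_true,
                            mediation = a_true * tb[["m"]],
                            moderation = tb[["m:z"]])))
  }
  stop("need an mlsem_data or pn_data object with latent sidecar")
}

extract_mlsam <- function(fit) {
  w <- if (!is.null(fit$within)) fit$within$coefficients else NULL
  b <- if (!is.null(fit$between)) fit$between$coefficients else NULL
  list(within = w, between = b, failed = fit$status != "converged")
}

# one fully nested Monte Carlo condition
run_condition_mlsem <- function(params, design, n2, n1, R, estimators, seed,
                                keep_estimates = FALSE) {
  pop <- pop_coefficients(params, design)
  levs <- names(Filter(Negate(is.null), pop))
  est_store <- list()
  true_store <- list()
  fail <- stats::setNames(numeric(length(estimators)), estimators)
  times <- stats::setNames(numeric(length(estimators)), estimators)
  for (r in seq_len(R)) {
    d <- generate_mlsem(params, design, n2, n1, seed = rep_seed(seed, r))
    tf <- true_empirical_fit(d)
    for (lev in levs)
      true_store[[lev]] <- rbind(true_store[[lev]], tf[[lev]][names(pop[[lev]])])
    for (e in estimators) {
      t0 <- proc.time()[3]
      f <- mlsam(d, design, estimator = e)
      times[e] <- times[e] + (proc.time()[3] - t0)
      ex <- extract_mlsam(f)
      if (ex$failed) {
        fail[e] <- fail[e] + 1
        for (lev in levs)
          est_store[[paste(e, lev)]] <- rbind(est_store[[paste(e, lev)]],
                                              rep(NA_real_, length(pop[[lev]])))
      } else {
        for (lev in levs)
          est_store[[paste(e, lev)]] <- rbind(est_store[[paste(e, lev)]],
                                              ex[[lev]][names(pop[[lev]])])
      }
    }
  }
  rows <- list()
  for (e in estimators) for (lev in levs) {
    E <- est_store[[paste(e, lev)]]
    Tm <- true_store[[lev]]
    cn <- names(pop[[lev]])
    mean_est <- colMeans(E, na.rm = TRUE)
    bias <- mean_est - pop[[lev]]
    sds <- apply(E, 2, stats::sd, na.rm = TRUE)
    rmse <- sqrt(bias^2 + sds^2)
    abb <- abs(mean_est - colMeans(Tm))
    rows[[paste(e, lev)]] <- data.frame(
      design = design, n2 = n2, n1 = n1, estimator = e, level = lev,
      coefficient = cn, pop = unname(pop[[lev]]),
      mean_est = unname(mean_est), bias = unname(bias),
      true_mean = unname(colMeans(Tm)), abs_bias_vs_true = unname(abb),
      sd = unname(sds), rmse = unname(rmse),
      n_converged = unname(colSums(!is.na(E))),
      failure_rate = unname(fail[e]) / R,
      mean_time = unname(times[e]) / R,
      row.names = NULL)
  }
  out <- list(per_coef = do.call(rbind, rows))
  out$summary <- do.call(rbind, lapply(split(out$per_coef,
                                             interaction(out$per_coef$estimator,
                                                         out$per_coef$level,
                                                         drop = TRUE)),
    function(g) data.frame(
      design = g$design[1], n2 = g$n2[1], n1 = g$n1[1],
      estimator = g$estimator[1], level = g$level[1],
      avg_abs_bias = mean(g$abs_bias_vs_true),
      avg_sd = mean(g$sd), avg_rmse = mean(g$rmse),
      failure_rate = g$failure_rate[1], row.names = NULL)))
  if (keep_estimates) out$estimates <- est_store
  out
}

run_condition_pn <- function(params, n2, n1, R, estimators, seed,
                             keep_estimates = FALSE) {
  pop <- pop_coefficients(params, "pn")
  comp <- c("effects", "treat_between", "treat_within", "control")
  est_store <- list()
  true_store <- list()
  fail_t <- fail_c <- stats::setNames(numeric(length(estimators)), estimators)
  times <- stats::setNames(numeric(length(estimators)), estimators)
  for (r in seq_len(R)) {
    d <- generate_pn(params, n2, n1, seed = rep_seed(seed, r))
    tf <- true_empirical_fit(d)
    for (cc in comp)
      true_store[[cc]] <- rbind(true_store[[cc]], tf[[cc]][names(pop[[cc]])])
    for (e in estimators) {
      t0 <- proc.time()[3]
      f <- pnsam(d, estimator = e)
      times[e] <- times[e] + (proc.time()[3] - t0)
      if (f$status_treatment != "converged") fail_t[e] <- fail_t[e] + 1
      if (f$status_control != "converged") fail_c[e] <- fail_c[e] + 1
      vals <- list(
        effects = if (f$status == "converged")
          unlist(f$effects[c("main", "mediation", "moderation")])
          else rep(NA_real_, 3),
        treat_between = if (f$between$status == "converged")
          f$between$coefficients[names(pop$treat_between)]
          else rep(NA_real_, 3),
        treat_within = if (f$within$status == "converged")
          f$within$coefficients[names(pop$treat_within)] else NA_real_,
        control = if (f$control$status == "converged")
          f$control$coefficients[names(pop$control)] else NA_real_)
      for (cc in comp)
        est_store[[paste(e, cc)]] <- rbind(est_store[[paste(e, cc)]],
                                           unname(vals[[cc]]))
    }
  }
  rows <- list()
  for (e in estimators) for (cc in comp) {
    E <- est_store[[paste(e, cc)]]
    cn <- names(pop[[cc]])
    mean_est <- colMeans(E, na.rm = TRUE)
    bias <- mean_est - pop[[cc]]
    sds <- apply(E, 2, stats::sd, na.rm = TRUE)
    fr <- if (cc == "control") fail_c[e] / R else fail_t[e] / R
    rows[[paste(e, cc)]] <- data.frame(
      design = "pn", n2 = n2, n1 = n1, estimator = e, component = cc,
      coefficient = cn, pop = unname(pop[[cc]]), mean_est = unname(mean_est),
      bias = unname(bias),
      true_mean = unname(colMeans(true_store[[cc]], na.rm = TRUE)),
      abs_bias_vs_true = unname(abs(mean_est - colMeans(true_store[[cc]], na.rm = TRUE))),
      sd = unname(sds), rmse = unname(sqrt(bias^2 + sds^2)),
      n_converged = unname(colSums(!is.na(E))),
      failure_rate = unname(fr), mean_time = unname(times[e]) / R,
      row.names = NULL)
  }
  out <- list(per_coef = do.call(rbind, rows))
  if (keep_estimates) out$estimates <- est_store
  out
}

#' Run one Monte Carlo condition
#'
#' Generates `R` replications of a design at one sample-size condition,
#' estimates each with the requested estimators, and summarises bias against
#' the population values, average absolute bias against the true-model
#' benchmark on exact latent values, the SD of estimates across converged
#' replications, RMSE (`sqrt(bias^2 + SD^2)`), and the convergence-failure
#' rate (computed over all replications; all other metrics over converged
#' replications only).
#'
#' @param params a [sam_params()] object.
#' @param design `"within"`, `"cross"`, `"between"` or `"pn"`.
#' @param n2,n1 clusters and cluster size (treatment arm for `"pn"`).
#' @param R replications (>= 1).
#' @param estimators subset of `c("fs", "croon")`.
#' @param seed master seed; replication seeds are derived deterministically.
#' @param keep_estimates keep the raw per-replication estimates.
#' @return A list with `per_coef` (one row per condition x estimator x
#'   coefficient) and, for the fully nested designs, `summary` (per-level
#'   averages).
#' @export
run_condition <- function(params = sam_params(),
                          design = c("within", "cross", "between", "pn"),
                          n2, n1, R = 500, estimators = c("fs", "croon"),
                          seed = 1, keep_estimates = FALSE) {
  design <- match.arg(design)
  stopifnot(R >= 1)
  if (design == "pn")
    run_condition_pn(params, n2, n1, R, estimators, seed, keep_estimates)
  else
    run_condition_mlsem(params, design, n2, n1, R, estimators, seed,
                        keep_estimates)
}

#' Run a full Monte Carlo study over a sample-size grid
#'
#' Aggregates [run_condition()] over designs and a sample-size grid and
#' renders the standard result tables: convergence-failure rates,
#' interaction-coefficient bias (SD), per-level average absolute bias
#' (average SD), and per-level average RMSE for the fully nested designs;
#' per-arm failure rates, effect bias (SD) and per-component RMSE for the
#' partially nested design.
#'
#' @param config list with elements `designs` (character subset of within /
#'   cross / between / pn), `grid` (data frame with `n2`, `n1`),
#'   `R`, `seed`, `estimators`, and optional `out_dir` (tables written as CSV
#'   plus a JSON manifest) and `params` (argument list for [sam_params()]).
#' @return Named list of result tables (data frames); raw per-coefficient
#'   rows under `$per_coef`.
#' @export
run_study <- function(config) {
  stopifnot(is.list(config), !is.null(config$designs), !is.null(config$grid))
  grid <- as.data.frame(config$grid)
  stopifnot(nrow(grid) >= 0, all(c("n2", "n1") %in% names(grid)))
  R <- config$R %||% 500
  seed <- config$seed %||% 1
  estimators <- config$estimators %||% c("fs", "croon")
  params <- if (is.null(config$params)) sam_params()
            else do.call(sam_params, config$params)
  rows <- list()
  for (design in config$designs) for (i in seq_len(nrow(grid))) {
    cond_seed <- rep_seed(seed, match(design, c("within", "cross", "between", "pn")) * 100000 + i * 1000)
    res <- run_condition(params, design, grid$n2[i], grid$n1[i], R,
                         estimators, seed = cond_seed)
    rows[[paste(design, i)]] <- res$per_coef
  }
  per_coef <- do.call(rbind, lapply(rows, function(x) {
    if (!"component" %in% names(x)) x$component <- x$level
    if (!"level" %in% names(x)) x$level <- x$component
    x
  }))
  tables <- if (is.null(per_coef)) list() else render_tables(per_coef)
  tables$per_coef <- per_coef
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    for (nm in names(tables)) {
      f <- file.path(config$out_dir, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
    manifest <- list(command = "run_study", seed = seed, R = R,
                     designs = config$designs, grid = grid,
                     estimators = estimators,
                     package_version = as.character(utils::packageVersion("samcroon")),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     files = basename(files))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  tables
}

`%||%` <- function(a, b) if (is.null(a)) b else a

render_tables <- function(pc) {
  out <- list()
  fn <- pc[pc$design != "pn", , drop = FALSE]
  pn <- pc[pc$design == "pn", , drop = FALSE]
  two <- function(x) sprintf("%.2f", x)
  if (nrow(fn)) {
    key <- !duplicated(fn[, c("design", "n2", "n1", "estimator")])
    out$convergence_failure <- data.frame(
      fn[key, c("design", "n2", "n1", "estimator")],
      failure_rate = fn$failure_rate[key], row.names = NULL)
    int <- fn[fn$coefficient %in% c("x:z"), , drop = FALSE]
    out$interaction_bias <- data.frame(
      int[, c("design", "n2", "n1", "estimator", "level")],
      cell = paste0(two(int$bias), "(", two(int$sd), ")"),
      bias = int$bias, sd = int$sd, row.names = NULL)
    agg <- stats::aggregate(cbind(abs_bias_vs_true, sd, rmse) ~
                              design + n2 + n1 + estimator + level,
                            data = fn, FUN = mean)
    names(agg)[6:8] <- c("avg_abs_bias", "avg_sd", "avg_rmse")
    agg$cell <- paste0(two(agg$avg_abs_bias), "(", two(agg$avg_sd), ")")
    out$average_bias <- agg[, c("design", "n2", "n1", "estimator", "level",
                                "cell", "avg_abs_bias", "avg_sd")]
    out$rmse <- agg[, c("design", "n2", "n1", "estimator", "level",
                        "avg_rmse")]
  }
  if (nrow(pn)) {
    key <- !duplicated(pn[, c("n2", "n1", "estimator", "component")])
    fr <- pn[key & pn$component %in% c("treat_between", "control"), ,
             drop = FALSE]
    fr$arm <- ifelse(fr$component == "control", "control", "treatment")
    out$pn_convergence_failure <- data.frame(
      fr[, c("n2", "n1", "estimator", "arm")],
      failure_rate = fr$failure_rate, row.names = NULL)
    eff <- pn[pn$component == "effects", , drop = FALSE]
    out$pn_effect_bias <- data.frame(
      eff[, c("n2", "n1", "estimator", "coefficient")],
      cell = paste0(two(eff$bias), "(", two(eff$sd), ")"),
      bias = eff$bias, sd = eff$sd, row.names = NULL)
    slope <- pn[pn$component != "effects", , drop = FALSE]
    agg <- stats::aggregate(rmse ~ n2 + n1 + estimator + component,
                            data = slope, FUN = mean)
    names(agg)[5] <- "avg_rmse"
    out$pn_rmse <- agg
  }
  out
}
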
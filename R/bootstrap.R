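resample_mlsem <- function(data, idx_by_cluster) {
  sel <- sample.int(length(idx_by_cluster), replace = TRUE)
  rows <- unlist(idx_by_cluster[sel], use.names = FALSE)
  d <- data$data[rows, , drop = FALSE]
  d$cluster_id <- rep(seq_along(sel),
                      times = lengths(idx_by_cluster[sel]))
  structure(list(data = d, latent = NULL, design = data$design,
                 n2 = length(sel), n1 = data$n1, params = data$params),
            class = "mlsem_data")
}

resample_pn <- function(data, idx_t, idx_c) {
  sel_t <- sample.int(length(idx_t), replace = TRUE)
  sel_c <- sample.int(length(idx_c), replace = TRUE)
  rows_t <- unlist(idx_t[sel_t], use.names = FALSE)
  dt <- data$data[rows_t, , drop = FALSE]
  dt$cluster_id <- paste0("t", rep(seq_along(sel_t),
                                   times = lengths(idx_t[sel_t])))
  dc <- data$data[unlist(idx_c[sel_c], use.names = FALSE), , drop = FALSE]
  dc$cluster_id <- paste0("c", seq_along(sel_c))
  structure(list(data = rbind(dt, dc), latent = NULL,
                 n2_t = length(sel_t), n1_t = data$n1_t,
                 params = data$params),
            class = "pn_data")
}

#' Cluster bootstrap percentile confidence intervals
#'
#' Resamples clusters with replacement (arm-stratified for the partially
#' nested design; control singletons are resampled as units), reruns the full
#' SAM pipeline on each replicate, and returns percentile bounds of the
#' coefficient/effect estimates over the converged replicates, together with
#' the fraction of non-converged replicates.
#'
#' @param data an `mlsem_data` or `pn_data` object.
#' @param estimator `"croon"` or `"fs"`.
#' @param B bootstrap replicates (default 1000; >= 2).
#' @param probs percentile bounds (default 2.5\% and 97.5\%).
#' @param seed optional seed for the resampling.
#' @return List with `ci` (matrix: one row per coefficient, columns at
#'   `probs`), `estimates` (replicate-by-coefficient matrix),
#'   `prop_nonconverged`, `B`.
#' @export
bootstrap_ci <- function(data, estimator = c("croon", "fs"), B = 1000,
                         probs = c(0.025, 0.975), seed = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  is_pn <- inherits(data, "pn_data")
  if (is_pn) {
    arm <- data$data$arm
    idx_t <- split(which(arm == "treatment"),
                   data$data$cluster_id[arm == "treatment"])
    idx_c <- split(which(arm == "control"),
                   data$data$cluster_id[arm == "control"])
  } else {
    idx <- split(seq_len(nrow(data$data)), data$data$cluster_id)
  }
  est <- NULL
  n_bad <- 0L
  for (b in seq_len(B)) {
    db <- if (is_pn) resample_pn(data, idx_t, idx_c)
          else resample_mlsem(data, idx)
    f <- tryCatch(if (is_pn) pnsam(db, estimator)
                  else mlsam(db, estimator = estimator),
                  error = function(e) NULL)
    if (is.null(f) || f$status != "converged") {
      n_bad <- n_bad + 1L
      next
    }
    est <- rbind(est, if (is_pn) coef(f) else coef(f, level = "both"))
  }
  if (is.null(est)) stop("all bootstrap replicates failed to converge")
  ci <- t(apply(est, 2, stats::quantile, probs = probs, na.rm = TRUE))
  list(ci = ci, estimates = est, prop_nonconverged = n_bad / B, B = B)
}
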
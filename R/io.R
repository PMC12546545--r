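#' Write a generated dataset to delimited text
#'
#' Writes `<prefix>_data.csv` (long-format indicators), `<prefix>_latent.csv`
#' (the exact latent sidecar, when present) and `<prefix>_manifest.json`
#' (column manifest, design, sizes, generating parameters, package version).
#' Values are written at full double precision; missing values as empty
#' fields.
#'
#' @param x an `mlsem_data` or `pn_data` object.
#' @param prefix file path prefix (directories are created).
#' @return Invisibly, the manifest file path.
#' @export
write_dataset <- function(x, prefix) {
  stopifnot(inherits(x, c("mlsem_data", "pn_data")))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  f_data <- paste0(prefix, "_data.csv")
  f_latent <- paste0(prefix, "_latent.csv")
  utils::write.csv(x$data, f_data, row.names = FALSE, na = "")
  files <- basename(f_data)
  if (!is.null(x$latent)) {
    utils::write.csv(x$latent, f_latent, row.names = FALSE, na = "")
    files <- c(files, basename(f_latent))
  }
  manifest <- list(
    kind = if (inherits(x, "pn_data")) "pn" else "mlsem",
    design = if (inherits(x, "pn_data")) "pn" else x$design,
    n2 = if (inherits(x, "pn_data")) x$n2_t else x$n2,
    n1 = if (inherits(x, "pn_data")) x$n1_t else x$n1,
    columns = names(x$data),
    latent_columns = if (!is.null(x$latent)) names(x$latent) else NULL,
    params = unclass(x$params),
    package_version = as.character(utils::packageVersion("samcroon")),
    files = files)
  f_man <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(f_man)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param prefix the file path prefix used when writing.
#' @return The reconstructed `mlsem_data` / `pn_data` object (latent sidecar
#'   included when it was written).
#' @export
read_dataset <- function(prefix) {
  man <- jsonlite::read_json(paste0(prefix, "_manifest.json"),
                             simplifyVector = TRUE)
  d <- utils::read.csv(paste0(prefix, "_data.csv"), check.names = FALSE)
  latent <- NULL
  f_latent <- paste0(prefix, "_latent.csv")
  if (!is.null(man$latent_columns) && file.exists(f_latent))
    latent <- utils::read.csv(f_latent, check.names = FALSE)
  pl <- man$params
  params <- sam_params(
    n_ind = pl$n_ind, loadings = pl$loadings, intercepts = pl$intercepts,
    theta_within = pl$theta_within, theta_between = pl$theta_between,
    psi_within = pl$psi_within, psi_between = pl$psi_between,
    latent_corr_within = pl$latent_corr_within,
    latent_corr_between = pl$latent_corr_between,
    beta = pl$beta, gamma = pl$gamma,
    sigma2_y = pl$sigma2_y, tau2_y = pl$tau2_y,
    sigma2_m_t = pl$sigma2_m_t, tau2_m_t = pl$tau2_m_t,
    sigma2_m_c = pl$sigma2_m_c, psi_z_t = pl$psi_z_t,
    a_t = pl$a_t, a_c = pl$a_c, mu0_t = pl$mu0_t, mu0_c = pl$mu0_c,
    B_t = pl$B_t, b1_t = pl$b1_t, b1_c = pl$b1_c,
    xi1_t = pl$xi1_t, xi2_t = pl$xi2_t,
    sigma2_yt = pl$sigma2_yt, tau2_yt = pl$tau2_yt,
    sigma2_yc = pl$sigma2_yc, cov_MZ = pl$cov_MZ)
  if (man$kind == "pn")
    structure(list(data = d, latent = latent, n2_t = man$n2, n1_t = man$n1,
                   params = params), class = "pn_data")
  else
    structure(list(data = d, latent = latent, design = man$design,
                   n2 = man$n2, n1 = man$n1, params = params),
              class = "mlsem_data")
}

#' Read a Monte Carlo study configuration from JSON
#'
#' The configuration mirrors the [run_study()] argument: fields `designs`,
#' `grid` (records with `n2`, `n1`), `R`, `seed`, `estimators`, optional
#' `params` and `out_dir`.
#'
#' @param path path to a JSON file.
#' @return A config list suitable for [run_study()].
#' @export
read_study_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("designs", "grid")
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    stop("study config is missing field(s): ", paste(miss, collapse = ", "))
  cfg$grid <- as.data.frame(cfg$grid)
  if (!all(c("n2", "n1") %in% names(cfg$grid)))
    stop("study config field `grid` needs `n2` and `n1` columns")
  cfg
}
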
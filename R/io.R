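# Disk formats: YAML pipeline configuration, NIfTI maps with a JSON
# provenance sidecar, CSV loss curves, and .rds containers for k-space and
# image intermediates.

#' Read / write a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML; every pipeline run can
#' write its resolved configuration next to its outputs.
#'
#' @param config Named list (as stored in a `cmrf_fit$config`).
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write the maps of a fit to disk
#'
#' One NIfTI per map (relaxation times in ms, PDFF unitless; complex spin
#' densities are written as magnitude), plus `provenance.json` (method,
#' configuration, seed) and, for iterative methods, `loss.csv`.
#'
#' @param fit A `cmrf_fit`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cmrf_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- fit$config$fov_mm / fit$config$matrix
  for (nm in names(fit$maps)) {
    m <- fit$maps[[nm]]
    if (is.complex(m)) m <- abs(m)
    img <- RNifti::asNifti(array(m, c(dim(m), 1)), pixdim = c(vox, vox, 1))
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  jsonlite::write_json(list(method = fit$method, config = fit$config,
                            runtime_s = fit$runtime_s),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_config(fit$config, file.path(dir, "config.yaml"))
  curve <- fit$loss %||% fit$objective
  if (!is.null(curve))
    utils::write.csv(data.frame(iteration = seq_along(curve), loss = curve),
                     file.path(dir, "loss.csv"), row.names = FALSE)
  if (!is.null(fit$summary))
    utils::write.csv(fit$summary, file.path(dir, "roi_summary.csv"),
                     row.names = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a k-space container
#'
#' Runtime container for simulated or measured k-space (R serialization; the
#' plain-text interchange formats of the package are the trajectory CSV/JSON
#' and the YAML configuration).
#' @param kspace A `cmrf_kspace`.
#' @param path File path (.rds).
#' @export
write_kspace <- function(kspace, path) {
  saveRDS(kspace, path)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) readRDS(path)
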
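#' Read a 4D BOLD NIfTI volume with its mask
#'
#' @param bold_path Path to a 4D NIfTI file.
#' @param mask_path Path to a 3D brain-mask NIfTI on the same grid
#'   (`NULL` for all voxels).
#' @param tr Repetition time (s); taken from the NIfTI header `pixdim`
#'   when available, else this value.
#' @return A `bold_dataset` list (`data`: volumes x in-mask voxels,
#'   `dims`, `mask`, `tr`) compatible with [first_level()].
#' @export
read_bold <- function(bold_path, mask_path = NULL, tr = 0.72) {
  img <- RNifti::readNifti(bold_path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D BOLD image", call. = FALSE)
  dims <- d[1:3]
  hdr_tr <- tryCatch(RNifti::pixdim(img)[4], error = function(e) NA_real_)
  if (is.finite(hdr_tr) && hdr_tr > 0) tr <- hdr_tr
  mask <- if (is.null(mask_path)) array(TRUE, dims) else {
    m <- RNifti::readNifti(mask_path)
    if (!identical(dim(m)[1:3], dims))
      stop("mask grid does not match the BOLD grid", call. = FALSE)
    array(m > 0, dims)
  }
  mat <- matrix(img, prod(dims), d[4])
  list(data = t(mat[which(mask), , drop = FALSE]), dims = dims,
       mask = mask, tr = tr)
}

#' Write a statistic vector over in-mask voxels as a 3D NIfTI map
#'
#' @param values Vector over in-mask voxels (e.g. `z` or `beta` from a
#'   `level_result`).
#' @param mask Logical 3D array defining the in-mask voxels.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_size Isotropic voxel size (mm) recorded in the header.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(values, mask, path, voxel_size = 2) {
  vol <- array(0, dim(mask))
  vol[which(mask)] <- values
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a synthetic BOLD dataset to NIfTI (data, mask and truth)
#'
#' @param bold A [synth_bold()] dataset.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_bold <- function(bold, dir, prefix = "bold") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- bold$dims
  n_t <- nrow(bold$data)
  vol4 <- array(0, c(dims, n_t))
  flat <- matrix(0, prod(dims), n_t)
  flat[which(bold$mask), ] <- t(bold$data)
  vol4[] <- flat
  paths <- c(
    bold = file.path(dir, paste0(prefix, ".nii.gz")),
    mask = file.path(dir, paste0(prefix, "_mask.nii.gz")))
  img <- RNifti::asNifti(vol4)
  RNifti::pixdim(img) <- c(2, 2, 2, bold$tr)
  RNifti::writeNifti(img, paths["bold"])
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(bold$mask), dims)),
                     paths["mask"])
  if (!is.null(bold$truth$active_mask)) {
    paths["truth"] <- file.path(dir, paste0(prefix, "_truth_synthetic.nii.gz"))
    RNifti::writeNifti(
      RNifti::asNifti(array(as.numeric(bold$truth$active_mask), dims)),
      paths["truth"])
  }
  invisible(paths)
}

#' Write a fitted trajectory as CSV
#'
#' Columns: `t`, `g0`, `g1_0..g1_J`, `xi0`, `mu_hp`, `loglik`,
#' `converged`; the fit configuration is echoed to a JSON side file.
#'
#' @param fit A fitted [pphrv()] model.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(fit, path) {
  df <- data.frame(t = fit$times, g0 = fit$g0)
  df <- cbind(df, as.data.frame(fit$g1))
  df$xi0 <- fit$xi0
  df$mu_hp <- fit$mu_hp
  df$loglik <- fit$loglik
  df$converged <- fit$converged
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(fit$config, sub("\\.csv$", "_config.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
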
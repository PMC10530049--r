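#' Write a dynamic series or map as NIfTI-1
#'
#' Writes a 3D map or a 4D (row, col, slice, frame) series with the voxel
#' geometry of the protocol (in-plane size of the common matrix, slice
#' thickness, TR on the fourth dimension).
#'
#' @param x Numeric 3D or 4D array.
#' @param path Output file path (".nii" or ".nii.gz").
#' @param protocol Optional \code{hp_protocol} supplying voxel sizes.
#' @param in_plane_mm In-plane voxel size (mm) when no protocol is given.
#' @return The path, invisibly.
#' @export
write_series_nifti <- function(x, path, protocol = NULL, in_plane_mm = 7.5) {
  nd <- length(dim(x))
  stopifnot(nd %in% c(3, 4))
  pix <- c(in_plane_mm, in_plane_mm, 30, if (nd == 4) 3)
  if (!is.null(protocol))
    pix <- c(rep(min(protocol$channels$in_plane_mm), 2),
             protocol$slice_thickness_cm * 10, if (nd == 4) protocol$tr)
  img <- RNifti::asNifti(x, pixdim = pix)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI series written by \code{write_series_nifti}
#' @param path File path.
#' @return Numeric array.
#' @export
read_series_nifti <- function(path) {
  x <- RNifti::readNifti(path)
  array(as.numeric(x), dim(x))
}

#' Write phantom ground truth to a directory
#'
#' Rate, delivery and tissue-fraction maps go to NIfTI files; scalar
#' parameters (bolus, doublet asymmetry, noise sigma, seed) to JSON; coil
#' sensitivities to NIfTI as separate real/imaginary volumes.
#'
#' @param truth An \code{hp_phantom_truth}.
#' @param dir Output directory (created if needed).
#' @param protocol Optional protocol for voxel geometry.
#' @return \code{dir}, invisibly.
#' @export
write_truth <- function(truth, dir, protocol = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series_nifti(truth$kpl_map, file.path(dir, "kpl_truth.nii.gz"), protocol)
  write_series_nifti(truth$kpg_map, file.path(dir, "kpg_truth.nii.gz"), protocol)
  write_series_nifti(truth$delivery_map,
                     file.path(dir, "delivery.nii.gz"), protocol)
  fr <- truth$tissue_fractions
  for (nm in dimnames(fr)[[4]])
    write_series_nifti(array(fr[, , , nm], dim(fr)[1:3]),
                       file.path(dir, paste0("fraction_", nm, ".nii.gz")),
                       protocol)
  sens <- truth$coil_sensitivities
  write_series_nifti(aperm(Re(sens), c(2, 3, 4, 1)),
                     file.path(dir, "coil_sens_real.nii.gz"), protocol)
  write_series_nifti(aperm(Im(sens), c(2, 3, 4, 1)),
                     file.path(dir, "coil_sens_imag.nii.gz"), protocol)
  pars <- list(bolus = truth$bolus_params,
               doublet_asymmetry = truth$doublet_asymmetry,
               noise_sigma = truth$noise_sigma, seed = truth$seed)
  jsonlite::write_json(pars, file.path(dir, "truth_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write pipeline results to a directory
#'
#' Rate and AUC-ratio maps as NIfTI; the report, rate summary, ratio
#' summary and noise covariance (real/imaginary parts) as CSV; the stage
#' log as a text file.
#'
#' @param result An \code{hp_result} from \code{\link{run_pipeline}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proto <- result$dataset$stack$protocol
  for (nm in names(result$rates$maps))
    write_series_nifti(result$rates$maps[[nm]],
                       file.path(dir, paste0(nm, ".nii.gz")), proto)
  for (nm in names(result$ratios$maps))
    write_series_nifti(result$ratios$maps[[nm]],
                       file.path(dir, paste0("auc_ratio_", nm, ".nii.gz")),
                       proto)
  utils::write.csv(result$report, file.path(dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$rates$summary, file.path(dir, "rates_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$ratios$summary, file.path(dir, "ratios_summary.csv"),
                   row.names = FALSE)
  if (!is.null(result$qc$covariance)) {
    C <- result$qc$covariance$matrix
    utils::write.csv(Re(C), file.path(dir, "noise_cov_real.csv"),
                     row.names = FALSE)
    utils::write.csv(Im(C), file.path(dir, "noise_cov_imag.csv"),
                     row.names = FALSE)
  }
  writeLines(result$log, file.path(dir, "pipeline_log.txt"))
  invisible(dir)
}
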
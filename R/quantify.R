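#' Area-under-curve map
#'
#' Per-voxel sum of the dynamic signal over all timeframes.
#'
#' @param series Array with frames on the last dimension (e.g.
#'   row, col, slice, frame).
#' @return Array with the frame dimension summed out.
#' @export
auc_map <- function(series) {
  dm <- dim(series)
  if (is.null(dm) || length(dm) < 2) stop("series needs a frame dimension")
  nd <- length(dm)
  apply(series, seq_len(nd - 1), sum)
}

#' Normalize all channels to the global peak pyruvate signal
#'
#' Divides every channel by the maximum pyruvate signal over all voxels,
#' slices and frames ("global" peak), so the pyruvate peak maps to 1.
#'
#' @param series_by_channel Named list of 4D arrays (row, col, slice,
#'   frame) including \code{pyruvate}.
#' @return List of the same shape, normalized.
#' @export
normalize_to_peak_pyruvate <- function(series_by_channel) {
  if (is.null(series_by_channel$pyruvate)) stop("pyruvate channel required")
  pk <- max(series_by_channel$pyruvate)
  if (pk <= 0) stop("pyruvate channel is all zero or nonpositive")
  lapply(series_by_channel, function(a) a / pk)
}

#' Sum the lactate doublet
#'
#' Voxelwise combination of the individually processed downfield and
#' upfield lactate series into the total lactate observable. With the
#' default \code{asymmetry = 1} this is the plain voxelwise sum. Supplying
#' the doublet amplitude asymmetry (upfield/downfield amplitude ratio,
#' e.g. from \code{\link{doublet_asymmetry_estimate}}) rescales the upfield
#' channel so the total recovers the full lactate amplitude:
#' down + up / asymmetry.
#'
#' @param down_series,up_series Arrays of identical dimensions.
#' @param asymmetry Upfield/downfield amplitude ratio in (0, 1]; 1 gives
#'   the plain sum.
#' @return Combined total lactate array.
#' @export
sum_lactate_doublet <- function(down_series, up_series, asymmetry = 1) {
  if (!all(dim(down_series) == dim(up_series)))
    stop("doublet series dimensions differ")
  if (asymmetry <= 0 || asymmetry > 1) stop("asymmetry must lie in (0, 1]")
  down_series + up_series / asymmetry
}

#' Estimate the lactate doublet amplitude asymmetry from data
#'
#' Least-squares slope through the origin of the upfield versus downfield
#' AUC over the masked voxels: with the excitation-band amplitude model
#' up = asymmetry * down, the slope is the asymmetry. Used to correct the
#' doublet summation for the amplitude lost on the upfield peak.
#'
#' @param down_auc,up_auc AUC arrays of the two doublet channels.
#' @param mask Logical array of voxels to use (e.g. brain mask).
#' @return Estimated asymmetry, clamped to (0, 1].
#' @export
doublet_asymmetry_estimate <- function(down_auc, up_auc, mask) {
  d <- down_auc[mask]; u <- up_auc[mask]
  den <- sum(d^2)
  if (den == 0) stop("downfield AUC is zero over the mask")
  min(max(sum(d * u) / den, .Machine$double.eps), 1)
}

#' Structural similarity index (SSIM) of two images
#'
#' Windowed SSIM with the standard constants K1 = 0.01, K2 = 0.03, an
#' 11 x 11 Gaussian window of sd 1.5 pixels (truncated and renormalized at
#' the image borders), and dynamic range equal to the joint maximum unless
#' given. Returns the mean SSIM over the mask.
#'
#' @param a,b Numeric matrices of identical size.
#' @param mask Optional logical matrix: average SSIM over these pixels only.
#' @param dynamic_range Dynamic range L; default \code{max(a, b)}.
#' @param window_size,window_sigma Gaussian window parameters.
#' @return Mean SSIM (in [-1, 1]).
#' @export
ssim_index <- function(a, b, mask = NULL, dynamic_range = NULL,
                       window_size = 11, window_sigma = 1.5) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  if (is.null(dynamic_range)) dynamic_range <- max(a, b)
  if (dynamic_range <= 0) dynamic_range <- 1
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  W <- .gauss_weight_matrices(dim(a), window_size, window_sigma)
  smooth <- function(x) W$R %*% x %*% W$C
  mu_a <- smooth(a); mu_b <- smooth(b)
  va <- smooth(a * a) - mu_a^2
  vb <- smooth(b * b) - mu_b^2
  vab <- smooth(a * b) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  if (is.null(mask)) mean(ssim_map) else mean(ssim_map[mask])
}

# Row/column Gaussian weighting matrices for separable local averaging with
# border truncation + renormalization (weights at each pixel sum to 1).
.gauss_weight_matrices <- function(dm, window_size, window_sigma) {
  half <- (window_size - 1) %/% 2
  kern <- exp(-((-half):half)^2 / (2 * window_sigma^2))
  band <- function(n) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - half):min(n, i + half)
      M[i, j] <- kern[j - i + half + 1]
      M[i, ] <- M[i, ] / sum(M[i, ])
    }
    M
  }
  list(R = band(dm[1]), C = t(band(dm[2])))
}

#' Doublet agreement QC: Pearson correlation and SSIM
#'
#' Quantifies the agreement between the downfield and upfield lactate AUC
#' images: Pearson r over the masked voxels (all slices pooled) and SSIM
#' (standard constants, joint-maximum dynamic range) computed per 2D slice
#' and averaged over the mask.
#'
#' @param down_auc,up_auc 3D AUC arrays (row, col, slice).
#' @param mask Logical 3D array with at least 2 TRUE voxels.
#' @return List with \code{pearson_r} (NA with a warning if either image is
#'   constant over the mask) and \code{ssim}.
#' @export
doublet_agreement <- function(down_auc, up_auc, mask) {
  stopifnot(all(dim(down_auc) == dim(up_auc)), all(dim(mask) == dim(down_auc)))
  if (sum(mask) < 2) stop("need at least 2 masked voxels")
  x <- down_auc[mask]; y <- up_auc[mask]
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant image over mask: Pearson r undefined")
    NA_real_
  } else stats::cor(x, y)
  L <- max(down_auc, up_auc)
  ns <- dim(down_auc)[3]
  ssims <- numeric(0)
  for (s in seq_len(ns)) {
    ms <- mask[, , s]
    if (!any(ms)) next
    ssims <- c(ssims, ssim_index(down_auc[, , s], up_auc[, , s], mask = ms,
                                 dynamic_range = L))
  }
  list(pearson_r = r, ssim = mean(ssims))
}

#' Per-voxel SNR of the AUC image
#'
#' SNR_AUC = AUC / (sigma * sqrt(n_frames)): the AUC of white noise of
#' standard deviation sigma summed over n_frames frames has standard
#' deviation sigma * sqrt(n_frames).
#'
#' @param auc AUC array.
#' @param noise_sigma Per-frame noise standard deviation (> 0).
#' @param n_frames Number of frames summed into the AUC.
#' @return Array of SNR_AUC values.
#' @export
snr_auc_map <- function(auc, noise_sigma, n_frames) {
  if (noise_sigma <= 0) stop("noise_sigma must be positive")
  auc / (noise_sigma * sqrt(n_frames))
}

#' Brain mask from tissue fractions
#'
#' Voxels containing more than \code{gm_wm_min} combined gray- and
#' white-matter fraction are included.
#'
#' @param tissue_fractions 4D array (row, col, slice, tissue) with tissues
#'   named \code{gm} and \code{wm} among the fourth-dimension names, or a
#'   3D array already holding the GM+WM fraction.
#' @param gm_wm_min Inclusion threshold (default 0.40).
#' @return List of class \code{hp_brain_mask}: \code{include} logical array,
#'   \code{gm_wm_fraction}.
#' @export
brain_mask <- function(tissue_fractions, gm_wm_min = 0.40) {
  dm <- dim(tissue_fractions)
  gmwm <- if (length(dm) == 4) {
    nms <- dimnames(tissue_fractions)[[4]]
    if (is.null(nms) || !all(c("gm", "wm") %in% nms))
      stop("tissue dimension must name gm and wm")
    array(tissue_fractions[, , , "gm"] + tissue_fractions[, , , "wm"], dm[1:3])
  } else tissue_fractions
  structure(list(include = gmwm > gm_wm_min, gm_wm_fraction = gmwm,
                 gm_wm_min = gm_wm_min),
            class = "hp_brain_mask")
}

#' Apply a brain mask to maps
#'
#' Sets voxels outside the mask (GM+WM fraction at or below the threshold)
#' to NA.
#'
#' @param maps A single array or a named list of arrays on the mask grid.
#' @param mask An \code{hp_brain_mask} or logical array.
#' @return Masked array or list of arrays.
#' @export
apply_brain_mask <- function(maps, mask) {
  inc <- if (inherits(mask, "hp_brain_mask")) mask$include else mask
  mask_one <- function(a) {
    a[!inc] <- NA
    a
  }
  if (is.list(maps)) lapply(maps, mask_one) else mask_one(maps)
}

#' Masked AUC ratio maps and summaries
#'
#' Voxelwise metabolite AUC ratios (lactate/pyruvate, glutamate/pyruvate,
#' glutamate/lactate), defined only where the denominator passes the
#' SNR_AUC threshold, with masked means and standard errors.
#'
#' @param auc Named list of AUC arrays: \code{pyruvate}, \code{lactate}
#'   (doublet-summed), \code{glutamate}.
#' @param mask Logical array or \code{hp_brain_mask}.
#' @param snr_auc Optional named list of SNR_AUC maps used to gate the
#'   denominators (and numerators) at \code{snr_auc_min}; NULL disables.
#' @param snr_auc_min Threshold (default 3).
#' @return List with \code{maps} (three ratio arrays, NA where undefined)
#'   and \code{summary} data.frame (ratio, mean, se, n).
#' @export
auc_ratios <- function(auc, mask, snr_auc = NULL, snr_auc_min = 3) {
  inc <- if (inherits(mask, "hp_brain_mask")) mask$include else mask
  ok <- function(ch) {
    if (is.null(snr_auc)) array(TRUE, dim(auc[[ch]]))
    else snr_auc[[ch]] > snr_auc_min
  }
  pairs <- list(lac_pyr = c("lactate", "pyruvate"),
                glu_pyr = c("glutamate", "pyruvate"),
                glu_lac = c("glutamate", "lactate"))
  maps <- list()
  rows <- list()
  for (nm in names(pairs)) {
    num <- pairs[[nm]][1]; den <- pairs[[nm]][2]
    valid <- inc & ok(num) & ok(den) & auc[[den]] != 0
    r <- array(NA_real_, dim(auc[[num]]))
    r[valid] <- auc[[num]][valid] / auc[[den]][valid]
    maps[[nm]] <- r
    v <- r[valid]
    rows[[nm]] <- data.frame(ratio = nm,
                             mean = if (length(v)) mean(v) else NA_real_,
                             se = if (length(v) > 1)
                               stats::sd(v) / sqrt(length(v)) else NA_real_,
                             n = length(v))
  }
  list(maps = maps, summary = do.call(rbind, rows))
}

#' Two-fold Fourier zero-filling (display only)
#'
#' Interpolates each in-plane image two-fold by zero-padding its centred
#' 2D discrete Fourier spectrum. Used only for display; all quantification
#' operates on the acquired grid.
#'
#' @param img Numeric matrix.
#' @return Matrix of twice the size per in-plane dimension.
#' @export
zero_fill_display <- function(img) {
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  F <- stats::fft(img)
  # centre the spectrum, pad, and shift back
  sh <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))
  Fc <- F[sh(nr), sh(nc)]
  pad <- matrix(0i, 2 * nr, 2 * nc)
  pad[(nr - floor(nr / 2) + 1):(nr - floor(nr / 2) + nr),
      (nc - floor(nc / 2) + 1):(nc - floor(nc / 2) + nc)] <- Fc
  ish <- function(n) c((n - floor(n / 2) + 1):n, 1:(n - floor(n / 2)))
  big <- pad[ish(2 * nr), ish(2 * nc)]
  4 * Re(stats::fft(big, inverse = TRUE)) / length(big)
}
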
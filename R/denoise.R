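#' Robust noise standard deviation estimate
#'
#' Scaled median absolute deviation of designated signal-free samples
#' (noise-only region or pre-bolus frames) of a phased real-valued series.
#'
#' @param x Numeric array or vector of signal-free samples.
#' @return Estimated noise standard deviation (0 for all-zero input).
#' @export
estimate_sigma <- function(x) {
  x <- as.vector(x)
  if (length(x) == 0) stop("empty noise region")
  stats::mad(x)
}

#' Denoising parameters for the patch HOSVD method
#'
#' The study's parameterization: threshold scales \code{k_global} = 0.4 and
#' \code{k_local} = 0.8, reference-patch stride \code{step} = 2, and, per
#' resolution class, patch size 3 with search radius 4 (low resolution,
#' metabolites) or patch size 5 with search radius 6 (high resolution,
#' pyruvate).
#'
#' @param resolution \code{"low"} or \code{"high"}: selects the patch size /
#'   search radius pair.
#' @param sigma Noise standard deviation of the series (signal units);
#'   estimate with \code{\link{estimate_sigma}}. \code{sigma = 0} makes
#'   denoising the identity.
#' @param k_global,k_local Unitless threshold scales.
#' @param step Reference-grid stride in voxels (>= 1).
#' @param group_size Maximum number of similar patches stacked per group.
#' @param patch_size,search_radius Override the resolution-class defaults
#'   (voxels).
#' @return List of class \code{hp_denoise_params}.
#' @export
denoise_params <- function(resolution = c("low", "high"), sigma = NULL,
                           k_global = 0.4, k_local = 0.8, step = 2,
                           group_size = 32, patch_size = NULL,
                           search_radius = NULL) {
  resolution <- match.arg(resolution)
  if (is.null(patch_size))
    patch_size <- if (resolution == "low") 3L else 5L
  if (is.null(search_radius))
    search_radius <- if (resolution == "low") 4L else 6L
  stopifnot(k_global > 0, k_local >= 0, step >= 1, group_size >= 1,
            patch_size >= 1, search_radius >= patch_size / 2)
  structure(list(resolution = resolution, sigma = sigma,
                 k_global = k_global, k_local = k_local, step = as.integer(step),
                 group_size = as.integer(group_size),
                 patch_size = as.integer(patch_size),
                 search_radius = as.integer(search_radius)),
            class = "hp_denoise_params")
}

# mode-k unfolding / folding / tensor-times-matrix for 3rd-order tensors
.unfold <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(x, perm), d[mode], prod(d[-mode]))
}
.fold <- function(m, mode, dims) {
  perm <- c(mode, setdiff(1:3, mode))
  aperm(array(m, dims[perm]), order(perm))
}
.ttm <- function(x, M, mode) {
  d <- dim(x)
  out <- M %*% .unfold(x, mode)
  d[mode] <- nrow(M)
  .fold(out, mode, d)
}

# HOSVD of a 3rd-order tensor with hard thresholding of the core.
# Returns the reconstruction and the number of retained core coefficients.
.hosvd_shrink <- function(x, tau) {
  d <- dim(x)
  U <- lapply(1:3, function(m) {
    xm <- .unfold(x, m)
    svd(xm, nu = min(dim(xm)), nv = 0)$u
  })
  S <- .ttm(.ttm(.ttm(x, t(U[[1]]), 1), t(U[[2]]), 2), t(U[[3]]), 3)
  keep <- abs(S) >= tau
  S[!keep] <- 0
  rec <- .ttm(.ttm(.ttm(S, U[[1]], 1), U[[2]], 2), U[[3]], 3)
  list(rec = rec, n_retained = sum(keep))
}

#' Patch-based higher-order SVD denoising of a dynamic series
#'
#' Denoises one metabolite's (row, col, slice, frame) series. An optional
#' preliminary global pass thresholds the singular values of the full
#' series' space x time unfolding at
#' \eqn{\tau_g = k_{global}\,\sigma\sqrt{2\ln N_{total}}}. The main local
#' pass then proceeds slice by slice (slices are spatially decoupled): for
#' each reference patch position on a stride-\code{step} grid, the spatial
#' patches (all frames) inside the search window are ranked by Euclidean
#' distance to the reference patch, the most similar \code{group_size} are
#' stacked into a 3rd-order tensor (patch-pixels x frames x group), its
#' HOSVD core is hard-thresholded at
#' \eqn{\tau_l = k_{local}\,\sigma\sqrt{2\ln N_{tensor}}}, and the group is
#' reconstructed. Overlapping reconstructions are aggregated by weighted
#' averaging with weights inversely proportional to the retained-coefficient
#' count of their group.
#'
#' @param series 4D numeric array (row, col, slice, frame), phased
#'   real-valued data.
#' @param params An \code{hp_denoise_params} with \code{sigma} set.
#' @param global_pass Run the preliminary global SVD pass (default TRUE).
#' @param global_first If TRUE (default) the global pass precedes the local
#'   pass; the published order is not specified, so it is configurable.
#' @return Denoised array of the same dimensions, with attribute
#'   \code{"retained_fraction"}: mean fraction of core coefficients kept
#'   across patch groups.
#' @export
hosvd_denoise <- function(series, params, global_pass = TRUE,
                          global_first = TRUE) {
  stopifnot(inherits(params, "hp_denoise_params"))
  dm <- dim(series)
  if (length(dm) != 4) stop("series must be (row, col, slice, frame)")
  p <- params$patch_size
  if (p > min(dm[1:2])) stop("patch larger than image plane")
  sigma <- params$sigma
  if (is.null(sigma)) stop("params$sigma must be set (see estimate_sigma)")
  if (sigma == 0) return(series)

  run_global <- function(x) {
    tau <- params$k_global * sigma * sqrt(2 * log(length(x)))
    m <- matrix(x, prod(dm[1:3]), dm[4])
    sv <- svd(m)
    d <- sv$d
    d[d < tau] <- 0
    array(sv$u %*% (d * t(sv$v)), dm)
  }
  run_local <- function(x) {
    tau <- params$k_local * sigma *
      sqrt(2 * log(p * p * dm[4] * params$group_size))
    acc <- array(0, dm)
    wacc <- array(0, dm)
    kept <- c()
    npos_r <- dm[1] - p + 1
    npos_c <- dm[2] - p + 1
    refs_r <- unique(c(seq(1, npos_r, by = params$step), npos_r))
    refs_c <- unique(c(seq(1, npos_c, by = params$step), npos_c))
    for (s in seq_len(dm[3])) {
      # all patch vectors of this slice, one column per top-left position
      pat <- matrix(0, p * p * dm[4], npos_r * npos_c)
      for (cc in seq_len(npos_c)) for (rr in seq_len(npos_r))
        pat[, rr + (cc - 1) * npos_r] <-
          series[rr:(rr + p - 1), cc:(cc + p - 1), s, ]
      for (r0 in refs_r) for (c0 in refs_c) {
        rw <- max(1, r0 - params$search_radius):min(npos_r, r0 + params$search_radius)
        cw <- max(1, c0 - params$search_radius):min(npos_c, c0 + params$search_radius)
        cand <- as.matrix(expand.grid(rr = rw, cc = cw))
        ref_vec <- pat[, r0 + (c0 - 1) * npos_r]
        d2 <- colSums((pat[, cand[, 1] + (cand[, 2] - 1) * npos_r] - ref_vec)^2)
        ord <- order(d2)[seq_len(min(params$group_size, nrow(cand)))]
        grp <- cand[ord, , drop = FALSE]
        X <- array(pat[, grp[, 1] + (grp[, 2] - 1) * npos_r],
                   c(p * p, dm[4], nrow(grp)))
        hs <- .hosvd_shrink(X, tau)
        kept <- c(kept, hs$n_retained / length(X))
        w <- 1 / (1 + hs$n_retained)
        for (g in seq_len(nrow(grp))) {
          ri <- grp[g, 1]:(grp[g, 1] + p - 1)
          ci <- grp[g, 2]:(grp[g, 2] + p - 1)
          acc[ri, ci, s, ] <- acc[ri, ci, s, ] +
            w * array(hs$rec[, , g], c(p, p, dm[4]))
          wacc[ri, ci, s, ] <- wacc[ri, ci, s, ] + w
        }
      }
    }
    covered <- wacc > 0
    out <- x
    out[covered] <- acc[covered] / wacc[covered]
    attr(out, "retained_fraction") <- mean(kept)
    out
  }

  if (global_pass && global_first) series <- run_global(series)
  series <- run_local(series)
  rf <- attr(series, "retained_fraction")
  if (global_pass && !global_first) series <- run_global(series)
  attr(series, "retained_fraction") <- rf
  series
}

#' SNR gain of denoising
#'
#' Ratio of peak-signal-to-noise-std after denoising to that before, with
#' the peak taken over a fixed signal ROI (all frames) and the noise
#' standard deviation over a disjoint noise ROI.
#'
#' @param before,after 4D arrays (row, col, slice, frame) of the raw and
#'   denoised series.
#' @param signal_roi,noise_roi Logical 3D masks (disjoint).
#' @return Unitless SNR gain factor.
#' @export
snr_gain <- function(before, after, signal_roi, noise_roi) {
  stopifnot(all(dim(before) == dim(after)))
  if (any(signal_roi & noise_roi)) stop("ROIs must be disjoint")
  nf <- dim(before)[4]
  sel <- function(x, roi) {
    m <- matrix(x, length(roi), nf)
    m[as.vector(roi), , drop = FALSE]
  }
  sd_b <- stats::sd(sel(before, noise_roi))
  sd_a <- stats::sd(sel(after, noise_roi))
  if (sd_b == 0 || sd_a == 0) stop("noise ROI has zero standard deviation")
  (max(sel(after, signal_roi)) / sd_a) / (max(sel(before, signal_roi)) / sd_b)
}
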
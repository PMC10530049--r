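#' Estimate the inter-coil noise covariance
#'
#' Sample covariance of the complex coil noise from signalless samples (the
#' end-of-scan pyruvate frames in vivo; the appended pure-noise block of the
#' phantom). Hermitian by construction.
#'
#' @param noise_frames Complex matrix, coils x samples, signal-free.
#' @return Object of class \code{hp_noise_cov}: \code{matrix} (coil x coil
#'   complex Hermitian PSD), \code{n_samples}.
#' @export
estimate_noise_covariance <- function(noise_frames) {
  if (is.null(dim(noise_frames)))
    noise_frames <- matrix(noise_frames, nrow = 1)
  n_coils <- nrow(noise_frames)
  n <- ncol(noise_frames)
  if (n < 2) stop("need at least 2 noise samples per coil")
  if (n < n_coils)
    warning("fewer noise samples than coils: covariance is rank-deficient")
  x <- noise_frames - rowMeans(noise_frames)
  C <- (x %*% Conj(t(x))) / (n - 1)
  C <- (C + Conj(t(C))) / 2  # enforce exact Hermitian symmetry
  structure(list(matrix = C, n_samples = n), class = "hp_noise_cov")
}

#' @export
print.hp_noise_cov <- function(x, ...) {
  cat(sprintf("Noise covariance: %d coils from %d samples, mean diag %.4g\n",
              nrow(x$matrix), x$n_samples, mean(Re(diag(x$matrix)))))
  invisible(x)
}

# Cholesky factor L (lower triangular, L L^H = C) of a complex Hermitian
# positive-definite matrix; base chol() does not handle complex input.
.complex_chol <- function(C) {
  n <- nrow(C)
  L <- matrix(0i, n, n)
  for (j in seq_len(n)) {
    s <- Re(C[j, j]) - sum(Mod(L[j, seq_len(j - 1)])^2)
    if (s <= 0) stop("matrix is not positive definite")
    L[j, j] <- sqrt(s)
    if (j < n) for (i in (j + 1):n) {
      acc <- C[i, j]
      if (j > 1) acc <- acc - sum(L[i, 1:(j - 1)] * Conj(L[j, 1:(j - 1)]))
      L[i, j] <- acc / L[j, j]
    }
  }
  L
}

#' Prewhiten a coil stack
#'
#' Multiplies the per-coil data (and the noise samples) by the inverse
#' Cholesky factor of the noise covariance, after diagonal loading of
#' \code{loading * trace(C)/n} for numerical robustness, so the transformed
#' coil noise is independent with unit variance per complex component.
#'
#' @param stack An \code{hp_coil_stack}.
#' @param covariance An \code{hp_noise_cov} (e.g. from
#'   \code{\link{estimate_noise_covariance}}).
#' @param loading Relative diagonal loading (default 1e-6).
#' @return A prewhitened \code{hp_coil_stack}.
#' @export
prewhiten <- function(stack, covariance, loading = 1e-6) {
  stopifnot(inherits(stack, "hp_coil_stack"),
            inherits(covariance, "hp_noise_cov"))
  C <- covariance$matrix
  n <- nrow(C)
  C <- C + diag(loading * sum(Re(diag(C))) / n, n)
  L <- tryCatch(.complex_chol(C), error = function(e)
    stop("noise covariance is singular; increase diagonal loading"))
  Linv <- solve(L)
  dm <- dim(stack$data)
  flat <- matrix(stack$data, n, prod(dm[-1]))
  stack$data <- array(Linv %*% flat, dm)
  stack$noise_frames <- Linv %*% stack$noise_frames
  stack$whitened <- TRUE
  stack
}

#' SVD-based optimal coil combination
#'
#' Combines prewhitened per-coil complex data into one series per channel.
#' Per voxel, the sensitivity weight vector is the dominant left singular
#' vector of the coil x frame matrix of the reference (highest-SNR,
#' pyruvate) channel; the unit-norm weights are shared across all channels,
#' since the metabolite channels are too low-SNR to self-derive
#' sensitivities. The weight phase is referenced to the strongest coil so
#' the output phase is well defined.
#'
#' @param stack A (prewhitened) \code{hp_coil_stack}.
#' @param ref_channel Channel used to derive the weights.
#' @return Complex array (row, col, slice, frame, channel) of class
#'   \code{hp_series} with the channel names in \code{dimnames}.
#' @export
coil_combine <- function(stack, ref_channel = "pyruvate") {
  stopifnot(inherits(stack, "hp_coil_stack"))
  dm <- dim(stack$data)
  n_coils <- dm[1]
  ref <- match(ref_channel, stack$channel_names)
  if (is.na(ref)) stop("unknown reference channel: ", ref_channel)
  out <- array(0i, dm[-1])
  dimnames(out) <- list(NULL, NULL, NULL, NULL, stack$channel_names)
  for (s in seq_len(dm[4])) for (j in seq_len(dm[3])) for (i in seq_len(dm[2])) {
    M <- matrix(stack$data[, i, j, s, , ref], n_coils, dm[5])
    if (all(M == 0)) next  # all-zero voxel: combined value stays 0
    w <- svd(M, nu = 1, nv = 0)$u[, 1]
    kmax <- which.max(Mod(w))
    w <- w * exp(-1i * Arg(w[kmax]))
    for (ch in seq_len(dm[6]))
      out[i, j, s, , ch] <- crossprod(Conj(w),
                                      matrix(stack$data[, i, j, s, , ch],
                                             n_coils, dm[5]))
  }
  structure(out, class = c("hp_series", class(out)))
}

#' Zeroth-order phase correction
#'
#' Per voxel and channel, rotates the complex time course by the phase of
#' its temporal-peak frame (maximizing the real part at the peak) and
#' returns the real channel. The noise floor in signalless regions remains
#' zero-mean.
#'
#' @param combined Complex array (row, col, slice, frame, channel) from
#'   \code{\link{coil_combine}}, or a 4D single-channel array.
#' @return Real array of the same dimensions.
#' @export
phase_correct <- function(combined) {
  dm <- dim(combined)
  single <- length(dm) == 4
  if (single) dim(combined) <- c(dm, 1)
  dm5 <- dim(combined)
  out <- array(0, dm5, dimnames = dimnames(combined))
  for (ch in seq_len(dm5[5])) for (s in seq_len(dm5[3]))
    for (j in seq_len(dm5[2])) for (i in seq_len(dm5[1])) {
      x <- combined[i, j, s, , ch]
      if (all(x == 0)) next
      pk <- which.max(Mod(x))
      out[i, j, s, , ch] <- Re(x * exp(-1i * Arg(x[pk])))
    }
  if (single) dim(out) <- dm
  out
}
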
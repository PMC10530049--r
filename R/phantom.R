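#' Acquisition protocol for dynamic multi-metabolite 13C EPI
#'
#' Describes the multi-resolution acquisition: a fine-grid pyruvate channel
#' (7.5 x 7.5 mm in-plane, 20 deg nominal flip) and coarse-grid glutamate and
#' lactate-doublet channels (22.5 x 22.5 mm, 60 deg), five 3-cm slices on a
#' 32 x 32 common matrix, 20 timeframes at 3 s temporal resolution. The
#' coarse channels are simulated on a grid \code{coarse_factor} times coarser
#' and replicated onto the common matrix (nearest neighbour), keeping all
#' channels on one voxel grid as voxelwise ratios require.
#'
#' @param n_frames Number of timeframes (>= 2).
#' @param tr Temporal resolution (s).
#' @param matrix Common in-plane matrix size, c(rows, cols).
#' @param n_slices Number of slices.
#' @param slice_thickness_cm Slice thickness (cm).
#' @param coarse_factor Integer ratio of coarse to fine voxel size.
#' @return Object of class \code{hp_protocol} with a \code{channels}
#'   data.frame (name, in_plane_mm, nominal_flip_deg, chemical_shift_ppm).
#' @export
hp_protocol <- function(n_frames = 20, tr = 3, matrix = c(32, 32),
                        n_slices = 5, slice_thickness_cm = 3,
                        coarse_factor = 3) {
  stopifnot(n_frames >= 2, tr > 0, length(matrix) == 2, all(matrix >= 1),
            n_slices >= 1, coarse_factor >= 1)
  channels <- data.frame(
    name = c("pyruvate", "glutamate", "lactate_downfield", "lactate_upfield"),
    in_plane_mm = c(7.5, 22.5, 22.5, 22.5),
    nominal_flip_deg = c(20, 60, 60, 60),
    chemical_shift_ppm = c(206.00, 182.29, 72.39, 67.90),
    stringsAsFactors = FALSE)
  if (any(channels$nominal_flip_deg <= 0 | channels$nominal_flip_deg > 90))
    stop("nominal flips must lie in (0, 90]")
  structure(list(n_frames = as.integer(n_frames), tr = tr,
                 matrix = as.integer(matrix), n_slices = as.integer(n_slices),
                 slice_thickness_cm = slice_thickness_cm,
                 coarse_factor = as.integer(coarse_factor),
                 channels = channels),
            class = "hp_protocol")
}

#' @export
print.hp_protocol <- function(x, ...) {
  cat(sprintf("13C acquisition: %dx%d matrix, %d slices (%g cm), %d frames @ %g s\n",
              x$matrix[1], x$matrix[2], x$n_slices, x$slice_thickness_cm,
              x$n_frames, x$tr))
  print(x$channels, row.names = FALSE)
  invisible(x)
}

#' Frame sampling times of a protocol
#' @param protocol An \code{hp_protocol}.
#' @return Numeric vector of frame times in seconds, starting at 0.
#' @export
frame_times <- function(protocol) {
  (seq_len(protocol$n_frames) - 1) * protocol$tr
}

#' Gamma-variate bolus amplitude
#'
#' Gamma-variate delivery curve normalized so the peak value equals
#' \code{amplitude}, reached at \code{delay + shape * scale} seconds; zero
#' before \code{delay}. Stands in for the intravenous pyruvate injection.
#'
#' @param t Time(s) in seconds, nonnegative.
#' @param amplitude Peak amplitude (signal units, >= 0).
#' @param delay Arrival delay (s).
#' @param shape Unitless shape parameter (> 0).
#' @param scale Time scale (s, > 0).
#' @return Amplitude at each \code{t}.
#' @export
gamma_variate_bolus <- function(t, amplitude = 1, delay = 8, shape = 3,
                                scale = 4) {
  if (any(t < 0)) stop("t must be nonnegative")
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  if (amplitude < 0) stop("amplitude must be nonnegative")
  x <- (t - delay) / scale
  out <- ifelse(t > delay, amplitude * (x / shape)^shape * exp(shape - x), 0)
  out[!is.finite(out)] <- 0
  out
}

# Tissue classes of the digital phantom, in priority order at overlaps.
.tissues <- c("vessel", "csf", "wm", "gm")

#' Digital brain phantom ground truth
#'
#' Builds an ellipse-composite brain-like object per slice: a gray-matter rim
#' around a white-matter core, two CSF ventricles, and two vessel spots.
#' Tissue fractions are computed by subvoxel sampling (partial volume at
#' structure boundaries), so fractions lie in [0, 1] and sum to at most 1.
#' Rate maps are delivery-independent per-voxel mixtures of per-tissue rates;
#' the delivery map weights the gamma-variate bolus per voxel (vessels
#' strongest, then GM, WM, CSF).
#'
#' @param matrix In-plane matrix c(rows, cols), each >= 8.
#' @param n_slices Number of slices.
#' @param seed Integer seed controlling structural jitter and coil phases.
#' @param kpl,kpg Named per-tissue conversion rates (1/s), names
#'   \code{gm, wm, csf, vessel}. Defaults from representative gray/white
#'   matter voxel dynamics (GM kPL 0.012, WM kPL 0.0071, GM kPG 0.0019,
#'   WM kPG 0.0010 1/s).
#' @param bolus List of gamma-variate parameters \code{amplitude, delay,
#'   shape, scale}.
#' @param delivery_weights Named per-tissue relative pyruvate delivery.
#' @param doublet_asymmetry Upfield/downfield lactate amplitude ratio in
#'   (0, 1]; the lactate pool is split (1, asymmetry)/2 across the two
#'   doublet channels.
#' @param n_coils Number of receive channels (24-channel array by default).
#' @param noise_sigma Per-coil complex-noise standard deviation per real
#'   component (signal units).
#' @param head_axes_frac Semi-axes of the head ellipse as fractions of the
#'   matrix (rows, cols); 0 gives an empty phantom.
#' @return Object of class \code{hp_phantom_truth}: tissue fraction array
#'   (row, col, slice, tissue), \code{kpl_map}, \code{kpg_map},
#'   \code{delivery_map}, bolus parameters, coil sensitivities
#'   (coil, row, col, slice; complex), \code{noise_sigma}, \code{seed}.
#' @export
make_tissue_phantom <- function(matrix = c(32, 32), n_slices = 5, seed = 1,
                                kpl = c(gm = 0.012, wm = 0.0071,
                                        csf = 0, vessel = 0),
                                kpg = c(gm = 0.0019, wm = 0.0010,
                                        csf = 0, vessel = 0),
                                bolus = list(amplitude = 1, delay = 8,
                                             shape = 3, scale = 4),
                                delivery_weights = c(gm = 1, wm = 0.7,
                                                     csf = 0.15, vessel = 4),
                                doublet_asymmetry = 0.9,
                                n_coils = 24,
                                noise_sigma = 0.005,
                                head_axes_frac = c(0.40, 0.44)) {
  if (length(matrix) != 2 || any(matrix < 8))
    stop("matrix must have two dims, each >= 8 (too small for structures)")
  stopifnot(n_slices >= 1, n_coils >= 1, noise_sigma >= 0,
            doublet_asymmetry > 0, doublet_asymmetry <= 1)
  for (nm in .tissues) {
    if (is.na(kpl[nm]) || is.na(kpg[nm]) || is.na(delivery_weights[nm]))
      stop("kpl, kpg, delivery_weights must name all of: ",
           paste(.tissues, collapse = ", "))
  }
  if (any(kpl < 0) || any(kpg < 0)) stop("rates must be nonnegative")
  nr <- matrix[1]; nc <- matrix[2]
  set.seed(seed)
  jitter <- stats::runif(4, -0.02, 0.02)
  frac <- array(0, c(nr, nc, n_slices, 4),
                dimnames = list(NULL, NULL, NULL, c("gm", "wm", "csf", "vessel")))
  ss <- 3  # subvoxel sampling per dim
  off <- (seq_len(ss) - 0.5) / ss
  for (s in seq_len(n_slices)) {
    # slices shrink toward the ends of the stack
    zfrac <- if (n_slices == 1) 0 else (2 * (s - 1) / (n_slices - 1) - 1)
    shrink <- sqrt(max(0.35, 1 - 0.5 * zfrac^2))
    ax <- head_axes_frac * shrink
    wm_ax <- ax * 0.62
    inside <- function(r, c, ctr, axes) {
      if (any(axes <= 0)) return(rep(FALSE, length(r)))
      ((r - ctr[1]) / axes[1])^2 + ((c - ctr[2]) / axes[2])^2 <= 1
    }
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      rr <- rep((i - 1 + off) / nr, each = ss)
      cc <- rep((j - 1 + off) / nc, times = ss)
      head <- inside(rr, cc, c(0.5, 0.5), ax)
      wm <- inside(rr, cc, c(0.5, 0.5), wm_ax)
      csf <- inside(rr, cc, c(0.5, 0.46 + jitter[1]), c(0.10, 0.045)) |
        inside(rr, cc, c(0.5, 0.54 + jitter[2]), c(0.10, 0.045))
      ves <- inside(rr, cc, c(0.22 + jitter[3], 0.38), c(0.045, 0.045)) |
        inside(rr, cc, c(0.22 + jitter[4], 0.62), c(0.045, 0.045))
      ves <- ves & head
      csf <- csf & head & !ves
      wm <- wm & head & !ves & !csf
      gm <- head & !ves & !csf & !wm
      frac[i, j, s, ] <- c(sum(gm), sum(wm), sum(csf), sum(ves)) / (ss * ss)
    }
  }
  mix <- function(w, intensive = FALSE) {
    m <- array(0, c(nr, nc, n_slices))
    tot <- array(0, c(nr, nc, n_slices))
    for (nm in .tissues) {
      fm <- array(frac[, , , nm], c(nr, nc, n_slices))
      m <- m + fm * w[nm]
      tot <- tot + fm
    }
    if (intensive) {
      # rate constants are intensive: partial volume dilutes the signal
      # (delivery), not the per-magnetization conversion rate
      m <- ifelse(tot > 0, m / tot, 0)
    }
    m
  }
  truth <- structure(list(
    tissue_fractions = frac,
    kpl_map = mix(kpl, intensive = TRUE),
    kpg_map = mix(kpg, intensive = TRUE),
    delivery_map = mix(delivery_weights),
    bolus_params = bolus,
    doublet_asymmetry = doublet_asymmetry,
    coil_sensitivities = .coil_sensitivities(n_coils, nr, nc, n_slices, frac),
    coil_cov = NULL,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)),
    class = "hp_phantom_truth")
  truth
}

#' @export
print.hp_phantom_truth <- function(x, ...) {
  dm <- dim(x$kpl_map)
  cat(sprintf("Digital brain phantom %dx%dx%d, %d coils, sigma = %g\n",
              dm[1], dm[2], dm[3], dim(x$coil_sensitivities)[1],
              x$noise_sigma))
  cat(sprintf("  GM/WM/CSF/vessel voxel-equivalents: %s\n",
              paste(sprintf("%.1f", apply(x$tissue_fractions, 4, sum)),
                    collapse = " / ")))
  invisible(x)
}

# Smooth complex receive profiles for a ring of coils around the head,
# scaled so the mean root-sum-of-squares sensitivity over the head is 1.
.coil_sensitivities <- function(n_coils, nr, nc, n_slices, frac) {
  sens <- array(0i, c(n_coils, nr, nc, n_slices))
  r <- (seq_len(nr) - 0.5) / nr
  c <- (seq_len(nc) - 0.5) / nc
  gr <- outer(r, rep(1, nc))
  gc <- outer(rep(1, nr), c)
  phases <- stats::runif(n_coils, 0, 2 * pi)
  for (k in seq_len(n_coils)) {
    ang <- 2 * pi * (k - 1) / n_coils
    ctr <- c(0.5 + 0.62 * cos(ang), 0.5 + 0.62 * sin(ang))
    d2 <- (gr - ctr[1])^2 + (gc - ctr[2])^2
    mag <- exp(-d2 / (2 * 0.33^2))
    ph <- phases[k] + 1.5 * ((gr - 0.5) * sin(ang) - (gc - 0.5) * cos(ang))
    prof <- mag * exp(1i * ph)
    for (s in seq_len(n_slices)) {
      zmod <- 1 - 0.1 * abs(s - (n_slices + 1) / 2) / max(1, n_slices / 2)
      sens[k, , , s] <- prof * zmod
    }
  }
  # normalize to unit root-sum-of-squares gain everywhere: relative coil
  # profiles and phases vary, but the net receive gain field is flat, as for
  # an intensity-corrected (well-calibrated) array
  rss <- sqrt(apply(abs(sens)^2, 2:4, sum))
  for (k in seq_len(n_coils))
    sens[k, , , ] <- array(sens[k, , , ], dim(rss)) / rss
  sens
}

# Block aggregation helpers for the coarse metabolite grid ----------------

# Plain block mean of a (row, col, slice) array over factor x factor in-plane
# blocks (last blocks may be smaller).
block_average <- function(a, factor) {
  dm <- dim(a)
  cr <- ceiling(dm[1] / factor); cc <- ceiling(dm[2] / factor)
  out <- array(0, c(cr, cc, dm[3]))
  for (bi in seq_len(cr)) {
    ri <- ((bi - 1) * factor + 1):min(bi * factor, dm[1])
    for (bj in seq_len(cc)) {
      cj <- ((bj - 1) * factor + 1):min(bj * factor, dm[2])
      for (s in seq_len(dm[3])) out[bi, bj, s] <- mean(a[ri, cj, s])
    }
  }
  out
}

# Weighted block mean (weights w >= 0); falls back to plain mean where the
# block weight is zero.
block_average_weighted <- function(a, w, factor) {
  num <- block_average(a * w, factor)
  den <- block_average(w, factor)
  plain <- block_average(a, factor)
  out <- num / den
  out[!is.finite(out)] <- plain[!is.finite(out)]
  out
}

# Nearest-neighbour replication of a coarse (row, col, slice[, frame]) array
# back onto the fine in-plane matrix.
replicate_blocks <- function(coarse, factor, target_rc) {
  ri <- ((seq_len(target_rc[1]) - 1) %/% factor) + 1
  ci <- ((seq_len(target_rc[2]) - 1) %/% factor) + 1
  if (length(dim(coarse)) == 3) coarse[ri, ci, , drop = FALSE]
  else coarse[ri, ci, , , drop = FALSE]
}

# Vectorized forward simulation of the three-site model over a volume with
# per-voxel rates and delivery. Returns (row, col, slice, frame) arrays for
# the sampled P, L, G signals.
.simulate_volume <- function(kpl_map, kpg_map, delivery_map, bolus_frames,
                             spec) {
  vdim <- dim(kpl_map)
  nv <- prod(vdim)
  n <- spec$n_frames
  h <- spec$tr
  th <- effective_flips(spec)
  sp <- sin(th[["pyruvate"]]); cp <- cos(th[["pyruvate"]])
  sl <- sin(th[["lactate"]]); cl <- cos(th[["lactate"]])
  sg <- sin(th[["glutamate"]]); cg <- cos(th[["glutamate"]])
  kpl <- as.vector(kpl_map); kpg <- as.vector(kpg_map)
  a <- kpl + kpg + spec$r1p
  E11 <- exp(-a * h)
  E22 <- exp(-spec$r1l * h); E33 <- exp(-spec$r1g * h)
  E21 <- .decay_coupling(kpl, a, spec$r1l, h)
  E31 <- .decay_coupling(kpg, a, spec$r1g, h)
  u <- as.vector(delivery_map)
  P <- L <- G <- numeric(nv)
  sigP <- sigL <- sigG <- matrix(0, nv, n)
  for (i in seq_len(n)) {
    P <- P + u * bolus_frames[i] * h
    sigP[, i] <- P * sp; sigL[, i] <- L * sl; sigG[, i] <- G * sg
    P <- P * cp; L <- L * cl; G <- G * cg
    if (i < n) {
      Lnew <- E21 * P + E22 * L
      Gnew <- E31 * P + E33 * G
      P <- E11 * P
      L <- Lnew; G <- Gnew
    }
  }
  list(pyruvate = array(sigP, c(vdim, n)),
       lactate = array(sigL, c(vdim, n)),
       glutamate = array(sigG, c(vdim, n)))
}

#' Generate a multicoil dynamic dataset from a phantom
#'
#' Assembles the forward model: gamma-variate bolus delivery into the
#' pyruvate pool, three-site exchange kinetics under pulsed sampling,
#' multi-resolution acquisition (pyruvate on the fine grid; glutamate and
#' the lactate doublet simulated on the coarse grid with delivery-weighted
#' block rates, then replicated onto the common matrix), lactate split into
#' downfield/upfield channels with relative amplitudes (1, asymmetry)/2,
#' per-coil complex sensitivities, and i.i.d. circular complex Gaussian
#' noise (optionally mixed by a user-supplied inter-coil covariance in
#' \code{truth$coil_cov}). Appends pure-noise samples standing for the
#' signalless end-of-scan pyruvate frames used for covariance estimation.
#'
#' @param protocol An \code{hp_protocol}.
#' @param truth An \code{hp_phantom_truth} on the same grid.
#' @param spec Optional \code{hp_kinetic_spec}; defaults to the model spec
#'   implied by the protocol with the phantom's default relaxation rates.
#' @param n_noise_frames Number of frame-volumes of pure noise appended
#'   (>= 2 recommended).
#' @return Object of class \code{hp_dataset}: \code{stack} (an
#'   \code{hp_coil_stack} with complex \code{data} indexed
#'   (coil, row, col, slice, frame, channel) and \code{noise_frames}
#'   (coil x sample)), \code{noiseless} (row, col, slice, frame, channel)
#'   ground-truth sidecar, and \code{truth}.
#' @export
generate_dataset <- function(protocol, truth, spec = NULL,
                             n_noise_frames = 2) {
  stopifnot(inherits(protocol, "hp_protocol"),
            inherits(truth, "hp_phantom_truth"))
  vdim <- c(protocol$matrix, protocol$n_slices)
  if (!all(dim(truth$kpl_map) == vdim))
    stop("protocol grid and truth grid are inconsistent")
  if (truth$noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (is.null(spec)) {
    fl <- protocol$channels$nominal_flip_deg
    names(fl) <- protocol$channels$name
    spec <- kinetic_model_spec(
      flips_nominal = c(pyruvate = unname(fl["pyruvate"]),
                        lactate = unname(fl["lactate_downfield"]),
                        glutamate = unname(fl["glutamate"])),
      tr = protocol$tr, n_frames = protocol$n_frames)
  }
  bp <- truth$bolus_params
  bolus_frames <- gamma_variate_bolus(frame_times(protocol), bp$amplitude,
                                      bp$delay, bp$shape, bp$scale)
  # fine grid: pyruvate
  fine <- .simulate_volume(truth$kpl_map, truth$kpg_map, truth$delivery_map,
                           bolus_frames, spec)
  # coarse grid: metabolites, with delivery-weighted effective rates
  f <- protocol$coarse_factor
  w <- truth$delivery_map
  kpl_c <- block_average_weighted(truth$kpl_map, w, f)
  kpg_c <- block_average_weighted(truth$kpg_map, w, f)
  del_c <- block_average(truth$delivery_map, f)
  coarse <- .simulate_volume(kpl_c, kpg_c, del_c, bolus_frames, spec)
  glu <- replicate_blocks(coarse$glutamate, f, protocol$matrix)
  lac <- replicate_blocks(coarse$lactate, f, protocol$matrix)
  asym <- truth$doublet_asymmetry
  noiseless <- array(0, c(vdim, protocol$n_frames, 4),
                     dimnames = list(NULL, NULL, NULL, NULL,
                                     protocol$channels$name))
  noiseless[, , , , "pyruvate"] <- fine$pyruvate
  noiseless[, , , , "glutamate"] <- glu
  noiseless[, , , , "lactate_downfield"] <- 0.5 * lac
  noiseless[, , , , "lactate_upfield"] <- 0.5 * asym * lac

  sens <- truth$coil_sensitivities
  n_coils <- dim(sens)[1]
  set.seed(truth$seed + 1L)
  dm <- c(n_coils, vdim, protocol$n_frames, 4)
  data <- array(0i, dm)
  mix <- if (!is.null(truth$coil_cov)) .complex_chol(truth$coil_cov) else NULL
  nper <- prod(dm[-1])
  noise <- .complex_noise(n_coils, nper, truth$noise_sigma, mix)
  for (k in seq_len(n_coils)) {
    sk <- array(sens[k, , , ], vdim)
    sig <- array(0i, dm[-1])
    for (ch in seq_len(4))
      sig[, , , , ch] <- as.vector(sk) * matrix(noiseless[, , , , ch],
                                                prod(vdim),
                                                protocol$n_frames)
    data[k, , , , , ] <- sig + array(noise[k, ], dm[-1])
  }
  n_noise <- n_noise_frames * prod(vdim)
  noise_frames <- .complex_noise(n_coils, n_noise, truth$noise_sigma, mix)
  stack <- structure(list(data = data, noise_frames = noise_frames,
                          protocol = protocol,
                          channel_names = protocol$channels$name),
                     class = "hp_coil_stack")
  structure(list(stack = stack, noiseless = noiseless, truth = truth,
                 spec = spec),
            class = "hp_dataset")
}

# Circular complex Gaussian noise, sigma per real component; optional coil
# mixing matrix L (covariance = L L^H scaled by sigma^2).
.complex_noise <- function(n_coils, n_samples, sigma, mix = NULL) {
  z <- matrix(complex(real = stats::rnorm(n_coils * n_samples, sd = sigma),
                      imaginary = stats::rnorm(n_coils * n_samples,
                                               sd = sigma)),
              n_coils, n_samples)
  if (!is.null(mix)) z <- mix %*% z
  z
}

#' @export
print.hp_coil_stack <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("Coil stack: %d coils, %dx%dx%d voxels, %d frames, %d channels\n",
              dm[1], dm[2], dm[3], dm[4], dm[5], dm[6]))
  cat(sprintf("  noise samples per coil: %d\n", ncol(x$noise_frames)))
  invisible(x)
}
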
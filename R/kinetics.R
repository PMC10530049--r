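#' Three-site exchange kinetic model specification
#'
#' Bundles the parameters of the irreversible three-site exchange model for
#' hyperpolarized [2-13C]pyruvate: pyruvate feeds lactate (rate \code{k_pl})
#' and glutamate (rate \code{k_pg}) while all three pools relax longitudinally
#' at rates \code{r1p}, \code{r1l}, \code{r1g} (= 1/T1). Each RF excitation of
#' metabolite m with effective flip angle \eqn{\theta_m} measures
#' \eqn{M_z \sin\theta_m} and leaves \eqn{M_z \cos\theta_m}. The effective
#' flip is \code{b1_scale} times the nominal flip, reflecting the actual
#' transmit field calibration (80% of nominal by default).
#'
#' @param k_pl Pyruvate-to-lactate conversion rate (1/s).
#' @param k_pg Pyruvate-to-glutamate conversion rate (1/s).
#' @param r1p,r1l,r1g Longitudinal relaxation rates 1/T1 (1/s). Defaults:
#'   T1 pyruvate 47 s; lactate and glutamate 25 s.
#' @param flips_nominal Named numeric, nominal flip angles in degrees for
#'   \code{pyruvate}, \code{lactate}, \code{glutamate}.
#' @param b1_scale Unitless B1 scale in (0, 1.5]; effective flip =
#'   \code{b1_scale * nominal}.
#' @param tr Repetition (frame) time in seconds.
#' @param n_frames Number of timeframes (>= 2).
#' @return An object of class \code{hp_kinetic_spec}.
#' @export
kinetic_model_spec <- function(k_pl = 0.012, k_pg = 0.0019,
                               r1p = 1 / 47, r1l = 1 / 25, r1g = 1 / 25,
                               flips_nominal = c(pyruvate = 20, lactate = 60,
                                                 glutamate = 60),
                               b1_scale = 0.8, tr = 3, n_frames = 20) {
  stopifnot(k_pl >= 0, k_pg >= 0, r1p >= 0, r1l >= 0, r1g >= 0,
            b1_scale > 0, b1_scale <= 1.5, tr > 0, n_frames >= 2)
  if (!all(c("pyruvate", "lactate", "glutamate") %in% names(flips_nominal)))
    stop("flips_nominal must name pyruvate, lactate and glutamate")
  if (any(flips_nominal <= 0) || any(flips_nominal > 90))
    stop("nominal flips must lie in (0, 90] degrees")
  structure(list(k_pl = k_pl, k_pg = k_pg, r1p = r1p, r1l = r1l, r1g = r1g,
                 flips_nominal = flips_nominal, b1_scale = b1_scale,
                 tr = tr, n_frames = as.integer(n_frames)),
            class = "hp_kinetic_spec")
}

#' @export
print.hp_kinetic_spec <- function(x, ...) {
  cat("Three-site exchange model (pyruvate -> lactate, glutamate)\n")
  cat(sprintf("  kPL = %.4g 1/s, kPG = %.4g 1/s\n", x$k_pl, x$k_pg))
  cat(sprintf("  T1 (P/L/G) = %.3g / %.3g / %.3g s\n",
              1 / x$r1p, 1 / x$r1l, 1 / x$r1g))
  cat(sprintf("  flips (deg, nominal) P/L/G = %g / %g / %g, B1 scale %.2g\n",
              x$flips_nominal["pyruvate"], x$flips_nominal["lactate"],
              x$flips_nominal["glutamate"], x$b1_scale))
  cat(sprintf("  TR = %g s, %d frames\n", x$tr, x$n_frames))
  invisible(x)
}

#' Effective flip angles in radians
#' @param spec A \code{hp_kinetic_spec}.
#' @return Named numeric of effective flips (radians) for P/L/G.
#' @export
effective_flips <- function(spec) {
  spec$b1_scale * spec$flips_nominal * pi / 180
}

#' Inter-frame propagator of the three-site model
#'
#' Closed-form matrix exponential \eqn{e^{Ah}} of the lower-triangular rate
#' matrix with state order (pyruvate, lactate, glutamate):
#' \deqn{dP/dt = -(k_{PL}+k_{PG}+R_{1P}) P, \quad
#'       dL/dt = k_{PL} P - R_{1L} L, \quad
#'       dG/dt = k_{PG} P - R_{1G} G.}
#'
#' @param k_pl,k_pg Conversion rates (1/s).
#' @param r1p,r1l,r1g Relaxation rates (1/s).
#' @param h Time step (s).
#' @return 3x3 propagator matrix.
#' @export
three_site_propagator <- function(k_pl, k_pg, r1p, r1l, r1g, h) {
  stopifnot(k_pl >= 0, k_pg >= 0, h >= 0)
  a <- k_pl + k_pg + r1p
  E <- diag(c(exp(-a * h), exp(-r1l * h), exp(-r1g * h)))
  E[2, 1] <- .decay_coupling(k_pl, a, r1l, h)
  E[3, 1] <- .decay_coupling(k_pg, a, r1g, h)
  E
}

# k * (e^{-a h} - e^{-r h}) / (r - a), with the a -> r limit k h e^{-a h}
.decay_coupling <- function(k, a, r, h) {
  d <- r - a
  ifelse(abs(d) < 1e-10, k * h * exp(-a * h),
         k * (exp(-a * h) - exp(-r * h)) / d)
}

#' Simulate sampled three-site dynamics for one voxel
#'
#' Forward-simulates the model under pulsed sampling. The pyruvate input is a
#' delivery time course defined on the frame grid: at each frame time the
#' corresponding amount is added to the pyruvate longitudinal magnetization,
#' the three pools are then sampled (signal \eqn{M_z \sin\theta}), reduced by
#' \eqn{\cos\theta}, and evolved to the next frame with the exact matrix
#' exponential of the rate matrix.
#'
#' @param spec A \code{hp_kinetic_spec}.
#' @param pyruvate_input Numeric vector of length \code{spec$n_frames}:
#'   magnetization delivered to the pyruvate pool at each frame time
#'   (arbitrary units, nonnegative).
#' @return A numeric matrix \code{n_frames x 3} of measured signals, columns
#'   \code{pyruvate}, \code{lactate}, \code{glutamate}; attribute \code{"Mz"}
#'   holds the longitudinal magnetization at the sampling instants (before
#'   the flip).
#' @export
simulate_dynamics <- function(spec, pyruvate_input) {
  stopifnot(inherits(spec, "hp_kinetic_spec"))
  n <- spec$n_frames
  if (length(pyruvate_input) != n)
    stop("pyruvate_input must have one value per frame")
  if (any(pyruvate_input < 0)) stop("pyruvate_input must be nonnegative")
  th <- effective_flips(spec)[c("pyruvate", "lactate", "glutamate")]
  E <- three_site_propagator(spec$k_pl, spec$k_pg, spec$r1p, spec$r1l,
                             spec$r1g, spec$tr)
  Mz <- matrix(0, n, 3)
  sig <- matrix(0, n, 3, dimnames = list(NULL,
                c("pyruvate", "lactate", "glutamate")))
  m <- c(0, 0, 0)
  for (i in seq_len(n)) {
    m[1] <- m[1] + pyruvate_input[i]
    Mz[i, ] <- m
    sig[i, ] <- m * sin(th)
    m <- m * cos(th)
    if (i < n) m <- as.vector(E %*% m)
  }
  attr(sig, "Mz") <- Mz
  sig
}

# Inputless forward model for one metabolite given measured pyruvate.
# Returns predicted metabolite signal (length n) and its derivative wrt k.
# The pyruvate magnetization is reset to the measured value each frame, so
# inter-frame evolution only needs the 2x2 (P, M) propagator entries.
.predict_metabolite <- function(k, pz, m1, a0, r1m, th_p, th_m, h, n) {
  a <- a0 + k
  e22 <- exp(-r1m * h)
  d <- r1m - a
  if (abs(d) < 1e-10) {
    f <- NA_real_
    e21 <- k * h * exp(-a * h)
    de21 <- h * exp(-a * h) * (1 - k * h)
  } else {
    f <- exp(-a * h) - e22
    e21 <- k * f / d
    de21 <- f / d + k * (-h * exp(-a * h) * d + f) / d^2
  }
  cp <- cos(th_p)
  cm <- cos(th_m)
  mz <- numeric(n)
  dmz <- numeric(n)
  mz[1] <- m1
  for (i in 2:n) {
    mz[i] <- e21 * pz[i - 1] * cp + e22 * cm * mz[i - 1]
    dmz[i] <- de21 * pz[i - 1] * cp + e22 * cm * dmz[i - 1]
  }
  list(pred = mz * sin(th_m), grad = dmz * sin(th_m))
}

#' Fit a single conversion rate to one voxel's time courses
#'
#' Inputless voxelwise fit: the measured pyruvate signal is converted to
#' longitudinal magnetization by dividing by \eqn{\sin\theta_P} and used as
#' the source of the metabolite pool, with the pyruvate state reset to the
#' measured value at every frame and exact exponential evolution in between.
#' The single rate (kPL for lactate, kPG for glutamate) is estimated by
#' bounded nonlinear least squares (bounds [0, 0.1] 1/s) with an analytic
#' Jacobian and multistart; T1s, flips and the other conversion rate are
#' fixed at the values in \code{spec}. The fitting error is the relative
#' standard error, 100 * SE(k) / k, from the Jacobian-based covariance.
#'
#' @param pyr_signal,met_signal Measured signal time courses (same length,
#'   >= 5 frames).
#' @param spec A \code{hp_kinetic_spec} carrying the fixed T1s, flips, TR and
#'   the non-fitted conversion rate.
#' @param which \code{"lactate"} (fit kPL) or \code{"glutamate"} (fit kPG).
#' @param starts Multistart initial values (1/s).
#' @param upper Upper bound on the rate (1/s).
#' @return List with elements \code{k} (1/s), \code{fit_error_pct},
#'   \code{se}, \code{residual_norm}, \code{converged}.
#' @export
fit_voxel <- function(pyr_signal, met_signal, spec,
                      which = c("lactate", "glutamate"),
                      starts = c(0.001, 0.01, 0.05), upper = 0.1) {
  which <- match.arg(which)
  n <- length(pyr_signal)
  if (length(met_signal) != n) stop("time courses must have equal length")
  if (n < 5) stop("need at least 5 frames")
  stopifnot(inherits(spec, "hp_kinetic_spec"))
  if (all(met_signal == 0)) {
    return(list(k = 0, fit_error_pct = Inf, se = Inf, residual_norm = 0,
                converged = FALSE))
  }
  th <- effective_flips(spec)
  th_p <- th[["pyruvate"]]
  th_m <- th[[which]]
  r1m <- if (which == "lactate") spec$r1l else spec$r1g
  k_other <- if (which == "lactate") spec$k_pg else spec$k_pl
  a0 <- spec$r1p + k_other
  pz <- pyr_signal / sin(th_p)
  m1 <- met_signal[1] / sin(th_m)
  h <- spec$tr

  resid_fn <- function(par) {
    .predict_metabolite(par, pz, m1, a0, r1m, th_p, th_m, h, n)$pred[-1] -
      met_signal[-1]
  }
  jac_fn <- function(par) {
    matrix(.predict_metabolite(par, pz, m1, a0, r1m, th_p, th_m, h, n)$grad[-1],
           ncol = 1)
  }
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = 0, upper = upper, fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(list(k = NA_real_, fit_error_pct = Inf, se = Inf,
                residual_norm = NA_real_, converged = FALSE))
  }
  k <- unname(best$par)
  nres <- n - 1
  sigma2 <- best$deviance / max(nres - 1, 1)
  jtj <- sum(jac_fn(k)^2)
  se <- if (jtj > 0) sqrt(sigma2 / jtj) else Inf
  err <- if (k > 0) 100 * se / k else Inf
  list(k = k, fit_error_pct = err, se = se,
       residual_norm = sqrt(best$deviance),
       converged = best$info %in% 1:4)
}

#' Joint two-rate fit of one voxel (cross-check)
#'
#' Fits kPL and kPG simultaneously on the stacked lactate and glutamate
#' residuals, with the pyruvate state reset to the measured values. Because
#' the model decouples given measured pyruvate (the rates interact only
#' weakly through the pyruvate inter-frame decay), this should agree with
#' the two single-rate fits of \code{\link{fit_voxel}} to solver tolerance.
#'
#' @inheritParams fit_voxel
#' @param lac_signal,glu_signal Measured metabolite time courses.
#' @return List with \code{k_pl}, \code{k_pg}, \code{residual_norm}.
#' @export
fit_voxel_joint <- function(pyr_signal, lac_signal, glu_signal, spec,
                            starts = c(0.001, 0.01, 0.05), upper = 0.1) {
  n <- length(pyr_signal)
  th <- effective_flips(spec)
  pz <- pyr_signal / sin(th[["pyruvate"]])
  h <- spec$tr
  resid_fn <- function(par) {
    pl <- .predict_metabolite(par[1], pz, lac_signal[1] / sin(th[["lactate"]]),
                              spec$r1p + par[2], spec$r1l,
                              th[["pyruvate"]], th[["lactate"]], h, n)$pred
    pg <- .predict_metabolite(par[2], pz, glu_signal[1] / sin(th[["glutamate"]]),
                              spec$r1p + par[1], spec$r1g,
                              th[["pyruvate"]], th[["glutamate"]], h, n)$pred
    c(pl[-1] - lac_signal[-1], pg[-1] - glu_signal[-1])
  }
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = c(s, s / 5), lower = c(0, 0), upper = c(upper, upper),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12,
                                           ptol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  list(k_pl = best$par[1], k_pg = best$par[2],
       residual_norm = sqrt(best$deviance))
}

#' Voxelwise kinetic rate mapping over a volume
#'
#' Fits kPL (from the summed-lactate series) and kPG (from the glutamate
#' series) in every voxel of the mask, applying the study's inclusion
#' filters: voxels whose metabolite SNR of the AUC image is not greater
#' than \code{snr_auc_min} are excluded from the maps, and voxels with
#' fitting error at or above \code{fit_error_max} percent are excluded from
#' the whole-volume averages. Rates are refined by alternating passes so
#' each fit uses the other rate's current voxel estimate in the pyruvate
#' decay. Voxels with identical time courses (e.g. replicated coarse-grid
#' blocks) are fitted once and shared.
#'
#' @param series Named list of 4D arrays (row, col, slice, frame):
#'   \code{pyruvate}, \code{lactate} (doublet-summed), \code{glutamate}.
#' @param spec A \code{hp_kinetic_spec} of fixed T1s/flips and default rates.
#' @param mask Logical 3D array of voxels to consider (e.g. brain mask);
#'   default all voxels.
#' @param snr_auc Optional named list of per-voxel SNR_AUC maps for
#'   \code{lactate} and \code{glutamate}; \code{NULL} disables the SNR filter
#'   (noiseless data).
#' @param snr_auc_min SNR_AUC inclusion threshold (default 3).
#' @param fit_error_max Fit-error exclusion threshold in percent (default 30).
#' @param n_refine Number of alternating refinement passes.
#' @return List with \code{maps} (kpl, kpg, fit_error_pl, fit_error_pg; NA
#'   where excluded) and \code{summary} (data.frame of mean, SE, n and
#'   coverage per rate). Coverage is the fraction of mask voxels whose rate
#'   passed both the SNR and fit-error filters.
#' @export
fit_volume <- function(series, spec, mask = NULL, snr_auc = NULL,
                       snr_auc_min = 3, fit_error_max = 30, n_refine = 2) {
  stopifnot(all(c("pyruvate", "lactate", "glutamate") %in% names(series)))
  dm <- dim(series$pyruvate)
  stopifnot(length(dm) == 4)
  vdim <- dm[1:3]
  n_frames <- dm[4]
  if (is.null(mask)) mask <- array(TRUE, vdim)
  if (!all(dim(mask) == vdim)) stop("mask dims must match series")
  n_mask <- sum(mask)
  empty_map <- array(NA_real_, vdim)
  out <- list(maps = list(kpl = empty_map, kpg = empty_map,
                          fit_error_pl = empty_map, fit_error_pg = empty_map),
              summary = data.frame())
  if (n_mask == 0) {
    warning("empty mask: no voxels to fit")
    return(out)
  }

  flat <- function(a) matrix(a, prod(vdim), n_frames)
  pyr <- flat(series$pyruvate)
  met <- list(lactate = flat(series$lactate), glutamate = flat(series$glutamate))

  sel <- list()
  for (m in c("lactate", "glutamate")) {
    keep <- as.vector(mask)
    if (!is.null(snr_auc)) {
      if (is.null(snr_auc[[m]])) stop("snr_auc must supply map for ", m)
      keep <- keep & as.vector(snr_auc[[m]]) > snr_auc_min
    }
    sel[[m]] <- which(keep)
  }

  k_est <- list(lactate = rep(spec$k_pl, prod(vdim)),
                glutamate = rep(spec$k_pg, prod(vdim)))
  err_est <- list(lactate = rep(NA_real_, prod(vdim)),
                  glutamate = rep(NA_real_, prod(vdim)))

  fit_pass <- function(m, other_rates, starts) {
    idx <- sel[[m]]
    if (length(idx) == 0) return(NULL)
    key <- vapply(idx, function(v)
      paste(signif(c(pyr[v, ], met[[m]][v, ], other_rates[v]), 10),
            collapse = ","), character(1))
    first <- !duplicated(key)
    res_k <- numeric(length(idx))
    res_e <- numeric(length(idx))
    cache <- new.env(parent = emptyenv())
    for (j in seq_along(idx)) {
      if (first[j]) {
        v <- idx[j]
        sp <- spec
        if (m == "lactate") sp$k_pg <- other_rates[v] else sp$k_pl <- other_rates[v]
        f <- fit_voxel(pyr[v, ], met[[m]][v, ], sp, which = m, starts = starts)
        assign(key[j], c(f$k, f$fit_error_pct), envir = cache)
      }
      kv <- get(key[j], envir = cache)
      res_k[j] <- kv[1]
      res_e[j] <- kv[2]
    }
    list(idx = idx, k = res_k, err = res_e)
  }

  starts0 <- c(0.001, 0.01, 0.05)
  for (round in seq_len(n_refine + 1)) {
    for (m in c("lactate", "glutamate")) {
      other <- if (m == "lactate") "glutamate" else "lactate"
      st <- if (round == 1 && m == "lactate") starts0 else
        unique(pmin(pmax(c(stats::median(k_est[[m]][sel[[m]]]), 0.01), 1e-4), 0.1))
      fp <- fit_pass(m, k_est[[other]], st)
      if (!is.null(fp)) {
        k_est[[m]][fp$idx] <- fp$k
        err_est[[m]][fp$idx] <- fp$err
      }
    }
  }

  maps <- out$maps
  summary_rows <- list()
  for (m in c("lactate", "glutamate")) {
    idx <- sel[[m]]
    kmap <- rep(NA_real_, prod(vdim))
    emap <- rep(NA_real_, prod(vdim))
    kmap[idx] <- k_est[[m]][idx]
    emap[idx] <- err_est[[m]][idx]
    keep_avg <- idx[is.finite(err_est[[m]][idx]) &
                      err_est[[m]][idx] < fit_error_max]
    kv <- k_est[[m]][keep_avg]
    rate_name <- if (m == "lactate") "kpl" else "kpg"
    summary_rows[[m]] <- data.frame(
      rate = rate_name,
      mean = if (length(kv)) mean(kv) else NA_real_,
      se = if (length(kv) > 1) stats::sd(kv) / sqrt(length(kv)) else NA_real_,
      n = length(kv),
      coverage = length(kv) / n_mask)
    if (m == "lactate") {
      maps$kpl <- array(kmap, vdim); maps$fit_error_pl <- array(emap, vdim)
    } else {
      maps$kpg <- array(kmap, vdim); maps$fit_error_pg <- array(emap, vdim)
    }
  }
  list(maps = maps, summary = do.call(rbind, summary_rows))
}
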
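# Independent oracles used across tests.

# Fine-step ODE integration of the three-site model with per-frame
# injections and cos sampling losses, via deSolve at tight tolerance.
# Independent of the package's closed-form propagator.
ode_oracle_sim <- function(spec, pyruvate_input, dt = 0.01) {
  th <- effective_flips(spec)[c("pyruvate", "lactate", "glutamate")]
  a <- spec$k_pl + spec$k_pg + spec$r1p
  deriv <- function(t, y, parms) {
    list(c(-a * y[1],
           spec$k_pl * y[1] - spec$r1l * y[2],
           spec$k_pg * y[1] - spec$r1g * y[3]))
  }
  m <- c(0, 0, 0)
  sig <- matrix(0, spec$n_frames, 3)
  for (i in seq_len(spec$n_frames)) {
    m[1] <- m[1] + pyruvate_input[i]
    sig[i, ] <- m * sin(th)
    m <- m * cos(th)
    if (i < spec$n_frames) {
      sol <- deSolve::lsoda(m, seq(0, spec$tr, by = dt), deriv, NULL,
                            rtol = 1e-12, atol = 1e-14)
      m <- as.numeric(sol[nrow(sol), 2:4])
    }
  }
  colnames(sig) <- c("pyruvate", "lactate", "glutamate")
  sig
}

# Direct per-pixel SSIM with a truncated, renormalized Gaussian window;
# plain loops, no shared code with ssim_index().
naive_ssim <- function(a, b, mask = NULL, L = max(a, b),
                       win = 11, sig = 1.5) {
  half <- (win - 1) %/% 2
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  nr <- nrow(a); nc <- ncol(a)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - half):min(nr, i + half)
    ci <- max(1, j - half):min(nc, j + half)
    w <- outer(exp(-(ri - i)^2 / (2 * sig^2)), exp(-(ci - j)^2 / (2 * sig^2)))
    w <- w / sum(w)
    pa <- a[ri, ci]; pb <- b[ri, ci]
    mua <- sum(w * pa); mub <- sum(w * pb)
    va <- sum(w * pa^2) - mua^2; vb <- sum(w * pb^2) - mub^2
    vab <- sum(w * pa * pb) - mua * mub
    out[i, j] <- ((2 * mua * mub + C1) * (2 * vab + C2)) /
      ((mua^2 + mub^2 + C1) * (va + vb + C2))
  }
  if (is.null(mask)) mean(out) else mean(out[mask])
}

# Small low-rank spatiotemporal test series: n_comp separable
# (spatial pattern) x (temporal curve) components.
low_rank_series <- function(nr = 16, nc = 16, ns = 1, nf = 12, n_comp = 3,
                            seed = 1) {
  set.seed(seed)
  out <- array(0, c(nr, nc, ns, nf))
  for (k in seq_len(n_comp)) {
    r0 <- runif(1, 0.25, 0.75) * nr; c0 <- runif(1, 0.25, 0.75) * nc
    w <- runif(1, 2, 4)
    sp <- outer(exp(-((seq_len(nr) - r0)^2) / (2 * w^2)),
                exp(-((seq_len(nc) - c0)^2) / (2 * w^2)))
    tc <- dgamma(seq_len(nf), shape = runif(1, 2, 4), scale = runif(1, 1, 3))
    for (s in seq_len(ns)) out[, , s, ] <- out[, , s, ] +
        array(outer(sp, tc / max(tc)), c(nr, nc, nf))
  }
  out / max(out)
}

# Default single-voxel simulation used by several kinetics tests.
sim_voxel <- function(spec, amplitude = 1) {
  tt <- (seq_len(spec$n_frames) - 1) * spec$tr
  u <- gamma_variate_bolus(tt, amplitude = amplitude) * spec$tr
  simulate_dynamics(spec, u)
}
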
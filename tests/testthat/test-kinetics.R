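test_that("propagator matches a general-purpose matrix exponential", {
  spec <- kinetic_model_spec()
  A <- matrix(c(-(spec$k_pl + spec$k_pg + spec$r1p), 0, 0,
                spec$k_pl, -spec$r1l, 0,
                spec$k_pg, 0, -spec$r1g), 3, 3, byrow = TRUE)
  E <- three_site_propagator(spec$k_pl, spec$k_pg, spec$r1p, spec$r1l,
                             spec$r1g, 3)
  expect_equal(E, as.matrix(Matrix::expm(A * 3)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # degenerate case: lactate relaxation equal to total pyruvate decay
  a <- spec$k_pl + spec$k_pg + spec$r1p
  Ed <- three_site_propagator(spec$k_pl, spec$k_pg, spec$r1p,
                              a, spec$r1g, 3)
  Ad <- A; Ad[2, 2] <- -a
  expect_equal(Ed, as.matrix(Matrix::expm(Ad * 3)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("sampled dynamics match a fine-step ODE oracle", {
  for (kpl in c(0.012, 0.0071)) {
    spec <- kinetic_model_spec(k_pl = kpl, k_pg = 0.0019)
    tt <- frame_times(hp_protocol())
    u <- gamma_variate_bolus(tt) * spec$tr
    sim <- simulate_dynamics(spec, u)
    oracle <- ode_oracle_sim(spec, u)
    expect_lt(max(abs(sim - oracle)) / max(abs(oracle)), 1e-6)
  }
})

test_that("no conversion means no metabolite signal; magnetization is
          conserved without relaxation or excitation", {
  spec0 <- kinetic_model_spec(k_pl = 0, k_pg = 0)
  sim0 <- sim_voxel(spec0)
  expect_true(all(sim0[, c("lactate", "glutamate")] == 0))

  # R1 = 0 and (near-)zero flips: total magnetization P+L+G constant after
  # the last injection
  spec <- kinetic_model_spec(r1p = 0, r1l = 0, r1g = 0, b1_scale = 1e-6)
  u <- c(1, 2, rep(0, 18))
  sim <- simulate_dynamics(spec, u)
  tot <- rowSums(attr(sim, "Mz"))
  expect_equal(tot[2:20], rep(3, 19), tolerance = 1e-9)
})

test_that("negative rates and bad inputs are rejected", {
  expect_error(kinetic_model_spec(k_pl = -0.01))
  expect_error(three_site_propagator(-1, 0, 0, 0, 0, 1))
  spec <- kinetic_model_spec()
  expect_error(simulate_dynamics(spec, rep(-1, 20)))
  expect_error(simulate_dynamics(spec, rep(1, 3)))
})

test_that("noiseless round-trip recovery is exact across rates, T1s and flips", {
  grid <- expand.grid(k = c(0.0084, 0.012, 0.0071, 0.03),
                      t1m = c(25, 40), b1 = c(0.8, 1.0))
  for (i in seq_len(nrow(grid))) {
    spec <- kinetic_model_spec(k_pl = grid$k[i], k_pg = grid$k[i] / 7,
                               r1l = 1 / grid$t1m[i], r1g = 1 / grid$t1m[i],
                               b1_scale = grid$b1[i])
    sim <- sim_voxel(spec)
    fl <- fit_voxel(sim[, "pyruvate"], sim[, "lactate"], spec, "lactate")
    fg <- fit_voxel(sim[, "pyruvate"], sim[, "glutamate"], spec, "glutamate")
    expect_lt(abs(fl$k - spec$k_pl) / spec$k_pl, 1e-3)
    expect_lt(abs(fg$k - spec$k_pg) / spec$k_pg, 1e-3)
    expect_true(fl$converged && fg$converged)
  }
})

test_that("zero metabolite signal yields k = 0 with flagged fit error", {
  spec <- kinetic_model_spec()
  sim <- sim_voxel(spec)
  f <- fit_voxel(sim[, "pyruvate"], rep(0, 20), spec, "lactate")
  expect_identical(f$k, 0)
  expect_identical(f$fit_error_pct, Inf)
  expect_false(f$converged)
})

test_that("separate single-rate fits agree with the joint two-rate fit", {
  spec <- kinetic_model_spec(k_pl = 0.012, k_pg = 0.0019)
  sim <- sim_voxel(spec)
  fl <- fit_voxel(sim[, "pyruvate"], sim[, "lactate"], spec, "lactate")
  fg <- fit_voxel(sim[, "pyruvate"], sim[, "glutamate"], spec, "glutamate")
  fj <- fit_voxel_joint(sim[, "pyruvate"], sim[, "lactate"],
                        sim[, "glutamate"], spec)
  expect_equal(fl$k, fj$k_pl, tolerance = 2e-3)
  expect_equal(fg$k, fj$k_pg, tolerance = 2e-3)
})

test_that("recovered rate is invariant to global rescaling of both series", {
  spec <- kinetic_model_spec()
  sim <- sim_voxel(spec)
  f1 <- fit_voxel(sim[, "pyruvate"], sim[, "lactate"], spec, "lactate")
  f2 <- fit_voxel(37.5 * sim[, "pyruvate"], 37.5 * sim[, "lactate"], spec,
                  "lactate")
  expect_equal(f1$k, f2$k, tolerance = 1e-9)
})

test_that("rate estimates are unbiased under noise at moderate SNR", {
  # 200 noisy replicates at SNR_AUC about 10 for the metabolite
  spec <- kinetic_model_spec(k_pl = 0.012)
  sim <- sim_voxel(spec)
  lac <- sim[, "lactate"]
  n <- length(lac)
  sigma <- sum(lac) / (10 * sqrt(n))  # SNR_AUC = AUC/(sigma*sqrt(n)) = 10
  set.seed(11)
  ks <- replicate(200, {
    fit_voxel(sim[, "pyruvate"] + rnorm(n, sd = sigma),
              lac + rnorm(n, sd = sigma), spec, "lactate")$k
  })
  expect_lt(abs(mean(ks) - spec$k_pl) / spec$k_pl, 0.05)
})

test_that("fit_volume recovers maps, applies filters and dedupes voxels", {
  spec <- kinetic_model_spec(k_pl = 0.0096, k_pg = 0.0014)
  sim <- sim_voxel(spec)
  dims <- c(4, 4, 1)
  mk <- function(v) array(rep(v, each = prod(dims)), c(dims, length(v)))
  series <- list(pyruvate = mk(sim[, "pyruvate"]),
                 lactate = mk(sim[, "lactate"]),
                 glutamate = mk(sim[, "glutamate"]))
  fv <- fit_volume(series, spec)
  expect_equal(unname(fv$summary$mean[fv$summary$rate == "kpl"]), 0.0096,
               tolerance = 1e-3)
  expect_equal(unname(fv$summary$mean[fv$summary$rate == "kpg"]), 0.0014,
               tolerance = 1e-3)
  expect_equal(unname(fv$summary$coverage), c(1, 1))

  # an impossible SNR threshold removes every voxel
  inf_snr <- list(lactate = array(0, dims), glutamate = array(0, dims))
  fv2 <- fit_volume(series, spec, snr_auc = inf_snr, snr_auc_min = Inf)
  expect_true(all(is.na(fv2$maps$kpl)))
  expect_equal(fv2$summary$n, c(0, 0))

  expect_warning(fit_volume(series, spec, mask = array(FALSE, dims)),
                 "empty mask")
})
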
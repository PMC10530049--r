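test_that("gamma-variate bolus: delay, unimodal peak location, linearity", {
  expect_equal(gamma_variate_bolus(c(0, 4, 7.9)), c(0, 0, 0))
  # peak location and value against a dense grid search
  tt <- seq(0, 60, by = 0.001)
  v <- gamma_variate_bolus(tt, amplitude = 2.5, delay = 8, shape = 3,
                           scale = 4)
  expect_equal(tt[which.max(v)], 8 + 3 * 4, tolerance = 1e-2)
  expect_equal(max(v), 2.5, tolerance = 1e-6)
  # single mode: rises then falls
  pk <- which.max(v)
  expect_true(all(diff(v[1:pk]) >= 0))
  expect_true(all(diff(v[pk:length(v)]) <= 0))
  # linearity in amplitude
  expect_equal(gamma_variate_bolus(tt, amplitude = 2),
               2 * gamma_variate_bolus(tt, amplitude = 1))
  expect_error(gamma_variate_bolus(tt, shape = 0))
  expect_error(gamma_variate_bolus(-1))
})

test_that("phantom construction is deterministic and validates input", {
  p1 <- make_tissue_phantom(seed = 3)
  p2 <- make_tissue_phantom(seed = 3)
  expect_identical(p1, p2)
  p3 <- make_tissue_phantom(seed = 4)
  expect_false(identical(p1$coil_sensitivities, p3$coil_sensitivities))
  expect_error(make_tissue_phantom(matrix = c(4, 4)), "too small")
})

test_that("tissue fractions are proper and empty phantoms give zero rates", {
  ph <- make_tissue_phantom(seed = 1)
  fr <- ph$tissue_fractions
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(max(apply(fr, 1:3, sum)) <= 1 + 1e-12)
  expect_true(all(ph$kpl_map >= 0) && all(ph$kpg_map >= 0))
  # rates are intensive: wherever there is tissue of one class only, the
  # voxel carries that class's rate regardless of partial volume
  gm_only <- fr[, , , "gm"] > 0 & apply(fr[, , , c("wm", "csf", "vessel")],
                                        1:3, sum) == 0
  expect_true(all(abs(ph$kpl_map[gm_only] - 0.012) < 1e-12))

  empty <- make_tissue_phantom(seed = 1, head_axes_frac = c(0, 0))
  expect_true(all(empty$tissue_fractions == 0))
  expect_true(all(empty$kpl_map == 0) && all(empty$kpg_map == 0))
})

test_that("GM voxel count matches an independent recount of the fraction map", {
  ph <- make_tissue_phantom(seed = 1)
  fr <- ph$tissue_fractions
  fast <- sum(fr[, , , "gm"] > 0.5)
  slow <- 0L
  dm <- dim(fr)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (s in seq_len(dm[3]))
    if (fr[i, j, s, "gm"] > 0.5) slow <- slow + 1L
  expect_gt(fast, 0)
  expect_identical(fast, slow)
})

test_that("noiseless single uniform-gain coil reproduces the sidecar exactly", {
  proto <- hp_protocol(matrix = c(16, 16), n_slices = 2, n_frames = 12)
  ph <- make_tissue_phantom(matrix = c(16, 16), n_slices = 2, seed = 2,
                            n_coils = 1, noise_sigma = 0)
  ds <- generate_dataset(proto, ph)
  expect_equal(dim(ds$stack$data), c(1, 16, 16, 2, 12, 4))
  got <- abs(array(ds$stack$data[1, , , , , ], dim(ds$noiseless)))
  expect_equal(got, ds$noiseless, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dataset generation is deterministic and kPL=kPG=0 leaves only noise", {
  proto <- hp_protocol(matrix = c(16, 16), n_slices = 1, n_frames = 10)
  ph <- make_tissue_phantom(matrix = c(16, 16), n_slices = 1, seed = 5,
                            n_coils = 4,
                            kpl = c(gm = 0, wm = 0, csf = 0, vessel = 0),
                            kpg = c(gm = 0, wm = 0, csf = 0, vessel = 0))
  ds1 <- generate_dataset(proto, ph)
  ds2 <- generate_dataset(proto, ph)
  expect_identical(ds1$stack$data, ds2$stack$data)
  expect_true(all(ds1$noiseless[, , , , c("glutamate", "lactate_downfield",
                                          "lactate_upfield")] == 0))
  # the observed metabolite channels are then pure noise at sigma
  glu <- ds1$stack$data[, , , , , 2]
  expect_equal(sd(Re(glu)), ph$noise_sigma, tolerance = 0.05)
})

test_that("appended noise block matches the nominal sigma", {
  proto <- hp_protocol(matrix = c(32, 32), n_slices = 5)
  ph <- make_tissue_phantom(seed = 1, n_coils = 2, noise_sigma = 0.02)
  ds <- generate_dataset(proto, ph, n_noise_frames = 2)
  nf <- ds$stack$noise_frames
  expect_gte(ncol(nf), 1e4)
  expect_lt(abs(sd(Re(nf)) - 0.02) / 0.02, 0.05)
  expect_lt(abs(sd(Im(nf)) - 0.02) / 0.02, 0.05)
})

test_that("doublet split is consistent and recovers total lactate", {
  proto <- hp_protocol(matrix = c(16, 16), n_slices = 1, n_frames = 10)
  ph <- make_tissue_phantom(matrix = c(16, 16), n_slices = 1, seed = 6,
                            n_coils = 1, noise_sigma = 0,
                            doublet_asymmetry = 0.77)
  ds <- generate_dataset(proto, ph)
  down <- ds$noiseless[, , , , "lactate_downfield"]
  up <- ds$noiseless[, , , , "lactate_upfield"]
  expect_equal(up, 0.77 * down, tolerance = 1e-12)
  total <- down + up / 0.77          # asymmetry-corrected combination
  expect_equal(total, 2 * down, tolerance = 1e-12)
  # plain sum carries the (1 + asymmetry)/2 amplitude scale
  expect_equal(sum_lactate_doublet(down, up), (1 + 0.77) * down,
               tolerance = 1e-12)
})

test_that("vessel-voxel pyruvate equals the kinetics module's evolution of
          the bolus", {
  proto <- hp_protocol()
  ph <- make_tissue_phantom(seed = 1, noise_sigma = 0)
  ds <- generate_dataset(proto, ph)
  fr <- ph$tissue_fractions
  idx <- which(fr[, , , "vessel"] == 1, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  v <- idx[1, ]
  spec <- ds$spec
  spec$k_pl <- ph$kpl_map[v[1], v[2], v[3]]
  spec$k_pg <- ph$kpg_map[v[1], v[2], v[3]]
  u <- ph$delivery_map[v[1], v[2], v[3]] *
    gamma_variate_bolus(frame_times(proto)) * proto$tr
  sim <- simulate_dynamics(spec, u)
  expect_equal(as.numeric(ds$noiseless[v[1], v[2], v[3], , "pyruvate"]),
               as.numeric(sim[, "pyruvate"]), tolerance = 1e-10)
})

test_that("rejects inconsistent grids and negative noise", {
  proto <- hp_protocol()
  ph <- make_tissue_phantom(matrix = c(16, 16), n_slices = 1, seed = 1)
  expect_error(generate_dataset(proto, ph), "inconsistent")
  expect_error(make_tissue_phantom(noise_sigma = -1))
})
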
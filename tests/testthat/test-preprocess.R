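# Minimal coil stack wrapper around raw arrays for unit tests.
make_stack <- function(data, noise_frames,
                       channel_names = c("pyruvate", "glutamate",
                                         "lactate_downfield",
                                         "lactate_upfield")) {
  structure(list(data = data, noise_frames = noise_frames,
                 protocol = NULL, channel_names = channel_names),
            class = "hp_coil_stack")
}

cnoise <- function(n_coils, n, sigma = 1, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(n_coils * n, sd = sigma),
                 imaginary = rnorm(n_coils * n, sd = sigma)), n_coils, n)
}

test_that("sample covariance of i.i.d. noise approaches identity", {
  x <- cnoise(4, 1e5, sigma = sqrt(0.5))  # unit variance per complex sample
  cv <- estimate_noise_covariance(x)
  C <- cv$matrix
  expect_equal(C, Conj(t(C)))  # Hermitian
  expect_true(all(Re(eigen(C, only.values = TRUE)$values) > -1e-12))
  expect_lt(max(Mod(C - diag(4))), 0.02)
})

test_that("covariance handles single and duplicated coils", {
  x1 <- cnoise(1, 500)
  cv1 <- estimate_noise_covariance(x1)
  expect_equal(dim(cv1$matrix), c(1, 1))
  expect_gt(Re(cv1$matrix[1, 1]), 0)
  x <- cnoise(2, 2000)
  xdup <- rbind(x, x[2, ])
  cvd <- estimate_noise_covariance(xdup)$matrix
  expect_equal(cvd[2, 3], cvd[2, 2])  # perfectly correlated channels
  expect_equal(cvd[3, 3], cvd[2, 2])
  expect_warning(estimate_noise_covariance(cnoise(5, 3)), "rank-deficient")
})

test_that("prewhitening restores identity covariance from known mixing", {
  n_coils <- 4
  mixv <- matrix(complex(real = c(2, .5, 0, 0, 0, 1.5, .7, 0, 0, 0, 1, .3,
                                  .2, 0, 0, .8),
                         imaginary = c(0, .3, 0, 0, 0, 0, .2, 0, 0, 0, 0,
                                       .1, -.4, 0, 0, 0)), 4, 4)
  z <- mixv %*% cnoise(n_coils, 1e5, sigma = sqrt(0.5), seed = 2)
  dm <- c(n_coils, 4, 4, 1, 10, 1)
  dat <- array(z[, seq_len(prod(dm[-1]))], dm)
  st <- make_stack(dat, z, channel_names = "pyruvate")
  cv <- estimate_noise_covariance(st$noise_frames)
  wst <- prewhiten(st, cv)
  cv2 <- estimate_noise_covariance(wst$noise_frames)
  expect_lt(max(Mod(cv2$matrix - diag(n_coils))), 0.02)
  # whitening already-white data is near-identity (idempotence in
  # distribution)
  wst2 <- prewhiten(wst, cv2)
  expect_lt(max(Mod(wst2$data - wst$data)) / max(Mod(wst$data)), 0.02)
})

test_that("prewhitening with identity and scalar covariances", {
  dat <- array(cnoise(2, 160, seed = 3), c(2, 4, 4, 1, 5, 1))
  st <- make_stack(dat, cnoise(2, 100), channel_names = "pyruvate")
  idc <- structure(list(matrix = diag(2) + 0i, n_samples = 100),
                   class = "hp_noise_cov")
  expect_equal(prewhiten(st, idc)$data, dat, tolerance = 1e-5)
  sc <- structure(list(matrix = diag(2) * 4 + 0i, n_samples = 100),
                  class = "hp_noise_cov")
  expect_equal(prewhiten(st, sc)$data, dat / 2, tolerance = 1e-5)
  sing <- structure(list(matrix = matrix(0i, 2, 2), n_samples = 100),
                    class = "hp_noise_cov")
  expect_error(prewhiten(st, sing, loading = 0), "singular|positive")
})

test_that("combination matches the closed form for known sensitivities", {
  truth <- c(0, 1, 3, 2.5, 1.5, 0.8)
  s1 <- 0.8 * exp(1i * 0.4); s2 <- 1.1 * exp(-1i * 1.0)
  dat <- array(0i, c(2, 1, 1, 1, 6, 1))
  dat[1, 1, 1, 1, , 1] <- s1 * truth
  dat[2, 1, 1, 1, , 1] <- s2 * truth
  st <- make_stack(dat, cnoise(2, 100), channel_names = "pyruvate")
  comb <- coil_combine(st, "pyruvate")
  expect_equal(Mod(comb[1, 1, 1, , 1]),
               sqrt(Mod(s1)^2 + Mod(s2)^2) * truth, tolerance = 1e-10)
})

test_that("combination is invariant to coil order and handles zero voxels", {
  set.seed(4)
  dat <- array(cnoise(3, 3 * 2 * 2 * 1 * 8 * 1 / 3, seed = 4), c(3, 2, 2, 1, 8, 1))
  dat[, 2, 2, 1, , 1] <- 0
  st <- make_stack(dat, cnoise(3, 50), channel_names = "pyruvate")
  c1 <- coil_combine(st)
  st2 <- st; st2$data <- dat[c(3, 1, 2), , , , , , drop = FALSE]
  c2 <- coil_combine(st2)
  expect_equal(Mod(c1), Mod(c2), tolerance = 1e-9)
  expect_true(all(c1[2, 2, 1, , 1] == 0))
  expect_false(any(is.nan(Mod(c1))))
})

test_that("single coil with unit sensitivity passes through combination", {
  truth <- seq(0, 2, length.out = 10)
  dat <- array(0i, c(1, 1, 1, 1, 10, 1))
  dat[1, 1, 1, 1, , 1] <- truth
  st <- make_stack(dat, cnoise(1, 50), channel_names = "pyruvate")
  comb <- coil_combine(st)
  expect_equal(Mod(comb[1, 1, 1, , 1]), truth, tolerance = 1e-12)
})

test_that("phasing is exact for real input, invariant to global phase, and
          removes a known phase at the peak", {
  x <- array(0, c(2, 2, 1, 6))
  x[1, 1, 1, ] <- c(0, 1, 4, 3, 2, 1)
  expect_equal(phase_correct(x + 0i), x)
  rot <- (x + 0i) * exp(1i * 1.1)
  expect_equal(phase_correct(rot), x, tolerance = 1e-12)
  # per-frame phase ramp: residual imaginary energy at the peak is tiny
  ramp <- exp(1i * seq(0, 0.4, length.out = 6))
  y <- array(0i, c(1, 1, 1, 6))
  y[1, 1, 1, ] <- c(0, 1, 4, 3, 2, 1) * ramp * exp(1i * 0.7)
  out <- phase_correct(y)
  pk <- which.max(abs(out[1, 1, 1, ]))
  orig_pk <- Mod(y[1, 1, 1, pk])
  expect_lt((orig_pk^2 - out[1, 1, 1, pk]^2) / orig_pk^2, 0.01)
})

test_that("the noiseless preprocess chain is a positive gain times truth", {
  proto <- hp_protocol(matrix = c(16, 16), n_slices = 1, n_frames = 10)
  ph <- make_tissue_phantom(matrix = c(16, 16), n_slices = 1, seed = 8,
                            n_coils = 6, noise_sigma = 0)
  ds <- generate_dataset(proto, ph)
  phs <- phase_correct(coil_combine(ds$stack))
  # weights derive from pyruvate, so only voxels with pyruvate signal carry
  # a defined combination (block replication can put metabolite signal on
  # fine voxels whose own pyruvate is zero; those combine to 0 by design)
  pyr_nz <- apply(ds$noiseless[, , , , "pyruvate"], 1:3, max) > 1e-9
  nz <- ds$noiseless > 1e-9 &
    array(rep(pyr_nz, times = prod(dim(ds$noiseless)[4:5])),
          dim(ds$noiseless))
  gain <- phs[nz] / ds$noiseless[nz]
  expect_true(all(gain > 0))
  # unit-RSS coil array: gain field is 1
  expect_lt(max(abs(gain - 1)), 1e-6)
})
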
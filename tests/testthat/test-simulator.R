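test_that("the phantom volume is reproducible, nonnegative and asymmetric", {
  v1 <- make_phantom(24, seed = 5)
  v2 <- make_phantom(24, seed = 5)
  expect_identical(v1$density, v2$density)
  expect_true(all(is.finite(v1$density)) && all(v1$density >= 0))
  mirror <- v1$density[24:1, , ]
  expect_gt(sqrt(sum((v1$density - mirror)^2)), 0.01 * sqrt(sum(v1$density^2)))
})

test_that("orientation centers cover the upper hemisphere near-uniformly", {
  one <- sample_orientation_centers(1, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_true(one$theta >= 0 && one$theta <= 90)
  d1 <- euler_to_direction(one$phi, one$theta)
  expect_equal(sum(d1^2), 1, tolerance = 1e-12)

  cen <- sample_orientation_centers(100, seed = 2)
  expect_true(all(cen$theta >= 0 & cen$theta <= 90))
  dirs <- euler_to_direction(cen$phi, cen$theta)
  G <- tcrossprod(dirs)
  ang <- acos(pmin(1, pmax(-1, G[upper.tri(G)]))) * 180 / pi
  expect_gt(min(ang), 5)
})

test_that("orientation clusters have the requested angular spread", {
  cen <- sample_orientation_centers(5, seed = 3)
  exact <- sample_orientations_around(cen, 4, angular_sigma = 0, seed = 4)
  cd <- euler_to_direction(cen$phi, cen$theta)
  sd_dirs <- euler_to_direction(exact$phi, exact$theta)
  expect_equal(sd_dirs, cd[exact$center_index, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  # tangent-plane Gaussian: E[deflection^2] = 2 * sigma^2
  big <- sample_orientations_around(cen[1, ], 4000, angular_sigma = 5, seed = 6)
  dirs <- euler_to_direction(big$phi, big$theta)
  defl <- acos(pmin(1, dirs %*% t(cd[1, , drop = FALSE]))) * 180 / pi
  expect_equal(sqrt(mean(defl^2) / 2), 5, tolerance = 0.15)

  expect_true(all(big$psi >= 0 & big$psi < 360))
})

test_that("projection respects geometry, linearity and mass conservation", {
  D <- 24
  vol <- array(0, dim = c(D, D, D))
  vol[8, 15, 3] <- 1  # single voxel spike
  img <- project_volume(vol, list(phi = 0, theta = 0, psi = 0))
  expect_equal(img[8, 15], 1)
  expect_equal(sum(img), 1)

  v1 <- make_phantom(D, seed = 7)$density
  v2 <- make_phantom(D, seed = 8)$density
  o <- list(phi = 40, theta = 55, psi = 10)
  expect_equal(project_volume(v1 + v2, o),
               project_volume(v1, o) + project_volume(v2, o),
               tolerance = 1e-6)

  # mass conserved under rotation within interpolation tolerance
  expect_equal(sum(project_volume(v1, o)), sum(v1), tolerance = 0.01)
})

test_that("the CTF has the standard low-frequency and bounded behavior", {
  prm <- ctf_params(defocus = 2, voltage = 300, cs = 2, amplitude_contrast = 0.07)
  expect_equal(ctf_eval(0, prm), -0.07)
  f <- seq(0, 0.5, by = 1e-3)
  vals <- ctf_eval(f, prm)
  expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))

  # first zero agrees with an independent root-finder on the same physics
  i0 <- which(diff(sign(vals)) != 0)[1]
  lam <- 12.2643 / sqrt(3e5 * (1 + 0.978476e-6 * 3e5))
  gam <- function(fr) pi * lam * 2e4 * fr^2 - pi / 2 * 2e7 * lam^3 * fr^4
  ctf_fun <- function(fr) -(sqrt(1 - 0.07^2) * sin(gam(fr)) + 0.07 * cos(gam(fr)))
  root <- uniroot(ctf_fun, c(f[i0], f[i0 + 1]), tol = 1e-12)$root
  my_root <- uniroot(function(fr) ctf_eval(fr, prm), c(f[i0], f[i0 + 1]),
                     tol = 1e-12)$root
  expect_equal(my_root, root, tolerance = 1e-9)
})

test_that("CTF filtering is real, phase flipping an involution, |CTF| exact", {
  img <- smooth_image(32) + 0.1 * matrix(rnorm(1024), 32, 32)
  prm <- ctf_params(defocus = 1.5, pixel_size = 2)
  mod <- apply_ctf(img, prm)
  expect_true(is.numeric(mod) && all(is.finite(mod)))

  flipped <- phase_flip(img, prm)
  expect_equal(phase_flip(flipped, prm), img, tolerance = 1e-10)

  # flip(apply_ctf(x)) has spectrum |CTF| * X
  both <- phase_flip(apply_ctf(img, prm), prm)
  lam <- 12.2643 / sqrt(3e5 * (1 + 0.978476e-6 * 3e5))
  f1 <- c(0:15, -16:-1) / (32 * 2)
  fr <- sqrt(outer(f1^2, f1^2, `+`))
  gam <- pi * lam * 1.5e4 * fr^2 - pi / 2 * 2e7 * lam^3 * fr^4
  H <- -(sqrt(1 - 0.07^2) * sin(gam) + 0.07 * cos(gam))
  want <- Re(fft(fft(img) * abs(H), inverse = TRUE)) / 1024
  expect_equal(both, want, tolerance = 1e-8)
})

test_that("additive noise hits the target SNR and is seeded", {
  img <- smooth_image(64)
  noisy <- add_gaussian_noise(img, snr = 1 / 10, seed = 9)
  ratio <- var(as.vector(noisy - img)) / var(as.vector(img))
  expect_equal(ratio, 10, tolerance = 0.05)

  expect_identical(add_gaussian_noise(img, 1 / 10, seed = 9), noisy)
  clean <- add_gaussian_noise(img, snr = 1e9, seed = 9)
  expect_lt(max(abs(clean - img)), 1e-3)
  expect_error(add_gaussian_noise(matrix(1, 4, 4), 1), "variance")
})

test_that("the simulation pipeline is deterministic with full ground truth", {
  cfg <- sim_config(D = 16, n_centers = 3, per_center = 4, seed = 12)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$stack$pixels, d2$stack$pixels)
  expect_identical(d1$orientations, d2$orientations)

  expect_equal(n_images(d1$stack), 12)
  expect_equal(nrow(d1$orientations), 12)
  expect_equal(nrow(d1$ctf), 12)
  expect_true(all(d1$orientations$center_index %in% 1:3))
  expect_true(all(d1$ctf$defocus_um >= 1 & d1$ctf$defocus_um <= 3))
})

test_that("without noise, spread or in-plane rotation, clustermates coincide", {
  # noise amplitude scales as 1/sqrt(snr); snr = 1e14 keeps it below the
  # 1e-6 comparison tolerance
  cfg <- sim_config(D = 16, n_centers = 2, per_center = 3, angular_sigma = 0,
                    snr = 1e14, defocus_range = c(2, 2 + 1e-12),
                    random_psi = FALSE, seed = 13)
  ds <- simulate_dataset(cfg)
  for (ci in 1:2) {
    rows <- which(ds$orientations$center_index == ci)
    base <- ds$stack$pixels[rows[1], ]
    for (r in rows[-1]) {
      expect_equal(ds$stack$pixels[r, ], base, tolerance = 1e-6)
    }
  }
})
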
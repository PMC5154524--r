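# Ground-truth benchmark simulator: projections of an asymmetric phantom
# density from Gaussian-clustered hemisphere orientations, CTF modulation,
# additive Gaussian noise at a target SNR, and phase flipping.

#' Asymmetric Gaussian-blob phantom volume
#'
#' Builds a reproducible `D x D x D` density as a sum of `n_blobs`
#' anisotropic Gaussian blobs with seeded random centers, widths,
#' orientations and amplitudes, confined to a sphere of radius `0.4 * D`
#' around the volume center. With several randomly oriented anisotropic
#' blobs the density has no mirror or rotational symmetry, so distinct
#' projection directions give distinct images. A synthetic stand-in for a
#' macromolecular density map; any external MRC volume can be used instead
#' via the pipeline configuration.
#'
#' @param D cube side in voxels (>= 16).
#' @param n_blobs number of blobs (>= 3).
#' @param seed integer seed.
#' @param voxel_size voxel size in Angstrom (metadata only).
#' @return List of class `"sim_volume"` with elements `density` (array),
#'   `voxel_size`.
#' @export
make_phantom <- function(D, n_blobs = 8L, seed = 1L, voxel_size = 2.0) {
  D <- as.integer(D)
  if (D < 16L) stop("phantom side must be at least 16 voxels", call. = FALSE)
  if (n_blobs < 3L) stop("need at least 3 blobs", call. = FALSE)
  ctr <- D %/% 2
  prm <- local_seed(seed, {
    lapply(seq_len(n_blobs), function(b) {
      u <- stats::rnorm(3)
      r <- 0.25 * D * stats::runif(1)^(1 / 3)
      list(center = ctr + r * u / sqrt(sum(u^2)),
           widths = stats::runif(3, D / 16, D / 8),
           rot = qr.Q(qr(matrix(stats::rnorm(9), 3, 3))),
           amp = stats::runif(1, 0.5, 1.5))
    })
  })
  g <- 0:(D - 1L)
  coords <- as.matrix(expand.grid(x = g, y = g, z = g))
  dens <- numeric(nrow(coords))
  for (b in prm) {
    d <- sweep(coords, 2L, b$center)
    local <- d %*% b$rot
    q <- (local[, 1] / b$widths[1])^2 + (local[, 2] / b$widths[2])^2 +
      (local[, 3] / b$widths[3])^2
    dens <- dens + b$amp * exp(-0.5 * q)
  }
  # zero density outside the supporting sphere
  rad2 <- rowSums(sweep(coords, 2L, rep(ctr, 3))^2)
  dens[rad2 > (0.4 * D)^2] <- 0
  structure(list(density = array(dens, dim = c(D, D, D)),
                 voxel_size = voxel_size),
            class = "sim_volume")
}

#' Projection directions from ZYZ Euler angles
#'
#' The projection axis of an orientation `(phi, theta, psi)` (intrinsic ZYZ,
#' right-handed, degrees) is the rotated z-axis
#' `(cos(phi) sin(theta), sin(phi) sin(theta), cos(theta))`; the in-plane
#' angle `psi` does not affect it.
#'
#' @param phi,theta Euler angles in degrees (vectors of equal length).
#' @return `n x 3` matrix of unit direction vectors.
#' @export
euler_to_direction <- function(phi, theta) {
  pr <- phi * pi / 180
  tr <- theta * pi / 180
  cbind(cos(pr) * sin(tr), sin(pr) * sin(tr), cos(tr))
}

# ZYZ intrinsic rotation matrix, degrees.
rotation_zyz <- function(phi, theta, psi) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(phi) %*% ry(theta) %*% rz(psi)
}

#' Near-uniform orientation centers on the upper hemisphere
#'
#' Places `m` projection directions approximately uniformly over the upper
#' hemisphere (`theta` in `[0, 90]` degrees) with a generalized
#' (golden-angle) spiral: `cos(theta)` descends uniformly while the azimuth
#' advances by the golden angle, plus a seeded common azimuthal offset.
#' Deterministic given `m` and `seed`; `psi = 0` for all centers.
#'
#' @param m number of centers (>= 1).
#' @param seed integer seed (azimuthal offset only).
#' @return Data frame with columns `phi`, `theta`, `psi` (degrees).
#' @export
sample_orientation_centers <- function(m, seed = 1L) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be at least 1", call. = FALSE)
  offset <- local_seed(seed, stats::runif(1, 0, 360))
  i <- seq_len(m)
  z <- 1 - (i - 0.5) / m            # cos(theta), uniform on (0, 1)
  golden <- 180 * (3 - sqrt(5))     # golden angle in degrees
  phi <- (offset + i * golden) %% 360
  data.frame(phi = phi, theta = acos(z) * 180 / pi, psi = 0)
}

#' Gaussian-clustered orientations around given centers
#'
#' For each center direction, draws `per_center` orientations whose
#' directions are perturbed by a tangent-plane Gaussian: two independent
#' `N(0, angular_sigma)` components along an orthonormal tangent basis,
#' applied as a rotation away from the center by the resulting deflection
#' angle. In-plane angles `psi` are uniform on `[0, 360)`. The deflection
#' magnitude is Rayleigh-distributed with `E[deflection^2] =
#' 2 * angular_sigma^2`.
#'
#' @param centers data frame with `phi`, `theta` (degrees), e.g. from
#'   [sample_orientation_centers()].
#' @param per_center samples per center (>= 1).
#' @param angular_sigma tangent-plane Gaussian width in degrees (>= 0).
#' @param seed integer seed.
#' @return Data frame with columns `phi`, `theta`, `psi`, `center_index`
#'   (1-based row of `centers`).
#' @export
sample_orientations_around <- function(centers, per_center, angular_sigma = 5,
                                       seed = 1L) {
  if (per_center < 1L) stop("per_center must be at least 1", call. = FALSE)
  if (angular_sigma < 0) stop("angular_sigma must be nonnegative", call. = FALSE)
  m <- nrow(centers)
  dirs <- euler_to_direction(centers$phi, centers$theta)
  local_seed(seed, {
    out <- vector("list", m)
    srad <- angular_sigma * pi / 180
    for (ci in seq_len(m)) {
      d <- dirs[ci, ]
      # orthonormal tangent basis at d
      ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- ref - sum(ref * d) * d
      u <- u / sqrt(sum(u^2))
      v <- c(d[2] * u[3] - d[3] * u[2],
             d[3] * u[1] - d[1] * u[3],
             d[1] * u[2] - d[2] * u[1])
      a <- stats::rnorm(per_center, 0, srad)
      b <- stats::rnorm(per_center, 0, srad)
      alpha <- sqrt(a^2 + b^2)
      az <- atan2(b, a)
      nd <- cos(alpha) %o% d +
        (sin(alpha) * cos(az)) %o% u +
        (sin(alpha) * sin(az)) %o% v
      nd <- nd / sqrt(rowSums(nd^2))
      out[[ci]] <- data.frame(
        phi = (atan2(nd[, 2], nd[, 1]) * 180 / pi) %% 360,
        theta = acos(pmin(1, pmax(-1, nd[, 3]))) * 180 / pi,
        psi = stats::runif(per_center, 0, 360),
        center_index = ci)
    }
    do.call(rbind, out)
  })
}

#' Project a volume along an orientation
#'
#' Rotates the sampling grid by the ZYZ Euler angles of the orientation
#' (trilinear interpolation, zero outside the cube) and sums along the
#' z-axis. Linear in the volume; at the identity orientation the projection
#' is the plain z-sum.
#'
#' @param volume a `"sim_volume"` from [make_phantom()] or a `D x D x D`
#'   array.
#' @param orientation list/row with `phi`, `theta`, `psi` in degrees.
#' @return `D x D` numeric matrix.
#' @export
project_volume <- function(volume, orientation) {
  vol <- if (inherits(volume, "sim_volume")) volume$density else volume
  D <- dim(vol)[1]
  ctr <- D %/% 2
  R <- rotation_zyz(orientation$phi, orientation$theta, orientation$psi)
  g <- 0:(D - 1L) - ctr
  P <- as.matrix(expand.grid(x = g, y = g, z = g))
  Q <- P %*% t(R)
  sx <- Q[, 1] + ctr
  sy <- Q[, 2] + ctr
  sz <- Q[, 3] + ctr
  vals <- trilinear_sample(vol, sx, sy, sz)
  # sum over z (third, slowest-varying index of the expand.grid)
  matrix(rowSums(matrix(vals, D * D, D)), D, D)
}

trilinear_sample <- function(vol, sx, sy, sz) {
  D1 <- dim(vol)[1]; D2 <- dim(vol)[2]; D3 <- dim(vol)[3]
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  val <- function(xi, yi, zi) {
    ok <- xi >= 0 & xi <= D1 - 1L & yi >= 0 & yi <= D2 - 1L &
      zi >= 0 & zi <= D3 - 1L
    v <- numeric(length(xi))
    v[ok] <- vol[cbind(xi[ok] + 1L, yi[ok] + 1L, zi[ok] + 1L)]
    v
  }
  (1 - fx) * (1 - fy) * (1 - fz) * val(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * val(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * val(x0, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * val(x0, y0, z0 + 1) +
    fx * fy * (1 - fz) * val(x0 + 1, y0 + 1, z0) +
    fx * (1 - fy) * fz * val(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * val(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * val(x0 + 1, y0 + 1, z0 + 1)
}

#' Contrast transfer function parameters
#'
#' @param defocus defocus in micrometers (> 0; underfocus positive).
#' @param voltage acceleration voltage in kV.
#' @param cs spherical aberration in mm.
#' @param amplitude_contrast amplitude-contrast fraction in `[0, 1)`.
#' @param pixel_size pixel size in Angstrom.
#' @return List of class `"ctf_params"`.
#' @export
ctf_params <- function(defocus = 2.0, voltage = 300, cs = 2.0,
                       amplitude_contrast = 0.07, pixel_size = 2.0) {
  if (defocus <= 0) stop("defocus must be positive", call. = FALSE)
  if (voltage <= 0) stop("voltage must be positive", call. = FALSE)
  if (amplitude_contrast < 0 || amplitude_contrast >= 1) {
    stop("amplitude_contrast must lie in [0, 1)", call. = FALSE)
  }
  structure(list(defocus = defocus, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "ctf_params")
}

# Relativistic electron wavelength in Angstrom for voltage in kV.
electron_wavelength <- function(voltage_kv) {
  V <- voltage_kv * 1e3
  12.2643 / sqrt(V * (1 + 0.978476e-6 * V))
}

#' Evaluate the contrast transfer function
#'
#' Standard weak-phase-object CTF:
#' `CTF(f) = -(sqrt(1 - A^2) * sin(gamma(f)) + A * cos(gamma(f)))` with
#' phase perturbation
#' `gamma(f) = pi * lambda * dz * f^2 - (pi/2) * Cs * lambda^3 * f^4`,
#' electron wavelength `lambda` from the relativistic formula at the given
#' voltage, defocus `dz` and spherical aberration `Cs` converted to
#' Angstrom. At `f = 0` the value is `-A` (pure amplitude contrast); all
#' values lie in `[-1, 1]`.
#'
#' @param freq spatial frequencies in 1/Angstrom (nonnegative).
#' @param params a [ctf_params()].
#' @return Numeric vector/array of CTF values, same shape as `freq`.
#' @export
ctf_eval <- function(freq, params) {
  lam <- electron_wavelength(params$voltage)
  dz <- params$defocus * 1e4   # um -> A
  cs <- params$cs * 1e7        # mm -> A
  A <- params$amplitude_contrast
  gamma <- pi * lam * dz * freq^2 - (pi / 2) * cs * lam^3 * freq^4
  -(sqrt(1 - A^2) * sin(gamma) + A * cos(gamma))
}

# Radial frequency grid (1/A) matching R's fft layout for a D x D image.
fft_radial_freq <- function(D, pixel_size) {
  f1 <- c(0:(ceiling(D / 2) - 1L), -(floor(D / 2):1)) / (D * pixel_size)
  sqrt(outer(f1^2, f1^2, `+`))
}

#' Apply or sign-correct a contrast transfer function
#'
#' `apply_ctf()` multiplies the image's Fourier transform by the CTF
#' evaluated on the radial frequency grid and inverse-transforms (the
#' filter is real and radially symmetric, so the output is real).
#' `phase_flip()` multiplies by the sign of the CTF only (sign of 0 taken
#' as +1, making the operation an exact involution); flipping a
#' CTF-modulated image leaves its spectrum modulated by `|CTF|`, the usual
#' first-order CTF correction.
#'
#' @param image `D x D` numeric matrix.
#' @param params a [ctf_params()].
#' @return Filtered `D x D` matrix.
#' @export
apply_ctf <- function(image, params) {
  ctf_filter(image, function(H) H, params)
}

#' @rdname apply_ctf
#' @export
phase_flip <- function(image, params) {
  ctf_filter(image, function(H) ifelse(H < 0, -1, 1), params)
}

ctf_filter <- function(image, fmod, params) {
  image <- as.matrix(image)
  D <- nrow(image)
  if (ncol(image) != D) stop("image must be square", call. = FALSE)
  H <- fmod(ctf_eval(fft_radial_freq(D, params$pixel_size), params))
  Re(stats::fft(stats::fft(image) * H, inverse = TRUE)) / (D * D)
}

#' Add Gaussian noise at a target signal-to-noise ratio
#'
#' Adds i.i.d. zero-mean Gaussian noise with variance `var(image) / snr`
#' (SNR defined as the ratio of signal pixel variance to noise variance,
#' the dominant cryo-EM convention).
#'
#' @param image numeric matrix.
#' @param snr positive signal-to-noise ratio (e.g. `1/10`).
#' @param seed integer seed.
#' @return Noisy matrix of the same shape.
#' @export
add_gaussian_noise <- function(image, snr, seed = 1L) {
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  v <- stats::var(as.vector(image))
  if (v == 0) stop("image has zero variance; SNR is undefined", call. = FALSE)
  noise <- local_seed(seed, stats::rnorm(length(image), 0, sqrt(v / snr)))
  image + array(noise, dim = dim(image))
}

#' Simulation configuration
#'
#' Defaults follow the benchmark recipe at desk scale: 20 orientation
#' centers with 50 projections each (n = 1000), tangent-plane angular
#' spread 5 degrees, SNR 1/10, 300 kV, Cs 2 mm, amplitude contrast 0.07,
#' per-image defocus uniform on 1.0-3.0 um, 2.0 A/pixel, phase-flipped
#' output. The full-scale benchmark uses `n_centers = 100`,
#' `per_center = 100` (n = 10000).
#'
#' @param D image/volume side in pixels.
#' @param n_centers number of orientation centers on the hemisphere.
#' @param per_center projections per center.
#' @param angular_sigma orientation cluster width in degrees.
#' @param snr target signal-to-noise ratio.
#' @param defocus_range per-image defocus range in micrometers.
#' @param voltage,cs,amplitude_contrast,pixel_size CTF parameters.
#' @param n_blobs phantom blob count.
#' @param random_psi draw the in-plane angle `psi` uniformly on
#'   `[0, 360)` (default); with `FALSE`, `psi = 0` for every image, which
#'   makes same-center images at `angular_sigma = 0` pixel-identical up to
#'   CTF and noise.
#' @param apply_phase_flip phase-flip the final images (CTF correction).
#' @param seed master seed; stage seeds are derived from it.
#' @param volume optional pre-built `"sim_volume"` (or array) overriding
#'   the phantom.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(D = 32L, n_centers = 20L, per_center = 50L,
                       angular_sigma = 5, snr = 1 / 10,
                       defocus_range = c(1.0, 3.0), voltage = 300, cs = 2.0,
                       amplitude_contrast = 0.07, pixel_size = 2.0,
                       n_blobs = 8L, random_psi = TRUE,
                       apply_phase_flip = TRUE, seed = 1L, volume = NULL) {
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  if (length(defocus_range) != 2L || any(defocus_range <= 0)) {
    stop("defocus_range must be two positive values", call. = FALSE)
  }
  structure(list(D = as.integer(D), n_centers = as.integer(n_centers),
                 per_center = as.integer(per_center),
                 angular_sigma = angular_sigma, snr = snr,
                 defocus_range = sort(defocus_range), voltage = voltage,
                 cs = cs, amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size, n_blobs = as.integer(n_blobs),
                 random_psi = isTRUE(random_psi),
                 apply_phase_flip = isTRUE(apply_phase_flip),
                 seed = as.integer(seed), volume = volume),
            class = "sim_config")
}

#' Simulate a ground-truth benchmark dataset
#'
#' Full pipeline per image: project the phantom (or supplied volume) along
#' a Gaussian-clustered hemisphere orientation, modulate by the CTF at a
#' per-image uniform random defocus, add Gaussian noise at the target SNR,
#' then phase-flip. Stage seeds derive from `config$seed` (phantom:
#' `seed`; centers: `seed + 1`; orientations: `seed + 2`; defocus:
#' `seed + 3`; noise for image i: `seed + 10000 + i`).
#'
#' @param config a [sim_config()].
#' @return List of class `"simulated_dataset"`: `stack` (an
#'   [image_stack()]), `orientations` (data frame with `phi`, `theta`,
#'   `psi`, `center_index`), `ctf` (per-image data frame with
#'   `defocus_um` and the shared optics), `snr`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  vol <- config$volume %||% make_phantom(config$D, config$n_blobs,
                                         seed = config$seed,
                                         voxel_size = config$pixel_size)
  centers <- sample_orientation_centers(config$n_centers,
                                        seed = config$seed + 1L)
  ori <- sample_orientations_around(centers, config$per_center,
                                    config$angular_sigma,
                                    seed = config$seed + 2L)
  if (!config$random_psi) ori$psi <- 0
  n <- nrow(ori)
  defocus <- local_seed(config$seed + 3L,
                        stats::runif(n, config$defocus_range[1],
                                     config$defocus_range[2]))
  d2 <- config$D^2
  px <- matrix(0, n, d2)
  for (i in seq_len(n)) {
    img <- project_volume(vol, ori[i, ])
    ctf <- ctf_params(defocus[i], config$voltage, config$cs,
                      config$amplitude_contrast, config$pixel_size)
    img <- apply_ctf(img, ctf)
    img <- add_gaussian_noise(img, config$snr,
                              seed = config$seed + 10000L + i)
    if (config$apply_phase_flip) img <- phase_flip(img, ctf)
    px[i, ] <- as.vector(img)
  }
  structure(list(
    stack = image_stack(px, config$D),
    orientations = ori,
    ctf = data.frame(defocus_um = defocus, voltage = config$voltage,
                     cs = config$cs,
                     amplitude_contrast = config$amplitude_contrast,
                     pixel_size = config$pixel_size),
    snr = config$snr,
    config = config
  ), class = "simulated_dataset")
}
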
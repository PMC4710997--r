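#' Per-voxel diffusion tensor field
#'
#' Stores a 3 x 3 symmetric positive-semidefinite diffusion tensor (mm^2/s)
#' at every voxel of a `(rows, cols, n_slices)` grid, plus a logical mask of
#' non-background voxels. Background voxels are expected to hold small
#' isotropic tensors.
#'
#' @param tensors Numeric array of dimension `(rows, cols, n_slices, 3, 3)`.
#' @param mask Logical array `(rows, cols, n_slices)`.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(tensors, mask) {
  d <- dim(tensors)
  if (length(d) != 5L || d[4] != 3L || d[5] != 3L)
    stop_data("`tensors` must be a (rows, cols, n_slices, 3, 3) array")
  if (!identical(dim(mask), d[1:3]))
    stop_data("`mask` dimensions must match the voxel grid")
  asym <- max(abs(tensors - aperm(tensors, c(1, 2, 3, 5, 4))))
  if (asym > 1e-12)
    stop_data("tensors must be symmetric (max asymmetry ", signif(asym, 3), ")")
  structure(list(tensors = tensors, mask = array(as.logical(mask), d[1:3])),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$tensors)
  cat("tensor_field:", d[1], "x", d[2], "x", d[3], "voxels;",
      sum(x$mask), "masked\n")
  invisible(x)
}

# Smooth pseudo-random scalar field in roughly [-1, 1], built from a few
# low-frequency cosine components; deterministic given the RNG state.
smooth_random_field <- function(shape, n_comp = 4L, freq = 1.5) {
  r <- shape[1]; cc <- shape[2]; s <- shape[3]
  x <- matrix(seq_len(r) / r, r, cc)
  y <- matrix(seq_len(cc) / cc, r, cc, byrow = TRUE)
  out <- array(0, shape)
  amp <- stats::runif(n_comp, 0.3, 1)
  fx <- stats::runif(n_comp, -freq, freq)
  fy <- stats::runif(n_comp, -freq, freq)
  fz <- stats::runif(n_comp, -freq, freq)
  ph <- stats::runif(n_comp, 0, 2 * pi)
  for (l in seq_len(s)) {
    sl <- 0
    for (j in seq_len(n_comp))
      sl <- sl + amp[j] * cos(2 * pi * (fx[j] * x + fy[j] * y) +
                                fz[j] * l / s + ph[j])
    out[, , l] <- sl
  }
  out / sum(amp)
}

# tensor from eigenvalues (mm^2/s) and an in-plane principal angle theta
tensor_from_angle <- function(ev, theta) {
  ct <- cos(theta); st <- sin(theta)
  e1 <- c(ct, st, 0); e2 <- c(-st, ct, 0); e3 <- c(0, 0, 1)
  ev[1] * tcrossprod(e1) + ev[2] * tcrossprod(e2) + ev[3] * tcrossprod(e3)
}

#' Generate a synthetic diffusion tensor field
#'
#' Parametric stand-in for an anatomical DTI volume: a smooth elliptical
#' "tissue" mask containing both strongly anisotropic (FA around 0.8) and
#' near-isotropic (FA below 0.1) regions, with smoothly varying fibre
#' orientation and mild seeded spatial modulation, surrounded by an
#' isotropic low-diffusivity background. Patterns:
#' \describe{
#'   \item{uniform}{every masked voxel is isotropic, diag(0.7, 0.7, 0.7) x
#'     1e-3 mm^2/s (FA = 0).}
#'   \item{two_region}{an inner anisotropic region with rotating in-plane
#'     fibre orientation inside a near-isotropic annulus.}
#'   \item{crossing}{two orthogonal anisotropic stripes; in their overlap the
#'     tensor is planar (two equal large eigenvalues).}
#' }
#'
#' @param shape Integer vector `(rows, cols, n_slices)`.
#' @param pattern One of `"two_region"`, `"uniform"`, `"crossing"`.
#' @param seed Integer seed; the field is bit-identical for equal arguments.
#' @return A [tensor_field()].
#' @examples
#' fld <- make_tensor_field(c(32, 32, 3), "two_region", seed = 1)
#' sum(fld$mask)
#' @export
make_tensor_field <- function(shape = c(64, 64, 5),
                              pattern = c("two_region", "uniform", "crossing"),
                              seed = 1L) {
  if (length(shape) != 3L || !all(vapply(shape, is_count, logical(1))))
    stop_data("`shape` must be three positive integers (rows, cols, slices)")
  pattern <- match.arg(pattern)
  r <- shape[1]; cc <- shape[2]; s <- shape[3]

  xg <- matrix(seq_len(r), r, cc)
  yg <- matrix(seq_len(cc), r, cc, byrow = TRUE)
  cx <- (r + 1) / 2; cy <- (cc + 1) / 2
  rad2 <- ((xg - cx) / (0.45 * r))^2 + ((yg - cy) / (0.45 * cc))^2
  mask2d <- rad2 <= 1
  inner2d <- rad2 <= 0.45

  with_seed(seed, {
    pert_theta <- smooth_random_field(shape)   # orientation jitter
    pert_amp <- smooth_random_field(shape)     # diffusivity modulation

    tensors <- array(0, c(r, cc, s, 3, 3))
    mask <- array(FALSE, c(r, cc, s))
    bg <- diag(0.2e-3, 3)                      # small isotropic background
    iso <- diag(0.7e-3, 3)
    near_iso_ev <- c(0.75, 0.70, 0.65) * 1e-3  # FA ~ 0.07
    aniso_ev <- c(1.7, 0.3, 0.3) * 1e-3        # FA ~ 0.80
    planar_ev <- c(1.0, 1.0, 0.2) * 1e-3       # crossing region

    stripe_h <- abs(xg - cx) <= 0.16 * r       # horizontal band (constant row)
    stripe_v <- abs(yg - cy) <= 0.16 * cc

    for (l in seq_len(s)) {
      mask[, , l] <- mask2d
      for (i in seq_len(r)) for (j in seq_len(cc)) {
        if (!mask2d[i, j]) {
          tensors[i, j, l, , ] <- bg
          next
        }
        scale <- 1 + 0.05 * pert_amp[i, j, l]
        if (pattern == "uniform") {
          tensors[i, j, l, , ] <- iso
        } else if (pattern == "two_region") {
          if (inner2d[i, j]) {
            theta <- pi * (j / cc) + 0.3 * l / s + 0.25 * pert_theta[i, j, l]
            tensors[i, j, l, , ] <- scale * tensor_from_angle(aniso_ev, theta)
          } else {
            tensors[i, j, l, , ] <- scale * diag(near_iso_ev)
          }
        } else {                               # crossing
          if (stripe_h[i, j] && stripe_v[i, j]) {
            tensors[i, j, l, , ] <- scale * diag(planar_ev)
          } else if (stripe_h[i, j]) {
            tensors[i, j, l, , ] <-
              scale * tensor_from_angle(aniso_ev, 0.15 * pert_theta[i, j, l])
          } else if (stripe_v[i, j]) {
            tensors[i, j, l, , ] <-
              scale * tensor_from_angle(aniso_ev,
                                        pi / 2 + 0.15 * pert_theta[i, j, l])
          } else {
            tensors[i, j, l, , ] <- scale * diag(near_iso_ev)
          }
        }
      }
    }
    tensor_field(tensors, mask)
  })
}

#' Diffusion-weighted image sequence
#'
#' A 4D stack of 2D slices across gradient volumes: `data` has dimension
#' `(rows, cols, n_slices, n_volumes)` with `n_volumes` matching the gradient
#' scheme. `sigma` records the Rician noise standard deviation when known
#' (NULL for clean data).
#'
#' @param data Non-negative numeric 4D array.
#' @param scheme A [gradient_scheme()].
#' @param sigma Optional noise standard deviation (same units as `data`).
#' @return An object of class `dwi_sequence`.
#' @export
dwi_sequence <- function(data, scheme, sigma = NULL) {
  d <- dim(data)
  if (length(d) != 4L)
    stop_data("`data` must be a 4D array (rows, cols, n_slices, n_volumes)")
  if (!inherits(scheme, "gradient_scheme"))
    stop_data("`scheme` must be a gradient_scheme")
  if (d[4] != length(scheme$bvals))
    stop_data("number of volumes (", d[4], ") must equal gradient scheme ",
              "length (", length(scheme$bvals), ")")
  if (!is.null(sigma) && (!is_scalar(sigma) || sigma < 0))
    stop_data("`sigma` must be a non-negative scalar or NULL")
  structure(list(data = data, scheme = scheme, sigma = sigma),
            class = "dwi_sequence")
}

#' @export
print.dwi_sequence <- function(x, ...) {
  d <- dim(x$data)
  cat("dwi_sequence:", d[1], "x", d[2], "x", d[3], "voxels,", d[4],
      "volumes; sigma =",
      if (is.null(x$sigma)) "unset" else signif(x$sigma, 4), "\n")
  invisible(x)
}

#' Simulate a clean DWI sequence from a tensor field
#'
#' Evaluates the Stejskal-Tanner signal equation
#' `S = s0 * exp(-b * g' D g)` voxelwise for every volume of the gradient
#' scheme. Inside the mask the b = 0 signal equals `s0` exactly; background
#' voxels are attenuated to `background * s0` to emulate dark air background
#' (their tensors still shape the weighted signal).
#'
#' @param field A [tensor_field()]; masked tensors must be positive
#'   semidefinite (negative eigenvalues would imply signal growth with b).
#' @param scheme A [gradient_scheme()].
#' @param s0 Unweighted signal amplitude inside the mask (default 100,
#'   arbitrary units).
#' @param background Background amplitude as a fraction of `s0`
#'   (default 0.05).
#' @return A clean [dwi_sequence()] with `sigma` unset.
#' @examples
#' fld <- make_tensor_field(c(16, 16, 1), "uniform")
#' dwi <- simulate_dwi(fld, make_gradient_scheme(8), s0 = 100)
#' range(dwi$data[, , , 1][fld$mask])  # b = 0 volume: exactly s0 in mask
#' @export
simulate_dwi <- function(field, scheme, s0 = 100, background = 0.05) {
  if (!inherits(field, "tensor_field")) stop_data("`field` must be a tensor_field")
  if (!inherits(scheme, "gradient_scheme"))
    stop_data("`scheme` must be a gradient_scheme")
  if (!is_scalar(s0) || s0 <= 0) stop_data("`s0` must be positive")

  dims <- dim(field$tensors)[1:3]
  tn <- field$tensors
  # PSD check on masked voxels via the lower-triangular components
  ev_min <- apply_masked_eigmin(tn, field$mask)
  if (ev_min < -1e-10 * max(abs(tn)))
    stop_data("masked tensors must be positive semidefinite ",
              "(most negative eigenvalue ", signif(ev_min, 3), ")")

  nvol <- length(scheme$bvals)
  amp <- array(s0 * background, dims)
  amp[field$mask] <- s0
  data <- array(0, c(dims, nvol))
  Dxx <- array(tn[, , , 1, 1], dims); Dyy <- array(tn[, , , 2, 2], dims)
  Dzz <- array(tn[, , , 3, 3], dims); Dxy <- array(tn[, , , 1, 2], dims)
  Dxz <- array(tn[, , , 1, 3], dims); Dyz <- array(tn[, , , 2, 3], dims)
  for (v in seq_len(nvol)) {
    b <- scheme$bvals[v]
    if (b == 0) {
      data[, , , v] <- amp
    } else {
      g <- scheme$bvecs[, v]
      q <- g[1]^2 * Dxx + g[2]^2 * Dyy + g[3]^2 * Dzz +
        2 * (g[1] * g[2] * Dxy + g[1] * g[3] * Dxz + g[2] * g[3] * Dyz)
      data[, , , v] <- amp * exp(-b * q)
    }
  }
  dwi_sequence(data, scheme, sigma = NULL)
}

# minimum eigenvalue over masked voxels (vectorized closed form would do;
# a loop over masked voxels is clear and fast enough at phantom scales)
apply_masked_eigmin <- function(tensors, mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(0)
  d <- dim(tensors)[1:3]
  ar <- matrix(tensors, prod(d), 9)
  mn <- Inf
  for (i in idx) {
    e <- eigen(matrix(ar[i, ], 3, 3), symmetric = TRUE, only.values = TRUE)
    mn <- min(mn, e$values[3])
  }
  mn
}

#' Add independent Rician noise
#'
#' Each intensity x becomes `sqrt((x + e1)^2 + e2^2)` with `e1`, `e2`
#' independent zero-mean Gaussians of standard deviation `sigma` -- the
#' magnitude of a complex Gaussian perturbation, the standard model for
#' magnitude MR images. Noise is independent across voxels and volumes.
#'
#' @param clean A [dwi_sequence()].
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [dwi_sequence()] with `sigma` recorded.
#' @examples
#' fld <- make_tensor_field(c(16, 16, 1), "uniform")
#' dwi <- simulate_dwi(fld, make_gradient_scheme(8))
#' noisy <- add_rician_noise(dwi, sigma = 10, seed = 7)
#' all(noisy$data >= 0)
#' @export
add_rician_noise <- function(clean, sigma, seed = 1L) {
  if (!inherits(clean, "dwi_sequence")) stop_data("`clean` must be a dwi_sequence")
  if (!is_scalar(sigma) || sigma < 0)
    stop_data("`sigma` must be a non-negative scalar")
  if (sigma == 0) return(dwi_sequence(clean$data, clean$scheme, sigma = 0))
  n <- length(clean$data)
  with_seed(seed, {
    e1 <- rnorm(n, 0, sigma)
    e2 <- rnorm(n, 0, sigma)
    noisy <- sqrt((as.vector(clean$data) + e1)^2 + e2^2)
    dwi_sequence(array(noisy, dim(clean$data)), clean$scheme, sigma = sigma)
  })
}

#' Noise level calibrated from the image centre
#'
#' Returns 1/10 of the mean intensity over the central window of the first
#' b = 0 volume (all slices): the convention used to set the simulated noise
#' standard deviation relative to signal strength.
#'
#' @param clean A [dwi_sequence()] containing a b = 0 volume.
#' @param center_fraction Side length of the central window as a fraction of
#'   each in-plane dimension (default 0.25; 1 uses the whole image).
#' @return Scalar noise standard deviation.
#' @examples
#' fld <- make_tensor_field(c(32, 32, 1), "uniform")
#' dwi <- simulate_dwi(fld, make_gradient_scheme(8), s0 = 100)
#' center_noise_level(dwi)  # 10, i.e. s0 / 10
#' @export
center_noise_level <- function(clean, center_fraction = 0.25) {
  if (!inherits(clean, "dwi_sequence")) stop_data("`clean` must be a dwi_sequence")
  if (!is_scalar(center_fraction) || center_fraction <= 0 || center_fraction > 1)
    stop_data("`center_fraction` must be in (0, 1]")
  ib0 <- which(clean$scheme$bvals == 0)
  if (length(ib0) == 0) stop_data("sequence has no b = 0 volume")
  b0 <- clean$data[, , , ib0[1], drop = FALSE]
  d <- dim(b0)
  wr <- max(1L, round(center_fraction * d[1]))
  wc <- max(1L, round(center_fraction * d[2]))
  r0 <- floor((d[1] - wr) / 2)
  c0 <- floor((d[2] - wc) / 2)
  win <- b0[r0 + seq_len(wr), c0 + seq_len(wc), , 1, drop = FALSE]
  0.1 * mean(win)
}
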
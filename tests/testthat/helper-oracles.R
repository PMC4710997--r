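# Independent oracles and fixture builders used across the suite. All are
# deliberately naive implementations kept separate from the package's own
# algorithms.

rand_unit_dict <- function(n, k) {
  A <- matrix(rnorm(n * k), n, k)
  sweep(A, 2, sqrt(colSums(A^2)), "/")
}

# Minimum-L1 coding under a squared-error budget via glmnet (coordinate
# descent) with bisection on the penalty: an independent convex-programming
# solution of the same constrained problem.
glmnet_l1_oracle <- function(D, y, budget) {
  n <- nrow(D)
  lmax <- max(abs(crossprod(D, y))) / n
  lo <- 1e-12 * lmax
  hi <- lmax
  fit_at <- function(lam) {
    f <- glmnet::glmnet(D, y, intercept = FALSE, standardize = FALSE,
                        lambda = exp(seq(log(lmax), log(lam),
                                         length.out = 15)),
                        thresh = 1e-14, maxit = 1e7)
    as.numeric(f$beta[, ncol(f$beta)])
  }
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    a <- fit_at(mid)
    if (sum((y - D %*% a)^2) > budget) hi <- mid else lo <- mid
  }
  a <- fit_at(lo)
  list(coef = a, l1 = sum(abs(a)), r2 = sum((y - D %*% a)^2))
}

# Literal dense solve of the patch-aggregation normal equations: builds the
# explicit patch-extraction matrices R and solves
# (lam I + sum R'R) x = lam y + sum R' p by dense linear algebra.
dense_aggregate_oracle <- function(y, patchset, coded, lam, slice = 1L) {
  d <- patchset$image_shape
  npix <- d[1] * d[2]
  sel <- which(patchset$origin[, 1] == slice)
  M <- diag(lam, npix)
  rhs <- lam * as.vector(y)
  ps <- patchset$patch_side
  for (s in sel) {
    o <- patchset$origin[s, ]
    R <- matrix(0, ps^2, npix)
    q <- 0
    for (dr in 0:(ps - 1)) for (dc in 0:(ps - 1)) {
      q <- q + 1
      R[q, (o[2] + dr) + (o[3] + dc - 1) * d[1]] <- 1
    }
    M <- M + crossprod(R)
    rhs <- rhs + crossprod(R, coded[, s])
  }
  matrix(solve(M, rhs), d[1], d[2])
}

# Small simulated dataset shared by the denoising tests.
tiny_phantom <- function(shape = c(32, 32, 3), n_dirs = 12, seed = 1,
                         pattern = "two_region", sigma = NULL) {
  fld <- make_tensor_field(shape, pattern, seed = seed)
  sch <- make_gradient_scheme(n_dirs)
  clean <- simulate_dwi(fld, sch, s0 = 100)
  if (is.null(sigma)) sigma <- center_noise_level(clean)
  noisy <- add_rician_noise(clean, sigma, seed = seed + 1000)
  list(field = fld, scheme = sch, clean = clean, noisy = noisy,
       sigma = sigma)
}

rmse_to <- function(a, b) sqrt(mean((a - b)^2))
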
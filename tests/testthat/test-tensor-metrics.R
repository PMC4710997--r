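test_that("log-linear fit recovers noiseless tensors exactly", {
  fld <- make_tensor_field(c(24, 24, 2), "two_region", seed = 13)
  sch <- make_gradient_scheme(32)
  clean <- simulate_dwi(fld, sch, s0 = 120)
  fit <- fit_tensors(clean, mask = fld$mask)
  err <- apply(abs(fit$tensors - fld$tensors), 1:3, max)
  expect_lt(max(err[fld$mask]) / max(abs(fld$tensors)), 1e-8)

  # a single anisotropic tensor through the round trip
  tn <- array(0, c(4, 4, 1, 3, 3))
  for (i in 1:4) for (j in 1:4) tn[i, j, 1, , ] <- diag(c(1.7, .3, .3)) * 1e-3
  f1 <- tensor_field(tn, array(TRUE, c(4, 4, 1)))
  d1 <- simulate_dwi(f1, sch)
  ft1 <- fit_tensors(d1, mask = f1$mask)
  expect_equal(ft1$tensors[2, 2, 1, , ], diag(c(1.7, .3, .3)) * 1e-3,
               tolerance = 1e-9)

  # constant volumes (no decay): zero tensor
  cst <- dwi_sequence(array(90, c(4, 4, 1, length(sch$bvals))), sch)
  ftc <- fit_tensors(cst, mask = array(TRUE, c(4, 4, 1)))
  expect_lt(max(abs(ftc$tensors)), 1e-15)

  # too few directions is unidentifiable
  sch5 <- make_gradient_scheme(6)
  sch5$bvals <- sch5$bvals[1:6]; sch5$bvecs <- sch5$bvecs[, 1:6]
  d5 <- dwi_sequence(array(50, c(4, 4, 1, 6)), sch5)
  expect_error(fit_tensors(d5), "at least 6")

  # degenerate (repeated) directions: rejected with the condition number
  schd <- gradient_scheme(c(0, rep(1000, 8)),
                          cbind(0, matrix(c(1, 0, 0), 3, 8)))
  dd <- dwi_sequence(array(50, c(4, 4, 1, 9)), schd)
  expect_error(fit_tensors(dd), "condition")
})

test_that("FA matches its closed forms and invariances", {
  expect_equal(fa(diag(3)), 0)
  expect_equal(fa(diag(c(1, 0, 0))), 1)
  expect_equal(fa(diag(c(2, 1, 1))), 0.40825, tolerance = 1e-5)
  expect_equal(fa(matrix(0, 3, 3)), 0)
  expect_error(fa(matrix(rnorm(9), 3, 3)), "symmetric")

  set.seed(2)
  D <- crossprod(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(fa(Q %*% D %*% t(Q)), fa(D), tolerance = 1e-10)
  expect_equal(fa(3.7 * D), fa(D), tolerance = 1e-12)
})

test_that("colour maps encode direction as FA-scaled |principal eigenvector|", {
  tn <- array(0, c(3, 1, 1, 3, 3))
  tn[1, 1, 1, , ] <- diag(c(1, 0, 0)) * 1e-3          # pure left-right
  tn[2, 1, 1, , ] <- diag(0.7e-3, 3)                  # isotropic
  e1 <- c(1, 1, 0) / sqrt(2)                          # oblique in-plane
  tn[3, 1, 1, , ] <- 1e-3 * (1.5 * tcrossprod(e1) +
                               0.3 * diag(3))
  fld <- tensor_field(tn, array(TRUE, c(3, 1, 1)))
  maps <- colored_fa(fld)

  expect_equal(maps$rgb[1, 1, 1, ], c(1, 0, 0))
  expect_equal(maps$fa[2, 1, 1], 0)
  expect_equal(maps$rgb[2, 1, 1, ], c(0, 0, 0))
  f3 <- maps$fa[3, 1, 1]
  expect_equal(maps$rgb[3, 1, 1, ], c(f3 / sqrt(2), f3 / sqrt(2), 0),
               tolerance = 1e-10)
  expect_true(all(maps$fa >= 0 & maps$fa <= 1))
  expect_true(all(maps$rgb >= 0 & maps$rgb <= 1))
})

test_that("FA error statistics follow their algebraic identities", {
  mk_maps <- function(vals, mask) {
    f <- array(0, c(length(vals), 1, 1))
    f[, 1, 1] <- vals
    structure(list(fa = f, rgb = array(0, c(dim(f), 3)), mask = mask),
              class = "fa_maps")
  }
  msk <- array(TRUE, c(2, 1, 1))
  ref <- mk_maps(c(0.5, 0.5), msk)
  expect_equal(rmse_fa(ref, ref), 0)
  est <- mk_maps(c(0.6, 0.4), msk)
  expect_equal(rmse_fa(ref, est), 0.1)
  s <- fa_error_stats(ref, est)
  expect_equal(s$bias, 0)
  expect_equal(s$rmse, 0.1)
  expect_equal(s$q, 2L)

  # uniform offset: RMSE equals |offset|, variance 0
  msk4 <- array(TRUE, c(4, 1, 1))
  r4 <- mk_maps(c(.2, .4, .6, .8), msk4)
  e4 <- mk_maps(c(.2, .4, .6, .8) - 0.07, msk4)
  expect_equal(rmse_fa(r4, e4), 0.07)
  expect_equal(fa_error_stats(r4, e4)$variance, 0)

  # rmse^2 = bias^2 + variance (q-1)/q on random maps
  set.seed(41)
  mskn <- array(TRUE, c(50, 1, 1))
  rn <- mk_maps(runif(50), mskn)
  en <- mk_maps(runif(50), mskn)
  st <- fa_error_stats(rn, en)
  expect_equal(st$rmse^2,
               st$bias^2 + st$variance * (st$q - 1) / st$q,
               tolerance = 1e-12)

  bad <- mk_maps(c(0.5, 0.5), array(c(TRUE, FALSE), c(2, 1, 1)))
  expect_error(rmse_fa(ref, bad), "mask")
  none <- mk_maps(c(0.5, 0.5), array(FALSE, c(2, 1, 1)))
  expect_error(fa_error_stats(none, none), "empty mask")
})

test_that("denoising improves FA accuracy on the phantom", {
  ph <- tiny_phantom(c(32, 32, 3), n_dirs = 16, seed = 17)
  cfg <- denoise_config(group_size = 3, n_iterations = 5, seed = 1)
  res <- denoise_sequence(ph$noisy, cfg)
  msk <- ph$field$mask
  fa_ref <- colored_fa(fit_tensors(ph$clean, mask = msk))
  fa_noisy <- colored_fa(fit_tensors(ph$noisy, mask = msk))
  fa_den <- colored_fa(fit_tensors(res$denoised, mask = msk))
  expect_lt(rmse_fa(fa_ref, fa_den), rmse_fa(fa_ref, fa_noisy))
  s_noisy <- fa_error_stats(fa_ref, fa_noisy)
  s_den <- fa_error_stats(fa_ref, fa_den)
  expect_lt(abs(s_den$bias), abs(s_noisy$bias))
})
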
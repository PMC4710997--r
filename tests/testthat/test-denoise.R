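test_that("slice grouping is contiguous, covering and validated", {
  expect_equal(group_slices(5, 5), list(1:5))
  expect_equal(group_slices(7, 3), list(1:3, 4:6, 7L))
  expect_equal(group_slices(3, 1), list(1L, 2L, 3L))
  expect_equal(sort(unlist(group_slices(11, 4))), 1:11)
  expect_error(group_slices(5, 0), "group_size")
})

test_that("noiseless coding with zero fidelity weight passes images through", {
  set.seed(8)
  img <- array(abs(rnorm(16 * 16 * 2, 50, 10)), c(16, 16, 2))
  cfg <- denoise_config(patch_side = 4, k = 25, n_iterations = 2, lam = 0,
                        group_size = 2, seed = 1)
  out <- denoise_group(img, init_dct_dictionary(4, 25), cfg, sigma = 0)
  expect_lt(max(abs(out$clean - img)) / max(abs(img)), 1e-6)
})

test_that("group denoising reduces error to ground truth on every slice", {
  ph <- tiny_phantom(c(32, 32, 3), n_dirs = 12, seed = 4)
  cfg <- denoise_config(group_size = 3, n_iterations = 5, seed = 1)
  v <- 3  # a diffusion-weighted volume
  res <- denoise_group(ph$noisy$data[, , , v], init_dct_dictionary(8, 256),
                       cfg, ph$sigma)
  for (l in 1:3) {
    e_noisy <- rmse_to(ph$noisy$data[, , l, v], ph$clean$data[, , l, v])
    e_den <- rmse_to(res$clean[, , l], ph$clean$data[, , l, v])
    expect_lt(e_den, e_noisy)
  }
  expect_s3_class(res$dictionary, "sr_dictionary")
  expect_true(all(diff(res$history$error[res$history$stage == "update"]) < 1e6))
})

test_that("identical slices in a group are denoised identically", {
  ph <- tiny_phantom(c(24, 24, 1), n_dirs = 8, seed = 9)
  sl <- ph$noisy$data[, , 1, 4]
  stack <- array(sl, c(24, 24, 3))
  cfg <- denoise_config(patch_side = 4, k = 25, group_size = 3,
                        n_iterations = 3, seed = 1)
  res <- denoise_group(stack, init_dct_dictionary(4, 25), cfg, ph$sigma)
  expect_lt(max(abs(res$clean[, , 1] - res$clean[, , 2])), 1e-10)
  expect_lt(max(abs(res$clean[, , 1] - res$clean[, , 3])), 1e-10)

  # the learned dictionary matches training on the single slice (the
  # objective is symmetric under patch multiplicity)
  res1 <- denoise_group(array(sl, c(24, 24, 1)),
                        init_dct_dictionary(4, 25), cfg, ph$sigma)
  expect_equal(res$dictionary$atoms, res1$dictionary$atoms, tolerance = 1e-8)
  expect_equal(res$clean[, , 1], res1$clean[, , 1], tolerance = 1e-10)
})

test_that("background sigma estimate recovers a known Rayleigh noise level", {
  sch <- gradient_scheme(0, matrix(0, 3, 1))
  set.seed(12)
  n <- c(200, 250, 2, 1)
  ray <- sqrt(rnorm(prod(n), 0, 5)^2 + rnorm(prod(n), 0, 5)^2)
  seq <- dwi_sequence(array(ray, n), sch)
  expect_equal(estimate_sigma(seq), 5, tolerance = 0.05)
  expect_equal(estimate_sigma(dwi_sequence(array(0, n), sch)), 0)
})

test_that("sequence denoising preserves shape/scheme and matches the single-group path", {
  ph <- tiny_phantom(c(24, 24, 2), n_dirs = 8, seed = 2)
  cfg <- denoise_config(group_size = 2, n_iterations = 3, seed = 3)
  res <- denoise_sequence(ph$noisy, cfg)
  expect_equal(dim(res$denoised$data), dim(ph$noisy$data))
  expect_identical(res$denoised$scheme, ph$noisy$scheme)
  expect_equal(res$report$sigma, ph$sigma)
  expect_length(res$report$histories, dim(ph$noisy$data)[4])

  # a 1-volume sequence equals one denoise_group call with the DCT seed
  one <- dwi_sequence(ph$noisy$data[, , , 1, drop = FALSE],
                      gradient_scheme(0, matrix(0, 3, 1)), ph$sigma)
  r1 <- denoise_sequence(one, cfg)
  r2 <- denoise_group(ph$noisy$data[, , , 1], init_dct_dictionary(8, 256),
                      cfg, ph$sigma)
  expect_equal(r1$denoised$data[, , , 1], r2$clean, tolerance = 1e-12)

  # determinism end to end
  res2 <- denoise_sequence(ph$noisy, cfg)
  expect_identical(res$denoised$data, res2$denoised$data)

  # sigma_mode = "given" requires a recorded sigma
  bare <- dwi_sequence(ph$noisy$data, ph$noisy$scheme)
  expect_error(denoise_sequence(bare, cfg), "sigma")
})

test_that("warm-started dictionaries reach a fixed objective level in no more iterations", {
  ph <- tiny_phantom(c(32, 32, 2), n_dirs = 8, seed = 6)
  cfg <- denoise_config(group_size = 2, n_iterations = 10, seed = 1)
  dct <- init_dct_dictionary(8, 256)
  g1 <- denoise_group(ph$noisy$data[, , , 2], dct, cfg, ph$sigma)
  warm <- denoise_group(ph$noisy$data[, , , 3], g1$dictionary, cfg, ph$sigma)
  cold <- denoise_group(ph$noisy$data[, , , 3], dct, cfg, ph$sigma)
  upd <- function(h) h$error[h$stage == "update"]
  target <- 1.05 * min(upd(cold$history))
  iters_to <- function(h) which(upd(h) <= target)[1]
  expect_false(is.na(iters_to(warm$history)))
  expect_lte(iters_to(warm$history), iters_to(cold$history))
})

test_that("a second denoising pass changes the image less than the first", {
  # the full operator, sigma estimated from the data: after one pass the
  # residual noise (hence the estimated budget) is much smaller, so a
  # second application moves the image far less than the first
  ph <- tiny_phantom(c(24, 24, 2), n_dirs = 8, seed = 5)
  cfg <- denoise_config(group_size = 2, n_iterations = 4, seed = 1,
                        sigma_mode = "estimate")
  p1 <- denoise_sequence(ph$noisy, cfg)
  p2 <- denoise_sequence(p1$denoised, cfg)
  d1 <- mean((p1$denoised$data - ph$noisy$data)^2)
  d2 <- mean((p2$denoised$data - p1$denoised$data)^2)
  expect_lt(d2, d1)
})
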
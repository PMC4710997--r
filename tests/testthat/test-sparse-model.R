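test_that("DCT dictionary has the documented shape, norms and constant atom", {
  d <- init_dct_dictionary(8, 256)
  expect_equal(dim(d$atoms), c(64L, 256L))
  d2 <- init_dct_dictionary(6, 100)
  expect_equal(dim(d2$atoms), c(36L, 100L))
  for (dict in list(d, d2)) {
    expect_lt(max(abs(sqrt(colSums(dict$atoms^2)) - 1)), 1e-9)
    expect_equal(dict$atoms[, 1],
                 rep(1 / dict$patch_side, dict$patch_side^2))
  }
  expect_error(init_dct_dictionary(8, 200), "perfect square")
  expect_error(init_dct_dictionary(8, 64), "overcomplete")
  expect_error(sr_dictionary(matrix(1, 4, 3)), "overcomplete")
})

test_that("error-constrained coder handles the degenerate budgets exactly", {
  set.seed(11)
  dict <- sr_dictionary(rand_unit_dict(16, 32), 4)

  # a patch equal to one atom with zero budget: single unit coefficient
  sc <- sparse_code(dict$atoms[, 9, drop = FALSE], dict,
                    coding_budget(1, 0, 16, NULL))
  a <- as.numeric(sc$coefficients)
  expect_equal(which(a != 0), 9L)
  expect_equal(a[9], 1, tolerance = 1e-7)
  expect_lt(sc$residual_norms, 1e-6)

  # budget at least the patch energy: the zero code is optimal
  y <- rnorm(16)
  bz <- coding_budget(1, sqrt(1.5 * sum(y^2) / 16), 16, NULL)
  scz <- sparse_code(matrix(y, ncol = 1), dict, bz)
  expect_true(all(scz$coefficients == 0))
  expect_equal(scz$residual_norms, sqrt(sum(y^2)))

  # budget arithmetic: C * n_pix * sigma^2
  expect_equal(coding_budget(1.2, 10, 64)$error_bound, 1.2 * 64 * 100)

  # stored residuals match recomputation; budgets hold when feasible
  X <- matrix(rnorm(16 * 50, 0, 2), 16, 50)
  bud <- coding_budget(1.2, 0.8, 16, 5)
  scb <- sparse_code(X, dict, bud)
  R <- X - as.matrix(dict$atoms %*% scb$coefficients)
  expect_lt(max(abs(scb$residual_norms - sqrt(colSums(R^2)))), 1e-8)
  ok <- scb$feasible
  expect_true(all(scb$residual_norms[ok]^2 <= bud$error_bound + 1e-8))
  expect_true(all(colSums(as.matrix(scb$coefficients) != 0) <= 5))
})

test_that("coder reaches the convex-oracle minimum L1 norm", {
  skip_if_not_installed("glmnet")
  set.seed(77)
  for (t in 1:5) {
    D <- rand_unit_dict(16, 32)
    y <- rnorm(16)
    bud <- 0.4 * sum(y^2)
    sc <- sparse_code(matrix(y, ncol = 1), sr_dictionary(D, 4),
                      coding_budget(1, sqrt(bud / 16), 16, NULL))
    orc <- glmnet_l1_oracle(D, y, bud)
    expect_equal(sum(abs(sc$coefficients)), orc$l1, tolerance = 1e-4)
    expect_lte(sc$residual_norms^2, bud + 1e-9)
  }
})

test_that("K-SVD atom update is the optimal rank-1 refinement", {
  set.seed(21)
  dict <- sr_dictionary(rand_unit_dict(16, 24), 4)
  X <- matrix(rnorm(16 * 60, 0, 2), 16, 60)
  bud <- coding_budget(1.2, 0.7, 16, 4)
  codes <- sparse_code(X, dict, bud)

  m <- which.max(Matrix::rowSums(codes$coefficients != 0))
  use <- which(codes$coefficients[m, ] != 0)
  E <- X[, use, drop = FALSE] -
    as.matrix(dict$atoms %*% codes$coefficients[, use, drop = FALSE]) +
    outer(dict$atoms[, m], as.numeric(codes$coefficients[m, use]))

  up <- ksvd_update_atom(m, dict, codes, X)
  newE <- X[, use, drop = FALSE] -
    as.matrix(up$dictionary$atoms %*%
                up$codes$coefficients[, use, drop = FALSE])
  sv <- svd(E)
  optimal <- sqrt(sum(sv$d[-1]^2))
  expect_equal(norm(newE, "F"), optimal, tolerance = 1e-9)
  expect_lt(abs(sqrt(sum(up$dictionary$atoms[, m]^2)) - 1), 1e-9)

  # single using patch: atom becomes the normalized patch
  d1 <- sr_dictionary(rand_unit_dict(9, 12), 3)
  p <- rnorm(9)
  codes1 <- sparse_code(matrix(p, ncol = 1), d1,
                        coding_budget(1, 1e-6, 9, 1))
  m1 <- which(codes1$coefficients[, 1] != 0)[1]
  up1 <- ksvd_update_atom(m1, d1, codes1, matrix(p, ncol = 1))
  expect_equal(abs(as.numeric(crossprod(up1$dictionary$atoms[, m1],
                                        p / sqrt(sum(p^2))))), 1,
               tolerance = 1e-9)
  expect_equal(abs(up1$codes$coefficients[m1, 1]), sqrt(sum(p^2)),
               tolerance = 1e-9)

  # an atom used by no patch is replaced by the worst-represented patch
  Xs <- X[, 1:8]
  codess <- sparse_code(Xs, dict, bud)
  unused <- which(Matrix::rowSums(codess$coefficients != 0) == 0)[1]
  expect_false(is.na(unused))
  resid2 <- colSums((Xs - as.matrix(dict$atoms %*% codess$coefficients))^2)
  w <- which.max(resid2)
  upu <- ksvd_update_atom(unused, dict, codess, Xs)
  expect_equal(abs(as.numeric(
    crossprod(upu$dictionary$atoms[, unused],
              Xs[, w] / sqrt(sum(Xs[, w]^2))))), 1, tolerance = 1e-9)
  expect_identical(upu$codes$coefficients, codess$coefficients)

  expect_error(ksvd_update_atom(99, dict, codes, X), "atom index")
})

test_that("dictionary learning is monotone per round and respects the loop contract", {
  set.seed(33)
  X <- matrix(rnorm(16 * 300, 0, 2), 16, 300)
  init <- sr_dictionary(rand_unit_dict(16, 24), 4)
  bud <- coding_budget(1.2, 0.7, 16, 5)

  ld <- learn_dictionary(X, init, bud, n_iterations = 6, seed = 2)
  h <- ld$history
  expect_equal(max(h$iteration), 6L)
  for (it in split(h, h$iteration))
    expect_lte(it$error[it$stage == "update"],
               it$error[it$stage == "code"] + 1e-9)
  expect_lt(max(abs(sqrt(colSums(ld$dictionary$atoms^2)) - 1)), 1e-9)
  # sign canonicalization: first non-negligible entry of each atom positive
  firsts <- apply(ld$dictionary$atoms, 2, function(a) a[abs(a) > 1e-10][1])
  expect_true(all(firsts > 0))

  # n_iterations = 1 is exactly one coding pass plus one atom sweep
  ld1 <- learn_dictionary(X, init, bud, n_iterations = 1, seed = 2)
  expect_equal(nrow(ld1$history), 2L)
  cres <- dwisr:::sr_lasso_batch_cpp(init$atoms, X, bud$error_bound, 5L, TRUE)
  sw <- dwisr:::sr_ksvd_sweep_cpp(init$atoms, cres$A, X, 0.99, TRUE)
  expect_equal(ld1$dictionary$atoms, sw$D)
  expect_equal(ld1$history$error, c(sum(cres$resid^2), sw$err))

  # determinism under a fixed seed
  ld2 <- learn_dictionary(X, init, bud, n_iterations = 6, seed = 2)
  expect_identical(ld$dictionary$atoms, ld2$dictionary$atoms)

  expect_error(learn_dictionary(X[, 0], init, bud), "empty patch set")
})
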
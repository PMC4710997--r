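#' K-SVD update of a single dictionary atom
#'
#' Identifies the patches whose code uses atom `m`, forms the restricted
#' residual `E_m` with atom `m`'s contribution removed, and replaces the
#' atom and the corresponding coefficients by the leading singular triplet
#' of `E_m` (the optimal rank-1 approximation, so the restricted
#' representation error never increases). An atom used by no patch is
#' replaced by the normalized worst-represented patch, leaving coefficients
#' untouched. The updated atom's first nonzero entry is made positive to fix
#' the SVD sign ambiguity.
#'
#' @param m Atom index (1-based, `1 <= m <= k`).
#' @param dict An [sr_dictionary()].
#' @param codes A [sparse_code_set()] for `patches` over `dict`.
#' @param patches A [extract_patches()] result or `n_pix x P` matrix.
#' @return List with updated `dictionary` and `codes`.
#' @export
ksvd_update_atom <- function(m, dict, codes, patches) {
  X <- if (inherits(patches, "patch_set")) patches$patches else as.matrix(patches)
  if (!is_count(m) || m > dict$k)
    stop_data("`m` must be an atom index in 1..", dict$k)
  A <- codes$coefficients
  use <- which(A[m, ] != 0)
  D <- dict$atoms
  if (length(use) == 0) {
    resid2 <- colSums((X - as.matrix(D %*% A))^2)
    w <- which.max(resid2)
    p <- X[, w]
    if (sqrt(sum(p^2)) > 1e-12) {
      p <- p / sqrt(sum(p^2))
      nz <- which(abs(p) > 1e-10)[1]
      if (!is.na(nz) && p[nz] < 0) p <- -p
      D[, m] <- p
    }
    newdict <- sr_dictionary(D, dict$patch_side)
    return(list(dictionary = newdict, codes = codes))
  }
  E <- X[, use, drop = FALSE] -
    as.matrix(D %*% A[, use, drop = FALSE]) +
    outer(D[, m], as.numeric(A[m, use]))
  r1 <- sr_rank1_cpp(E)
  D[, m] <- as.numeric(r1$u)
  A[m, use] <- as.numeric(r1$v)
  newdict <- sr_dictionary(D, dict$patch_side)
  codes$coefficients <- A
  codes$residual_norms[use] <-
    sqrt(colSums((X[, use, drop = FALSE] -
                    as.matrix(D %*% A[, use, drop = FALSE]))^2))
  list(dictionary = newdict, codes = codes)
}

#' Learn a patch dictionary by alternating sparse coding and K-SVD
#'
#' Block-coordinate relaxation: each round sparse-codes the (possibly
#' subsampled) training patches over the current dictionary, then sweeps all
#' atoms sequentially with rank-1 SVD updates. The total representation
#' error is recorded after each half-step; the dictionary-update half-step
#' is provably non-increasing. After the rounds, a final coding pass covers
#' all patches with the learned dictionary. Dictionary maintenance between
#' rounds replaces unused atoms and atoms nearly collinear with another atom
#' (|correlation| > 0.99) by the worst-represented patches.
#'
#' @param patches A [extract_patches()] result or `n_pix x P` matrix.
#' @param init Initial [sr_dictionary()] (typically [init_dct_dictionary()]).
#' @param budget A [coding_budget()].
#' @param n_iterations Training rounds (default 15).
#' @param seed Seed for the training-set subsample.
#' @param train_cap Maximum number of patches used for training; a seeded
#'   uniform subsample is drawn above this size (default 40000).
#' @param tol Optional early-stopping tolerance: stop when the relative
#'   improvement of the post-update error falls below `tol` (default 0:
#'   always run all `n_iterations` rounds).
#' @return List with `dictionary`, `codes` (final coding pass over all
#'   patches), and `history` (data frame: iteration, stage
#'   `"code"`/`"update"`, total squared representation error over the
#'   training set, atoms replaced).
#' @export
learn_dictionary <- function(patches, init, budget, n_iterations = 15L,
                             seed = 1L, train_cap = 40000L, tol = 0) {
  X <- if (inherits(patches, "patch_set")) patches$patches else as.matrix(patches)
  if (ncol(X) == 0) stop_data("empty patch set")
  if (!is_count(n_iterations)) stop_data("`n_iterations` must be >= 1")
  if (!inherits(init, "sr_dictionary")) stop_data("`init` must be an sr_dictionary")

  Xtr <- if (ncol(X) > train_cap) {
    idx <- with_seed(seed, sample.int(ncol(X), train_cap))
    X[, sort(idx), drop = FALSE]
  } else X

  D <- init$atoms
  cap <- effective_cap(budget)
  hist <- data.frame(iteration = integer(), stage = character(),
                     error = numeric(), replaced = integer())
  prev_err <- Inf
  for (it in seq_len(n_iterations)) {
    cres <- sr_lasso_batch_cpp(D, Xtr, budget$error_bound, cap, dense_out = TRUE)
    err_code <- sum(cres$resid^2)
    sw <- sr_ksvd_sweep_cpp(D, cres$A, Xtr, dedup_thresh = 0.99,
                            maintain = TRUE)
    D <- sw$D
    hist <- rbind(hist,
                  data.frame(iteration = c(it, it),
                             stage = c("code", "update"),
                             error = c(err_code, sw$err),
                             replaced = c(0L, sw$replaced)))
    if (tol > 0 && is.finite(prev_err) &&
        (prev_err - sw$err) <= tol * max(prev_err, .Machine$double.eps)) {
      break
    }
    prev_err <- sw$err
  }
  dict <- sr_dictionary(D, init$patch_side)
  attr(dict, "provenance") <- list(patch_side = init$patch_side, k = init$k,
                                   n_iterations = max(hist$iteration),
                                   seed = seed)
  codes <- sparse_code(X, dict, budget)
  list(dictionary = dict, codes = codes, history = hist)
}
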
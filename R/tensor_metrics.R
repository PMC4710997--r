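#' Fit diffusion tensors by log-linear least squares
#'
#' Per masked voxel, ordinary least squares on the log-linearized signal
#' model `log S = log S0 - b g' D g`, solving jointly for the 6 unique
#' tensor entries and `log S0`. Non-positive intensities are floored to a
#' small epsilon before the log; negative eigenvalues of the fitted tensors
#' are clamped to 0 so the returned field is positive semidefinite (the
#' form downstream scalar metrics require).
#'
#' @param dwi A [dwi_sequence()] with at least one b = 0 and six b > 0
#'   volumes.
#' @param mask Optional logical array; default marks voxels whose b = 0
#'   intensity exceeds 10 percent of the b = 0 mean as non-background.
#' @param floor_eps Intensity floor applied before taking logs
#'   (default 1e-10).
#' @return A [tensor_field()] (zero tensors outside the mask).
#' @export
fit_tensors <- function(dwi, mask = NULL, floor_eps = 1e-10) {
  if (!inherits(dwi, "dwi_sequence")) stop_data("`dwi` must be a dwi_sequence")
  bv <- dwi$scheme$bvals
  if (sum(bv == 0) < 1) stop_data("need at least one b = 0 volume")
  if (sum(bv > 0) < 6)
    stop_data("need at least 6 diffusion-weighted volumes to identify the ",
              "tensor; got ", sum(bv > 0))
  d <- dim(dwi$data)
  if (is.null(mask)) {
    b0 <- array(dwi$data[, , , which(bv == 0)[1]], d[1:3])
    mask <- b0 > 0.1 * mean(b0)
  }
  if (!identical(dim(mask), d[1:3])) stop_data("`mask` shape mismatch")

  g <- dwi$scheme$bvecs
  # design: log S = W beta, beta = (log S0, Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)
  W <- cbind(1,
             -bv * g[1, ]^2, -2 * bv * g[1, ] * g[2, ], -bv * g[2, ]^2,
             -2 * bv * g[1, ] * g[3, ], -2 * bv * g[2, ] * g[3, ],
             -bv * g[3, ]^2)
  sv <- svd(W, nu = 0, nv = 0)$d
  cn <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  if (!is.finite(cn) || cn > 1e8)
    stop_data("rank-deficient gradient design (condition number ",
              signif(cn, 3), "); use more / better-spread directions")

  idx <- which(mask)
  S <- matrix(aperm(dwi$data, c(4, 1, 2, 3)), d[4], prod(d[1:3]))[, idx,
                                                                  drop = FALSE]
  S <- pmax(S, floor_eps)
  beta <- qr.solve(W, log(S))           # 7 x n_masked

  tensors <- array(0, c(d[1:3], 3, 3))
  flat <- matrix(tensors, prod(d[1:3]), 9)
  # lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) -> 3x3 positions
  comp <- beta[2:7, , drop = FALSE]
  for (i in seq_along(idx)) {
    Dv <- matrix(c(comp[1, i], comp[2, i], comp[4, i],
                   comp[2, i], comp[3, i], comp[5, i],
                   comp[4, i], comp[5, i], comp[6, i]), 3, 3)
    e <- eigen(Dv, symmetric = TRUE)
    if (e$values[3] < 0) {
      ev <- pmax(e$values, 0)
      Dv <- e$vectors %*% diag(ev) %*% t(e$vectors)
      Dv <- (Dv + t(Dv)) / 2
    }
    flat[idx[i], ] <- Dv
  }
  tensor_field(array(flat, c(d[1:3], 3, 3)), mask)
}

#' Fractional anisotropy of one tensor
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||` over the
#' eigenvalues, clamped to `[0, 1]`; the zero tensor maps to 0 by
#' convention. Negative eigenvalues (degenerate fits) are clamped to 0
#' first.
#'
#' @param tensor 3 x 3 symmetric numeric matrix.
#' @return FA in `[0, 1]`.
#' @examples
#' fa(diag(3))           # 0 (isotropic)
#' fa(diag(c(1, 0, 0)))  # 1 (maximal anisotropy)
#' @export
fa <- function(tensor) {
  tensor <- as.matrix(tensor)
  if (!identical(dim(tensor), c(3L, 3L)) ||
      max(abs(tensor - t(tensor))) > 1e-8 * max(1, max(abs(tensor))))
    stop_data("`tensor` must be a symmetric 3 x 3 matrix")
  ev <- pmax(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values, 0)
  nrm <- sqrt(sum(ev^2))
  if (nrm == 0) return(0)
  val <- sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) / nrm
  min(max(val, 0), 1)
}

#' FA and direction-encoded colour maps of a tensor field
#'
#' Computes per-voxel fractional anisotropy and the colour map
#' `rgb = FA * |e1|`, with `e1` the unit principal eigenvector: red encodes
#' left-right (x), green anterior-posterior (y), blue superior-inferior (z);
#' the absolute value removes the eigenvector sign ambiguity. Voxels outside
#' the mask are zero.
#'
#' @param field A [tensor_field()].
#' @return An object of class `fa_maps`: `fa` (array in `[0, 1]`), `rgb`
#'   (`(rows, cols, slices, 3)` array in `[0, 1]`), `mask`.
#' @export
colored_fa <- function(field) {
  if (!inherits(field, "tensor_field")) stop_data("`field` must be a tensor_field")
  d <- dim(field$tensors)[1:3]
  fa_arr <- array(0, d)
  rgb <- array(0, c(d, 3))
  flat <- matrix(field$tensors, prod(d), 9)
  rgbf <- matrix(0, prod(d), 3)
  idx <- which(field$mask)
  for (i in idx) {
    Dv <- matrix(flat[i, ], 3, 3)
    e <- eigen(Dv, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    nrm <- sqrt(sum(ev^2))
    f <- if (nrm == 0) 0 else
      min(max(sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) / nrm, 0), 1)
    fa_arr[i] <- f
    rgbf[i, ] <- f * abs(e$vectors[, 1])
  }
  rgb <- array(rgbf, c(d, 3))
  structure(list(fa = fa_arr, rgb = rgb, mask = field$mask),
            class = "fa_maps")
}

#' @export
print.fa_maps <- function(x, ...) {
  cat("fa_maps:", paste(dim(x$fa), collapse = " x "), "; FA range in mask [",
      signif(min(x$fa[x$mask]), 3), ",", signif(max(x$fa[x$mask]), 3), "]\n")
  invisible(x)
}

check_fa_pair <- function(fa_ref, fa_est) {
  if (!inherits(fa_ref, "fa_maps") || !inherits(fa_est, "fa_maps"))
    stop_data("inputs must be fa_maps")
  if (!identical(dim(fa_ref$fa), dim(fa_est$fa)))
    stop_data("FA map shapes differ")
  if (!identical(fa_ref$mask, fa_est$mask))
    stop_data("FA maps must share the same mask")
  if (!any(fa_ref$mask)) stop_data("empty mask")
  invisible(TRUE)
}

#' Root-mean-square FA error over the non-background mask
#'
#' `RMSE_FA = sqrt( sum_q (FA_q - FAhat_q)^2 / Q )` with `Q` the number of
#' masked voxels.
#'
#' @param fa_ref,fa_est [colored_fa()] results on the same mask (reference
#'   first).
#' @return Scalar RMSE.
#' @export
rmse_fa <- function(fa_ref, fa_est) {
  check_fa_pair(fa_ref, fa_est)
  sqrt(mean((fa_est$fa[fa_ref$mask] - fa_ref$fa[fa_ref$mask])^2))
}

#' Bias, variance and RMSE of the voxelwise FA error
#'
#' Summary statistics of `FA_est - FA_ref` over the shared mask: `bias`
#' (mean), `variance` (sample variance), `rmse` and the voxel count `q`.
#' These satisfy `rmse^2 = bias^2 + variance * (q - 1) / q`.
#'
#' @inheritParams rmse_fa
#' @return An object of class `fa_error_stats`.
#' @export
fa_error_stats <- function(fa_ref, fa_est) {
  check_fa_pair(fa_ref, fa_est)
  diff <- fa_est$fa[fa_ref$mask] - fa_ref$fa[fa_ref$mask]
  structure(list(bias = mean(diff),
                 variance = if (length(diff) > 1) var(diff) else 0,
                 rmse = sqrt(mean(diff^2)),
                 q = length(diff)),
            class = "fa_error_stats")
}

#' @export
print.fa_error_stats <- function(x, ...) {
  cat(sprintf("fa_error_stats: bias %.4g, variance %.4g, RMSE %.4g (Q = %d)\n",
              x$bias, x$variance, x$rmse, x$q))
  invisible(x)
}
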
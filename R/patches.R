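#' Extract overlapping square patches from a slice stack
#'
#' Collects every `patch_side` x `patch_side` patch whose top-left corner
#' lies on the `stride` grid, plus the patches flush against the right and
#' bottom borders so that every pixel is covered. Patches are vectorized
#' row-major within the patch (pixel `(dr, dc)` of a patch maps to vector
#' position `dr * patch_side + dc + 1`, `dr`/`dc` counted from 0), and
#' addressed by their 1-based top-left corner `(slice, row, col)`.
#'
#' @param images 2D matrix or 3D array `(rows, cols, n_slices)`.
#' @param patch_side Patch edge length in pixels.
#' @param stride Grid step between patch corners (default 1: maximal overlap).
#' @return An object of class `patch_set`: list with `patches`
#'   (`patch_side^2` x `n_patches` matrix), `origin` (`n_patches` x 3 matrix
#'   of `(slice, row, col)`), `patch_side`, `stride`, `image_shape`.
#' @examples
#' ps <- extract_patches(matrix(1:64, 8, 8), patch_side = 8)
#' ncol(ps$patches)  # a single patch covering the whole image
#' @export
extract_patches <- function(images, patch_side, stride = 1L) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  d <- dim(images)
  if (length(d) != 3L) stop_data("`images` must be 2D or 3D")
  if (!is_count(patch_side) || !is_count(stride))
    stop_data("`patch_side` and `stride` must be positive integers")
  if (patch_side > min(d[1], d[2]))
    stop_data("patch_side (", patch_side, ") exceeds image extent (",
              d[1], " x ", d[2], ")")

  starts <- function(n) {
    s <- seq.int(1L, n - patch_side + 1L, by = stride)
    if (s[length(s)] != n - patch_side + 1L) s <- c(s, n - patch_side + 1L)
    s
  }
  sr <- starts(d[1]); sc <- starts(d[2])
  # row-major in-patch offsets relative to the top-left linear index
  dr <- rep(0:(patch_side - 1L), each = patch_side)
  dc <- rep(0:(patch_side - 1L), times = patch_side)
  off <- dr + dc * d[1]
  # per-slice top-left linear indices (row varies fastest to fix patch order)
  tl <- as.vector(outer(sr, (sc - 1L) * d[1], "+"))
  idx2d <- outer(off, tl, "+")             # npix x npatches_per_slice
  npps <- length(tl)

  npix <- patch_side^2
  patches <- matrix(0, npix, npps * d[3])
  origin <- matrix(0L, npps * d[3], 3,
                   dimnames = list(NULL, c("slice", "row", "col")))
  og <- cbind(rep(sr, times = length(sc)), rep(sc, each = length(sr)))
  for (l in seq_len(d[3])) {
    cols <- (l - 1L) * npps + seq_len(npps)
    patches[, cols] <- images[, , l][idx2d]
    origin[cols, 1] <- l
    origin[cols, 2:3] <- og
  }
  structure(list(patches = patches, origin = origin,
                 patch_side = as.integer(patch_side),
                 stride = as.integer(stride), image_shape = d),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("patch_set:", ncol(x$patches), "patches of", x$patch_side, "x",
      x$patch_side, "from a", paste(x$image_shape, collapse = " x "),
      "stack (stride", x$stride, ")\n")
  invisible(x)
}

# per-slice npix x npatches matrix of 1-based linear pixel indices
patch_index_matrix <- function(patchset, slice) {
  d <- patchset$image_shape
  ps <- patchset$patch_side
  sel <- patchset$origin[, 1] == slice
  o <- patchset$origin[sel, , drop = FALSE]
  dr <- rep(0:(ps - 1L), each = ps)
  dc <- rep(0:(ps - 1L), times = ps)
  off <- dr + dc * d[1]
  tl <- o[, 2] + (o[, 3] - 1L) * d[1]
  outer(off, tl, "+")
}

#' Reassemble clean slices from represented patches
#'
#' Closed-form solution of the quadratic image-update problem: per slice,
#' `x = (lam * I + sum R'R)^(-1) (lam * y + sum R' p)` where `R` are the
#' patch-extraction operators and `p` the represented (coded) patches. Since
#' `sum R'R` is diagonal (the per-pixel patch-overlap counts), this reduces
#' to the pixelwise ratio `(lam * y + scatter-add of patches) / (lam +
#' overlap count)`.
#'
#' @param noisy 2D matrix or 3D array: the observed slices `y`.
#' @param patchset The [extract_patches()] result describing patch geometry.
#' @param coded_patches Matrix of represented patches, same shape as
#'   `patchset$patches`.
#' @param lam Fidelity weight `lam >= 0`; 0 averages the patch estimates,
#'   large values return `y`.
#' @return Array of the same shape as `noisy`.
#' @examples
#' img <- matrix(rnorm(36), 6, 6)
#' ps <- extract_patches(img, 3)
#' out <- aggregate_clean_image(img, ps, ps$patches, lam = 0)
#' max(abs(out - img))  # averaging exact copies reproduces the image
#' @export
aggregate_clean_image <- function(noisy, patchset, coded_patches, lam) {
  was2d <- is.matrix(noisy)
  if (was2d) noisy <- array(noisy, c(dim(noisy), 1L))
  if (!inherits(patchset, "patch_set")) stop_data("`patchset` must be a patch_set")
  if (!identical(dim(noisy), patchset$image_shape))
    stop_data("`noisy` shape does not match the patch set's image shape")
  if (!identical(dim(coded_patches), dim(patchset$patches)))
    stop_data("`coded_patches` must have the same shape as the extracted ",
              "patches (", nrow(patchset$patches), " x ",
              ncol(patchset$patches), ")")
  if (!is_scalar(lam) || lam < 0) stop_data("`lam` must be >= 0")

  d <- patchset$image_shape
  npix <- d[1] * d[2]
  out <- array(0, d)
  for (l in seq_len(d[3])) {
    idx <- patch_index_matrix(patchset, l)
    sel <- patchset$origin[, 1] == l
    vals <- coded_patches[, sel, drop = FALSE]
    num <- sr_scatter_add_cpp(vals, idx, npix)
    cnt <- sr_scatter_add_cpp(matrix(1, nrow(idx), ncol(idx)), idx, npix)
    y <- as.vector(noisy[, , l])
    out[, , l] <- (lam * y + num) / (lam + cnt)
  }
  if (was2d) out[, , 1] else out
}
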
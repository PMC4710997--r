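#' Overcomplete dictionary of patch atoms
#'
#' Wraps an `n_pix x k` matrix of unit-norm atom columns with `k > n_pix`
#' (overcomplete). Used both for the fixed DCT initialization and for
#' learned dictionaries.
#'
#' @param atoms Numeric matrix, columns of unit Euclidean norm (within 1e-9).
#' @param patch_side Patch edge length; `patch_side^2` must equal
#'   `nrow(atoms)`.
#' @return An object of class `sr_dictionary` with elements `atoms`,
#'   `patch_side`, `k`.
#' @export
sr_dictionary <- function(atoms, patch_side = NULL) {
  atoms <- as.matrix(atoms)
  n <- nrow(atoms); k <- ncol(atoms)
  if (k <= n)
    stop_data("dictionary must be overcomplete: k (", k,
              ") must exceed n_pix (", n, ")")
  nrm <- sqrt(colSums(atoms^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop_data("all atoms must have unit norm (max deviation ",
              signif(max(abs(nrm - 1)), 3), ")")
  if (is.null(patch_side)) patch_side <- as.integer(round(sqrt(n)))
  if (patch_side^2 != n)
    stop_data("patch_side^2 (", patch_side^2, ") must equal nrow(atoms) (",
              n, ")")
  structure(list(atoms = atoms, patch_side = as.integer(patch_side),
                 k = as.integer(k)),
            class = "sr_dictionary")
}

#' @export
print.sr_dictionary <- function(x, ...) {
  cat("sr_dictionary:", nrow(x$atoms), "x", x$k, "(patch",
      x$patch_side, "x", x$patch_side, ")\n")
  invisible(x)
}

#' Overcomplete separable 2D-DCT initial dictionary
#'
#' Builds `k = r^2` atoms as outer products of `r` sampled 1D cosine
#' vectors per axis (frequencies `0 .. r-1` sampled at `patch_side` points),
#' each column normalized to unit norm. The first atom is the constant patch
#' `1/patch_side`. This is the standard initialization for patch-based
#' dictionary learning.
#'
#' @param patch_side Patch edge length (atoms are `patch_side^2`-vectors).
#' @param k Number of atoms; must be a perfect square greater than
#'   `patch_side^2`.
#' @return An [sr_dictionary()].
#' @examples
#' d <- init_dct_dictionary(8, 256)
#' dim(d$atoms)  # 64 x 256
#' @export
init_dct_dictionary <- function(patch_side, k) {
  if (!is_count(patch_side)) stop_data("`patch_side` must be a positive integer")
  r <- round(sqrt(k))
  if (!is_count(k) || r^2 != k)
    stop_data("`k` must be a perfect square (got ", k, ")")
  if (k <= patch_side^2)
    stop_data("`k` (", k, ") must exceed patch_side^2 (", patch_side^2,
              ") for an overcomplete dictionary")
  t <- 0:(patch_side - 1)
  V <- sapply(0:(r - 1), function(p) {
    v <- cos(pi * p * t / r)
    v / sqrt(sum(v^2))
  })
  atoms <- kronecker(V, V)   # column (p, q) is the row-major 2D atom
  sr_dictionary(atoms, patch_side)
}

#' Save or load a dictionary
#'
#' Persists the dictionary together with provenance metadata (patch side,
#' atom count, iteration count and seed when produced by
#' [learn_dictionary()]) in a self-describing serialized container.
#'
#' @param dict An [sr_dictionary()].
#' @param path File path.
#' @return `save_dictionary` returns `path` invisibly; `load_dictionary`
#'   returns the [sr_dictionary()] with metadata in `attr(, "provenance")`.
#' @export
save_dictionary <- function(dict, path) {
  if (!inherits(dict, "sr_dictionary")) stop_data("`dict` must be an sr_dictionary")
  obj <- list(format = "dwisr_dictionary", version = 1L,
              patch_side = dict$patch_side, k = dict$k,
              atoms = dict$atoms,
              provenance = attr(dict, "provenance"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dwisr_dictionary"))
    stop_data("file does not contain a dwisr dictionary")
  d <- sr_dictionary(obj$atoms, obj$patch_side)
  attr(d, "provenance") <- obj$provenance
  d
}
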
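#' Diffusion gradient scheme
#'
#' A gradient scheme pairs one b-value (s/mm^2) with one gradient direction
#' per acquired volume. Directions of diffusion-weighted volumes (b > 0) must
#' be unit vectors; b = 0 volumes conventionally carry a zero direction.
#'
#' @param bvals Numeric vector of b-values, one per volume (s/mm^2).
#' @param bvecs 3 x n numeric matrix of gradient directions (columns).
#' @return An object of class `gradient_scheme` with elements `bvals` and
#'   `bvecs`.
#' @examples
#' sch <- gradient_scheme(c(0, 1000), cbind(c(0, 0, 0), c(1, 0, 0)))
#' sch$bvals
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L)
    stop_data("`bvecs` must have exactly 3 rows (x, y, z); got ",
              nrow(bvecs), " rows")
  if (ncol(bvecs) != length(bvals))
    stop_data("number of b-values (", length(bvals),
              ") must equal number of direction columns (", ncol(bvecs), ")")
  if (any(bvals < 0)) stop_data("b-values must be non-negative")
  if (!any(bvals == 0))
    stop_data("gradient scheme must contain at least one b = 0 volume")
  nrm <- sqrt(colSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-9
  if (any(bad))
    stop_data("directions with b > 0 must be unit vectors; ",
              sum(bad), " column(s) off by more than 1e-9")
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_scheme")
}

#' Build a quasi-uniform gradient scheme
#'
#' Generates `n_b0` unweighted volumes followed by `n_dirs` diffusion
#' directions spread quasi-uniformly over the upper hemisphere by a
#' deterministic golden-angle (Fibonacci) spiral, which yields a
#' well-conditioned tensor design for as few as 6 directions.
#'
#' @param n_dirs Number of diffusion-weighted directions (default 32).
#' @param bval b-value of the weighted volumes in s/mm^2 (default 1000).
#' @param n_b0 Number of unweighted (b = 0) volumes (default 1).
#' @return A [gradient_scheme()].
#' @examples
#' sch <- make_gradient_scheme(32)
#' length(sch$bvals)  # 33 volumes
#' @export
make_gradient_scheme <- function(n_dirs = 32L, bval = 1000, n_b0 = 1L) {
  if (!is_count(n_dirs) || n_dirs < 6)
    stop_data("`n_dirs` must be an integer >= 6 for an identifiable tensor")
  if (!is_count(n_b0)) stop_data("`n_b0` must be a positive integer")
  if (!is_scalar(bval) || bval <= 0) stop_data("`bval` must be positive")
  i <- seq_len(n_dirs)
  z <- (i - 0.5) / n_dirs                 # hemisphere: z in (0, 1)
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))            # golden angle
  phi <- i * golden
  dirs <- rbind(r * cos(phi), r * sin(phi), z)
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  bvecs <- cbind(matrix(0, 3, n_b0), dirs)
  bvals <- c(rep(0, n_b0), rep(bval, n_dirs))
  gradient_scheme(bvals, bvecs)
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("gradient_scheme:", length(x$bvals), "volumes (",
      sum(x$bvals == 0), "b=0,", sum(x$bvals > 0), "weighted; b =",
      paste(unique(x$bvals[x$bvals > 0]), collapse = ", "), "s/mm^2 )\n")
  invisible(x)
}
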
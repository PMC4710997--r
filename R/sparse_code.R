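#' Error budget for sparse coding
#'
#' The admissible squared representation error per patch is
#' `c_const * n_pix * sigma^2` (with `n_pix` the number of pixels per patch,
#' i.e. the squared patch side): patches need only be approximated down to
#' the noise floor, scaled by the constant `c_const`.
#'
#' @param c_const Positive constant scaling the noise floor (default 1.2).
#' @param sigma Noise standard deviation (>= 0).
#' @param n_pix Pixels per patch.
#' @param max_nonzeros Optional cap on the number of nonzero coefficients
#'   per patch (default 5; `NULL` disables the cap). Ignored when the error
#'   bound is 0, where exact representation is required.
#' @return An object of class `coding_budget` with the derived `error_bound`.
#' @examples
#' coding_budget(1.2, sigma = 10, n_pix = 64)$error_bound  # 1.2 * 64 * 100
#' @export
coding_budget <- function(c_const = 1.2, sigma, n_pix, max_nonzeros = 5L) {
  if (!is_scalar(c_const) || c_const <= 0) stop_data("`c_const` must be positive")
  if (!is_scalar(sigma) || sigma < 0) stop_data("`sigma` must be >= 0")
  if (!is_count(n_pix)) stop_data("`n_pix` must be a positive integer")
  if (!is.null(max_nonzeros) && !is_count(max_nonzeros))
    stop_data("`max_nonzeros` must be a positive integer or NULL")
  structure(list(c_const = c_const, sigma = sigma, n_pix = as.integer(n_pix),
                 max_nonzeros = if (is.null(max_nonzeros)) NULL
                                else as.integer(max_nonzeros),
                 error_bound = c_const * n_pix * sigma^2),
            class = "coding_budget")
}

#' Error-constrained minimum-L1 sparse coding
#'
#' For every patch solves `min ||a||_1 subject to ||p - Psi a||_2^2 <=
#' error_bound` exactly, by following the lasso regularization path
#' (homotopy over the Gram matrix) and stopping at the closed-form budget
#' crossing inside the active segment. With `max_nonzeros` set, the support
#' is additionally capped: once the cap is reached no further atoms join and
#' the path shrinks towards the active-set least-squares solution; if even
#' that cannot meet the budget the patch is flagged infeasible (never
#' silently accepted). A budget of 0 (noiseless coding) lifts the cap and
#' drives the residual to numerical zero where the patch lies in the
#' dictionary's span.
#'
#' @param patches A [extract_patches()] result, or a bare `n_pix x P` matrix.
#' @param dict An [sr_dictionary()].
#' @param budget A [coding_budget()]; `budget$n_pix` must match the
#'   dictionary.
#' @return An object of class `sparse_code_set`: `coefficients` (a
#'   `k x P` sparse `Matrix::dgCMatrix`), `residual_norms`, logical
#'   `feasible`, and the `budget`.
#' @examples
#' d <- init_dct_dictionary(4, 25)
#' p <- matrix(d$atoms[, 7], ncol = 1)            # a single atom
#' sc <- sparse_code(p, d, coding_budget(1, 0, 16, NULL))
#' sc$residual_norms                              # exactly representable
#' @export
sparse_code <- function(patches, dict, budget) {
  X <- if (inherits(patches, "patch_set")) patches$patches else as.matrix(patches)
  if (!inherits(dict, "sr_dictionary")) stop_data("`dict` must be an sr_dictionary")
  if (!inherits(budget, "coding_budget")) stop_data("`budget` must be a coding_budget")
  if (nrow(X) != nrow(dict$atoms))
    stop_data("patch length (", nrow(X), ") does not match dictionary atom ",
              "length (", nrow(dict$atoms), ")")
  if (budget$n_pix != nrow(dict$atoms))
    stop_data("budget n_pix (", budget$n_pix, ") does not match dictionary")
  cap <- effective_cap(budget)
  res <- sr_lasso_batch_cpp(dict$atoms, X, budget$error_bound, cap,
                            dense_out = FALSE)
  coef <- Matrix::sparseMatrix(i = res$i, j = res$j, x = res$x,
                               dims = c(dict$k, ncol(X)))
  feas <- as.logical(res$feasible)
  if (!all(feas) && budget$error_bound == 0)
    warning(sum(!feas), " patch(es) outside the dictionary span could not ",
            "be represented exactly; best residuals reported and flagged",
            call. = FALSE)
  structure(list(coefficients = coef, residual_norms = as.numeric(res$resid),
                 feasible = feas, budget = budget),
            class = "sparse_code_set")
}

effective_cap <- function(budget) {
  if (is.null(budget$max_nonzeros) || budget$error_bound == 0) 0L
  else as.integer(budget$max_nonzeros)
}

#' @export
print.sparse_code_set <- function(x, ...) {
  nnz <- Matrix::nnzero(x$coefficients)
  P <- ncol(x$coefficients)
  cat("sparse_code_set:", P, "patches,", nnz, "nonzeros (",
      signif(nnz / max(P, 1), 3), "per patch ); ",
      sum(!x$feasible), "infeasible\n")
  invisible(x)
}
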
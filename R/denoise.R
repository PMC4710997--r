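#' Denoising configuration
#'
#' Collects every tunable of the multi-slice sparse-representation denoiser.
#' Defaults follow the simulated-experiment configuration: 8 x 8 patches, a
#' 64 x 256 dictionary, error constant `c_const = 1.2`, sparsity cap 5, 15
#' training rounds, stride 1, and groups of 5 adjacent slices sharing one
#' dictionary.
#'
#' @param patch_side Patch edge in pixels (default 8).
#' @param k Number of dictionary atoms (default 256; perfect square >
#'   `patch_side^2`).
#' @param c_const Error-budget constant (default 1.2).
#' @param lam Fidelity weight of the observed image in the reconstruction;
#'   `NULL` (default) selects `30 / sigma`, the canonical K-SVD-denoising
#'   choice, or 0 when `sigma = 0`.
#' @param group_size Number of adjacent slices sharing one dictionary
#'   (default 5).
#' @param n_iterations Dictionary-learning rounds per group (default 15).
#' @param stride Patch grid stride (default 1, maximally overlapping).
#' @param max_nonzeros Sparsity cap per patch (default 5; NULL disables).
#' @param seed Integer seed governing all randomness (training subsample).
#' @param sigma_mode `"given"` (use the sequence's recorded sigma) or
#'   `"estimate"` (background-based estimate, see [estimate_sigma()]).
#' @param train_cap Training-subsample cap (default 40000 patches).
#' @param tol Early-stopping tolerance for dictionary learning (default 0:
#'   run all rounds).
#' @param bias_correct Apply the post-hoc magnitude-bias correction
#'   `x <- sqrt(max(x^2 - 2 sigma^2, 0))` to the output (default FALSE; the
#'   optimization itself treats noise as additive Gaussian).
#' @return An object of class `denoise_config`.
#' @examples
#' denoise_config(seed = 7)$k
#' @export
denoise_config <- function(patch_side = 8L, k = 256L, c_const = 1.2,
                           lam = NULL, group_size = 5L, n_iterations = 15L,
                           stride = 1L, max_nonzeros = 5L, seed = 1L,
                           sigma_mode = c("given", "estimate"),
                           train_cap = 40000L, tol = 0,
                           bias_correct = FALSE) {
  sigma_mode <- match.arg(sigma_mode)
  if (!is_count(group_size)) stop_data("`group_size` must be >= 1")
  if (!is_scalar(c_const) || c_const <= 0) stop_data("`c_const` must be > 0")
  if (!is.null(lam) && (!is_scalar(lam) || lam < 0))
    stop_data("`lam` must be >= 0 or NULL")
  if (!is_count(patch_side) || !is_count(k) || !is_count(n_iterations) ||
      !is_count(stride) || !is_count(train_cap))
    stop_data("patch_side, k, n_iterations, stride, train_cap must be ",
              "positive integers")
  structure(list(patch_side = as.integer(patch_side), k = as.integer(k),
                 c_const = c_const, lam = lam,
                 group_size = as.integer(group_size),
                 n_iterations = as.integer(n_iterations),
                 stride = as.integer(stride),
                 max_nonzeros = if (is.null(max_nonzeros)) NULL
                                else as.integer(max_nonzeros),
                 seed = as.integer(seed), sigma_mode = sigma_mode,
                 train_cap = as.integer(train_cap), tol = tol,
                 bias_correct = isTRUE(bias_correct)),
            class = "denoise_config")
}

#' Partition slices into contiguous dictionary groups
#'
#' Adjacent slices share image content, so one dictionary is learned per
#' contiguous group of up to `group_size` slices; the last group may be
#' smaller. `group_size = 1` degenerates to independent per-slice denoising.
#'
#' @param n_slices Number of slices (>= 1).
#' @param group_size Slices per group (>= 1).
#' @return List of 1-based integer index vectors covering `1:n_slices`.
#' @examples
#' group_slices(7, 3)  # list(1:3, 4:6, 7)
#' @export
group_slices <- function(n_slices, group_size) {
  if (!is_count(n_slices)) stop_data("`n_slices` must be >= 1")
  if (!is_count(group_size)) stop_data("`group_size` must be >= 1")
  idx <- seq_len(n_slices)
  unname(split(idx, ceiling(idx / group_size)))
}

#' Denoise one group of adjacent slices with a jointly learned dictionary
#'
#' Pools the patches of all slices in the group, learns a dictionary from
#' them (starting at `init_dict`), runs a final coding pass over every
#' patch, and reconstructs each slice by the closed-form weighted
#' aggregation of the represented patches
#' ([aggregate_clean_image()]).
#'
#' @param noisy_slices 2D matrix or 3D array of the group's slices.
#' @param init_dict Initial [sr_dictionary()].
#' @param config A [denoise_config()].
#' @param sigma Noise standard deviation (>= 0).
#' @return List with `clean` (same shape as input), `dictionary` (learned),
#'   and `history` (objective trace from [learn_dictionary()]).
#' @export
denoise_group <- function(noisy_slices, init_dict, config, sigma) {
  if (!inherits(config, "denoise_config"))
    stop_data("`config` must be a denoise_config")
  if (!is_scalar(sigma) || sigma < 0) stop_data("`sigma` must be >= 0")
  budget <- coding_budget(config$c_const, sigma, config$patch_side^2,
                          config$max_nonzeros)
  ps <- extract_patches(noisy_slices, config$patch_side, config$stride)
  ld <- learn_dictionary(ps, init_dict, budget,
                         n_iterations = config$n_iterations,
                         seed = config$seed, train_cap = config$train_cap,
                         tol = config$tol)
  coded <- as.matrix(ld$dictionary$atoms %*% ld$codes$coefficients)
  lam <- if (is.null(config$lam)) {
    if (sigma > 0) 30 / sigma else 0
  } else config$lam
  clean <- aggregate_clean_image(noisy_slices, ps, coded, lam)
  list(clean = clean, dictionary = ld$dictionary, history = ld$history)
}

#' Denoise a full DWI sequence
#'
#' Iterates over gradient volumes in acquisition order and, within each
#' volume, over contiguous slice groups ([group_slices()]), calling
#' [denoise_group()] per group. The dictionary learned for a group seeds the
#' same group of the next volume (warm start); the DCT dictionary seeds the
#' first volume. b = 0 and b > 0 volumes are processed identically with the
#' same sigma.
#'
#' @param noisy A [dwi_sequence()]. With `sigma_mode = "given"` its `sigma`
#'   field must be set; with `"estimate"` sigma is estimated from the b = 0
#'   background ([estimate_sigma()]).
#' @param config A [denoise_config()].
#' @param verbose Emit per-group progress messages (default FALSE).
#' @return List with `denoised` (a [dwi_sequence()], `sigma` unset) and
#'   `report` (class `denoise_report`: effective config, sigma used, and the
#'   per-volume, per-group objective histories).
#' @export
denoise_sequence <- function(noisy, config = denoise_config(),
                             verbose = FALSE) {
  if (!inherits(noisy, "dwi_sequence")) stop_data("`noisy` must be a dwi_sequence")
  if (!inherits(config, "denoise_config"))
    stop_data("`config` must be a denoise_config")
  d <- dim(noisy$data)
  sigma <- switch(config$sigma_mode,
    given = {
      if (is.null(noisy$sigma))
        stop_data("sigma_mode = \"given\" but the sequence has no recorded ",
                  "sigma; supply one or use sigma_mode = \"estimate\"")
      noisy$sigma
    },
    estimate = estimate_sigma(noisy))

  groups <- group_slices(d[3], config$group_size)
  dicts <- rep(list(init_dct_dictionary(config$patch_side, config$k)),
               length(groups))
  out <- array(0, d)
  histories <- vector("list", d[4])
  for (v in seq_len(d[4])) {
    histories[[v]] <- vector("list", length(groups))
    for (g in seq_along(groups)) {
      sl <- groups[[g]]
      res <- denoise_group(noisy$data[, , sl, v, drop = FALSE][, , , 1],
                           dicts[[g]], config, sigma)
      cl <- res$clean
      if (length(sl) == 1L && is.matrix(cl)) cl <- array(cl, c(dim(cl), 1))
      out[, , sl, v] <- cl
      dicts[[g]] <- res$dictionary
      histories[[v]][[g]] <- res$history
      if (verbose)
        message(sprintf(
          "volume %d group %d: %d iterations, final error %.4g, %d atoms replaced",
          v, g, max(res$history$iteration),
          tail(res$history$error, 1), sum(res$history$replaced)))
    }
  }
  if (config$bias_correct && sigma > 0)
    out <- sqrt(pmax(out^2 - 2 * sigma^2, 0))
  report <- structure(list(config = config, sigma = sigma,
                           histories = histories,
                           dictionaries = dicts),
                      class = "denoise_report")
  list(denoised = dwi_sequence(out, noisy$scheme, sigma = NULL),
       report = report)
}

#' @export
print.denoise_report <- function(x, ...) {
  cat("denoise_report: sigma =", signif(x$sigma, 4), ";",
      length(x$histories), "volumes x", length(x$histories[[1]]),
      "slice group(s)\n")
  invisible(x)
}

#' Background-based Rician noise estimate
#'
#' Heuristic estimator for real data where sigma is unknown: collects the
#' lowest-intensity decile of the first b = 0 volume (predominantly air
#' background, whose magnitude signal is Rayleigh distributed) and inverts
#' the analytic second moment of the decile-truncated Rayleigh
#' distribution. For a pure Rayleigh background the estimator is consistent;
#' with substantial tissue fraction it is upward biased and should be read
#' as an upper bound.
#'
#' @param noisy A [dwi_sequence()] with a b = 0 volume.
#' @param q Truncation quantile (default 0.1, the lowest decile).
#' @return Estimated sigma (0 for an all-zero image).
#' @export
estimate_sigma <- function(noisy, q = 0.1) {
  if (!inherits(noisy, "dwi_sequence")) stop_data("`noisy` must be a dwi_sequence")
  if (!is_scalar(q) || q <= 0 || q >= 1) stop_data("`q` must be in (0, 1)")
  ib0 <- which(noisy$scheme$bvals == 0)
  if (length(ib0) == 0) stop_data("sequence has no b = 0 volume")
  b0 <- as.vector(noisy$data[, , , ib0[1]])
  if (all(b0 == 0)) return(0)
  thr <- quantile(b0, q, names = FALSE)
  sel <- b0[b0 <= thr]
  # second moment of a Rayleigh truncated to its lowest q-quantile:
  # E[X^2 | X <= x_q] = 2 sigma^2 (1 - (1 - q)(1 + u_q)) / q, u_q = -log(1-q)
  uq <- -log1p(-q)
  corr <- 2 * (1 - (1 - q) * (1 + uq)) / q
  sqrt(mean(sel^2) / corr)
}
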
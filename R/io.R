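#' Read a DWI dataset (NIfTI + FSL-style bval/bvec)
#'
#' Loads a 4D NIfTI image together with its gradient table in the FSL
#' dialect: `bval` is one row of whitespace-separated b-values, `bvec` three
#' rows (x, y, z components). Volume counts across the three files must
#' agree. Directions of b > 0 volumes that deviate from unit norm by more
#' than 1e-3 are renormalized with a warning; the image affine is preserved
#' for write-back.
#'
#' @param image_path Path to a 4D NIfTI-1/2 image.
#' @param bval_path Path to the bval text file.
#' @param bvec_path Path to the bvec text file (3 rows).
#' @return A `dataset_bundle`: list with `sequence` (a [dwi_sequence()]),
#'   `header` (NIfTI template for write-back), `paths`, `provenance`.
#' @export
read_dwi <- function(image_path, bval_path, bvec_path) {
  for (p in c(image_path, bval_path, bvec_path))
    if (!file.exists(p)) stop_data("file not found: ", p)
  img <- RNifti::readNifti(image_path)
  d <- dim(img)
  if (length(d) == 3L)
    stop_data("image is 3D; a DWI dataset must be a 4D volume stack")
  if (length(d) != 4L)
    stop_data("image must be 4D, got ", length(d), " dimensions")

  bvals <- scan(bval_path, quiet = TRUE)
  bvec_lines <- readLines(bvec_path)
  bvec_lines <- bvec_lines[nzchar(trimws(bvec_lines))]
  bvecs <- do.call(rbind, lapply(bvec_lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (nrow(bvecs) != 3L) {
    hint <- if (ncol(bvecs) == 3L)
      "; the file looks transposed (column-major, one direction per row) - expected the FSL dialect with 3 rows (x, y, z)"
    else ""
    stop_data("bvec must have exactly 3 rows, got ", nrow(bvecs), hint)
  }
  if (d[4] != length(bvals) || d[4] != ncol(bvecs))
    stop_data("volume count mismatch: image has ", d[4], " volumes, bval ",
              length(bvals), " entries, bvec ", ncol(bvecs), " columns")

  nrm <- sqrt(colSums(bvecs^2))
  off <- bvals > 0 & abs(nrm - 1) > 1e-3
  if (any(off)) {
    warning(sum(off), " b > 0 direction(s) off unit norm by more than 1e-3; ",
            "renormalized", call. = FALSE)
  }
  fix <- bvals > 0 & abs(nrm - 1) > 1e-12 & nrm > 0
  bvecs[, fix] <- sweep(bvecs[, fix, drop = FALSE], 2, nrm[fix], "/")

  scheme <- gradient_scheme(bvals, bvecs)
  seq <- dwi_sequence(array(as.numeric(img), d), scheme)
  structure(list(sequence = seq, header = img,
                 paths = list(image = image_path, bval = bval_path,
                              bvec = bvec_path),
                 provenance = list(dim = d,
                                   pixdim = RNifti::pixdim(img),
                                   range = range(as.numeric(img)))),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("dataset_bundle:", paste(x$provenance$dim, collapse = " x "), "from",
      x$paths$image, "\n")
  invisible(x)
}

#' Write a DWI sequence as NIfTI + bval/bvec
#'
#' Writes the sequence as a 4D NIfTI with 32-bit float datatype. When a
#' `dataset_bundle` is supplied its affine/header is preserved exactly;
#' otherwise a default header is created. The gradient table is written in
#' the FSL dialect alongside (same path with `.bval` / `.bvec` extensions).
#' Negative intensities are preserved (not clipped) with a warning.
#'
#' @param sequence A [dwi_sequence()].
#' @param out_path Output image path (`.nii` or `.nii.gz`).
#' @param bundle Optional `dataset_bundle` whose header is reused; shapes
#'   must match.
#' @return Invisible list of the written file paths.
#' @export
write_dwi <- function(sequence, out_path, bundle = NULL) {
  if (!inherits(sequence, "dwi_sequence"))
    stop_data("`sequence` must be a dwi_sequence")
  d <- dim(sequence$data)
  if (!is.null(bundle)) {
    if (!identical(d, bundle$provenance$dim))
      stop_data("sequence shape (", paste(d, collapse = " x "),
                ") does not match bundle provenance (",
                paste(bundle$provenance$dim, collapse = " x "), ")")
  }
  if (any(sequence$data < 0))
    warning("negative intensities present; written unchanged", call. = FALSE)
  img <- if (!is.null(bundle))
    RNifti::asNifti(sequence$data, reference = bundle$header)
  else RNifti::asNifti(sequence$data)
  RNifti::writeNifti(img, out_path, datatype = "float")

  base <- sub("\\.nii(\\.gz)?$", "", out_path)
  bval_path <- paste0(base, ".bval")
  bvec_path <- paste0(base, ".bvec")
  write_gradient_table(sequence$scheme, bval_path, bvec_path)
  invisible(list(image = out_path, bval = bval_path, bvec = bvec_path))
}

write_gradient_table <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' Write a simulated phantom bundle
#'
#' Emits the simulated sequence as NIfTI + bval/bvec plus the ground-truth
#' tensor field as a 4D NIfTI with 6 channels in lower-triangular order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), and the non-background mask.
#'
#' @param field The ground-truth [tensor_field()].
#' @param sequence The simulated [dwi_sequence()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default "phantom").
#' @return Invisible list of written paths.
#' @export
write_phantom_bundle <- function(field, sequence, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- write_dwi(sequence, file.path(dir, paste0(prefix, "_dwi.nii.gz")))
  d <- dim(field$tensors)[1:3]
  lt <- array(0, c(d, 6))
  ord <- list(c(1, 1), c(1, 2), c(2, 2), c(1, 3), c(2, 3), c(3, 3))
  for (i in seq_along(ord))
    lt[, , , i] <- field$tensors[, , , ord[[i]][1], ord[[i]][2]]
  tpath <- file.path(dir, paste0(prefix, "_tensors.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(lt), tpath, datatype = "float")
  mpath <- file.path(dir, paste0(prefix, "_mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(field$mask), d)),
                     mpath, datatype = "uint8")
  invisible(c(paths, list(tensors = tpath, mask = mpath)))
}

#' Read a ground-truth tensor NIfTI written by [write_phantom_bundle()]
#'
#' @param tensor_path 6-channel tensor NIfTI (lower-triangular order).
#' @param mask_path Optional mask NIfTI; default marks voxels with any
#'   nonzero tensor entry.
#' @return A [tensor_field()].
#' @export
read_tensor_field <- function(tensor_path, mask_path = NULL) {
  lt <- RNifti::readNifti(tensor_path)
  d <- dim(lt)
  if (length(d) != 4L || d[4] != 6L)
    stop_data("expected a 4D NIfTI with 6 tensor channels")
  tensors <- array(0, c(d[1:3], 3, 3))
  ord <- list(c(1, 1), c(1, 2), c(2, 2), c(1, 3), c(2, 3), c(3, 3))
  for (i in seq_along(ord)) {
    a <- ord[[i]][1]; b <- ord[[i]][2]
    tensors[, , , a, b] <- lt[, , , i]
    tensors[, , , b, a] <- lt[, , , i]
  }
  mask <- if (!is.null(mask_path)) {
    array(as.numeric(RNifti::readNifti(mask_path)) > 0.5, d[1:3])
  } else {
    apply(abs(tensors), c(1, 2, 3), max) > 0
  }
  tensor_field(tensors, mask)
}

#' Write FA and colour-FA maps as NIfTI
#'
#' The scalar FA map is written as a 3D volume, the direction-encoded
#' colour map as a 4D volume with 3 channels (red = left-right, green =
#' anterior-posterior, blue = superior-inferior), both 32-bit float.
#'
#' @param maps A [colored_fa()] result.
#' @param fa_path Output path for the scalar FA NIfTI.
#' @param rgb_path Optional output path for the 3-channel colour NIfTI.
#' @return Invisible list of written paths.
#' @export
write_fa_maps <- function(maps, fa_path, rgb_path = NULL) {
  if (!inherits(maps, "fa_maps")) stop_data("`maps` must be an fa_maps object")
  RNifti::writeNifti(RNifti::asNifti(maps$fa), fa_path, datatype = "float")
  out <- list(fa = fa_path)
  if (!is.null(rgb_path)) {
    RNifti::writeNifti(RNifti::asNifti(maps$rgb), rgb_path,
                       datatype = "float")
    out$rgb <- rgb_path
  }
  invisible(out)
}

#' Write an evaluation/denoising report as JSON
#'
#' Embeds the effective configuration, the sigma used, the seed and any
#' supplied metrics so a run is fully reproducible from its report.
#'
#' @param report A `denoise_report` (or plain list) to serialize.
#' @param path Output JSON path.
#' @param metrics Optional named list of scalar metrics to embed.
#' @return Invisible `path`.
#' @export
write_report_json <- function(report, path, metrics = NULL) {
  obj <- list()
  if (inherits(report, "denoise_report")) {
    obj$config <- unclass(report$config)
    obj$sigma <- report$sigma
    obj$objective_traces <- lapply(report$histories, function(v)
      lapply(v, function(h) h$error))
  } else obj <- report
  if (!is.null(metrics)) obj$metrics <- metrics
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
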
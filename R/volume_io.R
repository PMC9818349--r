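# Volume and manifest I/O plus Gaussian smoothing.
#
# Volumes are expected to be spatially pre-normalized onto a common grid;
# no registration or resampling is performed here.

#' Construct a subject volume
#'
#' A `subject_volume` bundles a 3-D non-negative intensity array with its
#' voxel size and subject metadata. Orientation/header metadata read from
#' file is carried opaquely and never interpreted.
#'
#' @param data 3-D numeric array of finite, non-negative intensities with at
#'   least one strictly positive voxel.
#' @param voxel_size Numeric length-3 vector of voxel edge lengths in mm.
#' @param subject_id Optional subject identifier.
#' @param group Optional group label.
#' @param header Opaque header metadata (e.g. from a NIfTI file), or `NULL`.
#' @return An object of class `subject_volume`.
#' @export
subject_volume <- function(data, voxel_size = c(1, 1, 1), subject_id = NULL,
                           group = NULL, header = NULL) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L)
    ssm_stop("'data' must be a 3-D array", "validation_error")
  if (any(dim(data) < 1L))
    ssm_stop("all three dimensions must be >= 1", "validation_error")
  if (!all(is.finite(data)))
    ssm_stop("volume intensities must all be finite", "validation_error")
  if (any(data < 0))
    ssm_stop("volume intensities must be non-negative", "validation_error")
  if (!any(data > 0))
    ssm_stop("volume must contain at least one strictly positive voxel",
             "validation_error")
  new_subject_volume(data, voxel_size, subject_id, group, header)
}

# Internal constructor without the intensity invariants: files read back
# may legitimately hold signed maps (patterns, GMPs) or all-zero arrays.
new_subject_volume <- function(data, voxel_size, subject_id = NULL,
                               group = NULL, header = NULL) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || !all(is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    ssm_stop("'voxel_size' must be three positive numbers", "validation_error")
  structure(list(data = data, voxel_size = voxel_size,
                 subject_id = subject_id, group = group, header = header),
            class = "subject_volume")
}

#' @export
print.subject_volume <- function(x, ...) {
  cat(sprintf("<subject_volume> %s%s: %s voxels @ %s mm\n",
              if (is.null(x$subject_id)) "(unnamed)" else x$subject_id,
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' Read a brain volume from file
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) or Analyze 7.5 (`.hdr`/`.img`) volumes.
#' A 4-D file holding a single frame is squeezed to 3-D; genuinely
#' multi-frame files are rejected.
#'
#' @param path Path to the volume file.
#' @param subject_id,group Optional metadata attached to the result.
#' @return A [subject_volume()].
#' @export
read_volume <- function(path, subject_id = NULL, group = NULL) {
  if (!file.exists(path))
    ssm_stop(sprintf("file not found: %s", path), "format_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    ssm_stop(sprintf("cannot read volume '%s': %s",
                                     path, conditionMessage(e)),
                             "format_error"))
  d <- dim(img)
  if (length(d) > 3L) {
    extra <- d[-(1:3)]
    if (prod(extra) > 1L)
      ssm_stop(sprintf("'%s' has %d frames; expected a single 3-D volume",
                       path, prod(extra)), "multiframe_error")
    arr <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    arr <- array(as.numeric(img), dim = d)
  } else {
    ssm_stop(sprintf("'%s' is %d-dimensional; expected 3-D", path, length(d)),
             "format_error")
  }
  if (!all(is.finite(arr)))
    ssm_stop(sprintf("'%s' contains non-finite values", path), "format_error")
  vs <- RNifti::pixdim(img)[1:3]
  new_subject_volume(arr, voxel_size = vs, subject_id = subject_id,
                     group = group, header = RNifti::niftiHeader(img))
}

#' Write a volume to a NIfTI-1 file
#'
#' Accepts either a [subject_volume()] or a bare numeric array (e.g. a
#' pattern voxel map). All outputs are NIfTI; values are stored as
#' single-precision floats unless `datatype` says otherwise.
#'
#' @param v A `subject_volume` or a 3-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel size used when `v` is a bare array.
#' @param datatype Storage type passed to [RNifti::writeNifti()]
#'   (`"float"` or `"double"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, voxel_size = c(1, 1, 1),
                         datatype = "float") {
  if (inherits(v, "subject_volume")) {
    arr <- v$data
    voxel_size <- v$voxel_size
  } else {
    arr <- v
  }
  if (!is.array(arr) || length(dim(arr)) != 3L)
    ssm_stop("volume data must be a 3-D array", "validation_error")
  if (!all(is.finite(arr)))
    ssm_stop("volume contains non-finite values; refusing to write",
             "validation_error")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# FWHM -> Gaussian sigma conversion factor: FWHM = 2 sqrt(2 ln 2) sigma.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Normalized, truncated (4 sigma) discrete Gaussian kernel.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Convolve one axis of a 3-D array with a symmetric kernel, zero padding.
convolve_axis <- function(arr, kernel, axis) {
  n <- dim(arr)[axis]
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    if (any(ok)) K[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  out <- array(K %*% matrix(a, nrow = d[1]), dim = d)
  aperm(out, order(perm))
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian smoothing with per-axis
#' `sigma = (fwhm_mm / (2 sqrt(2 ln 2))) / voxel_size`, using zero padding at
#' the boundary (outside-brain signal is treated as zero). `fwhm_mm = 0`
#' returns the input unchanged.
#'
#' @param v A [subject_volume()] or a 3-D numeric array.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm; must be
#'   non-negative. When `v` is a bare array, `voxel_size` supplies the grid
#'   spacing (so passing `voxel_size = c(1,1,1)` interprets `fwhm_mm` in
#'   voxels).
#' @param voxel_size Voxel size used when `v` is a bare array.
#' @return Smoothed object of the same kind as the input.
#' @export
gaussian_smooth <- function(v, fwhm_mm, voxel_size = c(1, 1, 1)) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm < 0)
    ssm_stop("'fwhm_mm' must be a single non-negative number",
             "validation_error")
  if (fwhm_mm == 0) return(v)
  is_sv <- inherits(v, "subject_volume")
  arr <- if (is_sv) v$data else v
  vs <- if (is_sv) v$voxel_size else as.numeric(voxel_size)
  sigma <- fwhm_to_sigma(fwhm_mm) / vs
  for (axis in 1:3) {
    if (sigma[axis] > 0)
      arr <- convolve_axis(arr, gaussian_kernel(sigma[axis]), axis)
  }
  if (is_sv) {
    v$data <- arr
    v
  } else {
    arr
  }
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with header `subject_id,group,path`. Paths may be
#' absolute or relative to the manifest's own directory.
#'
#' @param path Manifest CSV path.
#' @param groups Optional character vector declaring the allowed group
#'   vocabulary; any undeclared group is an error.
#' @return A data frame with columns `subject_id`, `group`, `path`.
#' @export
read_manifest <- function(path, groups = NULL) {
  if (!file.exists(path))
    ssm_stop(sprintf("manifest not found: %s", path), "manifest_error")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m, groups = groups, base_dir = dirname(path))
}

validate_manifest <- function(m, groups = NULL, base_dir = NULL) {
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(m)))
    ssm_stop(sprintf("manifest must have columns %s",
                     paste(need, collapse = ", ")), "manifest_error")
  if (nrow(m) < 1L)
    ssm_stop("manifest has no rows", "manifest_error")
  dup <- m$subject_id[duplicated(m$subject_id)]
  if (length(dup))
    ssm_stop(sprintf("duplicate subject_id in manifest: %s",
                     paste(unique(dup), collapse = ", ")), "manifest_error")
  if (!is.null(groups)) {
    bad <- setdiff(unique(m$group), groups)
    if (length(bad))
      ssm_stop(sprintf("manifest group(s) not in declared vocabulary: %s",
                       paste(bad, collapse = ", ")), "manifest_error")
  }
  if (!is.null(base_dir)) {
    rel <- !file.exists(m$path)
    m$path[rel] <- file.path(base_dir, m$path[rel])
  }
  missing <- m$subject_id[!file.exists(m$path)]
  if (length(missing))
    ssm_stop(sprintf("volume file missing for subject(s): %s",
                     paste(missing, collapse = ", ")), "manifest_error")
  m[, need]
}

#' Load all volumes of a manifest
#'
#' Volumes are returned in manifest order and must share one grid: any
#' mismatch in array shape or voxel size is an error naming the offending
#' subject.
#'
#' @param manifest A data frame as returned by [read_manifest()].
#' @return A list of [subject_volume()] objects.
#' @export
load_cohort <- function(manifest) {
  manifest <- validate_manifest(manifest)
  vols <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    vols[[i]] <- read_volume(manifest$path[i],
                             subject_id = manifest$subject_id[i],
                             group = manifest$group[i])
    if (i > 1L) {
      if (!identical(dim(vols[[i]]$data), dim(vols[[1]]$data)))
        ssm_stop(sprintf(
          "subject '%s' has grid %s but cohort grid is %s",
          manifest$subject_id[i],
          paste(dim(vols[[i]]$data), collapse = "x"),
          paste(dim(vols[[1]]$data), collapse = "x")),
          "cohort_consistency_error")
      if (max(abs(vols[[i]]$voxel_size - vols[[1]]$voxel_size)) > 1e-6)
        ssm_stop(sprintf(
          "subject '%s' has voxel size %s but cohort voxel size is %s",
          manifest$subject_id[i],
          paste(signif(vols[[i]]$voxel_size, 6), collapse = "x"),
          paste(signif(vols[[1]]$voxel_size, 6), collapse = "x")),
          "cohort_consistency_error")
    }
  }
  vols
}

# Shared error helper: classed conditions so callers can test by class.
ssm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("ssmpca_", class),
                                     "ssmpca_error")))
}
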
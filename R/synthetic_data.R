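# Synthetic FDG-PET-like cohort generator with known ground truth.
#
# Generative model, on the brain mask:
#   raw_i(v) = g_i * B(v) * exp(a_i * P(v) + eps_i(v)),  0 outside,
# with log g_i ~ N(0, global_sd^2) a per-subject multiplicative global
# factor, a_i ~ N(loading_mean[group], loading_sd[group]^2) the pattern
# loading, P a smooth zero-mean unit-norm covariance pattern shared by the
# cohort, B a smooth strictly positive base metabolic profile, and eps_i a
# smooth Gaussian field with per-voxel sd noise_sd. With noise in the log
# domain the SSM model is exactly well-specified; a raw-domain additive
# noise switch exists to probe robustness to misspecification.

#' Synthetic cohort configuration
#'
#' Defaults emulate a pattern-derivation study on spatially normalized
#' FDG-PET volumes: a 24-voxel cubic grid at 2 mm voxels, 19 controls (`C`)
#' and 19 disease subjects (`PD`) with pattern-loading means 0 and 2.5
#' (sd 1 each), a per-subject log-normal global factor of sd 0.2, and
#' smooth log-domain voxel noise of sd 0.05.
#'
#' @param grid Cubic grid size in voxels.
#' @param semi_axes Brain-ellipsoid semi-axes in voxels (must fit the grid).
#' @param group_sizes Named integer vector, label -> number of subjects
#'   (each >= 2).
#' @param loading_mean Named numeric vector of per-group pattern-loading
#'   means; groups absent from the vector default to 0.
#' @param loading_sd Named numeric vector of per-group loading sds;
#'   missing groups default to 1.
#' @param global_sd Sd of the log global scaling factor.
#' @param noise_sd Per-voxel sd of the smooth log-domain noise field.
#' @param pattern_fwhm Smoothness (FWHM, voxels) of the embedded pattern.
#' @param noise_fwhm Smoothness (FWHM, voxels) of the noise fields.
#' @param voxel_size Voxel edge lengths in mm.
#' @param noise_domain `"log"` (default, model well-specified) or `"raw"`
#'   (additive raw-domain noise, misspecified on purpose).
#' @param seed Required integer seed; cohorts are bit-reproducible given
#'   the full configuration.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid = 24L, semi_axes = c(9, 11, 9),
                         group_sizes = c(C = 19L, PD = 19L),
                         loading_mean = c(C = 0, PD = 2.5),
                         loading_sd = NULL,
                         global_sd = 0.2, noise_sd = 0.05,
                         pattern_fwhm = 6, noise_fwhm = 3,
                         voxel_size = c(2, 2, 2),
                         noise_domain = c("log", "raw"), seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    ssm_stop("'seed' is required", "validation_error")
  noise_domain <- match.arg(noise_domain)
  if (is.null(names(group_sizes)) || any(names(group_sizes) == ""))
    ssm_stop("'group_sizes' must be a named vector", "validation_error")
  if (any(group_sizes < 2L))
    ssm_stop("every group needs >= 2 subjects", "validation_error")
  if (any(c(global_sd, noise_sd) < 0))
    ssm_stop("sds must be >= 0", "validation_error")
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    ssm_stop("'semi_axes' must be three positive numbers", "validation_error")
  if (any(semi_axes > (grid - 1) / 2))
    ssm_stop("ellipsoid exceeds the grid", "validation_error")
  labels <- names(group_sizes)
  lm_full <- stats::setNames(rep(0, length(labels)), labels)
  lm_full[names(loading_mean)[names(loading_mean) %in% labels]] <-
    loading_mean[names(loading_mean) %in% labels]
  ls_full <- stats::setNames(rep(1, length(labels)), labels)
  if (!is.null(loading_sd))
    ls_full[names(loading_sd)[names(loading_sd) %in% labels]] <-
      loading_sd[names(loading_sd) %in% labels]
  if (any(ls_full < 0))
    ssm_stop("loading sds must be >= 0", "validation_error")
  structure(list(grid = as.integer(grid), semi_axes = as.numeric(semi_axes),
                 group_sizes = group_sizes, loading_mean = lm_full,
                 loading_sd = ls_full, global_sd = global_sd,
                 noise_sd = noise_sd, pattern_fwhm = pattern_fwhm,
                 noise_fwhm = noise_fwhm, voxel_size = as.numeric(voxel_size),
                 noise_domain = noise_domain, seed = as.integer(seed)),
            class = "synth_config")
}

#' Build the phantom brain: ellipsoid mask and base metabolic profile
#'
#' The mask contains every voxel whose center lies inside the ellipsoid
#' centered on the grid. The base profile is the smooth quadratic radial
#' falloff `B(v) = 100 (1 - r2(v) / 2)` where `r2` is the normalized
#' ellipsoidal squared radius (so B ranges from 100 at the center to 50 at
#' the surface, strictly positive everywhere on the mask; zero outside).
#'
#' @param config A [synth_config()].
#' @return List with `mask` (an `ssm_mask`) and `base_profile` (3-D array).
#' @export
make_brain <- function(config) {
  g <- config$grid
  ctr <- (g + 1) / 2
  ax <- config$semi_axes
  d1 <- ((seq_len(g) - ctr) / ax[1])^2
  d2 <- ((seq_len(g) - ctr) / ax[2])^2
  d3 <- ((seq_len(g) - ctr) / ax[3])^2
  r2 <- outer(outer(d1, d2, `+`), d3, `+`)
  inside <- r2 <= 1
  if (!any(inside))
    ssm_stop("ellipsoid contains no voxel centers", "validation_error")
  B <- array(0, dim = c(g, g, g))
  B[inside] <- 100 * (1 - r2[inside] / 2)
  list(mask = new_mask(which(inside), c(g, g, g), config$voxel_size),
       base_profile = B)
}

#' Generate a smooth embedded covariance pattern
#'
#' A seeded white-noise field smoothed to `fwhm` (voxels), restricted to
#' the mask, mean-removed and scaled to unit Euclidean norm.
#'
#' @param mask An `ssm_mask`.
#' @param fwhm Smoothness in voxels.
#' @param seed Optional seed (`NULL`: current RNG stream).
#' @return Numeric vector over the mask voxels: mean 0, norm 1.
#' @export
make_pattern <- function(mask, fwhm, seed = NULL) {
  p <- with_seed(seed, {
    field <- array(stats::rnorm(prod(mask$dim)), dim = mask$dim)
    if (fwhm > 0)
      field <- gaussian_smooth(field, fwhm, voxel_size = c(1, 1, 1))
    field[mask$indices]
  })
  p <- p - mean(p)
  p / sqrt(sum(p^2))
}

# Marginal sd of a smoothed unit-variance white field at an interior voxel:
# the root energy of the smoothing kernel's impulse response.
smoothed_field_sd <- function(dim, fwhm) {
  if (fwhm <= 0) return(1)
  imp <- array(0, dim = dim)
  imp[ceiling(dim[1] / 2), ceiling(dim[2] / 2), ceiling(dim[3] / 2)] <- 1
  q <- gaussian_smooth(imp, fwhm, voxel_size = c(1, 1, 1))
  sqrt(sum(q^2))
}

#' Simulate a synthetic FDG-PET-like cohort
#'
#' Draws per-subject loadings and global factors, builds each volume from
#' the generative model, and records the ground truth. Deterministic given
#' the configuration (including its seed).
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_cohort`: `volumes` (list of
#'   [subject_volume()]), `truth` (data frame `subject_id`, `group`,
#'   `loading`, `global_factor`), `pattern` (embedded pattern over the
#'   mask), `base_profile`, `mask`, and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  brain <- make_brain(config)
  mask <- brain$mask
  B <- brain$base_profile
  logB <- log(B[mask$indices])
  dim3 <- mask$dim

  with_seed(config$seed, {
    P <- make_pattern(mask, config$pattern_fwhm)
    noise_gain <- if (config$noise_sd > 0)
      config$noise_sd / smoothed_field_sd(dim3, config$noise_fwhm) else 0

    labels <- names(config$group_sizes)
    volumes <- list()
    truth <- list()
    for (lab in labels) {
      n <- config$group_sizes[[lab]]
      for (i in seq_len(n)) {
        a <- stats::rnorm(1, config$loading_mean[[lab]],
                          config$loading_sd[[lab]])
        gfac <- exp(stats::rnorm(1, 0, config$global_sd))
        eps <- if (noise_gain > 0) {
          f <- array(stats::rnorm(prod(dim3)), dim = dim3) * noise_gain
          if (config$noise_fwhm > 0)
            f <- gaussian_smooth(f, config$noise_fwhm,
                                 voxel_size = c(1, 1, 1))
          f[mask$indices]
        } else rep(0, length(mask$indices))
        arr <- array(0, dim = dim3)
        if (config$noise_domain == "log") {
          arr[mask$indices] <- gfac * exp(logB + a * P + eps)
        } else {
          # additive raw-domain noise, clipped to keep intensities positive
          raw <- gfac * exp(logB + a * P) +
            mean(B[mask$indices]) * eps
          arr[mask$indices] <- pmax(raw, 1e-3 * B[mask$indices])
        }
        id <- sprintf("%s_%02d", lab, i)
        volumes[[id]] <- subject_volume(arr, voxel_size = config$voxel_size,
                                        subject_id = id, group = lab)
        truth[[id]] <- data.frame(subject_id = id, group = lab, loading = a,
                                  global_factor = gfac)
      }
    }
    structure(list(volumes = unname(volumes),
                   truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                   pattern = P, base_profile = B, mask = mask,
                   config = config),
              class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subjects (%s) on a %s grid, %d mask voxels\n",
              nrow(x$truth),
              paste(sprintf("%s:%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = ", "),
              paste(x$mask$dim, collapse = "x"), length(x$mask$indices)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one NIfTI volume per subject plus `manifest.csv`
#' (`subject_id,group,path`), `truth.csv`
#' (`subject_id,group,loading,global_factor`) and the embedded pattern as
#' `pattern.nii`.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "volumes"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- character(length(cohort$volumes))
  for (i in seq_along(cohort$volumes)) {
    v <- cohort$volumes[[i]]
    paths[i] <- file.path("volumes", paste0(v$subject_id, ".nii"))
    write_volume(v, file.path(dir, paths[i]))
  }
  manifest <- data.frame(subject_id = cohort$truth$subject_id,
                         group = cohort$truth$group, path = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_volume(mask_to_array(cohort$pattern, cohort$mask),
               file.path(dir, "pattern.nii"),
               voxel_size = cohort$mask$voxel_size, datatype = "double")
  invisible(file.path(dir, "manifest.csv"))
}
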
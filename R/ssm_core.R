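# SSM-PCA core: intensity masking, log transform, double centering,
# subject-space PCA and component selection.
#
# The decomposition is performed on the subjects x subjects covariance of the
# double-centered log data, which is feasible (and exact) because the number
# of subjects is far smaller than the number of voxels: the nonzero spectrum
# of R R^T equals that of the voxel-space covariance R^T R.

#' SSM-PCA configuration
#'
#' @param mask_threshold Fraction of each subject's mean positive-voxel
#'   activity below which a voxel is discarded (removes white matter / CSF
#'   signal). Default 0.35.
#' @param variance_cutoff Retain the smallest leading set of principal
#'   components whose cumulative variance fraction reaches this value.
#'   Default 0.5.
#' @param alpha_select Significance level of the two-sample t-test used for
#'   component selection. Default 0.05.
#' @return An object of class `ssm_config`. The log transform is fixed to
#'   the natural logarithm.
#' @export
ssm_config <- function(mask_threshold = 0.35, variance_cutoff = 0.5,
                       alpha_select = 0.05) {
  if (!is.numeric(mask_threshold) || mask_threshold <= 0 || mask_threshold >= 1)
    ssm_stop("'mask_threshold' must be in (0, 1)", "validation_error")
  if (!is.numeric(variance_cutoff) || variance_cutoff <= 0 ||
      variance_cutoff > 1)
    ssm_stop("'variance_cutoff' must be in (0, 1]", "validation_error")
  if (!is.numeric(alpha_select) || alpha_select <= 0 || alpha_select >= 1)
    ssm_stop("'alpha_select' must be in (0, 1)", "validation_error")
  structure(list(mask_threshold = mask_threshold,
                 variance_cutoff = variance_cutoff,
                 alpha_select = alpha_select),
            class = "ssm_config")
}

new_mask <- function(indices, dim, voxel_size) {
  structure(list(indices = as.integer(indices), dim = as.integer(dim),
                 voxel_size = as.numeric(voxel_size)),
            class = "ssm_mask")
}

#' @export
print.ssm_mask <- function(x, ...) {
  cat(sprintf("<ssm_mask> %d voxels on a %s grid\n", length(x$indices),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Compute the cohort analysis mask
#'
#' A voxel is retained iff, for every subject, its intensity is at least
#' `threshold` times that subject's mean intensity over its strictly
#' positive voxels (the threshold is relative to each subject's own global
#' activity, so per-subject global scaling does not move the mask). The
#' cohort mask is the intersection of the per-subject masks, which
#' guarantees strictly positive masked intensities for every subject and
#' hence a valid log transform.
#'
#' @param cohort List of [subject_volume()] on a shared grid.
#' @param threshold Relative threshold in (0, 1).
#' @return An `ssm_mask` (linear voxel indices plus grid shape).
#' @export
compute_mask <- function(cohort, threshold = 0.35) {
  if (length(cohort) < 1L)
    ssm_stop("cohort is empty", "validation_error")
  if (threshold <= 0 || threshold >= 1)
    ssm_stop("'threshold' must be in (0, 1)", "validation_error")
  d <- dim(cohort[[1]]$data)
  keep <- rep(TRUE, prod(d))
  for (v in cohort) {
    x <- as.vector(v$data)
    pos <- x > 0
    if (!any(pos))
      ssm_stop(sprintf("subject '%s' has no positive voxels",
                       v$subject_id %||% "?"), "validation_error")
    cut <- threshold * mean(x[pos])
    keep <- keep & (x >= cut)
  }
  idx <- which(keep)
  if (!length(idx))
    ssm_stop("mask is empty: no voxel survives the threshold in all subjects",
             "derivation_error")
  new_mask(idx, d, cohort[[1]]$voxel_size)
}

#' Build the subject-by-voxel log-intensity matrix
#'
#' @param cohort List of [subject_volume()].
#' @param mask An `ssm_mask`; all masked intensities must be strictly
#'   positive for every subject.
#' @return An object of class `volume_matrix`: natural-log intensities
#'   (subjects x masked voxels) with subject ids and group labels.
#' @export
build_log_matrix <- function(cohort, mask) {
  n <- length(cohort)
  V <- length(mask$indices)
  values <- matrix(NA_real_, n, V)
  for (i in seq_len(n)) {
    x <- as.vector(cohort[[i]]$data)[mask$indices]
    bad <- which(x <= 0)
    if (length(bad))
      ssm_stop(sprintf(
        "subject '%s' has nonpositive intensity at masked voxel %d",
        cohort[[i]]$subject_id %||% as.character(i),
        mask$indices[bad[1]]), "domain_error")
    values[i, ] <- log(x)
  }
  ids <- vapply(seq_len(n), function(i)
    cohort[[i]]$subject_id %||% sprintf("S%03d", i), character(1))
  grp <- vapply(seq_len(n), function(i)
    cohort[[i]]$group %||% NA_character_, character(1))
  structure(list(values = values, mask = mask, subject_ids = ids,
                 groups = grp),
            class = "volume_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Double centering of the log matrix
#'
#' Row (subject) means are removed first; the group mean profile (GMP) is
#' then the column mean of the row-centered matrix and is removed second.
#' This ordering matters for the stored GMP (which prospective scoring
#' reuses), though the final residuals are order-independent.
#'
#' @param m A `volume_matrix` or a numeric matrix (subjects x voxels).
#' @return List with `residuals` (subject residual profiles), `row_means`
#'   (per-subject global means) and `gmp` (per-voxel group mean profile).
#' @export
double_center <- function(m) {
  X <- if (inherits(m, "volume_matrix")) m$values else as.matrix(m)
  if (nrow(X) < 2L || ncol(X) < 2L)
    ssm_stop("double centering needs >= 2 subjects and >= 2 voxels",
             "validation_error")
  row_means <- rowMeans(X)
  Xc <- X - row_means
  gmp <- colMeans(Xc)
  residuals <- sweep(Xc, 2L, gmp)
  list(residuals = residuals, row_means = row_means, gmp = gmp)
}

#' Subject-space PCA of the residual profiles
#'
#' Eigendecomposition of the subjects x subjects covariance `R R^T` of the
#' double-centered matrix. Each retained component yields a unit-norm voxel
#' pattern (GIS) and subject scores that are the plain projections of the
#' residual rows onto it (no eigenvalue weighting); components with
#' eigenvalue at or below `1e-12` times the largest are dropped as numerical
#' zeros.
#'
#' @param residuals Double-centered numeric matrix (subjects x voxels).
#' @return List with `gis` (voxels x components, orthonormal columns),
#'   `scores` (subjects x components), `eigenvalues` (descending) and
#'   `variance_fraction` (eigenvalue / total variance).
#' @export
pca_decompose <- function(residuals) {
  R <- as.matrix(residuals)
  if (max(abs(R)) == 0)
    ssm_stop("residual matrix is identically zero", "degenerate_input_error")
  C <- R %*% t(R)
  e <- eigen(C, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  total <- sum(lambda)
  keep <- lambda > 1e-12 * lambda[1]
  lambda_k <- lambda[keep]
  U <- e$vectors[, keep, drop = FALSE]
  gis <- crossprod(R, U) %*% diag(1 / sqrt(lambda_k), length(lambda_k))
  scores <- U %*% diag(sqrt(lambda_k), length(lambda_k))
  list(gis = gis, scores = scores, eigenvalues = lambda_k,
       variance_fraction = lambda_k / total)
}

#' Select components by cumulative explained variance
#'
#' Returns the smallest leading prefix of components whose cumulative
#' variance fraction reaches `cutoff`; the component that crosses the
#' boundary is included (a cumulative sum exactly equal to the cutoff also
#' stops there).
#'
#' @param variance_fraction Per-component variance fractions, descending.
#' @param cutoff Fraction in (0, 1].
#' @return Integer vector of selected component indices (a prefix).
#' @export
select_by_variance <- function(variance_fraction, cutoff = 0.5) {
  if (!length(variance_fraction)) return(integer(0))
  cum <- cumsum(variance_fraction)
  k <- which(cum >= cutoff - 1e-12)[1]
  if (is.na(k)) k <- length(variance_fraction)
  seq_len(k)
}

#' Select components by two-sample t-test on subject scores
#'
#' Each candidate component is first sign-oriented so that the disease-group
#' mean score is at least the control-group mean (higher pattern expression
#' is disease-like), then tested with a pooled-variance (Student) two-tailed
#' t-test; it is retained iff `p < alpha`.
#'
#' @param scores Subjects x components score matrix.
#' @param groups Group label per subject.
#' @param disease_label,control_label Labels of the compared groups.
#' @param alpha Significance level.
#' @param candidates Component indices to test (default: all columns).
#' @return List with `selected` (indices with p < alpha), `sign`
#'   (orientation factor per candidate, +-1), and `table` (component, t, p).
#' @export
select_by_ttest <- function(scores, groups, disease_label, control_label,
                            alpha = 0.05, candidates = seq_len(ncol(scores))) {
  dis <- groups == disease_label
  ctl <- groups == control_label
  if (sum(dis) < 2L || sum(ctl) < 2L)
    ssm_stop("both compared groups need >= 2 subjects", "validation_error")
  sgn <- numeric(length(candidates))
  tval <- numeric(length(candidates))
  pval <- numeric(length(candidates))
  for (k in seq_along(candidates)) {
    j <- candidates[k]
    s <- scores[, j]
    sgn[k] <- if (mean(s[dis]) >= mean(s[ctl])) 1 else -1
    s <- s * sgn[k]
    tt <- stats::t.test(s[dis], s[ctl], var.equal = TRUE)
    tval[k] <- unname(tt$statistic)
    pval[k] <- tt$p.value
  }
  tab <- data.frame(component = candidates, sign = sgn, t = tval, p = pval)
  list(selected = candidates[pval < alpha], sign = sgn, table = tab)
}

#' Derive an SSM-PCA model from a cohort
#'
#' Chains the full derivation: intensity masking, natural-log transform,
#' double centering, subject-space PCA, variance-based pre-selection and
#' t-test-based component selection (disease vs control scores). Only
#' subjects belonging to the disease or control group enter the derivation;
#' every intermediate is recorded in the returned model.
#'
#' @param cohort List of [subject_volume()] sharing one grid; group labels
#'   must be set on the volumes (or supplied via `groups`).
#' @param disease_label,control_label Derivation group labels.
#' @param config An [ssm_config()].
#' @param groups Optional explicit group label per cohort element,
#'   overriding the labels carried by the volumes.
#' @return An object of class `ssm_model`.
#' @export
derive_ssm <- function(cohort, disease_label, control_label,
                       config = ssm_config(), groups = NULL) {
  if (is.null(groups))
    groups <- vapply(cohort, function(v) v$group %||% NA_character_,
                     character(1))
  sel <- groups %in% c(disease_label, control_label)
  if (sum(groups[sel] == disease_label) < 2L ||
      sum(groups[sel] == control_label) < 2L)
    ssm_stop("each derivation group needs >= 2 subjects", "validation_error")
  cohort <- cohort[sel]
  groups <- groups[sel]

  mask <- compute_mask(cohort, config$mask_threshold)
  lm_ <- build_log_matrix(cohort, mask)
  lm_$groups <- groups
  dc <- double_center(lm_)
  pca <- pca_decompose(dc$residuals)
  sel_var <- select_by_variance(pca$variance_fraction, config$variance_cutoff)
  tt <- select_by_ttest(pca$scores, groups, disease_label, control_label,
                        alpha = config$alpha_select, candidates = sel_var)
  # apply the disease-positive orientation to the stored patterns and scores
  gis <- pca$gis
  scores <- pca$scores
  gis[, sel_var] <- sweep(gis[, sel_var, drop = FALSE], 2L, tt$sign, `*`)
  scores[, sel_var] <- sweep(scores[, sel_var, drop = FALSE], 2L, tt$sign, `*`)

  structure(list(mask = mask,
                 gmp = dc$gmp,
                 row_means = dc$row_means,
                 residuals = dc$residuals,
                 gis = gis,
                 scores = scores,
                 eigenvalues = pca$eigenvalues,
                 variance_fraction = pca$variance_fraction,
                 subject_ids = lm_$subject_ids,
                 groups = groups,
                 disease_label = disease_label,
                 control_label = control_label,
                 selected_variance = sel_var,
                 selected_ttest = tt$selected,
                 ttest_table = tt$table,
                 config = config),
            class = "ssm_model")
}

#' @export
print.ssm_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<ssm_model> %d subjects (%s vs %s), %d mask voxels\n",
    "  %d components; variance-selected: %s; t-test-selected: %s\n"),
    length(x$subject_ids), x$disease_label, x$control_label,
    length(x$mask$indices), length(x$eigenvalues),
    paste(x$selected_variance, collapse = ","),
    if (length(x$selected_ttest)) paste(x$selected_ttest, collapse = ",")
    else "(none)"))
  invisible(x)
}

# Expand a per-mask-voxel vector to a full-grid 3-D array (zeros outside).
mask_to_array <- function(values, mask) {
  arr <- array(0, dim = mask$dim)
  arr[mask$indices] <- values
  arr
}

#' Persist an SSM model to a directory
#'
#' The mask, GMP and each component pattern are written as NIfTI maps
#' (double precision, zeros outside the mask); scalars, scores and labels go
#' into a JSON sidecar.
#'
#' @param model An `ssm_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ssm_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- model$mask
  write_volume(mask_to_array(rep(1, length(m$indices)), m),
               file.path(dir, "mask.nii"), voxel_size = m$voxel_size,
               datatype = "double")
  write_volume(mask_to_array(model$gmp, m), file.path(dir, "gmp.nii"),
               voxel_size = m$voxel_size, datatype = "double")
  for (j in seq_len(ncol(model$gis)))
    write_volume(mask_to_array(model$gis[, j], m),
                 file.path(dir, sprintf("gis_%02d.nii", j)),
                 voxel_size = m$voxel_size, datatype = "double")
  meta <- list(subject_ids = model$subject_ids,
               groups = model$groups,
               disease_label = model$disease_label,
               control_label = model$control_label,
               eigenvalues = model$eigenvalues,
               variance_fraction = model$variance_fraction,
               scores = apply(model$scores, 1L, identity, simplify = FALSE),
               row_means = model$row_means,
               selected_variance = model$selected_variance,
               selected_ttest = model$selected_ttest,
               ttest_table = model$ttest_table,
               config = unclass(model$config),
               n_components = ncol(model$gis))
  jsonlite::write_json(meta, file.path(dir, "model.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Load an SSM model saved by [save_ssm_model()]
#'
#' @param dir Directory written by [save_ssm_model()].
#' @return An `ssm_model`.
#' @export
load_ssm_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  mask_vol <- read_volume(file.path(dir, "mask.nii"))
  idx <- which(as.vector(mask_vol$data) > 0.5)
  mask <- new_mask(idx, dim(mask_vol$data), mask_vol$voxel_size)
  gmp <- as.vector(read_volume(file.path(dir, "gmp.nii"))$data)[idx]
  k <- meta$n_components
  gis <- matrix(NA_real_, length(idx), k)
  for (j in seq_len(k))
    gis[, j] <- as.vector(
      read_volume(file.path(dir, sprintf("gis_%02d.nii", j)))$data)[idx]
  scores <- if (is.list(meta$scores)) do.call(rbind, meta$scores)
            else as.matrix(meta$scores)
  structure(list(mask = mask, gmp = gmp, row_means = meta$row_means,
                 residuals = NULL, gis = gis, scores = scores,
                 eigenvalues = meta$eigenvalues,
                 variance_fraction = meta$variance_fraction,
                 subject_ids = meta$subject_ids, groups = meta$groups,
                 disease_label = meta$disease_label,
                 control_label = meta$control_label,
                 selected_variance = meta$selected_variance,
                 selected_ttest = meta$selected_ttest,
                 ttest_table = meta$ttest_table,
                 config = do.call(ssm_config, as.list(meta$config))),
            class = "ssm_model")
}
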
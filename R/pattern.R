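# Prospective pattern scoring (topographic profile rating), cross-validation
# of components on held-out cohorts, logistic-regression combination into a
# composite pattern, and Z-score normalization.

#' Topographic profile rating (TPR) of a single volume
#'
#' Prospectively scores a new subject against a stored model component or a
#' composite pattern: the volume is restricted to the stored mask,
#' log-transformed, centered by the subject's own mean over the mask, the
#' stored group mean profile (GMP) is subtracted, and the resulting subject
#' residual profile is projected onto the voxel weights. For subjects of the
#' derivation cohort this reproduces their PCA scores exactly.
#'
#' @param v A [subject_volume()] strictly positive on the pattern's mask.
#' @param object An `ssm_model` (with `component`) or a `composite_pattern`.
#' @param component Component index when `object` is an `ssm_model`.
#' @return The raw expression score (a single number).
#' @export
tpr_score <- function(v, object, component = NULL) {
  w <- pattern_weights(object, component)
  srp <- subject_residual_profile(v, object)
  sum(srp * w)
}

pattern_weights <- function(object, component = NULL) {
  if (inherits(object, "composite_pattern")) {
    object$voxel_weights
  } else if (inherits(object, "ssm_model")) {
    if (is.null(component))
      ssm_stop("scoring against an ssm_model requires 'component'",
               "validation_error")
    object$gis[, component]
  } else {
    ssm_stop("'object' must be an ssm_model or composite_pattern",
             "validation_error")
  }
}

subject_residual_profile <- function(v, object) {
  mask <- object$mask
  x <- as.vector(v$data)[mask$indices]
  bad <- which(x <= 0)
  if (length(bad))
    ssm_stop(sprintf(
      "subject '%s' has nonpositive intensity at masked voxel %d",
      v$subject_id %||% "?", mask$indices[bad[1]]), "domain_error")
  lx <- log(x)
  lx - mean(lx) - object$gmp
}

#' Cross-validate selected components on held-out cohorts
#'
#' Every disease-vs-control pairing of the derivation groups and the
#' supplied validation cohorts is tested with the pooled two-sample t-test
#' on expression scores of the candidate components (derivation subjects
#' contribute their PCA scores; validation subjects are scored
#' prospectively by TPR). A component survives iff `p < alpha` in every
#' pair. With one extra disease cohort and one extra control cohort this
#' yields the 2 x 2 = 4 crossed pairs; with no validation cohorts the
#' selection is returned unchanged (empty conjunction).
#'
#' @param model An `ssm_model` with a non-empty `selected_ttest` set.
#' @param disease_cohorts,control_cohorts Lists of validation cohorts (each
#'   a list of [subject_volume()]) playing the disease / control role.
#' @param alpha Significance level (default: the model's `alpha_select`).
#' @return List with `surviving` (component indices) and `table`
#'   (component x pair t and p values).
#' @export
cross_validate_components <- function(model, disease_cohorts = list(),
                                      control_cohorts = list(),
                                      alpha = model$config$alpha_select) {
  cand <- model$selected_ttest
  if (!length(cand))
    ssm_stop("model has no t-test-selected components", "validation_error")
  score_sets <- function(cohorts, derivation_label, role) {
    sets <- list()
    sets[[paste0("derivation_", role)]] <-
      model$scores[model$groups == derivation_label, cand, drop = FALSE]
    for (i in seq_along(cohorts)) {
      sc <- vapply(cohorts[[i]], function(v)
        vapply(cand, function(j) tpr_score(v, model, j), numeric(1)),
        numeric(length(cand)))
      nm <- names(cohorts)[i] %||% paste0("validation_", role, "_", i)
      if (is.null(names(cohorts)) || names(cohorts)[i] == "")
        nm <- paste0("validation_", role, "_", i)
      sets[[nm]] <- matrix(sc, ncol = length(cand), byrow = TRUE)
    }
    sets
  }
  dsets <- score_sets(disease_cohorts, model$disease_label, "disease")
  csets <- score_sets(control_cohorts, model$control_label, "control")
  if (length(disease_cohorts) == 0L && length(control_cohorts) == 0L)
    return(list(surviving = cand, table = NULL))

  rows <- list()
  surviving <- rep(TRUE, length(cand))
  for (dn in names(dsets)) for (cn in names(csets)) {
    d <- dsets[[dn]]; ctl <- csets[[cn]]
    if (nrow(d) < 2L || nrow(ctl) < 2L)
      ssm_stop(sprintf("pair %s vs %s has a side with < 2 subjects", dn, cn),
               "validation_error")
    for (k in seq_along(cand)) {
      tt <- stats::t.test(d[, k], ctl[, k], var.equal = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        component = cand[k], disease_set = dn, control_set = cn,
        t = unname(tt$statistic), p = tt$p.value)
      if (tt$p.value >= alpha) surviving[k] <- FALSE
    }
  }
  list(surviving = cand[surviving], table = do.call(rbind, rows))
}

#' Logistic-regression combination weights for selected components
#'
#' Fits a binary logistic regression of group membership (disease = 1) on
#' the subject scores of the surviving components; the slope coefficients
#' become the linear combination weights of the composite pattern. If the
#' classes are linearly separable (an unpenalized fit would diverge) the
#' model is refitted with a small fixed ridge penalty on the slopes
#' (`lambda = 1e-4`) and the result is flagged.
#'
#' @param scores Subjects x components score matrix.
#' @param labels Group label per subject.
#' @param disease_label Label coding the disease class; if `NULL`, `labels`
#'   must be logical (TRUE = disease).
#' @return List with `coefficients` (slopes), `intercept`, and `separated`
#'   (logical flag).
#' @export
fit_logistic_combination <- function(scores, labels, disease_label = NULL) {
  X <- as.matrix(scores)
  y <- if (is.null(disease_label)) as.logical(labels)
       else labels == disease_label
  if (length(unique(y)) < 2L)
    ssm_stop("both classes must be present in 'labels'", "validation_error")
  if (sum(y) < 2L || sum(!y) < 2L)
    ssm_stop("each class needs >= 2 subjects", "validation_error")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), as.numeric(y),
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) separated <- TRUE
  if (!separated && any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10))
    separated <- TRUE
  if (separated) {
    beta <- ridge_logistic(X, y, lambda = 1e-4)
  } else {
    beta <- fit$coefficients
  }
  list(coefficients = unname(beta[-1]), intercept = unname(beta[1]),
       separated = separated)
}

# Ridge-penalized logistic regression by Newton iteration; the penalty
# (0.5 * lambda * ||slopes||^2) excludes the intercept.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 200, tol = 1e-10) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(Xd, y - mu)) - drop(pen %*% beta)
    H <- crossprod(Xd, Xd * w) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Compose a weighted voxel pattern from model components
#'
#' The composite voxel weights are the coefficient-weighted sum of the
#' selected components' GIS maps. Z-score normalization constants are taken
#' from the derivation control group's composite raw scores (sample
#' standard deviation), so that derivation controls have Z mean 0 and sd 1
#' by construction. A voxel-wise Z map of the weights over the mask is also
#' stored for display/thresholding.
#'
#' @param model The derivation `ssm_model`.
#' @param indices Component indices entering the combination.
#' @param coefficients Weights, one per index (typically logistic slopes).
#' @param intercept Logistic intercept; stored for provenance, not used in
#'   scoring.
#' @param separated Separation flag from [fit_logistic_combination()].
#' @return An object of class `composite_pattern`.
#' @export
compose_pattern <- function(model, indices, coefficients, intercept = 0,
                            separated = FALSE) {
  if (length(indices) != length(coefficients))
    ssm_stop("'indices' and 'coefficients' must have equal length",
             "validation_error")
  if (!length(indices) || all(coefficients == 0))
    ssm_stop("coefficient vector is zero: degenerate pattern",
             "degenerate_pattern_error")
  w <- drop(model$gis[, indices, drop = FALSE] %*% coefficients)
  comp_scores <- drop(model$scores[, indices, drop = FALSE] %*% coefficients)
  ctl <- model$groups == model$control_label
  z_ref_mean <- mean(comp_scores[ctl])
  z_ref_sd <- stats::sd(comp_scores[ctl])
  if (!is.finite(z_ref_sd) || z_ref_sd <= 0)
    ssm_stop("derivation control scores have zero spread; cannot Z-normalize",
             "degenerate_pattern_error")
  structure(list(mask = model$mask,
                 gmp = model$gmp,
                 voxel_weights = w,
                 component_indices = indices,
                 coefficients = coefficients,
                 intercept = intercept,
                 separated = separated,
                 z_ref_mean = z_ref_mean,
                 z_ref_sd = z_ref_sd,
                 z_voxel = (w - mean(w)) / stats::sd(w),
                 derivation_scores = comp_scores,
                 derivation_ids = model$subject_ids,
                 derivation_groups = model$groups,
                 disease_label = model$disease_label,
                 control_label = model$control_label),
            class = "composite_pattern")
}

#' @export
print.composite_pattern <- function(x, ...) {
  cat(sprintf(paste0(
    "<composite_pattern> components %s, coefficients %s%s\n",
    "  %d mask voxels; Z ref: mean %.4g, sd %.4g (group %s)\n"),
    paste(x$component_indices, collapse = ","),
    paste(signif(x$coefficients, 4), collapse = ","),
    if (x$separated) " [separable fit: ridge]" else "",
    length(x$mask$indices), x$z_ref_mean, x$z_ref_sd, x$control_label))
  invisible(x)
}

#' Score a cohort against a composite pattern
#'
#' @param cohort List of [subject_volume()] strictly positive on the
#'   pattern's mask (an empty list yields an empty table).
#' @param pattern A `composite_pattern`.
#' @return A data frame (`score_table`) with one row per subject:
#'   `subject_id`, `group`, `raw_score`, and
#'   `z_score = (raw - z_ref_mean) / z_ref_sd`.
#' @export
score_cohort <- function(cohort, pattern) {
  n <- length(cohort)
  raw <- numeric(n)
  ids <- character(n)
  grp <- character(n)
  for (i in seq_len(n)) {
    raw[i] <- tpr_score(cohort[[i]], pattern)
    ids[i] <- cohort[[i]]$subject_id %||% sprintf("S%03d", i)
    grp[i] <- cohort[[i]]$group %||% NA_character_
  }
  structure(data.frame(subject_id = ids, group = grp, raw_score = raw,
                       z_score = (raw - pattern$z_ref_mean) / pattern$z_ref_sd),
            class = c("score_table", "data.frame"))
}

#' Persist a composite pattern to a directory
#'
#' Voxel weights, their Z map, the mask and the GMP are written as NIfTI
#' maps (double precision); coefficients, Z constants and provenance go
#' into a JSON sidecar.
#'
#' @param pattern A `composite_pattern`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_pattern <- function(pattern, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- pattern$mask
  write_volume(mask_to_array(pattern$voxel_weights, m),
               file.path(dir, "voxel_weights.nii"),
               voxel_size = m$voxel_size, datatype = "double")
  write_volume(mask_to_array(pattern$z_voxel, m),
               file.path(dir, "z_voxel.nii"),
               voxel_size = m$voxel_size, datatype = "double")
  write_volume(mask_to_array(rep(1, length(m$indices)), m),
               file.path(dir, "mask.nii"),
               voxel_size = m$voxel_size, datatype = "double")
  write_volume(mask_to_array(pattern$gmp, m), file.path(dir, "gmp.nii"),
               voxel_size = m$voxel_size, datatype = "double")
  meta <- list(component_indices = pattern$component_indices,
               coefficients = pattern$coefficients,
               intercept = pattern$intercept,
               separated = pattern$separated,
               z_ref_mean = pattern$z_ref_mean,
               z_ref_sd = pattern$z_ref_sd,
               derivation_scores = pattern$derivation_scores,
               derivation_ids = pattern$derivation_ids,
               derivation_groups = pattern$derivation_groups,
               disease_label = pattern$disease_label,
               control_label = pattern$control_label)
  jsonlite::write_json(meta, file.path(dir, "pattern.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Load a composite pattern saved by [save_pattern()]
#'
#' @param dir Directory written by [save_pattern()].
#' @return A `composite_pattern`.
#' @export
load_pattern <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "pattern.json"),
                              simplifyVector = TRUE)
  mask_vol <- read_volume(file.path(dir, "mask.nii"))
  idx <- which(as.vector(mask_vol$data) > 0.5)
  mask <- new_mask(idx, dim(mask_vol$data), mask_vol$voxel_size)
  grab <- function(f) as.vector(read_volume(file.path(dir, f))$data)[idx]
  structure(list(mask = mask,
                 gmp = grab("gmp.nii"),
                 voxel_weights = grab("voxel_weights.nii"),
                 component_indices = meta$component_indices,
                 coefficients = meta$coefficients,
                 intercept = meta$intercept,
                 separated = meta$separated,
                 z_ref_mean = meta$z_ref_mean,
                 z_ref_sd = meta$z_ref_sd,
                 z_voxel = grab("z_voxel.nii"),
                 derivation_scores = meta$derivation_scores,
                 derivation_ids = meta$derivation_ids,
                 derivation_groups = meta$derivation_groups,
                 disease_label = meta$disease_label,
                 control_label = meta$control_label),
            class = "composite_pattern")
}
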
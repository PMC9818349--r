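test_that("mask thresholds against each subject's own mean positive activity", {
  # one subject, voxels [1.0, 0.1, 0.9, 1.0, 0.05]: mean of positives 0.61,
  # cut 0.35 * 0.61 = 0.2135 -> voxels 1, 3, 4 survive
  arr <- array(0, c(5, 1, 1))
  arr[, 1, 1] <- c(1.0, 0.1, 0.9, 1.0, 0.05)
  v <- make_vol(arr)
  mask <- compute_mask(list(v), 0.35)
  expect_identical(mask$indices, c(1L, 3L, 4L))

  # intersection is idempotent and invariant to per-subject global scale
  expect_identical(compute_mask(list(v, v), 0.35)$indices, mask$indices)
  v10 <- make_vol(arr * 10)
  expect_identical(compute_mask(list(v, v10), 0.35)$indices, mask$indices)

  # disjoint high-activity regions -> empty intersection
  a1 <- array(0.001, c(10, 1, 1)); a1[1:5] <- 1
  a2 <- array(0.001, c(10, 1, 1)); a2[6:10] <- 1
  expect_error(compute_mask(list(make_vol(a1), make_vol(a2)), 0.9),
               class = "ssmpca_derivation_error")
})

test_that("log matrix is the natural log of masked intensities", {
  arr <- array(1, c(4, 1, 1))
  arr[2] <- exp(1)
  v <- make_vol(arr, id = "s1")
  mask <- compute_mask(list(v), 0.35)
  lm_ <- build_log_matrix(list(v), mask)
  expect_equal(lm_$values[1, ], c(0, 1, 0, 0)[seq_along(mask$indices)])

  ones <- make_vol(array(1, c(4, 1, 1)))
  expect_true(all(build_log_matrix(list(ones), mask)$values == 0))

  # a nonpositive masked value is a domain error naming subject and voxel
  bad <- array(1, c(4, 1, 1)); bad[3] <- 0
  mask_all <- ssmpca:::new_mask(1:4, c(4L, 1L, 1L), c(1, 1, 1))
  expect_error(build_log_matrix(list(make_vol(bad, id = "sX")), mask_all),
               "sX", class = "ssmpca_domain_error")
})

test_that("double centering removes row means first, then the GMP", {
  # additively separable matrix: zero interaction residual
  dc <- double_center(matrix(c(1, 4, 2, 5, 3, 6), 2))
  expect_equal(max(abs(dc$residuals)), 0)
  expect_equal(dc$row_means, c(2, 5))
  expect_equal(dc$gmp, c(-1, 0, 1))

  dc2 <- double_center(matrix(c(0, 2, 2, 0), 2))
  expect_equal(dc2$residuals, matrix(c(-1, 1, 1, -1), 2))
  expect_equal(dc2$gmp, c(0, 0))

  # adding a constant to one row is absorbed by that row's mean
  X <- matrix(rnorm(40), 4)
  Xc <- X; Xc[2, ] <- Xc[2, ] + 7
  expect_equal(double_center(X)$residuals, double_center(Xc)$residuals,
               tolerance = 1e-12)
})

test_that("residual row and column means vanish on random matrices", {
  set.seed(21)
  for (rep in 1:5) {
    R <- double_center(matrix(rnorm(20 * 500, sd = 3), 20))$residuals
    expect_lt(max(abs(rowMeans(R))), 1e-10)
    expect_lt(max(abs(colMeans(R))), 1e-10)
  }
})

test_that("PCA solves the 2x2 case exactly and reconstructs residuals", {
  R <- matrix(c(-1, 1, 1, -1), 2)
  p <- pca_decompose(R)
  expect_length(p$eigenvalues, 1)
  expect_equal(p$variance_fraction, 1)
  expect_equal(abs(p$gis[, 1]), c(1, 1) / sqrt(2))
  expect_equal(abs(p$scores[, 1]), c(sqrt(2), sqrt(2)))
  expect_equal(p$scores[, 1], drop(R %*% p$gis[, 1]), tolerance = 1e-12)

  # rank-1 residual: one component, pattern parallel to the profile
  a <- c(-2, 1, 1); prof <- c(1, -1, 0.5, -0.5, 0)
  R1 <- outer(a, prof)
  p1 <- pca_decompose(R1)
  expect_length(p1$eigenvalues, 1)
  expect_equal(abs(cor(p1$gis[, 1], prof)), 1, tolerance = 1e-12)

  # completeness: scores %*% t(gis) reproduces the residuals
  set.seed(9)
  R2 <- double_center(matrix(rnorm(8 * 30), 8))$residuals
  p2 <- pca_decompose(R2)
  expect_lt(max(abs(p2$scores %*% t(p2$gis) - R2)), 1e-8)

  expect_error(pca_decompose(matrix(0, 3, 5)),
               class = "ssmpca_degenerate_input_error")
})

test_that("GIS columns are orthonormal and score columns orthogonal", {
  set.seed(10)
  R <- double_center(matrix(rnorm(12 * 200), 12))$residuals
  p <- pca_decompose(R)
  G <- crossprod(p$gis)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  S <- crossprod(p$scores)
  expect_lt(max(abs(S - diag(p$eigenvalues))) / p$eigenvalues[1], 1e-8)
})

test_that("subject-space eigenvalues equal the voxel-space spectrum", {
  set.seed(12)
  R <- double_center(matrix(rnorm(6 * 50), 6))$residuals
  lambda_subject <- pca_decompose(R)$eigenvalues
  lambda_voxel <- eigen(crossprod(R), symmetric = TRUE, only.values = TRUE)$values
  lambda_voxel <- lambda_voxel[lambda_voxel > 1e-12 * lambda_voxel[1]]
  expect_equal(lambda_subject, lambda_voxel, tolerance = 1e-8)
})

test_that("variance selection takes the smallest boundary-crossing prefix", {
  expect_identical(select_by_variance(c(0.5, 0.3, 0.2), 0.5), 1L)
  expect_identical(select_by_variance(c(0.4, 0.2, 0.2, 0.2), 0.5), 1:2)
  expect_identical(select_by_variance(c(0.4, 0.2, 0.2, 0.2), 1.0), 1:4)
})

test_that("t-test selection uses the pooled Student test with disease-positive orientation", {
  scores <- cbind(c(1, 2, 3, 4, 5, 6))
  groups <- c("D", "D", "D", "C", "C", "C")
  sel <- select_by_ttest(scores, groups, "D", "C", alpha = 0.05)
  # oracle: pooled two-sample t on the oriented scores
  oracle <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(sel$table$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(sel$table$p, oracle$p.value, tolerance = 1e-12)
  expect_identical(sel$selected, 1L)
  expect_identical(sel$sign, -1)  # disease mean was below control: flipped

  # identical distributions: t = 0, not retained
  s0 <- cbind(c(1, 2, 3, 1, 2, 3))
  sel0 <- select_by_ttest(s0, groups, "D", "C")
  expect_equal(sel0$table$t, 0)
  expect_length(sel0$selected, 0)

  expect_error(select_by_ttest(scores, c("D", rep("C", 5)), "D", "C"),
               class = "ssmpca_validation_error")
})

test_that("derivation recovers an embedded pattern and its loadings", {
  sd_ <- small_derivation(seed = 31)
  m <- sd_$model; co <- sd_$cohort
  expect_gt(length(m$selected_ttest), 0)
  j <- m$selected_ttest[1]
  pos <- match(m$mask$indices, co$mask$indices)
  expect_gt(abs(cor(m$gis[, j], co$pattern[pos])), 0.9)
  expect_gt(cor(m$scores[, j], co$truth$loading), 0.9)
  # oriented: disease mean score above control mean score
  expect_gte(mean(m$scores[m$groups == "PD", j]) -
             mean(m$scores[m$groups == "C", j]), 0)
})

test_that("per-subject global scaling changes nothing after centering", {
  sd_ <- small_derivation(seed = 32)
  co <- sd_$cohort
  m1 <- sd_$model
  vols <- co$volumes
  vols[[1]]$data <- vols[[1]]$data * 3
  m2 <- derive_ssm(vols, "PD", "C")
  expect_identical(m1$mask$indices, m2$mask$indices)
  expect_equal(m1$gmp, m2$gmp, tolerance = 1e-8)
  expect_lt(max(abs(m1$residuals - m2$residuals)), 1e-8)
  expect_lt(max(abs(abs(m1$scores) - abs(m2$scores))), 1e-8)
})

test_that("derivation filters to the two named groups and validates sizes", {
  co <- simulate_cohort(synth_config(grid = 10L, semi_axes = c(3, 4, 3),
                                     group_sizes = c(C = 3L, PD = 3L, X = 2L),
                                     loading_mean = c(PD = 2),
                                     seed = 5))
  m <- derive_ssm(co$volumes, "PD", "C")
  expect_length(m$subject_ids, 6)
  expect_false(any(m$groups == "X"))
  expect_error(derive_ssm(co$volumes, "PD", "missing"),
               class = "ssmpca_validation_error")
})

test_that("models persist to NIfTI + JSON and load back", {
  sd_ <- small_derivation(seed = 33)
  d <- tempfile("model")
  save_ssm_model(sd_$model, d)
  m2 <- load_ssm_model(d)
  expect_identical(m2$mask$indices, sd_$model$mask$indices)
  expect_equal(m2$gmp, sd_$model$gmp, tolerance = 1e-10)
  expect_equal(m2$gis, sd_$model$gis, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(m2$scores, sd_$model$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(m2$selected_ttest, sd_$model$selected_ttest)
  expect_equal(m2$config$mask_threshold, sd_$model$config$mask_threshold)
})
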
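# Shared fixtures: tiny in-memory volumes and small synthetic cohorts.

make_vol <- function(arr, voxel_size = c(1, 1, 1), id = NULL, group = NULL) {
  subject_volume(arr, voxel_size = voxel_size, subject_id = id, group = group)
}

# A positive random volume on a small grid.
random_vol <- function(dim = c(8, 8, 8), id = NULL, group = NULL,
                       voxel_size = c(1, 1, 1)) {
  make_vol(array(exp(rnorm(prod(dim), sd = 0.3)) , dim),
           voxel_size = voxel_size, id = id, group = group)
}

# Small two-group synthetic configuration used across module tests.
small_synth <- function(seed, nC = 8L, nPD = 8L, dis_mean = 2.5, ...) {
  synth_config(grid = 14L, semi_axes = c(5, 6, 5),
               group_sizes = c(C = nC, PD = nPD),
               loading_mean = c(C = 0, PD = dis_mean),
               seed = seed, ...)
}

# Derive a model from a small synthetic cohort; returns cohort and model.
small_derivation <- function(seed = 7, ...) {
  co <- simulate_cohort(small_synth(seed, ...))
  list(cohort = co, model = derive_ssm(co$volumes, "PD", "C"))
}

# Write a cohort of subject_volumes to tempdir and return a manifest df.
write_temp_manifest <- function(vols, dir = withr_like_tempdir()) {
  paths <- character(length(vols))
  for (i in seq_along(vols)) {
    paths[i] <- file.path(dir, paste0(vols[[i]]$subject_id, ".nii"))
    write_volume(vols[[i]], paths[i])
  }
  data.frame(subject_id = vapply(vols, `[[`, "", "subject_id"),
             group = vapply(vols, `[[`, "", "group"),
             path = paths)
}

withr_like_tempdir <- function() {
  d <- tempfile("cohort")
  dir.create(d)
  d
}
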
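# Independent reference implementations (deliberately naive: explicit loops,
# no shared code with the package) plus small fixture builders.

# triple-loop reference for region_metrics on tiny grids
naive_region_metrics <- function(values, spacing_mm, voi_logical, meta,
                                 fraction = 0.42) {
  d <- dim(values)
  vmax <- -Inf
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (voi_logical[i, j, k] && values[i, j, k] > vmax)
      vmax <- values[i, j, k]
  thr <- fraction * vmax
  s <- 0; n <- 0; smax <- -Inf; n_anat <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!voi_logical[i, j, k]) next
    n_anat <- n_anat + 1
    v <- values[i, j, k]
    if (v >= thr) {
      n <- n + 1
      s <- s + v
      if (v > smax) smax <- v
    }
  }
  dt_h <- as.double(difftime(meta$acquisition_time, meta$injection_time,
                             units = "hours"))
  f <- 2^(dt_h / meta$half_life_h) *
    meta$body_weight_kg / meta$injected_activity_MBq
  vox_ml <- spacing_mm[1] * spacing_mm[2] * spacing_mm[3] / 1000
  mean_suv <- (s / n) * f
  list(dpd_mean = mean_suv, dpd_max = smax * f, v42_ml = n * vox_ml,
       dpd_load = mean_suv * n * vox_ml,
       n_voxels_anatomical = n_anat, n_voxels_thresholded = n)
}

# loop-based isocontour reference
naive_isocontour <- function(values, voi_idx, fraction) {
  vmax <- -Inf
  for (v in voi_idx) if (values[v] > vmax) vmax <- values[v]
  keep <- integer(0)
  for (v in voi_idx) if (values[v] >= fraction * vmax) keep <- c(keep, v)
  keep
}

# standard test meta: 740 MBq, 3 h uptake, 74.6 kg
test_meta <- function() {
  acquisition_meta(740, "2020-01-01 09:00:00", "2020-01-01 12:00:00", 74.6)
}

# meta with zero uptake time and dose == weight: SUV factor is exactly 1
unit_meta <- function() {
  acquisition_meta(70, "2020-01-01 09:00:00", "2020-01-01 09:00:00", 70)
}

# small uniform volume
uniform_volume <- function(value = 1, n = 4, spacing = rep(2, 3)) {
  voxel_volume(array(value, dim = rep(n, 3)), spacing_mm = spacing)
}

# small fast phantom spec, noiseless and unblurred unless overridden
fast_phantom_spec <- function(...) {
  phantom_spec(grid_dim = c(48L, 48L, 48L), psf_fwhm_mm = 0, count_scale = 0,
               ...)
}
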
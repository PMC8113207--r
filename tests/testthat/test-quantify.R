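# quantify: decay correction, SUV, isocontour segmentation, metrics,
# apical-sparing ratios.

test_that("decay correction follows the closed form", {
  m0 <- unit_meta()                       # dt = 0
  expect_identical(decay_correct(12.5, m0), 12.5)
  m_half <- acquisition_meta(740, "2020-01-01 00:00:00",
                             "2020-01-01 06:00:24.12", 74.6)  # dt = T1/2
  expect_equal(decay_correct(1, m_half), 2, tolerance = 1e-6)
  # value 10, dt 3 h, T1/2 6.0067 h -> 10 * 2^(3/6.0067) = 14.1368
  expect_equal(decay_correct(10, test_meta()), 10 * 2^(3 / 6.0067))
  expect_equal(decay_correct(10, test_meta()), 14.1368, tolerance = 1e-4)
})

test_that("SUV divides by injected dose per kilogram", {
  expect_equal(suv(123.4, unit_meta()), 123.4)  # dose == weight
  expect_equal(suv(500, test_meta()), 500 * 74.6 / 740)
  expect_equal(suv(500, test_meta()), 50.405, tolerance = 1e-3)
  expect_equal(suv(0, test_meta()), 0)
})

test_that("isocontour keeps voxels at or above the fractional VOI maximum", {
  a <- array(0, dim = c(4, 1, 1))
  a[, 1, 1] <- c(100, 50, 42, 41)
  v <- voxel_volume(a, rep(1, 3))
  voi <- 1:4
  expect_identical(segment_isocontour(v, voi, 0.42), 1:3)
  # uniform VOI retained entirely; single voxel VOI is itself
  u <- uniform_volume(5, 3)
  expect_identical(segment_isocontour(u, 1:27, 0.42), 1:27)
  expect_identical(segment_isocontour(u, 14L, 0.42), 14L)
  # degenerate all-zero VOI: full VOI with a warning
  z <- voxel_volume(array(0, dim = rep(3, 3)), rep(1, 3))
  expect_warning(res <- segment_isocontour(z, 1:27, 0.42), "degenerate")
  expect_identical(res, 1:27)
  expect_error(segment_isocontour(v, integer(0)), "empty")
  expect_error(segment_isocontour(v, voi, 0), "fraction")
  expect_error(segment_isocontour(v, voi, 1.2), "fraction")
})

test_that("isocontour equals brute-force enumeration on random VOIs", {
  set.seed(101)
  for (i in 1:25) {
    a <- array(round(runif(5^3, 0, 100)), dim = rep(5, 3))
    v <- voxel_volume(a, rep(1, 3))
    voi <- sort(sample(5^3, sample(5:60, 1)))
    frac <- sample(c(0.2, 0.42, 0.6, 0.8, 1.0), 1)
    if (max(a[voi]) == 0) next
    expect_identical(segment_isocontour(v, voi, frac),
                     naive_isocontour(a, voi, frac))
  }
})

test_that("region metrics reproduce the hand-worked example", {
  # thresholded SUVs {100, 60, 50}, voxel 0.5 ml
  a <- array(0, dim = c(4, 1, 1))
  a[, 1, 1] <- c(100, 60, 50, 10)  # 10 falls below 42
  v <- voxel_volume(a, spacing_mm = c(10, 10, 5))  # 0.5 ml voxels
  m <- region_metrics(v, 1:4, unit_meta(), region = "X")
  expect_equal(m$dpd_mean, 70)
  expect_equal(m$dpd_max, 100)
  expect_equal(m$v42_ml, 1.5)
  expect_equal(m$dpd_load, 105)
  expect_equal(m$n_voxels_anatomical, 4)
  expect_equal(m$n_voxels_thresholded, 3)
  expect_identical(m$region, "X")
})

test_that("region metrics match the naive triple-loop oracle exactly", {
  set.seed(202)
  for (i in 1:10) {
    d <- sample(3:6, 3, replace = TRUE)
    a <- array(round(runif(prod(d), 0, 80), 1), dim = d)
    voi_mask <- array(runif(prod(d)) < 0.5, dim = d)
    if (!any(voi_mask) || max(a[voi_mask]) == 0) next
    sp <- runif(3, 1, 5)
    v <- voxel_volume(a, sp)
    frac <- sample(c(0.3, 0.42, 0.7), 1)
    got <- region_metrics(v, which(voi_mask), test_meta(), frac)
    ref <- naive_region_metrics(a, sp, voi_mask, test_meta(), frac)
    for (f in names(ref)) expect_equal(got[[f]], ref[[f]], tolerance = 1e-12)
  }
})

test_that("fraction = 1 keeps only the argmax voxels", {
  a <- array(c(5, 9, 9, 1), dim = c(4, 1, 1))
  v <- voxel_volume(a, rep(1, 3))
  m <- region_metrics(v, 1:4, unit_meta(), fraction = 1)
  expect_equal(m$n_voxels_thresholded, 2)
  expect_equal(m$dpd_mean, m$dpd_max)
})

test_that("metric invariants hold over random volumes", {
  set.seed(303)
  for (i in 1:10) {
    a <- array(runif(6^3, 0, 50), dim = rep(6, 3))
    v <- voxel_volume(a, runif(3, 1, 5))
    voi <- sort(sample(6^3, 80))
    meta <- test_meta()

    m <- region_metrics(v, voi, meta)
    # invariant chain: max >= mean >= fraction * max; load identity
    expect_gte(m$dpd_max, m$dpd_mean)
    expect_gte(m$dpd_mean, 0.42 * m$dpd_max - 1e-12)
    expect_equal(m$dpd_load, m$dpd_mean * m$v42_ml)
    expect_lte(m$n_voxels_thresholded, m$n_voxels_anatomical)
    expect_equal(m$v42_ml, m$n_voxels_thresholded * voxel_size_ml(v))

    # scale equivariance: volume * c scales intensities, not volumes
    cscale <- 3.7
    v2 <- voxel_volume(a * cscale, v$spacing_mm)
    m2 <- region_metrics(v2, voi, meta)
    expect_equal(m2$dpd_mean, cscale * m$dpd_mean)
    expect_equal(m2$dpd_max, cscale * m$dpd_max)
    expect_equal(m2$dpd_load, cscale * m$dpd_load)
    expect_equal(m2$v42_ml, m$v42_ml)

    # threshold monotonicity across fractions
    prev_v42 <- Inf; prev_mean <- -Inf
    for (f in c(0.2, 0.42, 0.6, 0.8, 1.0)) {
      mf <- region_metrics(v, voi, meta, fraction = f)
      expect_lte(mf$v42_ml, prev_v42 + 1e-12)
      expect_gte(mf$dpd_mean, prev_mean - 1e-12)
      expect_equal(mf$dpd_max, m$dpd_max)  # max invariant in fraction
      prev_v42 <- mf$v42_ml; prev_mean <- mf$dpd_mean
    }
  }
})

test_that("merged-VOI maximum equals the maximum over member maxima", {
  ph <- make_phantom(fast_phantom_spec())
  m <- quantify_regions(ph$volume, ph$masks, ph$meta)
  lv_members <- m[m$region %in% c("LV_LATERAL", "IVS", "APEX"), ]
  expect_equal(m$dpd_max[m$region == "LV"], max(lv_members$dpd_max))
  expect_equal(m$dpd_max[m$region == "VENTRICLES"],
               max(m$dpd_max[m$region %in%
                               c("LV", "RV_FREE_WALL")]))
})

test_that("uptake apical-sparing ratio matches the cohort-mean example", {
  res <- apical_sparing_dpd(36.5, 54.6, 43.4)
  expect_equal(res$ratio, 36.5 / 49.0)
  expect_equal(res$ratio, 0.7449, tolerance = 1e-4)
  expect_true(is.na(res$sparing_flag))  # no cut-off for the uptake variant
  expect_equal(apical_sparing_dpd(10, 10, 10)$ratio, 1)
  expect_equal(apical_sparing_dpd(0, 10, 10)$ratio, 0)
  expect_error(apical_sparing_dpd(1, -2, -2), "positive")
})

test_that("echo apical-sparing ratio uses signed strains and a strict cut-off", {
  r1 <- apical_sparing_echo(-24, -10, -14)
  expect_equal(r1$ratio, 1)
  expect_false(r1$sparing_flag)  # strictly greater than 1
  r2 <- apical_sparing_echo(-30, -10, -10)
  expect_equal(r2$ratio, 1.5)
  expect_true(r2$sparing_flag)
  r3 <- apical_sparing_echo(-15, -15, -15)
  expect_equal(r3$ratio, 0.5)
  expect_false(r3$sparing_flag)
  expect_error(apical_sparing_echo(-10, 5, -5), "non-zero")
})

test_that("sternum exclusion is wired into quantify_regions", {
  u <- c(LV_LATERAL = 50, IVS = 50, APEX = 50, RV_FREE_WALL = 30,
         STERNUM = 150, BLOOD_POOL = 4, BACKGROUND = 1)
  ph <- make_phantom(fast_phantom_spec(uptake = u))
  m10 <- quantify_regions(ph$volume, ph$masks, ph$meta,
                          sternum_margin_mm = 10)
  m0 <- quantify_regions(ph$volume, ph$masks, ph$meta,
                         sternum_margin_mm = 0)
  m25 <- quantify_regions(ph$volume, ph$masks, ph$meta,
                          sternum_margin_mm = 25)
  n_rv <- function(m) m$n_voxels_anatomical[m$region == "RV_FREE_WALL"]
  expect_lte(n_rv(m10), n_rv(m0))
  expect_lt(n_rv(m25), n_rv(m0))  # 25 mm reaches across the chest-wall gap
  expect_lte(m25$n_voxels_anatomical[m25$region == "VENTRICLES"],
             m0$n_voxels_anatomical[m0$region == "VENTRICLES"])
})
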
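# Measurement core: decay correction, SUV, 42 % isocontour segmentation,
# DPD_mean / DPD_max / V_42% / DPD_load, apical-sparing ratios.

#' Decay-correct an uptake value to injection time
#'
#' Multiplies by `2^(dt / half_life)` where `dt` is the injection-to-
#' acquisition interval; the reference time is the injection (the standard
#' SUV convention).
#'
#' @param value numeric, raw uptake (any consistent concentration unit).
#' @param meta an [acquisition_meta()].
#' @return decay-corrected value(s), same units.
#' @examples
#' m <- acquisition_meta(740, "2020-01-01 09:00", "2020-01-01 12:00", 74.6)
#' decay_correct(10, m)  # 10 * 2^(3 / 6.0067)
#' @export
decay_correct <- function(value, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  value * 2^(uptake_time_h(meta) / meta$half_life_h)
}

#' Standardized uptake value
#'
#' Divides a decay-corrected tissue concentration by the injected dose per
#' kilogram body weight. No camera/well-counter cross-calibration factor is
#' applied, so the result is in consistent but arbitrary units (nominally
#' g/ml up to an unknown scale factor).
#'
#' @param concentration decay-corrected concentration (uptake units per ml).
#' @param meta an [acquisition_meta()].
#' @return SUV value(s).
#' @examples
#' m <- acquisition_meta(740, "2020-01-01 09:00", "2020-01-01 09:00", 74.6)
#' suv(500, m)  # 500 * 74.6 / 740
#' @export
suv <- function(concentration, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  concentration / (meta$injected_activity_MBq / meta$body_weight_kg)
}

#' Isocontour threshold segmentation within a VOI
#'
#' Keeps the voxels of an anatomical VOI whose value is at or above
#' `fraction` times the VOI's own maximum (default 42 %). The comparison is
#' inclusive (`>=`), so the maximum voxel is always retained and the output
#' is never empty. If the VOI is all zeros the threshold is degenerate and
#' the full VOI is returned with a warning.
#'
#' @param volume a [voxel_volume()].
#' @param voi integer vector of linear voxel indices (non-empty).
#' @param fraction scalar in (0, 1], default 0.42.
#' @return integer vector of linear indices, a subset of `voi`.
#' @export
segment_isocontour <- function(volume, voi, fraction = 0.42) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (length(voi) == 0L) stop("VOI is empty")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  vals <- volume$values[voi]
  vmax <- max(vals)
  if (vmax == 0) {
    warning("VOI maximum is 0; threshold degenerate, returning full VOI")
    return(voi)
  }
  voi[vals >= fraction * vmax]
}

#' Per-VOI uptake metrics
#'
#' The measurement pipeline for one VOI: threshold the anatomical VOI at
#' `fraction` of its maximum, then report over the thresholded set the mean
#' and maximum SUV (decay-corrected, dose-per-kg normalised), the thresholded
#' volume in ml, and the compound burden score
#' `dpd_load = dpd_mean * v42_ml`. Decay correction and SUV normalisation are
#' scalar multiplications, so they commute with each other and with the
#' thresholding (which depends only on value ratios).
#'
#' @param volume a [voxel_volume()] of raw (not yet corrected) uptake.
#' @param voi integer vector of linear voxel indices.
#' @param meta an [acquisition_meta()].
#' @param fraction isocontour fraction, default 0.42.
#' @param region label carried into the output, default `""`.
#' @return one-row `data.frame` with columns `region`, `dpd_mean`, `dpd_max`,
#'   `v42_ml`, `dpd_load`, `n_voxels_anatomical`, `n_voxels_thresholded`.
#' @export
region_metrics <- function(volume, voi, meta, fraction = 0.42, region = "") {
  stopifnot(inherits(volume, "voxel_volume"))
  if (length(voi) == 0L) stop("VOI is empty")
  seg <- segment_isocontour(volume, voi, fraction)
  suv_vals <- suv(decay_correct(volume$values[seg], meta), meta)
  v42_ml <- length(seg) * voxel_size_ml(volume)
  dpd_mean <- mean(suv_vals)
  data.frame(
    region = region,
    dpd_mean = dpd_mean,
    dpd_max = max(suv_vals),
    v42_ml = v42_ml,
    dpd_load = dpd_mean * v42_ml,
    n_voxels_anatomical = length(voi),
    n_voxels_thresholded = length(seg),
    stringsAsFactors = FALSE
  )
}

#' Quantify all standard VOIs of a volume/mask pair
#'
#' Runs [region_metrics()] for the four base regions and the merged `LV` and
#' `VENTRICLES` VOIs. The RV free wall is first cleaned of sternum
#' spill-over by [exclude_sternum_spillover()] (when a sternum region is
#' present); the cleaned RV set is also the one entering `VENTRICLES`.
#' Merged VOIs are thresholded as a whole, so a single merged maximum governs
#' their segmentation.
#'
#' @param volume a [voxel_volume()].
#' @param masks a [region_mask_set()] congruent with `volume`.
#' @param meta an [acquisition_meta()].
#' @param fraction isocontour fraction, default 0.42.
#' @param sternum_margin_mm exclusion margin around the sternum, mm;
#'   default 10.
#' @return `data.frame`, one row per region in the order
#'   `LV_LATERAL, IVS, APEX, RV_FREE_WALL, LV, VENTRICLES`.
#' @export
quantify_regions <- function(volume, masks, meta, fraction = 0.42,
                             sternum_margin_mm = 10) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(masks, "region_mask_set"))
  if (!identical(dim(volume$values), dim(masks$labels)))
    stop("volume and mask grids are not congruent")
  gd <- dim(volume$values)

  rv <- region_voxels(masks, "RV_FREE_WALL")
  if ("STERNUM" %in% names(masks$label_map)) {
    rv <- exclude_sternum_spillover(rv, region_voxels(masks, "STERNUM"),
                                    gd, masks$spacing_mm, sternum_margin_mm)
    if (length(rv) == 0L)
      stop("sternum exclusion removed the entire RV free wall")
  }
  lv <- merge_regions(masks, "LV")
  vois <- list(
    LV_LATERAL   = region_voxels(masks, "LV_LATERAL"),
    IVS          = region_voxels(masks, "IVS"),
    APEX         = region_voxels(masks, "APEX"),
    RV_FREE_WALL = rv,
    LV           = lv,
    VENTRICLES   = sort(unique(c(lv, rv)))
  )
  do.call(rbind, lapply(names(vois), function(nm)
    region_metrics(volume, vois[[nm]], meta, fraction, region = nm)))
}

#' Apical-sparing ratio from uptake
#'
#' `apex / ((IVS + lateral) / 2)` on regional mean (or max) SUVs. Lower
#' apical uptake relative to the septum and lateral wall mirrors the
#' echocardiographic apical-sparing pattern. No cut-off flag is defined for
#' the uptake variant.
#'
#' @param apex_mean,ivs_mean,lateral_mean regional SUVs; the denominator
#'   average must be positive.
#' @return list with `ratio` (dimensionless) and `sparing_flag` (`NA`).
#' @examples
#' apical_sparing_dpd(36.5, 54.6, 43.4)$ratio  # ~0.745
#' @export
apical_sparing_dpd <- function(apex_mean, ivs_mean, lateral_mean) {
  denom <- (ivs_mean + lateral_mean) / 2
  if (!is.finite(denom) || denom <= 0)
    stop("denominator (mean of IVS and lateral uptake) must be positive")
  list(ratio = apex_mean / denom, sparing_flag = NA)
}

#' Apical-sparing ratio from longitudinal strain
#'
#' `apical / (basal + mid)` on signed average longitudinal strains (strain is
#' negative, so negative over negative gives a positive ratio). A subject is
#' flagged as showing relative apical sparing when the ratio strictly
#' exceeds 1.
#'
#' @param apical_avg,basal_avg,mid_avg signed average longitudinal strains
#'   (percent, typically negative).
#' @return list with `ratio` and logical `sparing_flag` (`ratio > 1`).
#' @examples
#' apical_sparing_echo(-30, -10, -10)  # ratio 1.5, flag TRUE
#' @export
apical_sparing_echo <- function(apical_avg, basal_avg, mid_avg) {
  denom <- basal_avg + mid_avg
  if (!is.finite(denom) || denom == 0)
    stop("denominator (basal + mid strain) must be non-zero")
  ratio <- apical_avg / denom
  list(ratio = ratio, sparing_flag = ratio > 1)
}
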
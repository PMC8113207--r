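# Merged VOIs and the sternum spill-over exclusion.

#' Merged region definitions
#'
#' `LV` is the union of the lateral wall, septum and apex; `VENTRICLES` adds
#' the RV free wall. These are the two larger VOIs used against global strain
#' and circulating biomarkers, where a single merged maximum governs the
#' isocontour threshold.
#' @export
MERGED_REGIONS <- list(
  LV         = c("LV_LATERAL", "IVS", "APEX"),
  VENTRICLES = c("LV_LATERAL", "IVS", "APEX", "RV_FREE_WALL")
)

#' Merge base regions into a composite VOI
#'
#' Base labels are disjoint (one label per voxel), so the merged voxel count
#' is the sum of the member counts.
#'
#' @param masks a [region_mask_set()].
#' @param target `"LV"` or `"VENTRICLES"`, or a character vector of base
#'   region names to union.
#' @return integer vector of linear voxel indices (sorted, unique).
#' @export
merge_regions <- function(masks, target) {
  members <- if (length(target) == 1L && target %in% names(MERGED_REGIONS))
    MERGED_REGIONS[[target]] else as.character(target)
  idx <- lapply(members, function(nm) {
    vox <- region_voxels(masks, nm)
    if (length(vox) == 0L)
      stop("member region '", nm, "' is empty; cannot merge")
    vox
  })
  sort(unique(unlist(idx)))
}

#' Remove RV free-wall voxels within a margin of the sternum
#'
#' Spill-over from the hot sternum contaminates the adjacent RV free wall.
#' The sternum mask is dilated by `margin_mm` (exact Euclidean ball, in
#' physical millimetres) and any RV voxel falling inside the dilated set is
#' excluded. `margin_mm = 0` removes only voxels overlapping the sternum
#' itself.
#'
#' @param rv_voxels integer vector of linear indices (RV free wall).
#' @param sternum_voxels integer vector of linear indices (sternum).
#' @param grid_dim integer length-3 grid shape shared by both sets.
#' @param spacing_mm voxel spacing, mm.
#' @param margin_mm non-negative exclusion margin, mm; default 10 (about one
#'   system FWHM).
#' @return integer vector, a subset of `rv_voxels`.
#' @export
exclude_sternum_spillover <- function(rv_voxels, sternum_voxels, grid_dim,
                                      spacing_mm, margin_mm = 10) {
  if (margin_mm < 0) stop("'margin_mm' must be >= 0")
  if (length(sternum_voxels) == 0L || length(rv_voxels) == 0L)
    return(rv_voxels)
  grid_dim <- as.integer(grid_dim)
  stopifnot(length(grid_dim) == 3L, length(spacing_mm) == 3L)

  # voxel-offset ball of radius margin_mm in physical units
  r <- floor(margin_mm / spacing_mm)
  off <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (off$dx * spacing_mm[1])^2 + (off$dy * spacing_mm[2])^2 +
        (off$dz * spacing_mm[3])^2
  off <- off[d2 <= margin_mm^2 + 1e-9, , drop = FALSE]

  stern <- arrayInd(sternum_voxels, grid_dim)
  excl <- logical(prod(grid_dim))
  for (k in seq_len(nrow(off))) {
    x <- stern[, 1] + off$dx[k]
    y <- stern[, 2] + off$dy[k]
    z <- stern[, 3] + off$dz[k]
    ok <- x >= 1L & x <= grid_dim[1] & y >= 1L & y <= grid_dim[2] &
          z >= 1L & z <= grid_dim[3]
    if (!any(ok)) next
    lin <- x[ok] + (y[ok] - 1L) * grid_dim[1] +
           (z[ok] - 1L) * grid_dim[1] * grid_dim[2]
    excl[lin] <- TRUE
  }
  rv_voxels[!excl[rv_voxels]]
}
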
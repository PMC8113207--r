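# Core containers: uptake volumes, label mask sets, acquisition metadata.

#' Base anatomical region names
#'
#' The four myocardial volumes of interest plus the sternum. Merged regions
#' (`"LV"`, `"VENTRICLES"`) are derived from these by [merge_regions()].
#' @export
REGION_NAMES <- c("LV_LATERAL", "IVS", "APEX", "RV_FREE_WALL", "STERNUM")

#' Half-life of Tc-99m in hours
#' @export
TC99M_HALF_LIFE_H <- 6.0067

#' Construct an uptake volume
#'
#' A `voxel_volume` is a 3-D non-negative scalar grid in arbitrary uptake
#' (concentration) units, together with its voxel spacing and origin. Negative
#' entries — reconstruction artefacts — are clipped to zero and the clip count
#' is reported via a message and kept in the `n_clipped` attribute, because
#' threshold segmentation and SUV normalisation assume non-negative
#' concentration.
#'
#' @param values 3-D numeric array, finite.
#' @param spacing_mm numeric length-3, per-axis voxel edge length in mm, all
#'   positive.
#' @param origin_mm numeric length-3, position of the first voxel in mm.
#' @param axis_codes character length-3 anatomical axis labels; informational
#'   only (all quantification is in voxel space).
#' @return object of class `voxel_volume`.
#' @examples
#' v <- voxel_volume(array(1, dim = c(4, 4, 4)), spacing_mm = rep(4.42, 3))
#' voxel_size_ml(v)
#' @export
voxel_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                         axis_codes = c("R", "A", "S")) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("'values' contains non-finite entries")
  spacing_mm <- as.double(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be three positive finite numbers")
  n_clipped <- sum(values < 0)
  if (n_clipped > 0) {
    message("clipped ", n_clipped, " negative voxel(s) to 0")
    values[values < 0] <- 0
  }
  structure(
    list(values = values, spacing_mm = spacing_mm,
         origin_mm = as.double(origin_mm), axis_codes = as.character(axis_codes)),
    n_clipped = n_clipped,
    class = "voxel_volume"
  )
}

#' Volume of one voxel in millilitres
#'
#' @param x a `voxel_volume` or `region_mask_set`.
#' @return scalar, `prod(spacing_mm) / 1000`.
#' @export
voxel_size_ml <- function(x) prod(x$spacing_mm) / 1000

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm (", signif(voxel_size_ml(x), 4), " ml/voxel)\n", sep = "")
  cat("  range: [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Read an uptake volume from a NIfTI-1 file
#'
#' Spacing is taken from the file header; negative voxels are clipped to zero
#' (with a message giving the count).
#'
#' @param path path to a 3-D `.nii` / `.nii.gz` file.
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path) {
  nim <- read_nifti(path)
  voxel_volume(nim$values, nim$spacing_mm, nim$origin_mm, nim$axis_codes)
}

#' Write an uptake volume to a NIfTI-1 file
#'
#' @param volume a [voxel_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  write_nifti(volume$values, path, volume$spacing_mm, volume$origin_mm,
              datatype = "float64")
}

#' Construct acquisition metadata
#'
#' Injected activity, injection/acquisition timestamps, body weight and
#' isotope half-life: everything needed for decay correction and SUV
#' normalisation.
#'
#' @param injected_activity_MBq positive scalar, MBq.
#' @param injection_time,acquisition_time `POSIXct` or a string accepted by
#'   `as.POSIXct()` (UTC assumed for strings). Acquisition must not precede
#'   injection.
#' @param body_weight_kg positive scalar, kg.
#' @param half_life_h positive scalar, hours; defaults to Tc-99m
#'   ([TC99M_HALF_LIFE_H]).
#' @return object of class `acquisition_meta`.
#' @examples
#' meta <- acquisition_meta(740, "2020-01-01 09:00:00", "2020-01-01 12:00:00", 74.6)
#' uptake_time_h(meta)  # 3
#' @export
acquisition_meta <- function(injected_activity_MBq, injection_time,
                             acquisition_time, body_weight_kg,
                             half_life_h = TC99M_HALF_LIFE_H) {
  as_time <- function(t, what) {
    if (inherits(t, "POSIXct")) return(t)
    out <- tryCatch(as.POSIXct(t, tz = "UTC"), error = function(e) NA)
    if (is.na(out)) stop("cannot parse ", what, ": ", t)
    out
  }
  if (!is.numeric(injected_activity_MBq) || length(injected_activity_MBq) != 1L ||
      !is.finite(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop("'injected_activity_MBq' must be a positive scalar")
  if (!is.numeric(body_weight_kg) || length(body_weight_kg) != 1L ||
      !is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("'body_weight_kg' must be a positive scalar")
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L ||
      !is.finite(half_life_h) || half_life_h <= 0)
    stop("'half_life_h' must be a positive scalar")
  inj <- as_time(injection_time, "injection_time")
  acq <- as_time(acquisition_time, "acquisition_time")
  if (acq < inj)
    stop("acquisition_time precedes injection_time")
  structure(
    list(injected_activity_MBq = injected_activity_MBq,
         injection_time = inj, acquisition_time = acq,
         body_weight_kg = body_weight_kg, half_life_h = half_life_h),
    class = "acquisition_meta"
  )
}

#' Time between injection and acquisition, hours
#' @param meta an [acquisition_meta()].
#' @return non-negative scalar.
#' @export
uptake_time_h <- function(meta) {
  as.double(difftime(meta$acquisition_time, meta$injection_time, units = "hours"))
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat("<acquisition_meta> ", x$injected_activity_MBq, " MBq, ",
      signif(uptake_time_h(x), 4), " h uptake, ",
      x$body_weight_kg, " kg, T1/2 = ", x$half_life_h, " h\n", sep = "")
  invisible(x)
}

#' Read acquisition metadata from a flat JSON file
#'
#' Required keys: `injected_activity_MBq`, `injection_time`,
#' `acquisition_time`, `body_weight_kg`. Optional: `half_life_h` (defaults to
#' Tc-99m).
#'
#' @param path path to a JSON file.
#' @return an [acquisition_meta()].
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("injected_activity_MBq", "injection_time", "acquisition_time",
           "body_weight_kg")
  missing <- setdiff(req, names(j))
  if (length(missing))
    stop("metadata file missing required field(s): ",
         paste(missing, collapse = ", "))
  acquisition_meta(
    injected_activity_MBq = as.double(j$injected_activity_MBq),
    injection_time = j$injection_time,
    acquisition_time = j$acquisition_time,
    body_weight_kg = as.double(j$body_weight_kg),
    half_life_h = if (!is.null(j$half_life_h)) as.double(j$half_life_h)
                  else TC99M_HALF_LIFE_H
  )
}

#' Write acquisition metadata (plus optional extras) as JSON
#'
#' @param meta an [acquisition_meta()].
#' @param path output path.
#' @param extra named list merged into the JSON object (e.g. a label map).
#' @return `path`, invisibly.
#' @export
write_meta <- function(meta, path, extra = list()) {
  stopifnot(inherits(meta, "acquisition_meta"))
  obj <- c(list(
    injected_activity_MBq = meta$injected_activity_MBq,
    injection_time = format(meta$injection_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    acquisition_time = format(meta$acquisition_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    body_weight_kg = meta$body_weight_kg,
    half_life_h = meta$half_life_h
  ), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Construct a region mask set
#'
#' An integer label grid congruent with a companion [voxel_volume()], plus a
#' name-to-label mapping. Label 0 is background; labels are disjoint by
#' construction (one integer per voxel).
#'
#' @param labels 3-D integer array.
#' @param label_map named integer vector, e.g.
#'   `c(LV_LATERAL = 1, IVS = 2, APEX = 3, RV_FREE_WALL = 4, STERNUM = 5)`.
#' @param spacing_mm,origin_mm grid geometry, as for [voxel_volume()].
#' @param volume optional companion `voxel_volume`; when given, shape and
#'   spacing congruence is enforced.
#' @return object of class `region_mask_set`.
#' @export
region_mask_set <- function(labels, label_map, spacing_mm,
                            origin_mm = c(0, 0, 0), volume = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3-D array")
  if (any(labels != round(labels)))
    stop("'labels' must be integer-valued")
  storage.mode(labels) <- "integer"
  if (is.null(names(label_map)) || any(names(label_map) == ""))
    stop("'label_map' must be a fully named integer vector")
  label_map <- vapply(label_map, as.integer, integer(1))
  if (anyDuplicated(label_map))
    stop("'label_map' assigns the same label to two regions")
  spacing_mm <- as.double(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be three positive numbers")
  if (!is.null(volume)) {
    if (!identical(dim(labels), dim(volume$values)))
      stop("mask grid shape ", paste(dim(labels), collapse = "x"),
           " does not match volume shape ",
           paste(dim(volume$values), collapse = "x"))
    if (max(abs(spacing_mm - volume$spacing_mm)) > 1e-6)
      stop("mask spacing (", paste(signif(spacing_mm, 6), collapse = ", "),
           ") does not match volume spacing (",
           paste(signif(volume$spacing_mm, 6), collapse = ", "), ")")
  }
  present <- sort(unique(as.vector(labels)))
  empty <- names(label_map)[!label_map %in% present]
  if (length(empty))
    warning("label(s) absent from grid (empty regions): ",
            paste(empty, collapse = ", "))
  structure(
    list(labels = labels, label_map = label_map,
         spacing_mm = spacing_mm, origin_mm = as.double(origin_mm)),
    class = "region_mask_set"
  )
}

#' @export
print.region_mask_set <- function(x, ...) {
  counts <- vapply(x$label_map, function(l) sum(x$labels == l), numeric(1))
  cat("<region_mask_set> ", paste(dim(x$labels), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = " x "), " mm\n",
      sep = "")
  for (nm in names(x$label_map))
    cat(sprintf("  %-14s label %d, %d voxel(s)\n", nm, x$label_map[[nm]],
                as.integer(counts[[nm]])))
  invisible(x)
}

#' Read a label mask set from a NIfTI-1 file
#'
#' @param path path to an integer-valued 3-D NIfTI file.
#' @param label_map named integer vector naming the labels of interest.
#' @param volume optional companion [voxel_volume()] for geometry checks.
#' @return a [region_mask_set()].
#' @export
read_mask_set <- function(path, label_map, volume = NULL) {
  nim <- read_nifti(path)
  if (max(abs(nim$values - round(nim$values))) > 1e-6)
    stop("mask file is not integer-valued: ", path)
  region_mask_set(array(as.integer(round(nim$values)), dim = dim(nim$values)),
                  label_map, nim$spacing_mm, nim$origin_mm, volume = volume)
}

#' Write a label mask set to a NIfTI-1 file
#'
#' The label map itself is not stored in the NIfTI header; persist it via
#' [write_meta()]'s `extra` argument or alongside as JSON.
#'
#' @param masks a [region_mask_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_set <- function(masks, path) {
  stopifnot(inherits(masks, "region_mask_set"))
  write_nifti(masks$labels, path, masks$spacing_mm, masks$origin_mm,
              datatype = "int32")
}

#' Linear voxel indices of a named region
#'
#' @param masks a [region_mask_set()].
#' @param name a base region name present in the label map, or a merged name
#'   handled by [merge_regions()].
#' @return integer vector of linear indices into the grid.
#' @export
region_voxels <- function(masks, name) {
  if (!name %in% names(masks$label_map))
    stop("region '", name, "' not in label map (have: ",
         paste(names(masks$label_map), collapse = ", "), ")")
  which(masks$labels == masks$label_map[[name]])
}
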
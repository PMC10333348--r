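#' Peri-ventricular strips for hydrocephalus features
#'
#' Builds two strips of `width` voxel layers around the union of the
#' lateral-ventricle sub-regions: the outside strip (OLV; dilation minus
#' the ventricle union) and the inside strip (ILV; the union minus its
#' erosion). The sub-regions are merged before strip construction so shared
#' walls are not double counted. The structuring element is a 3D box
#' (Chebyshev metric): "5-voxel width" means 5 voxel layers. Strips are
#' clipped to the image grid.
#'
#' @param ventricles a [labeled_volume()] whose `ventricle`-scheme labels
#'   mark the lateral-ventricle sub-regions.
#' @param width strip width in voxel layers (default 5).
#' @return A `strip_pair`: `olv` and `ilv` as [lesion_mask()] plus
#'   `width_voxels`.
#' @export
build_ventricle_strips <- function(ventricles, width = 5L) {
  stopifnot(inherits(ventricles, "labeled_volume"))
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 1L)
    stop("`width` must be an integer >= 1")
  ids <- ventricles$table$id[ventricles$table$scheme == "ventricle"]
  if (!length(ids)) stop("no ventricle-scheme regions in the atlas")
  vent <- array(ventricles$labels %in% ids, dim = ventricles$grid$shape)
  if (!any(vent)) stop("ventricle regions are empty")
  olv <- dilate_box(vent, width) & !vent
  ilv <- vent & !erode_box(vent, width)
  structure(
    list(olv = lesion_mask(olv, ventricles$grid),
         ilv = lesion_mask(ilv, ventricles$grid),
         width_voxels = width),
    class = "strip_pair"
  )
}

#' Hydrocephalus ratio features from an ADC map
#'
#' Voxels with ADC above the CSF threshold (default 0.0018 mm^2/s) count as
#' CSF; below it, as non-CSF. Voxels exactly at the threshold count as
#' neither (both inequalities are strict). The two features are
#' `gamma_olvr`, the non-CSF fraction of the outside strip, and
#' `gamma_ilvr`, the CSF fraction of the inside strip. A `gamma_olvr` below
#' the cohort average suggests ventricular enlargement; a low `gamma_ilvr`
#' suggests ventricular compression or midline shift.
#'
#' If the 99th percentile of the ADC map exceeds 1.0 the map is assumed to
#' be in a scaled convention (e.g. 1e-6 mm^2/s units) and an error asks for
#' an explicit `adc_scale` instead of silently rescaling.
#'
#' @param adc a [scalar_volume()] ADC map in mm^2/s.
#' @param strips a `strip_pair` from [build_ventricle_strips()].
#' @param csf_threshold CSF cut in mm^2/s (default 0.0018).
#' @param adc_scale multiply ADC values by this before thresholding
#'   (default 1; set e.g. 1e-6 for micrometre-convention maps).
#' @return A `hydro_features` object: `gamma_olvr`, `gamma_ilvr`,
#'   `csf_threshold`.
#' @export
hydro_features <- function(adc, strips, csf_threshold = 0.0018,
                           adc_scale = 1) {
  stopifnot(inherits(adc, "scalar_volume"), inherits(strips, "strip_pair"))
  if (csf_threshold <= 0) stop("`csf_threshold` must be > 0")
  stop_if_incompatible(adc$grid, strips$olv$grid, "ADC map and strips")
  vals <- adc$values * adc_scale
  if (stats::quantile(vals, 0.99) > 1)
    stop("ADC intensities look scaled (99th percentile > 1 mm^2/s); ",
         "pass an explicit `adc_scale` instead of relying on rescaling")
  in_olv <- strips$olv$values == 1L
  in_ilv <- strips$ilv$values == 1L
  if (!any(in_olv) || !any(in_ilv)) stop("empty ventricle strip")
  structure(
    list(gamma_olvr = sum(vals[in_olv] < csf_threshold) / sum(in_olv),
         gamma_ilvr = sum(vals[in_ilv] > csf_threshold) / sum(in_ilv),
         csf_threshold = csf_threshold),
    class = "hydro_features"
  )
}

#' @export
print.hydro_features <- function(x, ...) {
  cat(sprintf("<hydro_features> gamma_olvr %.3f, gamma_ilvr %.3f (CSF > %g mm^2/s)\n",
              x$gamma_olvr, x$gamma_ilvr, x$csf_threshold))
  invisible(x)
}

#' Flag ventricular enlargement / compression against cohort averages
#'
#' Strict comparisons: a gamma exactly at its cohort mean raises no flag.
#'
#' @param features a `hydro_features` object.
#' @param cohort_means numeric length-2: cohort mean `gamma_olvr` and mean
#'   `gamma_ilvr`, both in \[0, 1\].
#' @return list with logicals `enlargement` and `compression`.
#' @export
hydro_flags <- function(features, cohort_means) {
  stopifnot(inherits(features, "hydro_features"),
            length(cohort_means) == 2L,
            all(cohort_means >= 0 & cohort_means <= 1))
  list(enlargement = features$gamma_olvr < cohort_means[[1]],
       compression = features$gamma_ilvr < cohort_means[[2]])
}
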
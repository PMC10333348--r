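#' Lesion volume in ml and log-ml
#'
#' Volume is lesion voxel count times the voxel volume (mm^3) over 1000.
#' The log is natural; the models use log-ml because lesion volumes span
#' orders of magnitude.
#'
#' @param mask a nonempty [lesion_mask()].
#' @param log_base base of the logarithm (default natural).
#' @return list with `ml` and `log_ml`.
#' @export
lesion_volume <- function(mask, log_base = exp(1)) {
  stopifnot(inherits(mask, "lesion_mask"))
  n <- mask_count(mask)
  if (n == 0L)
    stop("empty lesion mask: no detected infarct, volume (and its log) undefined")
  ml <- n * voxel_volume_mm3(mask$grid) / 1000
  list(ml = ml, log_ml = log(ml, base = log_base))
}

#' Quantitative feature vector: per-region injury fractions
#'
#' For every region r of the atlas, the fraction of its voxels covered by
#' the infarct mask: |mask = 1 and label = r| / |label = r|. The lesion
#' volume (ml, and natural-log ml) is carried alongside; lesion voxels
#' falling outside every labeled region count toward the volume but toward
#' no fraction, and their number is reported as `unassigned_voxels`.
#' Fractions are kept at full precision; rounding is display-only.
#'
#' @param mask a nonempty [lesion_mask()] on the atlas grid.
#' @param atlas a [labeled_volume()].
#' @param log_base base for the volume log (default natural).
#' @return A `qfv` object: named `fractions` in atlas-table order, per-ROI
#'   `roi_voxels` and `lesion_voxels`, `lesion_volume_ml`,
#'   `lesion_volume_log_ml`, `unassigned_voxels`, `scheme`.
#' @examples
#' ph <- make_phantom_atlas(shape = c(32, 32, 32), seed = 1)
#' les <- make_lesion(ph$arterial, targets = c(territory_1 = 0.5), seed = 1)
#' extract_qfv(les, ph$arterial)
#' @export
extract_qfv <- function(mask, atlas, log_base = exp(1)) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(atlas, "labeled_volume"))
  stop_if_incompatible(mask$grid, atlas$grid, "mask and atlas")
  vol <- lesion_volume(mask, log_base)     # errors on empty mask

  ids <- atlas$table$id
  nb <- max(ids)
  roi_n <- tabulate(atlas$labels, nbins = nb)[ids]
  if (any(roi_n == 0L))
    stop("atlas table lists regions with zero voxels: ",
         paste(atlas$table$name[roi_n == 0L], collapse = ", "))
  hit <- atlas$labels[mask$values == 1L]
  les_n <- tabulate(hit, nbins = nb)[ids]
  fractions <- les_n / roi_n
  names(fractions) <- atlas$table$name

  structure(
    list(scheme = paste(unique(atlas$table$scheme), collapse = "+"),
         fractions = fractions,
         roi_voxels = stats::setNames(roi_n, atlas$table$name),
         lesion_voxels = stats::setNames(les_n, atlas$table$name),
         lesion_volume_ml = vol$ml,
         lesion_volume_log_ml = vol$log_ml,
         unassigned_voxels = sum(hit == 0L)),
    class = "qfv"
  )
}

#' @export
print.qfv <- function(x, digits = 2, ...) {
  cat(sprintf("<qfv> scheme %s, lesion %.3f ml (log %.3f)\n",
              x$scheme, x$lesion_volume_ml, x$lesion_volume_log_ml))
  print(round(x$fractions, digits))
  invisible(x)
}

#' @export
as.data.frame.qfv <- function(x, ...) {
  data.frame(scheme = x$scheme,
             roi = names(x$fractions),
             fraction = unname(x$fractions),
             roi_voxels = unname(x$roi_voxels),
             lesion_voxels = unname(x$lesion_voxels),
             stringsAsFactors = FALSE)
}

#' Quality-control index: Dice agreement of brain contours
#'
#' Compares the subject's brain mask with the atlas brain mask by the Dice
#' coefficient 2|A n B| / (|A| + |B|) and flags the case when agreement
#' falls below a threshold, signalling that the atlas overlay (hence every
#' fraction computed from it) may be unreliable.
#'
#' @param subject_brain,atlas_brain [lesion_mask()] brain masks on one grid.
#' @param threshold flagging threshold on Dice (default 0.90).
#' @return list with `dice` and `flagged`.
#' @export
qc_index <- function(subject_brain, atlas_brain, threshold = 0.90) {
  stopifnot(inherits(subject_brain, "lesion_mask"),
            inherits(atlas_brain, "lesion_mask"))
  stop_if_incompatible(subject_brain$grid, atlas_brain$grid, "brain masks")
  na <- mask_count(subject_brain)
  nb <- mask_count(atlas_brain)
  if (na + nb == 0L) stop("both brain masks are empty")
  dice <- 2 * sum(subject_brain$values == 1L & atlas_brain$values == 1L) /
    (na + nb)
  list(dice = dice, flagged = dice < threshold)
}
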
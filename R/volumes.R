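#' Labeled parcellation volume
#'
#' A 3D integer parcellation (0 = background) plus a label table mapping
#' each region id to a name and a scheme. Schemes in use: `arterial`
#' (vascular territories), `structural` (classical anatomy), `aspects`
#' (the 10 MCA-ASPECTS regions), `ventricle` (lateral-ventricle
#' sub-regions) and `brainmask`.
#'
#' @param labels 3D array of non-negative integers.
#' @param grid a [volume_grid()] matching `dim(labels)`.
#' @param table data.frame with columns `id`, `name`, `scheme`; every
#'   nonzero label present in `labels` must appear in it.
#' @return A `labeled_volume` object.
#' @export
labeled_volume <- function(labels, grid, table) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(dim(labels), grid$shape))
    stop("label array dimensions do not match the grid shape")
  if (any(labels < 0L, na.rm = TRUE) || anyNA(labels))
    stop("labels must be non-negative integers with no missing values")
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  need <- c("id", "name", "scheme")
  if (!all(need %in% names(table)))
    stop("label table must have columns id, name, scheme")
  table$id <- as.integer(table$id)
  if (anyDuplicated(table$id)) stop("duplicate ids in label table")
  if (any(table$id == 0L)) stop("label 0 is reserved for background")
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(present, table$id)
  if (length(missing))
    stop(sprintf(
      "labels present in array but absent from table: %s (corrupt atlas pair?)",
      paste(missing, collapse = ", ")))
  structure(
    list(grid = grid, labels = labels,
         table = table[, need, drop = FALSE]),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %d region(s), scheme(s): %s, %s voxels\n",
              nrow(x$table), paste(unique(x$table$scheme), collapse = "/"),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

# voxel counts per table row, in table order
roi_voxel_counts <- function(lv) {
  tab <- tabulate(lv$labels, nbins = max(lv$table$id))
  tab[lv$table$id]
}

#' Scalar-valued volume (e.g. an ADC map)
#'
#' @param values 3D numeric array of finite values.
#' @param grid a [volume_grid()].
#' @param units unit string; ADC maps are expected in mm^2/s.
#' @return A `scalar_volume` object.
#' @export
scalar_volume <- function(values, grid, units = "") {
  values <- as.array(values)
  storage.mode(values) <- "double"
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(dim(values), grid$shape))
    stop("value array dimensions do not match the grid shape")
  if (!all(is.finite(values)))
    stop("scalar volume contains non-finite values")
  structure(list(grid = grid, values = values, units = units),
            class = "scalar_volume")
}

#' Binary lesion (or brain) mask
#'
#' @param values 3D array over {0,1} (logical arrays are accepted).
#' @param grid a [volume_grid()].
#' @return A `lesion_mask` object.
#' @export
lesion_mask <- function(values, grid) {
  values <- as.array(values)
  if (is.logical(values)) values <- values * 1L
  storage.mode(values) <- "integer"
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(dim(values), grid$shape))
    stop("mask dimensions do not match the grid shape")
  if (!all(values %in% c(0L, 1L)))
    stop("mask values must be 0 or 1")
  structure(list(grid = grid, values = values), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d of %d voxels set\n",
              sum(x$values), length(x$values)))
  invisible(x)
}

mask_count <- function(mask) sum(mask$values)

## ---- NIfTI + table I/O -----------------------------------------------------

# plain array, shedding RNifti image attributes
strip_array <- function(a) {
  a <- as.array(a)
  d <- dim(a)
  attributes(a) <- NULL
  dim(a) <- d
  a
}

grid_from_nifti <- function(img) {
  dm <- dim(img)
  if (length(dm) != 3L) stop("expected a 3D NIfTI volume")
  volume_grid(dm, RNifti::xform(img))
}

nifti_with_grid <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
}

read_label_table <- function(table_path) {
  if (!file.exists(table_path)) stop("label table not found: ", table_path)
  utils::read.delim(table_path, stringsAsFactors = FALSE)
}

write_label_table <- function(table, table_path) {
  utils::write.table(table, table_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(table_path)
}

#' Read a parcellation atlas (NIfTI + TSV label table)
#'
#' @param path NIfTI file (.nii or .nii.gz) of integer labels.
#' @param table_path tab-separated label table with columns
#'   `id`, `name`, `scheme`.
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(path, table_path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  labeled_volume(round(strip_array(img)), grid_from_nifti(img),
                 read_label_table(table_path))
}

#' Write a parcellation atlas (NIfTI + TSV label table)
#'
#' @param lv a [labeled_volume()].
#' @param path,table_path output NIfTI and TSV paths.
#' @return The NIfTI path, invisibly.
#' @export
write_labeled_volume <- function(lv, path, table_path) {
  RNifti::writeNifti(nifti_with_grid(lv$labels, lv$grid), path)
  write_label_table(lv$table, table_path)
  invisible(path)
}

#' Read or write a binary mask as NIfTI
#'
#' Values are rounded and validated to {0,1} on read.
#'
#' @param path NIfTI path.
#' @return [read_lesion_mask()] returns a [lesion_mask()].
#' @export
read_lesion_mask <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  lesion_mask(round(strip_array(img)), grid_from_nifti(img))
}

#' @rdname read_lesion_mask
#' @param mask a [lesion_mask()].
#' @export
write_lesion_mask <- function(mask, path) {
  RNifti::writeNifti(nifti_with_grid(mask$values, mask$grid), path)
  invisible(path)
}

#' Read or write a scalar volume as NIfTI
#'
#' @param path NIfTI path.
#' @param units unit string attached on read (NIfTI itself does not carry
#'   ADC units); ADC maps are expected in mm^2/s.
#' @return [read_scalar_volume()] returns a [scalar_volume()].
#' @export
read_scalar_volume <- function(path, units = "") {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  scalar_volume(strip_array(img), grid_from_nifti(img), units)
}

#' @rdname read_scalar_volume
#' @param vol a [scalar_volume()].
#' @export
write_scalar_volume <- function(vol, path) {
  RNifti::writeNifti(nifti_with_grid(vol$values, vol$grid), path)
  invisible(path)
}
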
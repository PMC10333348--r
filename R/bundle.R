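#' Write the per-case output bundle
#'
#' Writes the four deliverables for one case into `outdir`: the rendered
#' report (`report.txt`, UTF-8), the structured record (`report.json`,
#' including QFV summary fields and any QC index), the feature table
#' (`qfv.csv`) and the prediction table (`predictions.csv`, probabilities
#' and labels, with one column per feature of Shapley contributions when
#' explanations are supplied).
#'
#' @param report a `radiology_report`.
#' @param qfvs a `qfv` or list of `qfv` objects (e.g. both schemes).
#' @param preds a `region_predictions` data.frame (may have zero rows).
#' @param outdir output directory (created if needed).
#' @param explanations optional named list of `shap_explanation` objects
#'   keyed by region, as from [shapley_explain()].
#' @param qc optional [qc_index()] result to embed in the JSON.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_report_bundle <- function(report, qfvs, preds, outdir,
                                explanations = NULL, qc = NULL) {
  stopifnot(inherits(report, "radiology_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  if (inherits(qfvs, "qfv")) qfvs <- list(qfvs)

  paths <- c(text = file.path(outdir, "report.txt"),
             json = file.path(outdir, "report.json"),
             qfv = file.path(outdir, "qfv.csv"),
             predictions = file.path(outdir, "predictions.csv"))

  writeLines(report$text, paths[["text"]], useBytes = TRUE)

  record <- unclass(report)
  record$lesion_volume_log_ml <-
    if (length(qfvs)) qfvs[[1]]$lesion_volume_log_ml else NULL
  record$unassigned_voxels <-
    if (length(qfvs)) qfvs[[1]]$unassigned_voxels else NULL
  if (!is.null(qc)) record$qc <- qc
  jsonlite::write_json(record, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, null = "null")

  qfv_df <- if (length(qfvs))
    do.call(rbind, lapply(qfvs, as.data.frame))
  else data.frame(scheme = character(0), roi = character(0),
                  fraction = numeric(0), roi_voxels = integer(0),
                  lesion_voxels = integer(0))
  utils::write.csv(qfv_df, paths[["qfv"]], row.names = FALSE)

  pred_df <- as.data.frame(preds)
  if (!is.null(explanations) && nrow(pred_df)) {
    feats <- names(explanations[[1]]$contributions)
    shap <- matrix(NA_real_, nrow(pred_df), length(feats),
                   dimnames = list(NULL, paste0("shap_", feats)))
    for (i in seq_len(nrow(pred_df))) {
      ex <- explanations[[pred_df$roi[i]]]
      if (!is.null(ex)) shap[i, ] <- ex$contributions
    }
    pred_df <- cbind(pred_df, as.data.frame(shap))
  }
  utils::write.csv(pred_df, paths[["predictions"]], row.names = FALSE)
  invisible(paths)
}
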
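#' Binary-threshold (BT) classifier: cross-validated threshold fit
#'
#' The BT model classifies a region as injured when its own QFV component
#' (the fraction of the region occupied by the infarct) reaches a
#' threshold. The threshold is the smallest grid value achieving the
#' highest cross-validated sum of balanced accuracy and F1: for every grid
#' value the rule `fraction >= t` is scored on each validation fold (the
#' rule has no fitted state, so folds act as validation subsets), fold
#' scores are averaged, and ties on the maximum are resolved toward the
#' smallest threshold.
#'
#' @param fractions numeric vector: the region's QFV component per case.
#' @param labels binary expert labels (1 = injured), same length.
#' @param grid ascending candidate thresholds (default 0 to 1 by 0.01).
#' @param folds number of stratified CV folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @return The selected threshold (one element of `grid`).
#' @export
fit_binary_threshold <- function(fractions, labels,
                                 grid = seq(0, 1, by = 0.01),
                                 folds = 5L, seed = 1L) {
  fractions <- as.numeric(fractions)
  labels <- as.integer(labels)
  stopifnot(length(fractions) == length(labels))
  if (is.unsorted(grid)) stop("`grid` must be sorted ascending")
  if (length(unique(labels)) < 2L)
    stop("single-class labels: threshold is not identifiable ",
         "(use a prevalence predictor for this region)")
  fold <- stratified_folds(labels, folds, seed)
  used <- sort(unique(fold))
  scores <- vapply(grid, function(t) {
    mean(vapply(used, function(f) {
      sel <- fold == f
      m <- suppressWarnings(
        classification_metrics(labels[sel], as.integer(fractions[sel] >= t)))
      m$bacc + m$f1
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(scores)]   # which.max takes the first (smallest) maximizer
}
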
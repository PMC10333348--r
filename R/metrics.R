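#' Binary classification performance metrics
#'
#' Computes the metric set used throughout model selection and evaluation:
#' sensitivity TP/(TP+FN), precision TP/(TP+FP), balanced accuracy
#' (sensitivity + specificity)/2, F1, and Cohen's kappa with
#' marginal-product expected agreement. Ratios with a zero denominator
#' (e.g. precision of an all-negative predictor) return 0 with a warning.
#'
#' @param truth,pred equal-length vectors over {0,1}.
#' @return A one-row data.frame with columns `bacc`, `f1`, `precision`,
#'   `sensitivity`, `kappa`.
#' @examples
#' classification_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'                        c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
#' @export
classification_metrics <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred) || length(truth) < 1L)
    stop("`truth` and `pred` must have equal length >= 1")
  if (!all(truth %in% 0:1) || !all(pred %in% 0:1))
    stop("`truth` and `pred` must be binary (0/1)")
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  tn <- sum(truth == 0L & pred == 0L)
  n <- tp + fp + fn + tn

  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  sens <- safe_ratio(tp, tp + fn, "sensitivity")
  spec <- safe_ratio(tn, tn + fp, "specificity")
  prec <- safe_ratio(tp, tp + fp, "precision")
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe == 1) {
    # degenerate marginals: agreement is forced, no chance-corrected signal
    0
  } else {
    (po - pe) / (1 - pe)
  }
  data.frame(bacc = (sens + spec) / 2, f1 = f1, precision = prec,
             sensitivity = sens, kappa = kappa)
}

#' Intraclass correlation ICC(3,1): two-way mixed, consistency
#'
#' Single-rater consistency ICC from the two-way ANOVA decomposition of an
#' n-subjects x k-raters matrix: (MS_subjects - MS_error) /
#' (MS_subjects + (k - 1) MS_error), where MS_error is the
#' subject-by-rater interaction mean square. Being a consistency form, it
#' is invariant to adding a constant to any single rater's column.
#'
#' @param ratings numeric matrix, rows = subjects (n >= 2), columns =
#'   raters (k >= 2), no missing cells.
#' @return The ICC as a single number in \[-1, 1\].
#' @examples
#' icc3(cbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))  # perfect consistency: 1
#' @export
icc3 <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("`ratings` must have no missing cells")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_err
  if (denom == 0)
    stop("zero between-subject and error variance: ICC3 undefined")
  (ms_rows - ms_err) / denom
}
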
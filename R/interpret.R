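#' Mean-decrease-in-impurity importance over repeated forests
#'
#' Fits `n_models` independently seeded random forests per region and
#' summarizes the impurity-decrease importance of every feature,
#' normalized within each forest to sum to one, as mean and standard
#' deviation over the repeats. Averaging over repeated forests separates
#' stable importance signal from the randomness of any single forest.
#'
#' @param cohort a [stroke_cohort()] training set.
#' @param rois regions to analyse (default: all labeled regions).
#' @param hyperparams forest hyperparameters (see [fit_model()]).
#' @param n_models forests per region (default 100).
#' @param seed master seed; each forest gets a derived seed.
#' @return data.frame `roi`, `feature`, `mean`, `sd` (MDI share in
#'   \[0, 1\], summing to 1 over features within each roi).
#' @export
mdi_importance <- function(cohort, rois = colnames(cohort$labels),
                           hyperparams = NULL, n_models = 100L, seed = 1L) {
  stopifnot(inherits(cohort, "stroke_cohort"), n_models >= 1L)
  x <- cohort$features
  out <- lapply(rois, function(roi) {
    y <- cohort$labels[, roi]
    if (length(unique(y)) < 2L)
      stop("region ", roi, " has single-class labels; MDI undefined")
    imp <- vapply(seq_len(n_models), function(m) {
      clf <- clf_fit("rf", x, y, hyperparams %||% list(),
                     seed = derive_seed(seed, roi, m))
      v <- randomForest::importance(clf$fit, type = 2)[, 1]
      v / sum(v)
    }, numeric(ncol(x)))
    imp <- matrix(imp, nrow = ncol(x))
    data.frame(roi = roi, feature = colnames(x),
               mean = rowMeans(imp), sd = apply(imp, 1, stats::sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Permutation feature importance
#'
#' Importance of a feature is the mean drop in a score (balanced accuracy
#' by default) when that feature's column is permuted, over `n_iter`
#' seeded permutations. Irrelevant features hover around zero and may go
#' negative.
#'
#' @param model a fitted [fit_model()] result.
#' @param cohort the cohort to score on (training or held-out).
#' @param rois regions to analyse (default all).
#' @param n_iter permutations per feature (default 100).
#' @param metric `"bacc"`, `"f1"` or `"bacc_f1"`.
#' @param cut probability cut for labels (default 0.5).
#' @param seed master seed.
#' @return data.frame `roi`, `feature`, `mean`, `sd` (score drops).
#' @export
permutation_importance <- function(model, cohort,
                                   rois = colnames(cohort$labels),
                                   n_iter = 100L, metric = "bacc",
                                   cut = 0.5, seed = 1L) {
  stopifnot(inherits(model, "location_model"),
            inherits(cohort, "stroke_cohort"), n_iter >= 1L)
  score_fun <- switch(metric,
                      bacc = function(m) m$bacc,
                      f1 = function(m) m$f1,
                      bacc_f1 = function(m) m$bacc + m$f1,
                      stop("unknown metric: ", metric))
  x <- cohort$features[, model$feature_names, drop = FALSE]
  n <- nrow(x)
  out <- lapply(rois, function(roi) {
    clf <- model$fits[[roi]]
    if (is.null(clf)) stop("model has no classifier for region ", roi)
    y <- cohort$labels[, roi]
    score <- function(xx) {
      p <- clf_prob(clf, xx)
      score_fun(suppressWarnings(
        classification_metrics(y, as.integer(p >= cut))))
    }
    base <- score(x)
    drops <- vapply(colnames(x), function(j) {
      with_local_seed(derive_seed(seed, roi, j), {
        vapply(seq_len(n_iter), function(it) {
          xx <- x
          xx[, j] <- xx[sample(n), j]
          base - score(xx)
        }, numeric(1))
      })
    }, numeric(n_iter))
    drops <- matrix(drops, nrow = n_iter)
    data.frame(roi = roi, feature = colnames(x),
               mean = colMeans(drops),
               sd = if (n_iter > 1L) apply(drops, 2, stats::sd) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Additive Shapley explanation of a per-region prediction
#'
#' Attributes the predicted injury probability of each region to the
#' individual features by Shapley values estimated over feature orderings:
#' for an ordering, features are switched one at a time from background
#' values to the case's values and the change in mean predicted
#' probability is credited to the switched feature. Orderings telescope,
#' so `base_value + sum(contributions) = predicted_probability` holds
#' exactly (the efficiency property) for any number of sampled orderings;
#' sampling noise affects only how credit is split. With `exact = TRUE`
#' all orderings are enumerated (feasible for small feature counts), which
#' also makes symmetric features receive identical credit.
#'
#' @param model a fitted [fit_model()] result.
#' @param features named numeric vector: the case's feature values in
#'   model order (e.g. via the `qfv`/`hydro_features` objects).
#' @param background matrix of background cases (rows) defining the
#'   reference distribution; typically a seeded sample of ~100 training
#'   cases.
#' @param rois regions to explain (default all).
#' @param n_samples sampled orderings (default 200; ignored when exact).
#' @param exact enumerate all orderings (requires <= 7 features).
#' @param seed RNG seed for ordering sampling.
#' @return Named list of `shap_explanation` objects (`base_value`,
#'   `contributions`, `predicted_probability`), one per region.
#' @export
shapley_explain <- function(model, features, background,
                            rois = names(model$fits), n_samples = 200L,
                            exact = FALSE, seed = 1L) {
  stopifnot(inherits(model, "location_model"))
  background <- as.matrix(background)
  if (nrow(background) < 1L) stop("empty background sample")
  fn <- model$feature_names
  if (!all(fn %in% names(features)))
    stop("`features` must cover every model feature")
  x <- features[fn]
  background <- background[, fn, drop = FALSE]
  p <- length(fn)
  orderings <- if (exact) {
    if (p > 7L) stop("exact enumeration limited to 7 features")
    perms <- all_permutations(p)
    lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  } else {
    with_local_seed(derive_seed(seed, "orderings"),
                    lapply(seq_len(n_samples), function(i) sample.int(p)))
  }
  m <- nrow(background)
  out <- lapply(rois, function(roi) {
    clf <- model$fits[[roi]]
    base <- mean(clf_prob(clf, background))
    phi <- numeric(p)
    for (ord in orderings) {
      z <- background
      # stack the p switched states into one prediction call
      states <- matrix(NA_real_, nrow = p * m, ncol = p,
                       dimnames = list(NULL, fn))
      for (step in seq_len(p)) {
        z[, ord[step]] <- x[ord[step]]
        states[((step - 1) * m + 1):(step * m), ] <- z
      }
      pr <- clf_prob(clf, states)
      means <- colMeans(matrix(pr, nrow = m))
      prev <- base
      for (step in seq_len(p)) {
        phi[ord[step]] <- phi[ord[step]] + (means[step] - prev)
        prev <- means[step]
      }
    }
    phi <- phi / length(orderings)
    pred <- clf_prob(clf, matrix(x, nrow = 1, dimnames = list(NULL, fn)))
    structure(list(base_value = base,
                   contributions = stats::setNames(phi, fn),
                   predicted_probability = as.numeric(pred)),
              class = "shap_explanation")
  })
  stats::setNames(out, rois)
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> base %.4f -> predicted %.4f\n",
              x$base_value, x$predicted_probability))
  print(round(sort(x$contributions, decreasing = TRUE), 4))
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); recursion is fine for the
# small n allowed by exact enumeration
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}
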
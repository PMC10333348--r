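#' Labeled training cohort container
#'
#' Holds the feature matrix (per-region injury fractions from one or both
#' parcellation schemes, the log-ml lesion volume and the two ventricular
#' CSF ratios, in a fixed recorded order), the per-region expert labels and
#' the hydrocephalus label.
#'
#' @param features numeric matrix n x p with column names.
#' @param labels integer matrix n x R over {0,1}; column names are region
#'   names and must be a subset of `colnames(features)`.
#' @param hydro integer vector length n over {0,1}.
#' @param roi_scheme named character vector: scheme of each label column.
#' @param meta optional list of generator/provenance metadata.
#' @return A `stroke_cohort` object.
#' @export
stroke_cohort <- function(features, labels, hydro, roi_scheme = NULL,
                          meta = list()) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  stopifnot(nrow(features) == nrow(labels),
            nrow(features) == length(hydro),
            !is.null(colnames(features)), !is.null(colnames(labels)),
            all(labels %in% 0:1), all(hydro %in% 0:1))
  structure(
    list(features = features, labels = labels, hydro = as.integer(hydro),
         roi_scheme = roi_scheme, meta = meta),
    class = "stroke_cohort"
  )
}

#' @export
print.stroke_cohort <- function(x, ...) {
  cat(sprintf("<stroke_cohort> %d cases, %d features, %d labeled regions\n",
              nrow(x$features), ncol(x$features), ncol(x$labels)))
  invisible(x)
}

#' Subset a cohort by case index
#' @param cohort a [stroke_cohort()].
#' @param idx integer or logical case index.
#' @return A `stroke_cohort` restricted to `idx`.
#' @export
cohort_subset <- function(cohort, idx) {
  meta <- cohort$meta
  for (nm in c("primary", "hydro_clean"))
    if (!is.null(meta[[nm]])) meta[[nm]] <- meta[[nm]][idx]
  if (!is.null(meta$labels_clean))
    meta$labels_clean <- meta$labels_clean[idx, , drop = FALSE]
  stroke_cohort(cohort$features[idx, , drop = FALSE],
                cohort$labels[idx, , drop = FALSE],
                cohort$hydro[idx], cohort$roi_scheme, meta)
}

# features used by the hydrocephalus classifier; the location models use
# the full concatenated vector instead
HYDRO_FEATURES <- c("gamma_olvr", "gamma_ilvr", "lesion_volume_log_ml")

# mean over folds of held-out (BACC + F1) for one family/hyperparameter set
cv_bacc_f1 <- function(family, hp, x, y, fold, seed, roi = NULL) {
  used <- sort(unique(fold))
  mean(vapply(used, function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    clf <- clf_fit(family, x[tr, , drop = FALSE], y[tr], hp,
                   seed = derive_seed(seed, f))
    p <- clf_prob(clf, x[!tr, , drop = FALSE])
    m <- suppressWarnings(classification_metrics(y[!tr], as.integer(p >= 0.5)))
    m$bacc + m$f1
  }, numeric(1)), na.rm = TRUE)
}

#' Two-stage cross-validated hyperparameter selection
#'
#' Stage 1 scores every grid point by a single 5-fold cross-validation on
#' the training set (held-out balanced accuracy + F1, averaged over folds).
#' The top three settings advance to stage 2, a 10-repeat 5-fold
#' cross-validation, whose winner is returned. Ties at either stage keep
#' the earlier entry in grid order; a one-entry grid skips stage 2.
#'
#' @param family model family (one of `r paste(MODEL_FAMILIES, collapse=", ")`).
#' @param grid list of named hyperparameter lists.
#' @param x,y training feature matrix and binary labels.
#' @param folds folds per CV (default 5).
#' @param repeats stage-2 repeats (default 10).
#' @param seed RNG seed controlling every fold assignment.
#' @return The winning hyperparameter list, with attribute `"scores"`.
#' @export
select_hyperparameters <- function(family, grid, x, y, folds = 5L,
                                   repeats = 10L, seed = 1L) {
  stopifnot(is.list(grid), length(grid) >= 1L)
  if (length(grid) == 1L) return(grid[[1L]])
  x <- as.matrix(x); y <- as.integer(y)
  if (min(table(y)) < folds)
    warning("fewer cases in the minority class than folds; ",
            "some validation folds will be single-class")
  fold1 <- stratified_folds(y, folds, derive_seed(seed, "stage1"))
  s1 <- vapply(grid, function(hp)
    cv_bacc_f1(family, hp, x, y, fold1, derive_seed(seed, "s1fit")),
    numeric(1))
  top <- order(-s1)[seq_len(min(3L, length(grid)))]
  top <- sort(top)                       # stable: earlier grid entries first
  s2 <- vapply(top, function(i) {
    mean(vapply(seq_len(repeats), function(r) {
      foldr <- stratified_folds(y, folds, derive_seed(seed, "stage2", r))
      cv_bacc_f1(family, grid[[i]], x, y, foldr, derive_seed(seed, "s2fit", r))
    }, numeric(1)))
  }, numeric(1))
  winner <- top[which.max(s2)]
  structure(grid[[winner]],
            scores = list(stage1 = s1, stage2_candidates = top, stage2 = s2))
}

#' Fit the per-region location model (one family, all regions)
#'
#' Fits one independent binary classifier per labeled region over the full
#' feature vector, plus a hydrocephalus classifier over
#' (gamma_olvr, gamma_ilvr, log volume). Regions with fewer than two cases
#' in either class get a constant prevalence predictor and are flagged in
#' the model card. The BT family thresholds each region's own QFV
#' component; since hydrocephalus has no QFV component, BT carries no
#' hydrocephalus model (its prediction is NA).
#'
#' @param cohort a [stroke_cohort()] training set.
#' @param family model family: one of
#'   `r paste(MODEL_FAMILIES, collapse = ", ")`.
#' @param hyperparams named hyperparameter list (NULL = family defaults;
#'   see [default_hyper_grid()] for the searchable grids).
#' @param seed RNG seed; fits are reproducible given the seed.
#' @return A `location_model`: per-region classifiers, feature ordering,
#'   family, seed and a `model_card` data.frame of flags.
#' @export
fit_model <- function(cohort, family, hyperparams = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "stroke_cohort"))
  family <- match.arg(family, MODEL_FAMILIES)
  x <- cohort$features
  rois <- colnames(cohort$labels)
  fits <- vector("list", length(rois))
  names(fits) <- rois
  flags <- character(length(rois))
  for (i in seq_along(rois)) {
    y <- cohort$labels[, i]
    npos <- sum(y == 1L); nneg <- sum(y == 0L)
    if (npos < 2L || nneg < 2L) {
      fits[[i]] <- clf_fit("constant", x, y, seed = derive_seed(seed, i))
      flags[i] <- sprintf("constant predictor (%d positive, %d negative)",
                          npos, nneg)
    } else {
      hp <- hyperparams %||% list()
      if (family == "bt") {
        if (!rois[i] %in% colnames(x))
          stop("BT needs a feature column matching region ", rois[i])
        hp$feature <- rois[i]
      }
      fits[[i]] <- clf_fit(family, x, y, hp, seed = derive_seed(seed, i))
      flags[i] <- ""
    }
  }
  hydro_fit <- NULL
  if (family != "bt") {
    yh <- cohort$hydro
    xh <- x[, intersect(HYDRO_FEATURES, colnames(x)), drop = FALSE]
    if (ncol(xh) && sum(yh == 1L) >= 2L && sum(yh == 0L) >= 2L) {
      hydro_fit <- clf_fit(family, xh, yh, hyperparams %||% list(),
                           seed = derive_seed(seed, "hydro"))
    } else if (ncol(xh)) {
      hydro_fit <- clf_fit("constant", xh, yh, seed = derive_seed(seed, "hydro"))
    }
  }
  structure(
    list(family = family, fits = fits, hydro_fit = hydro_fit,
         feature_names = colnames(x), roi_scheme = cohort$roi_scheme,
         hyperparams = hyperparams, seed = seed,
         model_card = data.frame(roi = rois, flag = flags,
                                 stringsAsFactors = FALSE)),
    class = "location_model"
  )
}

#' @export
print.location_model <- function(x, ...) {
  cat(sprintf("<location_model> family %s, %d regions%s\n", x$family,
              length(x$fits),
              if (is.null(x$hydro_fit)) ", no hydrocephalus model" else ""))
  flagged <- x$model_card$flag != ""
  if (any(flagged))
    cat("flagged:", paste(x$model_card$roi[flagged], collapse = ", "), "\n")
  invisible(x)
}

# assemble the model's feature vector from QFVs (+ optional hydro features)
build_feature_vector <- function(model, qfvs, hydro = NULL) {
  if (inherits(qfvs, "qfv")) qfvs <- list(qfvs)
  feats <- unlist(lapply(qfvs, function(q) q$fractions))
  feats["lesion_volume_log_ml"] <- qfvs[[1]]$lesion_volume_log_ml
  if (!is.null(hydro)) {
    feats["gamma_olvr"] <- hydro$gamma_olvr
    feats["gamma_ilvr"] <- hydro$gamma_ilvr
  }
  missing <- setdiff(model$feature_names, names(feats))
  if (length(missing))
    stop("feature-order mismatch; model expects missing feature(s): ",
         paste(missing, collapse = ", "))
  matrix(feats[model$feature_names], nrow = 1,
         dimnames = list(NULL, model$feature_names))
}

# probability matrix (n x regions) for a case/feature matrix
predict_prob_matrix <- function(model, x) {
  x <- as.matrix(x)[, model$feature_names, drop = FALSE]
  p <- vapply(model$fits, function(clf) clf_prob(clf, x), numeric(nrow(x)))
  if (!is.matrix(p))
    p <- matrix(p, nrow = nrow(x), dimnames = list(NULL, names(model$fits)))
  p
}

#' Predict per-region injury for one case
#'
#' @param model a fitted [fit_model()] result.
#' @param qfvs a `qfv` or list of `qfv` objects (both schemes, in the
#'   training order).
#' @param hydro optional `hydro_features` for the case.
#' @param cut probability cut turning probabilities into labels
#'   (default 0.5; the BT family emits 0/1 probabilities so the cut is
#'   immaterial for it).
#' @return A `region_predictions` data.frame: `roi`, `scheme`,
#'   `probability`, `label`, with the hydrocephalus call as an attribute
#'   row (`roi == "hydrocephalus"`).
#' @export
predict_regions <- function(model, qfvs, hydro = NULL, cut = 0.5) {
  stopifnot(inherits(model, "location_model"))
  x <- build_feature_vector(model, qfvs, hydro)
  p <- as.numeric(predict_prob_matrix(model, x))
  rois <- names(model$fits)
  scheme <- if (!is.null(model$roi_scheme)) unname(model$roi_scheme[rois])
  else rep(NA_character_, length(rois))
  out <- data.frame(roi = rois, scheme = scheme, probability = p,
                    label = as.integer(p >= cut), stringsAsFactors = FALSE)
  if (!is.null(model$hydro_fit)) {
    ph <- clf_prob(model$hydro_fit,
                   x[, intersect(HYDRO_FEATURES, colnames(x)), drop = FALSE])
    out <- rbind(out, data.frame(roi = "hydrocephalus", scheme = "finding",
                                 probability = ph,
                                 label = as.integer(ph >= cut),
                                 stringsAsFactors = FALSE))
  } else if (model$family == "bt") {
    out <- rbind(out, data.frame(roi = "hydrocephalus", scheme = "finding",
                                 probability = NA_real_, label = NA_integer_,
                                 stringsAsFactors = FALSE))
  }
  class(out) <- c("region_predictions", class(out))
  out
}

#' Evaluate a fitted model on a labeled cohort
#'
#' @param model a [fit_model()] result.
#' @param cohort a [stroke_cohort()] (held-out test set).
#' @param cut probability cut for labels (default 0.5).
#' @return data.frame, one row per region (plus hydrocephalus when the
#'   family supports it): `roi`, `family`, `n_positive`, and the
#'   [classification_metrics()] columns.
#' @export
evaluate_model <- function(model, cohort, cut = 0.5) {
  stopifnot(inherits(model, "location_model"),
            inherits(cohort, "stroke_cohort"))
  probs <- predict_prob_matrix(model, cohort$features)
  rows <- lapply(colnames(cohort$labels), function(roi) {
    truth <- cohort$labels[, roi]
    m <- suppressWarnings(
      classification_metrics(truth, as.integer(probs[, roi] >= cut)))
    cbind(data.frame(roi = roi, family = model$family,
                     n_positive = sum(truth), stringsAsFactors = FALSE), m)
  })
  out <- do.call(rbind, rows)
  if (!is.null(model$hydro_fit)) {
    xh <- cohort$features[, intersect(HYDRO_FEATURES,
                                      colnames(cohort$features)),
                          drop = FALSE]
    ph <- clf_prob(model$hydro_fit, xh)
    m <- suppressWarnings(
      classification_metrics(cohort$hydro, as.integer(ph >= cut)))
    out <- rbind(out, cbind(data.frame(roi = "hydrocephalus",
                                       family = model$family,
                                       n_positive = sum(cohort$hydro),
                                       stringsAsFactors = FALSE), m))
  }
  rownames(out) <- NULL
  out
}

#' Default hyperparameter search grids
#'
#' The searchable defaults used when no grid is supplied: modest,
#' documented grids per family (the selection harness accepts arbitrary
#' grids).
#'
#' @param family model family.
#' @return list of named hyperparameter lists.
#' @export
default_hyper_grid <- function(family) {
  switch(match.arg(family, MODEL_FAMILIES),
         bt = list(list()),
         lda = list(list()),
         qda = list(list()),
         rf = lapply(c(100L, 300L, 500L), function(nt) list(ntree = nt)),
         knn = lapply(c(3L, 5L, 11L, 21L), function(k) list(k = k)),
         svm = do.call(c, lapply(c(0.1, 1, 10), function(cost)
           list(list(kernel = "radial", cost = cost)))),
         mlp = lapply(c(4L, 8L, 16L), function(s)
           list(size = s, decay = 1e-3)))
}

#' Save / load a fitted location model
#'
#' Writes a versioned archive directory: `model.json` with the family,
#' feature ordering, hyperparameters and model card, and `model.rds` with
#' the fitted per-region classifier objects.
#'
#' @param model a `location_model`.
#' @param dir archive directory (created if needed).
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "location_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = 1L, family = model$family,
               feature_names = model$feature_names,
               hyperparams = model$hyperparams,
               seed = model$seed, model_card = model$model_card)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  model <- readRDS(file.path(dir, "model.rds"))
  stopifnot(inherits(model, "location_model"))
  model
}
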
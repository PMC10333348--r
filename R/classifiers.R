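# Internal per-region binary classifiers over a numeric feature matrix.
# Each family exposes two verbs: clf_fit(family, x, y, hp, seed) and
# clf_prob(clf, x) returning P(injured). Families mirror the model set of
# the harness: BT (own-component threshold), LDA, QDA, RF, KNN, SVM, MLP,
# plus an internal constant (prevalence) predictor for degenerate regions.

MODEL_FAMILIES <- c("bt", "lda", "qda", "rf", "knn", "svm", "mlp")

# run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards so pipeline determinism never depends on call
# order
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic child seeds derived from a master seed (kept < 2^31)
derive_seed <- function(seed, ...) {
  key <- c(as.integer(seed), unlist(lapply(list(...), function(v) {
    if (is.character(v)) utf8ToInt(paste(v, collapse = "")) else as.integer(v)
  })))
  s <- 0
  for (k in key) s <- (s * 69069 + (k %% 65011)) %% 2147483629
  as.integer(s) + 1L
}

# stratified fold assignment: positives and negatives are spread over folds
# separately so severe class imbalance still yields usable folds
stratified_folds <- function(y, k, seed) {
  with_local_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

drop_constant_cols <- function(x) {
  keep <- apply(x, 2, function(col) stats::var(col) > 0)
  if (!any(keep)) stop("all feature columns are constant")
  x[, keep, drop = FALSE]
}

clf_fit <- function(family, x, y, hp = list(), seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2L && family != "constant")
    stop("single-class labels: fit a constant predictor instead")
  obj <- switch(
    family,
    constant = list(prob = mean(y)),
    bt = {
      stopifnot(!is.null(hp$feature))
      thr <- if (!is.null(hp$threshold)) hp$threshold else
        fit_binary_threshold(x[, hp$feature], y,
                             grid = hp$grid %||% seq(0, 1, by = 0.01),
                             folds = hp$folds %||% 5L, seed = seed)
      list(feature = hp$feature, threshold = thr)
    },
    lda = {
      xk <- drop_constant_cols(x)
      list(fit = MASS::lda(xk, grouping = factor(y, levels = 0:1)),
           cols = colnames(xk))
    },
    qda = {
      xk <- drop_constant_cols(x)
      list(fit = MASS::qda(xk, grouping = factor(y, levels = 0:1)),
           cols = colnames(xk))
    },
    rf = with_local_seed(seed, {
      list(fit = randomForest::randomForest(
        x, factor(y, levels = 0:1),
        ntree = hp$ntree %||% 300L,
        mtry = hp$mtry %||% max(1L, floor(sqrt(ncol(x)))),
        nodesize = hp$nodesize %||% 1L))
    }),
    knn = list(x = x, y = y, k = hp$k %||% 5L),
    svm = with_local_seed(seed, {
      xk <- drop_constant_cols(x)
      list(fit = e1071::svm(xk, factor(y, levels = 0:1),
                            kernel = hp$kernel %||% "radial",
                            cost = hp$cost %||% 1,
                            gamma = hp$gamma %||% (1 / ncol(xk)),
                            probability = TRUE),
           cols = colnames(xk))
    }),
    mlp = with_local_seed(seed, {
      ctr <- scale(x)
      ctr[is.nan(ctr)] <- 0
      list(fit = nnet::nnet(ctr, y, size = hp$size %||% 8L,
                            decay = hp$decay %||% 1e-3,
                            maxit = hp$maxit %||% 300L,
                            entropy = TRUE, trace = FALSE),
           center = attr(ctr, "scaled:center"),
           scale = attr(ctr, "scaled:scale"))
    }),
    stop("unknown model family: ", family)
  )
  structure(c(obj, list(family = family)), class = "roi_classifier")
}

clf_prob <- function(clf, x) {
  x <- as.matrix(x)
  p <- switch(
    clf$family,
    constant = rep(clf$prob, nrow(x)),
    bt = as.numeric(x[, clf$feature] >= clf$threshold),
    lda = stats::predict(clf$fit, x[, clf$cols, drop = FALSE])$posterior[, "1"],
    qda = stats::predict(clf$fit, x[, clf$cols, drop = FALSE])$posterior[, "1"],
    rf = stats::predict(clf$fit, x, type = "prob")[, "1"],
    knn = {
      pred <- class::knn(clf$x, x, factor(clf$y, levels = 0:1),
                         k = min(clf$k, nrow(clf$x)), prob = TRUE)
      pwin <- attr(pred, "prob")
      ifelse(pred == "1", pwin, 1 - pwin)
    },
    svm = {
      pr <- stats::predict(clf$fit, x[, clf$cols, drop = FALSE],
                           probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    mlp = {
      sc <- sweep(sweep(x, 2, clf$center), 2,
                  ifelse(clf$scale == 0, 1, clf$scale), "/")
      as.numeric(stats::predict(clf$fit, sc))
    },
    stop("unknown model family: ", clf$family)
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
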
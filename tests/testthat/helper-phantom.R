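# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# small phantom for geometry-level tests
phantom32 <- function() fixture("ph32", function()
  make_phantom_atlas(shape = c(32, 32, 32), n_art_pairs = 2,
                     n_str_pairs = 3, seed = 101))

# full-size phantom backing the cohort fixtures
phantom64 <- function() fixture("ph64", function()
  make_phantom_atlas(seed = 3))

# the default synthetic cohort at study-condition defaults (n = 400,
# 5% label noise), split 75/25; clean-truth test labels kept alongside
default_cohort_split <- function() fixture("cohort400", function() {
  ph <- phantom64()
  coh <- make_cohort(ph$arterial, ph$structural, seed = 2024)
  train <- cohort_subset(coh, 1:300)
  test <- cohort_subset(coh, 301:400)
  test_clean <- stroke_cohort(test$features, test$meta$labels_clean,
                              test$meta$hydro_clean, test$roi_scheme)
  list(full = coh, train = train, test = test, test_clean = test_clean)
})

# a lighter cohort for model-behaviour tests that do not need n = 400
small_cohort <- function() fixture("cohort80", function() {
  ph <- phantom32()
  make_cohort(ph$arterial, ph$structural, n = 80, seed = 77)
})

# fabricate qfv / hydro_features objects from a cohort row so
# predict_regions can be exercised without re-running the imaging path
qfv_from_row <- function(coh, i) {
  f <- coh$features[i, ]
  rois <- colnames(coh$labels)
  structure(list(scheme = "combined", fractions = f[rois],
                 lesion_volume_ml = exp(f[["lesion_volume_log_ml"]]),
                 lesion_volume_log_ml = f[["lesion_volume_log_ml"]],
                 roi_voxels = setNames(rep(1L, length(rois)), rois),
                 lesion_voxels = setNames(rep(0L, length(rois)), rois),
                 unassigned_voxels = 0L),
            class = "qfv")
}

hydro_from_row <- function(coh, i) {
  structure(list(gamma_olvr = unname(coh$features[i, "gamma_olvr"]),
                 gamma_ilvr = unname(coh$features[i, "gamma_ilvr"]),
                 csf_threshold = 0.0018),
            class = "hydro_features")
}

# hand-rolled balanced accuracy + F1 (independent of the package metrics)
oracle_bacc_f1 <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0); tn <- sum(truth == 0 & pred == 0)
  sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  (sens + spec) / 2 + f1
}

# exhaustive grid evaluation of the BT rule on fixed folds
oracle_bt_threshold <- function(fractions, labels, grid, fold) {
  scores <- vapply(grid, function(t) {
    mean(vapply(sort(unique(fold)), function(f) {
      sel <- fold == f
      oracle_bacc_f1(labels[sel], as.integer(fractions[sel] >= t))
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(scores)]
}
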
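test_that("BT threshold matches the exhaustive grid-search oracle", {
  set.seed(10)
  n <- 60
  labels <- rep(c(1L, 0L), each = n / 2)
  fractions <- ifelse(labels == 1L, runif(n / 2, 0.30, 0.90),
                      runif(n / 2, 0.00, 0.09))
  fractions[labels == 0L][1] <- 0.09   # a negative exactly at the boundary
  grid <- seq(0, 1, by = 0.01)
  thr <- fit_binary_threshold(fractions, labels, grid, folds = 5, seed = 4)
  # separable data: minimal grid point with perfect fold scores
  expect_gt(thr, 0.09)
  expect_lte(thr, 0.30)
  fold <- strokescribe:::stratified_folds(labels, 5, 4)
  expect_identical(thr, oracle_bt_threshold(fractions, labels, grid, fold))

  # oracle identity on noisy, non-separable labels too
  set.seed(11)
  fr2 <- runif(80)
  lb2 <- as.integer(fr2 + rnorm(80, 0, 0.3) > 0.5)
  fold2 <- strokescribe:::stratified_folds(lb2, 5, 9)
  expect_identical(fit_binary_threshold(fr2, lb2, grid, folds = 5, seed = 9),
                   oracle_bt_threshold(fr2, lb2, grid, fold2))

  expect_error(fit_binary_threshold(fr2, rep(1L, 80)), "single-class")
})

test_that("two-stage hyperparameter selection follows the protocol", {
  expect_identical(select_hyperparameters("knn", list(list(k = 3L)),
                                          matrix(0, 2, 1), c(0L, 1L)),
                   list(k = 3L))             # one-entry grid skips stage 2

  # separable cohort: tight neighbourhoods should beat k = 51
  set.seed(21)
  n <- 60
  y <- rep(0:1, each = n / 2)
  x <- cbind(f1 = y + rnorm(n, 0, 0.2), f2 = rnorm(n))
  grid <- list(list(k = 1L), list(k = 5L), list(k = 51L))
  won <- select_hyperparameters("knn", grid, x, y, seed = 31)
  expect_true(won$k %in% c(1L, 5L))
  won2 <- select_hyperparameters("knn", grid, x, y, seed = 31)
  expect_identical(won$k, won2$k)            # same seed, same winner
})

test_that("fit_model delegates BT to the per-region threshold fit", {
  coh <- small_cohort()
  m <- fit_model(coh, "bt", seed = 6)
  roi <- colnames(coh$labels)[1]
  expect_identical(
    m$fits[[roi]]$threshold,
    fit_binary_threshold(coh$features[, roi], coh$labels[, roi],
                         seed = strokescribe:::derive_seed(6, 1L)))
  expect_null(m$hydro_fit)                   # BT has no hydrocephalus model
  preds <- predict_regions(m, qfv_from_row(coh, 1), hydro_from_row(coh, 1))
  expect_true(is.na(preds$probability[preds$roi == "hydrocephalus"]))

  # fraction exactly at the threshold classifies as injured (>= rule)
  x <- coh$features[1, , drop = FALSE]
  x[, roi] <- m$fits[[roi]]$threshold
  expect_equal(strokescribe:::clf_prob(m$fits[[roi]], x), 1)
})

test_that("constant-label regions fall back to flagged prevalence predictors", {
  coh <- small_cohort()
  labs <- coh$labels
  labs[, 1] <- 0L; labs[1, 1] <- 1L          # one lone positive
  degen <- stroke_cohort(coh$features, labs, coh$hydro, coh$roi_scheme)
  m <- fit_model(degen, "rf", seed = 2)
  roi <- colnames(labs)[1]
  expect_match(m$model_card$flag[m$model_card$roi == roi], "constant")
  p <- strokescribe:::clf_prob(m$fits[[roi]], coh$features[1:5, ])
  expect_equal(p, rep(mean(labs[, 1]), 5))
})

test_that("every family fits and emits probabilities in [0, 1]", {
  coh <- small_cohort()
  # compact, well-conditioned feature set for the covariance-based families
  feats <- coh$features[, c(colnames(coh$labels)[1:3],
                            "lesion_volume_log_ml", "gamma_olvr")]
  feats <- feats + matrix(rnorm(length(feats), 0, 1e-4), nrow(feats))
  coh2 <- stroke_cohort(feats, coh$labels[, 1:3, drop = FALSE], coh$hydro)
  case <- feats[5, ]
  for (family in c("lda", "qda", "rf", "knn", "svm", "mlp")) {
    m <- fit_model(coh2, family, seed = 14)
    p <- strokescribe:::predict_prob_matrix(m, feats)
    expect_true(all(p >= 0 & p <= 1), label = family)
  }
})

test_that("seeded RF fits give bit-identical predictions", {
  coh <- small_cohort()
  m1 <- fit_model(coh, "rf", seed = 99)
  m2 <- fit_model(coh, "rf", seed = 99)
  p1 <- strokescribe:::predict_prob_matrix(m1, coh$features)
  p2 <- strokescribe:::predict_prob_matrix(m2, coh$features)
  expect_identical(p1, p2)
})

test_that("classification metrics match hand-computed contingency values", {
  truth <- c(rep(1, 4), rep(0, 6))
  pred <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)   # TP=3 FP=1 FN=1 TN=5
  m <- classification_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$bacc, (0.75 + 5 / 6) / 2)  # 0.7917
  expect_equal(m$f1, 0.75)
  expect_equal(m$kappa, 0.5833, tolerance = 1e-4)

  perfect <- classification_metrics(truth, truth)
  expect_equal(unlist(perfect), c(bacc = 1, f1 = 1, precision = 1,
                                  sensitivity = 1, kappa = 1))

  expect_warning(allneg <- classification_metrics(c(1, 1, 0, 0), rep(0, 4)),
                 "precision")
  expect_equal(allneg$bacc, 0.5)
  expect_equal(allneg$f1, 0)
})

test_that("a random predictor scores at chance level", {
  set.seed(123)
  n <- 10000
  truth <- rbinom(n, 1, 0.5)
  pred <- rbinom(n, 1, 0.5)
  m <- classification_metrics(truth, pred)
  se <- 1 / (2 * sqrt(n))                    # rough SE of BACC at p = 0.5
  expect_lt(abs(m$bacc - 0.5), 3 * se)
  expect_lt(abs(m$kappa), 3 * 2 * se)        # independence: kappa near 0
})

test_that("ICC3 matches the two-way ANOVA decomposition", {
  ratings <- cbind(c(2, 4, 6, 8), c(2, 4, 6, 8))
  expect_equal(icc3(ratings), 1.0)
  expect_equal(icc3(rbind(c(1, 2), c(2, 1))), -1.0)
  # consistency form: shifting one rater's column changes nothing
  set.seed(5)
  r <- matrix(rnorm(30), 10, 3)
  shifted <- r; shifted[, 2] <- shifted[, 2] + 5
  expect_equal(icc3(r), icc3(shifted))
  expect_error(icc3(matrix(1, 3, 2)), "undefined")
})

test_that("model archives round-trip through save/load", {
  coh <- small_cohort()
  m <- fit_model(coh, "rf", seed = 1)
  td <- withr::local_tempdir()
  save_model(m, td)
  expect_true(file.exists(file.path(td, "model.json")))
  back <- load_model(td)
  expect_identical(
    strokescribe:::predict_prob_matrix(back, coh$features[1:5, ]),
    strokescribe:::predict_prob_matrix(m, coh$features[1:5, ]))
})
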
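test_that("phantom parcellations are bilateral, space-filling and seeded", {
  ph <- phantom64()
  brain <- ph$brain$values == 1L
  for (lv in list(ph$arterial, ph$structural)) {
    expect_true(all((lv$labels > 0L) == brain))   # regions partition the brain

    # homologous halves share one label and approximately one volume
    g <- lv$grid
    idx <- which(lv$labels > 0L, arr.ind = TRUE)
    wx <- strokescribe:::world_coords(g, idx)[, 1]
    lab <- lv$labels[idx]
    paired <- setdiff(lv$table$id, max(lv$table$id))  # last id is midline
    for (id in paired) {
      nr <- sum(lab == id & wx > 0); nl <- sum(lab == id & wx < 0)
      expect_lt(abs(nr - nl) / max(nr, nl), 0.05)
    }
  }
  vent_ids <- sort(unique(ph$ventricles$labels[ph$ventricles$labels > 0]))
  expect_identical(as.integer(vent_ids), 1:5)       # five LV sub-regions

  ph2 <- make_phantom_atlas(seed = 3)
  expect_identical(ph2$arterial$labels, ph$arterial$labels)
  expect_identical(ph2$structural$labels, ph$structural$labels)
})

test_that("lesion growth hits requested overlaps and spills into neighbours", {
  ph <- phantom32()
  les <- make_lesion(ph$arterial, c(territory_1 = 0.61), tol = 0.02,
                     seed = 40)
  q <- extract_qfv(les, ph$arterial)
  expect_gte(unname(q$fractions["territory_1"]), 0.59)
  expect_lte(unname(q$fractions["territory_1"]), 0.63)
  expect_true(all(q$fractions[setdiff(names(q$fractions), "territory_1")]
                  <= 0.02))

  # heavy targeting of one region must coalesce into >= 1 spatial neighbour
  les9 <- make_lesion(ph$arterial, c(territory_1 = 0.9), seed = 41)
  q9 <- extract_qfv(les9, ph$arterial)
  others <- q9$fractions[setdiff(names(q9$fractions), "territory_1")]
  expect_gt(sum(others), 0)

  expect_error(make_lesion(ph$arterial, numeric(0)), "empty target")
  expect_identical(make_lesion(ph$arterial, c(territory_1 = 0.3), seed = 7),
                   make_lesion(ph$arterial, c(territory_1 = 0.3), seed = 7))
})

test_that("ADC phantoms respond monotonically to ventricle scaling", {
  ph <- phantom32()
  sp <- build_ventricle_strips(ph$ventricles, width = 2)
  gam <- function(s) hydro_features(
    make_adc_phantom(ph$ventricles, ventricle_scale = s, seed = 9), sp)
  expect_gte(gam(1.0)$gamma_ilvr, 0.95)
  expect_lt(gam(1.5)$gamma_olvr, gam(1.0)$gamma_olvr)
  expect_lt(gam(0.5)$gamma_ilvr, gam(1.0)$gamma_ilvr)
  expect_identical(gam(1.2), gam(1.2))      # pure function of the seed
})

test_that("cohorts honour prevalence, noise and neighbour-coalescence", {
  coh <- small_cohort()                      # n = 80, uniform prevalence
  art <- colnames(coh$labels)[coh$roi_scheme[colnames(coh$labels)] ==
                                "arterial"]
  n <- nrow(coh$features)
  p0 <- 1 / length(art)
  for (r in art) {
    k <- sum(coh$meta$primary == r)
    ci <- qbinom(c(0.025, 0.975), n, p0)     # binomial 95% band
    expect_gte(k, ci[1]); expect_lte(k, ci[2])
  }

  # labels with noise 0 are a deterministic function of the features
  ph <- phantom32()
  c0 <- make_cohort(ph$arterial, ph$structural, n = 20, noise = 0,
                    seed = 55)
  expect_identical(unname(c0$labels), unname(c0$meta$labels_clean))
  rule <- (c0$features[, colnames(c0$labels)] >= c0$meta$tau) * 1L
  expect_identical(unname(c0$labels), unname(rule))

  # observed flip rate consistent with the requested 5% noise
  flips <- mean(coh$labels != coh$meta$labels_clean)
  ciN <- qbinom(c(0.025, 0.975), length(coh$labels), 0.05) / length(coh$labels)
  expect_gte(flips, ciN[1]); expect_lte(flips, ciN[2])

  # spatially neighbouring regions have positively correlated labels
  adj <- strokescribe:::roi_adjacency(ph$arterial)
  cors <- unlist(lapply(art, function(r) {
    vapply(intersect(adj[[r]], art), function(s)
      suppressWarnings(cor(coh$labels[, r], coh$labels[, s])), numeric(1))
  }))
  cors <- cors[!is.na(cors)]
  expect_gt(mean(cors), 0)

  expect_error(make_cohort(ph$arterial, ph$structural, n = 10), "at least 20")
})

test_that("cohorts are pure functions of the seed", {
  ph <- phantom32()
  c1 <- make_cohort(ph$arterial, ph$structural, n = 20, seed = 70)
  c2 <- make_cohort(ph$arterial, ph$structural, n = 20, seed = 70)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$hydro, c2$hydro)
})

test_that("severe class imbalance still yields a usable cohort and model", {
  ph <- phantom32()
  art <- ph$arterial$table$name
  prev <- setNames(rep(1, length(art)), art)
  prev["territory_2"] <- 0.05 * sum(prev[-2]) / (1 - 0.05)  # ~5% primaries
  coh <- make_cohort(ph$arterial, ph$structural, n = 40, prevalence = prev,
                     seed = 91)
  m <- fit_model(coh, "rf", seed = 1)        # must not error; may flag
  expect_s3_class(m, "location_model")
})
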
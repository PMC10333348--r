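preds_df <- function(roi, p) {
  data.frame(roi = roi, scheme = "x", probability = p,
             label = as.integer(p >= 0.5), stringsAsFactors = FALSE)
}

test_that("hemisphere attribution uses world x with a bilateral band", {
  ph <- phantom32()
  g <- ph$arterial$grid
  right <- array(0L, g$shape); right[24:28, 14:18, 14:18] <- 1L
  expect_identical(determine_hemisphere(lesion_mask(right, g)), "right")
  left <- array(0L, g$shape); left[5:9, 14:18, 14:18] <- 1L
  expect_identical(determine_hemisphere(lesion_mask(left, g)), "left")

  both <- right; both[5:9, 14:18, 14:18] <- 1L        # 50/50
  expect_identical(determine_hemisphere(lesion_mask(both, g)), "bilateral")

  # 95/5 split stays single-sided at the default 0.10 band
  skew <- array(0L, g$shape)
  skew[20:29, 10:20, 10:20] <- 1L                     # 1210 right voxels
  skew[4, 10:17, 10:17] <- 1L                         # 64 left voxels (~5%)
  expect_identical(determine_hemisphere(lesion_mask(skew, g)), "right")
  expect_identical(determine_hemisphere(lesion_mask(skew, g),
                                        bilateral_fraction = 0.04),
                   "bilateral")
  expect_error(determine_hemisphere(lesion_mask(array(0L, g$shape), g)),
               "empty")
})

test_that("ASPECTS counts involved regions against tau and is monotone", {
  mk <- function(fr) structure(
    list(scheme = "aspects", fractions = setNames(fr, paste0("r", 1:10)),
         lesion_volume_ml = 1, lesion_volume_log_ml = 0,
         roi_voxels = setNames(rep(100L, 10), paste0("r", 1:10)),
         lesion_voxels = setNames(as.integer(fr * 100), paste0("r", 1:10)),
         unassigned_voxels = 0L),
    class = "qfv")
  expect_equal(compute_aspects(mk(rep(0, 10))), 10L)
  expect_equal(compute_aspects(mk(rep(0.5, 10))), 0L)
  expect_equal(compute_aspects(mk(c(rep(0.3, 8), 0.01, 0.04))), 2L)
  expect_equal(compute_aspects(mk(c(0.05, rep(0, 9)))), 9L)  # >= rule at tau

  fr <- runif(10, 0, 0.2)
  grown <- pmin(fr + runif(10, 0, 0.2), 1)
  expect_lte(compute_aspects(mk(grown)), compute_aspects(mk(fr)))

  bad <- mk(rep(0, 10)); bad$fractions <- bad$fractions[1:9]
  expect_error(compute_aspects(bad), "10 regions")
})

test_that("the worked large-MCA-infarct example renders verbatim", {
  pa <- preds_df(c("ACA", "MCA", "PCA", "cerebellar", "basilar",
                   "Lateral Lenticulostriate",
                   "Choroidal and Thalamoperforating"),
                 c(0.01, 0.98, 0.05, 0.01, 0, 0.54, 0.05))
  ps <- preds_df(c("basal ganglia", "deep white matter", "cerebellum",
                   "frontal lobe", "insula", "internal capsule", "brainstem",
                   "occipital lobe", "parietal lobe", "temporal lobe",
                   "thalamus"),
                 c(0.72, 0.79, 0.01, 0.74, 0.81, 0.04, 0.14, 0.16, 0.86,
                   0.77, 0.09))
  rep <- render_report(pa, ps, hydro = FALSE, volume_ml = 165.195,
                       hemisphere = "right", aspects = 2)
  expect_identical(
    rep$text,
    paste0("Area of restricted diffusion within the right brain hemisphere,",
           " with 165.195 ml, in the territory of the middle cerebral artery",
           " and possibly Lateral Lenticulostriate. The area involves the",
           " following brain regions: basal ganglia, deep white matter,",
           " frontal lobe, insula, parietal lobe, and temporal lobe.",
           " There is no hydrocephalus. The predicted MCA-ASPECTS is 2."))
  expect_identical(rep$territories_asserted, "MCA")
  expect_identical(rep$territories_possible, "Lateral Lenticulostriate")
  expect_length(intersect(rep$territories_asserted,
                          rep$territories_possible), 0L)

  # determinism: identical fields render identical strings
  rep2 <- render_report(pa, ps, hydro = FALSE, volume_ml = 165.195,
                        hemisphere = "right", aspects = 2)
  expect_identical(rep$text, rep2$text)
})

test_that("the template degrades gracefully without territories", {
  pa <- preds_df("MCA", 0.1)
  ps <- preds_df("thalamus", 0.9)
  rep <- render_report(pa, ps, hydro = TRUE, volume_ml = 2.5,
                       hemisphere = "left", aspects = NULL)
  expect_identical(
    rep$text,
    paste0("Area of restricted diffusion within the left brain hemisphere,",
           " with 2.5 ml. The area involves the following brain regions:",
           " thalamus. There is hydrocephalus."))
})

test_that("rendered reports parse back to their fields and re-render", {
  cases <- list(
    list(pa = preds_df(c("ACA", "MCA"), c(0.95, 0.6)),
         ps = preds_df(c("insula", "thalamus"), c(0.8, 0.9)),
         hydro = TRUE, vol = 12.345, hemi = "bilateral", aspects = 7L),
    list(pa = preds_df("PCA", 0.55),
         ps = preds_df("occipital lobe", 0.99),
         hydro = FALSE, vol = 0.98, hemi = "left", aspects = NULL),
    list(pa = preds_df(c("basilar", "cerebellar"), c(0.9, 0.85)),
         ps = preds_df("cerebellum", 0.97),
         hydro = FALSE, vol = 165.195, hemi = "right", aspects = 10L))
  for (cs in cases) {
    rep <- render_report(cs$pa, cs$ps, cs$hydro, cs$vol, cs$hemi, cs$aspects)
    back <- parse_report(rep$text)
    expect_identical(back$text, rep$text)
    expect_identical(back$hemisphere, rep$hemisphere)
    expect_identical(back$structures, rep$structures)
    expect_identical(back$territories_asserted, rep$territories_asserted)
    expect_identical(back$territories_possible, rep$territories_possible)
    expect_equal(back$volume_ml, round(rep$volume_ml, 3))
    expect_identical(back$hydrocephalus, rep$hydrocephalus)
    expect_identical(back$aspects, rep$aspects)
  }
})
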
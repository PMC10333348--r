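#' Synthetic phantom atlases
#'
#' Generates a download-free stand-in for the template-space atlas pair:
#' an ellipsoidal brain mask carrying two space-filling bilateral
#' parcellations (an arterial-territory-like and a structural-like scheme,
#' Voronoi regions of midline-mirrored seed points so homologous halves
#' share one label and approximately one volume, plus one unpaired midline
#' region per scheme — the brainstem analogue), and a ventricle volume of
#' five lateral-ventricle sub-regions near the centre. Voronoi seeds keep
#' the spatial adjacency structure that lesion coalescence and the feature
#' analysis depend on.
#'
#' The grid affine centres world x = 0 on the midline (RAS), so hemisphere
#' attribution works on phantoms exactly as on template-space data.
#'
#' @param shape grid shape, minimum 32 per axis (default 64^3, 1 mm
#'   voxels).
#' @param n_art_pairs,n_str_pairs bilateral region pairs per scheme
#'   (defaults 4 and 6; minimum 2).
#' @param seed RNG seed; the phantom is a pure function of it.
#' @return list with `arterial`, `structural`, `ventricles`
#'   ([labeled_volume()]) and `brain` ([lesion_mask()]), all on one grid.
#' @export
make_phantom_atlas <- function(shape = c(64, 64, 64), n_art_pairs = 4L,
                               n_str_pairs = 6L, seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 32L)) stop("phantom grid must be at least 32 voxels per axis")
  if (n_art_pairs < 2L || n_str_pairs < 2L) stop("need at least 2 region pairs")
  affine <- diag(4)
  affine[1:3, 4] <- -(shape - 1) / 2     # world origin at the grid centre
  grid <- volume_grid(shape, affine)

  ctr <- (shape + 1) / 2                 # 1-based centre (x = ctr[1] is midline)
  ax <- seq_len(shape[1]); ay <- seq_len(shape[2]); az <- seq_len(shape[3])
  radii <- 0.42 * shape
  dist2 <- outer(outer(((ax - ctr[1]) / radii[1])^2,
                       ((ay - ctr[2]) / radii[2])^2, "+"),
                 ((az - ctr[3]) / radii[3])^2, "+")
  brain <- dist2 <= 1
  vox <- which(brain, arr.ind = TRUE)

  # one bilateral Voronoi parcellation: n seed pairs mirrored over the
  # midline plus one midline seed near the base (unpaired)
  parcellate <- function(n_pairs, scheme, midline_name, sub_seed) {
    with_local_seed(sub_seed, {
      cand <- vox[vox[, 1] >= ctr[1] + 2, , drop = FALSE]
      pick <- cand[sample(nrow(cand), n_pairs), , drop = FALSE]
      nearer <- matrix(Inf, nrow(vox), n_pairs + 1L)
      for (p in seq_len(n_pairs)) {
        s <- pick[p, ]
        m <- c(2 * ctr[1] - s[1], s[2], s[3])   # mirrored seed
        d1 <- (vox[, 1] - s[1])^2 + (vox[, 2] - s[2])^2 + (vox[, 3] - s[3])^2
        d2 <- (vox[, 1] - m[1])^2 + (vox[, 2] - m[2])^2 + (vox[, 3] - m[3])^2
        nearer[, p] <- pmin(d1, d2)
      }
      mid <- c(ctr[1], ctr[2] - 0.18 * shape[2], ctr[3] - 0.30 * shape[3])
      nearer[, n_pairs + 1L] <- 1.6 * ((vox[, 1] - mid[1])^2 +
        (vox[, 2] - mid[2])^2 + (vox[, 3] - mid[3])^2)
      lab <- max.col(-nearer, ties.method = "first")
      arr <- array(0L, shape)
      arr[vox] <- lab
      nm <- c(sprintf("%s_%d", scheme_stub(scheme), seq_len(n_pairs)),
              midline_name)
      labeled_volume(arr, grid,
                     data.frame(id = seq_len(n_pairs + 1L), name = nm,
                                scheme = scheme, stringsAsFactors = FALSE))
    })
  }
  arterial <- parcellate(n_art_pairs, "arterial", "territory_midline",
                         derive_seed(seed, "arterial"))
  structural <- parcellate(n_str_pairs, "structural", "brainstem",
                           derive_seed(seed, "structural"))

  # five lateral-ventricle sub-regions: mirrored bodies and anterior horns
  # plus one posterior midline part
  box <- function(fx, fy, fz) {
    rng <- function(f, s) max(1L, round(f[1] * s)):min(s, round(f[2] * s))
    as.matrix(expand.grid(rng(fx, shape[1]), rng(fy, shape[2]),
                          rng(fz, shape[3])))
  }
  mirror_x <- function(fx) sort((shape[1] + 1 - rev(range(fx * shape[1]))) /
                                  shape[1])
  vent <- array(0L, shape)
  vent[box(c(0.40, 0.46), c(0.42, 0.58), c(0.45, 0.60))] <- 1L
  vent[box(mirror_x(c(0.40, 0.46)), c(0.42, 0.58), c(0.45, 0.60))] <- 2L
  vent[box(c(0.40, 0.46), c(0.60, 0.70), c(0.48, 0.58))] <- 3L
  vent[box(mirror_x(c(0.40, 0.46)), c(0.60, 0.70), c(0.48, 0.58))] <- 4L
  vent[box(c(0.47, 0.54), c(0.30, 0.41), c(0.45, 0.56))] <- 5L
  vent[!brain] <- 0L
  ventricles <- labeled_volume(
    vent, grid,
    data.frame(id = 1:5,
               name = c("lv_body_left", "lv_body_right", "lv_horn_left",
                        "lv_horn_right", "lv_posterior"),
               scheme = "ventricle", stringsAsFactors = FALSE))

  list(arterial = arterial, structural = structural,
       ventricles = ventricles, brain = lesion_mask(brain, grid))
}

scheme_stub <- function(scheme) {
  switch(scheme, arterial = "territory", structural = "structure", scheme)
}

#' Grow a lesion with known per-region overlap
#'
#' Grows a roughly ball-shaped, coalescent lesion outward from a seeded
#' voxel of the most-targeted region until every targeted region's overlap
#' fraction is within `tol` of its target. Voxels are taken in order of
#' jittered distance from the seed point; each targeted region contributes
#' its nearest voxels up to quota, and untargeted regions inside the
#' growth radius may contribute at most `tol` of their voxels (the
#' spillover that makes phantom lesions coalescent, like real infarcts
#' crossing atlas boundaries).
#'
#' @param atlas a [labeled_volume()]; growth is confined to its labeled
#'   (brain) voxels.
#' @param targets named numeric vector: region name to target overlap
#'   fraction in (0, 1].
#' @param tol tolerance on achieved fractions (default 0.02); untargeted
#'   regions stay at or below it.
#' @param seed RNG seed (seed voxel and distance jitter).
#' @return A [lesion_mask()] with the requested overlap profile.
#' @export
make_lesion <- function(atlas, targets, tol = 0.02, seed = 1L) {
  stopifnot(inherits(atlas, "labeled_volume"))
  if (length(targets) == 0L)
    stop("empty target map: a lesion must target at least one region")
  if (tol <= 0) stop("`tol` must be > 0")
  if (is.null(names(targets)) || !all(names(targets) %in% atlas$table$name))
    stop("targets must be named after atlas regions")
  if (any(targets <= 0 | targets > 1))
    stop("target fractions must be in (0, 1]")

  tab <- atlas$table
  sizes <- stats::setNames(roi_voxel_counts(atlas), tab$name)
  quota <- round(targets * sizes[names(targets)])
  if (any(quota < 1L))
    stop("targets too small to realize on this atlas (quota < 1 voxel)")

  vox <- which(atlas$labels > 0L, arr.ind = TRUE)
  lab <- atlas$labels[vox]
  name_of <- stats::setNames(tab$name, tab$id)
  vname <- name_of[as.character(lab)]

  with_local_seed(seed, {
    primary <- names(targets)[which.max(targets)]
    own <- which(vname == primary)
    seed_vox <- vox[own[sample(length(own), 1L)], ]
    d <- sqrt((vox[, 1] - seed_vox[1])^2 + (vox[, 2] - seed_vox[2])^2 +
                (vox[, 3] - seed_vox[3])^2) + stats::runif(nrow(vox), 0, 0.75)

    sel <- logical(nrow(vox))
    radius_needed <- 0
    for (r in names(targets)) {
      ir <- which(vname == r)
      if (quota[r] > length(ir)) stop("unreachable target for region ", r)
      ord <- ir[order(d[ir])][seq_len(quota[r])]
      sel[ord] <- TRUE
      radius_needed <- max(radius_needed, d[ord[quota[r]]])
    }
    for (r in setdiff(tab$name, names(targets))) {
      ir <- which(vname == r & d <= radius_needed)
      cap <- floor(tol * sizes[r])
      if (length(ir) > cap) ir <- ir[order(d[ir])][seq_len(cap)]
      sel[ir] <- TRUE
    }
    arr <- array(0L, atlas$grid$shape)
    arr[vox[sel, , drop = FALSE]] <- 1L
    mask <- lesion_mask(arr, atlas$grid)

    achieved <- extract_qfv(mask, atlas)$fractions[names(targets)]
    if (any(abs(achieved - targets) > tol))
      stop("unreachable targets: achieved fractions deviate beyond `tol`")
    mask
  })
}

#' Synthetic ADC phantom around a ventricle atlas
#'
#' CSF-like intensities (normal around 0.003 mm^2/s) inside a scaled
#' ventricle zone and parenchyma-like intensities (around 0.0008 mm^2/s)
#' elsewhere, truncated positive. `ventricle_scale` > 1 dilates the CSF
#' zone (emulating ventricular enlargement: the outside strip fills with
#' CSF, lowering gamma_olvr); < 1 erodes it (emulating compression: the
#' inside strip drains of CSF, lowering gamma_ilvr).
#'
#' @param ventricles a [labeled_volume()] with ventricle-scheme labels.
#' @param ventricle_scale CSF-zone scale factor > 0 (1 = normal).
#' @param seed RNG seed.
#' @return A [scalar_volume()] in mm^2/s.
#' @export
make_adc_phantom <- function(ventricles, ventricle_scale = 1.0, seed = 1L) {
  stopifnot(inherits(ventricles, "labeled_volume"))
  if (ventricle_scale <= 0) stop("`ventricle_scale` must be > 0")
  ids <- ventricles$table$id[ventricles$table$scheme == "ventricle"]
  zone <- array(ventricles$labels %in% ids, dim = ventricles$grid$shape)
  layers <- round(abs(ventricle_scale - 1) * 4)
  if (layers > 0) {
    zone <- if (ventricle_scale > 1) dilate_box(zone, layers)
    else erode_box(zone, layers)
  }
  with_local_seed(seed, {
    vals <- array(stats::rnorm(length(zone), 0.0008, 0.0001),
                  dim = dim(zone))
    ncsf <- sum(zone)
    if (ncsf) vals[zone] <- stats::rnorm(ncsf, 0.003, 0.0003)
    vals <- pmax(vals, 1e-6)
    scalar_volume(vals, ventricles$grid, units = "mm^2/s")
  })
}

#' Synthetic labeled cohort with known ground truth
#'
#' Emulates the training table behind the location models: each case draws
#' a primary arterial-like region (by `prevalence`), grows a coalescent
#' lesion there (optionally extending into spatial neighbours), extracts
#' the QFVs on both schemes, draws ventricular CSF ratios from a
#' hydrocephalus-dependent mixture, and labels every region by the true
#' overlap rule `fraction >= label_rule_tau`, flipping each label with
#' probability `noise` (annotator error). The pre-noise truth is kept in
#' `meta$labels_clean` / `meta$hydro_clean` so recovery of the generating
#' rule can be measured.
#'
#' @param arterial,structural the two [labeled_volume()] schemes on one
#'   grid (e.g. from [make_phantom_atlas()]).
#' @param n cohort size (>= 20; default 400).
#' @param prevalence named weights over arterial regions for the primary
#'   draw (default uniform).
#' @param label_rule_tau injury-labeling threshold on the true fraction
#'   (default 0.05).
#' @param noise per-label flip probability (default 0.05).
#' @param neighbor_prob probability each spatial neighbour of the primary
#'   region is co-targeted (default 0.6).
#' @param seed master RNG seed; the cohort is a pure function of it.
#' @return A [stroke_cohort()]; `meta` holds `primary`, `labels_clean`,
#'   `hydro_clean`, `tau`, `noise`.
#' @export
make_cohort <- function(arterial, structural, n = 400L, prevalence = NULL,
                        label_rule_tau = 0.05, noise = 0.05,
                        neighbor_prob = 0.6, seed = 1L) {
  stopifnot(inherits(arterial, "labeled_volume"),
            inherits(structural, "labeled_volume"))
  stop_if_incompatible(arterial$grid, structural$grid, "atlases")
  if (n < 20L) stop("cohort size must be at least 20")
  art_rois <- arterial$table$name
  str_rois <- structural$table$name
  if (is.null(prevalence))
    prevalence <- stats::setNames(rep(1, length(art_rois)), art_rois)
  prevalence <- prevalence[art_rois]
  adj <- roi_adjacency(arterial)

  feat_names <- c(art_rois, str_rois, "lesion_volume_log_ml",
                  "gamma_olvr", "gamma_ilvr")
  features <- matrix(NA_real_, n, length(feat_names),
                     dimnames = list(NULL, feat_names))
  clean <- matrix(NA_integer_, n, length(art_rois) + length(str_rois),
                  dimnames = list(NULL, c(art_rois, str_rois)))
  hydro_clean <- integer(n)
  primary <- character(n)

  for (i in seq_len(n)) {
    si <- derive_seed(seed, "case", i)
    draws <- with_local_seed(si, {
      pr <- sample(art_rois, 1L, prob = prevalence)
      tg <- stats::setNames(stats::runif(1, 0.15, 0.85), pr)
      nb <- adj[[pr]]
      if (length(nb)) {
        take <- nb[stats::runif(length(nb)) < neighbor_prob]
        if (length(take))
          tg <- c(tg, stats::setNames(stats::runif(length(take), 0.08, 0.40),
                                      take))
      }
      olvr <- stats::runif(1, 0.50, 1.00)
      ilvr <- stats::runif(1, 0.60, 1.00)
      list(primary = pr, targets = tg, olvr = olvr, ilvr = ilvr)
    })
    lesion <- make_lesion(arterial, draws$targets, tol = 0.02,
                          seed = derive_seed(seed, "lesion", i))
    qa <- extract_qfv(lesion, arterial)
    qs <- extract_qfv(lesion, structural)
    features[i, ] <- c(qa$fractions, qs$fractions, qa$lesion_volume_log_ml,
                       draws$olvr, draws$ilvr)
    clean[i, ] <- as.integer(c(qa$fractions, qs$fractions) >= label_rule_tau)
    hydro_clean[i] <- as.integer(draws$olvr < 0.78)
    primary[i] <- draws$primary
  }

  labels <- with_local_seed(derive_seed(seed, "noise"), {
    flip <- matrix(stats::runif(length(clean)) < noise, nrow(clean))
    out <- ifelse(flip, 1L - clean, clean)
    dimnames(out) <- dimnames(clean)
    out
  })
  hydro <- with_local_seed(derive_seed(seed, "hydronoise"), {
    flip <- stats::runif(n) < noise
    ifelse(flip, 1L - hydro_clean, hydro_clean)
  })

  stroke_cohort(
    features, labels, hydro,
    roi_scheme = stats::setNames(
      c(rep("arterial", length(art_rois)), rep("structural", length(str_rois))),
      c(art_rois, str_rois)),
    meta = list(primary = primary, labels_clean = clean,
                hydro_clean = as.integer(hydro_clean),
                tau = label_rule_tau, noise = noise, seed = seed))
}

# spatial adjacency of atlas regions via 6-neighbourhood label contacts
roi_adjacency <- function(atlas) {
  lab <- atlas$labels
  pairs <- NULL
  for (axis in 1:3) {
    sh <- shift3(lab, axis, 1L, fill = 0L)
    touch <- lab > 0L & sh > 0L & lab != sh
    if (any(touch))
      pairs <- rbind(pairs, unique(cbind(lab[touch], sh[touch])))
  }
  pairs <- unique(pairs)
  name_of <- stats::setNames(atlas$table$name, atlas$table$id)
  out <- lapply(atlas$table$id, function(id) {
    nb <- unique(c(pairs[pairs[, 1] == id, 2], pairs[pairs[, 2] == id, 1]))
    unname(name_of[as.character(nb)])
  })
  stats::setNames(out, atlas$table$name)
}
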
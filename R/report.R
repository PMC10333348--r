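#' Attribute the lesion to a hemisphere
#'
#' Lesion voxels are mapped through the grid affine to world space (RAS;
#' x > 0 is the right hemisphere). If the minor side holds at least
#' `bilateral_fraction` of the lesion voxels the lesion is called
#' bilateral, else the major side wins. Voxels exactly on the midline
#' (world x = 0) count toward neither side.
#'
#' @param mask a nonempty [lesion_mask()].
#' @param bilateral_fraction minor-side fraction for a bilateral call
#'   (default 0.10).
#' @return `"left"`, `"right"` or `"bilateral"`.
#' @export
determine_hemisphere <- function(mask, bilateral_fraction = 0.10) {
  stopifnot(inherits(mask, "lesion_mask"))
  idx <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty lesion mask")
  wx <- world_coords(mask$grid, idx)[, 1]
  nr <- sum(wx > 0); nl <- sum(wx < 0)
  if (nr + nl == 0L) return("bilateral")   # all voxels on the midline
  minor <- min(nr, nl) / (nr + nl)
  if (minor >= bilateral_fraction) "bilateral"
  else if (nr >= nl) "right" else "left"
}

#' MCA-ASPECTS from an ASPECTS-scheme QFV
#'
#' Starts at 10 and subtracts one point for every ASPECTS region whose
#' injury fraction reaches the involvement threshold `tau`. Adding lesion
#' voxels can only decrease the score.
#'
#' @param qfv_aspects a `qfv` over exactly the 10 ASPECTS regions
#'   (caudate, lentiform nucleus, internal capsule, insular ribbon, M1-M6).
#' @param tau involvement threshold on the fraction (default 0.05).
#' @return Integer score in 0..10.
#' @export
compute_aspects <- function(qfv_aspects, tau = 0.05) {
  stopifnot(inherits(qfv_aspects, "qfv"))
  if (length(qfv_aspects$fractions) != 10L)
    stop("ASPECTS requires exactly 10 regions, got ",
         length(qfv_aspects$fractions))
  10L - sum(qfv_aspects$fractions >= tau)
}

# report phrases for the standard arterial-territory names; territories not
# listed render under their atlas name unchanged
TERRITORY_PHRASES <- c(
  ACA = "the anterior cerebral artery",
  MCA = "the middle cerebral artery",
  PCA = "the posterior cerebral artery",
  cerebellar = "the cerebellar arteries",
  basilar = "the basilar artery"
)

territory_phrase <- function(name) {
  out <- as.character(name)
  hit <- out %in% names(TERRITORY_PHRASES)
  out[hit] <- TERRITORY_PHRASES[out[hit]]
  out
}

phrase_to_territory <- function(phrase) {
  rev_map <- stats::setNames(names(TERRITORY_PHRASES), TERRITORY_PHRASES)
  out <- as.character(phrase)
  hit <- out %in% names(rev_map)
  out[hit] <- rev_map[out[hit]]
  out
}

oxford_join <- function(x) {
  n <- length(x)
  if (n == 0L) ""
  else if (n == 1L) x
  else if (n == 2L) paste(x, collapse = " and ")
  else paste0(paste(x[-n], collapse = ", "), ", and ", x[n])
}

format_ml <- function(v) {
  format(round(v, 3), trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

hemisphere_clause <- function(h) {
  switch(h,
         left = "the left brain hemisphere",
         right = "the right brain hemisphere",
         bilateral = "both brain hemispheres",
         stop("unknown hemisphere: ", h))
}

#' Render the structured radiological report
#'
#' Builds the structured record and its deterministic templated text.
#' Territories predicted injured are asserted plainly when their
#' probability reaches `possible_band`, and qualified with "possibly"
#' below it. Structures predicted injured are listed in prediction-set
#' (atlas-table) order. The hydrocephalus sentence takes its
#' present/absent form from the flag; the MCA-ASPECTS sentence is
#' appended when a score is given.
#'
#' @param preds_arterial,preds_structural `region_predictions` for the two
#'   schemes (the hydrocephalus row, if present, is ignored here).
#' @param hydro logical hydrocephalus finding.
#' @param volume_ml lesion volume in ml.
#' @param hemisphere `"left"`, `"right"` or `"bilateral"`.
#' @param aspects integer MCA-ASPECTS in 0..10, or NULL to omit.
#' @param possible_band probability below which a positive territory is
#'   qualified with "possibly" (default 0.70).
#' @return A `radiology_report`: the structured fields plus the rendered
#'   `text` (regenerable from the fields).
#' @export
render_report <- function(preds_arterial, preds_structural, hydro,
                          volume_ml, hemisphere, aspects = NULL,
                          possible_band = 0.70) {
  ta <- preds_arterial[preds_arterial$roi != "hydrocephalus", , drop = FALSE]
  ts <- preds_structural[preds_structural$roi != "hydrocephalus", ,
                         drop = FALSE]
  pos <- ta$label == 1L
  asserted <- ta$roi[pos & ta$probability >= possible_band]
  possible <- ta$roi[pos & ta$probability < possible_band]
  structures <- ts$roi[ts$label == 1L]
  if (!is.null(aspects)) {
    aspects <- as.integer(aspects)
    stopifnot(aspects >= 0L, aspects <= 10L)
  }
  fields <- list(hemisphere = hemisphere, volume_ml = volume_ml,
                 territories_asserted = as.character(asserted),
                 territories_possible = as.character(possible),
                 structures = as.character(structures),
                 hydrocephalus = isTRUE(hydro), aspects = aspects)
  fields$text <- render_report_text(fields)
  structure(fields, class = "radiology_report")
}

# pure text renderer over the structured fields
render_report_text <- function(f) {
  lead <- sprintf("Area of restricted diffusion within %s, with %s ml",
                  hemisphere_clause(f$hemisphere), format_ml(f$volume_ml))
  terr <- character(0)
  if (length(f$territories_asserted))
    terr <- oxford_join(territory_phrase(f$territories_asserted))
  if (length(f$territories_possible)) {
    poss <- paste0("possibly ",
                   oxford_join(territory_phrase(f$territories_possible)))
    terr <- if (length(terr) && nzchar(terr)) paste(terr, poss, sep = " and ")
    else poss
  }
  sent1 <- if (length(terr) && nzchar(terr))
    sprintf("%s, in the territory of %s.", lead, terr)
  else paste0(lead, ".")
  parts <- sent1
  if (length(f$structures))
    parts <- c(parts,
               sprintf("The area involves the following brain regions: %s.",
                       oxford_join(f$structures)))
  parts <- c(parts, if (f$hydrocephalus) "There is hydrocephalus."
             else "There is no hydrocephalus.")
  if (!is.null(f$aspects))
    parts <- c(parts, sprintf("The predicted MCA-ASPECTS is %d.", f$aspects))
  paste(parts, collapse = " ")
}

#' @export
print.radiology_report <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' @export
format.radiology_report <- function(x, ...) x$text

#' Parse a rendered report back into its structured fields
#'
#' Inverse of the report template over its field domain; used for
#' round-trip checking and for consuming reports downstream.
#'
#' @param text a report string produced by [render_report()].
#' @return A `radiology_report` (fields plus regenerated text).
#' @export
parse_report <- function(text) {
  hemisphere <-
    if (grepl("within the right brain hemisphere", text, fixed = TRUE)) "right"
    else if (grepl("within the left brain hemisphere", text, fixed = TRUE)) "left"
    else if (grepl("within both brain hemispheres", text, fixed = TRUE)) "bilateral"
    else stop("cannot parse hemisphere")
  vol <- as.numeric(sub(".*with ([0-9.]+) ml.*", "\\1", text))

  split_list <- function(s) {
    s <- gsub(", and ", ", ", s, fixed = TRUE)
    s <- gsub(" and ", ", ", s, fixed = TRUE)
    trimws(strsplit(s, ", ", fixed = TRUE)[[1]])
  }
  asserted <- possible <- character(0)
  if (grepl("in the territory of ", text, fixed = TRUE)) {
    terr <- sub(".*in the territory of ([^.]*)\\..*", "\\1", text)
    if (grepl("possibly ", terr, fixed = TRUE)) {
      halves <- strsplit(terr, "(, | and )possibly ")[[1]]
      if (length(halves) == 2L) {
        if (nzchar(halves[1])) asserted <- split_list(halves[1])
        possible <- split_list(halves[2])
      } else possible <- split_list(sub("^possibly ", "", terr))
    } else asserted <- split_list(terr)
    asserted <- unname(phrase_to_territory(asserted))
    possible <- unname(phrase_to_territory(possible))
  }
  structures <- character(0)
  if (grepl("brain regions: ", text, fixed = TRUE))
    structures <- split_list(sub(".*brain regions: ([^.]*)\\..*", "\\1", text))
  hydro <- grepl("There is hydrocephalus\\.", text)
  aspects <- NULL
  if (grepl("MCA-ASPECTS is", text, fixed = TRUE))
    aspects <- as.integer(sub(".*MCA-ASPECTS is ([0-9]+)\\..*", "\\1", text))
  fields <- list(hemisphere = hemisphere, volume_ml = vol,
                 territories_asserted = asserted,
                 territories_possible = possible,
                 structures = structures, hydrocephalus = hydro,
                 aspects = aspects)
  fields$text <- render_report_text(fields)
  structure(fields, class = "radiology_report")
}
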
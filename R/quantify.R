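# Marker-logic compartmentalization and exposure-normalized
# intensity-per-area scoring.
#
# Compartments are pixel sets, not segmented cells: epithelium is
# panCK-positive; stroma is vimentin-positive, panCK-negative, and within a
# configurable radius of a DAPI-positive nucleus (vimentin is cytoplasmic
# and DAPI nuclear, so strict per-pixel coincidence would empty the stroma).
# Pixels positive for both vimentin and panCK are assigned to epithelium,
# never to stroma.

#' Segmentation parameters for compartment masks
#'
#' @param threshold_method `"otsu"` (per-channel Otsu threshold, the
#'   default) or `"fixed"` (use `fixed_thresholds`).
#' @param fixed_thresholds Named numeric vector of per-channel positivity
#'   thresholds on the 0-1 intensity scale (`dapi`, `vimentin`, `panck`);
#'   required when `threshold_method = "fixed"`.
#' @param nucleus_association_radius Pixels; a vimentin-positive pixel
#'   counts as stroma only if a DAPI-positive pixel lies within this radius.
#'   Default 10 px, roughly one cell diameter at TMA scan resolution.
#' @param min_region_px Connected components smaller than this (8-neighbour
#'   connectivity) are dropped from each mask; 0 disables the filter.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_thresholds = NULL,
                                nucleus_association_radius = 10,
                                min_region_px = 0L) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed") {
    req <- c("dapi", "vimentin", "panck")
    if (is.null(fixed_thresholds) || !all(req %in% names(fixed_thresholds)))
      stop("fixed thresholds must name channels ",
           paste(req, collapse = ", "), call. = FALSE)
    if (any(fixed_thresholds < 0) || any(fixed_thresholds > 1))
      stop("fixed thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (nucleus_association_radius < 0)
    stop("nucleus_association_radius must be >= 0", call. = FALSE)
  if (min_region_px < 0)
    stop("min_region_px must be >= 0", call. = FALSE)
  structure(list(threshold_method = threshold_method,
                 fixed_thresholds = fixed_thresholds,
                 nucleus_association_radius = nucleus_association_radius,
                 min_region_px = as.integer(min_region_px)),
            class = "segmentation_params")
}

channel_positive <- function(ch, name, params) {
  if (max(ch) == 0) {
    warning("channel '", name, "' is all zero; its mask is empty",
            call. = FALSE)
    return(ch > 0)
  }
  thr <- if (params$threshold_method == "fixed") {
    params$fixed_thresholds[[name]]
  } else {
    EBImage::otsu(ch, range = c(0, 1), levels = 256L)
  }
  ch > thr
}

drop_small_regions <- function(mask, min_px) {
  if (min_px <= 0 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Build disjoint stroma and epithelium compartment masks
#'
#' Epithelium is the panCK-positive pixel set. Stroma is the
#' vimentin-positive, panCK-negative pixel set lying within
#' `nucleus_association_radius` of a DAPI-positive pixel (the nucleus
#' requirement); pixels positive for both vimentin and panCK are excluded
#' from the stroma and belong to the epithelium. The two masks are disjoint
#' by construction. An all-zero channel yields a warning and an empty
#' corresponding mask, not an error.
#'
#' @param image A `multiplex_core_image`.
#' @param params A [segmentation_params()].
#' @return Object of class `compartment_masks`: logical matrices `stroma`
#'   and `epithelium` plus the `thresholds` actually used.
#' @export
build_compartment_masks <- function(image, params = segmentation_params()) {
  validate_multiplex_core_image(image)
  dapi <- channel_positive(image$channels$dapi, "dapi", params)
  vim <- channel_positive(image$channels$vimentin, "vimentin", params)
  panck <- channel_positive(image$channels$panck, "panck", params)

  thr_used <- vapply(c("dapi", "vimentin", "panck"), function(nm) {
    ch <- image$channels[[nm]]
    if (max(ch) == 0) NA_real_
    else if (params$threshold_method == "fixed")
      params$fixed_thresholds[[nm]]
    else EBImage::otsu(ch, range = c(0, 1), levels = 256L)
  }, numeric(1))

  near_nucleus <- dapi
  r <- params$nucleus_association_radius
  if (r > 0 && any(dapi)) {
    brush <- EBImage::makeBrush(2L * ceiling(r) + 1L, shape = "disc")
    near_nucleus <- EBImage::dilate(dapi * 1, brush) > 0
  }

  epithelium <- panck
  stroma <- vim & !panck & near_nucleus

  epithelium <- drop_small_regions(epithelium, params$min_region_px)
  stroma <- drop_small_regions(stroma, params$min_region_px)

  structure(list(stroma = stroma, epithelium = epithelium,
                 thresholds = thr_used),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf("compartment masks: stroma %d px, epithelium %d px\n",
              sum(x$stroma), sum(x$epithelium)))
  invisible(x)
}

#' Exposure-normalized intensity-per-area (AQUA-style) compartment score
#'
#' The score is the sum of Cav-1 pixel intensity over the compartment mask,
#' divided by the compartment area and normalized for the Cav-1 exposure
#' time, so it is directly proportional to protein concentration per unit
#' area:
#' `score = scale * (sum(cav1[mask]) / area) * (reference_exposure / exposure)`.
#' Only the whole-cell ("overall") score is computed. An empty mask yields a
#' missing (`NA`) score flagged as such, never zero.
#'
#' @param image A `multiplex_core_image`.
#' @param masks A `compartment_masks` object (or any list with logical
#'   `stroma`/`epithelium` matrices, e.g. simulator ground truth).
#' @param compartment `"stroma"` or `"epithelium"`.
#' @param scale Arbitrary-units multiplier applied to the normalized mean
#'   intensity. The default 1000 puts noise-free simulated scores on the
#'   familiar hundreds scale.
#' @param reference_exposure Exposure time (ms) that the score is
#'   standardized to; scores from cores acquired at different Cav-1
#'   exposures are comparable after this normalization.
#' @return Object of class `aqua_score`: `value`, `compartment`, `area_px`,
#'   `missing`, plus core/subject identifiers.
#' @export
compute_aqua_score <- function(image, masks,
                               compartment = c("stroma", "epithelium"),
                               scale = 1000,
                               reference_exposure = 100) {
  validate_multiplex_core_image(image)
  compartment <- match.arg(compartment)
  mask <- masks[[compartment]]
  stopifnot(identical(dim(mask), dim(image$channels$cav1)))
  area <- sum(mask)
  if (area == 0) {
    value <- NA_real_
  } else {
    exposure <- image$exposure_ms[["cav1"]]
    value <- scale * (sum(image$channels$cav1[mask]) / area) *
      (reference_exposure / exposure)
  }
  structure(list(value = value, compartment = compartment,
                 area_px = as.integer(area), missing = area == 0,
                 core_id = image$core_id, subject_id = image$subject_id,
                 roi_class = image$roi_class),
            class = "aqua_score")
}

#' @export
print.aqua_score <- function(x, ...) {
  cat(sprintf("AQUA score [%s, core %s]: %s over %d px\n", x$compartment,
              x$core_id, if (x$missing) "missing" else format(x$value),
              x$area_px))
  invisible(x)
}

#' Quantify a set of cores into a per-core score table
#'
#' Convenience wrapper: builds masks and computes both compartment scores
#' for each core.
#'
#' @param images List of `multiplex_core_image` objects.
#' @param params A [segmentation_params()].
#' @param scale,reference_exposure Passed to [compute_aqua_score()].
#' @return Data frame with one row per core x compartment: `subject_id`,
#'   `core_id`, `roi_class`, `compartment`, `score`, `area_px`.
#' @export
quantify_cores <- function(images, params = segmentation_params(),
                           scale = 1000, reference_exposure = 100) {
  rows <- lapply(images, function(img) {
    masks <- build_compartment_masks(img, params)
    do.call(rbind, lapply(c("stroma", "epithelium"), function(cmp) {
      s <- compute_aqua_score(img, masks, cmp, scale, reference_exposure)
      data.frame(subject_id = s$subject_id, core_id = s$core_id,
                 roi_class = s$roi_class, compartment = s$compartment,
                 score = s$value, area_px = s$area_px,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average duplicate cores into one record per subject x ROI x compartment
#'
#' Duplicate cores from the same participant are combined by the arithmetic
#' mean of their non-missing compartment scores; the number of cores that
#' contributed is recorded. A subject x ROI whose duplicates are all
#' missing yields a missing record (`score = NA`, `n_cores = 0`).
#'
#' @param scores Data frame with columns `subject_id`, `roi_class`,
#'   `compartment`, `score` (one row per core), as from [quantify_cores()]
#'   or [generate_cohort()].
#' @return Data frame with one row per subject x ROI x compartment:
#'   `subject_id`, `roi_class`, `compartment`, `score`, `n_cores`.
#' @export
aggregate_duplicate_cores <- function(scores) {
  req <- c("subject_id", "roi_class", "compartment", "score")
  if (!all(req %in% names(scores)))
    stop("scores must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  key <- interaction(scores$subject_id, scores$roi_class,
                     scores$compartment, drop = TRUE)
  out <- do.call(rbind, lapply(split(scores, key), function(g) {
    ok <- !is.na(g$score)
    data.frame(subject_id = g$subject_id[1], roi_class = g$roi_class[1],
               compartment = g$compartment[1],
               score = if (any(ok)) mean(g$score[ok]) else NA_real_,
               n_cores = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$subject_id, out$roi_class, out$compartment), , drop = FALSE]
}

#' Dichotomize IF expression at the median
#'
#' Labels each record `"high"` when its score is greater than or equal to
#' the median of the non-missing scores (ties at the median are high), else
#' `"low"`. Missing scores stay unlabelled (`NA`).
#'
#' @param records Data frame with a `score` column (typically the output of
#'   [aggregate_duplicate_cores()] filtered to one compartment/ROI class).
#' @param compartment Optional; if given and `records` has a `compartment`
#'   column, only rows of that compartment are labelled (others get `NA`).
#' @return `records` with added columns `expression_level`
#'   (`"low"`/`"high"`) and `cutoff` (the median used).
#' @export
dichotomize_if <- function(records, compartment = NULL) {
  if (!("score" %in% names(records)) || nrow(records) == 0)
    stop("records must be a non-empty data frame with a 'score' column",
         call. = FALSE)
  use <- rep(TRUE, nrow(records))
  if (!is.null(compartment) && "compartment" %in% names(records))
    use <- records$compartment == compartment
  vals <- records$score[use & !is.na(records$score)]
  if (length(vals) < 2)
    stop("need at least 2 non-missing scores to dichotomize", call. = FALSE)
  cutoff <- stats::median(vals)
  level <- rep(NA_character_, nrow(records))
  level[use] <- ifelse(is.na(records$score[use]), NA_character_,
                       ifelse(records$score[use] >= cutoff, "high", "low"))
  records$expression_level <- level
  records$cutoff <- ifelse(use, cutoff, NA_real_)
  records
}
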
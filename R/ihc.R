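# Semi-quantitative IHC scoring: a pathologist's intensity category (0-3)
# multiplied by a percent-positive category (0-3), giving an H-score in
# {0, 1, 2, 3, 4, 6, 9}.

#' Convert percent positive cells to its scoring category
#'
#' Categories: 0 for exactly 0%, 1 for (0, 33]%, 2 for (33, 66]%, 3 for
#' (66, 100]%. The printed bins are integers (0, 1-33, 34-66, 67-100);
#' fractional percentages fall into the half-open intervals above.
#'
#' @param percent_positive Percent of positive cells, in `[0, 100]`
#'   (vectorized).
#' @return Integer category 0-3.
#' @export
percent_to_category <- function(percent_positive) {
  if (any(is.na(percent_positive)))
    stop("percent_positive contains missing values", call. = FALSE)
  if (any(percent_positive < 0 | percent_positive > 100))
    stop("percent_positive must lie in [0, 100]", call. = FALSE)
  as.integer(cut(percent_positive, breaks = c(-Inf, 0, 33, 66, 100),
                 labels = FALSE)) - 1L
}

#' Compute the IHC H-score
#'
#' `h_score = intensity_cat * percent_category`, with intensity scored
#' 0 (negative), 1 (weak), 2 (moderate), 3 (strong) and the percent of
#' positive cells categorized by [percent_to_category()]. Supply either
#' `percent_positive` (a percentage) or `percent_cat` (an already
#' categorized 0-3 value). Vectorized.
#'
#' @param intensity_cat Integer 0-3 staining intensity category.
#' @param percent_positive Percent positive cells in `[0, 100]`.
#' @param percent_cat Integer 0-3 percent category (alternative to
#'   `percent_positive`).
#' @return Integer H-score in `{0, 1, 2, 3, 4, 6, 9}`.
#' @export
compute_h_score <- function(intensity_cat, percent_positive = NULL,
                            percent_cat = NULL) {
  if (any(is.na(intensity_cat)) ||
      any(intensity_cat != as.integer(intensity_cat)) ||
      any(intensity_cat < 0 | intensity_cat > 3))
    stop("intensity_cat must be an integer in 0..3", call. = FALSE)
  if (is.null(percent_cat)) {
    if (is.null(percent_positive))
      stop("supply percent_positive or percent_cat", call. = FALSE)
    percent_cat <- percent_to_category(percent_positive)
  } else {
    if (any(is.na(percent_cat)) ||
        any(percent_cat != as.integer(percent_cat)) ||
        any(percent_cat < 0 | percent_cat > 3))
      stop("percent_cat must be an integer in 0..3", call. = FALSE)
  }
  as.integer(intensity_cat) * as.integer(percent_cat)
}

#' Dichotomize an H-score as presence vs absence of staining
#'
#' A zero H-score (no staining, or 0% positive cells) is `"absent"`; any
#' positive H-score is `"present"`. Vectorized.
#'
#' @param h_score Integer H-score(s) in `{0, 1, 2, 3, 4, 6, 9}`.
#' @return Character vector of `"present"`/`"absent"`.
#' @export
dichotomize_ihc <- function(h_score) {
  valid <- c(0L, 1L, 2L, 3L, 4L, 6L, 9L)
  if (any(is.na(h_score)) || !all(h_score %in% valid))
    stop("h_score must be a product of two 0-3 categories (",
         paste(valid, collapse = ", "), ")", call. = FALSE)
  ifelse(h_score > 0, "present", "absent")
}

#' Score a table of IHC observations
#'
#' @param obs Data frame with columns `subject_id`, `roi_class`,
#'   `intensity_cat` and either `percent_positive` or `percent_cat`.
#' @return `obs` with added `h_score` and `cav1_presence` columns.
#' @export
score_ihc_table <- function(obs) {
  if (!all(c("subject_id", "intensity_cat") %in% names(obs)))
    stop("obs must have columns subject_id and intensity_cat", call. = FALSE)
  obs$h_score <- if ("percent_positive" %in% names(obs)) {
    compute_h_score(obs$intensity_cat, percent_positive = obs$percent_positive)
  } else if ("percent_cat" %in% names(obs)) {
    compute_h_score(obs$intensity_cat, percent_cat = obs$percent_cat)
  } else {
    stop("obs needs a percent_positive or percent_cat column", call. = FALSE)
  }
  obs$cav1_presence <- dichotomize_ihc(obs$h_score)
  obs
}
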
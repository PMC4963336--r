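#' Response categories
#'
#' The fixed category order used throughout: progressive, stable,
#' regressive. Matches the column order of the study's classification
#' tables.
#'
#' @return Character vector of the three categories.
#' @export
change_categories <- function() c("progressive", "stable", "regressive")

#' Fractional change between two uptake values
#'
#' @param v1 baseline value (> 0).
#' @param v2 follow-up value (>= 0).
#' @return \code{(v2 - v1) / v1}. Vectorized.
#' @examples
#' fractional_change(10, 14)  # +0.4
#' @export
fractional_change <- function(v1, v2) {
  if (any(!is.finite(v1)) || any(v1 <= 0))
    stop("baseline uptake must be positive", call. = FALSE)
  if (any(v2 < 0, na.rm = TRUE))
    stop("follow-up uptake must be non-negative", call. = FALSE)
  (v2 - v1) / v1
}

#' Classify a fractional change
#'
#' Response-criteria-style three-way call: an increase of more than the
#' threshold (default 30 \%) is progressive, a decrease of more than the
#' threshold regressive, anything in between stable. The inequalities are
#' strict, so a change of exactly +/- the threshold is stable.
#'
#' @param delta fractional change(s), e.g. from
#'   \code{\link{fractional_change}}.
#' @param threshold positive fractional threshold (default 0.30).
#' @return Factor with levels \code{\link{change_categories}}.
#' @examples
#' classify_change(c(0.31, 0.30, -0.196, -0.31))
#' @export
classify_change <- function(delta, threshold = 0.30) {
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a single positive value", call. = FALSE)
  out <- ifelse(delta > threshold, "progressive",
                ifelse(delta < -threshold, "regressive", "stable"))
  factor(out, levels = change_categories())
}

#' Classify lesions from two-time-point metrics
#'
#' Absolute mode compares SUV_peak directly between time points. Ratio
#' mode first divides each lesion's SUV_peak by the subject's
#' reference-region SUV_mean of the same time point, cancelling global
#' bone-metabolism fluctuations; lesions lacking a reference value at
#' either time point are excluded with a message.
#'
#' @param metrics_tp1,metrics_tp2 data.frames with columns
#'   \code{lesion_id}, \code{suv_peak}, and (for ratio mode)
#'   \code{ref_suv_mean} (NA when no reference region was available).
#'   Lesion ids must match across time points.
#' @param mode \code{"absolute"} or \code{"ratio"}.
#' @param threshold passed to \code{\link{classify_change}}.
#' @param source name tag for the resulting rating vector.
#' @return A data.frame (also a valid \code{\link{rating_vector}}) with
#'   columns \code{lesion_id, mode, value_tp1, value_tp2, delta, category,
#'   source}, and attribute \code{n_excluded} (lesions dropped in ratio
#'   mode for lack of a reference).
#' @export
classify_lesions <- function(metrics_tp1, metrics_tp2,
                             mode = c("absolute", "ratio"),
                             threshold = 0.30, source = NULL) {
  mode <- match.arg(mode)
  for (m in list(metrics_tp1, metrics_tp2)) {
    if (!all(c("lesion_id", "suv_peak") %in% names(m)))
      stop("metrics need columns 'lesion_id' and 'suv_peak'", call. = FALSE)
  }
  if (!setequal(metrics_tp1$lesion_id, metrics_tp2$lesion_id) ||
      anyDuplicated(metrics_tp1$lesion_id) || anyDuplicated(metrics_tp2$lesion_id))
    stop("lesion ids must match one-to-one across time points; mismatch: ",
         paste(union(setdiff(metrics_tp1$lesion_id, metrics_tp2$lesion_id),
                     setdiff(metrics_tp2$lesion_id, metrics_tp1$lesion_id)),
               collapse = ", "), call. = FALSE)
  m2 <- metrics_tp2[match(metrics_tp1$lesion_id, metrics_tp2$lesion_id), ]
  n_excluded <- 0L
  if (mode == "absolute") {
    v1 <- metrics_tp1$suv_peak
    v2 <- m2$suv_peak
    ids <- metrics_tp1$lesion_id
  } else {
    if (!all(c("ref_suv_mean") %in% names(metrics_tp1)) ||
        !all(c("ref_suv_mean") %in% names(m2)))
      stop("ratio mode needs a 'ref_suv_mean' column at both time points",
           call. = FALSE)
    ok <- is.finite(metrics_tp1$ref_suv_mean) & metrics_tp1$ref_suv_mean > 0 &
      is.finite(m2$ref_suv_mean) & m2$ref_suv_mean > 0
    n_excluded <- sum(!ok)
    if (n_excluded > 0L)
      message(n_excluded, " lesion(s) without a reference region excluded ",
              "from ratio-mode classification")
    v1 <- uptake_ratio(metrics_tp1$suv_peak[ok], metrics_tp1$ref_suv_mean[ok])
    v2 <- uptake_ratio(m2$suv_peak[ok], m2$ref_suv_mean[ok])
    ids <- metrics_tp1$lesion_id[ok]
  }
  delta <- fractional_change(v1, v2)
  if (is.null(source)) source <- paste0("quantitative (", mode, ")")
  out <- data.frame(lesion_id = ids, mode = mode, value_tp1 = v1,
                    value_tp2 = v2, delta = delta,
                    category = classify_change(delta, threshold),
                    source = source, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}
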
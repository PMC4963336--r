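#' Published reader classification tallies
#'
#' Loads the per-reader, per-method classification tallies bundled with
#' the package: for each of two readers, the numbers of lesions called
#' progressive / stable / regressive by the quantitative reference method
#' and by visual reading of planar scintigraphy and SPECT/CT, together
#' with the count of lesions on which the visual reading disagreed with
#' the quantitative reference. Two blocks are included: \code{"absolute"}
#' (peak-SUV classification of 52 metastatic bone lesions) and
#' \code{"ratio"} (uptake-ratio classification of the 46 lesions with a
#' reference vertebra).
#'
#' Because unweighted Cohen's kappa depends only on the two sources'
#' marginal counts and the number of agreements, these tallies suffice to
#' reconstruct the aggregated inter-method kappas exactly (see
#' \code{\link{inter_method_agreement}}).
#'
#' @param path CSV path; defaults to the bundled fixture.
#' @return A data.frame with columns \code{mode, reader, method,
#'   progressive, stable, regressive, discrepant_vs_reference}.
#' @export
load_reader_tallies <- function(path = system.file(
  "extdata", "reader_classification_tallies.csv", package = "bonetrack")) {
  if (!nzchar(path) || !file.exists(path))
    stop("tallies file not found", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mode", "reader", "method", "progressive", "stable",
            "regressive", "discrepant_vs_reference")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("tallies file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$n <- df$progressive + df$stable + df$regressive
  expected_n <- c(absolute = 52L, ratio = 46L)
  bad <- df$n != expected_n[df$mode]
  if (any(bad))
    stop("tally row(s) do not sum to the study lesion count: ",
         paste(sprintf("%s reader %d %s (n=%d)", df$mode[bad],
                       df$reader[bad], df$method[bad], df$n[bad]),
               collapse = "; "), call. = FALSE)
  df
}

#' Aggregated inter-method agreement from tallies
#'
#' Reconstructs the reader-aggregated inter-method Cohen's kappas from
#' per-reader marginal tallies and discrepancy counts: marginals of both
#' readers are summed per method, \code{n} doubles (both readers' lesions
#' are pooled), and the number of agreements is \code{n} minus the summed
#' discrepancy counts. Four comparisons are reconstructible: visual planar
#' and visual SPECT/CT, each against the quantitative classification in
#' absolute-SUV mode (n = 104) and in uptake-ratio mode (n = 92).
#'
#' @param tallies data.frame from \code{\link{load_reader_tallies}}.
#' @return A data.frame with one row per comparison: \code{comparison,
#'   mode, n, n_agree, p0, pe, kappa, kappa_2dp, label}.
#' @export
inter_method_agreement <- function(tallies = load_reader_tallies()) {
  cats <- change_categories()
  rows <- list()
  for (mode in unique(tallies$mode)) {
    blk <- tallies[tallies$mode == mode, ]
    ref <- blk[blk$method == "quantitative", ]
    ref_marg <- colSums(ref[, cats])
    for (vis in setdiff(unique(blk$method), "quantitative")) {
      v <- blk[blk$method == vis, ]
      v_marg <- colSums(v[, cats])
      n <- sum(v_marg)
      n_agree <- n - sum(v$discrepant_vs_reference)
      kr <- kappa_from_marginals(v_marg, ref_marg, n_agree = n_agree, n = n)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = sprintf("visual %s vs quantitative (%s)", vis, mode),
        mode = mode, n = n, n_agree = n_agree, p0 = kr$p0, pe = kr$pe,
        kappa = kr$kappa, kappa_2dp = round_half_up(kr$kappa, 2),
        label = kr$label, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Half-up decimal rounding for report tables (base round() rounds half to
# even).
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Load a paired longitudinal study from files
#'
#' @param volume_tp1,volume_tp2 NIfTI paths for the two count volumes.
#' @param meta_tp1,meta_tp2 JSON paths for the two acquisition metadata
#'   records.
#' @param vois CSV path of VOI definitions shared by both time points.
#' @param truth optional CSV path of a ground-truth lesion table.
#' @return A list \code{tp1}, \code{tp2} (each \code{counts} + \code{meta}),
#'   \code{vois}, \code{truth} (or NULL), \code{grid}. Errors if the two
#'   volumes are not on the same grid (the study design requires an
#'   overlapping field of view).
#' @export
load_study <- function(volume_tp1, volume_tp2, meta_tp1, meta_tp2, vois,
                       truth = NULL) {
  v1 <- read_volume(volume_tp1)
  v2 <- read_volume(volume_tp2)
  if (!same_grid(v1$grid, v2$grid))
    stop("the two time points are not on the same voxel grid ",
         "(overlapping field of view required)", call. = FALSE)
  list(tp1 = list(counts = v1, meta = read_meta(meta_tp1)),
       tp2 = list(counts = v2, meta = read_meta(meta_tp2)),
       vois = read_vois(vois),
       truth = if (!is.null(truth)) utils::read.csv(truth, stringsAsFactors = FALSE),
       grid = v1$grid)
}

#' Write analysis outputs as CSV / JSON
#'
#' \code{write_metrics} and \code{write_ratings} are lossless CSV
#' round-trips for the data.frames produced by
#' \code{\link{quantify_study}} and \code{\link{classify_lesions}};
#' \code{write_kappa_report} serializes one or more
#' \code{\link{kappa_from_table}} results to JSON.
#'
#' @param metrics,ratings data.frames to write.
#' @param kappas a single \code{kappa_result} or a named list of them.
#' @param path output file path.
#' @return \code{path}, invisibly, for the writers; the corresponding
#'   \code{read_*} return data.frames.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop("no such metrics file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_metrics
#' @export
write_ratings <- function(ratings, path) {
  ratings$category <- as.character(ratings$category)
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("no such ratings file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$category <- factor(df$category, levels = change_categories())
  df
}

#' @rdname write_metrics
#' @export
write_kappa_report <- function(kappas, path) {
  if (inherits(kappas, "kappa_result")) kappas <- list(kappa = kappas)
  out <- lapply(kappas, function(k) {
    stopifnot(inherits(k, "kappa_result"))
    unclass(k)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
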
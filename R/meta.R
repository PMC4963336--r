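#' Acquisition metadata
#'
#' Everything needed to turn a count volume into SUVs: the activity
#' prepared in the syringe and when it was measured, the residual syringe
#' activity after injection, injection and acquisition-start times, body
#' weight, the camera calibration factor, the dwell time, and the isotope
#' half-life. Times are minutes on an arbitrary common study clock; only
#' differences matter.
#'
#' The default half-life is Tc-99m (360.4 min = 6.0067 h). The calibration
#' factor summarizes the camera sensitivity chain of a quantitative
#' reconstruction: counts per second registered in a voxel per kBq of
#' activity in that voxel.
#'
#' @param prepared_activity_MBq syringe activity (MBq) at
#'   \code{t_prepared_min}.
#' @param t_prepared_min time the prepared activity was measured.
#' @param residual_activity_MBq activity left in the syringe (MBq) at
#'   \code{t_residual_min}.
#' @param t_residual_min time the residual activity was measured.
#' @param t_injection_min injection time.
#' @param t_acquisition_start_min SPECT acquisition start time.
#' @param body_weight_kg patient weight in kg.
#' @param calibration_factor counts s^-1 per kBq in a voxel (> 0).
#' @param dwell_time_s effective acquisition time per voxel in seconds.
#' @param half_life_min isotope half-life in minutes.
#' @return An object of class \code{acquisition_meta}.
#' @examples
#' meta <- acquisition_meta(prepared_activity_MBq = 600, t_prepared_min = -30,
#'                          residual_activity_MBq = 20, t_residual_min = 5,
#'                          t_injection_min = 0, t_acquisition_start_min = 231,
#'                          body_weight_kg = 75)
#' net_injected_activity(meta)
#' @export
acquisition_meta <- function(prepared_activity_MBq,
                             t_prepared_min,
                             residual_activity_MBq = 0,
                             t_residual_min = t_injection_min,
                             t_injection_min,
                             t_acquisition_start_min,
                             body_weight_kg,
                             calibration_factor = 10,
                             dwell_time_s = 15,
                             half_life_min = 360.4) {
  num1 <- function(x, nm) {
    if (length(x) != 1L || !is.finite(as.numeric(x)))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  m <- list(prepared_activity_MBq = num1(prepared_activity_MBq, "prepared_activity_MBq"),
            t_prepared_min = num1(t_prepared_min, "t_prepared_min"),
            residual_activity_MBq = num1(residual_activity_MBq, "residual_activity_MBq"),
            t_residual_min = num1(t_residual_min, "t_residual_min"),
            t_injection_min = num1(t_injection_min, "t_injection_min"),
            t_acquisition_start_min = num1(t_acquisition_start_min, "t_acquisition_start_min"),
            body_weight_kg = num1(body_weight_kg, "body_weight_kg"),
            calibration_factor = num1(calibration_factor, "calibration_factor"),
            dwell_time_s = num1(dwell_time_s, "dwell_time_s"),
            half_life_min = num1(half_life_min, "half_life_min"))
  if (m$prepared_activity_MBq < m$residual_activity_MBq || m$residual_activity_MBq < 0)
    stop("need prepared_activity_MBq >= residual_activity_MBq >= 0", call. = FALSE)
  if (m$body_weight_kg <= 0) stop("body weight must be positive", call. = FALSE)
  if (m$calibration_factor <= 0) stop("calibration factor must be positive", call. = FALSE)
  if (m$dwell_time_s <= 0) stop("dwell time must be positive", call. = FALSE)
  if (m$half_life_min <= 0) stop("half-life must be positive", call. = FALSE)
  if (m$t_prepared_min > m$t_injection_min ||
      m$t_injection_min > m$t_acquisition_start_min)
    stop("times must satisfy t_prepared <= t_injection <= t_acquisition_start",
         call. = FALSE)
  structure(m, class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf(paste0("acquisition_meta: %.1f MBq prepared (t=%.0f min), ",
                     "%.1f MBq residual (t=%.0f min), injected t=%.0f, ",
                     "acquired t=%.0f, %.0f kg, S=%.3g cps/kBq, T=%.0f s, ",
                     "T1/2=%.1f min\n"),
              x$prepared_activity_MBq, x$t_prepared_min,
              x$residual_activity_MBq, x$t_residual_min,
              x$t_injection_min, x$t_acquisition_start_min,
              x$body_weight_kg, x$calibration_factor, x$dwell_time_s,
              x$half_life_min))
  invisible(x)
}

#' Radioactive decay correction factor
#'
#' Returns \code{2^(delta_t / half_life)}: the factor that corrects an
#' activity measured \code{delta_t} minutes after a reference time back to
#' that reference time. With \code{delta_t = t_acq - t_inj >= 0} this
#' rescales acquisition-time activity to injection time; a negative
#' \code{delta_t} gives forward decay.
#'
#' @param delta_t_min elapsed time in minutes (may be negative).
#' @param half_life_min isotope half-life in minutes (> 0).
#' @return The dimensionless decay-correction factor.
#' @examples
#' decay_factor(360.4, 360.4)  # one half-life -> 2
#' @export
decay_factor <- function(delta_t_min, half_life_min = 360.4) {
  if (any(half_life_min <= 0)) stop("half-life must be positive", call. = FALSE)
  2^(delta_t_min / half_life_min)
}

#' Net injected activity at injection time
#'
#' Decays the prepared syringe activity and the post-injection residual
#' activity each to injection time and subtracts:
#' \deqn{A_{net} = A_{prep} 2^{-(t_{inj}-t_{prep})/T_{1/2}} -
#'       A_{res} 2^{-(t_{inj}-t_{res})/T_{1/2}}}
#'
#' @param meta an \code{\link{acquisition_meta}}.
#' @return Net injected activity in MBq (> 0).
#' @export
net_injected_activity <- function(meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  t12 <- meta$half_life_min
  a_prep <- meta$prepared_activity_MBq *
    decay_factor(-(meta$t_injection_min - meta$t_prepared_min), t12)
  a_res <- meta$residual_activity_MBq *
    decay_factor(-(meta$t_injection_min - meta$t_residual_min), t12)
  a_net <- a_prep - a_res
  if (a_net <= 0)
    stop("non-positive net injected activity: residual exceeds decayed ",
         "prepared activity", call. = FALSE)
  a_net
}

#' Read and write acquisition metadata as JSON
#'
#' @param meta an \code{\link{acquisition_meta}}.
#' @param path JSON file path.
#' @return \code{read_meta} returns an \code{acquisition_meta};
#'   \code{write_meta} returns \code{path} invisibly.
#' @export
write_meta <- function(meta, path) {
  stopifnot(inherits(meta, "acquisition_meta"))
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_meta
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) stop("no such metadata file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("prepared_activity_MBq", "t_prepared_min", "t_injection_min",
            "t_acquisition_start_min", "body_weight_kg")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("metadata file ", path, " lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(acquisition_meta, x[intersect(names(x), names(formals(acquisition_meta)))])
}
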
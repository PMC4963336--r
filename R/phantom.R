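#' Lesion specification for the synthetic phantom
#'
#' An ellipsoidal bone lesion with a target baseline uptake and a true
#' fractional change between the two time points:
#' \code{suv_tp2 = suv_tp1 * (1 + fractional_change)}.
#'
#' @param id lesion label.
#' @param center world mm centre.
#' @param semi_axes mm semi-axes (scalar gives a sphere).
#' @param suv_tp1 target SUV inside the lesion at baseline (> 0).
#' @param fractional_change true fractional change (> -1).
#' @param region anatomical tag carried into output tables.
#' @return An object of class \code{lesion_spec}.
#' @export
lesion_spec <- function(id, center, semi_axes, suv_tp1, fractional_change = 0,
                        region = "bone") {
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3L)
  if (any(semi_axes <= 0)) stop("lesion semi-axes must be positive", call. = FALSE)
  if (suv_tp1 <= 0) stop("lesion suv_tp1 must be positive", call. = FALSE)
  if (fractional_change <= -1)
    stop("fractional_change must exceed -1", call. = FALSE)
  structure(list(id = as.character(id), center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 suv_tp1 = as.numeric(suv_tp1),
                 fractional_change = as.numeric(fractional_change),
                 region = as.character(region)),
            class = "lesion_spec")
}

lesion_suv <- function(lesion, time_point) {
  if (time_point == 1L) lesion$suv_tp1
  else lesion$suv_tp1 * (1 + lesion$fractional_change)
}

lesion_voi <- function(lesion) {
  ellipsoid_voi(lesion$id, lesion$center, lesion$semi_axes,
                label = "lesion", region = lesion$region)
}

#' Two-time-point phantom specification
#'
#' Defines a synthetic paired bone-SPECT study: a voxel grid, a uniform
#' soft-tissue background, a healthy-vertebra reference region whose
#' SUV_mean may drift between time points (global bone-metabolism
#' fluctuation), a set of lesions with true fractional changes, and the
#' per-time-point acquisition parameters.
#'
#' @param grid a \code{\link{grid_geometry}}.
#' @param background_suv soft-tissue SUV painted everywhere else (>= 0).
#' @param reference_suv length-2 vector: reference-region SUV at TP1, TP2.
#' @param reference_voi an \code{\link{ellipsoid_voi}} with label
#'   \code{"reference"}.
#' @param lesions list of \code{\link{lesion_spec}}.
#' @param subject_weight_kg body weight (constant across time points).
#' @param injected_activity_MBq length-2: net injected activity per TP.
#' @param time_to_acquisition_min length-2: injection-to-acquisition delay
#'   per TP.
#' @param calibration_factor,dwell_time_s,half_life_min forward-model and
#'   decay parameters shared by both acquisitions.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid, background_suv = 1.0,
                         reference_suv = c(5.6, 4.9),
                         reference_voi,
                         lesions = list(),
                         subject_weight_kg = 75,
                         injected_activity_MBq = c(573, 542),
                         time_to_acquisition_min = c(231, 234),
                         calibration_factor = 10,
                         dwell_time_s = 15,
                         half_life_min = 360.4) {
  stopifnot(inherits(grid, "grid_geometry"),
            inherits(reference_voi, "ellipsoid_voi"))
  if (reference_voi$label != "reference")
    stop("reference_voi must have label 'reference'", call. = FALSE)
  if (background_suv < 0 || any(reference_suv < 0))
    stop("SUVs must be non-negative", call. = FALSE)
  if (length(reference_suv) != 2L || length(injected_activity_MBq) != 2L ||
      length(time_to_acquisition_min) != 2L)
    stop("per-time-point parameters must have length 2", call. = FALSE)
  if (subject_weight_kg <= 0 || any(injected_activity_MBq <= 0))
    stop("weight and injected activity must be positive", call. = FALSE)
  if (!all(vapply(lesions, inherits, logical(1), "lesion_spec")))
    stop("'lesions' must be a list of lesion_spec objects", call. = FALSE)
  ids <- vapply(lesions, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate lesion ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!voi_inside_grid(reference_voi, grid))
    stop("reference VOI extends outside the grid", call. = FALSE)
  for (l in lesions) {
    if (!voi_inside_grid(lesion_voi(l), grid))
      stop("lesion '", l$id, "' extends outside the grid", call. = FALSE)
  }
  structure(list(grid = grid, background_suv = as.numeric(background_suv),
                 reference_suv = as.numeric(reference_suv),
                 reference_voi = reference_voi, lesions = lesions,
                 subject_weight_kg = as.numeric(subject_weight_kg),
                 injected_activity_MBq = as.numeric(injected_activity_MBq),
                 time_to_acquisition_min = as.numeric(time_to_acquisition_min),
                 calibration_factor = as.numeric(calibration_factor),
                 dwell_time_s = as.numeric(dwell_time_s),
                 half_life_min = as.numeric(half_life_min)),
            class = "phantom_spec")
}

#' Acquisition metadata implied by a phantom time point
#'
#' The phantom's injected activity is taken as the net activity at
#' injection time (prepared measured at injection, zero residual).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param time_point 1 or 2.
#' @return An \code{\link{acquisition_meta}}.
#' @export
phantom_meta <- function(spec, time_point) {
  stopifnot(inherits(spec, "phantom_spec"), time_point %in% c(1L, 2L))
  acquisition_meta(
    prepared_activity_MBq = spec$injected_activity_MBq[time_point],
    t_prepared_min = 0, residual_activity_MBq = 0, t_residual_min = 0,
    t_injection_min = 0,
    t_acquisition_start_min = spec$time_to_acquisition_min[time_point],
    body_weight_kg = spec$subject_weight_kg,
    calibration_factor = spec$calibration_factor,
    dwell_time_s = spec$dwell_time_s,
    half_life_min = spec$half_life_min)
}

#' Ground-truth SUV map of a phantom time point
#'
#' Paints target SUVs voxel by voxel with precedence lesion > reference >
#' background (lesions replace marrow uptake where they overlap the
#' reference region). Overlapping lesions are an error.
#'
#' @inheritParams phantom_meta
#' @return An \code{\link{uptake_volume}} in \code{"SUV"} units.
#' @export
build_suv_map <- function(spec, time_point) {
  stopifnot(inherits(spec, "phantom_spec"), time_point %in% c(1L, 2L))
  suv <- array(spec$background_suv, dim = spec$grid$shape)
  suv[voi_mask(spec$reference_voi, spec$grid)] <-
    spec$reference_suv[time_point]
  masks <- lapply(spec$lesions, function(l) voi_mask(lesion_voi(l), spec$grid))
  if (length(masks) > 1L) {
    for (i in seq_along(masks)[-1]) {
      for (j in seq_len(i - 1L)) {
        if (any(masks[[i]] & masks[[j]]))
          stop("overlapping lesions: '", spec$lesions[[j]]$id, "' and '",
               spec$lesions[[i]]$id, "'", call. = FALSE)
      }
    }
  }
  for (i in seq_along(masks)) {
    suv[masks[[i]]] <- lesion_suv(spec$lesions[[i]], time_point)
  }
  uptake_volume(suv, spec$grid, units = "SUV")
}

#' Ground-truth activity-concentration volume
#'
#' Inverts the SUV definition to obtain the injection-time activity
#' concentration that the painted SUV map implies:
#' \code{C[kBq/mL] = SUV * A_net[kBq] / W[g]} (1 g/mL density), which
#' reduces to \code{SUV * A_net_MBq / W_kg}.
#'
#' @inheritParams phantom_meta
#' @return An \code{\link{uptake_volume}} in \code{"kBq/mL"} units.
#' @export
build_activity_volume <- function(spec, time_point) {
  suv <- build_suv_map(spec, time_point)
  a_net <- spec$injected_activity_MBq[time_point]
  conc <- suv$data * a_net / spec$subject_weight_kg
  uptake_volume(conc, spec$grid, units = "kBq/mL")
}

# Expected (Poisson-mean) counts for a concentration volume.
expected_counts <- function(activity, meta) {
  stopifnot(inherits(activity, "uptake_volume"), inherits(meta, "acquisition_meta"))
  if (activity$units != "kBq/mL")
    stop("expected a volume in units 'kBq/mL'", call. = FALSE)
  if (any(activity$data < 0))
    stop("negative activity concentrations", call. = FALSE)
  dt <- meta$t_acquisition_start_min - meta$t_injection_min
  c_acq <- activity$data / decay_factor(dt, meta$half_life_min)
  c_acq * voxel_volume_ml(activity$grid) * meta$calibration_factor *
    meta$dwell_time_s
}

#' Simulate a count volume from ground-truth activity
#'
#' Forward model of a calibrated, fully corrected quantitative SPECT
#' reconstruction: the injection-time concentration is decayed forward to
#' acquisition start, converted to expected counts per voxel
#' \code{lambda = C_acq * v_vox * S * T}, and Poisson noise is drawn.
#' Attenuation, scatter and resolution effects are assumed already
#' corrected, as in the image domain where quantification operates.
#'
#' @param activity an \code{uptake_volume} of injection-time concentration
#'   (\code{"kBq/mL"}).
#' @param meta an \code{\link{acquisition_meta}} (supplies decay interval,
#'   calibration factor and dwell time).
#' @param seed integer seed; identical seeds give bit-identical volumes.
#' @param noiseless if \code{TRUE}, return the Poisson mean itself
#'   (useful for noise-free validation of the quantification chain).
#' @return An \code{uptake_volume} in \code{"counts"} units.
#' @export
simulate_counts <- function(activity, meta, seed = 1L, noiseless = FALSE) {
  lambda <- expected_counts(activity, meta)
  if (noiseless) {
    counts <- lambda
  } else {
    counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
    counts <- array(as.numeric(counts), dim = dim(lambda))
  }
  uptake_volume(counts, activity$grid, units = "counts")
}

#' Generate a complete paired longitudinal study
#'
#' Builds both time points of a phantom subject: ground-truth SUV maps,
#' activity volumes, Poisson count volumes, acquisition metadata, the VOI
#' list (lesions plus reference), and the ground-truth lesion table.
#' Mirrors the clinical study design of selecting at most six marker
#' lesions per subject across two acquisitions with a common field of view.
#'
#' @param spec a \code{\link{phantom_spec}} with 1 to 6 lesions.
#' @param seeds length-2 integer vector, one seed per time point.
#' @param noiseless if \code{TRUE}, count volumes carry the Poisson mean.
#' @return A list with elements \code{tp1}, \code{tp2} (each a list
#'   \code{counts}, \code{activity}, \code{suv_truth}, \code{meta}),
#'   \code{vois}, \code{truth} (data.frame \code{lesion_id, region,
#'   true_suv_tp1, true_suv_tp2, true_change, true_category}), and
#'   \code{grid}.
#' @export
make_longitudinal_pair <- function(spec, seeds = c(1L, 2L), noiseless = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$lesions) < 1L)
    stop("phantom needs at least one lesion", call. = FALSE)
  if (length(spec$lesions) > 6L)
    stop("phantom has ", length(spec$lesions),
         " lesions; the study design allows a maximum of six lesions ",
         "per subject", call. = FALSE)
  if (length(seeds) != 2L) stop("'seeds' must have length 2", call. = FALSE)
  tp <- lapply(1:2, function(t) {
    meta <- phantom_meta(spec, t)
    activity <- build_activity_volume(spec, t)
    list(counts = simulate_counts(activity, meta, seed = seeds[t],
                                  noiseless = noiseless),
         activity = activity,
         suv_truth = build_suv_map(spec, t),
         meta = meta)
  })
  truth <- do.call(rbind, lapply(spec$lesions, function(l) {
    data.frame(lesion_id = l$id, region = l$region,
               true_suv_tp1 = l$suv_tp1,
               true_suv_tp2 = lesion_suv(l, 2L),
               true_change = l$fractional_change,
               true_category = classify_change(l$fractional_change),
               stringsAsFactors = FALSE)
  }))
  vois <- c(lapply(spec$lesions, lesion_voi), list(spec$reference_voi))
  list(tp1 = tp[[1]], tp2 = tp[[2]], vois = vois, truth = truth,
       grid = spec$grid)
}

#' Default phantom emulating the study conditions
#'
#' A single-subject phantom with parameters drawn from the cohort the
#' package targets: 64^3 grid at 2.4 mm, three spherical lesions at
#' baseline SUV_peak around 20 with configurable true changes, reference
#' vertebra SUV_mean 5.6 / 4.9, 75 kg subject, 573 / 542 MBq injected,
#' acquisition 231 / 234 min after injection.
#'
#' @param fractional_changes numeric vector (length 1 to 6) of true lesion
#'   fractional changes.
#' @param lesion_suv_tp1 baseline lesion SUV.
#' @param n n-th axis size of the cubic grid.
#' @return A \code{\link{phantom_spec}}.
#' @export
example_phantom_spec <- function(fractional_changes = c(0.5, 0, -0.5),
                                 lesion_suv_tp1 = 20.4, n = 64L) {
  grid <- grid_geometry(rep(n, 3L), 2.4)
  half <- (n - 1) / 2 * 2.4
  ref <- ellipsoid_voi("ref_vertebra", c(0, 0, -half * 0.5),
                       c(12, 12, 14), label = "reference",
                       region = "lumbar spine")
  k <- length(fractional_changes)
  if (k < 1L || k > 6L)
    stop("between 1 and 6 lesions supported", call. = FALSE)
  ang <- 2 * pi * (seq_len(k) - 1) / max(k, 2)
  lesions <- lapply(seq_len(k), function(i) {
    lesion_spec(sprintf("lesion_%02d", i),
                center = c(0.45 * half * cos(ang[i]),
                           0.45 * half * sin(ang[i]), half * 0.35),
                semi_axes = 9, suv_tp1 = lesion_suv_tp1,
                fractional_change = fractional_changes[i])
  })
  phantom_spec(grid, background_suv = 1.0, reference_suv = c(5.6, 4.9),
               reference_voi = ref, lesions = lesions)
}

#' Stochastic visual-reader model
#'
#' Emulates a human reader as a per-category confusion matrix: row i gives
#' the probability of each emitted rating when the true change category is
#' i. Rows and columns follow the fixed category order (progressive,
#' stable, regressive).
#'
#' @param confusion 3x3 row-stochastic matrix (rows sum to 1 within 1e-12,
#'   entries in [0, 1]). Default is a perfectly accurate reader.
#' @param seed integer seed used by \code{\link{simulate_reader}}.
#' @return An object of class \code{reader_model}.
#' @export
reader_model <- function(confusion = diag(3), seed = 1L) {
  confusion <- as.matrix(confusion)
  if (!identical(dim(confusion), c(3L, 3L)))
    stop("confusion must be a 3x3 matrix", call. = FALSE)
  if (any(confusion < 0) || any(confusion > 1))
    stop("confusion entries must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(confusion) - 1) > 1e-12))
    stop("confusion rows must each sum to 1", call. = FALSE)
  dimnames(confusion) <- list(true = change_categories(),
                              rated = change_categories())
  structure(list(confusion = confusion, seed = as.integer(seed)),
            class = "reader_model")
}

#' Simulate a visual reading of true change categories
#'
#' Each rating is drawn from the confusion-matrix row of the lesion's true
#' category; reproducible under the model's seed.
#'
#' @param true_changes character vector (or factor) of true categories in
#'   \code{c("progressive", "stable", "regressive")}.
#' @param model a \code{\link{reader_model}}.
#' @param lesion_ids optional ids for the output rating vector.
#' @param source name tag for the simulated reader.
#' @return A \code{\link{rating_vector}} data.frame.
#' @export
simulate_reader <- function(true_changes, model, lesion_ids = NULL,
                            source = "simulated reader") {
  stopifnot(inherits(model, "reader_model"))
  cats <- change_categories()
  true_changes <- as.character(true_changes)
  if (!all(true_changes %in% cats))
    stop("true categories must be in {",
         paste(cats, collapse = ", "), "}", call. = FALSE)
  if (is.null(lesion_ids)) lesion_ids <- seq_along(true_changes)
  ratings <- with_seed(model$seed, {
    vapply(true_changes, function(tc) {
      sample(cats, 1L, prob = model$confusion[tc, ])
    }, character(1), USE.NAMES = FALSE)
  })
  rating_vector(lesion_ids, ratings, source = source)
}

# Evaluate 'expr' under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
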
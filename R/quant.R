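#' Convert a count volume to activity concentration
#'
#' Inverts the calibrated imaging chain: counts in a voxel over the dwell
#' time \code{T} at calibration factor \code{S} correspond to
#' \code{C_acq = counts / (v_vox * S * T)} kBq/mL at acquisition start, and
#' decay correction to injection time multiplies by
#' \code{2^((t_acq - t_inj)/T_half)}. All concentrations in this package
#' are referenced to injection time, which makes studies acquired at
#' different delays after injection comparable.
#'
#' @param counts an \code{\link{uptake_volume}} with units \code{"counts"}.
#' @param meta an \code{\link{acquisition_meta}}.
#' @return An \code{uptake_volume} with units \code{"kBq/mL"}.
#' @export
counts_to_concentration <- function(counts, meta) {
  stopifnot(inherits(counts, "uptake_volume"), inherits(meta, "acquisition_meta"))
  if (counts$units != "counts")
    stop("expected a volume in units 'counts', got '", counts$units, "'",
         call. = FALSE)
  v_vox <- voxel_volume_ml(counts$grid)
  c_acq <- counts$data / (v_vox * meta$calibration_factor * meta$dwell_time_s)
  dt <- meta$t_acquisition_start_min - meta$t_injection_min
  c_inj <- c_acq * decay_factor(dt, meta$half_life_min)
  uptake_volume(c_inj, counts$grid, units = "kBq/mL")
}

#' Convert activity concentration to SUV
#'
#' Body-weight SUV under the 1 g/mL tissue-density convention:
#' \code{SUV = C[kBq/mL] * W[g] / A_net[kBq]}, which reduces to
#' \code{C * W_kg / A_net_MBq}. SUVs inherit the injection-time reference
#' of the concentration volume.
#'
#' @param conc an \code{uptake_volume} with units \code{"kBq/mL"}.
#' @param a_net_MBq net injected activity in MBq (> 0), e.g. from
#'   \code{\link{net_injected_activity}}.
#' @param weight_kg body weight in kg (> 0).
#' @return An \code{uptake_volume} with units \code{"SUV"}.
#' @export
concentration_to_suv <- function(conc, a_net_MBq, weight_kg) {
  stopifnot(inherits(conc, "uptake_volume"))
  if (conc$units != "kBq/mL")
    stop("expected a volume in units 'kBq/mL', got '", conc$units, "'",
         call. = FALSE)
  if (length(a_net_MBq) != 1L || !is.finite(a_net_MBq) || a_net_MBq <= 0)
    stop("net injected activity must be a single positive value", call. = FALSE)
  if (length(weight_kg) != 1L || !is.finite(weight_kg) || weight_kg <= 0)
    stop("body weight must be a single positive value", call. = FALSE)
  uptake_volume(conc$data * weight_kg / a_net_MBq, conc$grid, units = "SUV")
}

# Shared mask/volume sanity checks for the VOI statistics.
check_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "uptake_volume"))
  if (!is.logical(mask) || !identical(dim(mask), dim(volume$data)))
    stop("mask must be a logical array of the volume's shape", call. = FALSE)
  if (!any(mask)) stop("empty VOI mask", call. = FALSE)
}

#' VOI uptake statistics
#'
#' \code{suv_mean} and \code{suv_max} are the arithmetic mean and maximum
#' over the masked voxels. \code{suv_peak} averages over a fixed-volume
#' sphere (default 1 mL, i.e. radius \eqn{(3V/4\pi)^{1/3} \approx} 6.204 mm)
#' centred on the hottest masked voxel; the sphere may extend beyond the
#' VOI but is clipped to the grid. Peak averaging makes the statistic
#' robust to single-voxel noise, the rationale behind peak-uptake response
#' criteria.
#'
#' When several masked voxels tie for the maximum (exact ties arise in
#' noise-free phantoms, where every voxel of a homogeneous lesion is
#' maximal), the sphere is seeded at the tied voxel whose sphere average
#' is greatest — the placement that maximizes the reported peak, as in
#' peak-uptake response criteria — with remaining ties broken by lowest
#' linear (column-major) index for determinism. A homogeneous lesion that
#' fully contains the sphere therefore reports its own value.
#'
#' @param volume an \code{\link{uptake_volume}} (any units; typically SUV).
#' @param mask logical array from \code{\link{voi_mask}}.
#' @return \code{suv_mean}/\code{suv_max}: a scalar. \code{suv_peak}: a
#'   scalar with attributes \code{n_peak} (voxels in the peak sphere) and
#'   \code{peak_center} (world mm of the seed voxel).
#' @export
suv_mean <- function(volume, mask) {
  check_mask(volume, mask)
  mean(volume$data[mask])
}

#' @rdname suv_mean
#' @export
suv_max <- function(volume, mask) {
  check_mask(volume, mask)
  max(volume$data[mask])
}

#' @rdname suv_mean
#' @param peak_volume_mL volume of the peak-averaging sphere in mL.
#' @export
suv_peak <- function(volume, mask, peak_volume_mL = 1.0) {
  check_mask(volume, mask)
  if (peak_volume_mL <= 0) stop("peak volume must be positive", call. = FALSE)
  grid <- volume$grid
  shape <- grid$shape
  r <- (3 * peak_volume_mL * 1000 / (4 * pi))^(1 / 3)  # mm
  # sphere membership relative to a seed voxel centre: since both seed and
  # candidates sit on voxel centres, membership is a fixed integer-offset
  # stencil on a regular grid
  reach <- floor(r / grid$spacing)
  offs <- as.matrix(expand.grid(dx = -reach[1]:reach[1],
                                dy = -reach[2]:reach[2],
                                dz = -reach[3]:reach[3]))
  offs <- offs[colSums(t(offs)^2 * grid$spacing^2) <= r^2, , drop = FALSE]
  sphere_mean <- function(sub) {
    nb <- sweep(offs, 2, sub, "+")
    keep <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    nb <- nb[keep, , drop = FALSE]
    vals <- volume$data[nb[, 1] + (nb[, 2] - 1) * shape[1] +
                          (nb[, 3] - 1) * shape[1] * shape[2]]
    c(mean(vals), nrow(nb))
  }
  idx <- which(mask)                    # ascending linear index
  vmax <- max(volume$data[idx])
  cand <- idx[volume$data[idx] == vmax]
  best <- NULL
  for (seed in cand) {                  # ascending: first best wins ties
    sub <- arrayInd(seed, shape)[1, ]
    sm <- sphere_mean(sub)
    if (is.null(best) || sm[1] > best$mean + 1e-15) {
      best <- list(mean = sm[1], n = sm[2], sub = sub)
    }
  }
  center <- grid$origin + (best$sub - 1) * grid$spacing
  structure(best$mean, n_peak = as.integer(best$n), peak_center = center)
}

#' Lesion-to-reference uptake ratio
#'
#' Ratio of a lesion's SUV_peak to the reference region's SUV_mean. Both
#' scale identically with injected dose and body weight, so the ratio
#' cancels global fluctuations in bone metabolism between time points.
#'
#' @param lesion_peak lesion SUV_peak (>= 0).
#' @param reference_mean reference-region SUV_mean (> 0).
#' @return The dimensionless ratio.
#' @export
uptake_ratio <- function(lesion_peak, reference_mean) {
  if (any(!is.finite(reference_mean)) || any(reference_mean <= 0))
    stop("reference SUV_mean must be positive (no reference region available)",
         call. = FALSE)
  lesion_peak / reference_mean
}

#' Quantify a study
#'
#' Runs the full quantification chain on one acquisition: counts to
#' decay-corrected concentration, concentration to SUV, then SUV_max,
#' SUV_mean and SUV_peak for each VOI.
#'
#' @param counts an \code{uptake_volume} of counts (or a volume already in
#'   \code{"SUV"} units, which skips the conversion).
#' @param meta an \code{\link{acquisition_meta}}.
#' @param vois list of \code{\link{ellipsoid_voi}}.
#' @param peak_volume_mL passed to \code{\link{suv_peak}}.
#' @return A data.frame with one row per VOI: \code{voi_id, label, region,
#'   n_voxels, n_peak, suv_mean, suv_max, suv_peak,
#'   activity_concentration_peak} (kBq/mL at injection time).
#' @export
quantify_study <- function(counts, meta, vois, peak_volume_mL = 1.0) {
  stopifnot(inherits(counts, "uptake_volume"))
  if (counts$units == "SUV") {
    suv <- counts
    suv_per_conc <- meta$body_weight_kg / net_injected_activity(meta)
  } else {
    conc <- counts_to_concentration(counts, meta)
    suv <- concentration_to_suv(conc, net_injected_activity(meta),
                                meta$body_weight_kg)
    suv_per_conc <- meta$body_weight_kg / net_injected_activity(meta)
  }
  rows <- lapply(vois, function(v) {
    m <- voi_mask(v, suv$grid)
    pk <- suv_peak(suv, m, peak_volume_mL)
    data.frame(voi_id = v$voi_id, label = v$label, region = v$region,
               n_voxels = sum(m), n_peak = attr(pk, "n_peak"),
               suv_mean = suv_mean(suv, m), suv_max = suv_max(suv, m),
               suv_peak = as.numeric(pk),
               activity_concentration_peak = as.numeric(pk) / suv_per_conc)
  })
  do.call(rbind, rows)
}
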
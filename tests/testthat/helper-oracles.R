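# Independent brute-force oracles and small fixtures used across tests.
# The oracles deliberately recompute quantities from first principles
# (exhaustive voxel loops, direct formulas) rather than calling the
# package code paths they check.

# Exhaustive ellipsoid membership over every voxel centre.
brute_voi_mask <- function(voi, grid) {
  mask <- array(FALSE, grid$shape)
  for (k in seq_len(grid$shape[3])) {
    for (j in seq_len(grid$shape[2])) {
      for (i in seq_len(grid$shape[1])) {
        x <- grid$origin + (c(i, j, k) - 1) * grid$spacing
        mask[i, j, k] <- sum(((x - voi$center) / voi$semi_axes)^2) <= 1
      }
    }
  }
  mask
}

# Exhaustive peak-sphere averaging: every masked voxel tied for the
# maximum is a candidate seed; the sphere mean is recomputed by direct
# world-distance thresholding over the full grid; best mean wins, earliest
# linear index on remaining ties.
brute_suv_peak <- function(volume, mask, peak_volume_mL = 1.0) {
  grid <- volume$grid
  r <- (3 * peak_volume_mL * 1000 / (4 * pi))^(1 / 3)
  coords <- as.matrix(expand.grid(
    x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
    y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
    z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]))
  idx <- which(mask)
  vmax <- max(volume$data[idx])
  cand <- idx[volume$data[idx] == vmax]
  best <- -Inf
  for (seed in cand) {
    ctr <- coords[seed, ]
    inside <- rowSums(sweep(coords, 2, ctr)^2) <= r^2
    m <- mean(volume$data[inside])
    if (m > best + 1e-15) best <- m
  }
  best
}

# A random three-category rating vector.
rand_ratings <- function(n, seed, source = "r",
                         prob = c(1, 1, 1) / 3) {
  set.seed(seed)
  rating_vector(seq_len(n),
                sample(change_categories(), n, replace = TRUE, prob = prob),
                source = source)
}

# A small phantom (24^3 voxels) with one lesion and a reference region,
# quick enough for per-test simulation.
small_phantom <- function(fractional_change = 0,
                          lesion_suv = 20.4,
                          reference_suv = c(5.6, 4.9),
                          background_suv = 1.0,
                          n = 24L) {
  grid <- grid_geometry(rep(n, 3L), 2.4)
  half <- (n - 1) / 2 * 2.4
  phantom_spec(
    grid,
    background_suv = background_suv,
    reference_suv = reference_suv,
    reference_voi = ellipsoid_voi("ref", c(0, 0, -half * 0.45), c(9, 9, 10),
                                  label = "reference", region = "vertebra"),
    lesions = list(lesion_spec("les1", c(0, 0, half * 0.45), 8,
                               suv_tp1 = lesion_suv,
                               fractional_change = fractional_change)))
}

# Lesion metrics table in the shape classify_lesions() consumes.
as_lesion_metrics <- function(metrics, ref_suv_mean = NA_real_) {
  d <- metrics[metrics$label == "lesion", ]
  data.frame(lesion_id = d$voi_id, suv_peak = d$suv_peak,
             ref_suv_mean = ref_suv_mean, stringsAsFactors = FALSE)
}
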
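#' Ellipsoidal volumes of interest
#'
#' Lesions and reference regions are delineated as axis-aligned ellipsoids
#' in world (mm) coordinates, mirroring the ellipsoidal VOI tools of
#' clinical fused SPECT/CT workstations. A voxel belongs to the VOI when
#' its centre satisfies \eqn{\sum_i ((x_i - c_i)/a_i)^2 \le 1}.
#'
#' @param voi_id character label, unique within a study.
#' @param center numeric length-3 world mm centre.
#' @param semi_axes numeric length-3 semi-axes in mm (all > 0); a scalar
#'   gives a sphere.
#' @param label \code{"lesion"} or \code{"reference"}.
#' @param region free-text anatomical tag (e.g. \code{"rib"},
#'   \code{"lumbar spine"}).
#' @return An object of class \code{ellipsoid_voi}.
#' @export
ellipsoid_voi <- function(voi_id, center, semi_axes,
                          label = c("lesion", "reference"), region = "") {
  label <- match.arg(label)
  center <- as.numeric(center)
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3L)
  semi_axes <- as.numeric(semi_axes)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("'center' must be 3 finite mm coordinates", call. = FALSE)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0))
    stop("'semi_axes' must be 3 positive mm values", call. = FALSE)
  structure(list(voi_id = as.character(voi_id), center = center,
                 semi_axes = semi_axes, label = label,
                 region = as.character(region)),
            class = "ellipsoid_voi")
}

#' @export
print.ellipsoid_voi <- function(x, ...) {
  cat(sprintf("ellipsoid_voi '%s' (%s, %s): centre (%s) mm, semi-axes (%s) mm\n",
              x$voi_id, x$label, x$region,
              paste(format(x$center), collapse = ", "),
              paste(format(x$semi_axes), collapse = ", ")))
  invisible(x)
}

#' Rasterize a VOI onto a grid
#'
#' Membership is decided by voxel-centre inclusion (no partial volumes),
#' so masks are deterministic and verifiable by exhaustive looping.
#'
#' @param voi an \code{\link{ellipsoid_voi}}.
#' @param grid a \code{\link{grid_geometry}}.
#' @return A logical 3-D array of the grid's shape.
#' @export
voi_mask <- function(voi, grid) {
  stopifnot(inherits(voi, "ellipsoid_voi"), inherits(grid, "grid_geometry"))
  q <- lapply(1:3, function(a) {
    ((axis_coords(grid, a) - voi$center[a]) / voi$semi_axes[a])^2
  })
  mask <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
  if (!any(mask))
    stop("VOI '", voi$voi_id, "' contains no voxel centers", call. = FALSE)
  mask
}

# TRUE when the ellipsoid's bounding box lies inside the half-voxel-padded
# grid extent.
voi_inside_grid <- function(voi, grid) {
  ext <- grid_extent(grid)
  all(voi$center - voi$semi_axes >= ext[, "lo"]) &&
    all(voi$center + voi$semi_axes <= ext[, "hi"])
}

#' Read and write VOI tables
#'
#' CSV layout: one row per VOI with columns \code{voi_id, label, region,
#' cx_mm, cy_mm, cz_mm, ax_mm, ay_mm, az_mm}.
#'
#' @param vois a list of \code{\link{ellipsoid_voi}} objects.
#' @param path CSV file path.
#' @return \code{read_vois} returns a list of \code{ellipsoid_voi};
#'   \code{write_vois} returns \code{path} invisibly.
#' @export
write_vois <- function(vois, path) {
  df <- do.call(rbind, lapply(vois, function(v) {
    data.frame(voi_id = v$voi_id, label = v$label, region = v$region,
               cx_mm = v$center[1], cy_mm = v$center[2], cz_mm = v$center[3],
               ax_mm = v$semi_axes[1], ay_mm = v$semi_axes[2],
               az_mm = v$semi_axes[3])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vois
#' @export
read_vois <- function(path) {
  if (!file.exists(path)) stop("no such VOI file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("voi_id", "label", "region", "cx_mm", "cy_mm", "cz_mm",
            "ax_mm", "ay_mm", "az_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("VOI file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    ellipsoid_voi(df$voi_id[i],
                  c(df$cx_mm[i], df$cy_mm[i], df$cz_mm[i]),
                  c(df$ax_mm[i], df$ay_mm[i], df$az_mm[i]),
                  label = df$label[i], region = df$region[i])
  })
}
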
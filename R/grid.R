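#' Voxel grid geometry
#'
#' Describes a regular 3-D voxel grid: number of voxels per axis, voxel
#' spacing in millimetres, and the world coordinate (mm) of the centre of
#' the first voxel. World coordinates of voxel \code{(i, j, k)} (1-based)
#' are \code{origin + (index - 1) * spacing}.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, voxel spacing in mm (all > 0).
#'   A scalar is recycled to an isotropic grid.
#' @param origin numeric vector of length 3, world mm coordinate of the
#'   centre of voxel (1,1,1). Default places the grid centre at the world
#'   origin.
#' @return An object of class \code{grid_geometry}.
#' @examples
#' g <- grid_geometry(c(64, 64, 64), 2.4)
#' voxel_volume_ml(g)
#' @export
grid_geometry <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)", call. = FALSE)
  if (is.null(origin)) origin <- -(shape - 1L) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @rdname grid_geometry
#' @param grid a \code{grid_geometry}.
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "grid_geometry"))
  prod(grid$spacing) / 1000  # mm^3 -> mL
}

# World mm coordinates of voxel centres along one axis.
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

# Half-voxel-padded world extent of the grid, rows = axis, cols = (lo, hi).
grid_extent <- function(grid) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 1) * grid$spacing + grid$spacing / 2
  cbind(lo = lo, hi = hi)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Voxel volumes with units
#'
#' A 3-D numeric array bound to a \code{\link{grid_geometry}} and a unit
#' tag: raw detector \code{"counts"}, activity concentration
#' \code{"kBq/mL"} (referenced to injection time), or dimensionless
#' \code{"SUV"}.
#'
#' @param data 3-D numeric array matching \code{grid$shape}.
#' @param grid a \code{grid_geometry}.
#' @param units one of \code{"counts"}, \code{"kBq/mL"}, \code{"SUV"}.
#' @return An object of class \code{uptake_volume}.
#' @export
uptake_volume <- function(data, grid, units = c("counts", "kBq/mL", "SUV")) {
  units <- match.arg(units)
  stopifnot(inherits(grid, "grid_geometry"))
  data <- as.array(data)
  if (!identical(dim(data), as.integer(grid$shape)))
    stop("volume dimensions do not match grid shape", call. = FALSE)
  if (any(data < 0, na.rm = TRUE))
    stop("volume values must be non-negative", call. = FALSE)
  structure(list(data = data, grid = grid, units = units),
            class = "uptake_volume")
}

#' @export
print.uptake_volume <- function(x, ...) {
  cat(sprintf("uptake_volume [%s]: %s voxels, range %.4g .. %.4g\n",
              x$units, paste(x$grid$shape, collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read and write volumes as NIfTI
#'
#' The grid geometry is stored in the NIfTI sform (a diagonal affine whose
#' offset is the world coordinate of the first voxel centre) and the unit
#' tag in the \code{descrip} header field.
#'
#' @param volume an \code{uptake_volume}.
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return \code{write_volume} returns \code{path} invisibly;
#'   \code{read_volume} returns an \code{uptake_volume}.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "uptake_volume"))
  img <- RNifti::asNifti(volume$data)
  aff <- diag(c(volume$grid$spacing, 1))
  aff[1:3, 4] <- volume$grid$origin
  img <- RNifti::`sform<-`(img, value = structure(aff, code = 2L))
  img$descrip <- volume$units
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param units unit tag to assume when the header carries none.
#' @export
read_volume <- function(path, units = NULL) {
  if (!file.exists(path)) stop("no such volume file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- grid_geometry(dim(img), spacing, origin = aff[1:3, 4])
  hdr_units <- trimws(RNifti::niftiHeader(img)$descrip)
  if (is.null(units)) {
    if (!hdr_units %in% c("counts", "kBq/mL", "SUV"))
      stop("volume file ", path, " carries no unit tag; pass 'units'",
           call. = FALSE)
    units <- hdr_units
  }
  uptake_volume(as.array(img), grid, units)
}
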
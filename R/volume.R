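#' 3D scalar volume with voxel geometry
#'
#' A `vx_volume` wraps a 3D numeric array together with the physical voxel
#' spacing (mm per voxel along each axis) and the physical coordinate of voxel
#' `(0, 0, 0)`. All grids in the package use a single internal axis convention
#' (the array's column-major i, j, k axes); conversion from on-disk
#' orientations happens at the I/O boundary. Voxel indices are 0-based in
#' every exported interface that talks about coordinates.
#'
#' @param data numeric 3D array; must contain no `NA`/`NaN` values.
#' @param spacing numeric length-3, strictly positive, voxel size in mm.
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return An object of class `vx_volume`.
#' @examples
#' v <- vx_volume(array(rnorm(8^3), dim = c(8, 8, 8)), spacing = c(1.5, 1.5, 1.5))
#' dim(v$data)
#' @export
vx_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ",
         if (is.array(data)) paste0(length(dim(data)), "D") else class(data)[1])
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("volume data contains NA/NaN values")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vx_volume")
}

#' Binary mask sharing the geometry of a volume
#'
#' @param data 3D array coercible to 0/1 (logical or numeric).
#' @inheritParams vx_volume
#' @return An object of class `vx_mask`; `data` is stored as a logical array.
#' @export
vx_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3D array")
  if (anyNA(data)) stop("mask data contains NA values")
  vals <- as.numeric(data)
  if (!all(vals %in% c(0, 1)))
    stop("mask data must contain only 0 and 1")
  m <- array(as.logical(data), dim = dim(data))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers")
  structure(list(data = m, spacing = spacing, origin = origin),
            class = "vx_mask")
}

#' @export
print.vx_volume <- function(x, ...) {
  cat("<vx_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, range [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.vx_mask <- function(x, ...) {
  cat("<vx_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

#' @keywords internal
is_vx_volume <- function(x) inherits(x, "vx_volume")

#' @keywords internal
is_vx_mask <- function(x) inherits(x, "vx_mask")

# Geometry equality check used before any voxelwise operation.
#' @keywords internal
check_same_geometry <- function(a, b, what = "inputs") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(what, " differ in grid size: ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(what, " differ in voxel spacing")
  invisible(TRUE)
}
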
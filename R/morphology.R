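# Binary morphology on 3D logical arrays with a ball structuring element,
# implemented by OR/AND over integer shifts of the array. Adequate for the
# small structuring radii used in rough mask extraction.

# Integer offsets inside a Euclidean ball of the given radius (voxels).
#' @keywords internal
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
}

# Shift a logical array by integer offsets, padding with `fill`.
#' @keywords internal
shift_array <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  src_x <- sx - dx; src_y <- sy - dy; src_z <- sz - dz
  okx <- src_x >= 1L & src_x <= d[1]
  oky <- src_y >= 1L & src_y <= d[2]
  okz <- src_z >= 1L & src_z <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[src_x[okx], src_y[oky], src_z[okz]]
  out
}

#' @keywords internal
dilate_ball <- function(a, radius) {
  offs <- ball_offsets(radius)
  out <- array(FALSE, dim = dim(a))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_array(a, offs$dx[i], offs$dy[i], offs$dz[i], FALSE)
  out
}

#' @keywords internal
erode_ball <- function(a, radius) {
  !dilate_ball(!a, radius)
}

#' @keywords internal
close_ball <- function(a, radius) {
  erode_ball(dilate_ball(a, radius), radius)
}

# Fill interior holes: background components (6-connectivity) that do not
# touch the grid border become foreground.
#' @keywords internal
fill_holes <- function(a) {
  d <- dim(a)
  labs <- label_components_cpp(as.logical(!a), as.integer(d), 6L)
  labs <- array(labs, dim = d)
  border_labels <- unique(c(labs[1, , ], labs[d[1], , ],
                            labs[, 1, ], labs[, d[2], ],
                            labs[, , 1], labs[, , d[3]]))
  border_labels <- border_labels[border_labels != 0L]
  interior <- (labs != 0L) & !(labs %in% border_labels)
  dim(interior) <- d
  a | interior
}

#' Connected components of a 3D binary array
#'
#' @param a logical 3D array.
#' @param connectivity 6 or 26.
#' @return Integer array of component labels (0 = background).
#' @export
connected_components <- function(a, connectivity = 26) {
  stopifnot(is.array(a), length(dim(a)) == 3L)
  array(label_components_cpp(as.logical(a), as.integer(dim(a)),
                             as.integer(connectivity)),
        dim = dim(a))
}
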
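#' Read a 3D volume from a NIfTI file
#'
#' Reads a NIfTI-1/2 image into a [vx_volume]. Integer-typed files are
#' promoted to double; voxel spacing and the position of voxel (0,0,0) are
#' taken from the file header. Only genuinely 3D images are accepted: 4D
#' inputs (e.g. cine sequences) are rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [vx_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D (", path,
         "); 4D inputs are not supported")
  xf <- RNifti::xform(img)
  vx_volume(array(as.numeric(img), dim = d),
            spacing = as.numeric(RNifti::pixdim(img))[1:3],
            origin = as.numeric(xf[1:3, 4]))
}

#' Write a 3D volume to a NIfTI file
#'
#' Stores the data as 32-bit floats; round trips are exact at that precision.
#' Volumes containing `NaN` are refused at write time.
#'
#' @param v a [vx_volume].
#' @param path destination path (`.nii` or `.nii.gz`); parent must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_vx_volume(v))
  if (anyNA(v$data) || any(!is.finite(v$data)))
    stop("volume contains NA/NaN/Inf values; refusing to write")
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(v$data)
  xf <- diag(4)
  diag(xf)[1:3] <- v$spacing
  xf[1:3, 4] <- v$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#'
#' Any strictly positive stored value counts as foreground.
#'
#' @inheritParams read_volume
#' @return A [vx_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  vx_mask(array(v$data > 0, dim = dim(v$data)),
          spacing = v$spacing, origin = v$origin)
}

#' Write a binary mask to a NIfTI file (lossless, uint8)
#'
#' @param m a [vx_mask].
#' @inheritParams write_volume
#' @export
write_mask <- function(m, path) {
  stopifnot(is_vx_mask(m))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(array(as.integer(m$data), dim = dim(m$data)))
  xf <- diag(4)
  diag(xf)[1:3] <- m$spacing
  xf[1:3, 4] <- m$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::pixdim(img) <- m$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Serialise a diagnosis report to JSON
#'
#' @param report a `vx_report` as returned by [voxar_diagnose()] or
#'   [isa_diagnose()].
#' @param path destination `.json` path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "vx_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a diagnosis report back from JSON
#'
#' @param path a `.json` file written by [write_report()].
#' @return A `vx_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "vx_report")
}

#' @export
print.vx_report <- function(x, ...) {
  cat("<vx_report> method: ", x$method, ", diagnosis: ",
      if (is.null(x$diagnosis)) "(refused)" else x$diagnosis, "\n", sep = "")
  if (!is.null(x$histogram) && length(x$histogram$percent)) {
    h <- unlist(x$histogram$percent)
    cat("  rating histogram (%):",
        paste(sprintf("%s=%.1f", names(h), h), collapse = ", "), "\n")
  }
  if (!is.null(x$ncc_scores)) {
    s <- unlist(x$ncc_scores)
    cat("  NCC scores:",
        paste(sprintf("%s=%.4f", names(s), s), collapse = ", "), "\n")
  }
  invisible(x)
}
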
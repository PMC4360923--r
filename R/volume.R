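#' 3D scalar volumes and aligned masks
#'
#' `mr_volume()` wraps a 3D numeric array of voxel intensities together with
#' its voxel spacing in millimetres. All arithmetic in the package is done in
#' 64-bit floating point regardless of the on-disk storage type, because the
#' bias-correction subtractions performed after denoising are
#' precision-sensitive. Indices are 0-based conceptually but stored as plain R
#' arrays; no reorientation is ever performed — the denoising method is
#' orientation-agnostic.
#'
#' @param data 3D numeric array of finite intensities.
#' @param spacing Numeric length-3, mm per axis, strictly positive.
#' @return An object of class `mr_volume` with elements `data` (double array)
#'   and `spacing`.
#' @examples
#' v <- mr_volume(array(1, c(4, 5, 6)))
#' dim(v)
#' @export
mr_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("not a 3D volume: 'data' must be a 3-dimensional array")
  if (!is.numeric(data))
    stop("volume data must be numeric")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers")
  structure(list(data = data, spacing = spacing), class = "mr_volume")
}

#' Coerce to an `mr_volume`
#'
#' Plain 3D arrays are accepted anywhere a volume is, via this coercion.
#'
#' @param x An `mr_volume` or a 3D numeric array.
#' @param spacing Spacing used when `x` is a bare array.
#' @return An `mr_volume`.
#' @export
as_mr_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "mr_volume")) return(x)
  mr_volume(x, spacing)
}

#' @export
dim.mr_volume <- function(x) dim(x$data)

#' @export
print.mr_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mr_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Boolean mask aligned to a volume
#'
#' @param data 3D logical array; `TRUE` marks voxels belonging to the mask
#'   (e.g. the image background used for noise estimation).
#' @return An object of class `mr_mask`.
#' @export
mr_mask <- function(data) {
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("numeric mask data must be 0/1")
    data <- array(data != 0, dim(data))
  }
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("mask data must be a 3D logical array")
  structure(list(data = data), class = "mr_mask")
}

#' @export
dim.mr_mask <- function(x) dim(x$data)

#' @export
print.mr_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mr_mask> %d x %d x %d voxels, %d TRUE (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

#' @rdname mr_mask
#' @param x An `mr_mask`, 3D logical array, or 0/1 numeric array.
#' @export
as_mr_mask <- function(x) {
  if (inherits(x, "mr_mask")) return(x)
  mr_mask(x)
}

# every volume/mask or volume/volume pairing is shape-checked at use
check_same_shape <- function(a, b) {
  da <- if (inherits(a, c("mr_volume", "mr_mask"))) dim(a$data) else dim(a)
  db <- if (inherits(b, c("mr_volume", "mr_mask"))) dim(b$data) else dim(b)
  if (!identical(da, db))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Intensities are cast to 64-bit float; the shape is taken from the header.
#' Files whose payload is not 3-dimensional are rejected.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An `mr_volume` with spacing taken from the header `pixdim`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  a <- as.array(img)
  d <- dim(a)
  # tolerate trailing singleton dims some writers emit
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) d <- d[1:3]
  a <- array(as.vector(a), d)  # plain array, free of header attributes
  if (length(d) != 3L)
    stop("not a 3D volume: '", path, "' has ", length(d), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  mr_volume(a, sp)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v An `mr_volume` (or 3D array).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype On-disk storage type; `"double"` preserves values bitwise,
#'   the default `"float"` halves file size.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "float") {
  v <- as_mr_volume(v)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = datatype)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stop("could not write volume to: ", path)
  invisible(path)
}

#' Write a mask as a 0/1 NIfTI volume
#'
#' @param m An `mr_mask` or logical array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path) {
  m <- as_mr_mask(m)
  write_volume(mr_volume(array(as.double(m$data), dim(m$data))), path,
               datatype = "uint8")
}

#' Read a 0/1 NIfTI volume as a mask
#'
#' @param path Path to a NIfTI file containing 0/1 values.
#' @return An `mr_mask`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (!all(v$data %in% c(0, 1)))
    stop("mask file contains values other than 0/1: ", path)
  mr_mask(array(v$data != 0, dim(v$data)))
}
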
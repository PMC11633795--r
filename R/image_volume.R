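#' 3-D image volume with physical geometry
#'
#' An `image_volume` is a 3-D scalar lattice (CT intensities in HU, dose in
#' cGy, or a binary mask) together with its physical geometry: the position
#' in mm of the centre of the first voxel (`origin`) and the voxel spacing in
#' mm along each lattice axis. The anatomical axis convention is fixed
#' package-wide: lattice axis 1 runs left-right (LR), axis 2 anterior to
#' posterior (AP, increasing index = more posterior) and axis 3 inferior to
#' superior (SI, increasing index = more superior). All physical coordinates
#' are `origin + (index - 1) * spacing` in mm.
#'
#' @param data numeric 3-D array.
#' @param origin numeric length-3, mm position of the centre of voxel (1,1,1).
#' @param spacing numeric length-3, strictly positive voxel spacing in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("'origin' and 'spacing' must have length 3")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be strictly positive and finite")
  if (any(!is.finite(data)))
    stop("image values must be finite")
  structure(list(data = data, origin = origin, spacing = spacing),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): %s\n", paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  origin  (mm): %s\n", paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Extract the lattice geometry of a volume or vector field
#'
#' @param x an `image_volume` or `vector_field`.
#' @return A list with elements `dim`, `origin`, `spacing`.
#' @export
geometry <- function(x) {
  d <- if (inherits(x, "vector_field")) dim(x$u)[1:3] else dim(x$data)
  list(dim = as.integer(d), origin = x$origin, spacing = x$spacing)
}

#' Construct a bare lattice geometry
#'
#' @param dim integer length-3 lattice dimensions.
#' @param origin,spacing physical geometry in mm.
#' @export
make_geometry <- function(dim, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  list(dim = as.integer(dim), origin = as.numeric(origin),
       spacing = as.numeric(spacing))
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- if (is.list(a) && !is.null(a$dim)) a else geometry(a)
  gb <- if (is.list(b) && !is.null(b$dim)) b else geometry(b)
  identical(ga$dim, gb$dim) &&
    all(abs(ga$origin - gb$origin) < tol) &&
    all(abs(ga$spacing - gb$spacing) < tol)
}

#' Physical coordinates of every voxel centre
#'
#' @param geom a geometry list (see [make_geometry()]) or an object with one.
#' @return n x 3 matrix of mm coordinates (column order LR, AP, SI), voxels
#'   in column-major lattice order.
#' @export
voxel_centers <- function(geom) {
  if (!is.list(geom) || is.null(geom$dim)) geom <- geometry(geom)
  d <- geom$dim
  xs <- geom$origin[1] + (seq_len(d[1]) - 1) * geom$spacing[1]
  ys <- geom$origin[2] + (seq_len(d[2]) - 1) * geom$spacing[2]
  zs <- geom$origin[3] + (seq_len(d[3]) - 1) * geom$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

# physical extent: mm positions of first and last voxel centres
extent_mm <- function(geom) {
  if (!is.list(geom) || is.null(geom$dim)) geom <- geometry(geom)
  lo <- geom$origin
  hi <- geom$origin + (geom$dim - 1) * geom$spacing
  rbind(lo = lo, hi = hi)
}

#' Read / write image volumes as NIfTI
#'
#' Geometry (origin and spacing in mm) is stored in the NIfTI qform and
#' round-trips exactly. Masks should be written with `datatype = "uint8"`.
#'
#' @param vol an `image_volume`.
#' @param path file path, conventionally `.nii.gz`.
#' @param datatype NIfTI on-disk datatype, e.g. `"double"` or `"uint8"`.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::`pixdim<-`(img, vol$spacing) -> img
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  image_volume(arr, origin = as.numeric(m[1:3, 4]),
               spacing = as.numeric(RNifti::pixdim(img)[1:3]))
}

# logical mask helpers -------------------------------------------------------

as_mask_array <- function(m) {
  if (inherits(m, "image_volume")) m <- m$data
  if (!is.logical(m)) m <- m != 0
  m
}

# erode a logical mask by `n` voxels (6-connected, separable min filter)
erode_mask <- function(mask, n = 1L) {
  m <- as_mask_array(mask)
  for (it in seq_len(n)) {
    d <- dim(m)
    out <- m
    out[-1, , ] <- out[-1, , ] & m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] & m[-1, , ]
    out[, -1, ] <- out[, -1, ] & m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] & m[, -1, ]
    out[, , -1] <- out[, , -1] & m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] & m[, , -1]
    # boundary slabs lose their outer neighbour: treat outside as background
    out[c(1, d[1]), , ] <- FALSE
    out[, c(1, d[2]), ] <- FALSE
    out[, , c(1, d[3])] <- FALSE
    m <- out
  }
  m
}
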
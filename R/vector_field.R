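#' Displacement vector field on an image lattice
#'
#' A `vector_field` stores a per-voxel 3-component displacement in mm on an
#' [image_volume()] geometry. Components are addressed by anatomical label
#' and stored in fixed order LR, AP, SI along the fourth array dimension.
#' The package-wide convention is *push-forward*: a material point at
#' planning position `p` lies at `p + u(p)` in the deformed anatomy. Fields
#' parameterising resampling (pull-back) must be converted with
#' [invert_dvf()] before entering the QA pipeline.
#'
#' @param u numeric 4-D array `dim x 3` of displacements in mm, component
#'   order LR, AP, SI.
#' @param origin,spacing lattice geometry in mm.
#' @param convention `"pushforward"` (canonical) or `"pullback"`.
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(u, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                         convention = "pushforward") {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("'u' must be a 4-D array with 3 components in the last dimension")
  if (any(!is.finite(u)))
    stop("displacements must be finite")
  convention <- match.arg(convention, c("pushforward", "pullback"))
  structure(list(u = u, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), convention = convention),
            class = "vector_field")
}

DVF_COMPONENTS <- c("LR", "AP", "SI")

#' Zero displacement field on a geometry
#' @param geom geometry list or object carrying one.
#' @export
zero_field <- function(geom) {
  if (!is.list(geom) || is.null(geom$dim)) geom <- geometry(geom)
  vector_field(array(0, dim = c(geom$dim, 3L)), geom$origin, geom$spacing)
}

#' Extract one anatomical component of a field
#' @param f a `vector_field`.
#' @param comp `"LR"`, `"AP"` or `"SI"`.
#' @return 3-D array of that displacement component in mm.
#' @export
field_component <- function(f, comp) {
  i <- match(match.arg(comp, DVF_COMPONENTS), DVF_COMPONENTS)
  d <- dim(f$u)
  array(f$u[, , , i], dim = d[1:3])
}

#' @export
print.vector_field <- function(x, ...) {
  d <- dim(x$u)
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<vector_field> %d x %d x %d voxels, %s, |u| max %.3f mm\n",
              d[1], d[2], d[3], x$convention, max(mag)))
  invisible(x)
}

#' Per-voxel displacement magnitude
#'
#' Euclidean norm of the three displacement components at every voxel;
#' per-ROI maxima and means of this map summarise the motion range of a
#' ground-truth field.
#'
#' @param f a `vector_field`.
#' @return An `image_volume` of magnitudes in mm on the field's geometry.
#' @export
magnitude_map <- function(f) {
  stopifnot(inherits(f, "vector_field"))
  mag <- sqrt(f$u[, , , 1]^2 + f$u[, , , 2]^2 + f$u[, , , 3]^2)
  image_volume(mag, f$origin, f$spacing)
}

#' Write / read a displacement field as NIfTI plus JSON sidecar
#'
#' The field is written as a 4-D NIfTI (fourth dimension = components in the
#' order LR, AP, SI) and a `.json` sidecar recording units, the component
#' order and the field convention, so a reader never has to guess.
#'
#' @param f a `vector_field`.
#' @param path output path, conventionally `.nii.gz`; the sidecar is written
#'   next to it with extension `.json`.
#' @export
write_dvf <- function(f, path) {
  stopifnot(inherits(f, "vector_field"))
  img <- RNifti::asNifti(f$u)
  RNifti::`pixdim<-`(img, c(f$spacing, 1)) -> img
  m <- diag(c(f$spacing, 1))
  m[1:3, 4] <- f$origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(units = "mm", convention = f$convention,
         components = as.list(DVF_COMPONENTS)),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Import a displacement field, normalising convention and component order
#'
#' Reads a 3-component displacement volume plus its JSON sidecar and returns
#' the field in the canonical representation: millimetre units, component
#' order LR/AP/SI, push-forward convention. A pull-back field is converted
#' with [invert_dvf()]. If no sidecar is found the convention must be passed
#' explicitly; it is never guessed.
#'
#' @param path NIfTI path written by [write_dvf()] or an external tool.
#' @param convention override or supply the field convention
#'   (`"pushforward"`/`"pullback"`) when the sidecar is absent.
#' @param invert_iters,invert_tol passed to [invert_dvf()] when conversion is
#'   required.
#' @return A `vector_field` in push-forward convention.
#' @export
import_dvf <- function(path, convention = NULL,
                       invert_iters = 50L, invert_tol = 0.01) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 4L || d[length(d)] != 3L)
    stop("expected a 3-component displacement volume")
  m <- RNifti::xform(img)
  u <- array(as.numeric(img), dim = c(d[1:3], 3L))
  comps <- DVF_COMPONENTS
  conv <- convention
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$units) && !identical(meta$units, "mm"))
      stop("unsupported displacement units: ", meta$units)
    if (!is.null(meta$components)) comps <- as.character(meta$components)
    if (is.null(conv)) conv <- meta$convention
  }
  if (is.null(conv))
    stop("field convention not recorded in a sidecar and not supplied; ",
         "pass convention = \"pushforward\" or \"pullback\"")
  perm <- match(DVF_COMPONENTS, comps)
  if (any(is.na(perm))) stop("sidecar component labels must be LR, AP, SI")
  u <- u[, , , perm, drop = FALSE]
  f <- vector_field(u, origin = as.numeric(m[1:3, 4]),
                    spacing = as.numeric(RNifti::pixdim(img)[1:3]),
                    convention = match.arg(conv, c("pushforward", "pullback")))
  if (f$convention == "pullback") {
    f <- invert_dvf(f, iters = invert_iters, tol = invert_tol)
    f$convention <- "pushforward"
  }
  f
}
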
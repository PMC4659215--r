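#' Construct a hyperspectral cube
#'
#' A hyperspectral microscopy image in which every pixel carries a full
#' vibrational spectrum (infrared absorption or Raman/CARS emission).
#'
#' @param values numeric array of dimension rows x cols x bands, non-negative
#'   absorptions/emissions in arbitrary units.
#' @param wavenumbers numeric vector of length bands, strictly monotonic
#'   spectral axis in cm^-1.
#' @param pixel_size pixel edge length in micrometers per pixel.
#' @return An object of class \code{hyper_cube}.
#' @export
hyper_cube <- function(values, wavenumbers, pixel_size) {
  if (length(dim(values)) != 3L)
    stop("values must be a rows x cols x bands array")
  if (dim(values)[3L] != length(wavenumbers))
    stop("length(wavenumbers) must equal the number of bands")
  if (length(wavenumbers) >= 2L) {
    d <- diff(wavenumbers)
    if (!(all(d > 0) || all(d < 0)))
      stop("wavenumbers must be strictly monotonic")
  }
  if (any(dim(values)[1:2] < 1L)) stop("cube must have at least one pixel")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive number (micrometers per pixel)")
  structure(list(values = values, wavenumbers = as.numeric(wavenumbers),
                 pixel_size = as.numeric(pixel_size)),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f cm^-1), %.3g um/px\n",
              d[1], d[2], d[3], min(x$wavenumbers), max(x$wavenumbers),
              x$pixel_size))
  invisible(x)
}

#' Construct an RGB stain image
#'
#' @param values numeric array rows x cols x 3, channel intensities in
#'   \code{[0, 255]}.
#' @param pixel_size micrometers per pixel.
#' @return An object of class \code{rgb_image}.
#' @export
rgb_image <- function(values, pixel_size) {
  if (length(dim(values)) != 3L || dim(values)[3L] != 3L)
    stop("values must be a rows x cols x 3 array")
  if (min(values) < 0 || max(values) > 255)
    stop("channel values must lie in [0, 255]")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive number (micrometers per pixel)")
  structure(list(values = values, pixel_size = as.numeric(pixel_size)),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rgb_image> %d x %d pixels, %.3g um/px\n", d[1], d[2],
              x$pixel_size))
  invisible(x)
}

#' Construct an index-color image
#'
#' A presegmentation: each pixel holds an integer cluster label in
#' \code{0..k}. Label 0 is reserved for background (substrate, no sample);
#' labels carry no ordinal meaning.
#'
#' @param labels integer matrix of labels in \code{[0, k]}.
#' @param k number of foreground clusters.
#' @param modality \code{"spectral"} or \code{"stained"}.
#' @param pixel_size micrometers per pixel.
#' @return An object of class \code{index_image}.
#' @export
index_image <- function(labels, k, modality = c("spectral", "stained"),
                        pixel_size = 1) {
  modality <- match.arg(modality)
  labels <- matrix(as.integer(round(labels)), nrow = nrow(labels))
  if (any(labels < 0L) || any(labels > k))
    stop("labels must lie in [0, k]")
  structure(list(labels = labels, k = as.integer(k), modality = modality,
                 pixel_size = as.numeric(pixel_size)),
            class = "index_image")
}

#' @export
print.index_image <- function(x, ...) {
  cat(sprintf("<index_image> %d x %d px, k = %d (%s), %.3g um/px\n",
              nrow(x$labels), ncol(x$labels), x$k, x$modality, x$pixel_size))
  invisible(x)
}

#' Construct a similarity transform
#'
#' Maps template (fixed-image) pixel coordinates into moving-image pixel
#' coordinates: rotation by \code{theta} degrees and isotropic scaling by
#' \code{s} about the template center, then translation of the template
#' center to the moving-image center offset by \code{(tx, ty)} pixels.
#' Rigid motions are the subgroup with \code{s = 1}.
#'
#' @param tx,ty translation in moving-image pixels (columns, rows).
#' @param theta rotation in degrees (interpreted modulo 360).
#' @param s isotropic scale factor, must be positive.
#' @return An object of class \code{similarity_transform}.
#' @export
similarity_transform <- function(tx = 0, ty = 0, theta = 0, s = 1) {
  if (!is.finite(s) || s <= 0) stop("scale s must be positive")
  structure(list(tx = as.numeric(tx), ty = as.numeric(ty),
                 theta = as.numeric(theta), s = as.numeric(s)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> tx = %.3f, ty = %.3f, theta = %.3f deg, s = %.4f\n",
              x$tx, x$ty, x$theta, x$s))
  invisible(x)
}

#' Homogeneous 3x3 matrix of a similarity transform
#'
#' Coordinates are 0-based pixel centers ordered (col, row); the matrix maps
#' homogeneous template coordinates to moving-image coordinates for given
#' image shapes (rotation/scale about the template center, see
#' \code{\link{map_coordinates}}).
#'
#' @param t a \code{\link{similarity_transform}}.
#' @param template_shape integer (rows, cols) of the template.
#' @param moving_shape integer (rows, cols) of the moving image.
#' @return a 3x3 numeric matrix.
#' @export
transform_matrix <- function(t, template_shape, moving_shape) {
  ct <- (rev(template_shape) - 1) / 2   # (col, row) center of template
  cm <- (rev(moving_shape) - 1) / 2
  th <- t$theta * pi / 180
  # in (col, row) coordinates the row-down mapping of map_coordinates()
  # reads c' = sin(th) dr + cos(th) dc, r' = cos(th) dr - sin(th) dc
  R <- t$s * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  shift <- cm + c(t$tx, t$ty) - R %*% ct
  rbind(cbind(R, shift), c(0, 0, 1))
}
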
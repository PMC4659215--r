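#' Integral absorption image of a hyperspectral cube
#'
#' Collapses the spectral axis by assigning each pixel the integral of its
#' spectrum over the wavenumber axis (trapezoidal rule). The resulting 2D
#' intensity image is the basis of automatic background identification for
#' raw (uncorrected) spectra: substrate pixels absorb little across the whole
#' infrared range, sample pixels absorb much more.
#'
#' @param cube a \code{\link{hyper_cube}}.
#' @return numeric matrix rows x cols of integral absorptions.
#' @export
integral_intensity_image <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  if (d[3L] < 2L) stop("cannot integrate single-band cube")
  wn <- cube$wavenumbers
  if (wn[1] > wn[length(wn)]) {            # integrate along ascending axis
    wn <- rev(wn)
    vals <- cube$values[, , rev(seq_len(d[3L])), drop = FALSE]
  } else vals <- cube$values
  dw <- diff(wn)
  w <- c(dw / 2, 0) + c(0, dw / 2)         # trapezoid quadrature weights
  matrix(matrix(vals, d[1L] * d[2L], d[3L]) %*% w, d[1L], d[2L])
}

#' Automatic foreground mask from an intensity image
#'
#' Chooses a cutoff intensity automatically with Otsu's method on a 256-bin
#' histogram of the (min/max-normalized) intensities; pixels exceeding the
#' cutoff are foreground. Normalizing first makes the mask invariant under
#' positive rescaling of the intensities.
#'
#' A region of interest may be entirely covered by sample (no substrate in
#' the field of view); a threshold would then split the tissue itself. Since
#' substrate absorbs far less than tissue across the whole spectrum, the
#' split is accepted only if the lower class is dark relative to the upper
#' one (\code{min_contrast}); otherwise every pixel is declared foreground.
#'
#' @param intensity numeric matrix (e.g. from
#'   \code{\link{integral_intensity_image}}).
#' @param min_contrast maximum admissible ratio of the mean intensity below
#'   the cutoff to the mean above it (default 0.5); beyond it the image is
#'   treated as all-foreground.
#' @return logical matrix, \code{TRUE} = foreground (sample).
#' @export
background_mask_from_intensity <- function(intensity, min_contrast = 0.5) {
  stopifnot(is.matrix(intensity))
  rng <- range(intensity)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("degenerate intensity histogram")
  norm <- (intensity - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(norm, range = c(0, 1), levels = 256)
  fg <- norm > thr
  if (any(fg) && any(!fg) &&
      mean(intensity[!fg]) > min_contrast * mean(intensity[fg]))
    fg[] <- TRUE
  fg
}

#' Estimate the background (substrate) color of an H&E image
#'
#' In the absence of tissue no light is absorbed, so the background of a
#' stained slide should be pure white; deviations from white in the bright
#' image regions measure the global color cast of staining and acquisition.
#' Candidate background pixels are those whose luminance
#' (0.299 R + 0.587 G + 0.114 B) reaches the \code{quantile} percentile; the
#' estimate is their per-channel mean.
#'
#' @param he an \code{\link{rgb_image}}.
#' @param quantile luminance percentile defining background candidates
#'   (default 0.90).
#' @return numeric length-3 background color in \code{[0, 255]^3}.
#' @export
estimate_background_color <- function(he, quantile = 0.90) {
  stopifnot(inherits(he, "rgb_image"))
  v <- he$values
  lum <- 0.299 * v[, , 1] + 0.587 * v[, , 2] + 0.114 * v[, , 3]
  thr <- stats::quantile(lum, quantile, names = FALSE)
  sel <- lum >= thr
  if (!any(sel)) stop("no background found; supply color manually")
  c(mean(v[, , 1][sel]), mean(v[, , 2][sel]), mean(v[, , 3][sel]))
}

#' Correct the global color cast of an H&E image
#'
#' Subtracts the background color in optical-density space, which for a
#' base-10 OD with reference intensity 255 is the same as dividing each
#' channel by the background value (then clipping at white). Pixels whose
#' corrected color lands within \code{white_dist} (Euclidean RGB distance) of
#' pure white are set to exactly (255, 255, 255), marking them as background.
#'
#' @param he an \code{\link{rgb_image}}.
#' @param bg length-3 background color, all channels > 0 (see
#'   \code{\link{estimate_background_color}}).
#' @param white_dist radius around pure white snapped to white (default 15).
#' @return corrected \code{\link{rgb_image}}.
#' @export
correct_color_cast <- function(he, bg, white_dist = 15) {
  stopifnot(inherits(he, "rgb_image"), length(bg) == 3L)
  if (any(bg <= 0)) stop("background color channels must all be positive")
  v <- he$values
  out <- v
  for (ch in 1:3)
    out[, , ch] <- round_half_up(255 * pmin(1, v[, , ch] / bg[ch]))
  d2 <- (255 - out[, , 1])^2 + (255 - out[, , 2])^2 + (255 - out[, , 3])^2
  white <- d2 < white_dist^2
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[white] <- 255
    out[, , ch] <- pl
  }
  rgb_image(out, he$pixel_size)
}

# Row/column weight matrix for exact area-average resampling: output pixel j
# covers input interval [j f, (j+1) f), f = n_in / n_out; entry (j, i) is the
# fractional overlap with input pixel i.
area_weights <- function(n_in, n_out) {
  f <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    a <- (j - 1) * f
    b <- j * f
    i0 <- floor(a)
    i1 <- min(ceiling(b), n_in)
    for (i in (i0 + 1):i1) {
      ov <- min(b, i) - max(a, i - 1)
      if (ov > 0) W[j, i] <- ov / f
    }
  }
  W
}

#' Resize an RGB image to a target pixel size
#'
#' Reduces the resolution of the (typically much finer) stained image to the
#' resolution of the spectral image. Downscaling uses exact area-average
#' (anti-aliasing) interpolation; output dimensions are
#' \code{round(dim * pixel_size / target_pixel_size)}. Requesting an upscale
#' (target finer than source) warns and falls back to bilinear interpolation.
#'
#' @param he an \code{\link{rgb_image}}.
#' @param target_pixel_size desired micrometers per pixel.
#' @return resized \code{\link{rgb_image}} with updated \code{pixel_size}.
#' @export
resize_to_resolution <- function(he, target_pixel_size) {
  stopifnot(inherits(he, "rgb_image"), target_pixel_size > 0)
  d <- dim(he$values)
  out_d <- pmax(1, round_half_up(d[1:2] * he$pixel_size / target_pixel_size))
  if (all(out_d == d[1:2]))
    return(rgb_image(he$values, target_pixel_size))
  if (target_pixel_size < he$pixel_size) {
    warning("upscaling beyond factor 1 requested; bilinear interpolation used")
    out <- EBImage::resize(he$values / 255, w = out_d[1], h = out_d[2],
                           filter = "bilinear") * 255
    out <- round_half_up(pmin(pmax(out, 0), 255))
    return(rgb_image(out, target_pixel_size))
  }
  Wr <- area_weights(d[1], out_d[1])
  Wc <- area_weights(d[2], out_d[2])
  out <- array(0, c(out_d, 3))
  for (ch in 1:3)
    out[, , ch] <- round_half_up(Wr %*% he$values[, , ch] %*% t(Wc))
  rgb_image(out, target_pixel_size)
}

#' Foreground mask of a cast-corrected H&E image
#'
#' After \code{\link{correct_color_cast}} the background is exactly pure
#' white; the mask is simply every non-white pixel.
#'
#' @param he_corrected cast-corrected \code{\link{rgb_image}}.
#' @return logical matrix, \code{TRUE} = foreground.
#' @export
he_background_mask <- function(he_corrected) {
  stopifnot(inherits(he_corrected, "rgb_image"))
  v <- he_corrected$values
  !(v[, , 1] == 255 & v[, , 2] == 255 & v[, , 3] == 255)
}
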
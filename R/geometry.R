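#' Map template pixel coordinates into the moving image
#'
#' Applies the similarity transform in 0-based pixel-center coordinates
#' (row down, column right): the pixel is rotated by \code{theta} degrees and
#' scaled by \code{s} about the template center, then placed at the moving
#' image center shifted by \code{(tx, ty)},
#' \deqn{x' = s R(\theta) (x - c) + c_m + (tx, ty).}
#'
#' @param t a \code{\link{similarity_transform}}.
#' @param template_shape integer (rows, cols) of the template grid.
#' @param moving_shape integer (rows, cols) of the moving image.
#' @param pixel numeric matrix n x 2 of (row, col) template coordinates (a
#'   single coordinate may be given as a length-2 vector).
#' @return numeric n x 2 matrix of (row, col) moving-image coordinates.
#' @export
map_coordinates <- function(t, template_shape, moving_shape, pixel) {
  stopifnot(inherits(t, "similarity_transform"))
  if (is.null(dim(pixel))) pixel <- matrix(pixel, ncol = 2)
  cr <- (template_shape[1] - 1) / 2
  cc <- (template_shape[2] - 1) / 2
  mr <- (moving_shape[1] - 1) / 2
  mc <- (moving_shape[2] - 1) / 2
  th <- t$theta * pi / 180
  dr <- pixel[, 1] - cr
  dc <- pixel[, 2] - cc
  # rotation positive = counter-clockwise in (col right, row down) display
  r2 <- t$s * (cos(th) * dr - sin(th) * dc) + mr + t$ty
  c2 <- t$s * (sin(th) * dr + cos(th) * dc) + mc + t$tx
  cbind(row = r2, col = c2)
}

#' Resample the moving index image onto the template grid
#'
#' Nearest-neighbour interpolation: each template pixel takes the label of
#' the moving-image pixel closest to its mapped coordinate (coordinates are
#' rounded half-up). Index colors are categorical, so nearest-neighbour is
#' the only meaningful interpolator. Coordinates falling outside the moving
#' image receive background label 0 (off-slide means no sample), which keeps
#' the pixel count of the joint histogram constant across transforms.
#'
#' @param moving an \code{\link{index_image}}.
#' @param t a \code{\link{similarity_transform}}.
#' @param template_shape integer (rows, cols) of the target grid.
#' @return an \code{\link{index_image}} of shape \code{template_shape}.
#' @export
sample_moving <- function(moving, t, template_shape) {
  stopifnot(inherits(moving, "index_image"))
  lab <- sample_moving_cpp(moving$labels, template_shape[1], template_shape[2],
                           t$tx, t$ty, t$theta, t$s)
  index_image(lab, moving$k, moving$modality, moving$pixel_size)
}

# Pure-R reference for sample_moving; the compiled path is asserted equal to
# this in the tests.
sample_moving_ref <- function(moving, t, template_shape) {
  co <- map_coordinates(t, template_shape, dim(moving$labels),
                        as.matrix(expand.grid(
                          row = 0:(template_shape[1] - 1),
                          col = 0:(template_shape[2] - 1))))
  ri <- round_half_up(co[, 1])
  ci <- round_half_up(co[, 2])
  ok <- ri >= 0 & ri < nrow(moving$labels) & ci >= 0 & ci < ncol(moving$labels)
  lab <- integer(nrow(co))
  lab[ok] <- moving$labels[cbind(ri[ok] + 1L, ci[ok] + 1L)]
  index_image(matrix(lab, template_shape[1], template_shape[2]),
              moving$k, moving$modality, moving$pixel_size)
}

#' Score a transform by restricted mutual information
#'
#' The objective function of the registration: resample the moving index
#' image onto the template grid under \code{t}, build the joint label
#' histogram and evaluate restricted mutual information.
#'
#' @param fixed template \code{\link{index_image}}.
#' @param moving moving \code{\link{index_image}}.
#' @param t a \code{\link{similarity_transform}}.
#' @param alpha background adjustment factor (default 0.25).
#' @param base logarithm base (default 2).
#' @return score in bits (for base 2).
#' @export
score_transform <- function(fixed, moving, t, alpha = 0.25, base = 2) {
  restricted_mi(joint_histogram(fixed, sample_moving(moving, t,
                                                     dim(fixed$labels)),
                                base = base), alpha)
}

#' Batch score function over transform space
#'
#' Returns a vectorized objective \code{f(par)} where \code{par} is an
#' n x 4 matrix with columns (tx, ty, theta, s); evaluation runs in compiled
#' code, one joint histogram per row. This is the function handed to the
#' optimizer.
#'
#' @inheritParams score_transform
#' @return a function mapping an n x 4 parameter matrix to n scores.
#' @export
make_score_fn <- function(fixed, moving, alpha = 0.25, base = 2) {
  force(fixed); force(moving); force(alpha); force(base)
  stopifnot(fixed$k <= 255, moving$k <= 255)
  fl <- fixed$labels
  ml <- moving$labels
  kx <- fixed$k
  ky <- moving$k
  function(par) {
    if (is.null(dim(par))) par <- matrix(par, ncol = 4)
    eval_transforms_cpp(fl, ml, kx, ky, par, alpha, base)
  }
}
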
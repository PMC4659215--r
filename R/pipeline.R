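#' Registration pipeline configuration
#'
#' Bundles every tunable of the pipeline with its default. Defaults follow
#' the standard operating point: template ROIs segmented into
#' \code{k_fixed = 8} clusters, whole-slide stained images into
#' \code{k_moving = 10}; restricted-MI adjustment \code{alpha = 0.25};
#' sparse-search threshold constants \code{k0 = 0.6} and
#' \code{delta_k = 0.5}; rigid transforms with rotations limited to
#' [-30, 30] degrees in template matching; scale limited to [0.8, 1.2] for
#' similarity transforms. Setting \code{k_fixed = k_moving = 1} reproduces
#' the binary foreground/background registration variant.
#'
#' @param k_fixed clusters for the spectral template (default 8).
#' @param k_moving clusters for the stained moving image (default 10).
#' @param alpha restricted-MI background adjustment in [0, 1].
#' @param k0 initial sparse-search threshold fraction (0, 1].
#' @param delta_k per-level threshold decay (0, 1].
#' @param transform_class \code{"translation"}, \code{"rigid"} or
#'   \code{"similarity"}.
#' @param rotation_limits,scale_limits,translation_limits see
#'   \code{\link{transform_bounds}}.
#' @param template_matching logical, see \code{\link{transform_bounds}}.
#' @param log_base logarithm base of the metric (default 2, bits).
#' @param seed integer seed for the k-means segmentations.
#' @param white_dist snap-to-white radius of the cast correction.
#' @param bg_quantile luminance percentile of the background-color estimate.
#' @param trace keep the full optimizer evaluation trace.
#' @return a list of class \code{registration_config}.
#' @export
registration_config <- function(k_fixed = 8, k_moving = 10, alpha = 0.25,
                                k0 = 0.6, delta_k = 0.5,
                                transform_class = c("rigid", "translation",
                                                    "similarity"),
                                rotation_limits = NULL,
                                scale_limits = c(0.8, 1.2),
                                translation_limits = NULL,
                                template_matching = TRUE,
                                log_base = 2, seed = 1,
                                white_dist = 15, bg_quantile = 0.90,
                                trace = FALSE) {
  transform_class <- match.arg(transform_class)
  stopifnot(k_fixed >= 1, k_moving >= 1, alpha >= 0, alpha <= 1,
            k0 > 0, k0 <= 1, delta_k > 0, delta_k <= 1, log_base > 1)
  structure(as.list(environment()), class = "registration_config")
}

#' Register a spectral template within a stained image
#'
#' End-to-end orchestration of the pipeline: preprocessing (integral
#' intensity + automatic cutoff mask for the cube; background color
#' estimation, optical-density cast correction, resolution matching and
#' white mask for the stained image), k-means presegmentation of both
#' modalities into index-color images, self-registration estimation of the
#' initial grid radius, and sparse-search maximization of restricted mutual
#' information. The spectral image is the template (fixed); the stained
#' image moves.
#'
#' Either input may be supplied as a ready-made \code{\link{index_image}},
#' in which case its preprocessing/segmentation is skipped (the two index
#' images must then already share one resolution).
#'
#' @param fixed a \code{\link{hyper_cube}} or \code{\link{index_image}}.
#' @param moving an \code{\link{rgb_image}} or \code{\link{index_image}}.
#' @param config a \code{\link{registration_config}}.
#' @param fixed_mask optional logical foreground mask for the cube,
#'   overriding the automatic intensity cutoff.
#' @return a \code{registration_result} (see \code{\link{sparse_search}})
#'   with the extra elements \code{fixed_index}, \code{moving_index},
#'   \code{r0}, \code{bounds} and \code{config}.
#' @export
register_images <- function(fixed, moving, config = registration_config(),
                            fixed_mask = NULL) {
  stopifnot(inherits(config, "registration_config"))
  if (inherits(fixed, "hyper_cube")) {
    if (is.null(fixed_mask))
      fixed_mask <- background_mask_from_intensity(
        integral_intensity_image(fixed))
    fixed_idx <- segment_spectral(fixed, fixed_mask, config$k_fixed,
                                  config$seed)
  } else if (inherits(fixed, "index_image")) {
    fixed_idx <- fixed
  } else stop("fixed must be a hyper_cube or index_image")

  if (inherits(moving, "rgb_image")) {
    he <- moving
    if (he$pixel_size < fixed_idx$pixel_size)
      he <- resize_to_resolution(he, fixed_idx$pixel_size)
    bg <- estimate_background_color(he, config$bg_quantile)
    he <- correct_color_cast(he, bg, config$white_dist)
    moving_mask <- he_background_mask(he)
    moving_idx <- segment_stained(he, moving_mask, config$k_moving,
                                  config$seed + 1L)
  } else if (inherits(moving, "index_image")) {
    moving_idx <- moving
  } else stop("moving must be an rgb_image or index_image")

  if (sum(fixed_idx$labels > 0L) == 0L)
    stop("degenerate input: template is entirely background")
  bounds <- transform_bounds(config$transform_class,
                             template_shape = dim(fixed_idx$labels),
                             moving_shape = dim(moving_idx$labels),
                             rotation_limits = config$rotation_limits,
                             scale_limits = config$scale_limits,
                             translation_limits = config$translation_limits,
                             template_matching = config$template_matching)
  r0 <- estimate_initial_radius(fixed_idx, bounds, alpha = config$alpha,
                                k0 = config$k0, base = config$log_base)
  f <- make_score_fn(fixed_idx, moving_idx, alpha = config$alpha,
                     base = config$log_base)
  res <- sparse_search(f, bounds, r0, k0 = config$k0,
                       delta_k = config$delta_k, trace = config$trace)
  res$fixed_index <- fixed_idx
  res$moving_index <- moving_idx
  res$r0 <- r0
  res$bounds <- bounds
  res$config <- config
  res
}

#' Corner-displacement error of a recovered transform
#'
#' Maps the four template corners under the recovered and the ground-truth
#' transform and reports the mean and maximum Euclidean displacement in
#' moving-image pixels — a geometry-level accuracy summary that is zero iff
#' the transforms act identically on the template.
#'
#' @param result a \code{registration_result} or
#'   \code{\link{similarity_transform}}.
#' @param truth the ground-truth \code{\link{similarity_transform}}.
#' @param template_shape integer (rows, cols) of the template (taken from
#'   \code{result$fixed_index} when present).
#' @param moving_shape integer (rows, cols) of the moving image (taken from
#'   \code{result$moving_index} when present; otherwise it cancels out and
#'   an arbitrary shape is used).
#' @return named numeric: \code{mean_px}, \code{max_px}.
#' @export
evaluate_registration <- function(result, truth, template_shape = NULL,
                                  moving_shape = NULL) {
  t_hat <- if (inherits(result, "registration_result")) result$transform
           else result
  stopifnot(inherits(t_hat, "similarity_transform"),
            inherits(truth, "similarity_transform"))
  if (is.null(template_shape) && inherits(result, "registration_result"))
    template_shape <- dim(result$fixed_index$labels)
  if (is.null(moving_shape)) {
    moving_shape <- if (inherits(result, "registration_result"))
      dim(result$moving_index$labels) else c(101, 101)
  }
  corners <- rbind(c(0, 0),
                   c(0, template_shape[2] - 1),
                   c(template_shape[1] - 1, 0),
                   c(template_shape[1] - 1, template_shape[2] - 1))
  a <- map_coordinates(t_hat, template_shape, moving_shape, corners)
  b <- map_coordinates(truth, template_shape, moving_shape, corners)
  d <- sqrt(rowSums((a - b)^2))
  c(mean_px = mean(d), max_px = max(d))
}

#' Draw the registered template outline on the moving image
#'
#' Renders the moving image (index images get a categorical palette) and
#' marks the mapped template boundary in red — the standard visual QC of a
#' template-matching registration.
#'
#' @param moving an \code{\link{rgb_image}} or \code{\link{index_image}}.
#' @param t the recovered \code{\link{similarity_transform}}.
#' @param template_shape integer (rows, cols) of the template.
#' @param path output PNG path.
#' @export
write_overlay_png <- function(moving, t, template_shape, path) {
  if (inherits(moving, "index_image")) {
    pal <- index_palette(moving$k)
    v <- array(0, c(dim(moving$labels), 3))
    for (ch in 1:3)
      v[, , ch] <- matrix(pal[moving$labels + 1L, ch], nrow(moving$labels))
  } else if (inherits(moving, "rgb_image")) {
    v <- moving$values
  } else stop("moving must be an rgb_image or index_image")
  tr <- template_shape[1]; tc <- template_shape[2]
  border <- rbind(cbind(0, 0:(tc - 1)), cbind(tr - 1, 0:(tc - 1)),
                  cbind(0:(tr - 1), 0), cbind(0:(tr - 1), tc - 1))
  co <- map_coordinates(t, template_shape, dim(v)[1:2], border)
  ri <- round_half_up(co[, 1]); ci <- round_half_up(co[, 2])
  ok <- ri >= 0 & ri < dim(v)[1] & ci >= 0 & ci < dim(v)[2]
  idx <- cbind(ri[ok] + 1L, ci[ok] + 1L)
  r1 <- v[, , 1]; g1 <- v[, , 2]; b1 <- v[, , 3]
  r1[idx] <- 255; g1[idx] <- 0; b1[idx] <- 0
  png::writePNG(array(c(r1, g1, b1), dim(v)) / 255, path)
  invisible(path)
}

index_palette <- function(k) {
  cols <- grDevices::col2rgb(c("black", grDevices::hcl.colors(max(k, 2),
                                                              "Spectral")))
  t(cols)[seq_len(k + 1), , drop = FALSE]
}

#' Display an index-color image
#'
#' @param x an \code{\link{index_image}}.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.index_image <- function(x, ...) {
  pal <- index_palette(x$k)
  graphics::image(t(x$labels)[, nrow(x$labels):1, drop = FALSE],
                  col = grDevices::rgb(pal[, 1], pal[, 2], pal[, 3],
                                       maxColorValue = 255),
                  breaks = seq(-0.5, x$k + 0.5, by = 1), axes = FALSE,
                  asp = nrow(x$labels) / ncol(x$labels), ...)
  invisible(x)
}

#' Render a translation score map
#'
#' Evaluates the objective on the full translation grid (rotation/scale at
#' neutral) and returns it as a matrix, optionally writing a grayscale PNG
#' heat map; useful for inspecting the score landscape the optimizer walks.
#'
#' @param score_fn vectorized objective (see \code{\link{make_score_fn}}).
#' @param bounds a \code{\link{transform_bounds}}.
#' @param step translation step in pixels (default 1).
#' @param path optional PNG output path.
#' @return numeric matrix of scores (rows = ty, cols = tx), with the grid
#'   coordinates as dimnames.
#' @export
score_map <- function(score_fn, bounds, step = 1, path = NULL) {
  txs <- seq(bounds$lo[1], bounds$hi[1], by = step)
  tys <- seq(bounds$lo[2], bounds$hi[2], by = step)
  g <- expand.grid(tx = txs, ty = tys)
  par <- cbind(g$tx, g$ty, bounds$neutral[3], bounds$neutral[4])
  sc <- score_fn(par)
  m <- matrix(sc, length(tys), length(txs), byrow = TRUE,
              dimnames = list(ty = tys, tx = txs))
  if (!is.null(path)) {
    fin <- is.finite(m)
    lo <- min(m[fin]); hi <- max(m[fin])
    norm <- (m - lo) / max(hi - lo, .Machine$double.eps)
    norm[!fin] <- 0
    png::writePNG(pmin(pmax(norm, 0), 1), path)
  }
  m
}
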
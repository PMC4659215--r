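#' Generate a tissue-like label map
#'
#' Smoothed random fields produce blob-shaped regions for each tissue class;
#' the per-pixel class is the field argmax, and a connected substrate border
#' (label 0) surrounds the tissue, carved out by a central smooth blob mask.
#' Every class is guaranteed present.
#'
#' @param rows,cols map size in pixels.
#' @param n_classes number of tissue classes (>= 2), labeled 1..n_classes.
#' @param seed RNG seed; identical seeds yield bit-identical maps.
#' @param tissue_fraction approximate fraction of pixels covered by tissue
#'   (default 0.6).
#' @return integer matrix of labels in 0..n_classes.
#' @export
make_label_map <- function(rows, cols, n_classes, seed,
                           tissue_fraction = 0.6) {
  stopifnot(n_classes >= 2)
  if (rows * cols < 25 * n_classes)
    stop("image too small for the requested number of classes")
  for (attempt in 0:9) {
    lab <- with_seed(seed + 100000L * attempt,
                     label_map_once(rows, cols, n_classes, tissue_fraction))
    if (all(tabulate(lab[lab > 0L], n_classes) > 0L)) return(lab)
  }
  stop("could not place all classes; reduce n_classes or enlarge the map")
}

label_map_once <- function(rows, cols, n_classes, tissue_fraction) {
  sigma <- max(2, min(rows, cols) / 12)
  # class compartments a few dozen pixels across: the scale of glands and
  # stroma bands at a few micrometers per pixel
  class_sigma <- max(3, min(min(rows, cols) / 28, 14))
  fields <- lapply(seq_len(n_classes), function(i)
    EBImage::gblur(matrix(stats::rnorm(rows * cols), rows, cols),
                   sigma = class_sigma))
  lab <- matrix(max.col(do.call(cbind, lapply(fields, as.vector)),
                        ties.method = "first"), rows, cols)
  # tissue support: central bump plus smooth noise, thresholded at the
  # requested coverage, with a hard substrate border
  r <- (seq_len(rows) - (rows + 1) / 2) / (rows / 2)
  cc <- (seq_len(cols) - (cols + 1) / 2) / (cols / 2)
  bump <- exp(-(outer(r^2, cc^2, `+`)) * 1.2)
  tf <- bump + 0.35 * EBImage::gblur(matrix(stats::rnorm(rows * cols),
                                            rows, cols), sigma = sigma)
  thr <- stats::quantile(tf, 1 - tissue_fraction, names = FALSE)
  tissue <- tf > thr
  tissue[c(1:2, rows - 1, rows), ] <- FALSE
  tissue[, c(1:2, cols - 1, cols)] <- FALSE
  lab[!tissue] <- 0L
  lab
}

# Smooth synthetic spectra: every class gets one dominant Gaussian band at
# its own position across the fingerprint region (guaranteeing pairwise
# separation) plus a few random minor bands; peak amplitudes near 1.
make_class_spectra <- function(n_classes, wavenumbers) {
  lo <- min(wavenumbers); hi <- max(wavenumbers)
  main <- seq(lo + 0.1 * (hi - lo), hi - 0.1 * (hi - lo),
              length.out = n_classes)
  t(vapply(seq_len(n_classes), function(i) {
    nb <- sample(3:6, 1)
    centers <- c(main[i], stats::runif(nb, lo, hi))
    widths <- c(stats::runif(1, 30, 60), stats::runif(nb, 20, 80))
    amps <- c(1, stats::runif(nb, 0.1, 0.5))
    s <- colSums(amps * exp(-outer(centers, wavenumbers, `-`)^2 /
                              (2 * widths^2)))
    s / max(s)
  }, numeric(length(wavenumbers))))
}

# H&E-like palette (hematoxylin purples through eosin pinks), jittered.
he_palette <- function(n_classes) {
  base <- matrix(c(
    90,  40, 140,   # dark nuclear purple
    150,  80, 170,  # light purple
    220, 120, 170,  # pink
    235, 160, 180,  # light eosin pink
    180,  60, 110,  # deep pink
    120, 100, 180,  # blue-purple
    200, 180, 210,  # pale stroma
    160, 140, 100,  # keratin tan
    230, 200, 160,  # pale tan
    100, 130, 160), # blue-gray
    ncol = 3, byrow = TRUE)
  idx <- ((seq_len(n_classes) - 1) %% nrow(base)) + 1
  jit <- base[idx, , drop = FALSE] +
    matrix(stats::runif(3 * n_classes, -10, 10), n_classes, 3)
  pmin(pmax(jit, 0), 255)
}

#' Define a synthetic co-registered phantom scene
#'
#' A phantom emulates the standard study setting: a whole-slide stained
#' image and a small hyperspectral region of interest cut out of the same
#' (virtual) tissue section under a known similarity transform. Rendering
#' parameters control class spectra/colors, the global stain color cast and
#' per-modality Gaussian noise. Defaults: 600 x 400 px slide and 160 x 120
#' px ROI, both at 5 um/px, 6 tissue classes, noise giving a class
#' signal-to-noise ratio near 10.
#'
#' @param seed RNG seed; the whole scene is reproducible from it.
#' @param slide_size (cols, rows) of the slide in pixels.
#' @param roi_size (cols, rows) of the spectral ROI in pixels.
#' @param n_classes number of tissue classes (>= 2).
#' @param true_transform a \code{\link{similarity_transform}} mapping ROI
#'   coordinates into slide coordinates, or \code{NULL} to draw one at
#'   random (rigid, rotation within \code{rotation_range}, ROI kept fully
#'   inside the slide).
#' @param rotation_range rotation interval (degrees) for random transforms.
#' @param scale_range scale interval for random transforms (default
#'   \code{c(1, 1)}, i.e. rigid).
#' @param cast_color global stain cast: the rendered background color
#'   (pure white means no cast).
#' @param noise_sigma_spectral,noise_sigma_rgb Gaussian pixel noise standard
#'   deviations (absorbance units / gray levels).
#' @param texture_amp_spectral,texture_amp_rgb amplitude of the smooth
#'   within-class intensity modulation, one independent field per modality,
#'   emulating spatially correlated biochemical (respectively staining)
#'   variation inside a tissue class (multiplicative, relative units).
#' @param texture_sigma_spectral,texture_sigma_rgb correlation length (px)
#'   of the two modulation fields: biochemical gradients are smooth and
#'   broad, staining texture is fine-grained.
#' @param slide_pixel_size,roi_pixel_size um/px of the two modalities.
#' @param wavenumbers spectral axis of the rendered cube (cm^-1).
#' @return an object of class \code{phantom_scene}.
#' @export
phantom_scene <- function(seed = 1,
                          slide_size = c(600, 400),
                          roi_size = c(160, 120),
                          n_classes = 6,
                          true_transform = NULL,
                          rotation_range = c(-30, 30),
                          scale_range = c(1, 1),
                          cast_color = c(236, 224, 230),
                          noise_sigma_spectral = 0.05,
                          noise_sigma_rgb = 3,
                          texture_amp_spectral = 0.15,
                          texture_amp_rgb = 0.15,
                          texture_sigma_spectral = 25,
                          texture_sigma_rgb = 3,
                          slide_pixel_size = 5,
                          roi_pixel_size = 5,
                          wavenumbers = seq(900, 1800, by = 15)) {
  rows <- slide_size[2]; cols <- slide_size[1]
  label_map <- make_label_map(rows, cols, n_classes, seed)
  sc <- with_seed(seed + 1L, {
    spectra <- make_class_spectra(n_classes, wavenumbers)
    colors <- he_palette(n_classes)
    smooth_field <- function(sg) {
      sg <- min(sg, (min(rows, cols) - 3) / 7)   # keep the kernel in-image
      f <- EBImage::gblur(matrix(stats::rnorm(rows * cols), rows, cols),
                          sigma = max(sg, 0.5))
      pmin(pmax(f / stats::sd(f), -2), 2)
    }
    tex_spec <- smooth_field(texture_sigma_spectral)
    tex_rgb <- smooth_field(texture_sigma_rgb)
    tr <- true_transform
    if (is.null(tr)) {
      s <- stats::runif(1, scale_range[1], scale_range[2])
      th <- stats::runif(1, rotation_range[1], rotation_range[2])
      # keep the transformed ROI fully inside the slide
      R <- s * corner_radius(c(roi_size[2], roi_size[1]))
      mx <- max(0, (cols - 1) / 2 - R - 2)
      my <- max(0, (rows - 1) / 2 - R - 2)
      tr <- similarity_transform(stats::runif(1, -mx, mx),
                                 stats::runif(1, -my, my), th, s)
    }
    list(spectra = spectra, colors = colors, tex_spec = tex_spec,
         tex_rgb = tex_rgb, tr = tr)
  })
  structure(list(label_map = label_map,
                 class_spectra = sc$spectra,
                 class_colors = sc$colors,
                 substrate_color = c(252, 252, 252),
                 substrate_level = 0.03,
                 texture_spectral = sc$tex_spec,
                 texture_rgb = sc$tex_rgb,
                 texture_amp_spectral = texture_amp_spectral,
                 texture_amp_rgb = texture_amp_rgb,
                 cast_color = cast_color,
                 noise_sigma_spectral = noise_sigma_spectral,
                 noise_sigma_rgb = noise_sigma_rgb,
                 true_transform = sc$tr,
                 slide_pixel_size = slide_pixel_size,
                 roi_pixel_size = roi_pixel_size,
                 roi_size = roi_size,
                 wavenumbers = wavenumbers,
                 seed = seed),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> slide %d x %d, ROI %d x %d, %d classes, seed %d\n",
              ncol(x$label_map), nrow(x$label_map), x$roi_size[1],
              x$roi_size[2], nrow(x$class_spectra), x$seed))
  print(x$true_transform)
  invisible(x)
}

#' Render a co-registered hyperspectral/RGB pair from a phantom scene
#'
#' The slide is rendered at slide resolution as class colors under the
#' global color cast (per-channel multiplication by cast/255) plus Gaussian
#' noise; the spectral ROI is rendered by pulling each ROI pixel through the
#' ground-truth transform, looking up the tissue class and emitting the
#' class spectrum plus noise. Substrate renders near-white in the slide and
#' as low-intensity spectra in the cube, so both automatic background masks
#' are well defined.
#'
#' @param scene a \code{\link{phantom_scene}}.
#' @return list with elements \code{cube} (\code{\link{hyper_cube}}),
#'   \code{slide} (\code{\link{rgb_image}}), \code{roi_labels} (the
#'   ground-truth class of every ROI pixel) and \code{scene}.
#' @export
render_pair <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  lm <- scene$label_map
  rows <- nrow(lm); cols <- ncol(lm)
  trows <- scene$roi_size[2]; tcols <- scene$roi_size[1]
  co <- map_coordinates(scene$true_transform, c(trows, tcols), c(rows, cols),
                        as.matrix(expand.grid(row = 0:(trows - 1),
                                              col = 0:(tcols - 1))))
  ri <- round_half_up(co[, 1]); ci <- round_half_up(co[, 2])
  if (any(ri < 0 | ri >= rows | ci < 0 | ci >= cols))
    stop("ROI is not fully inside the slide under the true transform")
  roi_lab <- matrix(lm[cbind(ri + 1L, ci + 1L)], trows, tcols)
  nb <- length(scene$wavenumbers)
  with_seed(scene$seed + 2L, {
    # spectral cube: class spectrum (or substrate baseline) + noise, >= 0
    spec_lut <- rbind(scene$substrate_level *
                        exp(-(scene$wavenumbers - 1200)^2 / (2 * 300^2)),
                      scene$class_spectra)
    cube_vals <- spec_lut[as.vector(roi_lab) + 1L, , drop = FALSE]
    tex_roi <- scene$texture_spectral[cbind(ri + 1L, ci + 1L)]
    mod <- ifelse(as.vector(roi_lab) > 0L,
                  1 + scene$texture_amp_spectral * tex_roi, 1)
    cube_vals <- cube_vals * mod
    if (scene$noise_sigma_spectral > 0)
      cube_vals <- cube_vals + matrix(stats::rnorm(length(cube_vals), 0,
                                                   scene$noise_sigma_spectral),
                                      nrow(cube_vals))
    cube <- hyper_cube(array(pmax(0, cube_vals), c(trows, tcols, nb)),
                       scene$wavenumbers, scene$roi_pixel_size)
    # stained slide: class colors under cast + noise
    col_lut <- rbind(scene$substrate_color, scene$class_colors)
    slide_vals <- col_lut[as.vector(lm) + 1L, , drop = FALSE]
    mod_s <- ifelse(as.vector(lm) > 0L,
                    1 + scene$texture_amp_rgb * as.vector(scene$texture_rgb), 1)
    slide_vals <- slide_vals * mod_s
    slide_vals <- sweep(slide_vals, 2L, scene$cast_color / 255, `*`)
    if (scene$noise_sigma_rgb > 0)
      slide_vals <- slide_vals + matrix(stats::rnorm(length(slide_vals), 0,
                                                     scene$noise_sigma_rgb),
                                        nrow(slide_vals))
    slide_vals <- round_half_up(pmin(255, pmax(0, slide_vals)))
    slide <- rgb_image(array(slide_vals, c(rows, cols, 3)),
                       scene$slide_pixel_size)
    list(cube = cube, slide = slide, roi_labels = roi_lab, scene = scene)
  })
}

#' Synthetic unimodal score landscape over 2D translations
#'
#' A rotated anisotropic Gaussian peak with random center and widths on a
#' bounded translation grid, plus a flat baseline: a stand-in score map for
#' validating the sparse optimizer against exhaustive search. The basin
#' half-width at fraction \code{k0} of the peak is known in closed form and
#' reported per axis.
#'
#' @param seed RNG seed.
#' @param shape (rows, cols) of the translation grid (odd sizes center the
#'   grid on zero); default \code{c(65, 65)}.
#' @param sigma_range range of the peak's principal standard deviations
#'   (default \code{c(3, 6)}). The widths are chosen for the 65 x 65 grid:
#'   much narrower basins force the coarse level toward the full grid, much
#'   broader ones make the peak's own skirt cover a large share of the
#'   space; either regime defeats the point of sparse refinement.
#' @param k0 fraction at which the basin half-width is measured (default
#'   0.6).
#' @return list with \code{score_fn} (n x 4 parameter matrix to scores),
#'   \code{bounds} (translation-only \code{\link{transform_bounds}}),
#'   \code{r0} (per-axis radius: the basin half-width floor, at least 1),
#'   \code{center} (true peak position) and \code{half_width}.
#' @export
unimodal_score_map <- function(seed = 1, shape = c(65, 65),
                               sigma_range = c(3, 6), k0 = 0.6) {
  htx <- (shape[2] - 1) / 2
  hty <- (shape[1] - 1) / 2
  par <- with_seed(seed, list(
    cx = stats::runif(1, -0.6 * htx, 0.6 * htx),
    cy = stats::runif(1, -0.6 * hty, 0.6 * hty),
    sx = stats::runif(1, sigma_range[1], sigma_range[2]),
    sy = stats::runif(1, sigma_range[1], sigma_range[2]),
    phi = stats::runif(1, 0, pi)))
  cphi <- cos(par$phi); sphi <- sin(par$phi)
  score_fn <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 4)
    dx <- p[, 1] - par$cx
    dy <- p[, 2] - par$cy
    u <- cphi * dx + sphi * dy
    v <- -sphi * dx + cphi * dy
    0.02 + exp(-(u^2 / par$sx^2 + v^2 / par$sy^2) / 2)
  }
  # half-width at fraction k0 along the grid axes (Gaussian closed form)
  w <- sqrt(2 * log(1 / k0))
  sig_x <- 1 / sqrt(cphi^2 / par$sx^2 + sphi^2 / par$sy^2)
  sig_y <- 1 / sqrt(sphi^2 / par$sx^2 + cphi^2 / par$sy^2)
  hw <- c(tx = sig_x * w, ty = sig_y * w)
  bounds <- transform_bounds("translation", template_shape = shape,
                             moving_shape = shape,
                             translation_limits = list(tx = c(-htx, htx),
                                                       ty = c(-hty, hty)))
  list(score_fn = score_fn, bounds = bounds,
       r0 = pmax(1, floor(hw)), center = c(tx = par$cx, ty = par$cy),
       half_width = hw)
}
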
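#' Rotation and scale grid units for a template
#'
#' The optimizer discretizes every transform parameter in units chosen so
#' that one unit step displaces the farthest template pixel by about one
#' pixel: translations in pixels, rotation in the angle whose chord at the
#' template corner radius is 1 px, scale in 1 / (corner radius). This makes
#' the search grid isotropic in image space.
#'
#' @param template_shape integer (rows, cols).
#' @return grid unit (degrees for rotation, scale fraction for scale).
#' @export
rotation_grid_unit <- function(template_shape) {
  R <- corner_radius(template_shape)
  2 * asin(min(1, 1 / (2 * R))) * 180 / pi
}

#' @rdname rotation_grid_unit
#' @export
scale_grid_unit <- function(template_shape) {
  1 / corner_radius(template_shape)
}

corner_radius <- function(template_shape) {
  cr <- (template_shape[1] - 1) / 2
  cc <- (template_shape[2] - 1) / 2
  max(sqrt(cr^2 + cc^2), 1)
}

#' Transform-space search bounds
#'
#' Closed parameter intervals and per-parameter grid units for the
#' optimizer. Translation bounds default to letting the template center fall
#' anywhere inside the moving image. Default rotation limits are [-30, 30]
#' degrees for template matching and [-180, 180] for full registration;
#' default scale limits are [0.8, 1.2].
#'
#' @param transform_class \code{"translation"} (tx, ty only), \code{"rigid"}
#'   (adds rotation) or \code{"similarity"} (adds isotropic scale).
#' @param template_shape,moving_shape integer (rows, cols) of the two index
#'   images.
#' @param rotation_limits rotation interval in degrees; default depends on
#'   \code{template_matching}.
#' @param scale_limits scale interval (default \code{c(0.8, 1.2)}).
#' @param translation_limits optional list with elements \code{tx}, \code{ty}
#'   overriding the translation intervals (pixels).
#' @param template_matching logical; template matching restricts rotations to
#'   [-30, 30] by default.
#' @return an object of class \code{transform_bounds}: per-parameter
#'   \code{lo}, \code{hi}, \code{unit}, \code{neutral}, \code{enabled}.
#' @export
transform_bounds <- function(transform_class = c("rigid", "translation",
                                                 "similarity"),
                             template_shape, moving_shape,
                             rotation_limits = NULL,
                             scale_limits = c(0.8, 1.2),
                             translation_limits = NULL,
                             template_matching = TRUE) {
  transform_class <- match.arg(transform_class)
  if (is.null(rotation_limits))
    rotation_limits <- if (template_matching) c(-30, 30) else c(-180, 180)
  tlim <- list(tx = c(-1, 1) * (moving_shape[2] - 1) / 2,
               ty = c(-1, 1) * (moving_shape[1] - 1) / 2)
  if (!is.null(translation_limits)) tlim[names(translation_limits)] <-
      translation_limits
  b <- list(
    param = c("tx", "ty", "theta", "s"),
    lo = c(tlim$tx[1], tlim$ty[1], rotation_limits[1], scale_limits[1]),
    hi = c(tlim$tx[2], tlim$ty[2], rotation_limits[2], scale_limits[2]),
    unit = c(1, 1, rotation_grid_unit(template_shape),
             scale_grid_unit(template_shape)),
    neutral = c(0, 0, 0, 1),
    enabled = c(TRUE, TRUE, transform_class != "translation",
                transform_class == "similarity"))
  if (any(b$lo > b$hi)) stop("bounds must satisfy lower <= upper")
  structure(b, class = "transform_bounds")
}

#' @export
print.transform_bounds <- function(x, ...) {
  cat("<transform_bounds>\n")
  for (j in seq_along(x$param))
    cat(sprintf("  %-5s [%8.3f, %8.3f] unit %.4f %s\n", x$param[j], x$lo[j],
                x$hi[j], x$unit[j], if (x$enabled[j]) "" else "(fixed)"))
  invisible(x)
}

# Lattice index range of dimension j: integer multiples of the grid unit
# inside [lo, hi], with the neutral value's index always representable.
lattice_range <- function(bounds, j) {
  ilo <- ceiling(bounds$lo[j] / bounds$unit[j] - 1e-9)
  ihi <- floor(bounds$hi[j] / bounds$unit[j] + 1e-9)
  if (ilo > ihi) ilo <- ihi <- round(bounds$neutral[j] / bounds$unit[j])
  c(ilo, ihi)
}

# Expand integer lattice indices (n x n_enabled) into a full n x 4 parameter
# matrix (tx, ty, theta, s) in natural units.
lattice_to_par <- function(idx, bounds) {
  n <- nrow(idx)
  par <- matrix(rep(bounds$neutral, each = n), n, 4)
  par[, bounds$enabled] <- sweep(idx, 2L, bounds$unit[bounds$enabled], `*`)
  colnames(par) <- bounds$param
  par
}

#' Estimate the initial grid radius by self-registration
#'
#' Registers the template against itself along one transform parameter at a
#' time: the score profile peaks at the neutral transform, and the width of
#' that peak tells how coarse the initial search grid may be without missing
#' the true optimum. For each enabled parameter the estimate is the largest
#' contiguous displacement d (in grid units, swept in both directions) for
#' which score(d) / score(0) >= k0, clamped to at least 1 unit.
#'
#' @param template an \code{\link{index_image}}.
#' @param bounds a \code{\link{transform_bounds}}.
#' @param alpha restricted-MI adjustment factor (default 0.25).
#' @param k0 peak-width fraction, same constant as the optimizer threshold
#'   (default 0.6).
#' @param base logarithm base (default 2).
#' @return named numeric vector of radii (grid units) for enabled parameters.
#' @export
estimate_initial_radius <- function(template, bounds, alpha = 0.25,
                                    k0 = 0.6, base = 2) {
  stopifnot(inherits(template, "index_image"),
            inherits(bounds, "transform_bounds"))
  f <- make_score_fn(template, template, alpha = alpha, base = base)
  score0 <- f(matrix(bounds$neutral, 1))
  if (!is.finite(score0) || score0 <= 0) stop("degenerate template")
  enabled <- which(bounds$enabled)
  r0 <- setNames(numeric(length(enabled)), bounds$param[enabled])
  for (e in seq_along(enabled)) {
    j <- enabled[e]
    ir <- lattice_range(bounds, j)
    i_neutral <- round(bounds$neutral[j] / bounds$unit[j])
    widths <- c(0, 0)
    for (dir in 1:2) {
      sgn <- c(1, -1)[dir]
      dmax <- if (sgn > 0) ir[2] - i_neutral else i_neutral - ir[1]
      d <- 0L
      while (d < dmax) {
        # evaluate the sweep in blocks of 8 displacements
        ds <- (d + 1):min(d + 8L, dmax)
        par <- matrix(rep(bounds$neutral, each = length(ds)), length(ds), 4)
        par[, j] <- bounds$neutral[j] + sgn * ds * bounds$unit[j]
        sc <- f(par)
        bad <- which(sc / score0 < k0)
        if (length(bad)) { d <- ds[bad[1]] - 1L; break }
        d <- ds[length(ds)]
      }
      widths[dir] <- d
    }
    r0[e] <- max(1, widths)
  }
  r0
}

#' Sparse coarse-to-fine grid search
#'
#' Maximizes a score function over the bounded transform lattice by
#' successively refined equidistant grids. Level 0 evaluates the full grid
#' at the per-parameter initial spacing \code{r0}; each later level halves
#' the spacing and evaluates only yet-unseen grid points within one
#' previous-level spacing (per-parameter Chebyshev neighbourhood) of a
#' retained point. A point is retained while its score, normalized by the
#' running minimum and maximum of all scores seen so far, reaches the
#' decaying threshold \code{nu = k0 * delta_k^level}. The search stops once
#' every parameter has reached its finest spacing (one grid unit: 1 px
#' translation, or the rotation/scale step displacing the farthest template
#' pixel by under 1 px) and returns the argmax over all evaluated points.
#' If all scores seen so far are equal, only the incumbent is retained so
#' that refinement stays local. An evaluation cache guarantees no point is
#' scored twice.
#'
#' @param score_fn vectorized objective: n x 4 parameter matrix (tx, ty,
#'   theta, s) to n scores (see \code{\link{make_score_fn}}).
#' @param bounds a \code{\link{transform_bounds}}.
#' @param r0 per-parameter initial radius in grid units: named vector from
#'   \code{\link{estimate_initial_radius}} (a scalar is recycled over the
#'   enabled parameters).
#' @param k0 initial threshold fraction (default 0.6).
#' @param delta_k per-level threshold decay (default 0.5).
#' @param trace keep the full evaluation trace as a data frame (default
#'   \code{FALSE}).
#' @return an object of class \code{registration_result}: \code{transform}
#'   (best \code{\link{similarity_transform}}), \code{score},
#'   \code{evaluations}, \code{levels} (per-level evaluation and retention
#'   counts), optional \code{trace}.
#' @export
sparse_search <- function(score_fn, bounds, r0, k0 = 0.6, delta_k = 0.5,
                          trace = FALSE) {
  stopifnot(inherits(bounds, "transform_bounds"),
            k0 > 0, k0 <= 1, delta_k > 0, delta_k <= 1)
  enabled <- which(bounds$enabled)
  nd <- length(enabled)
  if (length(r0) == 1L) r0 <- rep(r0, nd)
  stopifnot(length(r0) == nd, all(r0 >= 1))
  ranges <- vapply(enabled, function(j) lattice_range(bounds, j),
                   numeric(2))
  spacing <- pmax(1L, as.integer(round(r0)))
  # integer lattice codes (exact in doubles) for fast dedup and caching
  nsz <- ranges[2, ] - ranges[1, ] + 1
  strides <- cumprod(c(1, nsz[-nd]))
  lat_code <- function(idx)
    as.vector((idx - rep(ranges[1, ], each = nrow(idx))) %*% strides)
  seen_codes <- numeric(0)
  all_idx <- list(); all_sc <- list(); lvl_rows <- list()
  level <- 0L
  smax <- -Inf; smin <- Inf
  # level-0 grid: all lattice multiples of the initial spacing
  grid_axes <- lapply(seq_len(nd), function(e)
    seq.int(ceiling(ranges[1, e] / spacing[e]) * spacing[e], ranges[2, e],
            by = spacing[e]))
  cand <- as.matrix(expand.grid(grid_axes))
  active_idx <- NULL; active_sc <- NULL
  repeat {
    if (nrow(cand)) {
      codes <- lat_code(cand)
      new <- !(codes %in% seen_codes)
      cand <- cand[new, , drop = FALSE]
      if (nrow(cand)) {
        seen_codes <- c(seen_codes, codes[new])
        sc <- score_fn(lattice_to_par(cand, bounds))
        all_idx[[length(all_idx) + 1L]] <- cand
        all_sc[[length(all_sc) + 1L]] <- sc
        active_idx <- rbind(active_idx, cand)
        active_sc <- c(active_sc, sc)
        fin_new <- is.finite(sc)
        if (any(fin_new)) {
          smax <- max(smax, sc[fin_new])
          smin <- min(smin, sc[fin_new])
        }
      }
    }
    # retention filters the active set (the nested refinement region only):
    # scores are normalized by the running min/max of everything evaluated
    nu <- k0 * delta_k^level
    fin <- is.finite(active_sc)
    if (!any(fin)) {
      keep <- seq_len(min(1L, length(active_sc)))
    } else if (smax > smin) {
      # fraction of the running maximum; a score of zero (no dependence)
      # is the natural floor, so the baseline is max(running min, 0) --
      # unless all scores are negative, where the running min takes over
      base0 <- if (smax > 0) max(smin, 0) else smin
      norm <- (active_sc - base0) / (smax - base0)
      keep <- which(fin & norm >= nu)
      if (!length(keep)) keep <- which(fin)[which.max(active_sc[fin])]
    } else keep <- which(fin)[which.max(active_sc[fin])]
    n_eval <- sum(vapply(all_sc, length, numeric(1)))
    lvl_rows[[level + 1L]] <- c(level = level, evaluated = n_eval,
                                retained = length(keep), nu = nu)
    if (all(spacing == 1L) && level > 0L) break
    prev_spacing <- spacing
    spacing <- ifelse(spacing > 1L, as.integer(ceiling(spacing / 2)), 1L)
    if (all(prev_spacing == 1L)) break
    # refine: lattice multiples of the new spacing within one previous
    # spacing (Chebyshev, per dimension) of any retained point; expanded in
    # blocks so the peak allocation stays bounded however large the
    # retained set grows
    ret <- active_idx[keep, , drop = FALSE]
    offs <- lapply(seq_len(nd), function(e)
      seq.int(-prev_spacing[e] %/% spacing[e] * spacing[e], prev_spacing[e],
              by = spacing[e]))
    og <- as.matrix(expand.grid(offs))
    block <- max(1L, 200000L %/% nrow(og))
    starts <- seq.int(1L, nrow(ret), by = block)
    cand_list <- vector("list", length(starts))
    collected <- numeric(0)
    for (bi in seq_along(starts)) {
      rows <- starts[bi]:min(starts[bi] + block - 1L, nrow(ret))
      rb <- ret[rows, , drop = FALSE]
      cb <- rb[rep(seq_len(nrow(rb)), each = nrow(og)), , drop = FALSE] +
        og[rep(seq_len(nrow(og)), times = nrow(rb)), , drop = FALSE]
      ok <- rep(TRUE, nrow(cb))
      for (e in seq_len(nd))
        ok <- ok & cb[, e] >= ranges[1, e] & cb[, e] <= ranges[2, e]
      cb <- cb[ok, , drop = FALSE]
      codes_b <- lat_code(cb)
      fresh <- !duplicated(codes_b) & !(codes_b %in% seen_codes) &
        !(codes_b %in% collected)
      cb <- cb[fresh, , drop = FALSE]
      collected <- c(collected, codes_b[fresh])
      cand_list[[bi]] <- cb
    }
    cand <- do.call(rbind, cand_list)
    # the next active set: surviving parents plus the new candidates
    active_idx <- ret
    active_sc <- active_sc[keep]
    level <- level + 1L
  }
  finalize_result(do.call(rbind, all_idx), unlist(all_sc), bounds, lvl_rows,
                  trace)
}

# Argmax with lexicographic tie-breaking over lattice indices; builds the
# registration_result shared by sparse and exhaustive search.
finalize_result <- function(idx_mat, sc_vec, bounds, lvl_rows, trace) {
  par <- lattice_to_par(idx_mat, bounds)
  best_sc <- if (any(is.finite(sc_vec))) max(sc_vec[is.finite(sc_vec)]) else -Inf
  cand <- if (is.finite(best_sc)) which(sc_vec == best_sc) else seq_along(sc_vec)
  if (length(cand) > 1L) {
    ord <- do.call(order, as.data.frame(idx_mat[cand, , drop = FALSE]))
    cand <- cand[ord[1L]]
  }
  best <- par[cand[1L], ]
  res <- structure(list(
    transform = similarity_transform(best[1], best[2], best[3], best[4]),
    score = best_sc,
    evaluations = length(sc_vec),
    levels = as.data.frame(do.call(rbind, lvl_rows))),
    class = "registration_result")
  if (trace)
    res$trace <- data.frame(par, score = sc_vec)
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> score = %.4f after %d evaluations\n",
              x$score, x$evaluations))
  print(x$transform)
  invisible(x)
}

#' Exhaustive grid search
#'
#' Evaluates every lattice point of the bounded transform space at the given
#' per-parameter step (grid units) and returns the global argmax, ties
#' broken by lexicographic parameter order. Used as the reference optimizer
#' in validation; it is impractically slow beyond translation-only searches,
#' so grids larger than \code{cap} raise an error.
#'
#' @inheritParams sparse_search
#' @param step per-parameter step in grid units (scalar recycled; default 1).
#' @param cap maximum admissible grid size (default 2e6).
#' @return a \code{registration_result}.
#' @export
exhaustive_search <- function(score_fn, bounds, step = 1, cap = 2e6) {
  stopifnot(inherits(bounds, "transform_bounds"))
  enabled <- which(bounds$enabled)
  nd <- length(enabled)
  if (length(step) == 1L) step <- rep(step, nd)
  step <- pmax(1L, as.integer(round(step)))
  axes <- lapply(seq_len(nd), function(e) {
    ir <- lattice_range(bounds, enabled[e])
    seq.int(ceiling(ir[1] / step[e]) * step[e], ir[2], by = step[e])
  })
  total <- prod(vapply(axes, length, numeric(1)))
  if (total > cap) stop("grid too large for exhaustive search; use sparse search")
  idx <- as.matrix(expand.grid(axes))
  sc <- score_fn(lattice_to_par(idx, bounds))
  finalize_result(idx, sc, bounds,
                  list(c(level = 0, evaluated = nrow(idx),
                         retained = nrow(idx), nu = 0)), trace = FALSE)
}
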
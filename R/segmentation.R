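# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to the squared distance to the nearest chosen
# center. Operates on an n x p matrix; assumes the RNG state is already set.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

# Assign every row of x to its nearest center (squared Euclidean).
assign_nearest <- function(x, centers) {
  cross <- x %*% t(centers)
  cnorm <- rowSums(centers^2)
  max.col(sweep(2 * cross, 2L, cnorm), ties.method = "first")
}

# Lloyd k-means from k-means++ seeds, several restarts, best objective kept.
# When the data hold at most k distinct points the exact optimum (one
# cluster per distinct point) is returned directly. Fitting is capped at
# n_fit sampled rows for large images; all rows are then assigned to the
# nearest fitted center.
kmeans_pp <- function(x, k, seed, restarts = 5L, iter_max = 300L,
                      n_fit = 20000L) {
  stopifnot(nrow(x) >= k)
  with_seed(seed, {
    ux <- unique(x)
    if (nrow(ux) <= k) {
      cluster <- assign_nearest(x, ux)
      return(list(cluster = cluster, centers = ux, tot.withinss = 0))
    }
    xs <- if (nrow(x) > n_fit) x[sample.int(nrow(x), n_fit), , drop = FALSE]
          else x
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(xs, k)
      centers <- centers[!duplicated(centers), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(xs, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit)) next
      # reseed empty clusters at the farthest point, then re-run Lloyd
      if (nrow(fit$centers) < k || any(fit$size == 0)) {
        cen <- unique(fit$centers[fit$size > 0, , drop = FALSE])
        miss <- k - nrow(cen)
        if (miss > 0) {
          dmin <- rowSums((xs - cen[assign_nearest(xs, cen), ,
                                    drop = FALSE])^2)
          far <- order(dmin, decreasing = TRUE)[seq_len(miss)]
          cen <- unique(rbind(cen, xs[far, , drop = FALSE]))
          fit <- tryCatch(
            suppressWarnings(stats::kmeans(xs, centers = cen,
                                           iter.max = iter_max,
                                           algorithm = "Lloyd")),
            error = function(e) fit)
        }
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed on degenerate data")
    cluster <- assign_nearest(x, best$centers)
    list(cluster = cluster, centers = best$centers,
         tot.withinss = best$tot.withinss)
  })
}

segment_matrix <- function(feat, mask, k, seed, modality, pixel_size) {
  stopifnot(k >= 1)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  nfg <- sum(mask)
  if (nfg == 0L) {
    warning("image is entirely background; returning all-zero labels")
    return(index_image(labels, k, modality, pixel_size))
  }
  if (k == 1L) {                          # binary foreground/background image
    labels[mask] <- 1L
    return(index_image(labels, k, modality, pixel_size))
  }
  if (nfg < k)
    stop(sprintf("fewer foreground pixels (%d) than clusters (%d)", nfg, k))
  fit <- kmeans_pp(feat[as.vector(mask), , drop = FALSE], k, seed)
  labels[mask] <- fit$cluster
  index_image(labels, k, modality, pixel_size)
}

#' Presegment a hyperspectral cube into an index-color image
#'
#' Foreground pixel spectra are clustered by k-means (Euclidean distance on
#' the raw spectrum vectors, k-means++ seeding, 5 restarts keeping the best
#' objective); labels 1..k are the cluster ids, label 0 marks background.
#' With \code{k = 1} this degenerates to the binary foreground/background
#' image used by the binary registration variant.
#'
#' @param cube a \code{\link{hyper_cube}}.
#' @param mask logical foreground mask (same rows x cols as the cube).
#' @param k number of foreground clusters (default 8, the usual choice for
#'   small spectral regions of interest).
#' @param seed integer RNG seed making the segmentation reproducible.
#' @return an \code{\link{index_image}} with \code{modality = "spectral"}.
#' @export
segment_spectral <- function(cube, mask, k = 8, seed = 1) {
  stopifnot(inherits(cube, "hyper_cube"), is.logical(mask))
  d <- dim(cube$values)
  stopifnot(all(dim(mask) == d[1:2]))
  feat <- matrix(cube$values, d[1] * d[2], d[3])
  segment_matrix(feat, mask, as.integer(k), seed, "spectral", cube$pixel_size)
}

#' Presegment a stained RGB image into an index-color image
#'
#' Clusters the 3-dimensional RGB vectors of all foreground pixels; otherwise
#' identical to \code{\link{segment_spectral}}. Whole-slide stained images
#' are conventionally segmented into \code{k = 10} clusters.
#'
#' @param he an \code{\link{rgb_image}} (normally cast-corrected).
#' @param mask logical foreground mask.
#' @param k number of foreground clusters (default 10).
#' @param seed integer RNG seed.
#' @return an \code{\link{index_image}} with \code{modality = "stained"}.
#' @export
segment_stained <- function(he, mask, k = 10, seed = 1) {
  stopifnot(inherits(he, "rgb_image"), is.logical(mask))
  d <- dim(he$values)
  stopifnot(all(dim(mask) == d[1:2]))
  feat <- matrix(he$values, d[1] * d[2], 3)
  segment_matrix(feat, mask, as.integer(k), seed, "stained", he$pixel_size)
}
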
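#' Joint label histogram of two overlaid index images
#'
#' Counts co-occurring label pairs over all overlapping pixels of the fixed
#' image and the (already resampled) moving image. The two label sequences
#' are the discrete random variables X (fixed) and Y (moving) of the
#' registration metric; the table retains zero-count rows/columns so that
#' label 0 = background keeps its identity.
#'
#' @param fixed an \code{\link{index_image}} (the template).
#' @param moving_sampled an \code{\link{index_image}} already sampled onto
#'   the fixed grid (see \code{\link{sample_moving}}).
#' @param base logarithm base for the entropies (default 2, i.e. bits).
#' @return an object of class \code{joint_dist} with elements \code{counts}
#'   ((k_X+1) x (k_Y+1) integer matrix), \code{m} (total pixel count),
#'   \code{p} (joint probabilities), \code{px}, \code{py} (marginals),
#'   \code{HX}, \code{HY} (marginal entropies) and \code{base}.
#' @export
joint_histogram <- function(fixed, moving_sampled, base = 2) {
  stopifnot(inherits(fixed, "index_image"),
            inherits(moving_sampled, "index_image"))
  if (!all(dim(fixed$labels) == dim(moving_sampled$labels)))
    stop("fixed and moving images must have the same shape")
  kx <- fixed$k
  ky <- moving_sampled$k
  idx <- as.vector(fixed$labels) * (ky + 1L) + as.vector(moving_sampled$labels)
  counts <- matrix(tabulate(idx + 1L, nbins = (kx + 1L) * (ky + 1L)),
                   nrow = kx + 1L, ncol = ky + 1L, byrow = TRUE)
  dimnames(counts) <- list(X = 0:kx, Y = 0:ky)
  joint_dist(counts, base = base)
}

#' Build a joint distribution from a count (or probability) table
#'
#' @param counts non-negative matrix of pair counts; rows index the fixed
#'   image labels (0..k_X), columns the moving image labels (0..k_Y), with
#'   the first row/column belonging to background label 0.
#' @param base logarithm base for entropies (default 2).
#' @return a \code{joint_dist} object (see \code{\link{joint_histogram}}).
#' @export
joint_dist <- function(counts, base = 2) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  m <- sum(counts)
  if (m <= 0) stop("empty joint table")
  p <- counts / m
  px <- rowSums(p)
  py <- colSums(p)
  structure(list(counts = counts, m = m, p = p, px = px, py = py,
                 HX = entropy_p(px, base), HY = entropy_p(py, base),
                 base = base),
            class = "joint_dist")
}

#' @export
print.joint_dist <- function(x, ...) {
  cat(sprintf("<joint_dist> %d x %d labels, m = %g, H(X) = %.4f, H(Y) = %.4f (base %g)\n",
              nrow(x$counts), ncol(x$counts), x$m, x$HX, x$HY, x$base))
  invisible(x)
}

#' Background-adjusted joint distribution
#'
#' Reweights the observed joint probabilities with the prior knowledge that
#' label 0 means background in both modalities: probability mass on
#' background-to-foreground pairs is scaled down by (1 - alpha) and the
#' removed mass is moved onto the background-to-background cell,
#' \deqn{p_a(x,0) = (1-a) p(x,0), x != 0}
#' \deqn{p_a(0,y) = (1-a) p(0,y), y != 0}
#' \deqn{p_a(0,0) = (1-a) p(0,0) + a [P(X=0) + P(Y=0) - p(0,0)]}
#' leaving all foreground-foreground cells untouched. The total mass remains
#' 1 for every alpha in [0, 1]; alpha = 0 returns the observed distribution.
#'
#' @param jd a \code{\link{joint_dist}}.
#' @param alpha adjustment factor in \code{[0, 1]}.
#' @return a list of class \code{adjusted_dist} with \code{p_alpha} and
#'   \code{alpha}.
#' @export
adjust_distribution <- function(jd, alpha) {
  stopifnot(inherits(jd, "joint_dist"))
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  p <- jd$p
  pa <- p
  p00 <- p[1L, 1L]
  pa[, 1L] <- (1 - alpha) * p[, 1L]
  pa[1L, ] <- (1 - alpha) * p[1L, ]
  pa[1L, 1L] <- (1 - alpha) * p00 + alpha * (jd$px[1L] + jd$py[1L] - p00)
  structure(list(p_alpha = pa, alpha = alpha), class = "adjusted_dist")
}

#' Restricted mutual information
#'
#' The registration metric: mutual information evaluated against the
#' background-adjusted joint distribution,
#' \deqn{I_a(X,Y) = H(X) + H(Y) - H_a(X,Y)}
#' where \eqn{H_a(X,Y) = -\sum p(x,y) \log p_a(x,y)} is the cross-entropy of
#' the observed joint probabilities against the adjusted ones. Cells with
#' \eqn{p(x,y) = 0} contribute nothing; a cell with \eqn{p > 0} but
#' \eqn{p_a = 0} (possible only at alpha = 1 on background border cells)
#' yields \code{-Inf}, which callers treat as the worst possible score.
#' At alpha = 0 this is exactly conventional mutual information; for any
#' alpha it never exceeds it.
#'
#' @param jd a \code{\link{joint_dist}}.
#' @param alpha adjustment factor in \code{[0, 1]} (default 0.25).
#' @return score in the units of \code{jd$base} (bits by default).
#' @export
restricted_mi <- function(jd, alpha = 0.25) {
  ad <- adjust_distribution(jd, alpha)
  p <- jd$p
  pa <- ad$p_alpha
  sup <- p > 0
  if (any(sup & pa <= 0)) return(-Inf)
  Ha <- -sum(p[sup] * log(pa[sup], base = jd$base))
  jd$HX + jd$HY - Ha
}

#' Conventional mutual information
#'
#' \eqn{I(X,Y) = H(X) + H(Y) - H(X,Y)}; equals
#' \code{\link{restricted_mi}} at alpha = 0.
#'
#' @param jd a \code{\link{joint_dist}}.
#' @return score in the units of \code{jd$base}.
#' @export
standard_mi <- function(jd) {
  jd$HX + jd$HY - entropy_p(as.vector(jd$p), jd$base)
}
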
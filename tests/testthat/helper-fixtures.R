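# Shared in-code fixtures. Everything is generated deterministically; no
# data files.

# A small cube whose foreground carries two exactly distinct spectra.
two_spectrum_cube <- function() {
  wn <- seq(1000, 1100, by = 10)
  v <- array(0, c(6, 8, length(wn)))
  sA <- exp(-(wn - 1020)^2 / 200)
  sB <- exp(-(wn - 1080)^2 / 200)
  for (r in 1:6) for (c in 1:8)
    v[r, c, ] <- if ((r + c) %% 2 == 0) sA else sB
  hyper_cube(v, wn, pixel_size = 5)
}

random_index_image <- function(rows, cols, k, seed, modality = "spectral") {
  set.seed(seed)
  index_image(matrix(sample(0:k, rows * cols, replace = TRUE), rows, cols),
              k, modality)
}

# Brute-force joint count oracle, written independently of the package path.
joint_counts_oracle <- function(a, b, ka, kb) {
  cnt <- matrix(0L, ka + 1, kb + 1)
  for (i in seq_along(a)) {
    cnt[a[i] + 1L, b[i] + 1L] <- cnt[a[i] + 1L, b[i] + 1L] + 1L
  }
  cnt
}

# Textbook MI in bits from a probability table (independent oracle).
mi_oracle <- function(p) {
  px <- rowSums(p); py <- colSums(p)
  h <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  h(px) + h(py) - h(as.vector(p))
}

# A small phantom used across tests (fast to render and register).
small_phantom <- function(seed = 11, ...) {
  sc <- phantom_scene(seed = seed, slide_size = c(240, 180),
                      roi_size = c(80, 60), ...)
  list(scene = sc, pair = render_pair(sc))
}
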
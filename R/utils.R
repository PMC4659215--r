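# Round half-up (ties toward +Inf), used everywhere a pixel coordinate or
# gray level is discretized so results are bit-reproducible across platforms.
round_half_up <- function(x) floor(x + 0.5)

# Run expr with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Shannon entropy (given log base) of a probability vector; 0 log 0 := 0.
entropy_p <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}
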
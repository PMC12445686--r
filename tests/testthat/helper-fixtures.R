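# Shared fixtures: built models are expensive enough to cache per test run.

so7 <- so7_topology()

so7_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_hybrid_qdh(so7)
    m
  }
})

so7_gap_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_hybrid_qdh(so7, builder_params(junction_gap = 6.8))
    m
  }
})

# a random rigid motion applied to every atom (deterministic under seed)
rigid_motion <- function(structure, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3)
  R <- qdhkit:::.rot_axis(ax, runif(1, 0, 360))
  tr <- rnorm(3, sd = 20)
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(R)
  out <- structure
  out$x <- xyz[, 1] + tr[1]
  out$y <- xyz[, 2] + tr[2]
  out$z <- xyz[, 3] + tr[3]
  out
}

expect_angle_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(periodic_delta(a, b)), tol)
}
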
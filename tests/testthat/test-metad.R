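# Periodic bias machinery, Langevin sampler, and free-energy recovery.

test_that("periodic differences are minimal signed angles", {
  expect_equal(periodic_delta(179, -179), -2)
  expect_equal(periodic_delta(0, 0), 0)
  expect_equal(periodic_delta(-179, 179), 2)
  set.seed(5)
  a <- runif(200, -720, 720)
  b <- runif(200, -720, 720)
  d <- periodic_delta(a, b)
  expect_true(all(d > -180 & d <= 180))
  # brute force over wrapped candidates
  brute <- vapply(seq_along(a), function(i) {
    cand <- a[i] - b[i] + 360 * (-4:4)
    cand[which.min(abs(cand))]
  }, 0)
  expect_equal(abs(d), abs(brute), tolerance = 1e-9)
})

test_that("bias potential sums periodic Gaussians", {
  b <- bias_state(sigma = 10, w0 = 0.2)
  expect_equal(bias_potential(b, c(-100, 0, 100)), c(0, 0, 0))
  b <- deposit(b, 0)
  expect_equal(bias_potential(b, 0), 0.2)
  b179 <- deposit(bias_state(sigma = 10, w0 = 0.2), 179)
  expect_equal(
    bias_potential(b179, -179),
    0.2 * exp(-2^2 / (2 * 10^2))
  )
  # smooth across the seam: value and first difference continuous
  g <- seq(-180 + 0.01, 180, by = 0.01)
  v <- bias_potential(b179, g)
  expect_lt(abs(v[1] - v[length(v)]), 1e-4)
  expect_lt(abs(diff(v)[1] - diff(v)[length(v) - 1]), 1e-6)
})

test_that("well-tempered deposition damps revisited hills", {
  b <- bias_state(w0 = 0.2, gamma = 10, temperature = 300)
  b <- deposit(b, 0)
  expect_equal(b$heights[1], 0.2)
  b <- deposit(b, 0)
  dT <- (10 - 1) * 300
  expect_equal(b$heights[2], 0.2 * exp(-0.2 / (0.0019872 * dT)))
  for (k in 1:10) b <- deposit(b, 0)
  expect_true(all(diff(b$heights) < 0))
})

test_that("free-energy estimate negates and rescales the bias", {
  b <- deposit(bias_state(sigma = 20), 40)
  fes <- fes_estimate(b, n_grid = 720)
  expect_true(all(fes$free_energy >= 0))
  # a single hill marks where the walker sat: the free-energy minimum is at
  # the hill center, and the profile rises to a flat plateau away from it
  expect_angle_equal(fes$angle[which.min(fes$free_energy)], 40, tol = 1)
  expect_angle_equal(fes$angle[which.max(fes$free_energy)], 40 - 180, tol = 90)
  # doubling hill heights doubles the profile (linearity up to shift)
  b2 <- b
  b2$heights <- b$heights * 2
  f2 <- fes_estimate(b2, n_grid = 720)
  expect_equal(f2$free_energy, 2 * fes$free_energy, tolerance = 1e-10)
  expect_error(fes_estimate(bias_state()), "empty bias")
})

test_that("minima finding matches analytic cosine profiles", {
  g <- seq(-179, 180, by = 1)
  one <- tibble::tibble(angle = g, free_energy = 1 - cospi(g / 180))
  m1 <- find_minima(one)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$position, 0)
  expect_equal(m1$depth, 2)
  two <- tibble::tibble(angle = g, free_energy = 1 - cospi(2 * g / 180))
  m2 <- find_minima(two)
  expect_equal(nrow(m2), 2)
  expect_setequal(m2$position, c(0, 180))
  # a depth floor above the relief empties the list
  expect_equal(nrow(find_minima(two, depth_min = 3)), 0)
  # merge radius collapses twin minima into the deeper one
  twin <- tibble::tibble(
    angle = g,
    free_energy = 2 - cospi(g / 180) - 0.98 * cospi((g - 10) / 180)
  )
  expect_equal(nrow(find_minima(twin, merge_radius = 30)), 1)
})

test_that("the Langevin sampler is deterministic and relaxes to the minimum", {
  u <- single_well(3, center = 20)
  t1 <- run_langevin(u, gradient = attr(u, "gradient"),
    temperature = 1e-6, dt = 20, steps = 3000, s0 = 130, seed = 8)
  expect_lt(abs(tail(t1$angle, 1) - 20), 0.5)
  t2 <- run_langevin(u, gradient = attr(u, "gradient"),
    temperature = 1e-6, dt = 20, steps = 3000, s0 = 130, seed = 8)
  expect_identical(t1, t2)
})

test_that("unbiased sampling reproduces Boltzmann weights", {
  u <- single_well(2)
  tr <- run_langevin(u, gradient = attr(u, "gradient"),
    temperature = 300, dt = 20, steps = 200000, seed = 12)
  breaks <- seq(-180, 180, by = 30)
  h <- hist(tr$angle, breaks = breaks, plot = FALSE)
  got <- h$counts / sum(h$counts)
  # numerical Boltzmann integral per bin
  beta <- 1 / (0.0019872 * 300)
  dens <- function(s) exp(-beta * u(s))
  z <- integrate(dens, -180, 180)$value
  want <- vapply(seq_len(length(breaks) - 1), function(i) {
    integrate(dens, breaks[i], breaks[i + 1])$value / z
  }, 0)
  expect_lt(max(abs(got - want)), 0.03)
})

test_that("wt-metaD recovers single- and double-well profiles", {
  shifted_err <- function(fes, u) {
    d <- fes$free_energy - u(fes$angle)
    d <- d - (max(d) + min(d)) / 2
    max(abs(d))
  }
  uu <- double_well(3)
  wt <- run_wtmetad(uu, gradient = attr(uu, "gradient"),
    bias = bias_state(sigma = 15, stride = 250), dt = 20, steps = 300000, seed = 1)
  expect_lt(shifted_err(wt$fes, uu), 0.5)
  mn <- find_minima(wt$fes)
  expect_equal(nrow(mn), 2)
  for (true_pos in c(0, 180)) {
    expect_true(any(abs(periodic_delta(mn$position, true_pos)) < 10))
  }

  us <- single_well(3)
  wt1 <- run_wtmetad(us, gradient = attr(us, "gradient"),
    bias = bias_state(sigma = 15, stride = 250), dt = 20, steps = 300000, seed = 2)
  expect_lt(shifted_err(wt1$fes, us), 0.5)
  expect_equal(nrow(find_minima(wt1$fes)), 1)
})

test_that("well asymmetry is reproduced in the recovered profile", {
  ua <- double_well(3, asym = 1.2)
  wt <- run_wtmetad(ua, gradient = attr(ua, "gradient"),
    bias = bias_state(sigma = 15, stride = 250), dt = 20, steps = 300000, seed = 3)
  mn <- find_minima(wt$fes, depth_min = 0.5)
  expect_equal(nrow(mn), 2)
  dF <- abs(diff(sort(mn$value)))
  expect_lt(abs(dF - 1.2), 0.5)
})
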
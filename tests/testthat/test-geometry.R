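# Plane fits, rise, grooves, tilts, the angular CV, and superposition.

# brute-force plane fit: direct minimization over spherical normal angles
plane_oracle <- function(xyz) {
  ctr <- colMeans(xyz)
  ss <- function(p) {
    n <- c(cos(p[1]) * sin(p[2]), sin(p[1]) * sin(p[2]), cos(p[2]))
    sum((sweep(xyz, 2, ctr) %*% n)^2)
  }
  best <- list(value = Inf)
  for (a in seq(0, 2 * pi, length.out = 13)) {
    for (b in seq(0.01, pi, length.out = 7)) {
      fit <- optim(c(a, b), ss, control = list(reltol = 1e-14))
      if (fit$value < best$value) best <- fit
    }
  }
  n <- c(
    cos(best$par[1]) * sin(best$par[2]),
    sin(best$par[1]) * sin(best$par[2]), cos(best$par[2])
  )
  list(centroid = ctr, normal = n, rms = sqrt(best$value / nrow(xyz)))
}

test_that("plane fitting matches a brute-force least-squares oracle", {
  expect_equal(fit_plane(rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)
  ))$rms, 0)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0.5, 0.5, 1))
  got <- fit_plane(xyz)
  ora <- plane_oracle(xyz)
  expect_equal(got$centroid, ora$centroid, tolerance = 1e-8)
  expect_lt(1 - abs(sum(got$normal * ora$normal)), 1e-8)
  expect_equal(got$rms, ora$rms, tolerance = 1e-6)
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "3 points")
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), "collinear")
})

test_that("rise measures projected centroid separation", {
  p1 <- fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  p2 <- fit_plane(rbind(c(0, 0, 3.4), c(1, 0, 3.4), c(0, 1, 3.4), c(1, 1, 3.4)))
  expect_equal(rise(p1, p2), 3.4)
  # near-orthogonal planes are rejected
  p3 <- fit_plane(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 1, 1)))
  expect_error(rise(p1, p3), "60 degrees")
})

test_that("groove width follows the P-P conventions", {
  m <- tibble::tibble(
    model = 1L, resid = c(1L, 2L), base = "G", atom = "P", element = "P",
    x = c(0, 10), y = 0, z = 0, ligand = FALSE
  )
  expect_equal(groove_width(m, 1, 2, convention = "raw"), 10)
  expect_equal(groove_width(m, 1, 2, convention = "refined"), 4.2)
  # invariant under rigid motion
  mm <- rigid_motion(m, seed = 4)
  expect_equal(groove_width(mm, 1, 2, convention = "raw"), 10, tolerance = 1e-9)
  m2 <- m[m$resid == 1, ]
  expect_error(groove_width(m2, 1, 2), "no P atom")
  # refined width floors at zero
  close_m <- dplyr::mutate(m, x = c(0, 5.0))
  expect_warning(w <- groove_width(close_m, 1, 2), "floored")
  expect_equal(w, 0)
})

test_that("ring tilt recovers constructed rotations and folds to [0, 90]", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(ring_tilt(sq, sq + 5), 0)
  for (ang in c(10, 30, 75)) {
    R <- qdhkit:::.rot_axis(c(1, 0, 0), ang)
    expect_equal(ring_tilt(sq, sq %*% t(R)), ang, tolerance = 1e-8)
  }
  R90 <- qdhkit:::.rot_axis(c(1, 0, 0), 90)
  expect_equal(ring_tilt(sq, sq %*% t(R90)), 90, tolerance = 1e-8)
  # folding: 120-degree rotation reads as 60
  R120 <- qdhkit:::.rot_axis(c(1, 0, 0), 120)
  expect_equal(ring_tilt(sq, sq %*% t(R120)), 60, tolerance = 1e-8)
})

test_that("dihedral follows the IUPAC convention on the worked examples", {
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)), 180)
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)), -90)
})

test_that("dihedral agrees with an independent implementation on random input", {
  set.seed(42)
  for (i in 1:20) {
    x <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(
      dihedral_angle(x[1, ], x[2, ], x[3, ], x[4, ]),
      as.numeric(bio3d::torsion.xyz(as.numeric(t(x)), atm.inc = 4)),
      tolerance = 1e-8
    )
  }
})

test_that("the angular CV and junction descriptors are rigid-motion invariant", {
  pose <- place_ligand(so7_gap_model(), 77)
  a0 <- angular_position(pose)
  l0 <- lateral_displacement(pose)
  g0 <- groove_width(pose, 20, 27)
  for (seed in 1:3) {
    pm <- rigid_motion(pose, seed = seed)
    expect_angle_equal(angular_position(pm), a0, tol = 1e-6)
    expect_equal(lateral_displacement(pm), l0, tolerance = 1e-6)
    expect_equal(groove_width(pm, 20, 27), g0, tolerance = 1e-6)
  }
})

test_that("CV placement sweep closes within a degree over the full circle", {
  m <- so7_gap_model()
  for (phi in seq(-170, 180, by = 10)) {
    pose <- suppressWarnings(place_ligand(m, phi))
    expect_angle_equal(angular_position(pose), phi, tol = 1)
  }
})

test_that("lateral displacement is a pure in-plane projection", {
  pose <- place_ligand(so7_gap_model(), 0)
  expect_lt(lateral_displacement(pose), 1e-6)
  topo <- attr(pose, "topology")
  quartet <- topo$quartets[[topo$junction_quartet]]
  nrm <- base_plane(pose[!pose$ligand, ], quartet)$normal
  # out-of-plane shift leaves it unchanged; in-plane shift reads exactly
  shifted <- pose
  lig <- shifted$ligand
  shifted[lig, c("x", "y", "z")] <-
    shifted[lig, c("x", "y", "z")] + rep(2 * nrm, each = sum(lig))
  expect_lt(lateral_displacement(shifted), 1e-6)
  e1 <- qdhkit:::pracma_nullvec(nrm)
  inplane <- pose
  inplane[lig, c("x", "y", "z")] <-
    inplane[lig, c("x", "y", "z")] + rep(2 * e1, each = sum(lig))
  expect_equal(lateral_displacement(inplane), 2, tolerance = 1e-6)
})

test_that("superposition matches the quaternion oracle on random instances", {
  set.seed(7)
  for (i in 1:10) {
    A <- matrix(rnorm(30, sd = 5), 10, 3)
    B <- A %*% t(qdhkit:::.rot_axis(rnorm(3), runif(1, 0, 360)))
    B <- sweep(B, 2, rnorm(3, sd = 10), `+`)
    B <- B + matrix(rnorm(30, sd = 0.3), 10, 3)
    got <- superpose(A, B)
    expect_equal(got$rmsd, horn_oracle(A, B), tolerance = 1e-6)
    expect_equal(det(got$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition removes rigid motions exactly", {
  m <- so7_model()
  moved <- rigid_motion(m, seed = 9)
  expect_lt(superpose(m, moved)$rmsd, 1e-8)
  shifted <- dplyr::mutate(m, x = x + 5, y = y + 5, z = z + 5)
  expect_lt(superpose(m, shifted)$rmsd, 1e-10)
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 atoms")
})

test_that("ensemble RMSD summarizes pairwise superpositions", {
  m <- so7_model()
  ens <- dplyr::bind_rows(
    m,
    dplyr::mutate(rigid_motion(m, seed = 1), model = 2L),
    dplyr::mutate(perturb_model(m, 0.5, seed = 2), model = 3L)
  )
  r <- ensemble_rmsd(ens)
  expect_equal(nrow(r$pairs), 3)
  # oracle per pair: heavy atoms only, same mask as the implementation
  heavy <- function(s) as.matrix(s[s$element != "H", c("x", "y", "z")])
  ms <- lapply(1:3, function(k) ens[ens$model == k, ])
  expected <- c(
    horn_oracle(heavy(ms[[1]]), heavy(ms[[2]])),
    horn_oracle(heavy(ms[[1]]), heavy(ms[[3]])),
    horn_oracle(heavy(ms[[2]]), heavy(ms[[3]]))
  )
  expect_equal(r$pairs$rmsd, expected, tolerance = 1e-6)
  expect_equal(r$mean, mean(expected), tolerance = 1e-6)
  expect_error(ensemble_rmsd(m), "2 models")
  # identical models give zero spread
  same <- dplyr::bind_rows(m, dplyr::mutate(m, model = 2L))
  expect_equal(ensemble_rmsd(same)$mean, 0, tolerance = 1e-10)
})
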
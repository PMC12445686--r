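# NOE calibration/binning and the generated restraint categories.

test_that("ISPA calibration maps volumes through the r^-6 law", {
  peaks <- tibble::tibble(
    res_i = c(1L, 2L, 3L), atom_i = c("H5", "H8", "H8"),
    res_j = c(1L, 2L, 4L), atom_j = c("H6", "H1'", "H1'"),
    volume = c(1000, 1000, 1000 / 64),
    reference = c(TRUE, FALSE, FALSE)
  )
  cal <- calibrate_noe(peaks)
  expect_equal(cal$distance[1], 2.45)
  expect_equal(cal$distance[2], 2.45)
  expect_equal(cal$distance[3], 4.90) # 64^(1/6) = 2 exactly
  # strictly decreasing in volume
  vols <- sort(runif(20, 1, 1e4))
  p2 <- tibble::tibble(
    res_i = 1L, atom_i = "H5", res_j = 1L, atom_j = "H6", volume = 1000,
    reference = TRUE
  )
  p2 <- dplyr::bind_rows(p2, tibble::tibble(
    res_i = 2L, atom_i = "H8", res_j = 3L, atom_j = "H8",
    volume = vols, reference = FALSE
  ))
  d <- calibrate_noe(p2)$distance[-1]
  expect_true(all(diff(d) < 0))
  # missing reference and non-positive volumes
  expect_error(calibrate_noe(peaks[2:3, ]), "reference")
  p3 <- peaks
  p3$volume[2] <- -1
  cal3 <- calibrate_noe(p3)
  expect_equal(nrow(cal3), 2)
  expect_equal(nrow(attr(cal3, "rejected")), 1)
})

test_that("zero-noise simulated NOE tables are inverted exactly", {
  m <- so7_model()
  noe <- simulate_noe_table(m, cutoff = 5, sigma = 0)
  cal <- calibrate_noe(noe)
  h <- m[m$element == "H", ]
  key <- paste(h$resid, h$atom)
  xyz <- as.matrix(h[, c("x", "y", "z")])
  i <- match(paste(cal$res_i, cal$atom_i), key)
  j <- match(paste(cal$res_j, cal$atom_j), key)
  d_true <- sqrt(rowSums((xyz[i, ] - xyz[j, ])^2))
  off <- abs(cal$distance - d_true)[!cal$reference]
  expect_lt(max(off), 1e-6)
  # the calibration fixed point: a simulated pair at the reference volume
  expect_true(all(abs(cal$distance[cal$reference] - 2.45) < 1e-12))
})

test_that("noisy simulation is seed-deterministic and a tiny cutoff yields no restraints", {
  m <- so7_model()
  n1 <- simulate_noe_table(m, sigma = 0.2, seed = 3)
  n2 <- simulate_noe_table(m, sigma = 0.2, seed = 3)
  expect_identical(n1, n2)
  tiny <- simulate_noe_table(m, cutoff = 0.1)
  expect_true(all(tiny$reference))
  rs <- build_restraint_set(so7, noe_table = tiny)
  expect_equal(unname(rs$counts["noe"]), 0L)
})

test_that("distance classes carry the fixed bound menu", {
  cls <- classify_noe(c(2.45, 3.5, 5.5, 7.0))
  expect_equal(cls$category, c("noe_strong", "noe_medium", "noe_weak", NA))
  expect_equal(cls$lower, c(1.8, 2.6, 3.5, NA))
  expect_equal(cls$upper, c(3.6, 5.0, 6.5, NA))
})

test_that("Hoogsteen restraints emit two bonds per quartet edge", {
  r3 <- hoogsteen_restraints(so7)
  expect_equal(nrow(r3), 24)
  r1 <- hoogsteen_restraints(list(c(1, 2, 3, 4)), sequence = rep("G", 4))
  expect_equal(nrow(r1), 8)
  bounds <- unique(paste(r3$lower, r3$upper))
  expect_setequal(bounds, c("1.9 2.1", "1.7 1.9"))
  expect_true(all(r3$lower < r3$upper))
  expect_error(
    hoogsteen_restraints(list(c(1, 2, 3, 5)), sequence = c("G", "G", "G", "G", "C")),
    "non-guanine"
  )
})

test_that("Watson-Crick restraints emit three bonds per G-C pair", {
  r3 <- wc_restraints(so7)
  expect_equal(nrow(r3), 9)
  expect_true(all(r3$lower == 1.8 & r3$upper == 2.0))
  r1 <- wc_restraints(list(c(1, 2)), sequence = c("G", "C"))
  expect_equal(nrow(r1), 3)
  expect_setequal(r1$atom_i, c("O2", "N3", "O6"))
  expect_error(
    wc_restraints(list(c(1, 2)), sequence = c("A", "T")),
    "A-T"
  )
})

test_that("torsion restraints cover every residue with the declared windows", {
  tr <- torsion_restraints(so7)
  expect_equal(nrow(tr), 27)
  syn <- tr[tr$res_i %in% so7$syn_set, ]
  expect_true(all(syn$center == 60 & syn$width == 35))
  anti_pur <- tr[!(tr$res_i %in% so7$syn_set) & so7$sequence[tr$res_i] %in% c("G", "A"), ]
  expect_true(all(anti_pur$center == 240 & anti_pur$width == 40))
  anti_pyr <- tr[so7$sequence[tr$res_i] %in% c("C", "T"), ]
  expect_true(all(anti_pyr$center == 240 & anti_pyr$width == 70))
})

test_that("planarity groups follow the documented 3-per-guanine scheme", {
  pl <- planarity_restraints(so7$quartets, so7$wc_pairs)
  expect_equal(sum(pl$category == "quartet_plane"), 36)
  expect_equal(sum(pl$category == "pair_plane"), 9)
  expect_equal(nrow(planarity_restraints()), 0)
})

test_that("category counts scale as 8q + 3p over random valid topologies", {
  set.seed(21)
  for (rep in 1:5) {
    nq <- sample(1:3, 1)
    np <- sample(0:3, 1)
    n <- 4 * nq + 2 * np + sample(0:3, 1)
    bases <- rep("G", n)
    quartets <- split(seq_len(4 * nq), rep(seq_len(nq), each = 4))
    pairs <- NULL
    if (np > 0) {
      pstart <- 4 * nq
      pairs <- lapply(seq_len(np), function(k) c(pstart + 2 * k - 1, pstart + 2 * k))
      for (p in pairs) bases[p[2]] <- "C"
    }
    topo <- qdh_topology(paste(bases, collapse = ""),
      quartets = quartets, wc_pairs = if (is.null(pairs)) list() else pairs
    )
    rs <- build_restraint_set(topo)
    expect_equal(unname(rs$counts["hbond"]), 8L * nq + 3L * np)
    expect_equal(unname(rs$counts["torsion"]), as.integer(n))
    expect_true(all(rs$distance$lower < rs$distance$upper))
  }
})

test_that("restraint files round trip through the flat text format", {
  noe <- simulate_noe_table(so7_model(), cutoff = 4, sigma = 0)
  rs <- build_restraint_set(so7, noe_table = noe)
  expect_equal(unname(rs$counts["noe"]), sum(!noe$reference))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(rs, f)
  back <- read_restraints(f)
  expect_equal(back$counts, rs$counts)
  expect_equal(nrow(back$distance), nrow(rs$distance))
  expect_setequal(
    paste(back$distance$category, back$distance$res_i, back$distance$atom_i,
      back$distance$lower, back$distance$upper),
    paste(rs$distance$category, rs$distance$res_i, rs$distance$atom_i,
      rs$distance$lower, rs$distance$upper)
  )
  # an empty set still writes a parseable header-only table
  empty <- build_restraint_set(qdh_topology("GGGG", quartets = list(1:4)))
  empty$distance <- empty$distance[0, ]
  empty$torsion <- empty$torsion[0, ]
  empty$planarity <- empty$planarity[0, ]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(empty, f2)
  expect_equal(nrow(read_restraints(f2)$distance), 0)
})
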
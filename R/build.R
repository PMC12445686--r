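# Idealized QDH model construction: planar base templates placed with
# Hoogsteen-compatible quartet geometry, standard Watson-Crick pair
# geometry, declared syn/anti glycosidic torsions, and decorative loop
# placement. Downstream detectors and descriptors consume only the atoms
# built here (base ring + polar hydrogens, C1'/C2'/O4'/H1', backbone P).

.qdh_cache <- new.env(parent = emptyenv())

# run expr with a private RNG stream, leaving the global state untouched
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# planar base templates: ring in z ~ 0, glycosidic N at origin, C1' on +x
.templates <- function() {
  if (!is.null(.qdh_cache$templates)) {
    return(.qdh_cache$templates)
  }
  path <- system.file("extdata", "base_templates.tsv", package = "qdhkit")
  tpl <- readr::read_tsv(path, show_col_types = FALSE)
  .qdh_cache$templates <- split(tpl, tpl$base)
  .qdh_cache$templates
}

.glyc_atom <- function(base) if (base %in% c("G", "A")) "N9" else "N1"

# apply in-plane transform (theta about z, then translate tx, ty) to a template
.place2d <- function(tpl, theta, tx, ty) {
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(.rot_z(theta))
  xyz[, 1] <- xyz[, 1] + tx
  xyz[, 2] <- xyz[, 2] + ty
  tpl$x <- xyz[, 1]
  tpl$y <- xyz[, 2]
  tpl$z <- xyz[, 3]
  tpl
}

.tpl_at <- function(tpl, name) {
  i <- match(name, tpl$atom)
  as.numeric(unlist(tpl[i, c("x", "y", "z")]))
}

# coarse grid search + Nelder-Mead polish over (theta, tx, ty)
.grid_polish <- function(obj, theta_step = 10, t_range = 9, t_step = 1) {
  best <- list(value = Inf)
  for (th in seq(0, 360 - theta_step, by = theta_step)) {
    for (tx in seq(-t_range, t_range, by = t_step)) {
      for (ty in seq(-t_range, t_range, by = t_step)) {
        v <- obj(c(th, tx, ty))
        if (v < best$value) best <- list(value = v, par = c(th, tx, ty))
      }
    }
  }
  fit <- optim(best$par, obj,
    method = "Nelder-Mead",
    control = list(maxit = 10000, reltol = 1e-15)
  )
  optim(fit$par, obj, method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
}

# solve the in-plane placement of one guanine such that four copies related
# by +90-degree rotations about z form a Hoogsteen-bonded quartet; the
# donor presents its Watson-Crick edge (H1 and the cis-to-N1 amino proton)
# to the acceptor's O6/N7 edge. Both hydrogen and heavy-atom distances are
# targeted, which pins the bonds near-linear; the O6 half-diagonal enters
# as a soft preference (rigid ideal-geometry bases fix it near 2.8).
.solve_quartet_placement <- function(o6_half) {
  key <- sprintf("quartet_%.4f", o6_half)
  if (!is.null(.qdh_cache[[key]])) {
    return(.qdh_cache[[key]])
  }
  g <- .templates()$G
  gx <- as.matrix(g[, c("x", "y", "z")])
  ai <- function(n) match(n, g$atom)
  R90 <- .rot_z(90)
  obj <- function(p) {
    X <- gx %*% t(.rot_z(p[1]))
    X[, 1] <- X[, 1] + p[2]
    X[, 2] <- X[, 2] + p[3]
    A <- X %*% t(R90)
    (.vnorm(X[ai("H1"), ] - A[ai("O6"), ]) - 1.85)^2 +
      (.vnorm(X[ai("N1"), ] - A[ai("O6"), ]) - 2.87)^2 +
      (.vnorm(X[ai("H22"), ] - A[ai("N7"), ]) - 1.95)^2 +
      (.vnorm(X[ai("N2"), ] - A[ai("N7"), ]) - 2.95)^2 +
      0.02 * (.vnorm(X[ai("O6"), 1:2]) - o6_half)^2
  }
  best <- .grid_polish(obj)
  if (best$value > 0.1) {
    abort("internal: quartet geometry solver failed to converge")
  }
  .qdh_cache[[key]] <- best$par
  best$par
}

# solve the in-plane placement of a flipped cytosine against a fixed guanine
# so the three canonical Watson-Crick hydrogen bonds form (again with both
# H and heavy-atom targets to keep the bonds near-linear)
.solve_wc_placement <- function() {
  if (!is.null(.qdh_cache$wc)) {
    return(.qdh_cache$wc)
  }
  g <- .templates()$G
  gx <- as.matrix(g[, c("x", "y", "z")])
  gi <- function(n) match(n, g$atom)
  c0 <- .templates()$C
  cx <- as.matrix(c0[, c("x", "y", "z")])
  cx[, 2] <- -cx[, 2]
  cx[, 3] <- -cx[, 3]
  ci <- function(n) match(n, c0$atom)
  obj <- function(p) {
    X <- cx %*% t(.rot_z(p[1]))
    X[, 1] <- X[, 1] + p[2]
    X[, 2] <- X[, 2] + p[3]
    (.vnorm(X[ci("H41"), ] - gx[gi("O6"), ]) - 1.9)^2 +
      (.vnorm(X[ci("N4"), ] - gx[gi("O6"), ]) - 2.9)^2 +
      (.vnorm(gx[gi("H1"), ] - X[ci("N3"), ]) - 1.9)^2 +
      (.vnorm(gx[gi("N1"), ] - X[ci("N3"), ]) - 2.9)^2 +
      (.vnorm(gx[gi("H22"), ] - X[ci("O2"), ]) - 1.9)^2 +
      (.vnorm(gx[gi("N2"), ] - X[ci("O2"), ]) - 2.9)^2
  }
  best <- .grid_polish(obj)
  if (best$value > 0.1) {
    abort("internal: Watson-Crick geometry solver failed to converge")
  }
  .qdh_cache$wc <- best$par
  best$par
}

# rotate the sugar/backbone atoms about the glycosidic bond so that the
# chi torsion (O4'-C1'-N9-C4 or O4'-C1'-N1-C2) hits `target` degrees
.set_chi <- function(res, target) {
  base <- res$base[1]
  gl <- .glyc_atom(base)
  ref <- if (base %in% c("G", "A")) "C4" else "C2"
  sugar <- intersect(c("P", "O4'", "C2'", "H1'"), res$atom)
  axis_from <- .tpl_at(res, "C1'")
  axis_to <- .tpl_at(res, gl)
  cur <- dihedral_angle(
    .tpl_at(res, "O4'"), axis_from, axis_to, .tpl_at(res, ref)
  )
  rot_sugar <- function(delta) {
    R <- .rot_axis(axis_to - axis_from, delta)
    i <- res$atom %in% sugar
    xyz <- as.matrix(res[i, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, axis_from) %*% t(R), 2, axis_from, `+`)
    res2 <- res
    res2[i, c("x", "y", "z")] <- as.data.frame(xyz)
    res2
  }
  # sign of d(chi)/d(rotation) depends on axis orientation; probe it
  probe <- rot_sugar(10)
  chi_p <- dihedral_angle(
    .tpl_at(probe, "O4'"), axis_from, axis_to, .tpl_at(probe, ref)
  )
  sgn <- if (periodic_delta(chi_p, cur) > 0) 1 else -1
  rot_sugar(sgn * periodic_delta(target, cur %% 360))
}

#' Builder parameters for idealized QDH models
#'
#' @param o6_half_diagonal Half-diagonal of the quartet O6 square, in
#'   angstroms (distance of each O6 from the quartet axis).
#' @param rise Inter-quartet rise in angstroms.
#' @param twist Inter-quartet twist in degrees.
#' @param duplex_rise,duplex_twist Step parameters of the duplex stem.
#' @param junction_gap Rise between the junction quartet and the adjacent
#'   Watson-Crick pair; widen to ~6.8 (about two stacking distances) to
#'   leave room for an intercalated ligand.
#' @param loop_radius Radius at which decorative loop/overhang residues are
#'   placed, in angstroms.
#' @return A list of class `qdh_builder_params`.
#' @export
builder_params <- function(o6_half_diagonal = 2.5, rise = 3.3, twist = 30,
                           duplex_rise = 3.3, duplex_twist = 36,
                           junction_gap = 3.3, loop_radius = 18) {
  stopifnot(
    rise > 0, duplex_rise > 0, junction_gap > 0, o6_half_diagonal > 0,
    twist > -180, twist <= 180
  )
  structure(
    list(
      o6_half_diagonal = o6_half_diagonal, rise = rise, twist = twist,
      duplex_rise = duplex_rise, duplex_twist = duplex_twist,
      junction_gap = junction_gap, loop_radius = loop_radius
    ),
    class = "qdh_builder_params"
  )
}

#' Build an idealized quadruplex-duplex hybrid model
#'
#' Constructs full-residue coordinates realizing a declared topology:
#' each quartet's four guanines are arranged with Hoogsteen-compatible
#' geometry (amino/imino donors facing N7/O6 acceptors of the cyclic
#' neighbor at ~1.8-2.0 angstrom H...acceptor distances), quartet planes
#' are stacked at the declared rise/twist, Watson-Crick pairs are stacked
#' coaxially beyond the junction gap, syn-set residues are built with
#' chi = 60 degrees and all others with chi = 240 degrees, and loop and
#' overhang residues are placed on a smooth outer arc (decorative: no
#' physical refinement, and no descriptor in this package measures them).
#'
#' @param topology A `qdh_topology` (e.g. [so7_topology()]).
#' @param params A [builder_params()] list.
#' @return A single-model structure tibble with the topology attached as an
#'   attribute.
#' @export
build_hybrid_qdh <- function(topology, params = builder_params()) {
  stopifnot(inherits(topology, "qdh_topology"))
  if (length(topology$quartets) == 0) {
    abort("topology declares no quartets; nothing to build")
  }
  pyr_syn <- topology$syn_set[topology$sequence[topology$syn_set] %in% c("C", "T")]
  if (length(pyr_syn) > 0) {
    abort(sprintf(
      "syn_set residue(s) %s are pyrimidines; the syn construction requires purines",
      paste(pyr_syn, collapse = ", ")
    ))
  }
  tpl <- .templates()
  seqv <- topology$sequence
  placed <- vector("list", length(seqv))

  # quartet levels
  qpar <- .solve_quartet_placement(params$o6_half_diagonal)
  slot0 <- .place2d(tpl$G, qpar[1], qpar[2], qpar[3])
  # amino-proton labels follow hydrogen-bonding role: in quartet guanines
  # the quartet-internal (N7-donating) proton is H21
  i21 <- match("H21", slot0$atom)
  i22 <- match("H22", slot0$atom)
  slot0$atom[c(i21, i22)] <- c("H22", "H21")
  for (lev in seq_along(topology$quartets)) {
    q <- topology$quartets[[lev]]
    for (k in 0:3) {
      res <- slot0
      R <- .rot_z(90 * k + params$twist * (lev - 1))
      xyz <- as.matrix(res[, c("x", "y", "z")]) %*% t(R)
      xyz[, 3] <- xyz[, 3] + params$rise * (lev - 1)
      res[, c("x", "y", "z")] <- as.data.frame(xyz)
      placed[[q[k + 1]]] <- res
    }
  }

  # duplex pairs stacked coaxially above the junction quartet
  if (length(topology$wc_pairs) > 0) {
    wpar <- .solve_wc_placement()
    gq <- tpl$G
    cq <- tpl$C
    cq$y <- -cq$y
    cq$z <- -cq$z
    cq <- .place2d(cq, wpar[1], wpar[2], wpar[3])
    # recenter the pair on the helical axis using the base ring atoms, so
    # the ring plane lands exactly at the requested stack height
    ring <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
    pair_ctr <- colMeans(rbind(
      as.matrix(gq[gq$atom %in% ring, c("x", "y", "z")]),
      as.matrix(cq[cq$atom %in% ring, c("x", "y", "z")])
    ))
    z_top <- params$rise * (length(topology$quartets) - 1)
    for (j in seq_along(topology$wc_pairs)) {
      p <- topology$wc_pairs[[j]]
      gi <- p[which(seqv[p] == "G")]
      ci <- p[which(seqv[p] == "C")]
      if (length(gi) != 1 || length(ci) != 1) {
        abort(sprintf(
          "pair %s-%s is not a G-C pair; only G-C duplex steps are built",
          p[1], p[2]
        ))
      }
      zj <- z_top + params$junction_gap + params$duplex_rise * (j - 1)
      R <- .rot_z(params$duplex_twist * (j - 1))
      for (side in c("g", "c")) {
        res <- if (side == "g") gq else cq
        xyz <- sweep(as.matrix(res[, c("x", "y", "z")]), 2, pair_ctr)
        xyz <- xyz %*% t(R)
        xyz[, 3] <- xyz[, 3] + zj
        res[, c("x", "y", "z")] <- as.data.frame(xyz)
        placed[[if (side == "g") gi else ci]] <- res
      }
    }
  }

  # decorative loop/overhang residues on an outer helix arc
  rest <- which(vapply(placed, is.null, logical(1)))
  if (length(rest) > 0) {
    zr <- seq(-6, 10, length.out = max(length(rest), 2))
    for (k in seq_along(rest)) {
      i <- rest[k]
      res <- tpl[[seqv[i]]]
      phi <- 40 * (k - 1)
      # template +x (sugar side) points radially outward
      res <- .place2d(res, phi, 0, 0)
      dir <- c(cos(phi * pi / 180), sin(phi * pi / 180))
      res$x <- res$x + params$loop_radius * dir[1]
      res$y <- res$y + params$loop_radius * dir[2]
      res$z <- res$z + zr[k]
      placed[[i]] <- res
    }
  }

  rows <- purrr::imap(placed, function(res, i) {
    res <- res[, c("atom", "element", "x", "y", "z")]
    chi <- if (i %in% topology$syn_set) 60 else 240
    res2 <- res
    res2$base <- seqv[i]
    res2 <- .set_chi(res2, chi)
    tibble(
      model = 1L, resid = as.integer(i), base = seqv[i],
      atom = res2$atom, element = res2$element,
      x = res2$x, y = res2$y, z = res2$z, ligand = FALSE
    )
  })
  .new_structure(bind_rows(rows), topology = topology)
}

#' Insert a planar synthetic ligand at a requested angular position
#'
#' Rigid-body placement of the package's synthetic three-moiety ligand into
#' the quadruplex-duplex junction: the ligand plane is set parallel to the
#' junction quartet at `axial_offset` above it (default: halfway to the
#' adjacent Watson-Crick pair), the nine-atom center sits on the quartet
#' axis, and the moiety-I direction is chosen so that the angular-position
#' CV evaluates to `angle` exactly. A steric clash (any ligand-DNA contact
#' under 1 angstrom) sets the `clash` attribute and emits a warning.
#'
#' @param structure A built QDH model containing the junction quartet and
#'   at least one adjacent Watson-Crick pair.
#' @param angle Requested angular position, degrees in (-180, 180].
#' @param ligand_map A ligand moiety map; default the synthetic ligand.
#' @param axial_offset Offset of the ligand plane from the quartet plane,
#'   in angstroms; `NULL` for half the junction gap.
#' @param moiety_radius Distance of each moiety center from the ligand
#'   center, in angstroms.
#' @return The structure with ligand atoms appended (attribute `clash` is
#'   `TRUE` if a close contact was found).
#' @export
place_ligand <- function(structure, angle, ligand_map = ligand_moiety_map("SYN"),
                         axial_offset = NULL, moiety_radius = 3.5) {
  topo <- attr(structure, "topology")
  if (is.null(topo)) abort("place_ligand() needs a structure with a topology attribute")
  if (length(topo$wc_pairs) == 0) {
    abort("place_ligand() needs an adjacent Watson-Crick pair in the model")
  }
  quartet <- topo$quartets[[topo$junction_quartet]]
  flank <- topo$cv_flank %||% quartet[1:2]
  dna <- structure[!structure$ligand, ]

  qpl <- base_plane(dna, quartet)
  pair1 <- topo$wc_pairs[[1]]
  pair_ctr <- colMeans(.xyz(dna, resid = pair1))
  nrm <- qpl$normal
  if (sum(nrm * (pair_ctr - qpl$centroid)) < 0) nrm <- -nrm
  gap <- abs(sum((pair_ctr - qpl$centroid) * nrm))
  offset <- axial_offset %||% (gap / 2)

  p2 <- colMeans(.xyz(dna, resid = quartet, atom = "O6"))
  center <- p2 + offset * nrm
  # in-plane basis
  e1 <- .unit(pracma_nullvec(nrm))
  e2 <- c(
    nrm[2] * e1[3] - nrm[3] * e1[2],
    nrm[3] * e1[1] - nrm[1] * e1[3],
    nrm[1] * e1[2] - nrm[2] * e1[1]
  )
  p1 <- colMeans(.xyz(dna, resid = flank, atom = c("C2'", "O4'")))

  lig_xyz <- function(alpha) {
    u <- function(a) cos(a * pi / 180) * e1 + sin(a * pi / 180) * e2
    ctrs <- rbind(
      center + moiety_radius * u(alpha),
      center + moiety_radius * u(alpha + 120),
      center + moiety_radius * u(alpha - 120)
    )
    atoms <- lapply(1:3, function(m) {
      t(vapply(c(0, 120, 240), function(b) {
        ctrs[m, ] + 0.8 * u(alpha + b + 60 * m)
      }, numeric(3)))
    })
    do.call(rbind, atoms)
  }
  dihed_of <- function(alpha) {
    xyz <- lig_xyz(alpha)
    p3 <- colMeans(xyz)
    p4 <- colMeans(xyz[1:3, , drop = FALSE])
    dihedral_angle(p1, p2, p3, p4)
  }
  f0 <- dihed_of(0)
  slope <- sign(periodic_delta(dihed_of(10), f0) / 10)
  alpha <- slope * periodic_delta(angle, f0)
  # one Newton refinement against floating-point drift
  alpha <- alpha + slope * periodic_delta(angle, dihed_of(alpha))

  xyz <- lig_xyz(alpha)
  cvmap <- ligand_map[ligand_map$cv, ]
  ord <- order(match(cvmap$moiety, c("I", "II", "III")))
  cvmap <- cvmap[ord, ]
  lig <- tibble(
    model = structure$model[1],
    resid = max(structure$resid) + 1L,
    base = ligand_map$ligand[1],
    atom = cvmap$atom,
    element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    ligand = TRUE
  )
  dmin <- min(sqrt(outer(rowSums(xyz^2), rowSums(.xyz(dna)^2), `+`) -
    2 * xyz %*% t(.xyz(dna))))
  out <- .new_structure(bind_rows(structure, lig),
    topology = topo, ligand_map = ligand_map
  )
  clash <- is.finite(dmin) && dmin < 1.0
  if (clash) warn(sprintf("ligand placed with a %.2f angstrom contact to DNA", dmin))
  attr(out, "clash") <- clash
  out
}

# a vector orthogonal to v (deterministic)
pracma_nullvec <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- a - sum(a * .unit(v)) * .unit(v)
  .unit(w)
}

#' Gaussian coordinate perturbation of a model
#'
#' Adds i.i.d. Gaussian noise to every coordinate; deterministic under a
#' fixed seed and a no-op at `sigma = 0`.
#'
#' @param structure A structure tibble.
#' @param sigma Per-coordinate standard deviation in angstroms.
#' @param seed Integer seed.
#' @return The perturbed structure (attributes preserved).
#' @export
perturb_model <- function(structure, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) {
    return(structure)
  }
  n <- nrow(structure)
  eps <- .with_seed(seed, matrix(rnorm(3 * n, sd = sigma), ncol = 3))
  out <- structure
  out$x <- out$x + eps[, 1]
  out$y <- out$y + eps[, 2]
  out$z <- out$z + eps[, 3]
  out
}
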
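# Junction geometry descriptors: plane fits, rise, groove width, ring tilt,
# the angular-position pseudotorsion CV, and ensemble superposition/RMSD.

# ---- low-level vector helpers (internal) -----------------------------------

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) abort("zero-length vector where a direction is required")
  v / n
}

# rotation matrix about arbitrary unit axis (Rodrigues), angle in degrees
.rot_axis <- function(axis, angle_deg) {
  a <- .unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.rot_z <- function(angle_deg) .rot_axis(c(0, 0, 1), angle_deg)

# coordinates of selected atoms as an n x 3 matrix
.xyz <- function(structure, resid = NULL, atom = NULL) {
  d <- structure
  if (!is.null(resid)) d <- d[d$resid %in% resid, , drop = FALSE]
  if (!is.null(atom)) d <- d[d$atom %in% atom, , drop = FALSE]
  as.matrix(d[, c("x", "y", "z")])
}

# ---- plane fitting ---------------------------------------------------------

#' Least-squares plane through a set of atoms
#'
#' Fits the total-least-squares plane through three or more points by
#' eigen-decomposition of the coordinate covariance; the plane normal is the
#' eigenvector of the smallest eigenvalue.
#'
#' @param xyz A numeric matrix with 3 columns (x, y, z) or a data frame with
#'   `x`, `y`, `z` columns (e.g. rows of a structure tibble).
#' @param orient Optional point (length-3 numeric); if supplied the normal
#'   sign is flipped so that it points from the centroid toward this point.
#' @return A list of class `qdh_plane` with elements `centroid`, `normal`
#'   (unit length) and `rms` (root-mean-square out-of-plane deviation, in
#'   angstroms).
#' @export
fit_plane <- function(xyz, orient = NULL) {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz[, c("x", "y", "z")])
  if (!is.matrix(xyz) || ncol(xyz) != 3 || nrow(xyz) < 3) {
    abort("fit_plane() needs at least 3 points as an n x 3 matrix")
  }
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  if (ev$values[2] < 1e-10) abort("fit_plane(): points are collinear")
  n <- ev$vectors[, 3]
  if (!is.null(orient) && sum(n * (orient - ctr)) < 0) n <- -n
  res <- X %*% n
  structure(
    list(centroid = ctr, normal = as.numeric(n), rms = sqrt(mean(res^2))),
    class = "qdh_plane"
  )
}

#' Plane through the base ring atoms of one or more residues
#'
#' @param structure A structure tibble (single model).
#' @param resid Residue indices whose base ring atoms define the plane.
#' @param orient Passed to [fit_plane()].
#' @return A `qdh_plane` object.
#' @export
base_plane <- function(structure, resid, orient = NULL) {
  ring <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  d <- structure[structure$resid %in% resid & structure$atom %in% ring, ]
  if (nrow(d) < 3) abort("base_plane(): fewer than 3 ring atoms found")
  fit_plane(as.matrix(d[, c("x", "y", "z")]), orient = orient)
}

#' Rise between two stacked planes
#'
#' Distance between the two plane centroids projected onto the mean of the
#' two normals, the usual step-rise measure for stacked bases or base pairs.
#'
#' @param lower,upper `qdh_plane` objects (see [fit_plane()]).
#' @return Rise in angstroms (non-negative).
#' @export
rise <- function(lower, upper) {
  n1 <- lower$normal
  n2 <- upper$normal
  if (sum(n1 * n2) < 0) n2 <- -n2
  ang <- acos(pmin(1, pmax(-1, sum(n1 * n2)))) * 180 / pi
  if (ang > 60) {
    abort("rise(): plane normals differ by more than 60 degrees; check plane orientation")
  }
  nbar <- .unit(n1 + n2)
  abs(sum((upper$centroid - lower$centroid) * nbar))
}

#' Cross-groove phosphorus-phosphorus width
#'
#' Groove width between two residues measured as the P-P distance, either
#' raw or with the conventional 5.8 angstrom phosphate-radius correction
#' subtracted ("refined"). Both conventions are offered because absolute
#' widths depend on the choice; differences between structures cancel it.
#'
#' @param structure A structure tibble (single model).
#' @param res_i,res_j Residue indices on the two groove walls.
#' @param convention `"refined"` (default, P-P minus 5.8) or `"raw"`.
#' @return Width in angstroms (floored at 0 with a warning).
#' @export
groove_width <- function(structure, res_i, res_j,
                         convention = c("refined", "raw")) {
  convention <- match.arg(convention)
  pi_ <- .xyz(structure, resid = res_i, atom = "P")
  pj <- .xyz(structure, resid = res_j, atom = "P")
  if (nrow(pi_) != 1 || nrow(pj) != 1) {
    abort(sprintf("groove_width(): residue %s or %s has no P atom", res_i, res_j))
  }
  w <- .vnorm(pi_[1, ] - pj[1, ])
  if (convention == "refined") {
    w <- w - 5.8
    if (w < 0) {
      warn("refined groove width below 0; floored at 0")
      w <- 0
    }
  }
  w
}

#' Tilt angle between two ring planes
#'
#' Angle between the least-squares plane normals of two atom groups, folded
#' into [0, 90] degrees.
#'
#' @param group_a,group_b Coordinate matrices or data frames with x/y/z
#'   (at least 3 non-collinear atoms each).
#' @return Angle in degrees.
#' @export
ring_tilt <- function(group_a, group_b) {
  na <- fit_plane(group_a)$normal
  nb <- fit_plane(group_b)$normal
  ang <- acos(pmin(1, pmax(-1, abs(sum(na * nb))))) * 180 / pi
  ang
}

# ---- dihedral --------------------------------------------------------------

#' Dihedral angle over four points
#'
#' IUPAC sign convention: `atan2((n1 x n2) . b2_hat, n1 . n2)` with
#' `n1 = b1 x b2`, `n2 = b2 x b3` for bond vectors `b1 = p2 - p1`,
#' `b2 = p3 - p2`, `b3 = p4 - p3`.
#'
#' @param p1,p2,p3,p4 Length-3 numeric coordinates.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (.vnorm(b2) < 1e-9) abort("dihedral_angle(): central bond vector has zero length")
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2],
    b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2],
    b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9) {
    abort("dihedral_angle(): collinear points, dihedral undefined")
  }
  m <- c(
    n1[2] * n2[3] - n1[3] * n2[2],
    n1[3] * n2[1] - n1[1] * n2[3],
    n1[1] * n2[2] - n1[2] * n2[1]
  )
  ang <- atan2(sum(m * .unit(b2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# ---- angular-position collective variable ----------------------------------

# the four geometric centers defining the CV (internal)
.cv_points <- function(structure, ligand_map, quartet, flank) {
  dna <- structure[!structure$ligand, ]
  lig <- structure[structure$ligand, ]
  if (nrow(lig) == 0) abort("no ligand present in the model")
  p1m <- .xyz(dna, resid = flank, atom = c("C2'", "O4'"))
  if (nrow(p1m) != 4) abort("flank guanines must contribute C2' and O4' each")
  p2m <- .xyz(dna, resid = quartet, atom = "O6")
  if (nrow(p2m) != 4) abort("junction quartet must contribute four O6 atoms")
  cvmap <- ligand_map[ligand_map$cv, ]
  miss <- setdiff(cvmap$atom, lig$atom)
  if (length(miss) > 0) {
    abort(paste0("ligand is missing CV atoms: ", paste(miss, collapse = ", ")))
  }
  p3m <- .xyz(lig, atom = cvmap$atom)
  p4m <- .xyz(lig, atom = cvmap$atom[cvmap$moiety == "I"])
  list(
    P1 = colMeans(p1m), P2 = colMeans(p2m),
    P3 = colMeans(p3m), P4 = colMeans(p4m)
  )
}

#' Angular position of a bound ligand (pseudotorsion CV)
#'
#' The ligand angular-position collective variable: the pseudotorsion over
#' four geometric centers P1 (C2'/O4' atoms of the two duplex-adjacent
#' quartet guanines), P2 (the four O6 atoms of the junction quartet), P3
#' (the nine ligand CV atoms, three per aromatic moiety) and P4 (the three
#' moiety-I atoms). Zero corresponds to the ligand's middle ring sitting
#' between the junction quartet and the adjacent base pair.
#'
#' @param structure A structure tibble containing a placed ligand.
#' @param ligand_map A ligand moiety map (see [ligand_moiety_map()]);
#'   defaults to the map stored on the structure, if any.
#' @param quartet Four residue indices of the junction quartet; defaults to
#'   the junction quartet of the structure's topology attribute.
#' @param flank The two duplex-adjacent quartet guanines contributing
#'   C2'/O4' to P1; defaults come from the topology attribute.
#' @return Angle in degrees in (-180, 180].
#' @export
angular_position <- function(structure, ligand_map = NULL, quartet = NULL,
                             flank = NULL) {
  topo <- attr(structure, "topology")
  ligand_map <- ligand_map %||% attr(structure, "ligand_map")
  if (is.null(ligand_map)) abort("ligand_map is required (none stored on structure)")
  if (is.null(quartet)) {
    if (is.null(topo)) abort("quartet is required when the structure has no topology attribute")
    quartet <- topo$quartets[[topo$junction_quartet]]
  }
  flank <- flank %||% topo$cv_flank
  if (is.null(flank)) abort("flank residues are required")
  p <- .cv_points(structure, ligand_map, quartet, flank)
  dihedral_angle(p$P1, p$P2, p$P3, p$P4)
}

#' In-plane displacement of the ligand from the quartet axis
#'
#' Distance between the projections of the ligand center (P3) and the
#' quartet O6 center (P2) onto the junction-quartet plane, i.e. the lateral
#' sliding component of the ligand position.
#'
#' @inheritParams angular_position
#' @return Displacement in angstroms.
#' @export
lateral_displacement <- function(structure, ligand_map = NULL, quartet = NULL) {
  topo <- attr(structure, "topology")
  ligand_map <- ligand_map %||% attr(structure, "ligand_map")
  if (is.null(quartet)) {
    if (is.null(topo)) abort("quartet is required when the structure has no topology attribute")
    quartet <- topo$quartets[[topo$junction_quartet]]
  }
  flank <- topo$cv_flank %||% quartet[1:2]
  p <- .cv_points(structure, ligand_map, quartet, flank)
  pl <- base_plane(structure[!structure$ligand, ], quartet)
  d <- p$P3 - p$P2
  dperp <- d - sum(d * pl$normal) * pl$normal
  .vnorm(dperp)
}

# ---- superposition ---------------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of a mobile coordinate set onto a reference
#' via singular value decomposition, with a proper rotation enforced
#' (det R = +1).
#'
#' @param reference,mobile Coordinate matrices (n x 3) or single-model
#'   structure tibbles; when tibbles are given, `atom_mask` selects the
#'   atoms used (matched by residue and atom name).
#' @param atom_mask Optional function taking the structure tibble and
#'   returning a logical vector of rows to use; default keeps heavy atoms.
#' @return A list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), `rmsd` in angstroms,
#'   and `xyz`, the transformed mobile coordinates.
#' @export
superpose <- function(reference, mobile, atom_mask = NULL) {
  as_mat <- function(s) {
    if (is.matrix(s)) return(s)
    keep <- if (is.null(atom_mask)) s$element != "H" else atom_mask(s)
    s <- s[keep, ]
    s <- s[order(s$resid, s$atom), ]
    as.matrix(s[, c("x", "y", "z")])
  }
  A <- as_mat(reference)
  B <- as_mat(mobile)
  if (nrow(A) != nrow(B)) abort("superpose(): atom selections differ in length")
  if (nrow(A) < 3) abort("superpose(): need at least 3 atoms")
  ca <- colMeans(A)
  cb <- colMeans(B)
  H <- crossprod(sweep(B, 2, cb), sweep(A, 2, ca))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bt <- sweep(sweep(B, 2, cb) %*% t(R), 2, ca, `+`)
  rmsd <- sqrt(mean(rowSums((Bt - A)^2)))
  list(
    rotation = R,
    translation = as.numeric(ca - cb %*% t(R)),
    rmsd = rmsd,
    xyz = Bt
  )
}

#' Pairwise RMSD statistics over an ensemble
#'
#' Superposes every pair of models (all heavy atoms by default) and reports
#' the mean and standard deviation over the N(N-1)/2 pairwise RMSDs, the
#' usual convergence statistic for NMR ensembles.
#'
#' @param ensemble A multi-model structure tibble.
#' @param include_ligand Include ligand atoms in the mask (default `TRUE`).
#' @param atom_mask Optional mask function, as in [superpose()].
#' @return A list with `mean`, `sd` and `pairs`, a tibble of per-pair RMSDs.
#' @export
ensemble_rmsd <- function(ensemble, include_ligand = TRUE, atom_mask = NULL) {
  models <- sort(unique(ensemble$model))
  if (length(models) < 2) abort("ensemble_rmsd(): need at least 2 models")
  if (!include_ligand) ensemble <- ensemble[!ensemble$ligand, ]
  split_m <- lapply(models, function(m) ensemble[ensemble$model == m, ])
  pairs <- tidyr::expand_grid(i = seq_along(models), j = seq_along(models)) |>
    filter(.data$i < .data$j)
  pairs$rmsd <- purrr::map2_dbl(
    pairs$i, pairs$j,
    function(i, j) superpose(split_m[[i]], split_m[[j]], atom_mask = atom_mask)$rmsd
  )
  pairs$model_i <- models[pairs$i]
  pairs$model_j <- models[pairs$j]
  list(
    mean = mean(pairs$rmsd),
    sd = if (nrow(pairs) > 1) sd(pairs$rmsd) else 0,
    pairs = select(pairs, "model_i", "model_j", "rmsd")
  )
}
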
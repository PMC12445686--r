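# Coordinate-based topology detection: hydrogen bonds, G-quartets (directed
# Hoogsteen 4-cycles), Watson-Crick pairs, and glycosidic torsion classes.

# donor (heavy, H) and acceptor atoms per base, base hydrogen-bonding only
.donors <- list(
  G = list(c("N1", "H1"), c("N2", "H21"), c("N2", "H22")),
  C = list(c("N4", "H41"), c("N4", "H42")),
  A = list(c("N6", "H61"), c("N6", "H62")),
  T = list(c("N3", "H3"))
)
.acceptors <- list(
  G = c("O6", "N7", "N3"),
  C = c("O2", "N3"),
  A = c("N7", "N1", "N3"),
  T = c("O2", "O4")
)

#' Detect base-base hydrogen bonds from coordinates
#'
#' Enumerates all (donor-H, acceptor) pairs over the canonical base donors
#' and acceptors and keeps those with H...acceptor distance at most `d_max`
#' and donor-H...acceptor angle at least `angle_min`, excluding
#' intra-residue pairs. The defaults bracket the 1.7-2.1 angstrom restraint
#' targets of quartet and Watson-Crick bonds with room for perturbed
#' coordinates.
#'
#' @param structure A single-model structure tibble with explicit base
#'   hydrogens.
#' @param d_max Maximum H...acceptor distance in angstroms.
#' @param angle_min Minimum donor-H...acceptor angle in degrees.
#' @return A tibble with columns `donor_res`, `donor_base`, `donor_atom`,
#'   `h_atom`, `acceptor_res`, `acceptor_base`, `acceptor_atom`,
#'   `distance`, `angle`.
#' @export
find_hbonds <- function(structure, d_max = 2.5, angle_min = 120) {
  dna <- structure[!structure$ligand, ]
  if (!any(dna$element == "H")) {
    abort("model carries no hydrogens; build with the idealized builder or add hydrogens")
  }
  don <- purrr::map_dfr(names(.donors), function(b) {
    purrr::map_dfr(.donors[[b]], function(dh) {
      tibble(base = b, donor_atom = dh[1], h_atom = dh[2])
    })
  })
  dd <- dplyr::inner_join(dna, don, by = c("base", "atom" = "h_atom"))
  # heavy donor coordinates matched by residue
  heavy <- dna[paste(dna$resid, dna$atom) %in%
    paste(dd$resid, dd$donor_atom), c("resid", "atom", "x", "y", "z")]
  dd <- dplyr::left_join(dd, heavy,
    by = c("resid", "donor_atom" = "atom"), suffix = c("", "_d")
  )
  acc <- purrr::map_dfr(names(.acceptors), function(b) {
    tibble(base = b, atom = .acceptors[[b]])
  })
  aa <- dplyr::inner_join(dna, acc, by = c("base", "atom"))
  if (nrow(dd) == 0 || nrow(aa) == 0) {
    return(tibble(
      donor_res = integer(), donor_base = character(),
      donor_atom = character(), h_atom = character(),
      acceptor_res = integer(), acceptor_base = character(),
      acceptor_atom = character(), distance = double(), angle = double()
    ))
  }
  H <- as.matrix(dd[, c("x", "y", "z")])
  D <- as.matrix(dd[, c("x_d", "y_d", "z_d")])
  A <- as.matrix(aa[, c("x", "y", "z")])
  d2 <- outer(rowSums(H^2), rowSums(A^2), `+`) - 2 * H %*% t(A)
  hits <- which(d2 <= d_max^2, arr.ind = TRUE)
  if (nrow(hits) > 0) {
    same <- dd$resid[hits[, 1]] == aa$resid[hits[, 2]]
    hits <- hits[!same, , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    return(tibble(
      donor_res = integer(), donor_base = character(),
      donor_atom = character(), h_atom = character(),
      acceptor_res = integer(), acceptor_base = character(),
      acceptor_atom = character(), distance = double(), angle = double()
    ))
  }
  hi <- hits[, 1]
  ai <- hits[, 2]
  v1 <- D[hi, , drop = FALSE] - H[hi, , drop = FALSE]
  v2 <- A[ai, , drop = FALSE] - H[hi, , drop = FALSE]
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  keep <- ang >= angle_min
  tibble(
    donor_res = dd$resid[hi], donor_base = dd$base[hi],
    donor_atom = dd$donor_atom[hi], h_atom = dd$atom[hi],
    acceptor_res = aa$resid[ai], acceptor_base = aa$base[ai],
    acceptor_atom = aa$atom[ai],
    distance = sqrt(pmax(0, d2[hits])), angle = ang
  )[keep, ] |> arrange(.data$donor_res, .data$acceptor_res)
}

#' Detect G-quartets from a hydrogen-bond list
#'
#' A quartet is a directed 4-cycle of distinct guanines in which each
#' guanine donates a Hoogsteen bond (N1-H1 to O6 and/or N2-H21 to N7) to
#' the next. Overlapping cycles are resolved by keeping the cycle with the
#' larger total bond count (ties by lexicographic residue order). Each
#' quartet is reported once, starting from its lowest residue index, with
#' the cycle direction chosen so the second element is the Hoogsteen
#' acceptor of the first.
#'
#' @param hbonds A hydrogen-bond tibble from [find_hbonds()].
#' @return A tibble with columns `quartet` (id) and `residues` (list of
#'   length-4 integer vectors in cycle order).
#' @export
detect_quartets <- function(hbonds) {
  hg <- hbonds[
    hbonds$donor_base == "G" & hbonds$acceptor_base == "G" &
      ((hbonds$h_atom == "H1" & hbonds$acceptor_atom == "O6") |
        (hbonds$h_atom == "H21" & hbonds$acceptor_atom == "N7")),
  ]
  if (nrow(hg) == 0) {
    return(tibble(quartet = integer(), residues = list()))
  }
  edges <- hg |>
    group_by(.data$donor_res, .data$acceptor_res) |>
    summarise(nb = n(), .groups = "drop")
  adj <- split(edges$acceptor_res, edges$donor_res)
  wt <- setNames(edges$nb, paste(edges$donor_res, edges$acceptor_res))
  nodes <- sort(unique(c(edges$donor_res, edges$acceptor_res)))
  found <- list()
  for (a in nodes) {
    for (b in adj[[as.character(a)]] %||% integer()) {
      if (b == a) next
      for (d in adj[[as.character(b)]] %||% integer()) {
        if (d %in% c(a, b)) next
        for (e in adj[[as.character(d)]] %||% integer()) {
          if (e %in% c(a, b, d)) next
          if (a %in% (adj[[as.character(e)]] %||% integer())) {
            cyc <- c(a, b, d, e)
            if (min(cyc) == a) {
              bonds <- sum(wt[paste(cyc, c(cyc[-1], cyc[1]))])
              found[[length(found) + 1]] <- list(cycle = cyc, bonds = bonds)
            }
          }
        }
      }
    }
  }
  if (length(found) == 0) {
    return(tibble(quartet = integer(), residues = list()))
  }
  # dedupe identical residue sets; then drop overlapping weaker cycles
  keyset <- vapply(found, function(f) paste(sort(f$cycle), collapse = "-"), "")
  found <- found[!duplicated(keyset)]
  ord <- order(
    -vapply(found, `[[`, 0, "bonds"),
    vapply(found, function(f) paste(f$cycle, collapse = "-"), "")
  )
  found <- found[ord]
  used <- integer()
  kept <- list()
  for (f in found) {
    if (length(intersect(f$cycle, used)) == 0) {
      kept[[length(kept) + 1]] <- f$cycle
      used <- c(used, f$cycle)
    }
  }
  kept <- kept[order(vapply(kept, min, 0))]
  tibble(quartet = seq_along(kept), residues = kept)
}

#' Detect Watson-Crick base pairs from a hydrogen-bond list
#'
#' G-C pairs are reported when at least 2 of the 3 canonical bonds
#' (O6...H41, N1-H1...N3, N2-H22...O2) are present; A-T pairs require both
#' canonical bonds (N6-H61...O4, N3-H3...N1).
#'
#' @param hbonds A hydrogen-bond tibble from [find_hbonds()].
#' @return A tibble with columns `res_i`, `res_j` (i < j), `bases`,
#'   `n_bonds`.
#' @export
detect_wc_pairs <- function(hbonds) {
  canon <- tibble(
    donor_base = c("G", "C", "G", "A", "T"),
    h_atom = c("H1", "H41", "H22", "H61", "H3"),
    acceptor_base = c("C", "G", "C", "T", "A"),
    acceptor_atom = c("N3", "O6", "O2", "O4", "N1")
  )
  wc <- dplyr::inner_join(hbonds, canon,
    by = c("donor_base", "h_atom", "acceptor_base", "acceptor_atom")
  )
  if (nrow(wc) == 0) {
    return(tibble(res_i = integer(), res_j = integer(), bases = character(), n_bonds = integer()))
  }
  wc$res_i <- pmin(wc$donor_res, wc$acceptor_res)
  wc$res_j <- pmax(wc$donor_res, wc$acceptor_res)
  pairs <- wc |>
    group_by(.data$res_i, .data$res_j) |>
    summarise(
      bases = paste(sort(c(.data$donor_base[1], .data$acceptor_base[1])), collapse = "-"),
      n_bonds = dplyr::n_distinct(paste(.data$h_atom, .data$acceptor_atom)),
      .groups = "drop"
    )
  need <- ifelse(pairs$bases == "C-G", 2L, 2L)
  pairs[pairs$n_bonds >= need, ]
}

#' Glycosidic torsion chi of each residue
#'
#' The dihedral O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for
#' pyrimidines, reported in [0, 360), together with its syn/anti class.
#'
#' @param structure A single-model structure tibble.
#' @param resid Optional residue subset.
#' @param syn_window Half-open syn window in degrees, default [0, 120).
#' @return A tibble with columns `resid`, `base`, `chi`, `class`.
#' @export
chi_torsion <- function(structure, resid = NULL, syn_window = c(0, 120)) {
  dna <- structure[!structure$ligand, ]
  ids <- resid %||% sort(unique(dna$resid))
  rows <- purrr::map(ids, function(i) {
    r <- dna[dna$resid == i, ]
    b <- r$base[1]
    gl <- .glyc_atom(b)
    ref <- if (b %in% c("G", "A")) "C4" else "C2"
    need <- c("O4'", "C1'", gl, ref)
    miss <- setdiff(need, r$atom)
    if (length(miss) > 0) {
      abort(sprintf(
        "residue %s%d lacks atom(s) %s needed for chi", b, i,
        paste(miss, collapse = ", ")
      ))
    }
    chi <- dihedral_angle(
      .tpl_at(r, "O4'"), .tpl_at(r, "C1'"), .tpl_at(r, gl), .tpl_at(r, ref)
    ) %% 360
    tibble(resid = i, base = b, chi = chi)
  })
  out <- bind_rows(rows)
  out$class <- classify_glycosidic(out$chi, syn_window)
  out
}

#' Classify a glycosidic torsion as syn or anti
#'
#' @param chi Torsion in degrees (any real; reduced mod 360).
#' @param syn_window Half-open window `[lo, hi)` classified as syn.
#' @return Character vector `"syn"`/`"anti"`.
#' @export
classify_glycosidic <- function(chi, syn_window = c(0, 120)) {
  chi <- chi %% 360
  ifelse(chi >= syn_window[1] & chi < syn_window[2], "syn", "anti")
}
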
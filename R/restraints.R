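# NMR-style restraint engineering: ISPA calibration of NOE volumes,
# distance-class binning, Hoogsteen / Watson-Crick hydrogen-bond
# restraints, glycosidic torsion restraints, planarity groups, and a flat
# text restraint-file format.

# fixed bound menus (angstroms) and default force constants (metadata only)
.noe_bounds <- list(
  noe_strong = c(1.8, 3.6), noe_medium = c(2.6, 5.0), noe_weak = c(3.5, 6.5)
)
.force_constants <- c(
  distance = 20, planarity = 20, hbond = 50, torsion = 200, chirality = 100
)

#' Calibrate NOE volumes to distances (isolated spin-pair approximation)
#'
#' Converts cross-peak volumes to distances as
#' `d = d_ref * (V_ref / V)^(1/6)`, with the reference volume taken as the
#' average over the cytosine H5-H6 rows (or an explicit subset) assigned to
#' the 2.45 angstrom reference distance. Non-positive volumes are rejected
#' and reported via the `rejected` attribute.
#'
#' @param peaks A tibble with columns `res_i`, `atom_i`, `res_j`, `atom_j`,
#'   `volume`, and optionally a logical `reference` column marking the
#'   reference rows (as written by [simulate_noe_table()]).
#' @param reference Optional logical/integer index of reference rows,
#'   overriding the `reference` column.
#' @param ref_distance Calibration distance in angstroms.
#' @return The peak tibble with a `distance` column (reference rows map to
#'   `ref_distance` exactly); rejected rows in `attr(, "rejected")`.
#' @export
calibrate_noe <- function(peaks, reference = NULL, ref_distance = 2.45) {
  peaks <- as_tibble(peaks)
  if (is.null(reference)) {
    if (!"reference" %in% names(peaks)) {
      reference <- peaks$res_i == peaks$res_j &
        purrr::map2_lgl(peaks$atom_i, peaks$atom_j, ~ setequal(c(.x, .y), c("H5", "H6")))
    } else {
      reference <- peaks$reference
    }
  }
  if (is.numeric(reference)) reference <- seq_len(nrow(peaks)) %in% reference
  if (!any(reference)) abort("no reference peak (cytosine H5-H6) found")
  bad <- !is.finite(peaks$volume) | peaks$volume <= 0
  rejected <- peaks[bad, ]
  peaks <- peaks[!bad, ]
  reference <- reference[!bad]
  v_ref <- mean(peaks$volume[reference])
  if (!is.finite(v_ref) || v_ref <= 0) abort("reference volume is not positive")
  peaks$distance <- ref_distance * (v_ref / peaks$volume)^(1 / 6)
  peaks$reference <- reference
  attr(peaks, "rejected") <- rejected
  peaks
}

#' Bin a calibrated distance into an NOE restraint class
#'
#' Distances are assigned to the strong / medium / weak classes by the
#' class thresholds (defaults: strong d <= 2.8, medium d <= 4.2, weak
#' d <= 6.0, beyond that rejected); each class carries its fixed bound
#' pair: strong (1.8, 3.6), medium (2.6, 5.0), weak (3.5, 6.5) angstroms.
#' The thresholds sit inside the overlap regions of the class bounds and
#' are configurable; the bounds themselves are fixed.
#'
#' @param distance Numeric vector of calibrated distances (angstroms).
#' @param thresholds Named numeric `c(strong =, medium =, weak =)` class
#'   upper limits.
#' @return A tibble with `distance`, `category`, `lower`, `upper`
#'   (`NA` category for rejected distances beyond the weak threshold).
#' @export
classify_noe <- function(distance,
                         thresholds = c(strong = 2.8, medium = 4.2, weak = 6.0)) {
  stopifnot(all(distance > 0))
  cls <- dplyr::case_when(
    distance <= thresholds["strong"] ~ "noe_strong",
    distance <= thresholds["medium"] ~ "noe_medium",
    distance <= thresholds["weak"] ~ "noe_weak",
    TRUE ~ NA_character_
  )
  lo <- vapply(cls, function(k) if (is.na(k)) NA_real_ else .noe_bounds[[k]][1], 0)
  up <- vapply(cls, function(k) if (is.na(k)) NA_real_ else .noe_bounds[[k]][2], 0)
  tibble(distance = distance, category = cls, lower = unname(lo), upper = unname(up))
}

.restraint_row <- function(category, res_i, atom_i, res_j, atom_j,
                           lower, upper, fc) {
  tibble(
    type = "distance", category = category,
    res_i = as.integer(res_i), atom_i = atom_i,
    res_j = as.integer(res_j), atom_j = atom_j,
    lower = lower, upper = upper,
    center = NA_real_, width = NA_real_,
    force_constant = fc
  )
}

#' Hoogsteen hydrogen-bond restraints for G-quartets
#'
#' For each cyclic donor-to-acceptor edge of each quartet, two distance
#' restraints are emitted: acceptor N7 to donor H21 with bounds
#' (1.9, 2.1) and acceptor O6 to donor H1 with bounds (1.7, 1.9)
#' angstroms - eight per quartet.
#'
#' @param quartets A list of length-4 integer vectors in Hoogsteen-cycle
#'   order, or the tibble returned by [detect_quartets()], or a
#'   `qdh_topology`.
#' @param sequence Optional character vector of bases used to verify that
#'   every quartet member is guanine.
#' @return A restraint tibble (8 rows per quartet).
#' @export
hoogsteen_restraints <- function(quartets, sequence = NULL) {
  quartets <- .as_quartet_list(quartets, env = environment())
  rows <- purrr::map(quartets, function(q) {
    if (!is.null(sequence) && any(sequence[q] != "G")) {
      abort(sprintf(
        "quartet (%s) contains a non-guanine residue",
        paste(q, collapse = ",")
      ))
    }
    donor <- q
    acceptor <- c(q[-1], q[1])
    bind_rows(
      .restraint_row("hoogsteen_N7H21", acceptor, "N7", donor, "H21",
        1.9, 2.1, .force_constants[["hbond"]]),
      .restraint_row("hoogsteen_O6H1", acceptor, "O6", donor, "H1",
        1.7, 1.9, .force_constants[["hbond"]])
    )
  })
  bind_rows(rows)
}

# accept a qdh_topology, a detect_quartets() tibble, or a bare list
.as_quartet_list <- function(quartets, env = NULL) {
  if (inherits(quartets, "qdh_topology")) {
    if (!is.null(env) && is.null(env$sequence)) env$sequence <- quartets$sequence
    return(quartets$quartets)
  }
  if (is.data.frame(quartets)) {
    return(quartets$residues)
  }
  quartets
}

#' Watson-Crick hydrogen-bond restraints for G-C pairs
#'
#' Three distance restraints per G-C pair (acceptor-donor pairs O2-H22,
#' N3-H1, O6-H41), all with bounds (1.8, 2.0) angstroms. A-T pairs are not
#' supported and raise an error (no bounds are defined for them here).
#'
#' @param pairs A list of integer pairs, or the tibble returned by
#'   [detect_wc_pairs()], or a `qdh_topology`.
#' @param sequence Character vector of bases (required to orient G vs C
#'   unless `pairs` is a topology).
#' @return A restraint tibble (3 rows per pair).
#' @export
wc_restraints <- function(pairs, sequence = NULL) {
  if (inherits(pairs, "qdh_topology")) {
    sequence <- pairs$sequence
    pairs <- pairs$wc_pairs
  } else if (is.data.frame(pairs)) {
    pairs <- purrr::map2(pairs$res_i, pairs$res_j, c)
  }
  if (is.null(sequence)) abort("sequence is required to orient G vs C in each pair")
  rows <- purrr::map(pairs, function(p) {
    b <- sequence[p]
    if (setequal(b, c("A", "T"))) {
      abort(sprintf(
        "pair %d-%d is A-T: no A-T restraint bounds are defined; only G-C pairs are supported",
        p[1], p[2]
      ))
    }
    if (!setequal(b, c("G", "C"))) {
      abort(sprintf("pair %d-%d is not a G-C pair", p[1], p[2]))
    }
    g <- p[b == "G"]
    c_ <- p[b == "C"]
    bind_rows(
      .restraint_row("wc", c_, "O2", g, "H22", 1.8, 2.0, .force_constants[["hbond"]]),
      .restraint_row("wc", c_, "N3", g, "H1", 1.8, 2.0, .force_constants[["hbond"]]),
      .restraint_row("wc", g, "O6", c_, "H41", 1.8, 2.0, .force_constants[["hbond"]])
    )
  })
  bind_rows(rows)
}

#' Glycosidic torsion restraints for a topology
#'
#' Exactly one chi restraint per residue of the sequence: syn-set members
#' get 60 +/- 35 degrees; anti purines (G, A) get 240 +/- 40; anti
#' pyrimidines (C, T) get 240 +/- 70.
#'
#' @param topology A `qdh_topology`.
#' @return A torsion restraint tibble (one row per residue).
#' @export
torsion_restraints <- function(topology) {
  stopifnot(inherits(topology, "qdh_topology"))
  n <- length(topology$sequence)
  if (n == 0) {
    return(tibble(
      type = character(), category = character(), res_i = integer(),
      atom_i = character(), res_j = integer(), atom_j = character(),
      lower = double(), upper = double(), center = double(),
      width = double(), force_constant = double()
    ))
  }
  base <- topology$sequence
  is_syn <- seq_len(n) %in% topology$syn_set
  center <- ifelse(is_syn, 60, 240)
  width <- ifelse(is_syn, 35, ifelse(base %in% c("G", "A"), 40, 70))
  tibble(
    type = "torsion",
    category = ifelse(is_syn, "chi_syn", "chi_anti"),
    res_i = seq_len(n), atom_i = "chi",
    res_j = NA_integer_, atom_j = NA_character_,
    lower = NA_real_, upper = NA_real_,
    center = center, width = width,
    force_constant = .force_constants[["torsion"]]
  )
}

#' Planarity restraint groups for quartets and pairs
#'
#' The default scheme emits three atom groups per quartet guanine (12 per
#' quartet) and three per Watson-Crick pair, which reproduces the usual
#' 36 + 9 bookkeeping for a three-quartet, three-pair fold. The scheme is
#' one documented choice among several; counts are reported, not asserted.
#'
#' @param quartets List of quartets (as in [hoogsteen_restraints()]).
#' @param pairs List of pairs (as in [wc_restraints()]).
#' @param groups_per_guanine,groups_per_pair Scheme knobs.
#' @return A tibble with one row per planarity group: `plane_id`,
#'   `category`, `res_i`, `group`.
#' @export
planarity_restraints <- function(quartets = list(), pairs = list(),
                                 groups_per_guanine = 3, groups_per_pair = 3) {
  quartets <- .as_quartet_list(quartets)
  if (is.data.frame(pairs)) pairs <- purrr::map2(pairs$res_i, pairs$res_j, c)
  rows <- list()
  for (qi in seq_along(quartets)) {
    for (r in quartets[[qi]]) {
      for (g in seq_len(groups_per_guanine)) {
        rows[[length(rows) + 1]] <- tibble(
          plane_id = sprintf("quartet_%d", qi), category = "quartet_plane",
          res_i = as.integer(r), group = as.integer(g)
        )
      }
    }
  }
  for (pi_ in seq_along(pairs)) {
    for (g in seq_len(groups_per_pair)) {
      rows[[length(rows) + 1]] <- tibble(
        plane_id = sprintf("pair_%d", pi_), category = "pair_plane",
        res_i = as.integer(pairs[[pi_]][1]), group = as.integer(g)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      plane_id = character(), category = character(),
      res_i = integer(), group = integer()
    ))
  }
  bind_rows(rows)
}

#' Assemble the full restraint set for a topology
#'
#' Concatenates calibrated and classified NOE distance restraints (if a
#' peak table is given) with the Hoogsteen, Watson-Crick, torsion and
#' planarity categories generated from the topology. The hydrogen-bond
#' count is 8 per quartet plus 3 per G-C pair by construction.
#'
#' @param topology A `qdh_topology`.
#' @param noe_table Optional NOE peak tibble (see [calibrate_noe()]);
#'   reference rows are used for calibration, not emitted as restraints.
#' @return A list of class `qdh_restraint_set` with elements `distance`
#'   (tibble), `torsion` (tibble), `planarity` (tibble) and `counts`
#'   (named integer vector, including `hbond` and `noe` totals).
#' @export
build_restraint_set <- function(topology, noe_table = NULL) {
  stopifnot(inherits(topology, "qdh_topology"))
  hb <- bind_rows(
    hoogsteen_restraints(topology$quartets, sequence = topology$sequence),
    wc_restraints(topology)
  )
  noe <- NULL
  if (!is.null(noe_table) && nrow(noe_table) > 0) {
    cal <- calibrate_noe(noe_table)
    cal <- cal[!cal$reference, , drop = FALSE]
    if (nrow(cal) > 0) {
      cls <- classify_noe(cal$distance)
      keep <- !is.na(cls$category)
      noe <- .restraint_row(
        cls$category[keep], cal$res_i[keep], cal$atom_i[keep],
        cal$res_j[keep], cal$atom_j[keep],
        cls$lower[keep], cls$upper[keep], .force_constants[["distance"]]
      )
    }
  }
  dist <- bind_rows(noe, hb)
  tor <- torsion_restraints(topology)
  pla <- planarity_restraints(topology$quartets, topology$wc_pairs)
  counts <- c(
    noe = if (is.null(noe)) 0L else nrow(noe),
    hoogsteen = sum(grepl("^hoogsteen", hb$category)),
    wc = sum(hb$category == "wc"),
    hbond = nrow(hb),
    torsion = nrow(tor),
    planarity = nrow(pla)
  )
  structure(
    list(distance = dist, torsion = tor, planarity = pla, counts = counts),
    class = "qdh_restraint_set"
  )
}

#' @export
print.qdh_restraint_set <- function(x, ...) {
  cat("<qdh_restraint_set>\n")
  for (k in names(x$counts)) cat(sprintf("  %-10s %d\n", k, x$counts[[k]]))
  invisible(x)
}

#' Write a restraint set as flat text
#'
#' One record per line (tab-separated): type, category, residue/atom pair
#' or angle spec, bounds or center/width, and the force-constant metadata,
#' in stable (type, category, residue) order, under a versioned header.
#'
#' @param set A `qdh_restraint_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(set, path) {
  stopifnot(inherits(set, "qdh_restraint_set"))
  pla <- set$planarity
  pla_rows <- if (nrow(pla) > 0) {
    tibble(
      type = "planarity", category = pla$category, res_i = pla$res_i,
      atom_i = pla$plane_id, res_j = NA_integer_,
      atom_j = as.character(pla$group),
      lower = NA_real_, upper = NA_real_, center = NA_real_, width = NA_real_,
      force_constant = .force_constants[["planarity"]]
    )
  } else {
    NULL
  }
  all <- bind_rows(set$distance, set$torsion, pla_rows)
  all <- all[order(all$type, all$category, all$res_i, all$res_j), ]
  hdr <- c(
    "# qdhkit restraint file v1",
    sprintf("# counts: %s", paste(sprintf("%s=%d", names(set$counts), set$counts), collapse = " "))
  )
  writeLines(hdr, path)
  readr::write_tsv(all, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a flat-text restraint file back into a restraint set
#'
#' @param path A file written by [write_restraints()].
#' @return A `qdh_restraint_set`.
#' @export
read_restraints <- function(path) {
  all <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      type = "c", category = "c", res_i = "i", atom_i = "c",
      res_j = "i", atom_j = "c", lower = "d", upper = "d",
      center = "d", width = "d", force_constant = "d"
    )
  )
  dist <- all[all$type == "distance", ]
  tor <- all[all$type == "torsion", ]
  plr <- all[all$type == "planarity", ]
  pla <- tibble(
    plane_id = plr$atom_i, category = plr$category,
    res_i = plr$res_i, group = as.integer(plr$atom_j)
  )
  counts <- c(
    noe = sum(grepl("^noe", dist$category)),
    hoogsteen = sum(grepl("^hoogsteen", dist$category)),
    wc = sum(dist$category == "wc"),
    hbond = sum(grepl("^hoogsteen", dist$category) | dist$category == "wc"),
    torsion = nrow(tor),
    planarity = nrow(pla)
  )
  structure(
    list(distance = dist, torsion = tor, planarity = pla, counts = counts),
    class = "qdh_restraint_set"
  )
}
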
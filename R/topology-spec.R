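# Declarative fold descriptions (sequence, quartets, Watson-Crick pairs,
# syn set, loops) and ligand moiety maps.

.valid_bases <- c("A", "C", "G", "T")

#' Declare a quadruplex-duplex hybrid topology
#'
#' A declarative description of a QDH fold: the sequence, the G-quartets in
#' Hoogsteen-cycle order, the Watson-Crick pairs of the duplex stem-loop,
#' the residues in syn glycosidic conformation, and the loop/overhang
#' segments. Residue numbering is 1-based along the 5'-3' sequence.
#'
#' @param sequence A single string of A/C/G/T, 5' to 3'.
#' @param quartets List of integer vectors of length 4 (guanine indices in
#'   Hoogsteen-cycle order: each residue donates to the next).
#' @param wc_pairs List of integer pairs; order is the stacking order
#'   starting from the quartet-adjacent pair.
#' @param syn_set Integer vector of residues built/restrained syn.
#' @param loops Named list of integer vectors (loop segments); decorative.
#' @param overhang Integer vector (5' overhang residues).
#' @param junction_quartet Index into `quartets` of the quartet that abuts
#'   the duplex (default: the last one).
#' @param cv_flank The two duplex-adjacent quartet guanines whose C2'/O4'
#'   atoms define point P1 of the angular-position CV.
#' @param modified Integer vector of residues carrying a sugar modification
#'   (e.g. 2'-F-arabino reporter substitutions); a flag only.
#' @return An object of class `qdh_topology`.
#' @export
qdh_topology <- function(sequence, quartets, wc_pairs = list(),
                         syn_set = integer(), loops = list(),
                         overhang = integer(),
                         junction_quartet = length(quartets),
                         cv_flank = NULL, modified = integer()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq_vec <- strsplit(toupper(sequence), "")[[1]]
  if (!all(seq_vec %in% .valid_bases)) {
    abort("sequence may contain only A, C, G, T")
  }
  n <- length(seq_vec)
  quartets <- lapply(quartets, as.integer)
  wc_pairs <- lapply(wc_pairs, as.integer)
  syn_set <- as.integer(syn_set)
  for (q in quartets) {
    if (length(q) != 4 || anyDuplicated(q)) {
      abort("each quartet must list 4 distinct residue indices")
    }
    if (any(q < 1 | q > n)) abort("quartet residue index out of range")
    if (any(seq_vec[q] != "G")) {
      abort(sprintf(
        "quartet (%s) contains a non-guanine residue",
        paste(q, collapse = ",")
      ))
    }
  }
  for (p in wc_pairs) {
    if (length(p) != 2 || p[1] == p[2]) abort("each wc pair needs 2 distinct indices")
    b <- sort(seq_vec[p])
    if (!identical(b, c("C", "G")) && !identical(b, c("A", "T"))) {
      abort(sprintf("pair %s-%s is not Watson-Crick complementary", p[1], p[2]))
    }
  }
  if (any(syn_set < 1 | syn_set > n)) abort("syn_set residue does not exist")
  core <- c(unlist(quartets), unlist(wc_pairs))
  rest <- setdiff(seq_len(n), core)
  declared <- c(unlist(loops), overhang)
  if (length(declared) > 0 && !setequal(declared, rest)) {
    abort("loops + overhang must partition the non-quartet, non-pair residues")
  }
  structure(
    list(
      sequence = seq_vec, quartets = quartets, wc_pairs = wc_pairs,
      syn_set = syn_set, loops = loops, overhang = overhang,
      junction_quartet = as.integer(junction_quartet),
      cv_flank = if (is.null(cv_flank)) NULL else as.integer(cv_flank),
      modified = as.integer(modified)
    ),
    class = "qdh_topology"
  )
}

#' @export
print.qdh_topology <- function(x, ...) {
  cat("<qdh_topology> ", paste(x$sequence, collapse = ""), "\n", sep = "")
  cat(sprintf(
    "  %d nt, %d quartet(s), %d WC pair(s), %d syn residue(s)\n",
    length(x$sequence), length(x$quartets), length(x$wc_pairs), length(x$syn_set)
  ))
  for (q in x$quartets) cat("  quartet:", paste0("G", q, collapse = " . "), "\n")
  for (p in x$wc_pairs) {
    cat("  pair:   ", paste0(x$sequence[p], p, collapse = "-"), "\n")
  }
  invisible(x)
}

#' The hybrid-1 QDH topology of the PIM1 promoter sequence SO7
#'
#' The three-quartet hybrid fold of the 27-nt PIM1 promoter sequence
#' GCGGGAGGGCGCGCCAGCGGGGTCGGG: quartets G3.G25.G22.G7, G4.G8.G21.G26 and
#' G5.G9.G20.G27 (5' to 3' stack order, the last abutting the duplex),
#' Watson-Crick pairs G19-C10, G11-C18 and G17-C12 in the stem-loop, a
#' single-nucleotide propeller loop (A6), a two-nucleotide lateral loop
#' (T23, C24), a stem-capping tetraloop (G13-A16), and a 5' G1-C2 overhang.
#'
#' Two syn-set variants are in circulation for this fold; they differ in one
#' residue (G25 vs G27). Both are provided; neither is privileged by the
#' package.
#'
#' @param syn_variant `"g25"` (G1, G3, G7, G20, G21, G25; default) or
#'   `"g27"` (G1, G3, G7, G20, G21, G27).
#' @return A `qdh_topology` object.
#' @export
so7_topology <- function(syn_variant = c("g25", "g27")) {
  syn_variant <- match.arg(syn_variant)
  syn <- if (syn_variant == "g25") {
    c(1L, 3L, 7L, 20L, 21L, 25L)
  } else {
    c(1L, 3L, 7L, 20L, 21L, 27L)
  }
  qdh_topology(
    sequence = "GCGGGAGGGCGCGCCAGCGGGGTCGGG",
    quartets = list(c(3, 25, 22, 7), c(4, 8, 21, 26), c(5, 9, 20, 27)),
    wc_pairs = list(c(19, 10), c(11, 18), c(17, 12)),
    syn_set = syn,
    loops = list(propeller = 6L, tetraloop = 13:16, lateral = c(23L, 24L)),
    overhang = 1:2,
    junction_quartet = 3L,
    cv_flank = c(9L, 20L)
  )
}

# ---- ligand moiety maps ----------------------------------------------------

#' Ligand moiety map
#'
#' Maps a ligand's aromatic moieties I, II and III to atom names, marking
#' the three atoms per moiety that enter the angular-position CV (nine CV
#' atoms in total; moiety I is the middle ring). Maps are read from the
#' packaged alias table `inst/extdata/ligand_atom_map.tsv`, which users can
#' extend to match deposited atom naming.
#'
#' The `"SYN"` map describes the package's synthetic planar three-moiety
#' ligand (atoms I1..I3, II1..II3, III1..III3) used by [place_ligand()].
#'
#' @param name Ligand name: `"SYN"` (synthetic), `"PDC"` (Phen-DC3 alias)
#'   or `"36A"` (360A alias).
#' @param table Optional path to an alternative alias table.
#' @return A tibble with columns `ligand`, `moiety`, `label`, `atom`, `cv`.
#' @export
ligand_moiety_map <- function(name = "SYN", table = NULL) {
  path <- table %||% system.file("extdata", "ligand_atom_map.tsv", package = "qdhkit")
  map <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  map <- map[map$ligand == name, ]
  if (nrow(map) == 0) abort(sprintf("no ligand named '%s' in the alias table", name))
  if (any(is.na(map$atom))) {
    abort(sprintf(
      "ligand '%s' has unmapped atoms in the alias table; edit %s to supply deposited atom names",
      name, path
    ))
  }
  cvn <- table(map$moiety[map$cv])
  if (!all(cvn == 3) || length(cvn) != 3) {
    abort("each moiety (I, II, III) must contribute exactly 3 CV atoms")
  }
  as_tibble(map)
}
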
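# The coordinate container: a tidy atom table (one row per atom, one model
# per `model` value) plus PDB reading/writing and atom selection.

.ligand_aliases <- c("PDC", "36A", "LIG", "SYN")

# normalize unicode primes in atom names; idempotent
.normalize_atom <- function(x) {
  gsub("′", "'", x, fixed = TRUE)
}

.new_structure <- function(df, topology = NULL, ligand_map = NULL) {
  df <- as_tibble(df)
  need <- c("model", "resid", "base", "atom", "element", "x", "y", "z", "ligand")
  stopifnot(all(need %in% names(df)))
  df$atom <- .normalize_atom(df$atom)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("non-finite coordinates in structure")
  }
  out <- structure(df, class = c("qdh_structure", class(tibble())))
  attr(out, "topology") <- topology
  attr(out, "ligand_map") <- ligand_map
  out
}

#' Number of models in a structure table
#' @param structure A structure tibble.
#' @return Integer count of distinct model numbers.
#' @export
n_models <- function(structure) length(unique(structure$model))

#' Extract one model from a multi-model structure
#' @param structure A structure tibble.
#' @param model Model number to keep.
#' @return A single-model structure tibble (attributes preserved).
#' @export
get_model <- function(structure, model) {
  out <- structure[structure$model == model, ]
  attributes(out)[c("topology", "ligand_map")] <-
    attributes(structure)[c("topology", "ligand_map")]
  out
}

# ---- PDB I/O ---------------------------------------------------------------

.base_from_resname <- function(resname) {
  up <- toupper(trimws(resname))
  map <- c(
    DG = "G", DC = "C", DA = "A", DT = "T",
    G = "G", C = "C", A = "A", T = "T", U = "T"
  )
  unname(map[up])
}

#' Read a (multi-model) PDB file into a structure table
#'
#' Reads fixed-column PDB text via \pkg{bio3d} and returns a tidy atom table
#' with one row per atom and model. Residues are renumbered 1-based along
#' the chain (5' to 3' file order); original author numbering is kept in
#' the `resid_author` column. HETATM records whose residue name matches a
#' known ligand alias are flagged `ligand = TRUE`; water is skipped.
#' Alternate locations other than blank/"A" are dropped with a warning.
#'
#' @param path Path to a PDB v3.3 file.
#' @param model_filter Optional integer vector of model numbers to keep.
#' @param ligand_aliases Residue names treated as ligands.
#' @return A structure tibble with columns `model`, `resid`, `resid_author`,
#'   `base`, `atom`, `element`, `x`, `y`, `z`, `ligand`.
#' @export
read_pdb <- function(path, model_filter = NULL,
                     ligand_aliases = .ligand_aliases) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) abort(sprintf("no ATOM/HETATM records in %s", path))
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad) > 0) {
    abort(sprintf("malformed ATOM record at line %d of %s", bad[1], path))
  }
  co <- suppressWarnings(cbind(
    as.numeric(substr(lines[rec], 31, 38)),
    as.numeric(substr(lines[rec], 39, 46)),
    as.numeric(substr(lines[rec], 47, 54))
  ))
  if (any(!is.finite(co))) {
    off <- which(rec)[which(!stats::complete.cases(co))[1]]
    abort(sprintf("malformed coordinates at line %d of %s", off, path))
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  nmod <- nrow(p$xyz)
  alt_bad <- !(is.na(at$alt) | at$alt %in% c("", "A"))
  if (any(alt_bad)) {
    warn(sprintf("dropping %d atoms with altloc other than blank/'A'", sum(alt_bad)))
  }
  keep0 <- !alt_bad & !(toupper(at$resid) %in% c("HOH", "WAT"))
  base <- .base_from_resname(at$resid)
  is_lig <- toupper(at$resid) %in% toupper(ligand_aliases)
  keep <- keep0 & (!is.na(base) | is_lig)
  # sequential residue numbering per chain, file order
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  models <- seq_len(nmod)
  if (!is.null(model_filter)) models <- intersect(models, model_filter)
  if (length(models) == 0) abort("model_filter removed every model")
  rows <- purrr::map(models, function(m) {
    xyz <- matrix(p$xyz[m, ], ncol = 3, byrow = TRUE)
    d <- tibble(
      model = m,
      chain = at$chain,
      resid_author = at$resno,
      key = key,
      base = base,
      atom = .normalize_atom(at$elety),
      element = ifelse(is.na(at$elesy) | at$elesy == "",
        substr(trimws(at$elety), 1, 1), trimws(at$elesy)
      ),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      ligand = is_lig
    )[keep, ]
    d$resid <- match(d$key, unique(d$key))
    d$base <- ifelse(d$ligand, toupper(at$resid[keep]), d$base)
    d
  })
  df <- bind_rows(rows)
  df <- select(df, "model", "resid", "resid_author", "base", "atom",
    "element", "x", "y", "z", "ligand")
  .new_structure(df)
}

#' Write a structure table as (multi-model) PDB
#'
#' Emits fixed-width PDB v3.3 records through \pkg{bio3d}, one MODEL block
#' per model number (a single implicit model when `model_cards = FALSE` and
#' only one model is present), coordinates to 3 decimals.
#'
#' @param structure A structure tibble.
#' @param path Output file path.
#' @param model_cards Write MODEL/ENDMDL cards even for a single model.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, model_cards = NULL) {
  if (nrow(structure) == 0) abort("write_pdb(): empty structure")
  models <- sort(unique(structure$model))
  m1 <- structure[structure$model == models[1], ]
  xyz <- do.call(rbind, lapply(models, function(m) {
    as.numeric(t(.xyz(structure[structure$model == m, ])))
  }))
  resname <- ifelse(m1$ligand, m1$base, paste0("D", m1$base))
  multi <- if (is.null(model_cards)) length(models) > 1 else model_cards
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = ifelse(m1$ligand, "HETATM", "ATOM"),
    resno = m1$resid,
    resid = resname,
    elety = m1$atom,
    elesy = m1$element,
    chain = "A"
  )
  if (!multi && length(models) == 1) {
    ln <- readLines(path)
    writeLines(ln[!grepl("^(MODEL|ENDMDL)", ln)], path)
  }
  invisible(path)
}

# ---- atom selection --------------------------------------------------------

#' Select atoms with a compact residue:atom expression
#'
#' The selection mini-language is a semicolon-separated list of
#' `RES:atom,atom,...` groups, e.g. `"G9:C2',O4'; G20:C2',O4'"`. The
#' residue token is a base letter plus the 1-based sequence index (the
#' letter is checked against the structure) or a bare index. Atoms are
#' returned in specification order.
#'
#' @param structure A single-model structure tibble.
#' @param spec Selection string.
#' @return A structure tibble of the selected atoms, in spec order.
#' @export
select_atoms <- function(structure, spec) {
  if (n_models(structure) > 1) abort("select_atoms() expects a single model")
  groups <- strsplit(spec, ";")[[1]]
  out <- list()
  for (g in trimws(groups)) {
    if (g == "") next
    parts <- strsplit(g, ":")[[1]]
    if (length(parts) != 2) abort(sprintf("cannot parse selection group '%s'", g))
    rtok <- trimws(parts[1])
    m <- regmatches(rtok, regexec("^([ACGT]?)([0-9]+)$", rtok))[[1]]
    if (length(m) == 0) abort(sprintf("cannot parse residue token '%s'", rtok))
    idx <- as.integer(m[3])
    rres <- structure[structure$resid == idx & !structure$ligand, ]
    if (nrow(rres) == 0) abort(sprintf("unknown residue index %d in selection", idx))
    if (m[2] != "" && rres$base[1] != m[2]) {
      abort(sprintf("residue %d is %s, not %s", idx, rres$base[1], m[2]))
    }
    atoms <- .normalize_atom(trimws(strsplit(parts[2], ",")[[1]]))
    miss <- setdiff(atoms, rres$atom)
    if (length(miss) > 0) {
      abort(sprintf(
        "residue %s%d lacks atom(s): %s", rres$base[1], idx,
        paste(miss, collapse = ", ")
      ))
    }
    out[[length(out) + 1]] <- rres[match(atoms, rres$atom), ]
  }
  bind_rows(out)
}
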
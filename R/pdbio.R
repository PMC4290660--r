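#' Atomic structures as tibbles
#'
#' A structure is a tibble with one row per atom and columns
#' `serial`, `atom` (PDB atom name, e.g. `"CA"`), `element`, `res_name`
#' (3-letter code), `chain`, `res_seq`, `ins` (insertion code, `""` if none),
#' `res_idx` (ordinal residue index, 1-based), `x`, `y`, `z` (Angstrom),
#' `occ` and `b`. The structure id is carried in the `"id"` attribute.
#'
#' @param atoms A data frame with the columns above except `res_idx`,
#'   which is recomputed from the (chain, res_seq, ins) triples in order.
#' @param id Structure identifier string.
#' @return A tibble of class `decoy_structure`.
#' @export
as_structure <- function(atoms, id = "structure") {
  atoms <- as_tibble(atoms)
  need <- c("serial", "atom", "element", "res_name", "chain", "res_seq",
            "ins", "x", "y", "z", "occ", "b")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("a structure must contain at least one residue")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  # a new residue starts whenever the (chain, res_seq, ins) key changes
  key <- paste(atoms$chain, atoms$res_seq, atoms$ins, sep = "\r")
  atoms$res_idx <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  if (anyDuplicated(key[!duplicated(atoms$res_idx)])) {
    abort("residue identifiers (chain, seq_number, insertion) must be unique")
  }
  attr(atoms, "id") <- id
  class(atoms) <- c("decoy_structure", class(tibble()))
  atoms
}

#' @export
print.decoy_structure <- function(x, ...) {
  cat("<structure ", structure_id(x), ": ", n_residues(x), " residues, ",
      nrow(x), " atoms>\n", sep = "")
  NextMethod()
}

#' Structure accessors
#'
#' @param structure A structure tibble (see [as_structure()]).
#' @return `structure_id()` the id string; `n_residues()` the residue count;
#'   `residue_table()` a one-row-per-residue tibble; `ca_coords()` an
#'   M x 3 matrix of C-alpha coordinates in residue order.
#' @export
structure_id <- function(structure) {
  id <- attr(structure, "id", exact = TRUE)
  if (is.null(id)) "structure" else id
}

#' @rdname structure_id
#' @export
n_residues <- function(structure) {
  if (nrow(structure) == 0) return(0L)
  max(structure$res_idx)
}

#' @rdname structure_id
#' @export
residue_table <- function(structure) {
  structure |>
    dplyr::distinct(.data$res_idx, .keep_all = TRUE) |>
    dplyr::select("res_idx", "chain", "res_seq", "ins", "res_name")
}

#' @rdname structure_id
#' @export
ca_coords <- function(structure) {
  ca <- structure[structure$atom == "CA" & structure$element == "C", ]
  ca <- ca[!duplicated(ca$res_idx), ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$res_idx
  m
}

coords_matrix <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

aa_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

aa_123 <- setNames(names(aa_321), unname(aa_321))

#' One-letter sequence of a structure
#'
#' One letter per residue in chain order; residues outside the 20 standard
#' amino acids (e.g. MSE) map to `"X"`.
#'
#' @param structure A structure tibble.
#' @return A single string.
#' @export
extract_sequence <- function(structure) {
  res <- residue_table(structure)
  letters1 <- unname(aa_321[res$res_name])
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

# van der Waals radii (Angstrom); hydrogens are ignored by SASA by default
# since decoy sets are typically heavy-atom only.
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

#' Per-atom radius and polarity annotation
#'
#' Radii come from a fixed van der Waals table (C 1.70, N 1.55, O 1.52,
#' S 1.80, H 1.20 Angstrom). Carbon and sulfur atoms are nonpolar; nitrogen
#' and oxygen are polar (hydrogens are tagged nonpolar but excluded from
#' surface calculations by default).
#'
#' @param structure A structure tibble.
#' @return The structure with `radius` and `polarity` columns appended.
#' @export
classify_atoms <- function(structure) {
  el <- structure$element
  unknown <- !(el %in% names(vdw_radii))
  if (any(unknown)) {
    i <- which(unknown)[1]
    abort(paste0("unknown element '", el[i], "' for atom ",
                 structure$atom[i], " (serial ", structure$serial[i], ")"))
  }
  structure$radius <- unname(vdw_radii[el])
  structure$polarity <- ifelse(el %in% c("N", "O"), "polar", "nonpolar")
  structure
}

infer_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z0-9]", "", atom_name)
  # names starting with a digit (1HB, 2HG...) are hydrogens
  first_digit <- grepl("^[0-9]", nm)
  nm <- gsub("[0-9]", "", nm)
  el <- toupper(substr(nm, 1, 1))
  el[first_digit] <- "H"
  el
}

validate_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_lines) == 0) {
    abort(paste0("no ATOM records found in '", path, "'"))
  }
  for (i in atom_lines) {
    ln <- lines[i]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      abort(paste0("malformed coordinate columns at line ", i,
                   " of '", path, "'"))
    }
  }
  invisible(TRUE)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (HETATM and waters are skipped), resolves alternate
#' locations by highest occupancy with alphabetic tie-break, and infers
#' elements from atom names when the element column is blank.
#'
#' @param path Path to a PDB file.
#' @param model_index Which MODEL to return for multi-model files
#'   (default: the first).
#' @param id Structure id; defaults to the file stem.
#' @return A structure tibble.
#' @export
read_structure <- function(path, model_index = NULL, id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: '", path, "'"))
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)

  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  n_models <- nrow(pdb$xyz)
  if (is.null(model_index)) model_index <- 1L
  if (model_index < 1 || model_index > n_models) {
    abort(paste0("model_index ", model_index, " out of range (file has ",
                 n_models, " model(s))"))
  }
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  keep <- at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) abort(paste0("no protein ATOM records in '", path, "'"))

  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- "A"
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0

  # altloc: highest occupancy wins, ties broken alphabetically
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(akey)) {
    ord <- order(akey, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(akey[ord]), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }

  el <- at$elesy
  blank <- is.na(el) | el == ""
  el[blank] <- infer_element(at$elety[blank])
  el <- toupper(trimws(el))

  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  as_structure(
    tibble(serial = at$eleno, atom = trimws(at$elety), element = el,
           res_name = at$resid, chain = at$chain, res_seq = at$resno,
           ins = at$insert, x = at$x, y = at$y, z = at$z,
           occ = at$o, b = at$b),
    id = id
  )
}

n_models_in_file <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  nrow(pdb$xyz)
}

#' Build a decoy pool from structures
#'
#' A pool is a tibble with columns `id` and `structure` (a list-column of
#' structure tibbles); all members must share one sequence and residue
#' count. The shared 1-letter sequence is carried in the `"sequence"`
#' attribute. Provenance columns (e.g. `noise_sigma`, `true_ca_rmsd`) may
#' be present.
#'
#' @param structures A list of structure tibbles.
#' @param ids Unique member ids; default taken from each structure's id.
#' @return A pool tibble of class `decoy_pool`.
#' @export
as_pool <- function(structures, ids = NULL) {
  if (length(structures) == 0) abort("a pool needs at least one structure")
  if (is.null(ids)) ids <- vapply(structures, structure_id, character(1))
  if (anyDuplicated(ids)) abort("pool ids must be unique")
  seqs <- vapply(structures, extract_sequence, character(1))
  if (length(unique(seqs)) > 1) {
    bad <- ids[seqs != seqs[1]]
    abort(paste0("pool members do not share one sequence; offending ids: ",
                 paste(bad, collapse = ", ")))
  }
  pool <- tibble(id = ids, structure = structures)
  attr(pool, "sequence") <- seqs[1]
  class(pool) <- c("decoy_pool", class(tibble()))
  pool
}

#' @rdname as_pool
#' @param pool A pool tibble.
#' @export
pool_sequence <- function(pool) {
  s <- attr(pool, "sequence", exact = TRUE)
  if (is.null(s)) extract_sequence(pool$structure[[1]]) else s
}

#' Read a decoy pool
#'
#' Accepts either a directory of PDB files (ids are file stems) or a single
#' multi-model PDB file (ids are `model_1`, `model_2`, ...).
#'
#' @param path Directory or multi-model PDB file.
#' @return A pool tibble (see [as_pool()]).
#' @export
read_pool <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(pdb|ent)$",
                             full.names = TRUE))
    if (length(files) == 0) abort(paste0("no PDB files in '", path, "'"))
    structures <- lapply(files, read_structure)
    return(as_pool(structures))
  }
  if (!file.exists(path)) abort(paste0("file not found: '", path, "'"))
  nm <- n_models_in_file(path)
  structures <- lapply(seq_len(nm), function(k) {
    read_structure(path, model_index = k, id = paste0("model_", k))
  })
  as_pool(structures)
}

#' Write a structure to a PDB file
#'
#' Standard fixed-column PDB with coordinates to 3 decimals; reading the
#' file back reproduces names, numbering and coordinates.
#'
#' @param structure A structure tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_structure <- function(structure, path) {
  if (nrow(structure) == 0) abort("cannot write an empty structure")
  ins <- structure$ins
  ins[ins == ""] <- NA
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords_matrix(structure))),
    type = rep("ATOM", nrow(structure)),
    resno = structure$res_seq,
    resid = structure$res_name,
    eleno = structure$serial,
    elety = structure$atom,
    chain = structure$chain,
    insert = ins,
    o = structure$occ,
    b = structure$b,
    elesy = structure$element
  )
  invisible(path)
}

#' Read a predicted secondary-structure string
#'
#' Accepts a plain text file holding an H/E/C string (whitespace and
#' comment lines ignored) or a PSIPRED `.ss2` file (the per-residue letter
#' in column 3). A literal H/E/C string is passed through.
#'
#' @param x File path or literal string.
#' @return A single H/E/C string.
#' @export
read_ss <- function(x) {
  if (length(x) == 1 && !grepl("^[HEC]+$", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "\\s+")
    looks_ss2 <- length(fields) > 0 &&
      all(vapply(fields, length, integer(1)) >= 3) &&
      all(vapply(fields, function(f) grepl("^[0-9]+$", f[1]), logical(1)))
    if (looks_ss2) {
      ss <- vapply(fields, `[[`, character(1), 3)
      x <- paste(ss, collapse = "")
    } else {
      x <- gsub("\\s", "", paste(lines, collapse = ""))
    }
  } else {
    x <- gsub("\\s", "", paste(x, collapse = ""))
  }
  x <- toupper(x)
  if (!grepl("^[HEC]+$", x)) {
    abort("secondary-structure string may contain only H, E and C")
  }
  x
}
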
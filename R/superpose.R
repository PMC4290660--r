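#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `coords_a` and the transformed `coords_b` (`x' = R x + t`).
#' The SVD sign correction guarantees `det(R) = +1`, so mirror images are
#' never superposed onto their target: a chiral pair retains a strictly
#' positive RMSD.
#'
#' @param coords_a,coords_b Conformable N x 3 coordinate matrices
#'   (Angstrom), N >= 3, not all collinear.
#' @return An object of class `superposition`: a list with `rotation`
#'   (3 x 3, determinant +1), `translation` (length 3), `rmsd` (Angstrom)
#'   and `n_atoms`.
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) {
    abort("coordinate sets must have identical dimensions")
  }
  if (ncol(coords_a) != 3) abort("coordinates must be N x 3 matrices")
  n <- nrow(coords_a)
  if (n < 3) abort("at least 3 atoms are required for a unique rotation")
  for (m in list(coords_a, coords_b)) {
    s <- svd(scale(m, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
    if (s[2] < 1e-9 * max(s[1], 1e-12)) {
      abort("degenerate (collinear) point configuration")
    }
  }
  fit <- kabsch_cpp(coords_a, coords_b)
  out <- list(rotation = fit$rotation,
              translation = as.vector(fit$translation),
              rmsd = fit$rmsd,
              n_atoms = n)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition: rmsd ", format(x$rmsd, digits = 6), " A over ",
      x$n_atoms, " atoms>\n", sep = "")
  invisible(x)
}

#' @export
tidy.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
         det_rotation = det(x$rotation))
}

#' Apply a superposition to coordinates
#'
#' @param transform A `superposition` object.
#' @param coords An N x 3 matrix.
#' @return The transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, transform$translation, `+`)
}

# paired coordinate matrices for two structures under a residue mapping
paired_coords <- function(structure_a, structure_b, subset, mapping) {
  if (is.null(mapping)) {
    if (extract_sequence(structure_a) != extract_sequence(structure_b)) {
      abort("sequences differ; supply an explicit residue mapping")
    }
    n <- n_residues(structure_a)
    mapping <- tibble(pos_a = seq_len(n), pos_b = seq_len(n))
  }
  mapping <- as_tibble(mapping)
  names(mapping)[1:2] <- c("pos_a", "pos_b")

  if (subset == "ca") {
    ca_a <- ca_coords(structure_a)
    ca_b <- ca_coords(structure_b)
    ia <- match(as.character(mapping$pos_a), rownames(ca_a))
    ib <- match(as.character(mapping$pos_b), rownames(ca_b))
    keep <- !is.na(ia) & !is.na(ib)
    if (!all(keep)) warn("mapped residues without CA atoms were dropped")
    return(list(a = ca_a[ia[keep], , drop = FALSE],
                b = ca_b[ib[keep], , drop = FALSE]))
  }

  # heavy: intersect atoms by (mapped residue, atom name)
  ha <- structure_a[structure_a$element != "H", ]
  hb <- structure_b[structure_b$element != "H", ]
  ha <- ha[ha$res_idx %in% mapping$pos_a, ]
  hb <- hb[hb$res_idx %in% mapping$pos_b, ]
  pos_of_a <- setNames(mapping$pos_b, mapping$pos_a)
  key_a <- paste(unname(pos_of_a[as.character(ha$res_idx)]), ha$atom)
  key_b <- paste(hb$res_idx, hb$atom)
  common <- intersect(key_a, key_b)
  if (length(setdiff(key_a, key_b)) + length(setdiff(key_b, key_a)) > 0) {
    warn("side-chain atom sets differ; intersecting atoms by name")
  }
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  list(a = as.matrix(ha[ia, c("x", "y", "z")]),
       b = as.matrix(hb[ib, c("x", "y", "z")]))
}

#' RMSD between two structures after optimal superposition
#'
#' @param structure_a,structure_b Structure tibbles.
#' @param subset `"ca"` (alpha carbons) or `"heavy"` (all non-hydrogen
#'   atoms shared by residue and atom name).
#' @param mapping Optional residue-pair mapping (two-column data frame of
#'   residue indices in `structure_a` and `structure_b`); defaults to the
#'   positional identity when the sequences are identical.
#' @return Superposed RMSD in Angstrom.
#' @export
rmsd <- function(structure_a, structure_b, subset = c("ca", "heavy"),
                 mapping = NULL) {
  subset <- match.arg(subset)
  pc <- paired_coords(structure_a, structure_b, subset, mapping)
  if (nrow(pc$a) == 0) abort("empty atom selection")
  kabsch(pc$a, pc$b)$rmsd
}
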
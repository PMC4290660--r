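# Rotate/translate coordinates into a canonical principal-axes frame
# (axis signs fixed by coordinate skewness). The point lattice is fixed
# in space, so canonicalizing first makes the areas invariant under
# rigid motion of the input.
canonical_frame <- function(xyz) {
  xyz <- sweep(xyz, 2, colMeans(xyz))
  if (nrow(xyz) < 3) return(xyz)
  ev <- eigen(crossprod(xyz), symmetric = TRUE)$vectors
  rot <- xyz %*% ev
  skew <- colSums(rot^3)
  flip <- ifelse(skew < 0, -1, 1)
  sweep(rot, 2, flip, `*`)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals spheres of the heavy atoms,
#' estimating per-atom accessible area from a deterministic
#' generalized-spiral point lattice, so repeated runs are bit-identical.
#' Per-atom area is `(exposed points / n_points) * 4*pi*(r + probe)^2`.
#'
#' @param structure A structure tibble.
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Lattice points per atom (>= 64). The default 960 agrees
#'   with a 10,242-point lattice to about 1 percent on protein-sized
#'   inputs.
#' @param include_h Include hydrogens (default FALSE: decoys are usually
#'   heavy-atom only).
#' @return An object of class `sasa_result`: list with `atoms` (per-atom
#'   tibble including `area`), `residues` (per-residue areas), `total`
#'   (Angstrom^2), `probe` and `n_points`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960L, include_h = FALSE) {
  if (nrow(structure) == 0) abort("empty structure")
  if (n_points < 64) abort("n_points must be at least 64")
  at <- classify_atoms(structure)
  if (!include_h) at <- at[at$element != "H", ]
  if (nrow(at) == 0) abort("no heavy atoms to analyse")

  xyz <- canonical_frame(as.matrix(at[, c("x", "y", "z")]))
  areas <- sasa_cpp(xyz, at$radius, probe, as.integer(n_points))
  atoms <- dplyr::select(as_tibble(at), "serial", "atom", "element",
                         "res_idx", "res_name", "polarity")
  atoms$area <- as.numeric(areas)
  residues <- atoms |>
    dplyr::group_by(.data$res_idx) |>
    dplyr::summarise(res_name = .data$res_name[1],
                     area = sum(.data$area), .groups = "drop")
  out <- list(atoms = atoms, residues = residues, total = sum(areas),
              probe = probe, n_points = as.integer(n_points))
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<SASA: total ", format(x$total, digits = 6), " A^2 over ",
      nrow(x$atoms), " atoms (probe ", x$probe, " A, ", x$n_points,
      " points)>\n", sep = "")
  invisible(x)
}

# Residues conventionally counted as nonpolar for the exposed-surface
# fraction A1.
nonpolar_residues_default <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE",
                               "MET", "TRP", "GLY")

# Kyte-Doolittle hydropathy by 3-letter code.
kd_hydropathy <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5
)

#' Surface-area descriptors A1-A4
#'
#' * `A1`: fraction of the total area contributed by exposed nonpolar
#'   residues (hydrophobic set, configurable).
#' * `A2`: fraction contributed by exposed nonpolar atoms (C and S).
#' * `A3`: weighted exposed area, `sum_r w(r) * area(r)` with
#'   `w = Kyte-Doolittle hydropathy + 4.5` (shifted to be nonnegative;
#'   configurable).
#' * `A4`: total accessible area.
#'
#' @param sasa_result A [sasa()] result for `structure`.
#' @param structure The same structure tibble.
#' @param nonpolar_residues 3-letter codes counted as nonpolar for A1.
#' @param weights Named per-residue weights for A3 (3-letter codes);
#'   residues not listed get the neutral shifted weight 4.5.
#' @return A one-row tibble with `A1`, `A2`, `A3`, `A4`.
#' @export
surface_terms <- function(sasa_result, structure,
                          nonpolar_residues = nonpolar_residues_default,
                          weights = kd_hydropathy + 4.5) {
  total <- sasa_result$total
  if (total <= 0) abort("total surface area is zero")
  res <- sasa_result$residues
  a1 <- sum(res$area[res$res_name %in% nonpolar_residues]) / total
  a2 <- sum(sasa_result$atoms$area[sasa_result$atoms$polarity == "nonpolar"]) /
    total
  w <- unname(weights[res$res_name])
  w[is.na(w)] <- 4.5
  a3 <- sum(w * res$area)
  tibble(A1 = a1, A2 = a2, A3 = a3, A4 = total)
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# torsion angle (degrees, in (-180, 180]) for each row of four points
dihedral_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  m1 <- cross_rows(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  -atan2(y, x) * 180 / pi
}

backbone_coords <- function(structure, name) {
  at <- structure[structure$atom == name, ]
  at <- at[!duplicated(at$res_idx), ]
  m <- matrix(NA_real_, nrow = n_residues(structure), ncol = 3)
  m[at$res_idx, ] <- as.matrix(at[, c("x", "y", "z")])
  m
}

#' Backbone dihedral angles
#'
#' @param structure A structure tibble with backbone N, CA and C atoms.
#' @return A tibble with `res_idx`, `phi` and `psi` in degrees (NA at the
#'   termini or where backbone atoms are missing).
#' @export
phi_psi <- function(structure) {
  m <- n_residues(structure)
  N <- backbone_coords(structure, "N")
  CA <- backbone_coords(structure, "CA")
  C <- backbone_coords(structure, "C")
  phi <- rep(NA_real_, m)
  psi <- rep(NA_real_, m)
  if (m >= 2) {
    i <- 2:m
    phi[i] <- dihedral_rows(C[i - 1, , drop = FALSE], N[i, , drop = FALSE],
                            CA[i, , drop = FALSE], C[i, , drop = FALSE])
    j <- 1:(m - 1)
    psi[j] <- dihedral_rows(N[j, , drop = FALSE], CA[j, , drop = FALSE],
                            C[j, , drop = FALSE], N[j + 1, , drop = FALSE])
  }
  tibble(res_idx = seq_len(m), phi = phi, psi = psi)
}

runs_at_least <- function(flag, min_run) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

#' Assign secondary structure from backbone geometry
#'
#' A dependency-free phi/psi-window method (not hydrogen-bond based, since
#' decoys often lack amide hydrogens): H where
#' `phi in (-100, -30)` and `psi in (-80, -5)` in runs of at least 4;
#' E where `phi in (-170, -40)` and `psi in (90, 180) or (-180, -170)` in
#' runs of at least 3; C otherwise. When backbone N/C atoms are missing, a
#' CA-only fallback marks H where the CA(i)-CA(i+3) distance is within
#' 5.0 +/- 1.0 Angstrom in runs of at least 4. Chains under 3 residues
#' are all C.
#'
#' @param structure A structure tibble.
#' @return An H/E/C string of length `n_residues(structure)`.
#' @export
assign_ss <- function(structure) {
  m <- n_residues(structure)
  if (m < 3) return(strrep("C", m))
  bb_ok <- !anyNA(backbone_coords(structure, "N")) &&
    !anyNA(backbone_coords(structure, "C")) &&
    !anyNA(backbone_coords(structure, "CA"))
  ss <- rep("C", m)
  if (bb_ok) {
    ang <- phi_psi(structure)
    h_win <- ang$phi > -100 & ang$phi < -30 & ang$psi > -80 & ang$psi < -5
    e_win <- ang$phi > -170 & ang$phi < -40 &
      ((ang$psi > 90 & ang$psi < 180) | (ang$psi > -180 & ang$psi < -170))
    ss[runs_at_least(h_win, 4L)] <- "H"
    ss[runs_at_least(e_win, 3L)] <- "E"
  } else {
    ca <- ca_coords(structure)
    if (nrow(ca) < m) return(paste(ss, collapse = ""))
    d13 <- sqrt(rowSums((ca[seq_len(m - 3), , drop = FALSE] -
                           ca[4:m, , drop = FALSE])^2))
    h_win <- c(abs(d13 - 5.0) <= 1.0, rep(FALSE, 3))
    ss[runs_at_least(h_win, 4L)] <- "H"
  }
  paste(ss, collapse = "")
}

#' Secondary-structure penalties
#'
#' `PH` is the percentage of residues predicted helical that the model
#' fails to realize as helix; `PS` the analogue for strand. An empty
#' predicted class scores 0.
#'
#' @param predicted,assigned H/E/C strings of equal length.
#' @return A one-row tibble with `PH` and `PS` (percent, 0-100).
#' @export
ss_penalty <- function(predicted, assigned) {
  p <- strsplit(predicted, "")[[1]]
  a <- strsplit(assigned, "")[[1]]
  if (length(p) != length(a)) {
    abort("predicted and assigned strings differ in length")
  }
  pen <- function(cls) {
    n <- sum(p == cls)
    if (n == 0) return(0)
    100 * sum(p == cls & a != cls) / n
  }
  tibble(PH = pen("H"), PS = pen("E"))
}

#' Euclidean compactness M1
#'
#' Mean Euclidean distance of the C-alpha atoms from their centroid, in
#' Angstrom. Collapsed chains give small values, unfolded ones large.
#'
#' @param structure A structure tibble with CA atoms.
#' @return M1 in Angstrom.
#' @export
euclidean_compactness <- function(structure) {
  ca <- ca_coords(structure)
  if (nrow(ca) == 0) abort("no CA atoms")
  cen <- colMeans(ca)
  mean(sqrt(rowSums(sweep(ca, 2, cen)^2)))
}

#' All seven pcSM descriptors for one structure
#'
#' Computes the surface terms A1-A4, the secondary-structure penalties
#' PH/PS against a predicted H/E/C string, and the compactness M1. The
#' cumulative score CS is added separately by [cumulative_score()].
#'
#' @param structure A structure tibble.
#' @param predicted_ss Predicted H/E/C string (length = residue count).
#' @inheritParams sasa
#' @inheritParams surface_terms
#' @return A one-row tibble with `A1`, `A2`, `A3`, `A4`, `PH`, `PS`, `M1`.
#' @export
describe <- function(structure, predicted_ss, probe = 1.4, n_points = 960L,
                     nonpolar_residues = nonpolar_residues_default,
                     weights = kd_hydropathy + 4.5) {
  predicted_ss <- read_ss(predicted_ss)
  if (nchar(predicted_ss) != n_residues(structure)) {
    abort("predicted secondary structure length must equal residue count")
  }
  sr <- sasa(structure, probe = probe, n_points = n_points)
  surf <- surface_terms(sr, structure, nonpolar_residues, weights)
  pen <- ss_penalty(predicted_ss, assign_ss(structure))
  dplyr::bind_cols(surf, pen, tibble(M1 = euclidean_compactness(structure)))
}

#' Descriptor table for a pool
#'
#' @param pool A pool tibble.
#' @param predicted_ss Predicted H/E/C string shared by the pool.
#' @inheritParams describe
#' @return A tibble with `id` plus the seven descriptor columns, one row
#'   per pool member.
#' @export
describe_pool <- function(pool, predicted_ss, probe = 1.4, n_points = 960L,
                          nonpolar_residues = nonpolar_residues_default,
                          weights = kd_hydropathy + 4.5) {
  rows <- purrr::map(pool$structure, describe, predicted_ss = predicted_ss,
                     probe = probe, n_points = n_points,
                     nonpolar_residues = nonpolar_residues, weights = weights)
  dplyr::bind_cols(tibble(id = pool$id), dplyr::bind_rows(rows))
}
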
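#' Ramachandran outlier fraction
#'
#' Fraction of non-terminal residues whose (phi, psi) pair falls outside a
#' union of generously bounded favored/allowed regions: a helix box
#' `phi in (-180, -20), psi in (-120, 45)`; a sheet box
#' `phi in (-180, -20), psi in (45, 240 mod 360)` (i.e. up through -120
#' after wrapping); and a left-handed-helix box
#' `phi in (20, 120), psi in (-60, 90)`. Residues with incomplete
#' backbone are skipped.
#'
#' @param structure A structure tibble with backbone N, CA, C atoms.
#' @return Outlier fraction in `[0, 1]`.
#' @export
ramachandran <- function(structure) {
  ang <- phi_psi(structure)
  ok <- !is.na(ang$phi) & !is.na(ang$psi)
  if (!any(ok)) return(0)
  phi <- ang$phi[ok]
  psi <- ang$psi[ok]
  helix <- phi > -180 & phi < -20 & psi > -120 & psi < 45
  # psi in (45, 240) on the wrapped circle: (45, 180] plus (-180, -120)
  sheet <- phi > -180 & phi < -20 & (psi > 45 | psi < -120)
  left <- phi > 20 & phi < 120 & psi > -60 & psi < 90
  mean(!(helix | sheet | left))
}

#' Steric clashes per residue
#'
#' Counts heavy-atom pairs closer than `cutoff` whose residues are at
#' least two apart in sequence (same and adjacent residues are excluded
#' as covalently constrained), divided by the residue count.
#'
#' @param structure A structure tibble with at least 2 atoms.
#' @param cutoff Clash distance in Angstrom (default 2.0).
#' @return Clashes per residue (>= 0).
#' @export
clashes <- function(structure, cutoff = 2.0) {
  h <- structure[structure$element != "H", ]
  if (nrow(h) < 2) abort("need at least 2 atoms")
  n <- clash_count_cpp(as.matrix(h[, c("x", "y", "z")]),
                       as.integer(h$res_idx), cutoff, 2L)
  n / n_residues(structure)
}

#' Composite structure-quality score
#'
#' A transparent two-component stand-in for a multi-tool quality
#' meta-score ("protsav-standin" in CLI output): torsion quality via the
#' Ramachandran outlier fraction and packing quality via the clash rate,
#' combined as `composite = 100 * rama_outlier_fraction +
#' 10 * clashes_per_residue`. Low values (near zero) indicate good
#' quality; high values poor quality.
#'
#' @param structure A structure tibble.
#' @param clash_cutoff Clash distance in Angstrom.
#' @return A one-row tibble with `rama_outlier_fraction`,
#'   `clashes_per_residue` and `composite`.
#' @export
composite_quality <- function(structure, clash_cutoff = 2.0) {
  r <- ramachandran(structure)
  cl <- clashes(structure, cutoff = clash_cutoff)
  tibble(rama_outlier_fraction = r, clashes_per_residue = cl,
         composite = 100 * r + 10 * cl)
}

#' Quality table for a pool
#'
#' @param pool A pool tibble.
#' @param clash_cutoff Clash distance in Angstrom.
#' @return A tibble with `id` and the [composite_quality()] columns.
#' @export
quality_pool <- function(pool, clash_cutoff = 2.0) {
  rows <- purrr::map(pool$structure, composite_quality,
                     clash_cutoff = clash_cutoff)
  dplyr::bind_cols(tibble(id = pool$id), dplyr::bind_rows(rows))
}
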
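# ideal backbone internal coordinates (Angstrom / degrees)
bond_n_ca <- 1.458
bond_ca_c <- 1.525
bond_c_n <- 1.329
bond_c_o <- 1.231
angle_n_ca_c <- 111.2
angle_ca_c_n <- 116.6
angle_c_n_ca <- 121.9
angle_ca_c_o <- 120.5

deg2rad <- function(x) x * pi / 180

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

# NeRF placement: the point at the given bond/angle/torsion from c,
# with the angle measured at c and the torsion about b-c relative to a.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  d2 <- c(-bond * cos(ang),
          bond * cos(tor) * sin(ang),
          bond * sin(tor) * sin(ang))
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

# per-topology (phi, psi) arrays; turn/loop residues use (-90, 0), which
# assigns as coil yet stays inside the allowed torsion boxes
topology_angles <- function(topology, n) {
  if (topology == "helix") {
    list(phi = rep(-57, n), psi = rep(-47, n))
  } else if (topology == "hairpin") {
    if (n < 12) abort("a hairpin needs at least 12 residues")
    n1 <- ceiling((n - 4) / 2)
    n2 <- n - 4 - n1
    list(phi = c(rep(-120, n1), rep(-90, 4), rep(-120, n2)),
         psi = c(rep(130, n1), rep(0, 4), rep(130, n2)))
  } else if (topology == "helix-loop-helix") {
    if (n < 16) abort("a helix-loop-helix needs at least 16 residues")
    h1 <- ceiling((n - 6) / 2)
    h2 <- n - 6 - h1
    list(phi = c(rep(-57, h1), rep(-90, 6), rep(-57, h2)),
         psi = c(rep(-47, h1), rep(0, 6), rep(-47, h2)))
  } else {
    abort(paste0("unknown topology '", topology, "'"))
  }
}

#' Build an ideal toy protein structure
#'
#' Constructs a full backbone (N, CA, C, O) plus C-beta from ideal
#' internal coordinates (bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329
#' Angstrom; angles 111.2 / 116.6 / 121.9 degrees; omega 180):
#' helices use `phi = -57, psi = -47`, strands `phi = -120, psi = 130`;
#' a hairpin joins two strands by a 4-residue turn and a
#' helix-loop-helix joins two helices by a 6-residue coil. These fixtures
#' are geometric idealizations for testing, not physical models.
#'
#' @param topology `"helix"`, `"hairpin"` or `"helix-loop-helix"`.
#' @param n_residues Chain length (>= 8; >= 12 for hairpins, >= 16 for
#'   helix-loop-helix).
#' @param sequence Optional 1-letter sequence; defaults to alternating
#'   nonpolar/polar residues (Leu/Ser) so surface fractions are
#'   non-degenerate.
#' @param id Structure id.
#' @return A structure tibble.
#' @export
make_toy <- function(topology = c("helix", "hairpin", "helix-loop-helix"),
                     n_residues = 30L, sequence = NULL,
                     id = NULL) {
  topology <- match.arg(topology)
  n <- as.integer(n_residues)
  if (n < 8) abort("n_residues must be at least 8")
  if (is.null(sequence)) {
    sequence <- paste(rep(c("L", "S"), length.out = n), collapse = "")
  }
  if (nchar(sequence) != n) abort("sequence length must equal n_residues")
  ang <- topology_angles(topology, n)
  if (is.null(id)) id <- paste0("toy_", topology, "_", n)
  build_chain(ang$phi, ang$psi, sequence, id = id)
}

# construct a full-backbone chain from per-residue (phi, psi) arrays;
# the geometric core shared by all toy topologies
build_chain <- function(phi, psi, sequence, id = "chain") {
  n <- length(phi)
  stopifnot(length(psi) == n, nchar(sequence) == n)
  res3 <- unname(aa_123[strsplit(sequence, "")[[1]]])
  if (anyNA(res3)) abort("sequence contains letters outside the 20 standard")

  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bond_n_ca, 0, 0)
  a0 <- deg2rad(angle_n_ca_c)
  C[1, ] <- CA[1, ] + bond_ca_c * c(-cos(a0), sin(a0), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         bond_c_n, angle_ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          bond_n_ca, angle_c_n_ca, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         bond_ca_c, angle_n_ca_c, phi[i])
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         bond_c_o, angle_ca_c_o, psi[i] + 180)
    # C-beta from the tetrahedral bisector of the N-CA-C frame
    u1 <- unit3(CA[i, ] - N[i, ])
    u2 <- unit3(CA[i, ] - C[i, ])
    bis <- unit3(u1 + u2)
    perp <- unit3(cross3(u2, u1))
    th <- deg2rad(125.26 - 90)  # half tetrahedral offset from the bisector
    CB[i, ] <- CA[i, ] + 1.53 * (bis * cos(th) + perp * sin(th))
  }

  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    names_i <- c("N", "CA", "C", "O")
    coords_i <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    elem_i <- c("N", "C", "C", "O")
    if (res3[i] != "GLY") {
      names_i <- c(names_i, "CB")
      coords_i <- rbind(coords_i, CB[i, ])
      elem_i <- c(elem_i, "C")
    }
    rows[[i]] <- tibble(
      serial = serial + seq_along(names_i),
      atom = names_i, element = elem_i, res_name = res3[i],
      chain = "A", res_seq = i, ins = "",
      x = coords_i[, 1], y = coords_i[, 2], z = coords_i[, 3],
      occ = 1, b = 0
    )
    serial <- serial + length(names_i)
  }
  as_structure(dplyr::bind_rows(rows), id = id)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a noise-calibrated decoy pool from a native structure
#'
#' For each noise level `sigma` and replicate, every atom is displaced by
#' i.i.d. Gaussian noise (standard deviation `sigma` per coordinate) and
#' the whole model receives a random rigid transform; the resulting true
#' C-alpha RMSD to the native is recorded as provenance. Cartesian noise
#' deliberately degrades compactness, surface area and local geometry
#' together, giving a controllable RMSD ladder for testing; it is a
#' fixture model, not a physical decoy generator.
#'
#' @param native A structure tibble.
#' @param sigmas Noise levels in Angstrom (>= 0).
#' @param decoys_per_sigma Replicates per noise level.
#' @param seed Integer seed; the pool is fully reproducible from it.
#' @return A pool tibble with provenance columns `noise_sigma` and
#'   `true_ca_rmsd`.
#' @export
perturb <- function(native, sigmas = c(0.5, 1, 2, 4), decoys_per_sigma = 10L,
                    seed = 1L) {
  if (any(sigmas < 0)) abort("sigmas must be nonnegative")
  if (length(sigmas) == 0) abort("at least one sigma is required")
  set.seed(seed)
  structures <- list()
  ids <- character(0)
  prov_sigma <- numeric(0)
  k <- 0L
  for (s in sigmas) {
    for (r in seq_len(decoys_per_sigma)) {
      k <- k + 1L
      dec <- native
      xyz <- coords_matrix(native)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = s), ncol = 3)
      rot <- random_rotation()
      shift <- stats::runif(3, -20, 20)
      xyz <- sweep(xyz %*% t(rot), 2, shift, `+`)
      dec$x <- xyz[, 1]; dec$y <- xyz[, 2]; dec$z <- xyz[, 3]
      id <- sprintf("d_s%04.1f_r%03d", s, r)
      attr(dec, "id") <- id
      structures[[k]] <- dec
      ids[k] <- id
      prov_sigma[k] <- s
    }
  }
  pool <- as_pool(structures, ids)
  pool$noise_sigma <- prov_sigma
  pool$true_ca_rmsd <- vapply(pool$structure,
                              function(d) rmsd(native, d, subset = "ca"),
                              numeric(1))
  pool
}

#' Generate a multi-target synthetic benchmark
#'
#' Builds `n_targets` toy natives of varied topology and length
#' (30-80 residues), a noise-ladder decoy pool per target (the
#' unperturbed native is always included under the id `"native"`), and a
#' predicted secondary-structure string taken from the native's assigned
#' secondary structure (a best-case prediction). Fully deterministic
#' given `seed`.
#'
#' @param n_targets Number of targets (>= 1).
#' @param seed Integer seed.
#' @param sigmas Noise ladder in Angstrom.
#' @param decoys_per_sigma Replicates per noise level.
#' @param length_range Inclusive residue-count range to sample from.
#' @return A tibble with columns `target`, `topology`, `n_residues`,
#'   `native` (list), `pool` (list) and `predicted_ss`.
#' @export
make_benchmark <- function(n_targets, seed = 1L,
                           sigmas = c(0.5, 1, 2, 4, 6),
                           decoys_per_sigma = 100L,
                           length_range = c(30L, 80L)) {
  if (n_targets < 1) abort("n_targets must be at least 1")
  set.seed(seed)
  topologies <- rep(c("helix", "hairpin", "helix-loop-helix"),
                    length.out = n_targets)
  lengths <- sample(seq(length_range[1], length_range[2]), n_targets,
                    replace = TRUE)
  sub_seeds <- sample.int(2^30, n_targets)
  out <- vector("list", n_targets)
  for (t in seq_len(n_targets)) {
    native <- make_toy(topologies[t], lengths[t], id = "native")
    pool <- perturb(native, sigmas = sigmas,
                    decoys_per_sigma = decoys_per_sigma,
                    seed = sub_seeds[t])
    pool <- dplyr::bind_rows(
      tibble(id = "native", structure = list(native),
             noise_sigma = 0, true_ca_rmsd = 0),
      as_tibble(pool)
    )
    attr(pool, "sequence") <- extract_sequence(native)
    class(pool) <- c("decoy_pool", class(tibble()))
    ss <- assign_ss(native)
    out[[t]] <- tibble(
      target = sprintf("T%02d", t),
      topology = topologies[t],
      n_residues = lengths[t],
      native = list(native),
      pool = list(pool),
      predicted_ss = ss
    )
  }
  dplyr::bind_rows(out)
}
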
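# Shared fixtures, built in code at load time (no files on disk).

fix_helix12 <- make_toy("helix", 12)
fix_helix60 <- make_toy("helix", 60)
fix_hairpin16 <- make_toy("hairpin", 16)
fix_hlh30 <- make_toy("helix-loop-helix", 30)
fix_all <- list(helix = fix_helix12, hairpin = fix_hairpin16,
                hlh = fix_hlh30)

# a minimal hand-built structure: one atom per residue
point_structure <- function(coords, res_names = NULL, atom = "CA",
                            element = "C", id = "points") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(res_names)) res_names <- rep("ALA", n)
  as_structure(tibble::tibble(
    serial = seq_len(n), atom = atom, element = element,
    res_name = res_names, chain = "A", res_seq = seq_len(n), ins = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3], occ = 1, b = 0
  ), id = id)
}

random_proper_transform <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
                2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
                2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  list(R = R, t = runif(3, -15, 15))
}

transform_structure <- function(structure, tr = random_proper_transform()) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(tr$R), 2, tr$t, `+`)
  structure$x <- xyz[, 1]; structure$y <- xyz[, 2]; structure$z <- xyz[, 3]
  structure
}
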
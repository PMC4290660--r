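test_that("SASA matches closed forms for isolated and distant spheres", {
  one <- point_structure(rbind(c(0, 0, 0)))
  s1 <- sasa(one)
  expect_equal(s1$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.005)

  two <- point_structure(rbind(c(0, 0, 0), c(100, 0, 0)))
  s2 <- sasa(two)
  expect_equal(s2$total, 2 * 4 * pi * 3.10^2, tolerance = 0.005)
})

test_that("a caged atom is buried", {
  offsets <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2),
                                   z = c(-2, 0, 2)))
  cage <- offsets[rowSums(offsets != 0) > 0, ]
  coords <- rbind(c(0, 0, 0), cage)
  s <- point_structure(coords)
  centre_fine <- sasa(s, n_points = 10242)$atoms$area[1]
  expect_lt(centre_fine, 1)
  expect_lt(sasa(s)$atoms$area[1], 1.5)
})

test_that("the 960-point lattice is converged to about 1 percent", {
  for (s in fix_all) {
    coarse <- sasa(s, n_points = 960)$total
    fine <- sasa(s, n_points = 10242)$total
    expect_lt(abs(coarse - fine) / fine, 0.01)
  }
})

test_that("surface terms follow their definitions", {
  all_ala <- make_toy("helix", 12, sequence = strrep("A", 12))
  sr <- sasa(all_ala)
  st <- surface_terms(sr, all_ala)
  expect_equal(st$A1, 1.0)  # every residue is in the nonpolar set
  expect_equal(st$A4, sr$total)
  expect_gte(st$A2, 0); expect_lte(st$A2, 1)

  # A3 equals an independent spreadsheet-style sum over the residue table
  helix <- fix_helix12
  sr2 <- sasa(helix)
  st2 <- surface_terms(sr2, helix)
  kd <- c(LEU = 3.8, SER = -0.8)
  hand <- sum((kd[sr2$residues$res_name] + 4.5) * sr2$residues$area)
  expect_equal(st2$A3, unname(hand), tolerance = 1e-9)
})

test_that("phi/psi windows assign helix, strand and coil correctly", {
  ss_h <- assign_ss(fix_helix12)
  expect_match(ss_h, "^C?H+C?$")
  expect_gte(nchar(gsub("[^H]", "", ss_h)), 10)

  ss_e <- assign_ss(fix_hairpin16)
  runs <- rle(strsplit(ss_e, "")[[1]])
  expect_equal(sum(runs$values == "E"), 2)

  # extended backbone with helical psi: no H runs
  ext <- decoyrank:::build_chain(rep(180, 12), rep(-47, 12),
                                 strrep("A", 12))
  expect_false(grepl("H", assign_ss(ext)))

  # short chains are all coil
  expect_equal(assign_ss(point_structure(rbind(c(0, 0, 0), c(4, 0, 0)))), "CC")
})

test_that("CA-only chains fall back to the i,i+3 distance rule", {
  helix_ca <- fix_helix60[fix_helix60$atom == "CA", ]
  helix_ca <- as_structure(helix_ca, id = "ca_only")
  ss <- assign_ss(helix_ca)
  expect_gte(nchar(gsub("[^H]", "", ss)), 50)
})

test_that("secondary-structure penalties are percentages of missed predictions", {
  expect_equal(ss_penalty(strrep("H", 10), strrep("H", 10))$PH, 0)
  pred <- strrep("H", 10)
  assigned <- paste0(strrep("H", 6), strrep("C", 4))
  expect_equal(ss_penalty(pred, assigned)$PH, 40)
  expect_equal(ss_penalty(strrep("H", 5), strrep("C", 5))$PS, 0)
  expect_error(ss_penalty("HH", "H"), "length")
})

test_that("compactness is the mean CA distance from the centroid", {
  coincident <- point_structure(matrix(0, 4, 3))
  expect_equal(euclidean_compactness(coincident), 0)
  two <- point_structure(rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(euclidean_compactness(two), 1.0)
  ca <- ca_coords(fix_helix60)
  hand <- mean(sqrt(rowSums(sweep(ca, 2, colMeans(ca))^2)))
  expect_equal(euclidean_compactness(fix_helix60), hand, tolerance = 1e-9)
})

test_that("descriptors are deterministic and rigid-invariant", {
  s <- fix_hairpin16
  ss <- assign_ss(s)
  d1 <- describe(s, ss)
  d2 <- describe(s, ss)
  expect_identical(d1, d2)
  set.seed(13)
  moved <- transform_structure(s)
  d3 <- describe(moved, ss)
  expect_equal(as.numeric(d1), as.numeric(d3), tolerance = 1e-6)
})

test_that("unfolding increases exposure and size descriptors", {
  set.seed(4)
  native <- make_toy("helix-loop-helix", 40)
  ss <- assign_ss(native)
  pool <- perturb(native, sigmas = 6, decoys_per_sigma = 5, seed = 44)
  d_nat <- describe(native, ss)
  d_noisy <- describe_pool(pool, ss)
  expect_gt(mean(d_noisy$A4), d_nat$A4)
  expect_gt(mean(d_noisy$A1), d_nat$A1)
  expect_gt(mean(d_noisy$M1), d_nat$M1)
  expect_true(all(d_noisy$A1 >= 0 & d_noisy$A1 <= 1))
  expect_true(all(d_noisy$A2 >= 0 & d_noisy$A2 <= 1))
})
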
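test_that("PDB write/read round-trip preserves names, numbering and coordinates", {
  for (s in fix_all) {
    path <- withr::local_tempfile(fileext = ".pdb")
    write_structure(s, path)
    s2 <- read_structure(path)
    expect_identical(s2$atom, s$atom)
    expect_identical(s2$res_name, s$res_name)
    expect_identical(s2$res_seq, s$res_seq)
    expect_equal(n_residues(s2), n_residues(s))
    expect_lt(max(abs(as.matrix(s2[, c("x", "y", "z")]) -
                        as.matrix(s[, c("x", "y", "z")]))), 1e-3)
  }
})

test_that("insertion codes survive the round-trip", {
  s <- fix_helix12
  s$ins[s$res_idx == 3] <- "A"
  s <- as_structure(s, id = "ins_test")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- read_structure(path)
  expect_identical(s2$ins, s$ins)
})

test_that("writing an empty structure errors", {
  expect_error(write_structure(fix_helix12[0, ], tempfile()), "empty")
})

test_that("multi-model files are indexed by model", {
  a <- fix_helix12
  b <- transform_structure(a, list(R = diag(3), t = c(50, 0, 0)))
  pa <- withr::local_tempfile(fileext = ".pdb")
  pb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(a, pa)
  write_structure(b, pb)
  multi <- withr::local_tempfile(fileext = ".pdb")
  lines <- c("MODEL     1",
             grep("^ATOM", readLines(pa), value = TRUE), "ENDMDL",
             "MODEL     2",
             grep("^ATOM", readLines(pb), value = TRUE), "ENDMDL", "END")
  writeLines(lines, multi)

  m1 <- read_structure(multi, model_index = 1)
  m2 <- read_structure(multi, model_index = 2)
  expect_lt(max(abs(m1$x - a$x)), 1e-3)
  expect_gt(mean(m2$x) - mean(m1$x), 49)
  expect_error(read_structure(multi, model_index = 3), "out of range")

  pool <- read_pool(multi)
  expect_equal(pool$id, c("model_1", "model_2"))
})

test_that("parse errors name the offence", {
  expect_error(read_structure("no_such_file.pdb"), "not found")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_structure(empty), "no ATOM records")
  bad <- withr::local_tempfile(fileext = ".pdb")
  good <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fix_helix12, good)
  lines <- grep("^ATOM", readLines(good), value = TRUE)
  substr(lines[4], 31, 38) <- "  xx.yyy"
  writeLines(lines, bad)
  expect_error(read_structure(bad), "line 4")
})

test_that("directory pools and sequence validation work", {
  dir <- withr::local_tempdir()
  for (i in 1:5) {
    write_structure(fix_helix12, file.path(dir, sprintf("m%02d.pdb", i)))
  }
  pool <- read_pool(dir)
  expect_equal(nrow(pool), 5)
  expect_equal(pool$id, sprintf("m%02d", 1:5))
  expect_equal(pool_sequence(pool), extract_sequence(fix_helix12))

  other <- make_toy("helix", 12, sequence = strrep("A", 12))
  write_structure(other, file.path(dir, "zz_other.pdb"))
  expect_error(read_pool(dir), "zz_other")
})

test_that("altloc resolution keeps the highest occupancy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       3.000   1.000   0.000  1.00  0.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(sum(s$atom == "CA"), 1)
  expect_equal(s$x[s$atom == "CA"], 2.0)
})

test_that("sequence extraction maps nonstandard residues to X", {
  s <- point_structure(diag(3) * 4, res_names = c("ALA", "GLY", "SER"))
  expect_equal(extract_sequence(s), "AGS")
  s2 <- point_structure(diag(3) * 4, res_names = c("MET", "MSE", "LYS"))
  expect_equal(extract_sequence(s2), "MXK")
})

test_that("atom classification uses the fixed radius/polarity table", {
  s <- as_structure(tibble::tibble(
    serial = 1:3, atom = c("CA", "N", "SD"), element = c("C", "N", "S"),
    res_name = "MET", chain = "A", res_seq = 1, ins = "",
    x = c(0, 1.4, 2.8), y = 0, z = 0, occ = 1, b = 0))
  cl <- classify_atoms(s)
  expect_equal(cl$radius, c(1.70, 1.55, 1.80))
  expect_equal(cl$polarity, c("nonpolar", "polar", "nonpolar"))
  s$element[2] <- "Q"
  expect_error(classify_atoms(s), "unknown element")
})

test_that("secondary-structure input accepts plain strings and ss2 files", {
  expect_equal(read_ss("HHHEEC"), "HHHEEC")
  expect_equal(read_ss(" hhh\nec "), "HHHEC")
  ss2 <- withr::local_tempfile(fileext = ".ss2")
  writeLines(c("# PSIPRED VFORMAT (PSIPRED V4.0)", "",
               "   1 L C   0.998  0.001  0.001",
               "   2 S H   0.010  0.980  0.010",
               "   3 L H   0.010  0.980  0.010",
               "   4 V E   0.050  0.050  0.900"), ss2)
  expect_equal(read_ss(ss2), "CHHE")
  expect_error(read_ss("HHQX"), "only H, E and C")
})

test_that("pools built from structures enforce shared sequences and unique ids", {
  expect_error(as_pool(list()), "at least one")
  expect_error(as_pool(list(fix_helix12, fix_helix12), ids = c("a", "a")),
               "unique")
  other <- make_toy("helix", 12, sequence = strrep("A", 12))
  expect_error(as_pool(list(fix_helix12, other), ids = c("a", "b")), "b")
})
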
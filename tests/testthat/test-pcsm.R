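unit_descriptor <- function(...) {
  d <- tibble::tibble(A1 = 0, A2 = 0, A3 = 0, A4 = 0, PH = 0, PS = 0, M1 = 0)
  over <- list(...)
  d[names(over)] <- over
  d
}

test_that("CS of descriptor unit vectors returns the printed coefficients", {
  co <- pcsm_coefficients()
  expect_identical(cumulative_score(unit_descriptor(A1 = 1))$CS, 10)
  expect_identical(cumulative_score(unit_descriptor(A2 = 1))$CS, 0.1)
  expect_identical(cumulative_score(unit_descriptor(A3 = 1))$CS, 0.00001)
  expect_identical(cumulative_score(unit_descriptor(A4 = 1))$CS, 0.001)
  expect_identical(cumulative_score(unit_descriptor(PH = 1))$CS, 0.15)
  expect_identical(cumulative_score(unit_descriptor(PS = 1))$CS, 0.21)
  expect_identical(cumulative_score(unit_descriptor(M1 = 1))$CS, 0.001)
  expect_identical(cumulative_score(unit_descriptor())$CS, 0)
  expect_equal(unname(co),
               c(10, 0.1, 0.00001, 0.001, 0.15, 0.21, 0.001))
})

test_that("the worked substitution reproduces 15.287 exactly", {
  d <- unit_descriptor(A1 = 0.30, A2 = 0.25, A3 = 5000, A4 = 8000,
                       PH = 10, PS = 20, M1 = 12)
  expect_equal(cumulative_score(d)$CS, 15.287, tolerance = 1e-12)
})

test_that("CS is linear in each descriptor and the penalty term takes the max", {
  base <- unit_descriptor(A1 = 0.4, A2 = 0.5, A3 = 3000, A4 = 6000,
                          PH = 5, PS = 2, M1 = 10)
  cs0 <- cumulative_score(base)$CS
  co <- pcsm_coefficients()
  for (f in c("A1", "A2", "A3", "A4", "M1")) {
    bumped <- base
    bumped[[f]] <- bumped[[f]] + 1
    cname <- paste0("c_", f)
    delta <- cumulative_score(bumped)$CS - cs0
    # finite differences of a ~6-unit score carry ~1e-15 absolute noise
    expect_lt(abs(delta - unname(co[[cname]])), 1e-9)
  }
  # with PH dominating, bumping PS below the crossover leaves CS unchanged
  d_h <- unit_descriptor(PH = 100, PS = 1)
  d_h2 <- unit_descriptor(PH = 100, PS = 2)
  expect_equal(cumulative_score(d_h)$CS, cumulative_score(d_h2)$CS)
  expect_equal(cumulative_score(unit_descriptor(PH = 10, PS = 20))$CS,
               0.21 * 20)
})

test_that("coefficients are overridable and validated", {
  co <- pcsm_coefficients(c_A1 = 2)
  expect_equal(unname(co["c_A1"]), 2)
  expect_equal(unname(co["c_pS"]), 0.21)
  d <- unit_descriptor(A1 = 1)
  expect_equal(cumulative_score(d, co)$CS, 2)
  expect_error(pcsm_coefficients(c_zz = 1), "unknown coefficient")
  expect_error(cumulative_score(unit_descriptor(A1 = NA)), "NA")
  expect_error(cumulative_score(tibble::tibble(A1 = 1)), "missing")
})

test_that("ranking is ascending, stable and matches a full sort", {
  set.seed(6)
  desc <- tibble::tibble(
    id = sprintf("d%03d", 1:200),
    A1 = runif(200), A2 = runif(200), A3 = runif(200, 0, 8000),
    A4 = runif(200, 3000, 9000), PH = runif(200, 0, 100),
    PS = runif(200, 0, 100), M1 = runif(200, 5, 30)
  )
  top <- rank_decoys(desc, k = 10)
  scored <- cumulative_score(desc)
  oracle <- scored$id[sort.list(scored$CS, method = "shell")][1:10]
  expect_equal(top$id, oracle)
  expect_true(all(diff(top$CS) >= 0))

  # degenerate and tie cases
  one <- rank_decoys(desc[5, ], k = 10)
  expect_equal(one$id, "d005")
  ties <- tibble::tibble(id = c("b", "a"),
                         A1 = 0.5, A2 = 0, A3 = 0, A4 = 0, PH = 0, PS = 0,
                         M1 = 0)
  expect_equal(rank_decoys(ties, k = 2)$id, c("b", "a"))
  expect_equal(rank_decoys(ties, k = 1)$id, "b")
})

test_that("low CS enriches for low true RMSD on synthetic pools", {
  set.seed(10)
  native <- make_toy("hairpin", 30)
  ss <- assign_ss(native)
  pool <- perturb(native, sigmas = c(0.5, 1, 2, 4), decoys_per_sigma = 8,
                  seed = 77)
  desc <- cumulative_score(describe_pool(pool, ss))
  top <- rank_decoys(desc, k = 10)
  top_rmsd <- pool$true_ca_rmsd[match(top$id, pool$id)]
  expect_lte(mean(top_rmsd), mean(pool$true_ca_rmsd))
})
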
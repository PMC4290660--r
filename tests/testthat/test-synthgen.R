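coords_sum <- function(pool) {
  sum(vapply(pool$structure, function(s) sum(s$x) + sum(s$y) + sum(s$z),
             numeric(1)))
}

test_that("toy folds have ideal local geometry and the intended topology", {
  helix <- make_toy("helix", 12)
  ca <- ca_coords(helix)
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  ss <- assign_ss(helix)
  expect_gte(nchar(gsub("[^H]", "", ss)), 10)

  hairpin <- make_toy("hairpin", 16)
  runs <- rle(strsplit(assign_ss(hairpin), "")[[1]])
  expect_equal(sum(runs$values == "E"), 2)

  expect_error(make_toy("helix", 5), "at least 8")
  expect_error(make_toy("hairpin", 10), "at least 12")
  expect_error(make_toy("helix", 12, sequence = "AAA"), "length")
})

test_that("perturbation produces the requested noise ladder with provenance", {
  native <- make_toy("helix-loop-helix", 40)
  zero <- perturb(native, sigmas = 0, decoys_per_sigma = 3, seed = 1)
  expect_true(all(zero$true_ca_rmsd < 1e-9))

  pool <- perturb(native, sigmas = c(0.5, 1, 2, 4), decoys_per_sigma = 10,
                  seed = 2)
  means <- tapply(pool$true_ca_rmsd, pool$noise_sigma, mean)
  expect_true(all(diff(means) > 0))
  # superposition can only reduce the raw expected displacement sqrt(3)*sigma
  expect_true(all(pool$true_ca_rmsd <= sqrt(3) * pool$noise_sigma * 1.2))

  # provenance agrees with an independent superposition oracle
  for (i in sample(nrow(pool), 5)) {
    expect_equal(pool$true_ca_rmsd[i],
                 quat_rmsd(ca_coords(native), ca_coords(pool$structure[[i]])),
                 tolerance = 1e-9)
  }
})

test_that("perturbation is reproducible from its seed", {
  native <- make_toy("helix", 15)
  p1 <- perturb(native, sigmas = 1, decoys_per_sigma = 4, seed = 123)
  p2 <- perturb(native, sigmas = 1, decoys_per_sigma = 4, seed = 123)
  expect_identical(p1$true_ca_rmsd, p2$true_ca_rmsd)
  expect_identical(p1$structure[[3]]$x, p2$structure[[3]]$x)
})

test_that("benchmarks are deterministic and always contain the native", {
  b1 <- make_benchmark(3, seed = 7, decoys_per_sigma = 2,
                       sigmas = c(0.5, 2))
  b2 <- make_benchmark(3, seed = 7, decoys_per_sigma = 2,
                       sigmas = c(0.5, 2))
  expect_identical(b1$n_residues, b2$n_residues)
  for (t in 1:3) {
    expect_identical(b1$pool[[t]]$true_ca_rmsd, b2$pool[[t]]$true_ca_rmsd)
    expect_identical(coords_sum(b1$pool[[t]]), coords_sum(b2$pool[[t]]))
    expect_true("native" %in% b1$pool[[t]]$id)
    expect_equal(nchar(b1$predicted_ss[t]), b1$n_residues[t])
  }
  expect_true(all(b1$n_residues >= 30 & b1$n_residues <= 80))
})

test_that("a small benchmark flows through evaluation and summary", {
  b <- make_benchmark(4, seed = 11, decoys_per_sigma = 2,
                      sigmas = c(0.5, 4))
  records <- purrr::map2_dfr(b$pool, seq_len(nrow(b)), function(pool, t) {
    few <- pool[pool$id != "native", ][1:3, ]
    attr(few, "sequence") <- attr(pool, "sequence", exact = TRUE)
    dplyr::mutate(evaluate(few, b$native[[t]]), target = b$target[t])
  })
  s <- summarize_targets(records)
  best <- best_by_target(records)
  expect_equal(s$frac_tm_ge, mean(best$best_tm >= 0.5))
  expect_equal(s$frac_rmsd_le, mean(best$best_rmsd <= 5))
  expect_equal(s$n_targets, 4)
})
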
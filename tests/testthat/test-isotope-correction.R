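a15N <- natural_abundance()$N[2]   # 0.00364

test_that("tracer-only matrices match direct binomial evaluation", {
  spec1 <- molecule_spec("m1", c(N = 1L), 1L)
  M1 <- correction_matrix(spec1)
  expect_equal(unclass(M1)[, 1], c(1 - a15N, a15N), tolerance = 1e-15)
  expect_equal(unclass(M1)[, 2], c(0, 1), tolerance = 1e-15)

  spec0 <- molecule_spec("m0", c(C = 3L, N = 1L), 0L)
  M0 <- correction_matrix(spec0)
  expect_equal(dim(M0), c(1L, 1L))
  expect_identical(M0[1, 1], 1)

  spec2 <- molecule_spec("m2", c(N = 2L), 2L)
  M2 <- unclass(correction_matrix(spec2))
  expect_equal(M2[, 1], c((1 - a15N)^2, 2 * a15N * (1 - a15N), a15N^2),
               tolerance = 1e-15)
  expect_equal(M2[, 2], c(0, 1 - a15N, a15N), tolerance = 1e-15)
  expect_equal(M2[, 3], c(0, 0, 1), tolerance = 1e-15)
})

test_that("closed-form matrices equal the atom-enumeration oracle", {
  abund <- natural_abundance()
  set.seed(101)
  # tracer-only: formulas up to C20 H30 N10 O10, n <= 10
  for (k in 1:40) {
    spec <- random_molecule(k)
    M <- correction_matrix(spec, mode = "tracer-only")
    O <- oracle_correction_matrix(spec$formula, spec$tracer_atom_count, abund,
                                  mode = "tracer-only")
    expect_lt(max(abs(unclass(M) - O)), 1e-12)
  }
  # all-elements: oracle restricted to small formulas for tractability
  for (k in 1:15) {
    spec <- random_molecule(k, small = TRUE)
    M <- correction_matrix(spec, mode = "all-elements")
    O <- oracle_correction_matrix(spec$formula, spec$tracer_atom_count, abund,
                                  mode = "all-elements")
    expect_lt(max(abs(unclass(M) - O)), 1e-12)
  }
})

test_that("matrix construction validates its inputs", {
  big <- molecule_spec("big", c(N = 70L), 70L)
  expect_error(correction_matrix(big), "cap")
  spec <- molecule_spec("m", c(N = 1L), 1L)
  expect_error(correction_matrix(spec, abundances = list(C = c(0.9893, 0.0107))),
               "tracer element")
  expect_error(validate_abundance(list(N = c(0.9, 0.2))), "sum")
  expect_error(validate_abundance(list(N = c(0, 1))), "mass-shift-0")
})

test_that("correct_vector inverts the forward model exactly on clean data", {
  spec <- molecule_spec("m", c(N = 1L), 1L)
  M <- correction_matrix(spec)
  cd <- correct_vector(c(1 - a15N, a15N), M, sample_id = "s")
  expect_equal(cd$fractions, c(1, 0), tolerance = 1e-12)
  expect_lt(cd$solver_residual, 1e-12)

  cd2 <- correct_vector(c(0, 1), M)
  expect_equal(cd2$fractions, c(0, 1), tolerance = 1e-12)

  cd3 <- correct_vector(c(0, 0), M)
  expect_true(cd3$undetected)
  expect_equal(cd3$pool_size, 0)

  expect_error(correct_vector(c(1, 0, 0), M), "dimension")
  expect_error(correct_vector(c(-1, 0), M), "non-negative")
})

test_that("round-trip recovery: exact when noiseless, bounded under 1% noise", {
  set.seed(202)
  worst_clean <- 0
  ok_noisy <- 0
  n_trials <- 200
  for (k in seq_len(n_trials)) {
    spec <- random_molecule(k, max_n = 6L)
    n <- spec$tracer_atom_count
    M <- correction_matrix(spec, mode = "all-elements")
    tru <- as.numeric(stats::rgamma(n + 1, 1)); tru <- tru / sum(tru)
    raw <- as.numeric(M %*% tru) * 1000
    est <- correct_vector(raw, M)$fractions
    worst_clean <- max(worst_clean, max(abs(est - tru)))
    noisy <- raw * stats::rlnorm(n + 1, 0, 0.01)
    est_n <- correct_vector(noisy, M)$fractions
    expect_true(all(est_n >= 0))
    if (max(abs(est_n - tru)) < 0.02) ok_noisy <- ok_noisy + 1
  }
  expect_lt(worst_clean, 1e-8)
  expect_gte(ok_noisy / n_trials, 0.95)
})

test_that("fractional enrichment and total labeling read the simplex correctly", {
  cd <- structure(list(metabolite_id = "m", sample_id = "s",
                       fractions = c(0.6, 0.3, 0.1), pool_size = 10,
                       solver_residual = 0, undetected = FALSE),
                  class = "corrected_distribution")
  expect_equal(fractional_enrichment(cd, 2), 0.1)
  expect_equal(total_labeling(cd), 0.4)
  expect_error(fractional_enrichment(cd, 5), "out of range")

  pure <- structure(list(metabolite_id = "m", sample_id = "s",
                         fractions = c(1, 0), pool_size = 10,
                         solver_residual = 0, undetected = FALSE),
                    class = "corrected_distribution")
  expect_equal(fractional_enrichment(pure, 0), 1)
  expect_identical(total_labeling(pure), 0)

  full <- pure; full$fractions <- c(0, 0, 1)
  expect_equal(total_labeling(full), 1)

  nd <- pure; nd$undetected <- TRUE
  expect_error(fractional_enrichment(nd, 0), "undetected")
  expect_error(total_labeling(nd), "undetected")
})

test_that("abundance overrides round-trip through YAML", {
  dir <- tempfile("abund"); dir.create(dir)
  p <- file.path(dir, "abundances.yaml")
  writeLines(c("N:", "  - {shift: 0, probability: 0.995}",
               "  - {shift: 1, probability: 0.005}"), p)
  ab <- read_abundance_table(p)
  expect_equal(ab$N, c(0.995, 0.005))
  spec <- molecule_spec("m", c(N = 1L), 1L)
  M <- correction_matrix(spec, abundances = ab)
  expect_equal(unclass(M)[2, 1], 0.005)
})

test_that("correct_dataset covers every metabolite x sample pair once", {
  res <- analyze_preset("sxo_vs_gsc", seed = 5)
  ds <- res$sim$dataset
  expect_equal(nrow(res$corrected$summary),
               nrow(ds$molecules) * nrow(ds$samples))
  key <- paste(res$corrected$summary$metabolite_id,
               res$corrected$summary$sample_id)
  expect_false(anyDuplicated(key) > 0)
  # GDP-mannose is undetectable in the GSC-like group
  gsc <- grepl("^GSC_like", res$corrected$summary$sample_id)
  gdpm <- res$corrected$summary$metabolite_id == "GDP-mannose"
  expect_true(all(res$corrected$summary$undetected[gdpm & gsc]))
})
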
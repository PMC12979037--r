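test_that("two-group comparison matches the closed-form pooled t oracle", {
  sc <- fake_scores(list(
    glutamate = c(a1 = 1, a2 = 1, a3 = 1, b1 = 1, b2 = 1, b3 = 1),
    met_x = c(a1 = 1.0, a2 = 1.1, a3 = 0.9, b1 = 2.0, b2 = 2.1, b3 = 1.9)))
  d <- compare_models(sc, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                      test = "pooled")
  row <- d[d$metabolite_id == "met_x", ]
  orc <- oracle_pooled_t(c(1.0, 1.1, 0.9), c(2.0, 2.1, 1.9))
  expect_equal(row$fold_change, 2, tolerance = 1e-12)
  expect_equal(abs(row$t_statistic), 12.247, tolerance = 1e-3)
  expect_equal(row$t_statistic, orc$t, tolerance = 1e-9)
  expect_equal(row$p_value, orc$p, tolerance = 1e-9)
  expect_true(row$significant)
})

test_that("identical groups give the null record: FC 1, t 0, p 1", {
  sc <- fake_scores(list(met_x = c(a1 = 2, a2 = 3, a3 = 4,
                                   b1 = 2, b2 = 3, b3 = 4)))
  for (tt in c("welch", "pooled")) {
    d <- compare_models(sc, c("a1", "a2", "a3"), c("b1", "b2", "b3"), test = tt)
    expect_equal(d$fold_change, 1)
    expect_false(d$significant)
  }
  # exactly constant groups hit the degenerate branch
  sc0 <- fake_scores(list(met_x = c(a1 = 1, a2 = 1, b1 = 1, b2 = 1)))
  d0 <- compare_models(sc0, c("a1", "a2"), c("b1", "b2"))
  expect_identical(d0$t_statistic, 0)
  expect_identical(d0$p_value, 1)
})

test_that("the fold-change gate blocks small effects however significant", {
  sc <- fake_scores(list(met_x = c(a1 = 1.000, a2 = 1.001, a3 = 0.999,
                                   b1 = 1.200, b2 = 1.201, b3 = 1.199)))
  d <- compare_models(sc, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_lt(d$p_value, 0.001)
  expect_equal(d$fold_change, 1.2, tolerance = 1e-9)
  expect_false(d$significant)
})

test_that("swapping groups inverts fold changes and preserves p-values", {
  res <- analyze_preset("sxo_vs_gsc", seed = 17)
  ga <- group_samples(res$sim$dataset$samples, "SXO_like")
  gb <- group_samples(res$sim$dataset$samples, "GSC_like")
  d1 <- compare_models(res$scores, ga, gb)
  d2 <- compare_models(res$scores, gb, ga)
  m <- merge(as.data.frame(d1), as.data.frame(d2), by = "metabolite_id")
  tested <- m$status.x == "tested" & m$status.y == "tested"
  expect_lt(max(abs(m$fold_change.x[tested] * m$fold_change.y[tested] - 1)),
            1e-12)
  expect_equal(m$p_value.x[tested], m$p_value.y[tested], tolerance = 1e-12)
  expect_true(all(m$status.y[m$status.x == "exclusive_to_A"] ==
                    "exclusive_to_B"))
})

test_that("group hygiene is enforced", {
  sc <- fake_scores(list(met_x = c(a1 = 1, a2 = 1, b1 = 2, b2 = 2)))
  expect_error(compare_models(sc, c("a1", "a2"), c("a2", "b1")), "overlap")
  expect_error(compare_models(sc, "a1", c("b1", "b2")), ">= 2")
  sc$traced[sc$sample_id == "b1"] <- FALSE
  expect_error(compare_models(sc, c("a1", "a2"), c("b1", "b2")), "tracer-free")
})

test_that("tested records sort by p, then |log2FC|, then id", {
  res <- analyze_preset("sxo_vs_gsc", seed = 23)
  d <- compare_models(res$scores,
                      group_samples(res$sim$dataset$samples, "SXO_like"),
                      group_samples(res$sim$dataset$samples, "GSC_like"))
  tested <- d[d$status == "tested", ]
  expect_false(is.unsorted(tested$p_value))
  expect_true(all(d$status[seq_len(nrow(tested))] == "tested"))
})

test_that("concordance reproduces closed-form regression and correlation", {
  x <- c(a = 1, b = 2, c = 3, d = 4)
  expect_identical(concordance(x, x)$r, 1)
  y_neg <- -x
  cc <- concordance(x, y_neg)
  expect_equal(cc$r, -1)
  expect_equal(cc$r_squared, 1, tolerance = 1e-12)

  y <- c(a = 1.1, b = 1.9, c = 3.2, d = 3.8)
  cc <- concordance(x, y)
  orc <- oracle_regression(unname(x), unname(y))
  expect_equal(cc$r, orc$r, tolerance = 1e-12)
  expect_equal(cc$slope, orc$slope, tolerance = 1e-12)
  expect_equal(cc$intercept, orc$intercept, tolerance = 1e-12)
  expect_equal(cc$r_squared, cc$r^2, tolerance = 1e-12)
  expect_equal(cc$n_points, 4L)

  expect_error(concordance(x[1:2], y[1:2]), ">= 3")
  expect_error(concordance(c(a = 1, b = 1, c = 1), y[1:3]), "variance")
})

test_that("per-metabolite panels route to ANOVA or the two-group t-test", {
  sc <- fake_scores(list(met_x = c(g1a = 1, g1b = 2, g1c = 3,
                                   g2a = 1, g2b = 2, g2c = 3,
                                   g3a = 1, g3b = 2, g3c = 3)))
  groups <- list(g1 = c("g1a", "g1b", "g1c"), g2 = c("g2a", "g2b", "g2c"),
                 g3 = c("g3a", "g3b", "g3c"))
  r <- paired_metabolite_test(sc, "met_x", groups)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  sc2 <- fake_scores(list(met_x = c(g1a = 0, g1b = 0, g1c = 0,
                                    g2a = 0, g2b = 0, g2c = 0,
                                    g3a = 10, g3b = 10.1, g3c = 9.9)))
  r2 <- paired_metabolite_test(sc2, "met_x", groups)
  orc <- oracle_anova_f(list(c(0, 0, 0), c(0, 0, 0), c(10, 10.1, 9.9)))
  expect_equal(r2$statistic, orc$f, tolerance = 1e-9)
  expect_equal(r2$p_value, orc$p, tolerance = 1e-9)
  expect_lt(r2$p_value, 0.001)

  # two groups: identical to compare_models for that metabolite
  sc3 <- fake_scores(list(met_x = c(a1 = 1.0, a2 = 1.1, a3 = 0.9,
                                    b1 = 2.0, b2 = 2.1, b3 = 1.9)))
  two <- list(A = c("a1", "a2", "a3"), B = c("b1", "b2", "b3"))
  r3 <- paired_metabolite_test(sc3, "met_x", two)
  d3 <- compare_models(sc3, two$A, two$B)
  expect_equal(r3$statistic, d3$t_statistic, tolerance = 1e-12)
  expect_equal(r3$p_value, d3$p_value, tolerance = 1e-12)

  expect_error(paired_metabolite_test(sc3, "met_x",
                                      list(A = "a1", B = two$B)), "< 2")
})

test_that("concordance results serialize to a one-row TSV", {
  cc <- concordance(c(a = 1, b = 2, c = 3, d = 4),
                    c(a = 1.1, b = 1.9, c = 3.2, d = 3.8))
  p <- tempfile(fileext = ".tsv")
  write_concordance(cc, p)
  back <- utils::read.delim(p)
  expect_equal(nrow(back), 1L)
  expect_equal(back$r, cc$r, tolerance = 1e-12)
  expect_equal(back$n_points, 4L)
})
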
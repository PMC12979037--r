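test_that("propagated distributions always lie on the simplex", {
  net <- preset_scenario("sxo_vs_gsc")$network
  for (mult in list(NULL, c(purine_degradation = 4, pyrimidine_degradation = 0),
                    c(purine_degradation = 0.5))) {
    pr <- propagate_labels(net, multipliers = mult)
    for (m in names(pr)) {
      expect_equal(sum(pr[[m]]$iso), 1, tolerance = 1e-12)
      expect_true(all(pr[[m]]$iso >= -1e-15))
      expect_equal(sum(pr[[m]]$state), 1, tolerance = 1e-12)
    }
  }
})

test_that("tracer entry distributions follow the labeling mode", {
  # independent mode at e = 0.5: binomial(2, 0.5)
  mets <- data.frame(metabolite_id = "glutamine", formula = "C5H10N2O3",
                     tracer_atom_count = 2L, pool_size = 100,
                     fraction_new = NA, pathway = "tracer",
                     stringsAsFactors = FALSE)
  net_ind <- network_spec(mets, list(),
                          list(metabolite_id = "glutamine", enrichment = 0.5,
                               mode = "independent"))
  pr <- propagate_labels(net_ind)
  expect_equal(pr$glutamine$iso, c(0.25, 0.5, 0.25), tolerance = 1e-12)

  net_joint <- network_spec(mets, list(),
                            list(metabolite_id = "glutamine", enrichment = 0.4,
                                 mode = "joint"))
  pr2 <- propagate_labels(net_joint)
  expect_equal(pr2$glutamine$iso, c(0.6, 0, 0.4), tolerance = 1e-12)
})

test_that("single-step mixing follows fraction_new x precursor enrichment", {
  mets <- data.frame(
    metabolite_id = c("glutamine", "prod"),
    formula = c("C5H10N2O3", "C4H7NO4"),
    tracer_atom_count = c(2L, 1L), pool_size = c(100, 100),
    fraction_new = c(NA, 0.6), pathway = c("tracer", "x"),
    stringsAsFactors = FALSE)
  rules <- list(list(product = "prod", precursor = "glutamine",
                     positions = c(`1` = 2L)))
  net <- network_spec(mets, rules,
                      list(metabolite_id = "glutamine", enrichment = 0.5,
                           mode = "joint"))
  pr <- propagate_labels(net)
  expect_equal(1 - pr$prod$iso[1], 0.3, tolerance = 1e-12)  # 0.6 x 0.5
})

test_that("the propagation engine matches the generative sampling oracle", {
  net <- preset_scenario("sxo_vs_gsc")$network
  mult <- c(purine_degradation = 4, pyrimidine_degradation = 0)
  pr <- propagate_labels(net, multipliers = mult)
  for (m in c("glutamate", "AMP", "adenosine", "uracil", "argininosuccinate")) {
    mc <- oracle_sample_iso(net, m, multipliers = mult, n_draws = 20000,
                            seed = 99)
    expect_lt(max(abs(pr[[m]]$iso - mc)), 0.02)
  }
})

test_that("zero enrichment yields zero labeling end to end", {
  pr <- propagate_labels(preset_scenario("sxo_vs_gsc")$network, enrichment = 0)
  for (m in names(pr)) expect_identical(1 - pr[[m]]$iso[1], 0)

  ps <- preset_scenario("sxo_vs_gsc", seed = 3, noise_cv = 0, enrichment = 0)
  sim <- simulate_dataset(ps$network, ps$scenario)
  corrected <- correct_dataset(sim$dataset, mode = "all-elements")
  tl <- total_labeling_table(corrected)
  expect_lt(max(tl$total_labeling[!tl$undetected]), 1e-9)
})

test_that("at zero noise the pipeline recovers true total labeling exactly", {
  res <- analyze_preset("sxo_vs_gsc", seed = 3, noise_cv = 0)
  tl <- total_labeling_table(res$corrected)
  truth <- res$sim$truth
  traced <- grepl("_traced_", tl$sample_id)
  for (k in which(traced & !tl$undetected)) {
    g <- sub("_traced.*", "", tl$sample_id[k])
    tt <- truth$true_total_labeling[truth$metabolite_id == tl$metabolite_id[k] &
                                      truth$group == g]
    expect_equal(tl$total_labeling[k], tt, tolerance = 1e-6)
  }
})

test_that("the sxo_vs_gsc preset encodes the intended contrasts", {
  ps <- preset_scenario("sxo_vs_gsc", seed = 2)
  sim <- simulate_dataset(ps$network, ps$scenario)
  truth <- sim$truth
  get <- function(m, g, col) truth[[col]][truth$metabolite_id == m &
                                            truth$group == g]
  # purine degradation products higher in the monoculture-like group
  for (m in c("adenosine", "hypoxanthine")) {
    expect_gt(get(m, "GSC_like", "true_score") / get(m, "SXO_like", "true_score"),
              1.25)
  }
  # GDP-mannose measurable only in the explant-like group
  expect_true(get("GDP-mannose", "SXO_like", "detectable"))
  expect_false(get("GDP-mannose", "GSC_like", "detectable"))
  # pyrimidine degradation off in the monoculture-like group
  for (m in c("uracil", "DHU")) {
    expect_gt(get(m, "SXO_like", "true_total_labeling"), 0)
    expect_identical(get(m, "GSC_like", "true_total_labeling"), 0)
  }
  expect_setequal(unique(truth$metabolite_id[truth$differential]),
                  c("adenosine", "hypoxanthine", "GDP-mannose", "uracil", "DHU"))
})

test_that("the null preset flags nothing as differential", {
  ps <- preset_scenario("null", seed = 2)
  sim <- simulate_dataset(ps$network, ps$scenario)
  expect_false(any(sim$truth$differential))
})

test_that("unknown presets and invalid networks are rejected", {
  expect_error(preset_scenario("bogus"), "sxo_vs_gsc")
  mets <- data.frame(metabolite_id = c("glutamine", "a", "b"),
                     formula = c("C5H10N2O3", "C4H7NO4", "C4H7NO4"),
                     tracer_atom_count = c(2L, 1L, 1L),
                     pool_size = 100, fraction_new = c(NA, 0.5, 0.5),
                     pathway = "x", stringsAsFactors = FALSE)
  cyclic <- list(
    list(product = "a", precursor = "b", positions = c(`1` = 1L)),
    list(product = "b", precursor = "a", positions = c(`1` = 1L)))
  expect_error(network_spec(mets, cyclic,
                            list(metabolite_id = "glutamine", enrichment = 0.4)),
               "cycle")
  expect_error(network_spec(mets, list(),
                            list(metabolite_id = "glutamine", enrichment = 1.2)),
               "\\[0, 1\\]")
  dup <- list(
    list(product = "a", precursor = "glutamine", positions = c(`1` = 1L)),
    list(product = "a", precursor = "glutamine", positions = c(`1` = 2L)))
  expect_error(network_spec(mets, dup,
                            list(metabolite_id = "glutamine", enrichment = 0.4)),
               "more than once")
  oob <- list(list(product = "a", precursor = "glutamine",
                   positions = c(`2` = 1L)))
  expect_error(network_spec(mets, oob,
                            list(metabolite_id = "glutamine", enrichment = 0.4)),
               "out of range")
})

test_that("simulation is deterministic given the scenario seed", {
  ps <- preset_scenario("sxo_vs_gsc", seed = 77)
  s1 <- simulate_dataset(ps$network, ps$scenario)
  s2 <- simulate_dataset(ps$network, ps$scenario)
  expect_identical(s1$dataset$intensities, s2$dataset$intensities)
  ps2 <- preset_scenario("sxo_vs_gsc", seed = 78)
  s3 <- simulate_dataset(ps2$network, ps2$scenario)
  expect_false(identical(s1$dataset$intensities$intensity,
                         s3$dataset$intensities$intensity))
})

test_that("the concordance preset converges to r^2 = 1 as noise vanishes", {
  r2_at <- function(cv, seed) {
    res <- analyze_preset("preconditioning_concordance", seed = seed,
                          noise_cv = cv, unlabeled_replicates = 0L)
    tl <- total_labeling_table(res$corrected)
    grp <- sub("_traced.*", "", tl$sample_id)
    mean_tl <- function(g) {
      sub <- tl[grp == g & grepl("_traced_", tl$sample_id) & !tl$undetected, ]
      tapply(sub$total_labeling, sub$metabolite_id, mean)
    }
    x <- mean_tl("precond_24h"); y <- mean_tl("precond_120h")
    concordance(x, y)$r_squared
  }
  expect_gt(r2_at(0.05, seed = 8), 0.9)
  expect_gt(r2_at(0, seed = 8), 0.999)
})

test_that("custom networks round-trip through the YAML format", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c(
    "tracer_entry: {metabolite_id: glutamine, enrichment: 0.5, mode: joint}",
    "metabolites:",
    "  - {metabolite_id: glutamine, formula: C5H10N2O3, tracer_atom_count: 2,",
    "     pool_size: 2000, fraction_new: ~, pathway: tracer}",
    "  - {metabolite_id: glutamate, formula: C5H9NO4, tracer_atom_count: 1,",
    "     pool_size: 5000, fraction_new: 0.6, pathway: core}",
    "rules:",
    "  - {product: glutamate, precursor: glutamine, positions: {1: 1}}"), p)
  net <- read_network_yaml(p)
  expect_s3_class(net, "network_spec")
  pr <- propagate_labels(net)
  expect_equal(1 - pr$glutamate$iso[1], 0.3, tolerance = 1e-12)
  expect_error(read_network_yaml(tempfile()), "not found")
})
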
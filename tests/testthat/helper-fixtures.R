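# Fixture builders: everything is generated in code at test time.

# write a minimal three-table dataset to a temp dir; returns the paths
write_minimal_dataset <- function(dir = tempfile("fixture"),
                                  drop_m1 = FALSE, extra_iso = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  molecules <- data.frame(metabolite_id = "glutamine", formula = "C5H10N2O3",
                          tracer_atom_count = 2L)
  samples <- data.frame(sample_id = "s1", model_system = "A",
                        tracer_condition = "traced", precondition_hours = 120,
                        replicate = 1L)
  ints <- data.frame(metabolite_id = "glutamine", sample_id = "s1",
                     isotopologue = 0:2, intensity = c(700, 20, 280))
  if (drop_m1) ints <- ints[ints$isotopologue != 1L, ]
  if (extra_iso) ints <- rbind(ints, data.frame(metabolite_id = "glutamine",
                                                sample_id = "s1",
                                                isotopologue = 3L,
                                                intensity = 5))
  paths <- file.path(dir, c("intensities.tsv", "metabolites.tsv", "samples.tsv"))
  utils::write.table(ints, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(molecules, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(samples, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

# fabricate a labeling_scores table from a list: metabolite -> c(sample = score)
fake_scores <- function(values, reference = "glutamate") {
  rows <- do.call(rbind, lapply(names(values), function(m) {
    v <- values[[m]]
    data.frame(metabolite_id = m, sample_id = names(v), traced = TRUE,
               total_labeling = unname(v) * 0.4, pool_size = 100,
               passed_filters = TRUE, score = unname(v),
               stringsAsFactors = FALSE)
  }))
  structure(rows, reference = reference, policy = filter_policy(),
            normalization = "per-sample",
            class = c("labeling_scores", "data.frame"))
}

# two-metabolite noiseless dataset with chosen total labelings (tracer-only
# forward model), for exercising the score arithmetic exactly
score_fixture_dataset <- function(tl_glutamate = 0.4, tl_x = 0.2,
                                  pool_x = 1000) {
  molecules <- data.frame(metabolite_id = c("glutamate", "met_x"),
                          formula = c("C5H9NO4", "C4H7NO4"),
                          tracer_atom_count = c(1L, 1L),
                          stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("t1", "t2"), model_system = "A",
                        tracer_condition = "traced", precondition_hours = 120,
                        replicate = 1:2, stringsAsFactors = FALSE)
  mk <- function(m, formula, tl, pool) {
    spec <- molecule_spec(m, formula, 1L)
    M <- correction_matrix(spec, mode = "tracer-only")
    meas <- as.numeric(M %*% c(1 - tl, tl)) * pool
    do.call(rbind, lapply(samples$sample_id, function(s) {
      data.frame(metabolite_id = m, sample_id = s, isotopologue = 0:1,
                 intensity = meas, stringsAsFactors = FALSE)
    }))
  }
  ints <- rbind(mk("glutamate", "C5H9NO4", tl_glutamate, 5000),
                mk("met_x", "C4H7NO4", tl_x, pool_x))
  tracing_dataset(molecules, samples, ints)
}

# simulate a preset and run correction + scoring with matched mode
analyze_preset <- function(name, seed, noise_cv = 0.10, n_replicates = 3L,
                           unlabeled_replicates = 2L, enrichment = 0.4,
                           policy = filter_policy()) {
  ps <- preset_scenario(name, n_replicates = n_replicates, noise_cv = noise_cv,
                        seed = seed, enrichment = enrichment,
                        unlabeled_replicates = unlabeled_replicates)
  sim <- simulate_dataset(ps$network, ps$scenario)
  corrected <- correct_dataset(sim$dataset, mode = "all-elements")
  scores <- compute_labeling_scores(corrected, sim$dataset$samples,
                                    policy = policy)
  list(preset = ps, sim = sim, corrected = corrected, scores = scores)
}

sxo_truth_targets <- c("adenosine", "hypoxanthine", "GDP-mannose", "uracil")

sxo_null_fillers <- c("glutamine", "glutamate", "aspartate", "alanine",
                      "serine", "glycine", "proline", "ornithine",
                      "citrulline", "argininosuccinate", "IMP", "AMP", "GMP",
                      "UMP", "uridine")
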
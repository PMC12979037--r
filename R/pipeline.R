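#' Assemble a pipeline run configuration
#'
#' @param intensities,metabolites,samples Paths to the three input tables.
#' @param sets Optional path to a GMT metabolite-set file (enables the QEA
#'   stage).
#' @param out_dir Output directory (created if absent).
#' @param group_A,group_B Model-system labels defining the two-group
#'   comparison (traced samples only). If `NULL`, the differential and QEA
#'   stages are skipped.
#' @param correction_mode `"tracer-only"` or `"all-elements"`.
#' @param reference Reference metabolite id (default `"glutamate"`).
#' @param min_total_labeling,min_pool,pool_size_mode Filter policy fields,
#'   see [filter_policy()].
#' @param p_threshold,fc_threshold Volcano thresholds.
#' @param test t-test flavour, `"pooled"` or `"welch"`.
#' @param n_permutations,qea_seed QEA permutation settings.
#' @param abundance_file Optional YAML abundance override
#'   (see [read_abundance_table()]).
#' @return Object of class `run_config`.
#' @export
run_config <- function(intensities, metabolites, samples, out_dir,
                       sets = NULL, group_A = NULL, group_B = NULL,
                       correction_mode = c("tracer-only", "all-elements"),
                       reference = "glutamate",
                       min_total_labeling = 0, min_pool = 0.01,
                       pool_size_mode = "fraction-of-sample-median",
                       p_threshold = 0.05, fc_threshold = 1.25,
                       test = c("pooled", "welch"),
                       n_permutations = 9999, qea_seed = 1L,
                       abundance_file = NULL) {
  structure(list(intensities = intensities, metabolites = metabolites,
                 samples = samples, sets = sets, out_dir = out_dir,
                 group_A = group_A, group_B = group_B,
                 correction_mode = match.arg(correction_mode),
                 reference = reference,
                 min_total_labeling = min_total_labeling, min_pool = min_pool,
                 pool_size_mode = pool_size_mode,
                 p_threshold = p_threshold, fc_threshold = fc_threshold,
                 test = match.arg(test), n_permutations = n_permutations,
                 qea_seed = as.integer(qea_seed),
                 abundance_file = abundance_file),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full tracing analysis pipeline
#'
#' Executes read -> correct -> score -> QC -> differential -> QEA in order,
#' writing each stage's TSV output plus a `manifest.json` that echoes the
#' resolved configuration, per-stage row counts and output paths. A re-run
#' with identical inputs and configuration is bit-identical. On a stage
#' error, outputs written so far are moved to a `quarantine/` subdirectory and
#' the error names the failing stage.
#'
#' @param config A [run_config()] or a path to a YAML config file.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$intensities, config$metabolites, config$samples,
              config$sets, config$abundance_file)) {
    if (!is.null(p) && !file.exists(p)) stop(sprintf("input file not found: %s", p))
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  written <- character(0)
  stage <- "setup"
  manifest <- list(package = "tracescore",
                   version = as.character(utils::packageVersion("tracescore")),
                   config = unclass(config), stages = list(), warnings = 0L)
  wcount <- 0L

  run_stage <- function(name, expr) {
    stage <<- name
    withCallingHandlers(expr, warning = function(w) {
      wcount <<- wcount + 1L
      invokeRestart("muffleWarning")
    })
  }

  tryCatch({
    abund <- if (is.null(config$abundance_file)) natural_abundance() else
      read_abundance_table(config$abundance_file)

    ds <- run_stage("read", read_tracing_dataset(config$intensities,
                                                 config$metabolites,
                                                 config$samples))
    manifest$stages$read <- list(metabolites = nrow(ds$molecules),
                                 samples = nrow(ds$samples),
                                 intensity_rows = nrow(ds$intensities),
                                 zero_filled = ds$n_zero_filled)

    corrected <- run_stage("correct",
                           correct_dataset(ds, mode = config$correction_mode,
                                           abundances = abund))
    p <- file.path(out, "corrected.tsv")
    write_corrected(corrected, p); written <- c(written, p)
    manifest$stages$correct <- list(
      rows = nrow(corrected$summary),
      undetected = sum(corrected$summary$undetected),
      mode = config$correction_mode)

    policy <- filter_policy(config$min_total_labeling, config$min_pool,
                            config$pool_size_mode)
    scores <- run_stage("score",
                        compute_labeling_scores(corrected, ds$samples,
                                                policy = policy,
                                                reference = config$reference))
    p <- file.path(out, "scores.tsv")
    write_scores(scores, p); written <- c(written, p)
    manifest$stages$score <- list(rows = nrow(scores),
                                  scored = sum(!is.na(scores$score)),
                                  passed = sum(scores$passed_filters))

    qc <- run_stage("qc", qc_report(ds, corrected, reference = config$reference))
    p <- file.path(out, "qc.tsv")
    write_tsv(qc, p); written <- c(written, p)
    manifest$stages$qc <- list(rows = nrow(qc), flagged = sum(qc$flag != "ok"))

    if (!is.null(config$group_A) && !is.null(config$group_B)) {
      ga <- group_samples(ds$samples, config$group_A)
      gb <- group_samples(ds$samples, config$group_B)
      diff <- run_stage("diff",
                        compare_models(scores, ga, gb,
                                       p_threshold = config$p_threshold,
                                       fc_threshold = config$fc_threshold,
                                       test = config$test))
      p <- file.path(out, "volcano.tsv")
      write_diff(diff, p); written <- c(written, p)
      st <- table(factor(diff$status, levels = c("tested", "exclusive_to_A",
                                                 "exclusive_to_B", "filtered")))
      manifest$stages$diff <- c(as.list(st),
                                list(significant = sum(diff$significant)))
      # counts reconcile with the metabolite total by construction; assert it
      stopifnot(sum(st) == nrow(ds$molecules))

      if (!is.null(config$sets)) {
        sets <- run_stage("qea", read_metabolite_sets(config$sets))
        qea <- run_stage("qea",
                         run_qea(scores, sets, ga, gb,
                                 n_permutations = config$n_permutations,
                                 seed = config$qea_seed))
        p <- file.path(out, "enrichment.tsv")
        write_enrichment(qea, p); written <- c(written, p)
        manifest$stages$qea <- list(sets = nrow(qea),
                                    tested = sum(qea$status == "tested"),
                                    exhaustive = attr(qea, "exhaustive"))
      }
    }

    manifest$warnings <- wcount
    manifest$outputs <- written
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }, error = function(e) {
    qdir <- file.path(out, "quarantine")
    if (length(written)) {
      if (!dir.exists(qdir)) dir.create(qdir, recursive = TRUE)
      file.rename(written, file.path(qdir, basename(written)))
    }
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Tracer-incorporation and background QC report
#'
#' Per sample: the reference metabolite's total labeling and the median total
#' labeling across detected metabolites, with flags for (a) traced samples
#' whose reference labeling falls below a floor (tracer failed to
#' incorporate) and (b) tracer-free samples whose median labeling exceeds a
#' ceiling (label contamination).
#'
#' @param dataset A [tracing_dataset()].
#' @param corrected The matching `corrected_set`.
#' @param reference Reference metabolite id (default `"glutamate"`).
#' @param reference_floor Minimum acceptable reference total labeling in
#'   traced samples (default 0.05).
#' @param background_ceiling Maximum acceptable median total labeling in
#'   tracer-free samples (default 0.01).
#' @return `data.frame` with one row per sample: `sample_id`,
#'   `tracer_condition`, `reference_total_labeling`, `median_total_labeling`,
#'   `flag` (`"ok"`, `"low_reference_labeling"` or `"high_background"`).
#' @export
qc_report <- function(dataset, corrected, reference = "glutamate",
                      reference_floor = 0.05, background_ceiling = 0.01) {
  stopifnot(inherits(dataset, "tracing_dataset"),
            inherits(corrected, "corrected_set"))
  if (!any(dataset$samples$tracer_condition == "traced")) {
    stop("dataset contains no traced samples")
  }
  tl <- total_labeling_table(corrected)
  rows <- lapply(seq_len(nrow(dataset$samples)), function(k) {
    s <- dataset$samples$sample_id[k]
    cond <- dataset$samples$tracer_condition[k]
    sub <- tl[tl$sample_id == s & !tl$undetected, ]
    ref <- sub$total_labeling[sub$metabolite_id == reference]
    ref <- if (length(ref)) ref else NA_real_
    med <- if (nrow(sub)) stats::median(sub$total_labeling) else NA_real_
    flag <- "ok"
    if (cond == "traced" && (is.na(ref) || ref < reference_floor)) {
      flag <- "low_reference_labeling"
    } else if (cond == "unlabeled" && !is.na(med) && med > background_ceiling) {
      flag <- "high_background"
    }
    data.frame(sample_id = s, tracer_condition = cond,
               reference_total_labeling = ref, median_total_labeling = med,
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
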
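#' Quality-filter policy for labeling scores
#'
#' Metabolites are scored only when their total labeling strictly exceeds
#' `min_total_labeling` (default 0, i.e. "total labeling > 0") and their pool
#' size is adequate. Pool adequacy is either an absolute intensity threshold
#' or, by default, a fraction of the sample's median detected-metabolite pool
#' (scale-free across instruments; 0.01 means "at least 1% of the sample's
#' median pool").
#'
#' @param min_total_labeling Strict lower bound on total labeling (default 0).
#' @param min_pool Pool threshold: a fraction of the per-sample median pool
#'   when `pool_size_mode = "fraction-of-sample-median"` (default 0.01), or an
#'   absolute intensity when `pool_size_mode = "absolute"`.
#' @param pool_size_mode `"fraction-of-sample-median"` or `"absolute"`.
#' @return Object of class `filter_policy`.
#' @export
filter_policy <- function(min_total_labeling = 0, min_pool = 0.01,
                          pool_size_mode = c("fraction-of-sample-median",
                                             "absolute")) {
  pool_size_mode <- match.arg(pool_size_mode)
  if (min_total_labeling < 0) stop("min_total_labeling must be >= 0")
  if (min_pool < 0) stop("min_pool must be >= 0")
  structure(list(min_total_labeling = min_total_labeling, min_pool = min_pool,
                 pool_size_mode = pool_size_mode),
            class = "filter_policy")
}

#' Compute Metabolite Labeling Scores
#'
#' For every metabolite x traced-sample pair: total labeling (`1 - f0`),
#' the quality-filter verdict under `policy`, and the score
#' `total_labeling / total_labeling(reference metabolite in the same sample)`.
#' Normalization is per sample by default (each traced sample's own reference
#' labeling), so the reference metabolite's own score is exactly 1 in every
#' sample where it passes filters. Tracer-free (`"unlabeled"`) samples are
#' carried in the table for accounting but are never scored; see
#' [qc_report()] for their background check.
#'
#' @param corrected A `corrected_set` from [correct_dataset()].
#' @param samples Sample metadata `data.frame` (as in [tracing_dataset()]).
#' @param policy A [filter_policy()].
#' @param reference Reference metabolite id (default `"glutamate"`). Must be
#'   detected with total labeling > 0 in every traced sample.
#' @param reference_isotopologue If `NULL` (default) the reference statistic
#'   is total labeling; otherwise the fractional enrichment of this
#'   isotopologue index of the reference metabolite.
#' @param normalization `"per-sample"` (default) or `"group-mean"`
#'   (normalizes by the mean reference labeling of the sample's model system).
#' @return Object of class `labeling_scores`: a `data.frame` with columns
#'   `metabolite_id`, `sample_id`, `traced`, `total_labeling`, `pool_size`,
#'   `passed_filters`, `score` plus attributes `reference`, `policy`,
#'   `normalization`.
#' @export
compute_labeling_scores <- function(corrected, samples,
                                    policy = filter_policy(),
                                    reference = "glutamate",
                                    reference_isotopologue = NULL,
                                    normalization = c("per-sample",
                                                      "group-mean")) {
  stopifnot(inherits(corrected, "corrected_set"), inherits(policy, "filter_policy"))
  normalization <- match.arg(normalization)
  tl <- total_labeling_table(corrected)
  idx <- match(tl$sample_id, samples$sample_id)
  if (any(is.na(idx))) stop("corrected set contains samples absent from metadata")
  traced <- samples$tracer_condition[idx] == "traced"
  traced_ids <- samples$sample_id[samples$tracer_condition == "traced"]

  if (!(reference %in% tl$metabolite_id)) {
    stop(sprintf("reference metabolite '%s' absent from corrected data", reference))
  }

  # reference statistic per traced sample
  ref_stat <- vapply(traced_ids, function(s) {
    row <- tl$metabolite_id == reference & tl$sample_id == s
    if (!any(row) || tl$undetected[row]) {
      stop(sprintf("reference metabolite '%s' undetected in traced sample '%s'",
                   reference, s))
    }
    if (is.null(reference_isotopologue)) {
      tl$total_labeling[row]
    } else {
      fractional_enrichment(corrected_distribution(corrected, reference, s),
                            reference_isotopologue)
    }
  }, numeric(1))
  if (any(ref_stat <= 0)) {
    stop(sprintf("reference metabolite '%s' has zero label accumulation in traced sample(s): %s",
                 reference, paste(traced_ids[ref_stat <= 0], collapse = ", ")))
  }
  if (normalization == "group-mean") {
    grp <- samples$model_system[match(traced_ids, samples$sample_id)]
    ref_stat <- stats::ave(ref_stat, grp, FUN = mean)
    names(ref_stat) <- traced_ids
  }

  # resolve the pool-size threshold per sample
  pool_thr <- vapply(unique(tl$sample_id), function(s) {
    if (policy$pool_size_mode == "absolute") return(policy$min_pool)
    pools <- tl$pool_size[tl$sample_id == s & !tl$undetected]
    if (!length(pools)) return(Inf)
    policy$min_pool * stats::median(pools)
  }, numeric(1))

  passed <- !tl$undetected &
    !is.na(tl$total_labeling) &
    tl$total_labeling > policy$min_total_labeling &
    tl$pool_size >= pool_thr[tl$sample_id]

  score <- rep(NA_real_, nrow(tl))
  ok <- traced & passed
  score[ok] <- tl$total_labeling[ok] / ref_stat[tl$sample_id[ok]]

  out <- data.frame(metabolite_id = tl$metabolite_id, sample_id = tl$sample_id,
                    traced = traced, total_labeling = tl$total_labeling,
                    pool_size = tl$pool_size, passed_filters = passed,
                    score = score, stringsAsFactors = FALSE)
  structure(out, reference = reference, policy = policy,
            normalization = normalization,
            reference_stat = ref_stat,
            class = c("labeling_scores", "data.frame"))
}

#' @export
print.labeling_scores <- function(x, ...) {
  cat(sprintf("<labeling_scores> %d metabolite x sample rows, reference '%s' (%s)\n",
              nrow(x), attr(x, "reference"), attr(x, "normalization")))
  cat(sprintf("  traced rows: %d scored / %d passing filters / %d total\n",
              sum(!is.na(x$score)), sum(x$passed_filters & x$traced),
              sum(x$traced)))
  invisible(x)
}

#' Write a labeling-score table to TSV
#'
#' @param scores A `labeling_scores` table.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "labeling_scores"))
  write_tsv(as.data.frame(scores), path)
  invisible(path)
}

#' Steady-state pool-size ratio between two metabolites
#'
#' A labeling-free readout on raw total intensities (e.g. the ratio of
#' dihydrouracil to uracil as a marker of pyrimidine degradation, or
#' argininosuccinate to citrulline for urea-cycle directionality).
#'
#' @param pools Named numeric vector of pool sizes for one sample
#'   (e.g. from [total_labeling_table()]).
#' @param numerator_id,denominator_id Metabolite ids present in `pools`.
#' @return `pool_size(numerator) / pool_size(denominator)`. A zero numerator
#'   pool returns 0 with a warning; a zero denominator pool is an error.
#' @export
steady_state_ratio <- function(pools, numerator_id, denominator_id) {
  if (is.null(names(pools))) stop("pools must be a named numeric vector")
  for (id in c(numerator_id, denominator_id)) {
    if (!(id %in% names(pools))) {
      stop(sprintf("metabolite '%s' absent from pools", id))
    }
  }
  den <- pools[[denominator_id]]
  num <- pools[[numerator_id]]
  if (is.na(den) || den <= 0) {
    stop(sprintf("denominator metabolite '%s' has zero or missing pool", denominator_id))
  }
  if (is.na(num) || num == 0) {
    warning(sprintf("numerator metabolite '%s' undetected; ratio is 0", numerator_id))
    return(0)
  }
  num / den
}

#' Per-sample fractional enrichment of one isotopologue
#'
#' Thin projection of [fractional_enrichment()] across samples, joined with
#' sample metadata when available (for figure-style per-isotopologue panels,
#' e.g. glutamine M+2).
#'
#' @param corrected A `corrected_set`.
#' @param metabolite_id Metabolite to report.
#' @param i Isotopologue index.
#' @param samples Optional sample metadata `data.frame` to join.
#' @return `data.frame` with `sample_id`, `fraction`, and metadata columns if
#'   `samples` was provided. Undetected samples are reported with NA fraction.
#' @export
isotopologue_report <- function(corrected, metabolite_id, i, samples = NULL) {
  stopifnot(inherits(corrected, "corrected_set"))
  sub <- corrected$summary[corrected$summary$metabolite_id == metabolite_id, ]
  if (!nrow(sub)) stop(sprintf("metabolite '%s' absent from corrected set", metabolite_id))
  fr <- vapply(seq_len(nrow(sub)), function(k) {
    if (sub$undetected[k]) return(NA_real_)
    fractional_enrichment(
      corrected_distribution(corrected, metabolite_id, sub$sample_id[k]), i)
  }, numeric(1))
  out <- data.frame(sample_id = sub$sample_id, isotopologue = as.integer(i),
                    fraction = fr, stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    out <- merge(out, samples, by = "sample_id", sort = FALSE)
  }
  out
}
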
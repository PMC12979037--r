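#' Select the traced samples of one model system
#'
#' @param samples Sample metadata `data.frame`.
#' @param model_system Model-system label to select.
#' @param traced_only Keep only traced samples (default TRUE).
#' @return Character vector of sample ids.
#' @export
group_samples <- function(samples, model_system, traced_only = TRUE) {
  keep <- samples$model_system == model_system
  if (traced_only) keep <- keep & samples$tracer_condition == "traced"
  samples$sample_id[keep]
}

# two-sample t robust to zero-variance degenerate inputs
two_sample_t <- function(a, b, pooled = FALSE) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p.value = 1))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                p.value = .Machine$double.xmin))
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Differential labeling analysis between two model systems
#'
#' Per metabolite, compares Metabolite Labeling Scores between two groups of
#' traced samples with an unpaired two-sample t-test (classic pooled-variance
#' Student test by default, the convention of mainstream GUI statistics
#' packages for the plain "unpaired t-test"; Welch's unequal-variance test is
#' a flag away, and is the safer choice when group variances differ strongly
#' and replication exceeds the usual n = 3), computes the
#' fold change of group means (B relative to A) and flags significance with
#' the volcano thresholds `p < p_threshold` and
#' `max(FC, 1/FC) > fc_threshold`. Benjamini-Hochberg q-values are reported
#' as an additional column (raw p drives the `significant` flag).
#'
#' Metabolites testable (at least two scored replicates) in exactly one group
#' are reported as categorical `exclusive_to_A` / `exclusive_to_B` records
#' with no p-value — the honest handling of structural "not detected" pools,
#' which yield zero or one noise-positive replicate in the other group — and
#' metabolites with insufficient replication in both groups as `filtered`.
#'
#' @param scores A `labeling_scores` table.
#' @param group_A,group_B Character vectors of traced sample ids
#'   (see [group_samples()]); must not overlap.
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param fc_threshold Fold-change threshold on `max(FC, 1/FC)`
#'   (default 1.25).
#' @param test `"pooled"` (default) or `"welch"`.
#' @return Object of class `trace_diff`: a `data.frame` with one row per
#'   metabolite (`metabolite_id`, `mean_score_A`, `mean_score_B`,
#'   `fold_change`, `log2_fold_change`, `t_statistic`, `p_value`, `q_value`,
#'   `n_A`, `n_B`, `status`, `significant`), tested records sorted by p
#'   ascending (ties: |log2FC| descending, then id).
#' @export
compare_models <- function(scores, group_A, group_B,
                           p_threshold = 0.05, fc_threshold = 1.25,
                           test = c("pooled", "welch")) {
  stopifnot(inherits(scores, "labeling_scores"))
  test <- match.arg(test)
  if (length(intersect(group_A, group_B))) {
    stop("groups overlap: ", paste(intersect(group_A, group_B), collapse = ", "))
  }
  for (g in list(A = group_A, B = group_B)) {
    if (length(g) < 2L) stop("each group needs >= 2 traced samples")
    miss <- setdiff(g, scores$sample_id)
    if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
    untr <- g[!scores$traced[match(g, scores$sample_id)]]
    if (length(untr)) {
      stop("group contains tracer-free sample(s): ", paste(untr, collapse = ", "))
    }
  }

  mets <- unique(scores$metabolite_id)
  rows <- lapply(mets, function(m) {
    sub <- scores[scores$metabolite_id == m & !is.na(scores$score), ]
    a <- sub$score[sub$sample_id %in% group_A]
    b <- sub$score[sub$sample_id %in% group_B]
    nA <- length(a); nB <- length(b)
    base <- data.frame(metabolite_id = m,
                       mean_score_A = if (nA) mean(a) else NA_real_,
                       mean_score_B = if (nB) mean(b) else NA_real_,
                       fold_change = NA_real_, log2_fold_change = NA_real_,
                       t_statistic = NA_real_, p_value = NA_real_,
                       n_A = nA, n_B = nB, status = "filtered",
                       stringsAsFactors = FALSE)
    if (nA >= 2L && nB >= 2L) {
      ht <- two_sample_t(a, b, pooled = test == "pooled")
      fc <- mean(b) / mean(a)
      base$fold_change <- fc
      base$log2_fold_change <- log2(fc)
      base$t_statistic <- ht$statistic
      base$p_value <- ht$p.value
      base$status <- "tested"
    } else if (nA >= 2L && nB < 2L) {
      base$status <- "exclusive_to_A"
    } else if (nB >= 2L && nA < 2L) {
      base$status <- "exclusive_to_B"
    }
    base
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  tested <- out$status == "tested"
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out$significant <- tested & out$p_value < p_threshold &
    pmax(out$fold_change, 1 / out$fold_change) > fc_threshold
  # order: tested by (p, -|log2FC|, id), then exclusives, then filtered by id
  rank_status <- match(out$status, c("tested", "exclusive_to_A",
                                     "exclusive_to_B", "filtered"))
  ord <- order(rank_status, out$p_value, -abs(out$log2_fold_change),
               out$metabolite_id, na.last = TRUE)
  out <- out[ord, c("metabolite_id", "mean_score_A", "mean_score_B",
                    "fold_change", "log2_fold_change", "t_statistic",
                    "p_value", "q_value", "n_A", "n_B", "status",
                    "significant")]
  rownames(out) <- NULL
  structure(out, groups = list(A = group_A, B = group_B),
            p_threshold = p_threshold, fc_threshold = fc_threshold,
            test = test, class = c("trace_diff", "data.frame"))
}

#' @export
print.trace_diff <- function(x, ...) {
  cat(sprintf("<trace_diff> %d metabolites (%s t-test; p < %g, FC > %g)\n",
              nrow(x), attr(x, "test"), attr(x, "p_threshold"),
              attr(x, "fc_threshold")))
  cat(sprintf("  tested: %d  significant: %d  exclusive: %d  filtered: %d\n",
              sum(x$status == "tested"), sum(x$significant),
              sum(grepl("^exclusive", x$status)), sum(x$status == "filtered")))
  invisible(x)
}

#' Volcano plot of a differential labeling analysis
#'
#' @param x A `trace_diff` object.
#' @param label_significant Label significant points with metabolite ids.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.trace_diff <- function(x, label_significant = TRUE, ...) {
  tested <- x[x$status == "tested", ]
  if (!nrow(tested)) {
    stop("no tested metabolites to plot")
  }
  lp <- -log10(tested$p_value)
  graphics::plot(tested$log2_fold_change, lp,
                 xlab = "log2 fold change (B / A)",
                 ylab = "-log10 p value",
                 pch = 19,
                 col = ifelse(tested$significant, "firebrick", "grey40"), ...)
  graphics::abline(h = -log10(attr(x, "p_threshold")), lty = 2)
  graphics::abline(v = c(-1, 1) * log2(attr(x, "fc_threshold")), lty = 2)
  if (label_significant && any(tested$significant)) {
    sig <- tested[tested$significant, ]
    graphics::text(sig$log2_fold_change, -log10(sig$p_value),
                   labels = sig$metabolite_id, pos = 3, cex = 0.7)
  }
  invisible(x)
}

#' Concordance between two conditions by ordinary least squares
#'
#' Inner-joins two per-metabolite vectors (e.g. mean total labeling under two
#' preconditioning times), fits `y ~ x` by OLS, and reports the Pearson
#' correlation, r squared, slope, intercept and the regression p-value for a
#' non-zero slope.
#'
#' @param scores_x,scores_y Named numeric vectors keyed by metabolite id.
#' @return Object of class `concordance_result`: list with `r`, `r_squared`,
#'   `slope`, `intercept`, `regression_p_value`, `n_points`.
#' @export
concordance <- function(scores_x, scores_y) {
  if (is.null(names(scores_x)) || is.null(names(scores_y))) {
    stop("scores_x and scores_y must be named by metabolite id")
  }
  shared <- intersect(names(scores_x), names(scores_y))
  x <- scores_x[shared]; y <- scores_y[shared]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop(sprintf("need >= 3 shared metabolites; have %d", length(x)))
  }
  if (stats::var(x) == 0) stop("zero variance in x; regression undefined")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  p <- summary(fit)$coefficients["x", "Pr(>|t|)"]
  structure(list(r = r, r_squared = r^2,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 regression_p_value = p, n_points = length(x)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance> n = %d  r = %.4f  r^2 = %.4f  slope = %.4f  intercept = %.4f  p = %.3g\n",
              x$n_points, x$r, x$r_squared, x$slope, x$intercept,
              x$regression_p_value))
  invisible(x)
}

#' Per-metabolite group comparison (ANOVA or t-test)
#'
#' Figure-panel style test for a single metabolite's scores across groups:
#' classic one-way ANOVA for three or more groups, or the same unpaired
#' two-sample t-test as [compare_models()] for two groups.
#'
#' @param scores A `labeling_scores` table.
#' @param metabolite_id Metabolite to test.
#' @param groups Named list of sample-id vectors, each of length >= 2.
#' @param design `"auto"` (default: ANOVA for >= 3 groups, t-test for 2),
#'   `"one_way_anova"`, or `"t_test"`.
#' @param test t-test flavour when two groups: `"pooled"` or `"welch"`.
#' @return List with `metabolite_id`, `design`, `statistic` (F or t),
#'   `p_value`, `group_means`, `n`.
#' @export
paired_metabolite_test <- function(scores, metabolite_id, groups,
                                   design = c("auto", "one_way_anova", "t_test"),
                                   test = c("pooled", "welch")) {
  stopifnot(inherits(scores, "labeling_scores"))
  design <- match.arg(design)
  test <- match.arg(test)
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  vals <- lapply(groups, function(g) {
    s <- scores$score[scores$metabolite_id == metabolite_id &
                        scores$sample_id %in% g & !is.na(scores$score)]
    s
  })
  ns <- lengths(vals)
  if (any(ns < 2L)) {
    stop("group(s) with < 2 scored samples: ",
         paste(names(groups)[ns < 2L], collapse = ", "))
  }
  if (design == "auto") design <- if (length(groups) >= 3L) "one_way_anova" else "t_test"
  if (design == "t_test") {
    if (length(groups) != 2L) stop("t_test design requires exactly 2 groups")
    ht <- two_sample_t(vals[[1L]], vals[[2L]], pooled = test == "pooled")
    stat <- ht$statistic; p <- ht$p.value
  } else {
    y <- unlist(vals, use.names = FALSE)
    g <- factor(rep(names(groups), ns))
    if (stats::var(y) == 0) {
      stat <- 0; p <- 1
    } else {
      ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  }
  list(metabolite_id = metabolite_id, design = design, statistic = stat,
       p_value = p, group_means = vapply(vals, mean, numeric(1)), n = ns)
}

#' Write a differential analysis table to TSV
#'
#' @param diff A `trace_diff` object.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_diff <- function(diff, path) {
  stopifnot(inherits(diff, "trace_diff"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fold_change = group_B / group_A; test = %s; p < %g; FC > %g",
                     attr(diff, "test"), attr(diff, "p_threshold"),
                     attr(diff, "fc_threshold")), con)
  utils::write.table(as.data.frame(diff), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a concordance result to TSV
#'
#' @param cc A `concordance_result`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_concordance <- function(cc, path) {
  stopifnot(inherits(cc, "concordance_result"))
  write_tsv(data.frame(r = cc$r, r_squared = cc$r_squared, slope = cc$slope,
                       intercept = cc$intercept,
                       p_value = cc$regression_p_value,
                       n_points = cc$n_points), path)
  invisible(path)
}
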
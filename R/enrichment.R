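# Squared two-sample Welch t statistics for every row of Y under a group split.
# Y: members x samples matrix; selA: logical selector of group-A columns.
# Zero-variance rows: 0 when the group means agree, Inf otherwise.
row_t_squared <- function(Y, selA) {
  Ya <- Y[, selA, drop = FALSE]
  Yb <- Y[, !selA, drop = FALSE]
  nA <- ncol(Ya); nB <- ncol(Yb)
  ma <- rowMeans(Ya); mb <- rowMeans(Yb)
  va <- (rowSums(Ya^2) - nA * ma^2) / (nA - 1)
  vb <- (rowSums(Yb^2) - nB * mb^2) / (nB - 1)
  va[va < 0] <- 0; vb[vb < 0] <- 0   # guard fp cancellation
  se2 <- va / nA + vb / nB
  d2 <- (ma - mb)^2
  t2 <- ifelse(se2 > 0, d2 / se2, ifelse(d2 > 0, Inf, 0))
  t2
}

#' Quantitative metabolite set enrichment analysis by permutation
#'
#' Tests each metabolite set for association between its members' Metabolite
#' Labeling Scores and group membership. The set statistic is the mean, over
#' tested members, of the squared two-sample (Welch) t statistic of that
#' member's scores between the groups — a quadratic association statistic.
#' The null distribution is generated by permuting the sample group labels
#' jointly across all metabolites, which preserves inter-metabolite
#' correlation. When the number of distinct label assignments
#' `choose(n_A + n_B, n_A)` is at most `exhaustive_limit`, all assignments are
#' enumerated and p-values are exact multiples of `1 / n_assignments`;
#' otherwise `n_permutations` random assignments are drawn and
#' `p = (1 + #(perm >= obs)) / (1 + n_permutations)`.
#'
#' Scores enter "as is": no additional normalization, filtering or scaling is
#' applied beyond the score table's own quality filters. A member is tested
#' only if it has a score in every sample of both groups (keeping the joint
#' permutation exchangeable); unmatched or incomplete members are reported,
#' never silently dropped.
#'
#' @param scores A `labeling_scores` table.
#' @param sets A `metabolite_sets` object (see [read_metabolite_sets()]) or a
#'   named list of member-id character vectors.
#' @param group_A,group_B Character vectors of traced sample ids.
#' @param n_permutations Number of random permutations when not exhaustive
#'   (default 9999).
#' @param seed Integer seed; identical seed and inputs give identical results.
#' @param exhaustive_limit Enumerate all label assignments when
#'   `choose(n, n_A)` is at most this (default 10000).
#' @param synonyms Optional named character vector mapping set-member names to
#'   dataset metabolite ids (applied before case-insensitive matching).
#' @return Object of class `qea_result`: `data.frame` with `set_name`,
#'   `n_members_tested`, `set_statistic`, `p_value`, `q_value`, `status`
#'   (`tested` / `untestable`), `members_tested` and `members_unmatched`
#'   (semicolon-joined); attribute `exhaustive` records the null mode.
#' @export
run_qea <- function(scores, sets, group_A, group_B, n_permutations = 9999,
                    seed = 1L, exhaustive_limit = 10000,
                    synonyms = NULL) {
  stopifnot(inherits(scores, "labeling_scores"))
  if (length(intersect(group_A, group_B))) stop("groups overlap")
  if (length(group_A) < 2L || length(group_B) < 2L) {
    stop("each group needs >= 2 traced samples")
  }
  if (inherits(sets, "metabolite_sets")) {
    member_lists <- lapply(sets, `[[`, "member_ids")
  } else {
    member_lists <- sets
  }
  if (is.null(names(member_lists)) || any(!nzchar(names(member_lists)))) {
    stop("sets must be named")
  }

  samp <- c(group_A, group_B)
  nA <- length(group_A)
  selA_obs <- c(rep(TRUE, nA), rep(FALSE, length(group_B)))

  # members x samples score matrix, complete cases only
  mets <- unique(scores$metabolite_id)
  Y <- matrix(NA_real_, length(mets), length(samp),
              dimnames = list(mets, samp))
  sub <- scores[scores$sample_id %in% samp, ]
  Y[cbind(match(sub$metabolite_id, mets), match(sub$sample_id, samp))] <- sub$score
  complete <- rowSums(is.na(Y)) == 0L
  Yc <- Y[complete, , drop = FALSE]
  avail <- rownames(Yc)
  lut <- stats::setNames(avail, tolower(avail))

  resolve <- function(ids) {
    if (!is.null(synonyms)) {
      hit <- ids %in% names(synonyms)
      ids[hit] <- unname(synonyms[ids[hit]])
    }
    matched <- unname(lut[tolower(ids)])
    list(tested = matched[!is.na(matched)], unmatched = ids[is.na(matched)])
  }
  resolved <- lapply(member_lists, resolve)

  # null splits
  n <- length(samp)
  n_all <- choose(n, nA)
  exhaustive <- n_all <= exhaustive_limit
  if (exhaustive) {
    combos <- utils::combn(n, nA)
    splits <- lapply(seq_len(ncol(combos)), function(k) {
      sel <- rep(FALSE, n); sel[combos[, k]] <- TRUE; sel
    })
    message(sprintf("run_qea: exhaustive enumeration of %d label assignments", n_all))
  } else {
    set.seed(seed)
    splits <- lapply(seq_len(n_permutations), function(k) {
      sel <- rep(FALSE, n); sel[sample.int(n, nA)] <- TRUE; sel
    })
  }

  if (nrow(Yc) > 0L) {
    t2_obs <- row_t_squared(Yc, selA_obs)
    t2_perm <- vapply(splits, function(sel) row_t_squared(Yc, sel),
                      numeric(nrow(Yc)))
    t2_perm <- matrix(t2_perm, nrow = nrow(Yc))
    rownames(t2_perm) <- rownames(Yc)
  }

  rows <- lapply(names(resolved), function(nm) {
    tested <- resolved[[nm]]$tested
    unmatched <- resolved[[nm]]$unmatched
    if (!length(tested)) {
      return(data.frame(set_name = nm, n_members_tested = 0L,
                        set_statistic = NA_real_, p_value = NA_real_,
                        status = "untestable",
                        members_tested = "",
                        members_unmatched = paste(unmatched, collapse = ";"),
                        stringsAsFactors = FALSE))
    }
    obs <- mean(t2_obs[tested])
    perm <- colMeans(t2_perm[tested, , drop = FALSE])
    p <- if (exhaustive) {
      mean(perm >= obs)
    } else {
      (1 + sum(perm >= obs)) / (1 + length(perm))
    }
    data.frame(set_name = nm, n_members_tested = length(tested),
               set_statistic = obs, p_value = p, status = "tested",
               members_tested = paste(tested, collapse = ";"),
               members_unmatched = paste(unmatched, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  tst <- out$status == "tested"
  out$q_value[tst] <- stats::p.adjust(out$p_value[tst], method = "BH")
  out <- out[order(!tst, out$p_value, out$set_name),
             c("set_name", "n_members_tested", "set_statistic", "p_value",
               "q_value", "status", "members_tested", "members_unmatched")]
  rownames(out) <- NULL
  structure(out, exhaustive = exhaustive,
            n_null = if (exhaustive) n_all else n_permutations,
            groups = list(A = group_A, B = group_B), seed = seed,
            class = c("qea_result", "data.frame"))
}

#' @export
print.qea_result <- function(x, ...) {
  cat(sprintf("<qea_result> %d set(s); null: %s (%d assignments)\n",
              nrow(x), if (attr(x, "exhaustive")) "exhaustive" else "sampled",
              attr(x, "n_null")))
  print(as.data.frame(x)[, c("set_name", "n_members_tested", "set_statistic",
                             "p_value", "q_value", "status")])
  invisible(x)
}

#' Write a QEA result table to TSV
#'
#' @param qea A `qea_result`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_enrichment <- function(qea, path) {
  stopifnot(inherits(qea, "qea_result"))
  write_tsv(as.data.frame(qea), path)
  invisible(path)
}
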
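#' Define a nitrogen-transfer network for label simulation
#'
#' A network is a set of metabolites (with baseline pool sizes and per-pool
#' "fraction new" mixing parameters), a set of positional transfer rules, and
#' a tracer entry point. Each rule maps labelable positions of a product to
#' positions of one precursor; a product molecule synthesized during the
#' tracing window draws one molecule from each precursor rule's pool
#' (positions within a rule stay correlated; draws across rules are
#' independent). Product positions not covered by any rule come from the
#' unlabeled pool. The transfer graph must be acyclic from the tracer entry,
#' so steady-state propagation is well defined in topological order.
#'
#' @param metabolites `data.frame` with columns `metabolite_id`, `formula`,
#'   `tracer_atom_count`, `pool_size`, `fraction_new`, `pathway`.
#' @param rules List of rules; each a list with `product`, `precursor` and
#'   `positions`, a named integer vector mapping product position (name) to
#'   precursor position (value), 1-based.
#' @param tracer_entry List with `metabolite_id`, `enrichment` in \[0, 1\] and
#'   `mode`: `"joint"` (all positions labeled together, e.g. a 15N2 tracer
#'   measured as pure M+n) or `"independent"` (each position labeled
#'   independently).
#' @param tracer_element Tracer element symbol (default `"N"`).
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(metabolites, rules, tracer_entry,
                         tracer_element = "N") {
  need <- c("metabolite_id", "formula", "tracer_atom_count", "pool_size",
            "fraction_new", "pathway")
  miss <- setdiff(need, names(metabolites))
  if (length(miss)) stop("metabolites table missing: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metabolites$metabolite_id)) stop("duplicate metabolite ids")
  if (any(metabolites$pool_size < 0)) stop("pool sizes must be >= 0")
  fn <- metabolites$fraction_new
  if (any(!is.na(fn) & (fn < 0 | fn > 1))) stop("fraction_new must lie in [0, 1]")
  # validate formulas / tracer counts
  specs <- mapply(molecule_spec, metabolites$metabolite_id, metabolites$formula,
                  metabolites$tracer_atom_count,
                  MoreArgs = list(tracer_element = tracer_element),
                  SIMPLIFY = FALSE)
  names(specs) <- metabolites$metabolite_id
  nlab <- stats::setNames(metabolites$tracer_atom_count,
                          metabolites$metabolite_id)

  if (!is.list(tracer_entry) ||
      !all(c("metabolite_id", "enrichment") %in% names(tracer_entry))) {
    stop("tracer_entry needs metabolite_id and enrichment")
  }
  if (is.null(tracer_entry$mode)) tracer_entry$mode <- "joint"
  if (!tracer_entry$mode %in% c("joint", "independent")) {
    stop("tracer_entry mode must be 'joint' or 'independent'")
  }
  e <- tracer_entry$enrichment
  if (is.na(e) || e < 0 || e > 1) stop("tracer enrichment must lie in [0, 1]")
  if (!(tracer_entry$metabolite_id %in% metabolites$metabolite_id)) {
    stop("tracer entry metabolite absent from metabolite table")
  }

  covered <- list()
  for (r in rules) {
    if (!all(c("product", "precursor", "positions") %in% names(r))) {
      stop("each rule needs product, precursor and positions")
    }
    for (id in c(r$product, r$precursor)) {
      if (!(id %in% metabolites$metabolite_id)) {
        stop(sprintf("rule references unknown metabolite '%s'", id))
      }
    }
    pp <- as.integer(names(r$positions))
    qq <- as.integer(r$positions)
    if (any(is.na(pp)) || any(pp < 1L) || any(pp > nlab[[r$product]])) {
      stop(sprintf("rule %s <- %s: product positions out of range",
                   r$product, r$precursor))
    }
    if (any(is.na(qq)) || any(qq < 1L) || any(qq > nlab[[r$precursor]])) {
      stop(sprintf("rule %s <- %s: precursor positions out of range",
                   r$product, r$precursor))
    }
    seen <- covered[[r$product]]
    if (any(pp %in% seen)) {
      stop(sprintf("product '%s': position mapped more than once", r$product))
    }
    covered[[r$product]] <- c(seen, pp)
  }

  # acyclicity (Kahn) over product <- precursor edges
  edges <- unique(do.call(rbind, lapply(rules, function(r) {
    data.frame(from = r$precursor, to = r$product, stringsAsFactors = FALSE)
  })))
  if (!is.null(edges) && nrow(edges)) {
    nodes <- unique(c(edges$from, edges$to))
    indeg <- stats::setNames(vapply(nodes, function(v) sum(edges$to == v),
                                    integer(1)), nodes)
    queue <- names(indeg)[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
      outs <- edges$to[edges$from == v]
      for (w in outs) {
        indeg[[w]] <- indeg[[w]] - 1L
        if (indeg[[w]] == 0L) queue <- c(queue, w)
      }
    }
    if (seen < length(nodes)) stop("transfer network contains a cycle")
  }

  structure(list(metabolites = metabolites, rules = rules,
                 tracer_entry = tracer_entry, specs = specs,
                 tracer_element = tracer_element),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d metabolites, %d transfer rules; tracer entry %s (e = %g, %s)\n",
              nrow(x$metabolites), length(x$rules),
              x$tracer_entry$metabolite_id, x$tracer_entry$enrichment,
              x$tracer_entry$mode))
  invisible(x)
}

# convolve two distributions over disjoint bit masks (masks add)
mask_convolve <- function(d1, d2) {
  out <- numeric(length(d1))
  nz1 <- which(d1 > 0); nz2 <- which(d2 > 0)
  for (i in nz1) for (j in nz2) {
    m <- (i - 1L) + (j - 1L)
    out[m + 1L] <- out[m + 1L] + d1[i] * d2[j]
  }
  out
}

#' Propagate tracer label through a network at steady state
#'
#' Computes, for every metabolite, the exact joint distribution over
#' position-label configurations and the implied true isotopologue
#' distribution. Each pool mixes a "new" (synthesized during the tracing
#' window) component with fraction `fraction_new * multiplier[pathway]`
#' (capped at 1) and a pre-existing unlabeled component. A pathway multiplier
#' of 0 therefore switches that route's downstream labeling off entirely.
#'
#' @param network A [network_spec()].
#' @param multipliers Named numeric vector of pathway activity multipliers
#'   (missing pathways default to 1).
#' @param enrichment Optional override of the tracer entry enrichment
#'   (e.g. 0 for the tracer-free condition).
#' @return Named list per metabolite: `state` (probabilities over the
#'   `2^n` position-label masks) and `iso` (true isotopologue fractions,
#'   length `n + 1`, summing to 1).
#' @export
propagate_labels <- function(network, multipliers = NULL, enrichment = NULL) {
  stopifnot(inherits(network, "network_spec"))
  mets <- network$metabolites
  e <- if (is.null(enrichment)) network$tracer_entry$enrichment else enrichment
  if (e < 0 || e > 1) stop("enrichment must lie in [0, 1]")
  mult <- function(pw) {
    if (is.null(multipliers) || !(pw %in% names(multipliers))) 1 else multipliers[[pw]]
  }
  if (!is.null(multipliers) && any(multipliers < 0)) {
    stop("activity multipliers must be >= 0")
  }

  # topological order: repeatedly emit metabolites whose precursors are done
  ids <- mets$metabolite_id
  pre <- lapply(ids, function(m) {
    unique(vapply(Filter(function(r) r$product == m, network$rules),
                  `[[`, character(1), "precursor"))
  })
  names(pre) <- ids
  done <- character(0)
  order_ids <- character(0)
  while (length(order_ids) < length(ids)) {
    ready <- ids[!(ids %in% order_ids) &
                   vapply(ids, function(m) all(pre[[m]] %in% done), logical(1))]
    if (!length(ready)) stop("transfer network contains a cycle")
    order_ids <- c(order_ids, ready)
    done <- c(done, ready)
  }

  states <- list()
  for (m in order_ids) {
    n <- mets$tracer_atom_count[mets$metabolite_id == m]
    size <- 2^n
    if (m == network$tracer_entry$metabolite_id) {
      st <- numeric(size)
      if (network$tracer_entry$mode == "joint" || n <= 1L) {
        st[1L] <- 1 - e
        st[size] <- st[size] + e
      } else {
        for (mask in 0:(size - 1L)) {
          k <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L)
          st[mask + 1L] <- e^k * (1 - e)^(n - k)
        }
      }
    } else {
      my_rules <- Filter(function(r) r$product == m, network$rules)
      if (!length(my_rules)) {
        st <- c(1, numeric(size - 1L))
      } else {
        newd <- c(1, numeric(size - 1L))
        for (r in my_rules) {
          ps <- states[[r$precursor]]
          contrib <- numeric(size)
          pp <- as.integer(names(r$positions))
          qq <- as.integer(r$positions)
          for (pm in seq_along(ps)) {
            q <- ps[pm]
            if (q <= 0) next
            bits <- bitwAnd(pm - 1L, bitwShiftL(1L, qq - 1L)) > 0L
            mask <- sum(bitwShiftL(1L, pp[bits] - 1L))
            contrib[mask + 1L] <- contrib[mask + 1L] + q
          }
          newd <- mask_convolve(newd, contrib)
        }
        f <- mets$fraction_new[mets$metabolite_id == m]
        if (is.na(f)) f <- 1
        f <- min(1, f * mult(mets$pathway[mets$metabolite_id == m]))
        st <- f * newd
        st[1L] <- st[1L] + (1 - f)
      }
    }
    states[[m]] <- st
  }

  lapply(states[ids], function(st) {
    n <- round(log2(length(st)))
    pops <- vapply(seq_along(st) - 1L, function(mask) {
      if (n == 0L) 0L else sum(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L)
    }, integer(1))
    iso <- vapply(0:n, function(k) sum(st[pops == k]), numeric(1))
    list(state = st, iso = iso)
  })
}

#' Define a simulation scenario
#'
#' @param groups List of group definitions; each a list with `name`,
#'   `n_replicates`, optional `multipliers` (named numeric pathway activity
#'   multipliers, default all 1) and optional `undetectable` (metabolite ids
#'   measured as all-zero in that group).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied to every intensity (default 0.10).
#' @param unlabeled_replicates Tracer-free replicates per group (default 2).
#' @param precondition_hours Either a single value for all groups or a vector,
#'   one per group (default 120).
#' @param seed Integer seed for the simulator's randomness.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(groups, noise_cv = 0.10, unlabeled_replicates = 2L,
                            precondition_hours = 120, seed = 1L) {
  if (!length(groups)) stop("need at least one group")
  for (g in groups) {
    if (!all(c("name", "n_replicates") %in% names(g))) {
      stop("each group needs name and n_replicates")
    }
    if (!is.null(g$multipliers) && any(g$multipliers < 0)) {
      stop("activity multipliers must be >= 0")
    }
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  ph <- rep_len(precondition_hours, length(groups))
  structure(list(groups = groups, noise_cv = noise_cv,
                 unlabeled_replicates = as.integer(unlabeled_replicates),
                 precondition_hours = ph, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a raw isotopologue tracing dataset
#'
#' For each group: (1) propagates the tracer through the network under the
#' group's pathway multipliers to obtain true isotopologue distributions
#' ([propagate_labels()]); (2) the tracer-free condition uses enrichment 0;
#' (3) forward-convolves each true distribution with natural abundance
#' (all-elements mode, the full measured spectrum); (4) scales by pool size
#' and applies multiplicative lognormal noise with the configured CV to every
#' intensity, zeroing metabolites flagged undetectable in that group; (5)
#' emits the ground truth (true total labeling, true score relative to the
#' reference metabolite, and per-metabolite differential flags). Deterministic
#' given `scenario$seed`.
#'
#' @param network A [network_spec()].
#' @param scenario A [scenario_config()].
#' @param reference Reference metabolite for true scores (default
#'   `"glutamate"`).
#' @param abundances Abundance table for the forward convolution.
#' @return List of class `trace_simulation` with elements `dataset` (a
#'   [tracing_dataset()]) and `truth` (`data.frame`: `metabolite_id`, `group`,
#'   `pathway`, `detectable`, `true_total_labeling`, `true_score`,
#'   `differential`).
#' @export
simulate_dataset <- function(network, scenario, reference = "glutamate",
                             abundances = natural_abundance()) {
  stopifnot(inherits(network, "network_spec"),
            inherits(scenario, "scenario_config"))
  set.seed(scenario$seed)
  mets <- network$metabolites
  ids <- mets$metabolite_id
  cv <- scenario$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2

  # measured (natural-abundance convolved) fractions per metabolite, given iso
  fwd <- lapply(ids, function(m) {
    correction_matrix(network$specs[[m]], abundances = abundances,
                      mode = "all-elements")
  })
  names(fwd) <- ids

  truth_rows <- list()
  sample_rows <- list()
  int_rows <- list()
  unlab <- propagate_labels(network, enrichment = 0)

  for (gi in seq_along(scenario$groups)) {
    g <- scenario$groups[[gi]]
    tr <- propagate_labels(network, multipliers = g$multipliers)
    undet <- if (is.null(g$undetectable)) character(0) else g$undetectable
    tl <- vapply(ids, function(m) 1 - tr[[m]]$iso[1L], numeric(1))
    ref_tl <- tl[[reference]]
    truth_rows[[gi]] <- data.frame(
      metabolite_id = ids, group = g$name, pathway = mets$pathway,
      detectable = !(ids %in% undet),
      true_total_labeling = tl,
      true_score = if (ref_tl > 0) tl / ref_tl else NA_real_,
      stringsAsFactors = FALSE)

    emit <- function(condition, n_rep, props) {
      for (r in seq_len(n_rep)) {
        sid <- sprintf("%s_%s_%d", g$name, condition, r)
        sample_rows[[length(sample_rows) + 1L]] <<- data.frame(
          sample_id = sid, model_system = g$name, tracer_condition = condition,
          precondition_hours = scenario$precondition_hours[gi], replicate = r,
          stringsAsFactors = FALSE)
        for (m in ids) {
          n <- mets$tracer_atom_count[ids == m]
          pool <- mets$pool_size[ids == m]
          meas <- as.numeric(fwd[[m]] %*% props[[m]]$iso)
          inten <- pool * meas
          if (cv > 0) {
            inten <- inten * stats::rlnorm(length(inten), meanlog, sdlog)
          }
          if (m %in% undet) inten <- numeric(length(inten))
          int_rows[[length(int_rows) + 1L]] <<- data.frame(
            metabolite_id = m, sample_id = sid, isotopologue = 0:n,
            intensity = inten, stringsAsFactors = FALSE)
        }
      }
    }
    emit("traced", g$n_replicates, tr)
    if (scenario$unlabeled_replicates > 0L) {
      emit("unlabeled", scenario$unlabeled_replicates, unlab)
    }
  }

  truth <- do.call(rbind, truth_rows)
  # differential flag: any group pair with exclusivity or true-score ratio
  # beyond 1.25 (or labeling present in one group only)
  diff_flag <- vapply(ids, function(m) {
    sub <- truth[truth$metabolite_id == m, ]
    if (nrow(sub) < 2L) return(FALSE)
    for (i in seq_len(nrow(sub) - 1L)) for (j in (i + 1L):nrow(sub)) {
      a <- sub[i, ]; b <- sub[j, ]
      if (a$detectable != b$detectable) return(TRUE)
      if (!a$detectable) next
      ta <- a$true_total_labeling; tb <- b$true_total_labeling
      if ((ta == 0) != (tb == 0)) return(TRUE)
      if (ta == 0) next
      sa <- a$true_score; sb <- b$true_score
      if (max(sa / sb, sb / sa) > 1.25) return(TRUE)
    }
    FALSE
  }, logical(1))
  truth$differential <- diff_flag[truth$metabolite_id]
  rownames(truth) <- NULL

  ds <- tracing_dataset(
    molecules = mets[, c("metabolite_id", "formula", "tracer_atom_count")],
    samples = do.call(rbind, sample_rows),
    intensities = do.call(rbind, int_rows),
    tracer_element = network$tracer_element)

  structure(list(dataset = ds, truth = truth), class = "trace_simulation")
}

#' @export
print.trace_simulation <- function(x, ...) {
  cat("<trace_simulation>\n")
  print(x$dataset)
  cat(sprintf("  ground-truth differential metabolites: %s\n",
              paste(unique(x$truth$metabolite_id[x$truth$differential]),
                    collapse = ", ")))
  invisible(x)
}

# Pedagogical 15N2-glutamine nitrogen-transfer network: glutamine feeds
# glutamate (amine N) and, via its amide N, de novo purine and pyrimidine
# synthesis; degradation products and GDP-mannose hang downstream. Atom
# mappings are textbook-level, not mechanistic stoichiometries.
glutamine_network <- function(enrichment = 0.4, mode = "joint") {
  metabolites <- data.frame(
    metabolite_id = c("glutamine", "glutamate", "aspartate", "alanine",
                      "serine", "glycine", "proline", "ornithine",
                      "citrulline", "argininosuccinate", "IMP", "AMP", "GMP",
                      "adenosine", "hypoxanthine", "GDP-mannose", "UMP",
                      "uridine", "uracil", "DHU"),
    formula = c("C5H10N2O3", "C5H9NO4", "C4H7NO4", "C3H7NO2", "C3H7NO3",
                "C2H5NO2", "C5H9NO2", "C5H12N2O2", "C6H13N3O3", "C10H18N4O6",
                "C10H13N4O8P", "C10H14N5O7P", "C10H14N5O8P", "C10H13N5O4",
                "C5H4N4O", "C16H25N5O16P2", "C9H13N2O9P", "C9H12N2O6",
                "C4H4N2O2", "C4H6N2O2"),
    tracer_atom_count = c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L,
                          3L, 2L, 3L, 2L, 2L, 2L, 2L),
    pool_size = c(2000, 5000, 1500, 3000, 1200, 2500, 800, 300, 250, 60,
                  400, 900, 500, 150, 120, 80, 600, 350, 200, 100),
    fraction_new = c(NA, 0.5, 0.4, 0.35, 0.3, 0.25, 0.3, 0.3, 0.3, 0.3,
                     0.6, 0.6, 0.6, 0.2, 0.2, 0.5, 0.5, 0.5, 0.7, 0.7),
    pathway = c("tracer", "core", "core", "core", "core", "core", "core",
                "urea_cycle", "urea_cycle", "urea_cycle",
                "purine_synthesis", "purine_synthesis", "purine_synthesis",
                "purine_degradation", "purine_degradation", "gdp_mannose",
                "pyrimidine_synthesis", "pyrimidine_synthesis",
                "pyrimidine_degradation", "pyrimidine_degradation"),
    stringsAsFactors = FALSE)

  rule <- function(product, precursor, positions) {
    list(product = product, precursor = precursor, positions = positions)
  }
  rules <- list(
    rule("glutamate", "glutamine", c(`1` = 1L)),
    rule("aspartate", "glutamate", c(`1` = 1L)),
    rule("alanine", "glutamate", c(`1` = 1L)),
    rule("serine", "glutamate", c(`1` = 1L)),
    rule("glycine", "serine", c(`1` = 1L)),
    rule("proline", "glutamate", c(`1` = 1L)),
    rule("ornithine", "glutamate", c(`1` = 1L)),
    rule("citrulline", "ornithine", c(`1` = 1L)),
    rule("argininosuccinate", "citrulline", c(`1` = 1L)),
    rule("argininosuccinate", "aspartate", c(`2` = 1L)),
    # two separate glutamine amide donations into the purine ring
    rule("IMP", "glutamine", c(`1` = 2L)),
    rule("IMP", "glutamine", c(`2` = 2L)),
    rule("AMP", "IMP", c(`1` = 1L, `2` = 2L)),
    rule("AMP", "aspartate", c(`3` = 1L)),
    rule("GMP", "IMP", c(`1` = 1L, `2` = 2L)),
    rule("GMP", "glutamine", c(`3` = 2L)),
    rule("adenosine", "AMP", c(`1` = 1L, `2` = 2L, `3` = 3L)),
    rule("hypoxanthine", "IMP", c(`1` = 1L, `2` = 2L)),
    rule("GDP-mannose", "GMP", c(`1` = 1L, `2` = 2L, `3` = 3L)),
    rule("UMP", "glutamine", c(`1` = 2L)),
    rule("UMP", "aspartate", c(`2` = 1L)),
    rule("uridine", "UMP", c(`1` = 1L, `2` = 2L)),
    rule("uracil", "uridine", c(`1` = 1L, `2` = 2L)),
    rule("DHU", "uracil", c(`1` = 1L, `2` = 2L))
  )
  network_spec(metabolites, rules,
               tracer_entry = list(metabolite_id = "glutamine",
                                   enrichment = enrichment, mode = mode))
}

#' Built-in simulation scenarios
#'
#' \describe{
#'   \item{`sxo_vs_gsc`}{Two model systems over a ~20-metabolite
#'     glutamine-nitrogen network: an explant-like group (`SXO_like`) with
#'     purine degradation at baseline, GDP-mannose present and pyrimidine
#'     degradation active, versus a monoculture-like group (`GSC_like`) with
#'     4-fold purine degradation, GDP-mannose undetectable and pyrimidine
#'     degradation off. Ground-truth differential metabolites: adenosine,
#'     hypoxanthine, GDP-mannose (exclusivity), uracil and DHU.}
#'   \item{`null`}{The same network with two identical groups — every
#'     differential flag false.}
#'   \item{`preconditioning_concordance`}{Two conditions (24 h vs 120 h
#'     preconditioning) with identical true labeling and independent noise,
#'     for concordance analysis.}
#' }
#'
#' @param name Preset name.
#' @param n_replicates Traced replicates per group (default 3).
#' @param noise_cv Lognormal intensity noise CV (default 0.10).
#' @param seed Simulator seed (default 1).
#' @param enrichment Tracer (glutamine M+2) enrichment (default 0.4).
#' @param unlabeled_replicates Tracer-free replicates per group (default 2).
#' @return List with elements `network` ([network_spec()]) and `scenario`
#'   ([scenario_config()]).
#' @export
preset_scenario <- function(name = c("sxo_vs_gsc", "null",
                                     "preconditioning_concordance"),
                            n_replicates = 3L, noise_cv = 0.10, seed = 1L,
                            enrichment = 0.4, unlabeled_replicates = 2L) {
  if (!is.character(name) || !(name[1L] %in% c("sxo_vs_gsc", "null",
                                               "preconditioning_concordance"))) {
    stop("unknown preset '", name[1L],
         "'; available: sxo_vs_gsc, null, preconditioning_concordance")
  }
  name <- match.arg(name)
  network <- glutamine_network(enrichment = enrichment)
  scenario <- switch(
    name,
    sxo_vs_gsc = scenario_config(
      groups = list(
        list(name = "SXO_like", n_replicates = n_replicates,
             multipliers = c(purine_degradation = 1, gdp_mannose = 1,
                             pyrimidine_degradation = 1)),
        list(name = "GSC_like", n_replicates = n_replicates,
             multipliers = c(purine_degradation = 4, gdp_mannose = 1,
                             pyrimidine_degradation = 0),
             undetectable = "GDP-mannose")),
      noise_cv = noise_cv, unlabeled_replicates = unlabeled_replicates,
      precondition_hours = 120, seed = seed),
    null = scenario_config(
      groups = list(
        list(name = "GroupA", n_replicates = n_replicates),
        list(name = "GroupB", n_replicates = n_replicates)),
      noise_cv = noise_cv, unlabeled_replicates = unlabeled_replicates,
      precondition_hours = 120, seed = seed),
    preconditioning_concordance = scenario_config(
      groups = list(
        list(name = "precond_24h", n_replicates = n_replicates),
        list(name = "precond_120h", n_replicates = n_replicates)),
      noise_cv = noise_cv, unlabeled_replicates = unlabeled_replicates,
      precondition_hours = c(24, 120), seed = seed)
  )
  list(network = network, scenario = scenario)
}

#' Metabolite sets matching the built-in network
#'
#' Pathway-level sets over the simulator's metabolites (purine metabolism,
#' purine degradation, pyrimidine metabolism, amino acids, urea cycle) for
#' exercising [run_qea()] without an external GMT file.
#'
#' @return A `metabolite_sets` object.
#' @export
preset_metabolite_sets <- function() {
  mk <- function(nm, desc, members) list(set_name = nm, description = desc,
                                         member_ids = members)
  sets <- list(
    mk("purine_metabolism", "purine nucleotides and degradation products",
       c("IMP", "AMP", "GMP", "adenosine", "hypoxanthine")),
    mk("purine_degradation", "purine degradation products",
       c("adenosine", "hypoxanthine")),
    mk("pyrimidine_metabolism", "pyrimidine synthesis and degradation",
       c("UMP", "uridine", "uracil", "DHU")),
    mk("amino_acid_metabolism", "nonessential amino acids",
       c("glutamate", "aspartate", "alanine", "serine", "glycine", "proline")),
    mk("urea_cycle", "urea cycle intermediates",
       c("ornithine", "citrulline", "argininosuccinate"))
  )
  names(sets) <- vapply(sets, `[[`, character(1), "set_name")
  structure(sets, class = "metabolite_sets")
}

#' Read a custom transfer network from YAML
#'
#' Expected layout:
#' ```yaml
#' tracer_entry: {metabolite_id: glutamine, enrichment: 0.4, mode: joint}
#' metabolites:
#'   - {metabolite_id: glutamine, formula: C5H10N2O3, tracer_atom_count: 2,
#'      pool_size: 2000, fraction_new: ~, pathway: tracer}
#'   - {metabolite_id: glutamate, formula: C5H9NO4, tracer_atom_count: 1,
#'      pool_size: 5000, fraction_new: 0.5, pathway: core}
#' rules:
#'   - {product: glutamate, precursor: glutamine, positions: {1: 1}}
#' ```
#' `positions` maps product position to precursor position (1-based).
#'
#' @param path YAML file path.
#' @return A [network_spec()].
#' @export
read_network_yaml <- function(path) {
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  raw <- yaml::read_yaml(path, handlers = list("bool#no" = function(x) x,
                                               "bool#yes" = function(x) x))
  for (field in c("metabolites", "rules", "tracer_entry")) {
    if (is.null(raw[[field]])) stop(sprintf("network YAML missing '%s'", field))
  }
  mets <- do.call(rbind, lapply(raw$metabolites, function(m) {
    data.frame(metabolite_id = m$metabolite_id, formula = m$formula,
               tracer_atom_count = as.integer(m$tracer_atom_count),
               pool_size = as.numeric(m$pool_size),
               fraction_new = if (is.null(m$fraction_new)) NA_real_ else
                 as.numeric(m$fraction_new),
               pathway = m$pathway, stringsAsFactors = FALSE)
  }))
  rules <- lapply(raw$rules, function(r) {
    pos <- unlist(r$positions)
    list(product = r$product, precursor = r$precursor,
         positions = stats::setNames(as.integer(pos), names(pos)))
  })
  network_spec(mets, rules, tracer_entry = raw$tracer_entry)
}
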
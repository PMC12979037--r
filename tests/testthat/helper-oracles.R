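# Independent oracles used across the suite. These deliberately avoid the
# package's convolution/propagation code paths.

# Brute-force correction matrix: for column j, enumerate the isotope state of
# every relevant atom (the n - j unlabeled tracer atoms, plus every non-tracer
# atom in all-elements mode) and bin molecules by total mass shift.
oracle_correction_matrix <- function(formula_counts, n, abundances,
                                     mode = "tracer-only", tracer = "N") {
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    dists <- rep(list(abundances[[tracer]]), n - j)
    if (mode == "all-elements") {
      for (el in names(formula_counts)) {
        k <- formula_counts[[el]] - if (el == tracer) n else 0L
        if (k > 0L) dists <- c(dists, rep(list(abundances[[el]]), k))
      }
    }
    if (!length(dists)) {
      M[j + 1L, j + 1L] <- 1
      next
    }
    states <- do.call(expand.grid, lapply(dists, function(d) seq_along(d) - 1L))
    probs <- rep(1, nrow(states))
    for (cidx in seq_along(dists)) {
      probs <- probs * dists[[cidx]][states[[cidx]] + 1L]
    }
    shift <- rowSums(states)
    for (s in 0:(n - j)) {
      M[j + 1L + s, j + 1L] <- sum(probs[shift == s])
    }
  }
  M
}

# random molecule generator for correction-matrix checks
random_molecule <- function(i, max_n = 10L, small = FALSE) {
  if (small) {
    # <= 12 atoms so the all-elements enumeration oracle stays tractable
    nC <- sample(0:4, 1); nH <- sample(0:4, 1); nN <- sample(1:3, 1)
    nO <- sample(0:2, 1)
  } else {
    nC <- sample(0:20, 1); nH <- sample(0:30, 1); nN <- sample(1:10, 1)
    nO <- sample(0:10, 1)
  }
  counts <- c(C = nC, H = nH, N = nN, O = nO)
  counts <- counts[counts > 0]
  n <- sample(0:min(nN, max_n), 1)
  molecule_spec(sprintf("mol%d", i), counts, n)
}

# closed-form pooled-variance two-sample t (textbook formula)
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# closed-form one-way ANOVA decomposition
oracle_anova_f <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# closed-form simple linear regression / Pearson r from raw sums
oracle_regression <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  list(r = sxy / sqrt(sxx * syy), slope = sxy / sxx,
       intercept = mean(y) - (sxy / sxx) * mean(x))
}

# Monte Carlo oracle for label propagation: literally follows the generative
# story (a pool molecule is old-and-unlabeled with prob 1 - f, otherwise newly
# made by drawing one fresh molecule from each precursor rule's pool).
oracle_sample_iso <- function(network, metabolite, multipliers = NULL,
                              enrichment = NULL, n_draws = 20000L, seed = 1L) {
  set.seed(seed)
  mets <- network$metabolites
  nlab <- setNames(mets$tracer_atom_count, mets$metabolite_id)
  fnew <- setNames(mets$fraction_new, mets$metabolite_id)
  pw <- setNames(mets$pathway, mets$metabolite_id)
  entry <- network$tracer_entry
  e <- if (is.null(enrichment)) entry$enrichment else enrichment
  mult <- function(p) {
    if (!is.null(multipliers) && p %in% names(multipliers)) multipliers[[p]] else 1
  }
  draw <- function(m) {
    n <- nlab[[m]]
    if (m == entry$metabolite_id) {
      if (identical(entry$mode, "independent")) return(runif(n) < e)
      return(rep(runif(1) < e, n))
    }
    bits <- rep(FALSE, n)
    rules <- Filter(function(r) r$product == m, network$rules)
    if (!length(rules)) return(bits)
    f <- fnew[[m]]
    if (is.na(f)) f <- 1
    f <- min(1, f * mult(pw[[m]]))
    if (runif(1) >= f) return(bits)
    for (r in rules) {
      pb <- draw(r$precursor)
      bits[as.integer(names(r$positions))] <- pb[as.integer(r$positions)]
    }
    bits
  }
  counts <- replicate(n_draws, sum(draw(metabolite)))
  vapply(0:nlab[[metabolite]], function(k) mean(counts == k), numeric(1))
}
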
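#' Build a natural-abundance correction matrix
#'
#' Constructs the lower-triangular matrix `M` with entry `(i, j)` equal to the
#' probability that a molecule carrying `j` tracer-derived labels is measured
#' at nominal mass shift `i`. Measured intensity vectors then satisfy
#' `raw = M %*% true` (up to truncation at shift `n`), and correction inverts
#' this relation ([correct_vector()]).
#'
#' Two modes:
#' \describe{
#'   \item{`tracer-only`}{column `j` is the mass-shift distribution of the
#'     `n - j` unlabeled tracer-element atoms (for 15N, the binomial
#'     `Binom(n - j, a)` with `a` the heavy-isotope probability). Appropriate
#'     for high-resolution data where isotopologues of other elements are
#'     mass-resolved from the tracer series.}
#'   \item{`all-elements`}{that distribution convolved with the mass-shift
#'     distributions of every non-tracer atom in the formula, truncated at
#'     shift `n` (columns may then sum to less than 1). Appropriate for
#'     unit-resolution data.}
#' }
#' Labeled tracer atoms contribute no further shift.
#'
#' @param spec A [molecule_spec()].
#' @param abundances Abundance table (see [natural_abundance()]).
#' @param mode `"tracer-only"` (default) or `"all-elements"`.
#' @param max_isotopologues Safety cap on `n + 1` (default 64).
#' @return `(n+1) x (n+1)` lower-triangular numeric matrix with attributes
#'   `metabolite_id` and `mode`.
#' @export
correction_matrix <- function(spec, abundances = natural_abundance(),
                              mode = c("tracer-only", "all-elements"),
                              max_isotopologues = 64L) {
  stopifnot(inherits(spec, "molecule_spec"))
  mode <- match.arg(mode)
  validate_abundance(abundances)
  n <- spec$tracer_atom_count
  if (n + 1L > max_isotopologues) {
    stop(sprintf("n + 1 = %d exceeds the isotopologue cap (%d)",
                 n + 1L, max_isotopologues))
  }
  tr <- spec$tracer_element
  if (!(tr %in% names(abundances))) {
    stop(sprintf("tracer element '%s' absent from abundance table", tr))
  }
  tracer_dist <- abundances[[tr]]

  # mass-shift distribution of the non-tracer atoms (all-elements mode)
  other <- 1
  if (mode == "all-elements") {
    counts <- spec$formula
    for (el in names(counts)) {
      k <- counts[[el]] - if (el == tr) n else 0L
      if (k > 0L) {
        if (!(el %in% names(abundances))) {
          stop(sprintf("element '%s' absent from abundance table", el))
        }
        other <- convolve_dist(other, conv_pow(abundances[[el]], k))
      }
    }
  }

  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    col <- conv_pow(tracer_dist, n - j)
    if (mode == "all-elements") col <- convolve_dist(col, other)
    keep <- seq_len(min(length(col), n - j + 1L))
    M[j + keep, j + 1L] <- col[keep]
  }
  structure(M, metabolite_id = spec$metabolite_id, mode = mode)
}

# linear (open) convolution of two probability vectors
convolve_dist <- function(a, b) {
  if (length(a) == 1L) return(a * b)
  if (length(b) == 1L) return(a * b)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# k-fold self-convolution (k = 0 gives the identity distribution)
conv_pow <- function(d, k) {
  out <- 1
  for (i in seq_len(k)) out <- convolve_dist(out, d)
  out
}

#' Correct one raw isotopologue vector for natural abundance
#'
#' Solves `M x = raw` for `x >= 0` by non-negative least squares and
#' renormalizes to fractions. The exact triangular inverse is used when it is
#' already non-negative (it is then the NNLS optimum with zero residual);
#' otherwise the Lawson-Hanson NNLS solver runs. Noiseless inputs are
#' recovered exactly; noisy inputs never yield negative fractions.
#'
#' @param raw Numeric vector of raw intensities, length `n + 1`.
#' @param matrix Correction matrix from [correction_matrix()].
#' @param metabolite_id,sample_id Optional identifiers carried on the result.
#' @return Object of class `corrected_distribution`: list with `fractions`
#'   (simplex vector, or NA if undetected), `pool_size` (sum of raw
#'   intensities), `solver_residual` (relative L2 residual) and `undetected`.
#' @export
correct_vector <- function(raw, matrix, metabolite_id = attr(matrix, "metabolite_id"),
                           sample_id = NA_character_) {
  if (!is.numeric(raw)) stop("raw must be numeric")
  if (length(raw) != nrow(matrix)) {
    stop(sprintf("raw vector length (%d) does not match matrix dimension (%d)",
                 length(raw), nrow(matrix)))
  }
  if (any(is.na(raw)) || any(raw < 0)) stop("raw intensities must be non-negative")
  pool <- sum(raw)
  if (pool == 0) {
    return(structure(list(metabolite_id = metabolite_id, sample_id = sample_id,
                          fractions = rep(NA_real_, length(raw)),
                          pool_size = 0, solver_residual = 0,
                          undetected = TRUE),
                     class = "corrected_distribution"))
  }
  x <- forwardsolve(matrix, raw)
  if (any(x < 0)) {
    x <- pracma::lsqnonneg(unclass(matrix), raw)$x
  }
  x[x < 0] <- 0
  resid <- sqrt(sum((matrix %*% x - raw)^2)) / max(sqrt(sum(raw^2)), .Machine$double.eps)
  s <- sum(x)
  fr <- if (s > 0) x / s else rep(NA_real_, length(x))
  structure(list(metabolite_id = metabolite_id, sample_id = sample_id,
                 fractions = fr, pool_size = pool, solver_residual = resid,
                 undetected = s <= 0),
            class = "corrected_distribution")
}

#' @export
print.corrected_distribution <- function(x, ...) {
  if (x$undetected) {
    cat(sprintf("<corrected_distribution> %s / %s: undetected\n",
                x$metabolite_id, x$sample_id))
  } else {
    cat(sprintf("<corrected_distribution> %s / %s  pool=%.4g  resid=%.2e\n",
                x$metabolite_id, x$sample_id, x$pool_size, x$solver_residual))
    cat("  fractions:", paste(sprintf("M+%d=%.4f", seq_along(x$fractions) - 1L,
                                      x$fractions), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Fractional enrichment of one isotopologue
#'
#' @param dist A `corrected_distribution` (not flagged undetected).
#' @param i Isotopologue index, `0 <= i <= n`.
#' @return The corrected fraction `f_i` in \[0, 1\].
#' @export
fractional_enrichment <- function(dist, i) {
  stopifnot(inherits(dist, "corrected_distribution"))
  if (dist$undetected) {
    stop("distribution is flagged undetected; filter undetected metabolites first")
  }
  i <- as.integer(i)
  if (is.na(i) || i < 0L || i >= length(dist$fractions)) {
    stop(sprintf("isotopologue index %s out of range 0..%d",
                 i, length(dist$fractions) - 1L))
  }
  dist$fractions[i + 1L]
}

#' Total labeling of a corrected distribution
#'
#' Total fractional enrichment, `1 - f_0`: the fraction of molecules carrying
#' at least one tracer-derived heavy atom.
#'
#' @param dist A `corrected_distribution` (not flagged undetected).
#' @return Number in \[0, 1\].
#' @export
total_labeling <- function(dist) {
  stopifnot(inherits(dist, "corrected_distribution"))
  if (dist$undetected) {
    stop("distribution is flagged undetected; filter undetected metabolites first")
  }
  min(max(1 - dist$fractions[1L], 0), 1)
}

#' Correct every metabolite x sample vector in a dataset
#'
#' Builds one correction matrix per metabolite and applies [correct_vector()]
#' to each sample's raw vector.
#'
#' @param dataset A [tracing_dataset()].
#' @param mode Correction mode, as in [correction_matrix()].
#' @param abundances Abundance table.
#' @return Object of class `corrected_set`: list with `fractions` (long
#'   `data.frame`: `metabolite_id`, `sample_id`, `isotopologue`, `fraction`)
#'   and `summary` (`metabolite_id`, `sample_id`, `pool_size`, `residual`,
#'   `undetected`), plus the `mode` used.
#' @export
correct_dataset <- function(dataset, mode = c("tracer-only", "all-elements"),
                            abundances = natural_abundance()) {
  stopifnot(inherits(dataset, "tracing_dataset"))
  mode <- match.arg(mode)
  mets <- dataset$molecules$metabolite_id
  samps <- dataset$samples$sample_id
  ints <- dataset$intensities
  # fast lookup: intensities are ordered by metabolite, sample, isotopologue
  frac_rows <- vector("list", length(mets) * length(samps))
  sum_rows <- vector("list", length(mets) * length(samps))
  k <- 0L
  for (m in mets) {
    spec <- dataset$specs[[m]]
    M <- correction_matrix(spec, abundances = abundances, mode = mode)
    sub <- ints[ints$metabolite_id == m, ]
    for (s in samps) {
      raw <- sub$intensity[sub$sample_id == s][order(sub$isotopologue[sub$sample_id == s])]
      cd <- correct_vector(raw, M, metabolite_id = m, sample_id = s)
      k <- k + 1L
      frac_rows[[k]] <- data.frame(metabolite_id = m, sample_id = s,
                                   isotopologue = seq_along(cd$fractions) - 1L,
                                   fraction = cd$fractions,
                                   stringsAsFactors = FALSE)
      sum_rows[[k]] <- data.frame(metabolite_id = m, sample_id = s,
                                  pool_size = cd$pool_size,
                                  residual = cd$solver_residual,
                                  undetected = cd$undetected,
                                  stringsAsFactors = FALSE)
    }
  }
  structure(list(fractions = do.call(rbind, frac_rows),
                 summary = do.call(rbind, sum_rows),
                 mode = mode),
            class = "corrected_set")
}

#' @export
print.corrected_set <- function(x, ...) {
  nd <- sum(x$summary$undetected)
  cat(sprintf("<corrected_set> %d metabolite x sample distributions (%s mode), %d undetected\n",
              nrow(x$summary), x$mode, nd))
  invisible(x)
}

#' Extract one corrected distribution from a corrected set
#'
#' @param corrected A `corrected_set` from [correct_dataset()].
#' @param metabolite_id,sample_id Identifiers.
#' @return A `corrected_distribution`.
#' @export
corrected_distribution <- function(corrected, metabolite_id, sample_id) {
  stopifnot(inherits(corrected, "corrected_set"))
  srow <- corrected$summary$metabolite_id == metabolite_id &
    corrected$summary$sample_id == sample_id
  if (!any(srow)) {
    stop(sprintf("no corrected distribution for '%s' in sample '%s'",
                 metabolite_id, sample_id))
  }
  sm <- corrected$summary[srow, ]
  fr <- corrected$fractions[corrected$fractions$metabolite_id == metabolite_id &
                              corrected$fractions$sample_id == sample_id, ]
  fr <- fr$fraction[order(fr$isotopologue)]
  structure(list(metabolite_id = metabolite_id, sample_id = sample_id,
                 fractions = fr, pool_size = sm$pool_size,
                 solver_residual = sm$residual, undetected = sm$undetected),
            class = "corrected_distribution")
}

#' Per metabolite x sample total labeling and pool size
#'
#' @param corrected A `corrected_set`.
#' @return `data.frame` with `metabolite_id`, `sample_id`, `total_labeling`
#'   (NA when undetected), `pool_size`, `undetected`.
#' @export
total_labeling_table <- function(corrected) {
  stopifnot(inherits(corrected, "corrected_set"))
  f0 <- corrected$fractions[corrected$fractions$isotopologue == 0L, ]
  key <- paste(corrected$summary$metabolite_id, corrected$summary$sample_id,
               sep = "\r")
  idx <- match(key, paste(f0$metabolite_id, f0$sample_id, sep = "\r"))
  tl <- pmin(pmax(1 - f0$fraction[idx], 0), 1)
  data.frame(metabolite_id = corrected$summary$metabolite_id,
             sample_id = corrected$summary$sample_id,
             total_labeling = ifelse(corrected$summary$undetected, NA_real_, tl),
             pool_size = corrected$summary$pool_size,
             undetected = corrected$summary$undetected,
             stringsAsFactors = FALSE)
}

#' Write a corrected set to TSV
#'
#' Long output table: `metabolite_id`, `sample_id`, `isotopologue`,
#' `fraction`, `pool_size`, `residual`, `undetected_flag`.
#'
#' @param corrected A `corrected_set`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_corrected <- function(corrected, path) {
  stopifnot(inherits(corrected, "corrected_set"))
  fr <- corrected$fractions
  key <- paste(fr$metabolite_id, fr$sample_id, sep = "\r")
  skey <- paste(corrected$summary$metabolite_id, corrected$summary$sample_id,
                sep = "\r")
  idx <- match(key, skey)
  out <- data.frame(fr,
                    pool_size = corrected$summary$pool_size[idx],
                    residual = corrected$summary$residual[idx],
                    undetected_flag = corrected$summary$undetected[idx])
  write_tsv(out, path)
  invisible(path)
}
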
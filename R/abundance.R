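#' Natural isotope abundance table
#'
#' Per-element mass-shift distributions for the elements commonly found in
#' polar metabolites. Entry `i + 1` of each vector is the probability that a
#' single atom of that element carries a nominal mass shift of `i` relative to
#' its lightest isotope. Values are IUPAC representative isotopic
#' compositions (2021); the 15N heavy-isotope probability is 0.00364.
#'
#' The table can be overridden per analysis, e.g. from a YAML file via
#' [read_abundance_table()].
#'
#' @return Named list of numeric probability vectors, one per element symbol.
#' @examples
#' natural_abundance()$N # c(0.99636, 0.00364)
#' @export
natural_abundance <- function() {
  list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    P = 1,
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
}

#' Validate an abundance table
#'
#' Checks that every element's distribution has a mass-shift-0 entry, all
#' probabilities lie in \[0, 1\], and each distribution sums to 1 within 1e-9.
#'
#' @param abundances Named list of numeric vectors as in [natural_abundance()].
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_abundance <- function(abundances) {
  if (!is.list(abundances) || is.null(names(abundances)) ||
      any(!nzchar(names(abundances)))) {
    stop("abundance table must be a named list of numeric vectors")
  }
  for (el in names(abundances)) {
    p <- abundances[[el]]
    if (!is.numeric(p) || length(p) < 1L) {
      stop(sprintf("abundances for element '%s' must be a numeric vector", el))
    }
    if (any(p < 0) || any(p > 1)) {
      stop(sprintf("abundances for element '%s' outside [0, 1]", el))
    }
    if (p[1L] <= 0) {
      stop(sprintf("element '%s' lacks a mass-shift-0 isotope entry", el))
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("abundances for element '%s' sum to %.12f, not 1", el, sum(p)))
    }
  }
  invisible(abundances)
}

#' Read an abundance override table from YAML
#'
#' Expected YAML layout: a mapping from element symbol to a list of
#' `{shift: <int>, probability: <num>}` entries. Shifts absent from the list
#' get probability 0; the resulting vector is validated.
#'
#' @param path Path to the YAML file.
#' @return Named list of numeric vectors (same shape as [natural_abundance()]).
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("abundance file not found: %s", path))
  # keep element symbols like "N" or "Y" as strings, not YAML 1.1 booleans
  raw <- yaml::read_yaml(path, handlers = list("bool#no" = function(x) x,
                                               "bool#yes" = function(x) x))
  out <- lapply(raw, function(entries) {
    shifts <- vapply(entries, function(e) as.integer(e$shift), integer(1))
    probs <- vapply(entries, function(e) as.numeric(e$probability), numeric(1))
    if (any(is.na(shifts)) || any(shifts < 0)) {
      stop("abundance shifts must be non-negative integers")
    }
    v <- numeric(max(shifts) + 1L)
    v[shifts + 1L] <- probs
    v
  })
  validate_abundance(out)
  out
}
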
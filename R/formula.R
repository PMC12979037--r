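#' Parse a molecular formula
#'
#' Parses a Hill-notation-style formula string (element symbol followed by an
#' optional positive integer, e.g. `"C5H10N2O3"`) into a named integer vector
#' of element counts. An absent integer means a count of 1. Repeated symbols
#' are summed. The result is returned in canonical Hill order (C, then H,
#' then remaining elements alphabetically) so that
#' `parse_formula(write_formula(x))` round-trips.
#'
#' @param formula_text Single non-empty character string.
#' @param elements Character vector of recognized element symbols. Defaults to
#'   the elements covered by [natural_abundance()].
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C5H10N2O3") # glutamine
#' parse_formula("N")
#' @seealso [write_formula()]
#' @export
parse_formula <- function(formula_text, elements = names(natural_abundance())) {
  if (!is.character(formula_text) || length(formula_text) != 1L ||
      is.na(formula_text)) {
    stop("formula_text must be a single character string")
  }
  txt <- trimws(formula_text)
  if (!nzchar(txt)) stop("empty formula string")

  pos <- 1L
  syms <- character(0)
  cnts <- integer(0)
  while (pos <= nchar(txt)) {
    rest <- substr(txt, pos, nchar(txt))
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1L])) {
      bad <- substr(rest, 1L, 1L)
      stop(sprintf("formula parse error at '%s' in \"%s\": not an element symbol",
                   bad, txt))
    }
    sym <- m[2L]
    # prefer the longest recognized symbol; fall back to the single letter
    if (!(sym %in% elements) && nchar(sym) == 2L &&
        substr(sym, 1L, 1L) %in% elements) {
      sym <- substr(sym, 1L, 1L)
      m[1L] <- paste0(sym, m[3L])
    }
    if (!(sym %in% elements)) {
      stop(sprintf("unknown element symbol '%s' in formula \"%s\"", sym, txt))
    }
    cnt <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    if (is.na(cnt) || cnt <= 0L) {
      stop(sprintf("invalid count for element '%s' in \"%s\"", sym, txt))
    }
    syms <- c(syms, sym)
    cnts <- c(cnts, cnt)
    pos <- pos + nchar(m[1L])
  }
  counts <- tapply(cnts, syms, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  hill_order(out)
}

#' Write a molecular formula
#'
#' Canonical inverse of [parse_formula()]: emits Hill order (C, H, then
#' alphabetical), omitting counts of 1.
#'
#' @param counts Named integer vector of element counts (all positive).
#' @return Single character string.
#' @export
write_formula <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector")
  }
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("all element counts must be positive integers")
  }
  counts <- hill_order(counts)
  paste0(names(counts),
         ifelse(counts == 1L, "", as.character(as.integer(counts))),
         collapse = "")
}

# Hill convention: C first, H second, remaining elements alphabetical.
hill_order <- function(counts) {
  nm <- names(counts)
  rest <- sort(setdiff(nm, c("C", "H")))
  ord <- c(intersect(c("C", "H"), nm), rest)
  counts[ord]
}
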
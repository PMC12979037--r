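#' Construct a metabolite annotation
#'
#' Bundles the identity, elemental composition and tracer-atom count of one
#' metabolite. `tracer_atom_count` is the number of atoms of the tracer
#' element that can carry label, i.e. the maximum isotopologue index `n`; the
#' measured intensity vector for the metabolite has length `n + 1`
#' (M+0 .. M+n).
#'
#' @param metabolite_id Metabolite identifier (whitespace is trimmed; ids are
#'   matched case-sensitively everywhere).
#' @param formula Formula string (see [parse_formula()]) or named count vector.
#' @param tracer_atom_count Integer `n >= 0`, at most the formula's count of
#'   the tracer element.
#' @param tracer_element Element symbol carrying the label (default `"N"`).
#' @return Object of class `molecule_spec`.
#' @export
molecule_spec <- function(metabolite_id, formula, tracer_atom_count,
                          tracer_element = "N") {
  metabolite_id <- trimws(as.character(metabolite_id))
  if (!nzchar(metabolite_id)) stop("metabolite_id must be non-empty")
  counts <- if (is.character(formula)) parse_formula(formula) else {
    stopifnot(is.numeric(formula), !is.null(names(formula)))
    hill_order(stats::setNames(as.integer(formula), names(formula)))
  }
  n <- as.integer(tracer_atom_count)
  if (is.na(n) || n < 0L) stop("tracer_atom_count must be a non-negative integer")
  avail <- if (tracer_element %in% names(counts)) counts[[tracer_element]] else 0L
  if (n > avail) {
    stop(sprintf("metabolite '%s': tracer_atom_count (%d) exceeds %s atoms in formula (%d)",
                 metabolite_id, n, tracer_element, avail))
  }
  structure(list(metabolite_id = metabolite_id, formula = counts,
                 tracer_atom_count = n, tracer_element = tracer_element),
            class = "molecule_spec")
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat(sprintf("<molecule_spec> %s  %s  (%d labelable %s atoms)\n",
              x$metabolite_id, write_formula(x$formula),
              x$tracer_atom_count, x$tracer_element))
  invisible(x)
}

#' Assemble and validate a tracing dataset
#'
#' The canonical in-memory container joining the three input tables: a long
#' intensity table (one row per metabolite x sample x isotopologue), a
#' metabolite annotation table and a sample metadata table. Missing
#' isotopologue rows are zero-filled with a warning; all-zero vectors are
#' retained (they surface later as `undetected`).
#'
#' @param molecules `data.frame` with columns `metabolite_id`, `formula`,
#'   `tracer_atom_count`.
#' @param samples `data.frame` with columns `sample_id`, `model_system`,
#'   `tracer_condition` (`"traced"` or `"unlabeled"`), `precondition_hours`,
#'   `replicate`.
#' @param intensities `data.frame` with columns `metabolite_id`, `sample_id`,
#'   `isotopologue`, `intensity`.
#' @param tracer_element Tracer element symbol (default `"N"`).
#' @return Object of class `tracing_dataset`: a list with validated
#'   `molecules`, `samples`, `intensities` (complete long table, ordered) and
#'   `tracer_element`.
#' @export
tracing_dataset <- function(molecules, samples, intensities,
                            tracer_element = "N") {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(sprintf("%s table missing column(s): %s",
                                   what, paste(miss, collapse = ", ")))
  }
  need(molecules, c("metabolite_id", "formula", "tracer_atom_count"), "metabolite")
  need(samples, c("sample_id", "model_system", "tracer_condition",
                  "precondition_hours", "replicate"), "sample")
  need(intensities, c("metabolite_id", "sample_id", "isotopologue", "intensity"),
       "intensity")

  molecules$metabolite_id <- trimws(as.character(molecules$metabolite_id))
  samples$sample_id <- trimws(as.character(samples$sample_id))
  intensities$metabolite_id <- trimws(as.character(intensities$metabolite_id))
  intensities$sample_id <- trimws(as.character(intensities$sample_id))

  if (anyDuplicated(molecules$metabolite_id)) {
    stop("duplicate metabolite_id in annotation table: ",
         paste(unique(molecules$metabolite_id[duplicated(molecules$metabolite_id)]),
               collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in metadata table: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  bad_cond <- setdiff(unique(samples$tracer_condition), c("traced", "unlabeled"))
  if (length(bad_cond)) {
    stop("tracer_condition must be 'traced' or 'unlabeled'; found: ",
         paste(bad_cond, collapse = ", "))
  }
  if (any(samples$precondition_hours < 0)) stop("precondition_hours must be >= 0")
  if (any(samples$replicate < 1)) stop("replicate must be >= 1")

  # validate formulas and tracer atom counts via the molecule_spec invariants
  specs <- mapply(molecule_spec, molecules$metabolite_id, molecules$formula,
                  molecules$tracer_atom_count,
                  MoreArgs = list(tracer_element = tracer_element),
                  SIMPLIFY = FALSE)
  names(specs) <- molecules$metabolite_id

  unk_m <- setdiff(unique(intensities$metabolite_id), molecules$metabolite_id)
  if (length(unk_m)) {
    stop("intensity rows reference unknown metabolite(s): ",
         paste(unk_m, collapse = ", "))
  }
  unk_s <- setdiff(unique(intensities$sample_id), samples$sample_id)
  if (length(unk_s)) {
    stop("intensity rows reference unknown sample(s): ",
         paste(unk_s, collapse = ", "))
  }
  if (any(is.na(intensities$intensity)) || any(intensities$intensity < 0)) {
    stop("negative or missing intensity values are not allowed")
  }
  iso <- intensities$isotopologue
  if (any(is.na(iso)) || any(iso != round(iso)) || any(iso < 0)) {
    stop("isotopologue indices must be non-negative integers")
  }
  nmax <- stats::setNames(molecules$tracer_atom_count, molecules$metabolite_id)
  over <- iso > nmax[intensities$metabolite_id]
  if (any(over)) {
    off <- unique(paste0(intensities$metabolite_id[over], " M+",
                         iso[over]))
    stop("isotopologue index exceeds tracer_atom_count for: ",
         paste(off, collapse = ", "))
  }
  key <- paste(intensities$metabolite_id, intensities$sample_id, iso, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate isotopologue rows for: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }

  # complete grid: zero-fill missing isotopologue rows with a warning
  grid <- do.call(rbind, lapply(molecules$metabolite_id, function(m) {
    expand.grid(metabolite_id = m, sample_id = samples$sample_id,
                isotopologue = 0:nmax[[m]], stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  }))
  gkey <- paste(grid$metabolite_id, grid$sample_id, grid$isotopologue, sep = "\r")
  idx <- match(gkey, key)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0L) {
    warning(sprintf("%d missing isotopologue row(s) zero-filled", n_missing))
  }
  grid$intensity <- ifelse(is.na(idx), 0, intensities$intensity[idx])
  grid <- grid[order(grid$metabolite_id, grid$sample_id, grid$isotopologue), ]
  rownames(grid) <- NULL

  structure(list(molecules = molecules[, c("metabolite_id", "formula",
                                           "tracer_atom_count")],
                 samples = samples[, c("sample_id", "model_system",
                                       "tracer_condition", "precondition_hours",
                                       "replicate")],
                 intensities = grid,
                 specs = specs,
                 tracer_element = tracer_element,
                 n_zero_filled = n_missing),
            class = "tracing_dataset")
}

#' @export
print.tracing_dataset <- function(x, ...) {
  cat(sprintf("<tracing_dataset> %d metabolites x %d samples (%s tracer)\n",
              nrow(x$molecules), nrow(x$samples), x$tracer_element))
  tab <- table(x$samples$model_system, x$samples$tracer_condition)
  print(tab)
  invisible(x)
}

#' Extract the raw isotopologue vector for one metabolite in one sample
#'
#' @param dataset A [tracing_dataset()].
#' @param metabolite_id,sample_id Identifiers present in the dataset.
#' @return Numeric vector of intensities, M+0 .. M+n.
#' @export
isotopologue_vector <- function(dataset, metabolite_id, sample_id) {
  stopifnot(inherits(dataset, "tracing_dataset"))
  rows <- dataset$intensities$metabolite_id == metabolite_id &
    dataset$intensities$sample_id == sample_id
  if (!any(rows)) {
    stop(sprintf("no rows for metabolite '%s' in sample '%s'",
                 metabolite_id, sample_id))
  }
  v <- dataset$intensities[rows, ]
  v$intensity[order(v$isotopologue)]
}

#' Read a tracing dataset from the three-table text format
#'
#' Reads tab-delimited `intensities`, `metabolites` and `samples` tables
#' (header rows required; see the package vignette for column layouts) and
#' validates them into a [tracing_dataset()].
#'
#' @param intensity_path Long intensity table: `metabolite_id`, `sample_id`,
#'   `isotopologue`, `intensity`.
#' @param annotation_path Metabolite table: `metabolite_id`, `formula`,
#'   `tracer_atom_count`.
#' @param metadata_path Sample table: `sample_id`, `model_system`,
#'   `tracer_condition`, `precondition_hours`, `replicate`.
#' @param tracer_element Tracer element symbol (default `"N"`).
#' @return A `tracing_dataset`.
#' @export
read_tracing_dataset <- function(intensity_path, annotation_path, metadata_path,
                                 tracer_element = "N") {
  for (p in c(intensity_path, annotation_path, metadata_path)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  }
  rd <- function(p) utils::read.delim(p, stringsAsFactors = FALSE,
                                      check.names = FALSE)
  tracing_dataset(molecules = rd(annotation_path),
                  samples = rd(metadata_path),
                  intensities = rd(intensity_path),
                  tracer_element = tracer_element)
}

#' Read a wide intensity table and normalize it to long format
#'
#' Convenience reader for tables with one column per isotopologue (`M0`,
#' `M1`, ... or `M+0`, `M+1`, ...) alongside `metabolite_id` and `sample_id`.
#' Ragged rows (columns beyond a metabolite's `n`) must be empty or absent.
#'
#' @param path Tab-delimited file path.
#' @return Long `data.frame` with columns `metabolite_id`, `sample_id`,
#'   `isotopologue`, `intensity` (NA cells dropped), suitable for
#'   [tracing_dataset()].
#' @export
read_intensities_wide <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  iso_cols <- grep("^M\\+?[0-9]+$", names(df), value = TRUE)
  if (!length(iso_cols)) stop("no isotopologue columns (M0, M1, ...) found")
  iso_idx <- as.integer(sub("^M\\+?", "", iso_cols))
  out <- do.call(rbind, lapply(seq_along(iso_cols), function(k) {
    data.frame(metabolite_id = df$metabolite_id, sample_id = df$sample_id,
               isotopologue = iso_idx[k], intensity = df[[iso_cols[k]]],
               stringsAsFactors = FALSE)
  }))
  out <- out[!is.na(out$intensity), ]
  out[order(out$metabolite_id, out$sample_id, out$isotopologue), ]
}

#' Write a tracing dataset back to the three-table text format
#'
#' @param dataset A [tracing_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths written
#'   (`intensities.tsv`, `metabolites.tsv`, `samples.tsv`).
#' @export
write_tracing_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tracing_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("intensities.tsv", "metabolites.tsv", "samples.tsv"))
  write_tsv(dataset$intensities, paths[1L])
  write_tsv(dataset$molecules, paths[2L])
  write_tsv(dataset$samples, paths[3L])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read metabolite sets from a GMT file
#'
#' One set per line, tab-separated: set name, description, then member
#' metabolite ids. Duplicate members within a line are deduplicated with a
#' warning; lines with fewer than three fields are an error.
#'
#' @param path GMT file path.
#' @return Object of class `metabolite_sets`: a named list, each element a
#'   list with `set_name`, `description` and `member_ids`.
#' @export
read_metabolite_sets <- function(path) {
  if (!file.exists(path)) stop(sprintf("sets file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(fields)))
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s' (line %d): duplicate member id(s) removed: %s",
                      fields[1L], i,
                      paste(unique(members[duplicated(members)]), collapse = ", ")))
      members <- unique(members)
    }
    list(set_name = fields[1L], description = fields[2L], member_ids = members)
  })
  names(sets) <- vapply(sets, `[[`, character(1), "set_name")
  structure(sets, class = "metabolite_sets")
}

#' @export
print.metabolite_sets <- function(x, ...) {
  cat(sprintf("<metabolite_sets> %d set(s)\n", length(x)))
  for (s in x) {
    cat(sprintf("  %s (%d members)\n", s$set_name, length(s$member_ids)))
  }
  invisible(x)
}
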
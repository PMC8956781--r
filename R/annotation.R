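HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity", "align_len",
                 "mismatches", "gap_opens", "q_start", "q_end", "s_start",
                 "s_end", "evalue", "bitscore")
HIT_NUMERIC <- HIT_COLUMNS[3:12]

#' Read a 12-column tabular alignment hit table
#'
#' Parses the standard tabular protein-alignment format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score). Lines starting with `#` and blank
#' lines are ignored. Malformed rows are reported with their 1-based line
#' number in the file.
#'
#' @param path Path to the tab-separated hit table.
#' @return A tibble with one row per hit and the 12 standard columns;
#'   coordinates are 1-based inclusive and carried through unchanged.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(empty_hit_table())
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 12L)) {
    i <- which(n_fields != 12L)[1L]
    stop("hit table line ", line_no[i], ": expected 12 columns, got ",
         n_fields[i], call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  hits <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                            .name_repair = "minimal")
  names(hits) <- HIT_COLUMNS
  for (col in HIT_NUMERIC) {
    parsed <- suppressWarnings(as.numeric(hits[[col]]))
    if (anyNA(parsed)) {
      i <- which(is.na(parsed))[1L]
      stop("hit table line ", line_no[i], ": non-numeric value '",
           hits[[col]][i], "' in column ", col, call. = FALSE)
    }
    hits[[col]] <- parsed
  }
  int_cols <- c("align_len", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end")
  hits[int_cols] <- lapply(hits[int_cols], as.integer)
  hits
}

empty_hit_table <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(),
    percent_identity = numeric(), align_len = integer(),
    mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bitscore = numeric()
  )
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits Tibble as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(HIT_COLUMNS %in% names(hits)))
  out <- hits[HIT_COLUMNS]
  # scientific notation for e-values, plain for the rest
  out$evalue <- formatC(out$evalue, format = "e", digits = 2)
  out$percent_identity <- formatC(out$percent_identity, format = "fg")
  out$bitscore <- formatC(out$bitscore, format = "fg")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Filter the hits of one query for LCA assignment
#'
#' Applies the two-stage rule used for taxonomic assignment: hits with e-value
#' above `cutoff` are discarded, then among the survivors only those with
#' e-value no greater than `factor` times the smallest surviving e-value are
#' retained. Returns the empty table when no hit passes the cutoff.
#'
#' @param hits Tibble of hits sharing one `query_id`.
#' @param cutoff E-value cutoff (default `1e-5`).
#' @param factor Width of the e-value window relative to the best hit
#'   (default 10).
#' @return The retained subset of `hits`, in input order.
#' @export
filter_hits_for_lca <- function(hits, cutoff = 1e-5, factor = 10) {
  if (length(unique(hits$query_id)) > 1L) {
    stop("filter_hits_for_lca() expects hits of a single query", call. = FALSE)
  }
  hits <- hits[hits$evalue <= cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  hits[hits$evalue <= min(hits$evalue) * factor, , drop = FALSE]
}

.as_lookup <- function(map, value_col) {
  if (is.character(map) && !is.null(names(map))) return(map)
  map <- tibble::as_tibble(map)
  if (ncol(map) < 2L) stop("subject map needs two columns", call. = FALSE)
  if (anyDuplicated(map[[1L]])) {
    stop("subject map is not single-valued for subject_id: ",
         map[[1L]][duplicated(map[[1L]])][1L], call. = FALSE)
  }
  stats::setNames(as.character(map[[2L]]), as.character(map[[1L]]))
}

#' Read a two-column subject map
#'
#' Reads the TSV `subject_id<TAB>value` files mapping database subjects to a
#' taxon id or a KEGG-ortholog id.
#'
#' @param path Path to the map.
#' @param value Name for the second column (`"taxon_id"` or `"ko_id"`).
#' @return Tibble with columns `subject_id` and `value`.
#' @export
read_subject_map <- function(path, value = "taxon_id") {
  map <- readr::read_tsv(path, col_names = c("subject_id", value),
                         col_types = "cc", comment = "#", progress = FALSE)
  if (anyDuplicated(map$subject_id)) {
    stop("subject map is not single-valued for subject_id: ",
         map$subject_id[duplicated(map$subject_id)][1L], call. = FALSE)
  }
  map
}

#' Assign per-unigene taxonomy by filtered LCA
#'
#' For each query, hits are filtered with [filter_hits_for_lca()], retained
#' subjects are mapped to taxa (subjects absent from the map are dropped, and
#' their count is attached as the `n_unmapped_subjects` attribute), and the
#' assignment is the lowest common ancestor of the resulting taxon set. A
#' query with an empty taxon set is unassigned (`NA`).
#'
#' @param hits Hit tibble covering any number of queries.
#' @param tree A `taxonomy_tree`; every mapped taxon must be present in it.
#' @param subject_taxon Subject-to-taxon map (tibble or named character vector).
#' @param cutoff,factor Passed to [filter_hits_for_lca()].
#' @return Tibble `unigene_id`, `taxon_id` (`NA` when unassigned), one row per
#'   query in `hits`.
#' @export
assign_taxonomy <- function(hits, tree, subject_taxon, cutoff = 1e-5, factor = 10) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  lookup <- .as_lookup(subject_taxon)
  n_unmapped <- 0L
  by_query <- split(seq_len(nrow(hits)), hits$query_id)
  assign_one <- function(rows) {
    kept <- filter_hits_for_lca(hits[rows, , drop = FALSE], cutoff, factor)
    if (nrow(kept) == 0L) return(NA_character_)
    taxa <- lookup[kept$subject_id]
    n_unmapped <<- n_unmapped + sum(is.na(taxa))
    taxa <- unique(taxa[!is.na(taxa)])
    if (length(taxa) == 0L) return(NA_character_)
    bad <- setdiff(taxa, names(tree$parent))
    if (length(bad) > 0L) {
      subj <- kept$subject_id[match(bad[1L], lookup[kept$subject_id])]
      stop("subject ", subj, " maps to taxon ", bad[1L],
           " which is absent from the taxonomy tree", call. = FALSE)
    }
    lca(tree, taxa)
  }
  res <- tibble::tibble(
    unigene_id = names(by_query),
    taxon_id = unname(vapply(by_query, assign_one, character(1L)))
  )
  attr(res, "n_unmapped_subjects") <- n_unmapped
  res
}

#' Assign per-unigene function by best hit
#'
#' Among hits passing the e-value cutoff whose subject maps to a KEGG
#' ortholog, picks the maximum bit score; ties break on lower e-value, then on
#' the lexicographically smallest subject id. Queries with no qualifying hit
#' are unassigned.
#'
#' @param hits Hit tibble covering any number of queries.
#' @param subject_ko Subject-to-KO map (tibble or named character vector).
#' @param cutoff E-value cutoff (default `1e-5`).
#' @return Tibble `unigene_id`, `ko_id` (`NA` when unassigned), one row per
#'   query in `hits`.
#' @export
assign_function <- function(hits, subject_ko, cutoff = 1e-5) {
  lookup <- .as_lookup(subject_ko)
  queries <- unique(hits$query_id)
  hits <- tibble::as_tibble(hits)
  hits$ko_id <- unname(lookup[hits$subject_id])
  qualified <- hits[hits$evalue <= cutoff & !is.na(hits$ko_id), , drop = FALSE]
  best <- qualified |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bitscore), .data$evalue,
                   .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
  tibble::tibble(
    unigene_id = queries,
    ko_id = best$ko_id[match(queries, best$query_id)]
  )
}

#' Read a unigene read-count matrix
#'
#' TSV with a header line; first column `unigene_id`, remaining columns one
#' per sample.
#'
#' @param path Path to the matrix.
#' @return Tibble, first column character, sample columns numeric.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    unigene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (names(counts)[1L] != "unigene_id") {
    stop("count matrix must have a first column named 'unigene_id'", call. = FALSE)
  }
  counts
}

#' Read unigene lengths
#'
#' Two-column TSV `unigene_id<TAB>length` with header.
#'
#' @param path Path to the table.
#' @return Tibble `unigene_id`, `length`.
#' @export
read_lengths <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    unigene_id = readr::col_character(), length = readr::col_double()
  ), progress = FALSE)
}

#' Length-normalised relative abundance
#'
#' Converts raw per-sample read counts into relative abundances using the
#' catalogue convention: each unigene's count is divided by its length, and
#' the resulting rates are renormalised to sum to one within each sample,
#' `abundance(i, s) = (count(i,s)/length(i)) / sum_j(count(j,s)/length(j))`.
#'
#' @param counts Wide tibble: `unigene_id` plus one numeric column per sample.
#' @param lengths Tibble `unigene_id`, `length` (nucleotides, > 0).
#' @return Long tibble `unigene_id`, `sample_id`, `abundance`; abundances sum
#'   to 1 per sample.
#' @export
compute_abundance <- function(counts, lengths) {
  counts <- tibble::as_tibble(counts)
  sample_cols <- setdiff(names(counts), "unigene_id")
  if (length(sample_cols) == 0L) stop("count matrix has no sample columns", call. = FALSE)
  len <- stats::setNames(lengths$length, lengths$unigene_id)[counts$unigene_id]
  if (anyNA(len)) {
    stop("no length for unigene ", counts$unigene_id[which(is.na(len))[1L]],
         call. = FALSE)
  }
  if (any(len <= 0)) stop("unigene lengths must be positive", call. = FALSE)
  mat <- as.matrix(counts[sample_cols])
  if (any(mat < 0)) stop("read counts must be non-negative", call. = FALSE)
  rate <- mat / len
  totals <- colSums(rate)
  if (any(totals == 0)) {
    stop("degenerate sample with all-zero counts: ",
         sample_cols[which(totals == 0)[1L]], call. = FALSE)
  }
  rel <- sweep(rate, 2L, totals, "/")
  tibble::tibble(
    unigene_id = rep(counts$unigene_id, times = length(sample_cols)),
    sample_id = rep(sample_cols, each = nrow(counts)),
    abundance = as.vector(rel)
  )
}

#' Full per-unigene annotation profile
#'
#' Convenience joiner: runs [assign_taxonomy()] and [assign_function()] on the
#' two hit tables, [compute_abundance()] on the count matrix, and returns one
#' long row per unigene and sample. Unigenes present in the count matrix but
#' absent from a hit table are carried with `NA` assignments.
#'
#' @param hits_tax Hit table against the taxonomy database.
#' @param hits_ko Hit table against the KEGG-ortholog database.
#' @param tree A `taxonomy_tree`.
#' @param subject_taxon,subject_ko Subject maps for the two databases.
#' @param counts,lengths Count matrix and length table.
#' @param cutoff,factor Alignment filter parameters.
#' @return Tibble `unigene_id`, `length`, `taxon_id`, `ko_id`, `sample_id`,
#'   `abundance`.
#' @export
annotate_unigenes <- function(hits_tax, hits_ko, tree, subject_taxon,
                              subject_ko, counts, lengths,
                              cutoff = 1e-5, factor = 10) {
  tax <- assign_taxonomy(hits_tax, tree, subject_taxon, cutoff, factor)
  fun <- assign_function(hits_ko, subject_ko, cutoff)
  abund <- compute_abundance(counts, lengths)
  abund |>
    dplyr::left_join(lengths, by = "unigene_id") |>
    dplyr::left_join(tax, by = "unigene_id") |>
    dplyr::left_join(fun, by = "unigene_id") |>
    dplyr::select("unigene_id", "length", "taxon_id", "ko_id",
                  "sample_id", "abundance")
}
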
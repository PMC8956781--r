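#' Define a pathway as an ordered gene set
#'
#' @param name Pathway name.
#' @param genes Character vector of unique gene symbols, in pathway order.
#' @param kos Optional character vector of KEGG-ortholog ids, one per gene
#'   (`NA` allowed); attach later with [set_pathway_kos()] when the mapping
#'   comes from an annotation run.
#' @return Object of class `pathway_definition`.
#' @export
pathway_definition <- function(name, genes, kos = NULL) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("a pathway needs at least one gene", call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol in pathway '", name, "': ",
         genes[duplicated(genes)][1L], call. = FALSE)
  }
  if (is.null(kos)) kos <- rep(NA_character_, length(genes))
  stopifnot(length(kos) == length(genes))
  structure(
    list(name = name,
         genes = tibble::tibble(gene = genes, ko = as.character(kos))),
    class = "pathway_definition"
  )
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat("<pathway> ", x$name, ": ", paste(x$genes$gene, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Built-in propionyl-CoA pathway definitions
#'
#' The two candidate routes to propionyl-CoA in glycogen-accumulating
#' organisms: the ethylmalonyl-CoA (EMC) pathway with its seven key genes
#' (`phbB`, `phaJ`, `ccr`, `ecm`, `mcd`, `mch`, `mcl`) and the three-step
#' succinate-propionate pathway (`MUT`, `MCEEepi`, `E2.1.3.1-5s`; the last is
#' a carboxytransferase label treated as an opaque symbol). Gene symbols carry
#' no KEGG ids until a mapping is supplied, either here or via
#' [set_pathway_kos()].
#'
#' @param ko_map Optional named character vector `gene symbol -> ko_id`.
#' @return Named list of two `pathway_definition` objects, `EMC` and
#'   `SucProp`.
#' @export
builtin_pathways <- function(ko_map = NULL) {
  defs <- list(
    EMC = pathway_definition(
      "EMC", c("phbB", "phaJ", "ccr", "ecm", "mcd", "mch", "mcl")),
    SucProp = pathway_definition(
      "SucProp", c("MUT", "MCEEepi", "E2.1.3.1-5s"))
  )
  if (!is.null(ko_map)) defs <- lapply(defs, set_pathway_kos, ko_map = ko_map)
  defs
}

#' Attach KEGG-ortholog ids to a pathway definition
#'
#' @param pathway A `pathway_definition`.
#' @param ko_map Named character vector or two-column table
#'   (`gene`, `ko_id`).
#' @return The definition with its `ko` column filled where the map covers a
#'   gene.
#' @export
set_pathway_kos <- function(pathway, ko_map) {
  stopifnot(inherits(pathway, "pathway_definition"))
  if (!is.character(ko_map)) {
    ko_map <- stats::setNames(as.character(ko_map[[2L]]), as.character(ko_map[[1L]]))
  }
  hit <- pathway$genes$gene %in% names(ko_map)
  pathway$genes$ko[hit] <- unname(ko_map[pathway$genes$gene[hit]])
  pathway
}

#' Read a gene-to-KO map
#'
#' Two-column TSV `gene<TAB>ko_id` with header, as written by the synthetic
#' generator or assembled from an annotation reference.
#'
#' @param path Path to the table.
#' @return Named character vector `gene -> ko_id`.
#' @export
read_gene_ko_map <- function(path) {
  map <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  stats::setNames(map[[2L]], map[[1L]])
}

#' Genes of a pathway present in a taxon
#'
#' A gene is present when the taxon's share of the gene's KEGG ortholog
#' exceeds `min_share` percent in at least one sample of the contribution
#' table. With the default threshold of zero this is the usual
#' presence/absence call across the whole run.
#'
#' @param contrib Contribution table from [attribute_genes()].
#' @param pathway A `pathway_definition` whose genes all carry a KO id.
#' @param taxon Genus-level taxon id.
#' @param min_share Exclusive share threshold in percent (default 0).
#' @return Character vector of present gene symbols, in definition order.
#' @export
presence <- function(contrib, pathway, taxon, min_share = 0) {
  stopifnot(inherits(pathway, "pathway_definition"))
  if (anyNA(pathway$genes$ko)) {
    stop("pathway '", pathway$name, "' has gene(s) without a KO mapping: ",
         paste(pathway$genes$gene[is.na(pathway$genes$ko)], collapse = ", "),
         call. = FALSE)
  }
  rows <- contrib[!is.na(contrib$genus_taxon_id) &
                    contrib$genus_taxon_id == taxon, , drop = FALSE]
  hit <- vapply(pathway$genes$ko, function(ko) {
    any(rows$ko_id == ko & rows$share_percent > min_share)
  }, logical(1L))
  pathway$genes$gene[hit]
}

#' Pathway completeness of a taxon
#'
#' @param present Character vector of present gene symbols (a subset of the
#'   definition, e.g. from [presence()]).
#' @param pathway A `pathway_definition`.
#' @param taxon Optional taxon id carried into the report.
#' @return One-row tibble `taxon`, `pathway`, `n_present`, `n_defined`,
#'   `completeness`, `complete`, `present_genes`.
#' @export
completeness <- function(present, pathway, taxon = NA_character_) {
  stopifnot(inherits(pathway, "pathway_definition"))
  stray <- setdiff(present, pathway$genes$gene)
  if (length(stray) > 0L) {
    stop("gene(s) not in pathway '", pathway$name, "': ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  present <- pathway$genes$gene[pathway$genes$gene %in% present]
  n_def <- nrow(pathway$genes)
  tibble::tibble(
    taxon = taxon,
    pathway = pathway$name,
    n_present = length(present),
    n_defined = n_def,
    completeness = length(present) / n_def,
    complete = length(present) == n_def,
    present_genes = paste(present, collapse = ",")
  )
}

#' Completeness of several pathways across several taxa
#'
#' @param contrib Contribution table from [attribute_genes()].
#' @param pathways List of `pathway_definition` objects with KO ids attached.
#' @param taxa Character vector of genus-level taxon ids; defaults to every
#'   genus in `contrib`.
#' @param min_share Passed to [presence()].
#' @return Tibble with one [completeness()] row per taxon and pathway.
#' @export
pathway_completeness <- function(contrib, pathways, taxa = NULL, min_share = 0) {
  if (is.null(taxa)) {
    taxa <- sort(unique(contrib$genus_taxon_id[!is.na(contrib$genus_taxon_id)]))
  }
  rows <- lapply(taxa, function(taxon) {
    dplyr::bind_rows(lapply(pathways, function(pw) {
      completeness(presence(contrib, pw, taxon, min_share), pw, taxon = taxon)
    }))
  })
  dplyr::bind_rows(rows)
}
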
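#' Attribute functional genes to host taxa by unigene co-location
#'
#' A unigene whose taxonomy and function were assigned on the same sequence is
#' taken as evidence that the host taxon contributes that gene. Each unigene
#' with an assigned KEGG ortholog contributes its abundance to the cell
#' `(sample, ko, genus)`, where the genus is obtained by projecting the
#' assigned taxon to `rank` with [rank_ancestor()]; assignments that do not
#' reach the requested rank (e.g. family-level LCA results, or unassigned
#' taxonomy) fall into an explicit `"unassigned"` bucket. Shares are
#' percentages of the KO's total abundance within the sample, so for each
#' `(sample, ko)` they sum to 100 over genera plus the bucket.
#'
#' @param profile Long annotation tibble from [annotate_unigenes()].
#' @param tree A `taxonomy_tree`.
#' @param rank Aggregation rank (default `"genus"`).
#' @return Tibble `sample_id`, `ko_id`, `genus_taxon_id` (`NA` for the
#'   bucket), `genus_name`, `abundance`, `share_percent`.
#' @export
attribute_genes <- function(profile, tree, rank = "genus") {
  stopifnot(inherits(tree, "taxonomy_tree"))
  with_ko <- profile[!is.na(profile$ko_id), , drop = FALSE]
  if (nrow(with_ko) == 0L) {
    return(tibble::tibble(
      sample_id = character(), ko_id = character(),
      genus_taxon_id = character(), genus_name = character(),
      abundance = numeric(), share_percent = numeric()
    ))
  }
  taxa <- unique(with_ko$taxon_id)
  taxa <- taxa[!is.na(taxa)]
  proj <- vapply(taxa, function(t) rank_ancestor(tree, t, rank), character(1L))
  with_ko$genus_taxon_id <- unname(proj[with_ko$taxon_id])
  contrib <- with_ko |>
    dplyr::group_by(.data$sample_id, .data$ko_id, .data$genus_taxon_id) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    dplyr::group_by(.data$sample_id, .data$ko_id) |>
    dplyr::mutate(share_percent = 100 * .data$abundance / sum(.data$abundance)) |>
    dplyr::ungroup()
  contrib$genus_name <- ifelse(
    is.na(contrib$genus_taxon_id), UNASSIGNED,
    taxon_name(tree, contrib$genus_taxon_id)
  )
  contrib[, c("sample_id", "ko_id", "genus_taxon_id", "genus_name",
              "abundance", "share_percent")]
}

#' Rank the top host genera of a gene
#'
#' Genera are ranked by their mean share of the gene's total abundance across
#' samples (a genus absent from a sample counts a zero share there). Ties
#' break on total abundance, then on genus id. The `"unassigned"` bucket never
#' enters the ranking.
#'
#' @param contrib Contribution table from [attribute_genes()].
#' @param ko_id KEGG-ortholog id present in `contrib`.
#' @param n Maximum number of hosts to return (default 5).
#' @return Tibble `ko_id`, `rank`, `genus_taxon_id`, `genus_name`,
#'   `mean_share_percent`, `total_abundance`, sorted by rank.
#' @export
top_hosts <- function(contrib, ko_id, n = 5) {
  if (!ko_id %in% contrib$ko_id) {
    stop("ko_id '", ko_id, "' not present in the contribution table", call. = FALSE)
  }
  rows <- contrib[contrib$ko_id == ko_id & !is.na(contrib$genus_taxon_id), ,
                  drop = FALSE]
  n_samples <- length(unique(contrib$sample_id[contrib$ko_id == ko_id]))
  ranked <- rows |>
    dplyr::group_by(.data$genus_taxon_id, .data$genus_name) |>
    dplyr::summarise(
      mean_share_percent = sum(.data$share_percent) / n_samples,
      total_abundance = sum(.data$abundance),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_share_percent),
                   dplyr::desc(.data$total_abundance),
                   .data$genus_taxon_id) |>
    utils::head(n)
  tibble::tibble(
    ko_id = ko_id,
    rank = seq_len(nrow(ranked)),
    ranked
  )
}

#' Community profile at a taxonomic rank
#'
#' Sums unigene relative abundance per sample and genus (taxon projected with
#' [rank_ancestor()]); unigenes that do not resolve to the rank are kept in
#' the `"unassigned"` bucket, so the profile sums to 1 in every sample.
#'
#' @param profile Long annotation tibble from [annotate_unigenes()].
#' @param tree A `taxonomy_tree`.
#' @param rank Aggregation rank (default `"genus"`).
#' @return Tibble `sample_id`, `genus_taxon_id`, `genus_name`, `abundance`.
#' @export
genus_profile <- function(profile, tree, rank = "genus") {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxa <- unique(profile$taxon_id)
  taxa <- taxa[!is.na(taxa)]
  proj <- vapply(taxa, function(t) rank_ancestor(tree, t, rank), character(1L))
  profile$genus_taxon_id <- unname(proj[profile$taxon_id])
  out <- profile |>
    dplyr::group_by(.data$sample_id, .data$genus_taxon_id) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
  out$genus_name <- ifelse(
    is.na(out$genus_taxon_id), UNASSIGNED, taxon_name(tree, out$genus_taxon_id)
  )
  out[, c("sample_id", "genus_taxon_id", "genus_name", "abundance")]
}
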
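#' Recognised taxonomic ranks
#'
#' The closed set of rank labels accepted by [taxonomy_tree()], ordered from
#' root to species. `"no_rank"` marks unranked internal clades; such nodes are
#' transparent to [rank_ancestor()].
#'
#' @return Character vector of rank labels.
#' @export
taxon_ranks <- function() {
  c("root", "domain", "phylum", "class", "order", "family", "genus",
    "species", "no_rank")
}

#' Build a validated taxonomy tree
#'
#' Constructs a rooted taxonomy from a node table. The root is encoded, NCBI
#' style, as the unique node that is its own parent. Validation rejects
#' duplicate ids, dangling parents, multiple roots and parent cycles, so that
#' downstream lineage and LCA queries always terminate.
#'
#' @param nodes Data frame with character columns `taxon_id`, `parent_id`,
#'   `rank`, `name`; one row per node.
#' @return An object of class `taxonomy_tree` holding the node table plus
#'   parent, rank, name and depth lookups keyed by `taxon_id`.
#' @seealso [load_taxonomy()] to read the tab-separated on-disk form.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("taxon_id", "parent_id", "rank", "name")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L) {
    stop("taxonomy table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  nodes <- dplyr::mutate(
    nodes[required],
    dplyr::across(dplyr::everything(), as.character)
  )
  if (nrow(nodes) == 0L) stop("taxonomy table is empty", call. = FALSE)

  ids <- nodes$taxon_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate taxon_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_rank <- setdiff(unique(nodes$rank), taxon_ranks())
  if (length(bad_rank) > 0L) {
    stop("unknown rank label(s): ", paste(bad_rank, collapse = ", "), call. = FALSE)
  }
  parent <- stats::setNames(nodes$parent_id, ids)
  orphans <- ids[!(parent %in% ids)]
  if (length(orphans) > 0L) {
    stop("unknown parent ", parent[orphans[1L]], " of node ", orphans[1L],
         call. = FALSE)
  }
  root <- ids[parent == ids]
  if (length(root) != 1L) {
    stop("expected exactly one root (parent_id == taxon_id), found ",
         length(root),
         if (length(root) > 0L) paste0(": ", paste(root, collapse = ", ")) else "",
         call. = FALSE)
  }

  # breadth-first depth assignment doubles as the cycle check: a node never
  # reached from the root sits on a parent cycle
  depth <- stats::setNames(rep(NA_real_, length(ids)), ids)
  depth[root] <- 0
  repeat {
    reachable <- is.na(depth) & !is.na(depth[parent[ids]])
    if (!any(reachable)) break
    depth[ids[reachable]] <- depth[parent[ids[reachable]]] + 1
  }
  if (anyNA(depth)) {
    stop("cycle detected in parent relation involving taxon_id ",
         ids[which(is.na(depth))[1L]], call. = FALSE)
  }

  structure(
    list(
      nodes = nodes,
      parent = parent,
      rank = stats::setNames(nodes$rank, ids),
      name = stats::setNames(nodes$name, ids),
      depth = depth,
      root = root
    ),
    class = "taxonomy_tree"
  )
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree> ", nrow(x$nodes), " nodes, depth ",
      max(x$depth), ", root '", x$name[[x$root]], "'\n", sep = "")
  invisible(x)
}

#' Read a taxonomy table from disk
#'
#' Parses the simplified 4-column dialect
#' `taxon_id<TAB>parent_id<TAB>rank<TAB>name` (UTF-8, no header, lines starting
#' with `#` ignored) and validates it via [taxonomy_tree()].
#'
#' @param path Path to the tab-separated node table.
#' @return A `taxonomy_tree`.
#' @export
load_taxonomy <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 4L)) {
    bad <- which(keep)[which(n_fields != 4L)[1L]]
    stop("taxonomy line ", bad, ": expected 4 tab-separated fields, got ",
         n_fields[which(n_fields != 4L)[1L]], call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  taxonomy_tree(tibble::tibble(
    taxon_id = mat[, 1L], parent_id = mat[, 2L],
    rank = mat[, 3L], name = mat[, 4L]
  ))
}

#' Write a taxonomy tree to disk
#'
#' Inverse of [load_taxonomy()]; rows come out in node-table order.
#'
#' @param tree A `taxonomy_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tree, path) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  readr::write_tsv(tree$nodes, path, col_names = FALSE)
  invisible(path)
}

.check_taxa_known <- function(tree, taxa) {
  unknown <- setdiff(taxa, names(tree$parent))
  if (length(unknown) > 0L) {
    stop("taxon_id not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Root-to-node lineage
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_id Single taxon id present in the tree.
#' @return Character vector of taxon ids from the root down to `taxon_id`.
#' @export
lineage <- function(tree, taxon_id) {
  stopifnot(inherits(tree, "taxonomy_tree"), length(taxon_id) == 1L)
  taxon_id <- as.character(taxon_id)
  .check_taxa_known(tree, taxon_id)
  path <- character(tree$depth[[taxon_id]] + 1L)
  node <- taxon_id
  for (i in seq_along(path)) {
    path[length(path) - i + 1L] <- node
    node <- tree$parent[[node]]
  }
  path
}

.lca_pair <- function(tree, a, b) {
  da <- tree$depth[[a]]
  db <- tree$depth[[b]]
  while (da > db) { a <- tree$parent[[a]]; da <- da - 1 }
  while (db > da) { b <- tree$parent[[b]]; db <- db - 1 }
  while (a != b) { a <- tree$parent[[a]]; b <- tree$parent[[b]] }
  a
}

#' Lowest common ancestor of a set of taxa
#'
#' Deepest node lying on the root path of every input taxon, computed by
#' pairwise depth-aligned climbing. Duplicated ids are ignored; a singleton set
#' returns its own element.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxa Non-empty character vector of taxon ids.
#' @return A single taxon id.
#' @export
lca <- function(tree, taxa) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("lca() requires a non-empty set of taxa", call. = FALSE)
  .check_taxa_known(tree, taxa)
  Reduce(function(a, b) .lca_pair(tree, a, b), taxa)
}

#' Ancestor (or self) at a requested rank
#'
#' Walks the lineage of `taxon_id` towards the root and returns the node whose
#' rank equals `rank`, or `NA` when the lineage carries no node of that rank.
#' `"no_rank"` nodes are transparent: they are skipped and cannot be queried.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_id Single taxon id present in the tree.
#' @param rank One of [taxon_ranks()] other than `"no_rank"`.
#' @return A taxon id, or `NA_character_` when the rank is absent.
#' @export
rank_ancestor <- function(tree, taxon_id, rank) {
  stopifnot(inherits(tree, "taxonomy_tree"), length(rank) == 1L)
  if (!rank %in% taxon_ranks() || identical(rank, "no_rank")) {
    stop("rank must be one of the named ranks, got '", rank, "'", call. = FALSE)
  }
  taxon_id <- as.character(taxon_id)
  .check_taxa_known(tree, taxon_id)
  node <- taxon_id
  repeat {
    if (tree$rank[[node]] == rank) return(node)
    if (node == tree$root) return(NA_character_)
    node <- tree$parent[[node]]
  }
}

#' Display name of a taxon
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_id Character vector of taxon ids.
#' @return Character vector of names (`NA` for ids not in the tree).
#' @export
taxon_name <- function(tree, taxon_id) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  unname(tree$name[as.character(taxon_id)])
}
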
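# shared fixtures and independent brute-force oracles

# root(1) -> family F(2) -> genus G(3), genus H(4); species S(5) under G;
# an unranked clade U(6) sits between H and its species T(7)
make_test_tree <- function() {
  taxonomy_tree(tibble::tibble(
    taxon_id = c("1", "2", "3", "4", "5", "6", "7"),
    parent_id = c("1", "1", "2", "2", "3", "4", "6"),
    rank = c("root", "family", "genus", "genus", "species", "no_rank",
             "species"),
    name = c("root", "F", "G", "H", "S", "U", "T")
  ))
}

# random rooted tree: node i attaches to a uniform earlier node
random_tree_nodes <- function(n) {
  parent <- c("1", as.character(vapply(
    seq_len(n - 1L) + 1L, function(i) sample(i - 1L, 1L), integer(1L))))
  tibble::tibble(
    taxon_id = as.character(seq_len(n)),
    parent_id = parent,
    rank = c("root", sample(c("family", "genus", "species", "no_rank"),
                            n - 1L, replace = TRUE)),
    name = paste0("n", seq_len(n))
  )
}

# oracle: parent-chasing on the raw node table, no package tree machinery
brute_lineage <- function(nodes, id) {
  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  path <- id
  while (parent[[id]] != id) {
    id <- parent[[id]]
    path <- c(id, path)
  }
  path
}

# oracle: LCA as the last common element of the intersected lineages
brute_lca <- function(nodes, ids) {
  common <- Reduce(intersect, lapply(ids, function(i) brute_lineage(nodes, i)))
  common[length(common)]
}

write_tree_file <- function(nodes, path = tempfile(fileext = ".tsv")) {
  writeLines(apply(nodes, 1L, paste, collapse = "\t"), path)
  path
}
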
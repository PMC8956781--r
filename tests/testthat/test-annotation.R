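make_hits <- function(query, subject, evalue, bitscore = -2 * log10(evalue)) {
  tibble::tibble(
    query_id = query, subject_id = subject,
    percent_identity = 90, align_len = 100L, mismatches = 10L, gap_opens = 0L,
    q_start = 1L, q_end = 300L, s_start = 1L, s_end = 100L,
    evalue = evalue, bitscore = bitscore
  )
}

test_that("hit tables parse, reject malformed rows, and round-trip", {
  empty <- tempfile()
  writeLines(c("# only a comment", ""), empty)
  expect_equal(nrow(read_hit_table(empty)), 0L)

  one <- tempfile()
  writeLines("u1\ts1\t95.2\t120\t5\t1\t1\t360\t1\t120\t1e-30\t250", one)
  hits <- read_hit_table(one)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$evalue, 1e-30)
  expect_identical(hits$align_len, 120L)

  bad_cols <- tempfile()
  writeLines(c("# header", "u1\ts1\t95.2"), bad_cols)
  expect_error(read_hit_table(bad_cols), "line 2.*12 columns")

  bad_num <- tempfile()
  writeLines("u1\ts1\t95.2\t120\t5\t1\t1\t360\t1\t120\tnot_a_number\t250",
             bad_num)
  expect_error(read_hit_table(bad_num), "non-numeric")

  set.seed(21)
  many <- dplyr::bind_rows(lapply(1:200, function(i) make_hits(
    sprintf("u%03d", sample(50, 1L)), sprintf("s%03d", i),
    signif(10^runif(1, -40, -6), 3)
  )))
  many$percent_identity <- round(runif(200, 50, 100), 1)
  many$bitscore <- round(runif(200, 50, 500), 1)
  path <- tempfile()
  write_hit_table(many, path)
  expect_equal(read_hit_table(path), many)
})

test_that("the LCA e-value filter applies cutoff first, then the x10 window", {
  hits <- make_hits("q", paste0("s", 1:4), c(1e-30, 5e-30, 2e-29, 1e-3))
  kept <- filter_hits_for_lca(hits)
  expect_setequal(kept$subject_id, c("s1", "s2"))

  # cutoff excludes everything
  expect_equal(nrow(filter_hits_for_lca(make_hits("q", "s1", 1e-4))), 0L)
  # equal e-values are all inside their own window
  all_eq <- make_hits("q", paste0("s", 1:3), rep(1e-8, 3))
  expect_equal(nrow(filter_hits_for_lca(all_eq)), 3L)
  # output is a subset and invariant to input order
  shuffled <- hits[c(3, 1, 4, 2), ]
  expect_setequal(filter_hits_for_lca(shuffled)$subject_id, kept$subject_id)
  expect_true(all(kept$subject_id %in% hits$subject_id))
  expect_error(filter_hits_for_lca(make_hits(c("a", "b"), "s", 1e-9)),
               "single query")
})

test_that("taxonomy assignment is the LCA of retained mapped hits", {
  tree <- make_test_tree()
  map <- c(sG = "3", sH = "4", sS = "5")

  one_genus <- make_hits("u1", c("sG", "sS"), c(1e-20, 2e-20))
  expect_equal(assign_taxonomy(one_genus, tree, map)$taxon_id, "3")

  # genera G and H under family F collapse to F, matching the oracle
  two_genera <- make_hits("u1", c("sG", "sH"), c(1e-20, 3e-20))
  expect_equal(assign_taxonomy(two_genera, tree, map)$taxon_id,
               brute_lca(tree$nodes, c("3", "4")))

  # hits outside the window do not deepen the assignment
  windowed <- make_hits("u1", c("sG", "sH"), c(1e-20, 5e-19))
  expect_equal(assign_taxonomy(windowed, tree, map)$taxon_id, "3")

  unmapped <- make_hits("u2", "sX", 1e-20)
  res <- assign_taxonomy(unmapped, tree, map)
  expect_true(is.na(res$taxon_id))
  expect_equal(attr(res, "n_unmapped_subjects"), 1L)

  bad_map <- c(sG = "404")
  expect_error(assign_taxonomy(one_genus[1, ], tree, bad_map), "sG")
})

test_that("function assignment picks the best hit with documented tie-breaks", {
  map <- c(sA = "K1", sB = "K2", sC = "K3")
  two <- dplyr::bind_rows(
    make_hits("u1", "sA", 1e-20, bitscore = 250),
    make_hits("u1", "sB", 1e-25, bitscore = 300)
  )
  expect_equal(assign_function(two, map)$ko_id, "K2")

  # bitscore tie: lower e-value wins
  tie_bs <- dplyr::bind_rows(
    make_hits("u1", "sA", 1e-20, bitscore = 300),
    make_hits("u1", "sB", 1e-25, bitscore = 300)
  )
  expect_equal(assign_function(tie_bs, map)$ko_id, "K2")

  # full tie: lexicographically smaller subject, whatever the input order
  tie_all <- dplyr::bind_rows(
    make_hits("u1", "sC", 1e-20, bitscore = 300),
    make_hits("u1", "sA", 1e-20, bitscore = 300)
  )
  expect_equal(assign_function(tie_all, map)$ko_id, "K1")
  expect_equal(assign_function(tie_all[2:1, ], map)$ko_id, "K1")

  # nothing under the cutoff -> unassigned
  weak <- make_hits("u1", "sA", 1e-3)
  expect_true(is.na(assign_function(weak, map)$ko_id))
})

test_that("abundance is length-normalised and sums to one per sample", {
  single <- tibble::tibble(unigene_id = "u1", s1 = 7)
  len1 <- tibble::tibble(unigene_id = "u1", length = 500)
  expect_equal(compute_abundance(single, len1)$abundance, 1)

  two <- tibble::tibble(unigene_id = c("u1", "u2"), s1 = c(100, 50))
  len2 <- tibble::tibble(unigene_id = c("u1", "u2"), length = c(1000, 500))
  expect_equal(compute_abundance(two, len2)$abundance, c(0.5, 0.5))

  set.seed(22)
  counts <- tibble::tibble(unigene_id = sprintf("u%03d", 1:100))
  for (s in c("a", "b", "c")) counts[[s]] <- rpois(100, 40)
  lens <- tibble::tibble(unigene_id = counts$unigene_id,
                         length = sample(300:3000, 100))
  ab <- compute_abundance(counts, lens)
  sums <- tapply(ab$abundance, ab$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # scale invariance within a sample
  scaled <- counts
  scaled$a <- scaled$a * 17
  expect_equal(compute_abundance(scaled, lens)$abundance, ab$abundance)

  zero <- tibble::tibble(unigene_id = c("u1", "u2"), s1 = c(0, 0))
  expect_error(compute_abundance(zero, len2), "degenerate")
})
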
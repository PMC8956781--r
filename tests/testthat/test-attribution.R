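make_profile <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) tibble::tibble(
    unigene_id = r[[1]], length = 1000, taxon_id = r[[2]], ko_id = r[[3]],
    sample_id = r[[4]], abundance = r[[5]]
  )))
}

test_that("co-located KO and genus assignments drive the contribution table", {
  tree <- make_test_tree()
  solo <- make_profile(list("u1", "3", "ccr", "s1", 0.02),
                       list("u2", "3", NA, "s1", 0.98))
  contrib <- attribute_genes(solo, tree)
  expect_equal(nrow(contrib), 1L)  # the KO-less unigene contributes nothing
  expect_equal(contrib$share_percent, 100)
  expect_equal(contrib$genus_name, "G")

  # species-level assignment rolls up to its genus
  rolled <- attribute_genes(make_profile(list("u1", "5", "ccr", "s1", 0.1)),
                            tree)
  expect_equal(rolled$genus_taxon_id, "3")

  # genus share 75%, unassigned-taxon share 25% (0.03 / 0.04)
  split2 <- make_profile(list("u1", "3", "ccr", "s1", 0.03),
                         list("u2", NA, "ccr", "s1", 0.01))
  contrib <- attribute_genes(split2, tree)
  expect_equal(contrib$share_percent[contrib$genus_name == "G"], 75)
  expect_equal(contrib$share_percent[contrib$genus_name == "unassigned"], 25)

  # family-level LCA result lands in the unassigned-genus bucket
  fam <- attribute_genes(make_profile(list("u1", "2", "ccr", "s1", 0.1)), tree)
  expect_equal(fam$genus_name, "unassigned")

  empty <- make_profile(list("u1", "3", "ccr", "s1", 0.1))[0, ]
  expect_equal(nrow(attribute_genes(empty, tree)), 0L)
})

test_that("shares conserve the per-sample KO total", {
  tree <- make_test_tree()
  set.seed(31)
  profile <- dplyr::bind_rows(lapply(1:60, function(i) make_profile(list(
    sprintf("u%02d", i),
    sample(c("3", "4", "5", NA), 1L),
    sample(c("ccr", "mcl", NA), 1L),
    sample(c("s1", "s2"), 1L),
    runif(1, 0, 0.05)
  ))))
  contrib <- attribute_genes(profile, tree)
  by_cell <- dplyr::summarise(
    dplyr::group_by(contrib, sample_id, ko_id),
    share = sum(share_percent), abund = sum(abundance), .groups = "drop"
  )
  expect_true(all(abs(by_cell$share - 100) < 1e-6))
  with_ko <- profile[!is.na(profile$ko_id), ]
  totals <- dplyr::summarise(dplyr::group_by(with_ko, sample_id, ko_id),
                             abund = sum(abundance), .groups = "drop")
  expect_equal(dplyr::arrange(by_cell[names(totals)], sample_id, ko_id),
               dplyr::arrange(totals, sample_id, ko_id))
})

test_that("adding a contributing unigene never decreases that genus's share", {
  tree <- make_test_tree()
  before <- make_profile(list("u1", "3", "ccr", "s1", 0.02),
                         list("u2", "4", "ccr", "s1", 0.05))
  after <- dplyr::bind_rows(before,
                            make_profile(list("u3", "3", "ccr", "s1", 0.01)))
  share_g <- function(p) {
    c <- attribute_genes(p, tree)
    c$share_percent[c$genus_taxon_id == "3"]
  }
  expect_gt(share_g(after), share_g(before))
})

test_that("top_hosts ranks by mean share with documented tie-breaks", {
  tree <- make_test_tree()
  contrib <- tibble::tibble(
    sample_id = "s1", ko_id = "ccr",
    genus_taxon_id = paste0("g", 1:3), genus_name = paste0("g", 1:3),
    abundance = c(0.4, 0.35, 0.25), share_percent = c(40, 35, 25)
  )
  ranked <- top_hosts(contrib, "ccr")
  expect_equal(ranked$mean_share_percent, c(40, 35, 25))
  expect_equal(ranked$rank, 1:3)

  # seven genera, n = 5: exactly the five largest, per an independent sort
  set.seed(32)
  shares <- round(runif(7, 1, 40), 3)
  shares <- 100 * shares / sum(shares)
  seven <- tibble::tibble(
    sample_id = "s1", ko_id = "k", genus_taxon_id = paste0("g", 1:7),
    genus_name = paste0("g", 1:7), abundance = shares / 100,
    share_percent = shares
  )
  top5 <- top_hosts(seven, "k", n = 5)
  expect_equal(top5$mean_share_percent, sort(shares, decreasing = TRUE)[1:5])

  # single-genus KO: one row at 100%
  solo <- seven[1, ]
  solo$share_percent <- 100
  expect_equal(top_hosts(solo, "k")$mean_share_percent, 100)

  # a genus absent from one sample averages a zero share there
  two_samples <- dplyr::bind_rows(
    tibble::tibble(sample_id = "s1", ko_id = "k", genus_taxon_id = "gA",
                   genus_name = "gA", abundance = 0.1, share_percent = 100),
    tibble::tibble(sample_id = "s2", ko_id = "k",
                   genus_taxon_id = c("gA", "gB"), genus_name = c("gA", "gB"),
                   abundance = c(0.05, 0.05), share_percent = c(50, 50))
  )
  ranked <- top_hosts(two_samples, "k")
  expect_equal(ranked$mean_share_percent[ranked$genus_taxon_id == "gB"], 25)

  # the unassigned bucket never enters the ranking
  with_bucket <- dplyr::bind_rows(seven, tibble::tibble(
    sample_id = "s1", ko_id = "k", genus_taxon_id = NA_character_,
    genus_name = "unassigned", abundance = 0.9, share_percent = 90
  ))
  expect_false(anyNA(top_hosts(with_bucket, "k")$genus_taxon_id))

  expect_error(top_hosts(contrib, "nope"), "not present")
})

test_that("genus_profile sums to one per sample and keeps the bucket", {
  tree <- make_test_tree()
  profile <- make_profile(
    list("u1", "5", NA, "s1", 0.4),  # species under G
    list("u2", "4", NA, "s1", 0.35),
    list("u3", "2", NA, "s1", 0.15), # family-level only
    list("u4", NA, NA, "s1", 0.10)
  )
  gp <- genus_profile(profile, tree)
  expect_equal(sum(gp$abundance), 1)
  expect_equal(gp$abundance[gp$genus_name == "G"], 0.4)
  expect_equal(gp$abundance[gp$genus_name == "unassigned"], 0.25)
})
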
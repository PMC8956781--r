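# small, fast configuration used throughout this file
small_config <- function(seed = 1, read_depth = 5e4, ...) {
  synthetic_config(seed = seed, n_genera = 6L, unigenes_per_genus = 5L,
                   read_depth = read_depth, ...)
}

test_that("community trajectories are anchored, monotone and deterministic", {
  cfg <- synthetic_config(seed = 9)
  comp <- simulate_community(cfg)
  sums <- tapply(comp$fraction, comp$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  dom <- comp$fraction[comp$genus == cfg$dominant_genus]
  expect_true(all(diff(dom) > 0))  # strictly increasing across days
  # planted anchor fractions are hit exactly at days 20 and 39
  expect_equal(comp$fraction[comp$genus == cfg$dominant_genus &
                               comp$day == 20], 0.026)
  expect_equal(comp$fraction[comp$genus == cfg$dominant_genus &
                               comp$day == 39], 0.069)
  expect_equal(comp$fraction[comp$genus == cfg$competitor_genus &
                               comp$day == 39], 0.020)

  expect_equal(simulate_community(cfg), comp)  # same seed, same draw

  flat <- synthetic_config(seed = 2, n_genera = 2,
                           dominant_initial = 0.5, dominant_final = 0.5,
                           competitor_initial = 0.5, competitor_final = 0.5)
  expect_true(all(simulate_community(flat)$fraction == 0.5))

  expect_error(synthetic_config(dominant_initial = 0), "between 0 and 1")
})

test_that("noise-free hit tables resolve every unigene to its true genus", {
  cfg <- small_config(seed = 4, taxonomy_noise = 0)
  meta <- simulate_metagenome(simulate_community(cfg), cfg)
  assigned <- assign_taxonomy(meta$hits_tax, meta$tree, meta$subject_taxon)
  truth <- stats::setNames(meta$catalogue$genus, meta$catalogue$unigene_id)
  got_genus <- vapply(assigned$taxon_id,
                      function(t) rank_ancestor(meta$tree, t, "genus"),
                      character(1L))
  expect_equal(unname(taxon_name(meta$tree, got_genus)),
               unname(truth[assigned$unigene_id]))
})

test_that("with taxonomy noise, misassigned unigenes stop at family", {
  cfg <- small_config(seed = 5, taxonomy_noise = 1)
  meta <- simulate_metagenome(simulate_community(cfg), cfg)
  assigned <- assign_taxonomy(meta$hits_tax, meta$tree, meta$subject_taxon)
  ranks <- unname(meta$tree$rank[assigned$taxon_id])
  expect_true(all(ranks %in% c("genus", "species", "family")))
  expect_true(any(ranks == "family"))
})

test_that("genus_profile error shrinks with sequencing depth", {
  err_at_depth <- function(depth) {
    cfg <- small_config(seed = 6, taxonomy_noise = 0, read_depth = depth)
    comp <- simulate_community(cfg)
    meta <- simulate_metagenome(comp, cfg)
    profile <- annotate_unigenes(meta$hits_tax, meta$hits_ko, meta$tree,
                                 meta$subject_taxon, meta$subject_ko,
                                 meta$counts, meta$lengths)
    gp <- genus_profile(profile, meta$tree)
    gp$genus <- gp$genus_name
    joined <- dplyr::inner_join(gp, comp, by = c("sample_id", "genus"))
    mean(abs(joined$abundance - joined$fraction))
  }
  expect_lt(err_at_depth(1e5), err_at_depth(1e3))
})

test_that("the written bundle round-trips through every reader silently", {
  dir <- tempfile()
  bundle <- simulate_dataset(small_config(seed = 7), dir)
  p <- bundle$paths
  expect_no_warning({
    tree <- load_taxonomy(p[["taxonomy"]])
    hits_tax <- read_hit_table(p[["hits_tax"]])
    hits_ko <- read_hit_table(p[["hits_ko"]])
    st <- read_subject_map(p[["subject_taxon"]])
    sk <- read_subject_map(p[["subject_ko"]], "ko_id")
    counts <- read_counts(p[["counts"]])
    lengths <- read_lengths(p[["lengths"]])
    gk <- read_gene_ko_map(p[["gene_ko"]])
    cycle <- read_cycle(p[["cycle"]])
    expr <- read_expression(p[["expression"]])
  })
  expect_true(all(hits_tax$subject_id %in% st$subject_id))
  expect_true(all(counts$unigene_id %in% lengths$unigene_id))
  expect_gt(nrow(cycle), 10)
})

test_that("one seed reproduces the full dataset byte for byte", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  p1 <- simulate_dataset(small_config(seed = 8), d1)$paths
  p2 <- simulate_dataset(small_config(seed = 8), d2)$paths
  p3 <- simulate_dataset(small_config(seed = 9), d3)$paths
  md5 <- function(p) unname(tools::md5sum(p))
  expect_equal(md5(p1), md5(p2))
  expect_false(all(md5(p1) == md5(p3)))
})

test_that("the simulated cycle honours its boundary conditions", {
  cfg <- synthetic_config(seed = 10, cycle_noise_sd = 0)
  series <- simulate_cycle(cfg)
  ana <- series[series$phase == "anaerobic", ]
  expect_equal(ana$acetate_mg_L[ana$time_min == cfg$depletion_minute], 0)
  expect_equal(ana$acetate_mg_L[1], cfg$vfa_0_mg_L)
  expect_true(all(series$phosphate_mgP_L == cfg$phosphate_mgP_L))
  expect_true(all(diff(series$time_min) > 0))
  expect_equal(attr(series, "n_clamped"), 0L)
  # aerobic phase restores glycogen towards its initial level
  aer <- series[series$phase == "aerobic", ]
  expect_true(all(diff(aer$glycogen_g_gSS) > 0))
  expect_true(all(diff(aer$phb_g_gSS) < 0))

  # a configured PHV/PHB yield ratio of 0.22 is returned exactly
  cfg22 <- synthetic_config(seed = 10, cycle_noise_sd = 0,
                            y_phb = 2, y_phv = 0.44)
  r <- cycle_ratios(simulate_cycle(cfg22), mlss_g_L = cfg22$mlss_g_L)
  expect_equal(r$PHV_per_PHB, 0.22)
})

test_that("planted expression trajectories reproduce the fold-change tiers", {
  cfg <- synthetic_config(seed = 11, expr_noise_sdlog = 0)
  expr <- simulate_expression(cfg)
  tiers <- expression_tiers(expr)
  final <- tiers[tiers$timepoint == max(tiers$timepoint), ]
  tier_of <- stats::setNames(final$tier, final$gene)
  expect_equal(unname(tier_of[c("ccr", "mcd", "mch")]), rep("gt4", 3))
  expect_equal(unname(tier_of[c("ecm", "mcl")]), rep("gt2", 2))
  expect_equal(unname(tier_of[c("phbB", "phaJ")]), rep("down_or_flat", 2))
  base <- tiers[tiers$timepoint == min(tiers$timepoint), ]
  expect_true(all(base$fold_change == 1))
})
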
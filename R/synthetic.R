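#' Configuration for the synthetic GAO-reactor dataset
#'
#' Bundles every knob of the generator, with defaults that emulate the study
#' conditions of a laboratory GAO enrichment: a dominant GAO genus whose
#' relative abundance rises from 2.6% to 6.9% between days 20 and 39, a
#' second GAO rising from 1.0% to 2.0% over the same window, an early
#' dominant denitrifier that declines as the enrichment takes over, the
#' planted pathway inventories (all seven ethylmalonyl-CoA genes plus `MUT`
#' in the dominant genus; `phaJ`, `ccr`, `ecm`, `mcd`, `mch` plus `MUT` in
#' the second GAO), five sampling days, and anaerobic cycle kinetics with
#' configurable carbon-mol yields and acetate depletion at 60 min of the
#' 90-min anaerobic phase.
#'
#' @param seed Integer seed; one seed reproduces the full dataset.
#' @param n_genera Number of genera in the community (>= 2).
#' @param days Sampling days.
#' @param dominant_initial,dominant_final Dominant-genus fractions at the two
#'   anchor days.
#' @param competitor_initial,competitor_final Second-GAO fractions at the two
#'   anchor days.
#' @param anchor_days Days at which the genus trajectories hit their initial
#'   and final fractions.
#' @param logistic_k Steepness of the logistic trajectories (per day).
#' @param community_conc Dirichlet concentration controlling day-to-day noise
#'   of the background genera (`Inf` for none).
#' @param unigenes_per_genus Background (function-free) unigenes per genus.
#' @param gene_unigenes Unigenes carrying each planted gene.
#' @param gene_placements Named list genus -> character vector of gene
#'   symbols placed in that genus.
#' @param read_depth Reads per metagenome sample.
#' @param taxonomy_noise Probability that a unigene's hit set includes a
#'   sibling-genus hit inside the e-value window (driving its LCA to family).
#' @param decoy_rate Probability of an extra decoy hit beyond the e-value
#'   cutoff.
#' @param vfa_0_mg_L Initial acetate, mg/L.
#' @param depletion_minute Minute of the anaerobic phase at which acetate is
#'   exhausted.
#' @param y_gly,y_phb,y_phv Anaerobic yields, C-mol per C-mol acetate taken
#'   up.
#' @param cycle_noise_sd Relative measurement noise of the cycle readings
#'   (fraction of each analyte's full scale).
#' @param mlss_g_L Biomass concentration, g suspended solids per litre.
#' @param glycogen_0,phb_0,phv_0 Initial intracellular polymer contents,
#'   g/gSS.
#' @param phosphate_mgP_L Dissolved phosphate-P, held constant, mg P/L.
#' @param fold_targets Named vector of planted final expression fold changes
#'   per EMC gene.
#' @param expr_noise_sdlog Log-normal noise of transcript readings (sdlog).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genera = 40L,
                             days = c(1L, 20L, 39L, 52L, 75L),
                             dominant_initial = 0.026,
                             dominant_final = 0.069,
                             competitor_initial = 0.010,
                             competitor_final = 0.020,
                             anchor_days = c(20, 39),
                             logistic_k = 0.25,
                             community_conc = 2000,
                             unigenes_per_genus = 12L,
                             gene_unigenes = 2L,
                             gene_placements = list(
                               Ca_Contendobacter = c("phbB", "phaJ", "ccr",
                                                     "ecm", "mcd", "mch",
                                                     "mcl", "MUT"),
                               Ca_Competibacter = c("phaJ", "ccr", "ecm",
                                                    "mcd", "mch", "MUT")
                             ),
                             read_depth = 1e6,
                             taxonomy_noise = 0.05,
                             decoy_rate = 0.3,
                             vfa_0_mg_L = 400,
                             depletion_minute = 60,
                             y_gly = 1.32,
                             y_phb = 1.72,
                             y_phv = 0.37,
                             cycle_noise_sd = 0.02,
                             mlss_g_L = 4,
                             glycogen_0 = 0.30,
                             phb_0 = 0.01,
                             phv_0 = 0.005,
                             phosphate_mgP_L = 5,
                             fold_targets = c(ccr = 6.0, mcd = 5.2, mch = 4.6,
                                              ecm = 3.2, mcl = 2.6,
                                              phbB = 1.4, phaJ = 0.8),
                             expr_noise_sdlog = 0.05) {
  fractions <- c(dominant_initial, dominant_final,
                 competitor_initial, competitor_final)
  if (any(fractions <= 0 | fractions >= 1)) {
    stop("genus fractions must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n_genera < 2L) stop("need at least two genera", call. = FALSE)
  if (any(c(y_gly, y_phb, y_phv) < 0)) stop("yields must be >= 0", call. = FALSE)
  if (read_depth <= 0) stop("read_depth must be positive", call. = FALSE)
  if (depletion_minute <= 0 || depletion_minute > 90) {
    stop("depletion_minute must fall inside the 90-min anaerobic phase",
         call. = FALSE)
  }
  genera <- c("Ca_Contendobacter", "Ca_Competibacter", "Thauera", "Nitrospira",
              "Dechloromonas", "Ca_Accumulibacter")
  if (n_genera > length(genera)) {
    genera <- c(genera, sprintf("Genus_%02d", seq_len(n_genera - length(genera))))
  } else {
    genera <- genera[seq_len(n_genera)]
  }
  unknown <- setdiff(names(gene_placements), genera)
  if (length(unknown) > 0L) {
    stop("gene placement in unknown genus: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), n_genera = as.integer(n_genera),
      genera = genera, days = as.integer(days),
      dominant_genus = genera[1L], competitor_genus = genera[2L],
      dominant_initial = dominant_initial, dominant_final = dominant_final,
      competitor_initial = competitor_initial,
      competitor_final = competitor_final,
      anchor_days = anchor_days, logistic_k = logistic_k,
      community_conc = community_conc,
      unigenes_per_genus = as.integer(unigenes_per_genus),
      gene_unigenes = as.integer(gene_unigenes),
      gene_placements = gene_placements,
      read_depth = read_depth, taxonomy_noise = taxonomy_noise,
      decoy_rate = decoy_rate,
      vfa_0_mg_L = vfa_0_mg_L, depletion_minute = depletion_minute,
      y_gly = y_gly, y_phb = y_phb, y_phv = y_phv,
      cycle_noise_sd = cycle_noise_sd, mlss_g_L = mlss_g_L,
      glycogen_0 = glycogen_0, phb_0 = phb_0, phv_0 = phv_0,
      phosphate_mgP_L = phosphate_mgP_L,
      fold_targets = fold_targets, expr_noise_sdlog = expr_noise_sdlog
    ),
    class = "synthetic_config"
  )
}

# logistic interpolation pinned so that f(a1) == v1 and f(a2) == v2 exactly
.anchored_logistic <- function(day, v1, v2, a1, a2, k) {
  if (v1 == v2) return(rep(v1, length(day)))
  mid <- (a1 + a2) / 2
  l <- stats::plogis(k * (day - mid))
  l1 <- stats::plogis(k * (a1 - mid))
  l2 <- stats::plogis(k * (a2 - mid))
  v1 + (v2 - v1) * (l - l1) / (l2 - l1)
}

#' Simulate the per-day genus composition
#'
#' The two GAO genera follow deterministic logistic trajectories anchored at
#' the configured days (so the planted day-20 and day-39 fractions are exact);
#' the early dominant `Thauera` declines logistically; the remaining mass is
#' split over background genera with per-day Dirichlet noise. Deterministic
#' under the configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return Tibble `sample_id`, `day`, `genus`, `fraction`; fractions sum to 1
#'   per sample.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 101L)
  a <- config$anchor_days
  dom <- .anchored_logistic(config$days, config$dominant_initial,
                            config$dominant_final, a[1L], a[2L],
                            config$logistic_k)
  comp <- .anchored_logistic(config$days, config$competitor_initial,
                             config$competitor_final, a[1L], a[2L],
                             config$logistic_k)
  remainder <- 1 - dom - comp
  if (any(remainder < -1e-9)) {
    stop("dominant and competitor fractions exceed 1", call. = FALSE)
  }
  fillers <- setdiff(config$genera,
                     c(config$dominant_genus, config$competitor_genus))
  rows <- lapply(seq_along(config$days), function(i) {
    day <- config$days[i]
    frac <- c(dom[i], comp[i])
    if (length(fillers) > 0L) {
      w <- rep(1, length(fillers))
      names(w) <- fillers
      if ("Thauera" %in% fillers) {
        w[["Thauera"]] <- .anchored_logistic(day, 3.0, 0.3, a[1L], a[2L],
                                             config$logistic_k)
      }
      w <- w / sum(w)
      if (is.finite(config$community_conc)) {
        draw <- rgamma(length(w), shape = config$community_conc * w, rate = 1)
        w <- draw / sum(draw)
      }
      frac <- c(frac, remainder[i] * w)
    } else if (remainder[i] > 1e-9) {
      stop("two-genus community does not sum to 1", call. = FALSE)
    }
    tibble::tibble(
      sample_id = sprintf("d%02d", day), day = day,
      genus = c(config$dominant_genus, config$competitor_genus, fillers),
      fraction = unname(frac)
    )
  })
  dplyr::bind_rows(rows)
}

# deterministic reference taxonomy: root -> domain -> families of ~2 genera
# -> genera -> 2 species each, plus subject pools for both databases
.synthetic_reference <- function(config) {
  genera <- config$genera
  n_fam <- max(1L, length(genera) %/% 2L)
  fam_of <- pmin(ceiling(seq_along(genera) / 2), n_fam)
  next_id <- 1L
  take_id <- function(n) {
    ids <- as.character(seq.int(next_id, length.out = n))
    next_id <<- next_id + n
    ids
  }
  root_id <- take_id(1L)
  dom_id <- take_id(1L)
  fam_ids <- take_id(n_fam)
  gen_ids <- take_id(length(genera))
  sp_ids <- take_id(2L * length(genera))
  nodes <- tibble::tibble(
    taxon_id = c(root_id, dom_id, fam_ids, gen_ids, sp_ids),
    parent_id = c(root_id, root_id, rep(dom_id, n_fam), fam_ids[fam_of],
                  rep(gen_ids, each = 2L)),
    rank = c("root", "domain", rep("family", n_fam),
             rep("genus", length(genera)), rep("species", 2L * length(genera))),
    name = c("cellular organisms", "Bacteria", sprintf("Family_%02d", seq_len(n_fam)),
             genera, paste0(rep(genera, each = 2L), "_sp", 1:2))
  )
  species <- tibble::tibble(
    genus = rep(genera, each = 2L),
    species_id = sp_ids
  )
  subj_per_species <- 3L
  subject_taxon <- tibble::tibble(
    subject_id = sprintf("SB%05d", seq_len(nrow(species) * subj_per_species)),
    taxon_id = rep(species$species_id, each = subj_per_species)
  )
  genes <- sort(unique(c(unlist(config$gene_placements),
                         builtin_pathways()$EMC$genes$gene,
                         builtin_pathways()$SucProp$genes$gene)))
  gene_ko <- stats::setNames(sprintf("K14%03d", seq_along(genes)), genes)
  subject_ko <- tibble::tibble(
    subject_id = sprintf("KB%05d", seq_len(2L * length(genes))),
    ko_id = rep(unname(gene_ko), each = 2L)
  )
  list(
    nodes = nodes,
    genus_taxa = stats::setNames(gen_ids, genera),
    species = species,
    fam_of = stats::setNames(fam_ids[fam_of], genera),
    subject_taxon = subject_taxon,
    gene_ko = gene_ko,
    subject_ko = subject_ko
  )
}

#' Simulate a metagenome input bundle from a community composition
#'
#' Builds a unigene catalogue (background unigenes per genus plus unigenes
#' carrying the planted pathway genes), multinomial per-sample read counts
#' proportional to genus fraction x within-genus weight x unigene length (so
#' that length-normalised abundance recovers the composition), a taxonomy hit
#' table (both species of the true genus inside the e-value window, so a
#' noise-free unigene resolves to exactly its genus; with probability
#' `taxonomy_noise` a sibling-genus hit joins the window and drives the LCA
#' to family; occasional decoys fall beyond the cutoff), a single best KO hit
#' per gene-carrying unigene, the subject maps and the reference taxonomy.
#' Every table parses through the corresponding package reader.
#'
#' @param composition Output of [simulate_community()].
#' @param config The same [synthetic_config()].
#' @return List with `nodes`, `tree`, `catalogue`, `counts`, `lengths`,
#'   `hits_tax`, `hits_ko`, `subject_taxon`, `subject_ko`, `gene_ko`,
#'   `genus_taxa`.
#' @export
simulate_metagenome <- function(composition, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 202L)
  ref <- .synthetic_reference(config)
  genera <- config$genera

  cat_rows <- lapply(genera, function(g) {
    placed <- config$gene_placements[[g]]
    n_bg <- config$unigenes_per_genus
    genes <- c(rep(NA_character_, n_bg),
               rep(placed, each = config$gene_unigenes))
    tibble::tibble(genus = g, gene = genes,
                   weight = c(rep(1, n_bg),
                              rep(0.4, length(genes) - n_bg)))
  })
  catalogue <- dplyr::bind_rows(cat_rows)
  catalogue$unigene_id <- sprintf("UG%05d", seq_len(nrow(catalogue)))
  catalogue$length <- sample(300:3000, nrow(catalogue), replace = TRUE)
  catalogue <- catalogue[, c("unigene_id", "genus", "gene", "weight", "length")]

  # per-genus weight normalisation, then counts ~ multinomial per sample
  catalogue <- catalogue |>
    dplyr::group_by(.data$genus) |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
  samples <- unique(composition$sample_id)
  counts <- tibble::tibble(unigene_id = catalogue$unigene_id)
  for (s in samples) {
    frac <- composition$fraction[composition$sample_id == s]
    names(frac) <- composition$genus[composition$sample_id == s]
    p <- frac[catalogue$genus] * catalogue$weight * catalogue$length
    counts[[s]] <- as.vector(stats::rmultinom(1L, size = config$read_depth,
                                              prob = p / sum(p)))
  }

  species_of <- split(ref$species$species_id, ref$species$genus)
  subjects_of_species <- split(ref$subject_taxon$subject_id,
                               ref$subject_taxon$taxon_id)
  genus_of_family <- split(genera, unname(ref$fam_of[genera]))
  snap <- function(x) signif(x, 3)

  make_hit <- function(query, subject, evalue, length) {
    evalue <- snap(evalue)
    align_len <- max(30L, as.integer(length %/% 3 * runif(1, 0.5, 0.9)))
    pid <- round(runif(1, 60, 99.9), 1)
    tibble::tibble(
      query_id = query, subject_id = subject, percent_identity = pid,
      align_len = align_len,
      mismatches = as.integer(round(align_len * (1 - pid / 100))),
      gap_opens = 0L,
      q_start = 1L, q_end = min(as.integer(length), align_len * 3L),
      s_start = 1L, s_end = align_len,
      evalue = evalue,
      bitscore = round(-2 * log10(evalue) + runif(1, 0, 5), 1)
    )
  }

  tax_hits <- vector("list", nrow(catalogue))
  ko_hits <- vector("list", nrow(catalogue))
  ko_subjects <- split(ref$subject_ko$subject_id, ref$subject_ko$ko_id)
  for (i in seq_len(nrow(catalogue))) {
    ug <- catalogue$unigene_id[i]
    g <- catalogue$genus[i]
    len <- catalogue$length[i]
    e_best <- 10^runif(1, -40, -20)
    sp <- species_of[[g]]
    rows <- list(
      make_hit(ug, sample(subjects_of_species[[sp[1L]]], 1L), e_best, len),
      make_hit(ug, sample(subjects_of_species[[sp[2L]]], 1L),
               e_best * runif(1, 1, 9), len)
    )
    n_extra <- sample(0:2, 1L)
    for (k in seq_len(n_extra)) {
      rows <- c(rows, list(make_hit(
        ug, sample(subjects_of_species[[sample(sp, 1L)]], 1L),
        e_best * runif(1, 1, 9), len
      )))
    }
    if (runif(1) < config$taxonomy_noise) {
      siblings <- setdiff(genus_of_family[[unname(ref$fam_of[g])]], g)
      if (length(siblings) > 0L) {
        sib_sp <- sample(species_of[[sample(siblings, 1L)]], 1L)
        rows <- c(rows, list(make_hit(
          ug, sample(subjects_of_species[[sib_sp]], 1L),
          e_best * runif(1, 1, 9), len
        )))
      }
    }
    if (runif(1) < config$decoy_rate) {
      any_sp <- sample(ref$species$species_id, 1L)
      rows <- c(rows, list(make_hit(
        ug, sample(subjects_of_species[[any_sp]], 1L), 10^runif(1, -4, -2), len
      )))
    }
    tax_hits[[i]] <- dplyr::bind_rows(rows)
    gene <- catalogue$gene[i]
    if (!is.na(gene)) {
      ko <- ref$gene_ko[[gene]]
      best <- make_hit(ug, sample(ko_subjects[[ko]], 1L), 10^runif(1, -35, -20),
                       len)
      ko_rows <- list(best)
      if (runif(1) < 0.3) {
        other_ko <- sample(setdiff(names(ko_subjects), ko), 1L)
        ko_rows <- c(ko_rows, list(make_hit(
          ug, sample(ko_subjects[[other_ko]], 1L), snap(best$evalue) * 1e6, len
        )))
      }
      ko_hits[[i]] <- dplyr::bind_rows(ko_rows)
    }
  }

  list(
    nodes = ref$nodes,
    tree = taxonomy_tree(ref$nodes),
    catalogue = catalogue,
    counts = counts,
    lengths = catalogue[, c("unigene_id", "length")],
    hits_tax = dplyr::bind_rows(tax_hits),
    hits_ko = dplyr::bind_rows(ko_hits),
    subject_taxon = ref$subject_taxon,
    subject_ko = ref$subject_ko,
    gene_ko = ref$gene_ko,
    genus_taxa = ref$genus_taxa
  )
}

#' Simulate one anaerobic-aerobic reactor cycle
#'
#' Anaerobic phase (90 min): acetate declines linearly to zero at the
#' configured depletion minute; glycogen is consumed and PHB/PHV produced in
#' proportion to the acetate carbon taken up, at the configured C-mol yields;
#' dissolved phosphate-P stays constant (no anaerobic release, the GAM
#' signature). Settle and decant hold the anaerobic end state. Aerobic phase
#' (240 min): PHAs decay first-order back towards their initial contents and
#' glycogen recovers on the same time constant. Gaussian measurement noise
#' (relative sd `cycle_noise_sd` of each analyte's scale) is added to every
#' reading; negative readings are clamped to zero and the clamp count is
#' attached as attribute `n_clamped`.
#'
#' @param config A [synthetic_config()].
#' @return Cycle tibble in the [read_cycle()] column layout.
#' @export
simulate_cycle <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 303L)
  const <- analyte_constants()
  g_per_cmol <- stats::setNames(const$monomer_mass / pmax(const$carbons, 1),
                                const$analyte)

  t_ana <- seq(0, 90, by = 5)
  t_settle <- c(92, 104)
  t_decant <- c(106, 110)
  t_aer <- seq(115, 350, by = 20)
  t_idle <- c(352, 360)
  consumed <- function(t) pmin(t / config$depletion_minute, 1)
  ac_cmol <- function(t) {
    to_cmol(config$vfa_0_mg_L / 1000 / config$mlss_g_L, "acetate") * consumed(t)
  }
  gly <- function(t) config$glycogen_0 - config$y_gly * ac_cmol(t) * g_per_cmol[["glycogen"]]
  phb <- function(t) config$phb_0 + config$y_phb * ac_cmol(t) * g_per_cmol[["PHB"]]
  phv <- function(t) config$phv_0 + config$y_phv * ac_cmol(t) * g_per_cmol[["PHV"]]
  if (gly(90) < 0) {
    stop("configured yields exhaust glycogen; raise glycogen_0", call. = FALSE)
  }

  hold <- function(times, phase) tibble::tibble(
    time_min = times, phase = phase,
    acetate_mg_L = 0, glycogen_g_gSS = gly(90),
    phb_g_gSS = phb(90), phv_g_gSS = phv(90)
  )
  k_aer <- 0.012
  aer <- tibble::tibble(
    time_min = t_aer, phase = "aerobic",
    acetate_mg_L = 0,
    glycogen_g_gSS = config$glycogen_0 +
      (gly(90) - config$glycogen_0) * exp(-k_aer * (t_aer - t_aer[1L])),
    phb_g_gSS = config$phb_0 + (phb(90) - config$phb_0) * exp(-k_aer * (t_aer - t_aer[1L])),
    phv_g_gSS = config$phv_0 + (phv(90) - config$phv_0) * exp(-k_aer * (t_aer - t_aer[1L]))
  )
  series <- dplyr::bind_rows(
    tibble::tibble(
      time_min = t_ana, phase = "anaerobic",
      acetate_mg_L = config$vfa_0_mg_L * (1 - consumed(t_ana)),
      glycogen_g_gSS = gly(t_ana), phb_g_gSS = phb(t_ana), phv_g_gSS = phv(t_ana)
    ),
    hold(t_settle, "settle"),
    hold(t_decant, "decant"),
    aer,
    tibble::tibble(
      time_min = t_idle, phase = "idle",
      acetate_mg_L = 0,
      glycogen_g_gSS = aer$glycogen_g_gSS[nrow(aer)],
      phb_g_gSS = aer$phb_g_gSS[nrow(aer)],
      phv_g_gSS = aer$phv_g_gSS[nrow(aer)]
    )
  )
  series$phosphate_mgP_L <- config$phosphate_mgP_L

  n_clamped <- 0L
  if (config$cycle_noise_sd > 0) {
    for (col in unname(.cycle_column)) {
      scale <- max(series[[col]])
      noisy <- series[[col]] + rnorm(nrow(series), 0, config$cycle_noise_sd * scale)
      n_clamped <- n_clamped + sum(noisy < 0)
      series[[col]] <- pmax(noisy, 0)
    }
  }
  attr(series, "n_clamped") <- n_clamped
  series
}

#' Simulate the metatranscriptome expression series
#'
#' Each ethylmalonyl-CoA gene follows a geometric trajectory from its
#' baseline level at the first sampling day to the planted final fold change
#' (`fold_targets`), with multiplicative log-normal measurement noise. The
#' defaults plant the qualitative tiering of a stabilising enrichment: `ccr`,
#' `mcd`, `mch` end above four-fold, `ecm`, `mcl` between two- and four-fold,
#' `phbB`, `phaJ` flat or down.
#'
#' @param config A [synthetic_config()].
#' @return Tibble `gene`, `timepoint`, `abundance`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 404L)
  genes <- names(config$fold_targets)
  days <- config$days
  base <- runif(length(genes), 5, 50)
  rows <- lapply(seq_along(genes), function(i) {
    target <- config$fold_targets[[i]]
    fc <- target^((days - days[1L]) / (days[length(days)] - days[1L]))
    noise <- if (config$expr_noise_sdlog > 0) {
      rlnorm(length(days), 0, config$expr_noise_sdlog)
    } else {
      rep(1, length(days))
    }
    tibble::tibble(gene = genes[i], timepoint = as.numeric(days),
                   abundance = base[i] * fc * noise)
  })
  dplyr::bind_rows(rows)
}

#' Write the complete synthetic input bundle to a directory
#'
#' Runs [simulate_community()], [simulate_metagenome()], [simulate_cycle()]
#' and [simulate_expression()] and writes every file the pipeline consumes:
#' `taxonomy.tsv`, `hits_tax.tsv`, `hits_ko.tsv`, `subject_taxon.tsv`,
#' `subject_ko.tsv`, `counts.tsv`, `lengths.tsv`, `gene_ko.tsv`, `cycle.csv`,
#' `expression.tsv`, plus the structured ground truth `truth.json`
#' (composition, gene placements, yields, planted fold targets, genus taxon
#' ids).
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `truth`.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  composition <- simulate_community(config)
  meta <- simulate_metagenome(composition, config)
  cycle <- simulate_cycle(config)
  expr <- simulate_expression(config)

  paths <- c(
    taxonomy = "taxonomy.tsv", hits_tax = "hits_tax.tsv",
    hits_ko = "hits_ko.tsv", subject_taxon = "subject_taxon.tsv",
    subject_ko = "subject_ko.tsv", counts = "counts.tsv",
    lengths = "lengths.tsv", gene_ko = "gene_ko.tsv", cycle = "cycle.csv",
    expression = "expression.tsv", truth = "truth.json"
  )
  paths <- stats::setNames(file.path(dir, paths), names(paths))
  write_taxonomy(meta$tree, paths[["taxonomy"]])
  write_hit_table(meta$hits_tax, paths[["hits_tax"]])
  write_hit_table(meta$hits_ko, paths[["hits_ko"]])
  readr::write_tsv(meta$subject_taxon, paths[["subject_taxon"]],
                   col_names = FALSE)
  readr::write_tsv(meta$subject_ko, paths[["subject_ko"]], col_names = FALSE)
  readr::write_tsv(meta$counts, paths[["counts"]])
  readr::write_tsv(meta$lengths, paths[["lengths"]])
  readr::write_tsv(
    tibble::tibble(gene = names(meta$gene_ko), ko_id = unname(meta$gene_ko)),
    paths[["gene_ko"]]
  )
  readr::write_csv(cycle, paths[["cycle"]])
  readr::write_tsv(expr, paths[["expression"]])

  truth <- list(
    composition = composition,
    gene_placements = config$gene_placements,
    gene_ko = as.list(meta$gene_ko),
    genus_taxa = as.list(meta$genus_taxa),
    dominant_genus = config$dominant_genus,
    competitor_genus = config$competitor_genus,
    yields = list(y_gly = config$y_gly, y_phb = config$y_phb,
                  y_phv = config$y_phv),
    fold_targets = as.list(config$fold_targets),
    seed = config$seed
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}
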
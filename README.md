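# gaoscope

Gene-source attribution and storage-polymer stoichiometry for
glycogen-accumulating organism (GAO) enrichment reactors.

## The problem

In anaerobic–aerobic sequencing batch reactors fed with acetate, GAOs take
up the volatile fatty acid (VFA) anaerobically, fuel that uptake by
degrading intracellular glycogen, and store the carbon as
polyhydroxyalkanoates (PHB and PHV) — with essentially no phosphate
cycling. Two routes can supply the propionyl-CoA needed for PHV: the
three-step succinate–propionate pathway (`MUT`, `MCEEepi`, `E2.1.3.1-5s`)
and the ethylmalonyl-CoA (EMC) pathway with its seven key genes (`phbB`,
`phaJ`, `ccr`, `ecm`, `mcd`, `mch`, `mcl`). Deciding **which genus carries
which pathway genes** from shotgun metagenomes, and whether the reactor
expresses glycogen-accumulating metabolism (GAM) at all, takes two analysis
tracks that this package implements end to end:

1. **Gene-source analysis.** Assembled unigenes are aligned against a
   taxonomy database and a KEGG-ortholog database. Taxonomy is assigned by
   a filtered lowest common ancestor (LCA): hits with e-value above 1e-5
   are discarded, hits with e-value ≤ 10 × the best surviving e-value are
   retained, and the assignment is the LCA of their taxa. Function is the
   best hit (maximum bit score). When both land on the same unigene, the
   gene is attributed to that taxon; per-gene host genera are ranked by
   their mean share of the gene's length-normalised relative abundance, and
   per-genus pathway completeness is scored against the two gene sets.
2. **Cycle stoichiometry.** Anaerobic deltas of acetate, glycogen, PHB, PHV
   and phosphate-P are converted to carbon-mol (mol P for phosphorus) and
   expressed as the six classic model ratios — P/VFA, Gly/VFA, PHB/VFA,
   PHV/VFA, PHAs/VFA, PHV/PHB — which are compared against bundled
   published GAO/PAO model rows and classified as GAM, PAM or mixed.

A seeded synthetic-data generator produces every input the pipeline
consumes (hit tables, taxonomy, subject maps, counts, cycle series,
transcript series) with planted ground truth, so the whole analysis is
testable without downloads.

## Worked example

```r
library(gaoscope)

cfg <- synthetic_config(seed = 1)        # the default study-like conditions
bundle <- simulate_dataset(cfg, "gao_inputs")
res <- run_all("gao_inputs", "gao_results")

res$ratios
#> <gao_ratios> (C-mol basis; mol P for phosphorus)
#>    P_per_VFA  Gly_per_VFA  PHB_per_VFA  PHV_per_VFA PHAs_per_VFA  PHV_per_PHB
#>         0.00         1.42         1.62         0.36         1.99         0.22

res$completeness[, c("taxon_name", "pathway", "n_present", "n_defined", "complete")]
#>          taxon_name pathway n_present n_defined complete
#> 1 Ca_Contendobacter     EMC         7         7     TRUE
#> 2 Ca_Contendobacter SucProp         1         3    FALSE
#> 3  Ca_Competibacter     EMC         5         7    FALSE
#> 4  Ca_Competibacter SucProp         1         3    FALSE

res$phenotype
#> [1] "GAM"
```

Reading the output: the cycle shows no anaerobic phosphate release
(P/VFA = 0.00) with heavy glycogen use (Gly/VFA = 1.42 C-mol/C-mol), the
GAM signature. The dominant GAO genus carries the complete EMC pathway
(7/7 genes) while the second GAO carries only 5/7, and both carry just the
first succinate–propionate gene (`MUT`, 1/3) — so the complete-EMC genus is
the one that can make propionyl-CoA, hence PHV, on its own. The measured
ratio deltas differ from the planted yields (1.32/1.72/0.37) only through
the configured 2% measurement noise. `gao_results/` also contains
`top_hosts.tsv` (top-5 host genera per gene), `genus_profile.tsv`,
`fold_changes.tsv` (transcript tiers: >2-fold, >4-fold),
`literature_comparison.tsv` and a run manifest with input checksums.

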
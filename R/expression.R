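#' Read a metatranscriptome expression series
#'
#' Three-column TSV `gene<TAB>timepoint<TAB>abundance` with header; one row
#' per gene and timepoint, abundances are relative transcript levels.
#'
#' @param path Path to the table.
#' @return Tibble `gene`, `timepoint`, `abundance`.
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    timepoint = readr::col_double(),
    abundance = readr::col_double()
  ), progress = FALSE)
}

#' Fold change of one gene's expression series versus a baseline
#'
#' `fold_change(t) = abundance(t) / abundance(baseline)`, so the baseline
#' itself maps to 1 and the result is invariant to uniform rescaling of the
#' series. No pseudo-count is applied: a zero baseline is an error here (see
#' [expression_tiers()] for the batch interface that flags such genes as not
#' quantifiable instead).
#'
#' @param series Tibble `timepoint`, `abundance` for a single gene
#'   (a `gene` column is allowed and carried through).
#' @param baseline Baseline timepoint; defaults to the earliest timepoint.
#' @return Tibble `timepoint`, `fold_change`, `tier` (and `gene` if present),
#'   ordered by timepoint.
#' @export
fold_change <- function(series, baseline = NULL) {
  series <- tibble::as_tibble(series)
  if ("gene" %in% names(series) && length(unique(series$gene)) > 1L) {
    stop("fold_change() expects a single gene; use expression_tiers()",
         call. = FALSE)
  }
  if (any(series$abundance < 0)) stop("abundances must be >= 0", call. = FALSE)
  if (anyDuplicated(series$timepoint)) {
    stop("duplicated timepoint in series", call. = FALSE)
  }
  series <- series[order(series$timepoint), , drop = FALSE]
  if (is.null(baseline)) baseline <- series$timepoint[1L]
  idx <- match(baseline, series$timepoint)
  if (is.na(idx)) stop("baseline timepoint ", baseline, " not in series", call. = FALSE)
  base <- series$abundance[idx]
  if (base == 0) {
    stop("baseline abundance is zero; fold change undefined", call. = FALSE)
  }
  series$fold_change <- series$abundance / base
  series$tier <- classify_tier(series$fold_change)
  series[setdiff(names(series), "abundance")]
}

#' Classify a fold change into up-regulation tiers
#'
#' Strict boundaries matching "more than two-fold" / "more than four-fold":
#' `gt4` when fc > 4, `gt2` when 2 < fc <= 4, otherwise `down_or_flat`
#' (a fold change of exactly 2 or 4 stays in the lower tier).
#'
#' @param fc Numeric vector of fold changes, all >= 0.
#' @return Character vector in `{"down_or_flat", "gt2", "gt4"}`.
#' @export
classify_tier <- function(fc) {
  if (any(fc < 0)) stop("fold change must be >= 0", call. = FALSE)
  ifelse(fc > 4, "gt4", ifelse(fc > 2, "gt2", "down_or_flat"))
}

#' Fold-change table for a multi-gene expression series
#'
#' Applies [fold_change()] per gene. Genes whose baseline abundance is zero
#' are reported with `NA` fold changes and `quantifiable = FALSE` rather than
#' an infinite ratio. A gene's overall tier (its maximum across timepoints) is
#' attached, since a gene is called up-regulated when any later timepoint
#' crosses the threshold.
#'
#' @param expr Tibble `gene`, `timepoint`, `abundance`.
#' @param baseline Baseline timepoint, default the earliest per gene.
#' @return Tibble `gene`, `timepoint`, `fold_change`, `tier`, `quantifiable`,
#'   `max_tier`.
#' @export
expression_tiers <- function(expr, baseline = NULL) {
  tier_order <- c(down_or_flat = 0L, gt2 = 1L, gt4 = 2L)
  per_gene <- lapply(split(expr, expr$gene), function(series) {
    base_t <- if (is.null(baseline)) min(series$timepoint) else baseline
    base <- series$abundance[match(base_t, series$timepoint)]
    if (is.na(base) || base == 0) {
      out <- series[order(series$timepoint), c("gene", "timepoint")]
      out$fold_change <- NA_real_
      out$tier <- NA_character_
      out$quantifiable <- FALSE
      out$max_tier <- NA_character_
      return(out)
    }
    out <- fold_change(series, baseline = base_t)
    out$quantifiable <- TRUE
    out$max_tier <- names(tier_order)[max(tier_order[out$tier]) + 1L]
    out[, c("gene", "timepoint", "fold_change", "tier", "quantifiable",
            "max_tier")]
  })
  dplyr::bind_rows(per_gene)
}
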
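#' Monomer constants of the cycle analytes
#'
#' Fixed chemistry used for the carbon-mol bookkeeping: acetate C2H4O2
#' (60.05 g/mol, 2 C), glycogen counted as glucosyl units C6H10O5
#' (162.14 g/mol, 6 C), PHB monomer C4H6O2 (86.09 g/mol, 4 C), PHV monomer
#' C5H8O2 (100.12 g/mol, 5 C). Phosphate is tracked as mol of P
#' (31.0 g/mol, no carbon).
#'
#' @return Tibble `analyte`, `monomer_mass`, `carbons`.
#' @export
analyte_constants <- function() {
  tibble::tibble(
    analyte = c("acetate", "glycogen", "PHB", "PHV", "phosphate_P"),
    monomer_mass = c(60.05, 162.14, 86.09, 100.12, 31.0),
    carbons = c(2, 6, 4, 5, 0)
  )
}

.cycle_column <- c(
  acetate = "acetate_mg_L", glycogen = "glycogen_g_gSS", PHB = "phb_g_gSS",
  PHV = "phv_g_gSS", phosphate_P = "phosphate_mgP_L"
)

#' Read an anaerobic-aerobic cycle time series
#'
#' CSV with columns `time_min`, `phase`, `acetate_mg_L`, `glycogen_g_gSS`,
#' `phb_g_gSS`, `phv_g_gSS`, `phosphate_mgP_L`. Intracellular polymers are on
#' a per-biomass basis (g per g suspended solids); dissolved acetate and
#' phosphate-P are bulk concentrations. Times must be strictly increasing and
#' concentrations non-negative; phases come from
#' `{anaerobic, settle, decant, aerobic, idle}`.
#'
#' @param path Path to the CSV.
#' @return Tibble, one row per sampling time.
#' @export
read_cycle <- function(path) {
  series <- readr::read_csv(path, col_types = readr::cols(
    time_min = readr::col_double(), phase = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  required <- c("time_min", "phase", unname(.cycle_column))
  missing_cols <- setdiff(required, names(series))
  if (length(missing_cols) > 0L) {
    stop("cycle series lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(diff(series$time_min) <= 0)) {
    stop("cycle times must be strictly increasing", call. = FALSE)
  }
  bad_phase <- setdiff(unique(series$phase),
                       c("anaerobic", "settle", "decant", "aerobic", "idle"))
  if (length(bad_phase) > 0L) {
    stop("unknown phase label(s): ", paste(bad_phase, collapse = ", "),
         call. = FALSE)
  }
  if (any(as.matrix(series[unname(.cycle_column)]) < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  series
}

#' Net change of an analyte over a cycle phase
#'
#' Signed difference: value at the last sampling time of the phase minus value
#' at the first. Consumption therefore comes out negative and production
#' positive, in the analyte's native units.
#'
#' @param series Cycle tibble from [read_cycle()] or [simulate_cycle()].
#' @param analyte One of `"acetate"`, `"glycogen"`, `"PHB"`, `"PHV"`,
#'   `"phosphate_P"`.
#' @param phase Phase label, e.g. `"anaerobic"`.
#' @return Signed numeric delta.
#' @export
phase_delta <- function(series, analyte, phase) {
  col <- .cycle_column[analyte]
  if (is.na(col)) stop("unknown analyte '", analyte, "'", call. = FALSE)
  rows <- series[series$phase == phase, , drop = FALSE]
  if (nrow(rows) < 2L) {
    stop("phase '", phase, "' has fewer than 2 rows in the series", call. = FALSE)
  }
  rows[[col]][nrow(rows)] - rows[[col]][1L]
}

#' Convert an analyte mass change to carbon-mol (or mol P)
#'
#' `|mass| / monomer_mass * carbons_per_monomer`, sign preserved; for
#' `phosphate_P` the result is mol of P (`mass / 31.0`).
#'
#' @param mass Mass change, g (per gSS for intracellular polymers).
#' @param analyte Analyte name, see [analyte_constants()].
#' @return C-mol (or mol P for phosphate), same sign as `mass`.
#' @export
to_cmol <- function(mass, analyte) {
  const <- analyte_constants()
  i <- match(analyte, const$analyte)
  if (is.na(i)) stop("unknown analyte '", analyte, "'", call. = FALSE)
  if (analyte == "phosphate_P") return(mass / const$monomer_mass[i])
  mass / const$monomer_mass[i] * const$carbons[i]
}

#' Anaerobic stoichiometric ratio set
#'
#' Builds the six model ratios used to compare glycogen- and
#' phosphorus-accumulating metabolisms, on a carbon-mol basis (mol P for
#' phosphorus): P/VFA, Gly/VFA, PHB/VFA, PHV/VFA, PHAs/VFA and PHV/PHB.
#' Deltas follow the [phase_delta()] sign convention (glycogen consumption
#' negative, polymer production positive, phosphate release positive);
#' internally glycogen consumption and phosphate release are taken as
#' positive magnitudes. `PHAs_per_VFA` is the exact sum of the PHB and PHV
#' ratios by construction.
#'
#' @param deltas Named list of signed anaerobic deltas: `glycogen`, `PHB`,
#'   `PHV` in g/gSS and `phosphate_P` in mol P per gSS (default 0).
#' @param vfa_uptake Acetate taken up over the same window, C-mol per gSS,
#'   > 0.
#' @return Object of class `gao_ratios`: named list `P_per_VFA`,
#'   `Gly_per_VFA`, `PHB_per_VFA`, `PHV_per_VFA`, `PHAs_per_VFA`,
#'   `PHV_per_PHB` (full precision; the print method rounds to 2 decimals).
#' @export
gam_ratios <- function(deltas, vfa_uptake) {
  if (!is.numeric(vfa_uptake) || vfa_uptake <= 0) {
    stop("vfa_uptake must be a positive C-mol quantity", call. = FALSE)
  }
  d <- function(name) if (is.null(deltas[[name]])) 0 else deltas[[name]]
  gly_cmol <- to_cmol(-d("glycogen"), "glycogen")  # consumption as positive
  phb_cmol <- to_cmol(d("PHB"), "PHB")
  phv_cmol <- to_cmol(d("PHV"), "PHV")
  p_mol <- d("phosphate_P")
  phv_per_phb <- if (phb_cmol == 0) {
    if (phv_cmol != 0) {
      warning("zero PHB production with nonzero PHV; PHV/PHB undefined")
    }
    NA_real_
  } else {
    phv_cmol / phb_cmol
  }
  structure(
    list(
      P_per_VFA = p_mol / vfa_uptake,
      Gly_per_VFA = gly_cmol / vfa_uptake,
      PHB_per_VFA = phb_cmol / vfa_uptake,
      PHV_per_VFA = phv_cmol / vfa_uptake,
      PHAs_per_VFA = (phb_cmol + phv_cmol) / vfa_uptake,
      PHV_per_PHB = phv_per_phb
    ),
    class = "gao_ratios"
  )
}

#' @export
print.gao_ratios <- function(x, ...) {
  vals <- vapply(unclass(x), function(v) round(v, 2), numeric(1L))
  cat("<gao_ratios> (C-mol basis; mol P for phosphorus)\n")
  print(vals)
  invisible(x)
}

#' One-row tibble form of a ratio set
#'
#' @param ratios A `gao_ratios` object.
#' @param digits Rounding applied for reporting (default 2, matching the
#'   conventional table style); use `NULL` for full precision.
#' @return One-row tibble with the six ratio columns.
#' @export
ratio_row <- function(ratios, digits = 2) {
  stopifnot(inherits(ratios, "gao_ratios"))
  row <- tibble::as_tibble(unclass(ratios))
  if (!is.null(digits)) row <- dplyr::mutate(row, dplyr::across(
    dplyr::everything(), ~ round(.x, digits)))
  row
}

#' Ratio set straight from a cycle time series
#'
#' Computes the anaerobic deltas, converts the dissolved analytes to a
#' per-biomass basis with the mixed-liquor suspended-solids concentration,
#' and calls [gam_ratios()]. The accounting window is either the full
#' anaerobic phase or only up to acetate depletion (the first time the
#' acetate reading falls to zero), which matters when substrate runs out well
#' before the phase ends.
#'
#' @param series Cycle tibble from [read_cycle()] or [simulate_cycle()].
#' @param mlss_g_L Biomass concentration, g suspended solids per litre, > 0.
#' @param window `"full"` (default) or `"to_depletion"`.
#' @return A `gao_ratios` object.
#' @export
cycle_ratios <- function(series, mlss_g_L, window = c("full", "to_depletion")) {
  window <- match.arg(window)
  if (!is.numeric(mlss_g_L) || mlss_g_L <= 0) {
    stop("mlss_g_L must be positive", call. = FALSE)
  }
  rows <- series[series$phase == "anaerobic", , drop = FALSE]
  if (nrow(rows) < 2L) stop("anaerobic phase has fewer than 2 rows", call. = FALSE)
  if (window == "to_depletion") {
    depleted <- which(rows$acetate_mg_L <= 0)
    if (length(depleted) > 0L) rows <- rows[seq_len(depleted[1L]), , drop = FALSE]
  }
  last <- nrow(rows)
  delta <- function(col) rows[[col]][last] - rows[[col]][1L]
  acetate_g_gSS <- delta("acetate_mg_L") / 1000 / mlss_g_L
  vfa_uptake <- to_cmol(-acetate_g_gSS, "acetate")
  p_mol_gSS <- to_cmol(delta("phosphate_mgP_L") / 1000 / mlss_g_L, "phosphate_P")
  gam_ratios(
    deltas = list(
      glycogen = delta("glycogen_g_gSS"),
      PHB = delta("phb_g_gSS"),
      PHV = delta("phv_g_gSS"),
      phosphate_P = p_mol_gSS
    ),
    vfa_uptake = vfa_uptake
  )
}

#' Classify the anaerobic phenotype from its ratio set
#'
#' Glycogen-accumulating metabolism (GAM) shows essentially no phosphate
#' release and heavy glycogen use; phosphorus-accumulating metabolism (PAM)
#' shows strong phosphate release. Thresholds reflect the spread of published
#' model rows (GAM-like rows sit at P/VFA 0.00-0.08, PAO rows at 0.62-0.73):
#' GAM when `P/VFA <= p_gam_max` and `Gly/VFA >= gly_gam_min`; PAM when
#' `P/VFA >= p_pam_min`; otherwise `mixed`.
#'
#' @param ratios A `gao_ratios` object.
#' @param p_gam_max Maximum P/VFA for a GAM call (default 0.10).
#' @param gly_gam_min Minimum Gly/VFA for a GAM call (default 1.0).
#' @param p_pam_min Minimum P/VFA for a PAM call (default 0.30).
#' @return `"GAM"`, `"PAM"` or `"mixed"`.
#' @export
classify_metabolism <- function(ratios, p_gam_max = 0.10, gly_gam_min = 1.0,
                                p_pam_min = 0.30) {
  stopifnot(inherits(ratios, "gao_ratios"))
  if (ratios$P_per_VFA >= p_pam_min) return("PAM")
  if (ratios$P_per_VFA <= p_gam_max && ratios$Gly_per_VFA >= gly_gam_min) {
    return("GAM")
  }
  "mixed"
}

#' Anaerobic carbon recovery fraction
#'
#' PHA carbon formed divided by carbon consumed (acetate taken up plus
#' glycogen degraded), all in C-mol. Values below 1 are expected because part
#' of the carbon leaves as CO2; a value above 1 indicates inconsistent
#' measurements and raises a warning.
#'
#' @param x Either a `gao_ratios` object, or the PHA carbon formed in C-mol.
#' @param vfa_cmol,gly_cmol When `x` is numeric: acetate and glycogen carbon
#'   consumed, C-mol; their sum must be positive.
#' @param ... Unused.
#' @return Recovery fraction in `[0, Inf)`.
#' @export
carbon_balance <- function(x, ...) UseMethod("carbon_balance")

#' @rdname carbon_balance
#' @export
carbon_balance.gao_ratios <- function(x, ...) {
  carbon_balance(x$PHAs_per_VFA, vfa_cmol = 1, gly_cmol = x$Gly_per_VFA)
}

#' @rdname carbon_balance
#' @export
carbon_balance.default <- function(x, vfa_cmol, gly_cmol, ...) {
  denom <- vfa_cmol + gly_cmol
  if (denom <= 0) stop("carbon consumed must be positive", call. = FALSE)
  recovery <- x / denom
  if (recovery > 1) {
    warning("carbon recovery above 1: PHA formed exceeds carbon consumed")
  }
  recovery
}

#' Published GAO/PAO model ratio rows
#'
#' The literature comparison panel of anaerobic stoichiometric ratios from
#' classic GAO, PAO and PAO-GAM enrichment studies, used as the reference
#' rows for [compare_to_literature()]. `NA` marks a ratio the source did not
#' report.
#'
#' @return Tibble `study`, `model`, `srt_days`, `ph`, plus the six ratio
#'   columns.
#' @export
literature_ratios <- function() {
  tibble::tribble(
    ~study,                 ~model,          ~srt_days, ~ph,         ~P_per_VFA, ~Gly_per_VFA, ~PHB_per_VFA, ~PHV_per_VFA, ~PHAs_per_VFA, ~PHV_per_PHB,
    "Zeng 2003",            "GAO",           6.6,       "7 +/- 0.1", NA,         1.20,         1.39,         0.52,         1.91,          0.38,
    "Lopez-Vazquez 2007",   "GAO",           10,        "7 +/- 0.1", 0.01,       1.20,         1.28,         0.69,         1.97,          0.54,
    "Lu 2006",              "PAO",           8,         "7.0-8.0",   0.62,       0.46,         1.18,         0.07,         1.25,          0.06,
    "Acevedo 2012",         "PAO",           8,         "7.0-8.9",   0.73,       0.35,         1.30,         0.06,         1.36,          0.05,
    "Welles 2015",          "PAOII-GAO-GAM", 8,         "7.0 +/- 0.1", 0.03,     1.28,         1.45,         0.50,         1.95,          0.34,
    "Acevedo 2012 (GAM)",   "PAO-GAM",       8,         "7.0-8.9",   0.08,       1.08,         1.74,         0.28,         2.02,          0.16,
    "Acevedo 2014 (GAM)",   "PAO-GAM",       8,         "7.0-9.0",   0.05,       1.19,         1.31,         0.63,         1.94,          0.48
  )
}

#' Compare a computed ratio set with the literature panel
#'
#' Appends the computed row to the bundled model rows of
#' [literature_ratios()] and flags the nearest published row by Euclidean
#' distance over the six ratios (coordinates the source did not report are
#' skipped pairwise).
#'
#' @param ratios A `gao_ratios` object.
#' @param label Row label for the computed entry (default `"this run"`).
#' @return Tibble: literature rows plus the computed row, with `distance`
#'   to the computed row and a logical `nearest` flag.
#' @export
compare_to_literature <- function(ratios, label = "this run") {
  stopifnot(inherits(ratios, "gao_ratios"))
  lit <- literature_ratios()
  ratio_cols <- c("P_per_VFA", "Gly_per_VFA", "PHB_per_VFA", "PHV_per_VFA",
                  "PHAs_per_VFA", "PHV_per_PHB")
  own <- unlist(unclass(ratios)[ratio_cols])
  dist <- apply(as.matrix(lit[ratio_cols]), 1L, function(row) {
    ok <- !is.na(row) & !is.na(own)
    sqrt(sum((row[ok] - own[ok])^2))
  })
  lit$distance <- dist
  lit$nearest <- dist == min(dist)
  this_row <- dplyr::bind_cols(
    tibble::tibble(study = label, model = classify_metabolism(ratios),
                   srt_days = NA_real_, ph = NA_character_),
    ratio_row(ratios, digits = NULL),
    tibble::tibble(distance = 0, nearest = FALSE)
  )
  dplyr::bind_rows(lit, this_row)
}
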
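#' Intrinsic exchange-rate parameter tables
#'
#' Loads the reference parameterization for unprotected (random-coil) amide
#' hydrogen exchange into D2O: poly-DL-alanine reference rate constants with
#' Arrhenius activation energies, and the per-side-chain acid/base log10
#' catalysis factors with their titration pK values, after Bai, Milne, Mayne
#' & Englander (1993) Proteins 17:75 and Connelly et al. (1993) Proteins
#' 17:87. Shipped as versioned CSVs (`hx_sidechain_factors_v1.csv`,
#' `hx_reference_rates_v1.csv`) under `inst/extdata`; pass paths to override
#' with a recalibrated table of the same shape.
#'
#' Reference rates are in M^-1 min^-1 (acid, base) and min^-1 (water) at the
#' reference temperature; the water catalysis term is modulated by the base
#' side-chain factors, following the reference spreadsheet convention.
#'
#' @param factors_path,rates_path Optional overriding CSV paths.
#' @return A list with `factors` (tibble) and `rates` (named numeric vector),
#'   class `hx_params`.
#' @export
intrinsic_rate_params <- function(factors_path = NULL, rates_path = NULL) {
  factors_path <- factors_path %||%
    system.file("extdata", "hx_sidechain_factors_v1.csv", package = "mshdx")
  rates_path <- rates_path %||%
    system.file("extdata", "hx_reference_rates_v1.csv", package = "mshdx")
  factors <- readr::read_csv(
    factors_path,
    col_types = readr::cols(
      residue = readr::col_character(),
      form = readr::col_character(),
      acid_lambda = readr::col_double(),
      acid_rho = readr::col_double(),
      base_lambda = readr::col_double(),
      base_rho = readr::col_double(),
      pk = readr::col_double()
    ),
    progress = FALSE
  )
  rates_df <- readr::read_csv(
    rates_path,
    col_types = readr::cols(
      parameter = readr::col_character(),
      value = readr::col_double()
    ),
    progress = FALSE
  )
  rates <- setNames(rates_df$value, rates_df$parameter)
  needed <- c(
    "log10_ka", "log10_kb", "log10_kw", "ea_acid_kcal_mol",
    "ea_base_kcal_mol", "ea_water_kcal_mol", "pkd", "t_ref_k"
  )
  missing <- setdiff(needed, names(rates))
  if (length(missing) > 0L) {
    abort(paste0("Reference-rate table is missing: ", paste(missing, collapse = ", ")))
  }
  structure(list(factors = factors, rates = rates), class = "hx_params")
}

# log10 of a titration-weighted catalysis factor: Henderson-Hasselbalch mix of
# the protonated and deprotonated factors at the working pD.
titrate_factor <- function(f_prot, f_deprot, pk, pd) {
  log10((10^(f_prot - pd) + 10^(f_deprot - pk)) / (10^(-pd) + 10^(-pk)))
}

# Look up one side-chain log10 factor (column = acid_lambda, acid_rho,
# base_lambda or base_rho) for residue code `res`, titrated where needed.
sidechain_factor <- function(factors, res, column, pd) {
  rows <- factors[factors$residue == res, , drop = FALSE]
  if (nrow(rows) == 0L) abort(sprintf("No side-chain factors for residue '%s'.", res))
  if (nrow(rows) == 1L) {
    val <- rows[[column]][1]
    return(if (is.na(val)) 0 else val)
  }
  prot <- rows[rows$form %in% "prot", , drop = FALSE]
  deprot <- rows[rows$form %in% "deprot", , drop = FALSE]
  fp <- prot[[column]][1]
  fd <- deprot[[column]][1]
  if (is.na(fp) || is.na(fd)) return(0)
  titrate_factor(fp, fd, prot$pk[1], pd)
}

#' Sequence-dependent intrinsic amide exchange rates
#'
#' Computes the intrinsic (random-coil) chemical exchange rate constant of
#' each backbone amide in a peptide under the given labeling conditions. For
#' the amide of residue i the rate is the sum of acid-, base- and
#' water-catalyzed terms, each scaled by the log-additive side-chain factors
#' of residue i and of its left neighbor i-1, with catalyst concentrations
#' set by the glass-electrode-corrected pD (pD = pD_read + 0.4) and the D2O
#' ion product, and each term corrected to the working temperature by an
#' Arrhenius factor. The C-terminal carboxyl contributes a titrated factor to
#' the last residue's amide. Residues 1 and 2 and all prolines are excluded
#' and carry a rate of exactly zero.
#'
#' @param peptide A `peptide_spec` or sequence string.
#' @param cond A [labeling_conditions()] object.
#' @param params Parameter tables from [intrinsic_rate_params()].
#' @return A tibble with one row per residue: `position`, `residue`, `aa`,
#'   `k_int` (s^-1; exactly 0 for excluded residues), `included`,
#'   `exclusion_reason`.
#' @examples
#' residue_intrinsic_rates("AAAA", labeling_conditions(7.0 - 0.4, 293.15, 1))
#' @export
residue_intrinsic_rates <- function(peptide,
                                    cond = labeling_conditions(),
                                    params = intrinsic_rate_params()) {
  peptide <- as_peptide_spec(peptide)
  if (!inherits(cond, "labeling_conditions")) {
    abort("`cond` must be a labeling_conditions object.")
  }
  pos <- amide_positions(peptide)
  aa <- pos$aa
  n <- nrow(pos)
  pd <- cond$pd
  r <- params$rates

  # catalyst concentrations (molar) from the corrected pD and D2O ion product
  conc_d <- 10^(-pd)
  conc_od <- 10^(pd - r[["pkd"]])

  # Arrhenius correction of each catalytic rate constant to the working
  # temperature; R in kcal mol^-1 K^-1
  gas_r <- 1.987e-3
  arr <- function(ea) exp(-(ea / gas_r) * (1 / cond$temperature - 1 / r[["t_ref_k"]]))
  ka <- 10^r[["log10_ka"]] * arr(r[["ea_acid_kcal_mol"]])
  kb <- 10^r[["log10_kb"]] * arr(r[["ea_base_kcal_mol"]])
  kw <- 10^r[["log10_kw"]] * arr(r[["ea_water_kcal_mol"]])

  factors <- params$factors
  k_int <- numeric(n)
  for (i in seq_len(n)) {
    if (!pos$included[i]) next
    la <- sidechain_factor(factors, aa[i], "acid_lambda", pd)
    lb <- sidechain_factor(factors, aa[i], "base_lambda", pd)
    ra <- sidechain_factor(factors, aa[i - 1], "acid_rho", pd)
    rb <- sidechain_factor(factors, aa[i - 1], "base_rho", pd)
    if (i == n) {
      la <- la + sidechain_factor(factors, "cterm", "acid_lambda", pd)
      lb <- lb + sidechain_factor(factors, "cterm", "base_lambda", pd)
    }
    fa <- 10^(la + ra)
    fb <- 10^(lb + rb)
    # per-minute rate; water term shares the base-catalysis factors
    k_min <- ka * fa * conc_d + kb * fb * conc_od + kw * fb
    k_int[i] <- k_min / 60
  }
  if (any(k_int[pos$included] <= 0)) {
    abort("Internal error: non-positive intrinsic rate for an included residue.")
  }
  dplyr::mutate(pos, k_int = k_int, .after = "aa")
}

#' Theoretical maximum-exchange uptake curve
#'
#' The uptake of a fully unprotected peptide:
#' D_int(t) = d2o_fraction * sum_i (1 - exp(-k_int,i * t)) over the included
#' residues. Non-decreasing in t, zero at t = 0, and bounded by
#' `d2o_fraction * Q`.
#'
#' @param rates Tibble from [residue_intrinsic_rates()] (excluded residues
#'   carry k_int = 0 and contribute nothing).
#' @param times Labeling times in seconds, all >= 0.
#' @param d2o_fraction D2O fraction of the labeling reaction, in (0, 1].
#' @return A tibble with `exposure` (s) and `uptake` (Da).
#' @export
intrinsic_uptake_curve <- function(rates, times, d2o_fraction = 0.95) {
  if (any(times < 0)) abort("Labeling times must be non-negative.")
  if (d2o_fraction <= 0 || d2o_fraction > 1) abort("`d2o_fraction` must lie in (0, 1].")
  k <- rates$k_int[rates$included]
  uptake <- vapply(
    times,
    function(t) d2o_fraction * sum(1 - exp(-k * t)),
    numeric(1)
  )
  tibble::tibble(exposure = as.numeric(times), uptake = uptake)
}

#' Theoretical maximum uptake of a peptide
#'
#' `d2o_fraction * Q` where Q counts the exchangeable amides.
#'
#' @inheritParams intrinsic_uptake_curve
#' @param peptide A `peptide_spec` or sequence string.
#' @return Maximum uptake in Da.
#' @export
theoretical_max_uptake <- function(peptide, d2o_fraction = 0.95) {
  peptide <- as_peptide_spec(peptide)
  d2o_fraction * peptide$n_amides
}
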
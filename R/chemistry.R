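## Derived chemistry indices: organic carbon, H/C_org, century-scale
## persistent carbon, CEC-based cation retention, basis conversion and
## community waste-stream arithmetic.

#' Molar masses and valences of the exchangeable base cations
#'
#' Constants used by [cation_retention()]: molar mass (g/mol, equal to
#' mg/mmol) and cation valence for K, Ca and Mg.
#'
#' @return data.frame with columns `element`, `mw`, `valence`.
#' @export
element_constants <- function() {
  data.frame(element = c("k", "ca", "mg"),
             mw = c(39.10, 40.08, 24.31),
             valence = c(1L, 2L, 2L),
             stringsAsFactors = FALSE)
}

#' Organic carbon as total minus inorganic carbon
#'
#' @param c_total total carbon mass fraction in \[0, 1\].
#' @param c_inorg inorganic (carbonate) carbon mass fraction; must not
#'   exceed `c_total`.
#' @return organic-carbon mass fraction.
#' @export
organic_carbon <- function(c_total, c_inorg) {
  stopifnot(is.numeric(c_total), is.numeric(c_inorg))
  if (any(c_total < 0 | c_total > 1, na.rm = TRUE) ||
      any(c_inorg < 0 | c_inorg > 1, na.rm = TRUE))
    abort("carbon inputs must be mass fractions in [0, 1]")
  if (any(c_inorg > c_total, na.rm = TRUE))
    abort("c_inorg exceeds c_total")
  c_total - c_inorg
}

#' Hydrogen to organic carbon molar ratio
#'
#' Converts mass fractions to a molar ratio using atomic masses
#' H = 1.008 and C = 12.011 g/mol.
#'
#' @param h_mass_frac hydrogen mass fraction.
#' @param corg_mass_frac organic-carbon mass fraction; must be > 0.
#' @return molar H/C_org ratio (dimensionless).
#' @export
h_over_corg <- function(h_mass_frac, corg_mass_frac) {
  if (any(h_mass_frac < 0, na.rm = TRUE)) abort("negative hydrogen fraction")
  if (any(corg_mass_frac <= 0, na.rm = TRUE))
    abort("organic carbon must be positive to form H/C_org")
  (h_mass_frac / 1.008) / (corg_mass_frac / 12.011)
}

#' Century-scale persistent carbon from the H/C_org molar ratio
#'
#' Predicts the percentage of organic carbon expected to persist in soil
#' beyond 100 years as a linear function of the molar H/C_org ratio,
#' `-61.6 * H/C_org + 105`, clamped to \[0, 100\] (the intercept of 105
#' otherwise permits values above 100 percent). The unclamped value is
#' returned alongside.
#'
#' @param h_over_corg molar H/C_org ratio, nonnegative.
#' @return data.frame with columns `raw` and `bc100` (clamped percent of
#'   organic carbon).
#' @export
bc100 <- function(h_over_corg) {
  if (any(h_over_corg < 0, na.rm = TRUE)) abort("H/C_org must be nonnegative")
  raw <- -61.6 * h_over_corg + 105
  data.frame(raw = raw, bc100 = pmin(pmax(raw, 0), 100))
}

#' Cation retention attributable to cation exchange capacity
#'
#' Apportions the exchange capacity of an amendment over the three
#' plant-available (Mehlich-III extractable) base cations in proportion to
#' their mass-concentration shares, and converts the allotted charge to a
#' retained mass per cation:
#' `retention_i = share_i * (cec / valence_i) * Mw_i` (mg/kg), with CEC in
#' mmol_c/kg and Mw in mg/mmol.
#'
#' @param mehlich_k,mehlich_ca,mehlich_mg Mehlich-III extractable K, Ca and
#'   Mg concentrations (mg/kg amendment).
#' @param cec cation exchange capacity (mmol_c/kg amendment).
#' @param constants element constant table, by default [element_constants()].
#' @return list with `retention_mg_kg` (named vector over k/ca/mg) and
#'   `total_g_per_kg`.
#' @export
cation_retention <- function(mehlich_k, mehlich_ca, mehlich_mg, cec,
                             constants = element_constants()) {
  conc <- c(k = mehlich_k, ca = mehlich_ca, mg = mehlich_mg)
  if (any(conc < 0) || cec < 0) abort("inputs must be nonnegative")
  if (cec == 0) {
    ret <- c(k = 0, ca = 0, mg = 0)
    return(list(retention_mg_kg = ret, total_g_per_kg = 0))
  }
  tot <- sum(conc)
  if (tot == 0)
    abort("cation shares undefined: CEC > 0 but all Mehlich K/Ca/Mg are zero")
  share <- conc / tot
  idx <- match(names(conc), constants$element)
  ret <- share * (cec / constants$valence[idx]) * constants$mw[idx]
  list(retention_mg_kg = ret, total_g_per_kg = sum(ret) / 1000)
}

#' Back-derive CEC from a printed retained-cation total
#'
#' Composition tables report the CEC row as the total retained mass of
#' K+, Ca2+ and Mg2+ in g/kg. Given that total and the Mehlich-III
#' concentrations, this inverts [cation_retention()] to recover the
#' exchange capacity in mmol_c/kg.
#'
#' @param total_g_per_kg retained K+Ca+Mg mass, g/kg amendment.
#' @inheritParams cation_retention
#' @return CEC in mmol_c/kg.
#' @export
cec_from_retained_total <- function(total_g_per_kg, mehlich_k, mehlich_ca,
                                    mehlich_mg,
                                    constants = element_constants()) {
  conc <- c(k = mehlich_k, ca = mehlich_ca, mg = mehlich_mg)
  if (total_g_per_kg == 0) return(0)
  if (sum(conc) == 0) abort("cation shares undefined for nonzero retention")
  share <- conc / sum(conc)
  idx <- match(names(conc), constants$element)
  denom <- sum(share * constants$mw[idx] / constants$valence[idx])
  total_g_per_kg * 1000 / denom
}

#' Convert a per-Mg-amendment quantity to a per-Mg-feedstock basis
#'
#' Multiplies by the treatment's dry-mass yield (Mg amendment recovered per
#' Mg dry feedstock).
#'
#' @param value_per_amendment quantity per Mg amendment.
#' @param mass_yield dry-mass yield in (0, 1\].
#' @return the quantity per Mg of dry feedstock.
#' @export
per_feedstock <- function(value_per_amendment, mass_yield) {
  if (any(is.na(mass_yield)) || any(mass_yield <= 0) || any(mass_yield > 1))
    abort("mass_yield must lie in (0, 1]")
  value_per_amendment * mass_yield
}

#' Nutrient supplied by land-applying one ton of amendment
#'
#' @param concentration_mg_kg concentration in mg/kg amendment.
#' @return kg of the component per Mg of amendment.
#' @export
per_ton_supply <- function(concentration_mg_kg) {
  if (any(concentration_mg_kg < 0, na.rm = TRUE))
    abort("concentration must be nonnegative")
  concentration_mg_kg * 1e-3
}

#' Fold change between two concentrations
#'
#' @param numerator,denominator same-unit quantities; `denominator` > 0.
#' @return `numerator / denominator`.
#' @export
fold_change <- function(numerator, denominator) {
  if (any(denominator == 0, na.rm = TRUE))
    abort("fold change undefined for zero denominator")
  numerator / denominator
}

#' Community-scale waste-stream generation
#'
#' Scales per-capita generation rates to a community: dry solid waste in
#' Mg/day and urine in m^3/day.
#'
#' @param spec data.frame (or one-row list) with fields `population`,
#'   `dry_g_per_person_day` and `urine_ml_per_person_day` (see
#'   [hsw_fixture()] for the packaged specifications).
#' @return data.frame with columns `population`, `dry_mg_day`
#'   (Mg/community/day) and `urine_m3_day` (m^3/community/day).
#' @export
waste_stream <- function(spec) {
  spec <- as.data.frame(spec, stringsAsFactors = FALSE)
  stopifnot(all(c("population", "dry_g_per_person_day",
                  "urine_ml_per_person_day") %in% names(spec)))
  if (any(spec$population < 0)) abort("population must be nonnegative")
  spec$population <- as.numeric(spec$population)  # avoid integer overflow
  out <- data.frame(
    population = spec$population,
    dry_mg_day = spec$population * spec$dry_g_per_person_day * 1e-6,
    urine_m3_day = spec$population * spec$urine_ml_per_person_day * 1e-6
  )
  if ("community" %in% names(spec)) out <- cbind(community = spec$community, out)
  out
}

#' Validate a waste-stream specification table
#'
#' Checks nonnegativity, water content in \[0, 1\], and that the dry rate
#' agrees with `fresh * (1 - water_content)` within a declared tolerance.
#'
#' @param spec data.frame with columns `population`,
#'   `fresh_g_per_person_day`, `water_content`, `dry_g_per_person_day`,
#'   `urine_ml_per_person_day`.
#' @param tol relative tolerance for the fresh/dry consistency check.
#' @return `spec`, invisibly.
#' @export
validate_waste_stream <- function(spec, tol = 0.02) {
  num <- c("population", "fresh_g_per_person_day", "water_content",
           "dry_g_per_person_day", "urine_ml_per_person_day")
  for (cn in intersect(num, names(spec)))
    if (any(spec[[cn]] < 0, na.rm = TRUE)) abort("negative ", cn)
  if (any(spec$water_content > 1, na.rm = TRUE))
    abort("water_content must lie in [0, 1]")
  implied <- spec$fresh_g_per_person_day * (1 - spec$water_content)
  off <- abs(implied - spec$dry_g_per_person_day) / pmax(implied, 1e-12)
  if (any(off > tol, na.rm = TRUE))
    abort("dry rate inconsistent with fresh * (1 - water_content)")
  invisible(spec)
}
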
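## Bottom-up valuation: price-weighted sum of ten agronomic components at
## empirical price quantiles, with the 0.9 - 0.1 quantile sensitivity.

#' The ten valued agronomic components
#'
#' @return character vector of component labels in report order.
#' @export
valuation_components <- function() {
  c("available_n", "p", "k", "ca", "mg", "s", "micronutrients",
    "cec_cations", "caco3", "bc100")
}

#' Value of one component at one price
#'
#' @param concentration component amount per Mg amendment (kg/Mg).
#' @param unit_price USD per unit amount (USD/kg).
#' @return USD per Mg amendment.
#' @export
component_value <- function(concentration, unit_price) {
  if (any(concentration < 0, na.rm = TRUE) || any(unit_price < 0, na.rm = TRUE))
    abort("concentration and price must be nonnegative")
  concentration * unit_price
}

# internal: physical loadings of the ten components for one record.
# Returns list(simple = named kg/Mg for the directly priced components,
# cec = named kg/Mg retained K/Ca/Mg). The bc100 entry is kg CO2-eq/Mg:
# persistent C = (BC+100 / 100) * C_org * 1000 kg/Mg, times 44/12.
.component_loadings <- function(record) {
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  stopifnot(nrow(record) == 1)
  g <- function(cn) if (cn %in% names(record)) record[[cn]][1] else NA_real_
  need <- function(v, what) {
    if (is.na(v)) abort("cannot value treatment '", record$treatment_id[1],
                        "': missing ", what)
    v
  }
  kg <- function(mg_kg) mg_kg * 1e-3   # mg/kg amendment -> kg/Mg amendment
  simple <- c(
    available_n = kg(need(g("available_n"), "available_n")),
    p = kg(need(g("p"), "p")), k = kg(need(g("k"), "k")),
    ca = kg(need(g("ca"), "ca")), mg = kg(need(g("mg"), "mg")),
    s = kg(need(g("s"), "s")),
    micronutrients = kg(need(g("micronutrients"), "micronutrients")),
    caco3 = need(g("caco3_equiv"), "caco3_equiv") * 10,  # % w/w -> kg/Mg
    bc100 = NA_real_)
  bc <- g("bc100")
  if (is.na(bc)) {
    corg <- organic_carbon(need(g("c_total"), "c_total or bc100"),
                           need(g("c_inorg"), "c_inorg or bc100"))
    bc <- bc100(h_over_corg(need(g("h_total"), "h_total or bc100"), corg))$bc100
  }
  corg <- organic_carbon(need(g("c_total"), "c_total (for BC+100 pricing)"),
                         need(g("c_inorg"), "c_inorg (for BC+100 pricing)"))
  simple[["bc100"]] <- (bc / 100) * corg * 1000 * (44 / 12)
  cec <- g("cec")
  if (is.na(cec) && !is.na(g("cec_cations")))
    cec <- cec_from_retained_total(g("cec_cations"), need(g("k"), "k"),
                                   need(g("ca"), "ca"), need(g("mg"), "mg"))
  cec <- need(cec, "cec or cec_cations")
  ret <- cation_retention(g("k"), g("ca"), g("mg"), cec)$retention_mg_kg
  list(simple = simple, cec = ret * 1e-3)  # retained mg/kg -> kg/Mg
}

#' Bottom-up monetary value of amendments at price quantiles
#'
#' Values each amendment as the sum over ten agronomic components of
#' physical loading (kg/Mg) times unit price (USD/kg), at every price
#' quantile. The CEC-retained base cations are valued at the K, Ca and Mg
#' prices applied to the retained masses; the liming equivalency at the
#' CaCO3 price; and century-persistent carbon as CO2-equivalents (factor
#' 44/12 on the persistent organic C mass) at the CO2 price. On the
#' feedstock basis every entry is multiplied by the treatment's dry-mass
#' yield.
#'
#' @param records amendment table in internal units ([hsw_fixture()],
#'   [read_amendments()] or [gen_compositions()]).
#' @param quantiles `price_quantiles` table covering all components of
#'   [price_components()] at every probability.
#' @param basis `"amendment"` (per Mg of finished product, default) or
#'   `"feedstock"` (per Mg of dry unsanitized input).
#' @return `hsw_valuation` object: 3-d value array
#'   (treatment x component x probability, USD/Mg), per-quantile totals,
#'   basis, and the inputs needed by [price_sensitivity()] and the
#'   reporting methods.
#' @export
bottom_up_value <- function(records, quantiles,
                            basis = c("amendment", "feedstock")) {
  basis <- match.arg(basis)
  stopifnot(inherits(quantiles, "data.frame"))
  probs <- sort(unique(quantiles$prob))
  missing <- setdiff(price_components(), unique(quantiles$component))
  if (length(missing))
    abort("missing price quantiles for component(s): ",
          paste(missing, collapse = ", "))
  comps <- valuation_components()
  n <- nrow(records)
  vals <- array(0, dim = c(n, length(comps), length(probs)),
                dimnames = list(records$treatment_id, comps, probs))
  for (i in seq_len(n)) {
    ld <- .component_loadings(records[i, , drop = FALSE])
    for (pj in seq_along(probs)) {
      p <- probs[pj]
      price <- function(comp) .price_at(quantiles, comp, p)
      for (comp in names(ld$simple)) {
        series <- if (comp == "bc100") "co2" else comp
        vals[i, comp, pj] <- component_value(ld$simple[[comp]], price(series))
      }
      vals[i, "cec_cations", pj] <-
        component_value(ld$cec[["k"]], price("k")) +
        component_value(ld$cec[["ca"]], price("ca")) +
        component_value(ld$cec[["mg"]], price("mg"))
    }
    if (basis == "feedstock") {
      y <- records$mass_yield[i]
      if (is.na(y)) abort("feedstock basis requires mass_yield for '",
                          records$treatment_id[i], "'")
      vals[i, , ] <- per_feedstock(vals[i, , ], y)
    }
  }
  totals <- apply(vals, c(1, 3), sum)
  structure(list(values = vals, totals = totals, basis = basis,
                 probs = probs, components = comps,
                 treatment_id = records$treatment_id,
                 hht_celsius = records$hht_celsius,
                 mass_yield = records$mass_yield),
            class = "hsw_valuation")
}

#' Per-component price sensitivity (0.9 minus 0.1 quantile value)
#'
#' @param result an `hsw_valuation` containing the 0.1 and 0.9 quantiles.
#' @return data.frame mirroring the sensitivity report: one row per
#'   component, one column per treatment, USD/Mg on the valuation's basis.
#' @export
price_sensitivity <- function(result) {
  stopifnot(inherits(result, "hsw_valuation"))
  need <- c(0.1, 0.9)
  if (!all(vapply(need, function(p) any(abs(result$probs - p) < 1e-12), TRUE)))
    abort("valuation lacks the 0.1 and/or 0.9 quantile")
  i1 <- which(abs(result$probs - 0.1) < 1e-12)
  i9 <- which(abs(result$probs - 0.9) < 1e-12)
  slice <- function(i) {
    m <- result$values[, , i, drop = FALSE]
    dim(m) <- dim(result$values)[1:2]
    m
  }
  d <- t(slice(i9) - slice(i1))   # components x treatments
  out <- data.frame(component = result$components, d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("component", result$treatment_id)
  out
}

#' @export
print.hsw_valuation <- function(x, digits = 1, ...) {
  cat("Bottom-up HSW amendment valuation (USD/Mg ", x$basis, ")\n\n",
      sep = "")
  print(round(x$totals, digits))
  cat("\n(totals over ", length(x$components),
      " agronomic components at ", length(x$probs),
      " price quantiles; see summary() for the per-component table)\n",
      sep = "")
  invisible(x)
}

#' @export
summary.hsw_valuation <- function(object, ...) {
  df <- as.data.frame(object)
  med <- df[abs(df$prob - 0.5) < 1e-12, , drop = FALSE]
  structure(list(basis = object$basis, totals = object$totals,
                 median_by_component = stats::reshape(
                   med[, c("treatment_id", "component", "value")],
                   idvar = "component", timevar = "treatment_id",
                   direction = "wide")),
            class = "summary.hsw_valuation")
}

#' @export
print.summary.hsw_valuation <- function(x, digits = 1, ...) {
  cat("Totals (USD/Mg ", x$basis, ") by price quantile:\n", sep = "")
  print(round(x$totals, digits))
  cat("\nMedian-quantile value by component (USD/Mg ", x$basis, "):\n",
      sep = "")
  tab <- x$median_by_component
  names(tab) <- sub("^value\\.", "", names(tab))
  tab[-1] <- lapply(tab[-1], round, digits = 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.hsw_valuation <- function(x, ...) {
  d <- dim(x$values)
  grid <- expand.grid(treatment_id = x$treatment_id,
                      component = x$components, prob = x$probs,
                      stringsAsFactors = FALSE)
  grid$value <- as.vector(x$values)
  grid$basis <- x$basis
  grid
}

#' @export
plot.hsw_valuation <- function(x, ...) {
  graphics::matplot(x$probs, t(x$totals), type = "b", pch = 19, lty = 1,
                    xlab = "price quantile probability",
                    ylab = paste0("total value (USD/Mg ", x$basis, ")"),
                    main = "Bottom-up amendment value by price quantile",
                    ...)
  graphics::legend("topleft", legend = x$treatment_id, bty = "n",
                   col = seq_along(x$treatment_id), lty = 1, pch = 19)
  invisible(x)
}
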
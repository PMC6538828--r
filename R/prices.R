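## Component price observations and empirical quantile aggregation.

#' The closed vocabulary of priced agronomic components
#'
#' Nine price series feed the ten-component bottom-up valuation: the
#' CEC-retained base cations are valued at the K, Ca and Mg prices rather
#' than at a price of their own, and century-persistent carbon is priced
#' through carbon-dioxide (`co2`, USD per mass of CO2).
#'
#' @return character vector of component labels.
#' @export
price_components <- function() {
  c("available_n", "p", "k", "ca", "mg", "s", "micronutrients",
    "caco3", "co2")
}

# recognized price units -> factor converting to the internal USD per kg
# of elemental (or material) component. Oxide-basis quotes are converted
# to the elemental basis by the P2O5 -> P (0.4364) and K2O -> K (0.8301)
# mass factors.
.price_unit_factor <- function(unit) {
  factors <- c("USD/kg" = 1,
               "USD/Mg" = 1e-3, "USD/t" = 1e-3,
               "USD/kg P2O5" = 1 / 0.4364,
               "USD/Mg P2O5" = 1e-3 / 0.4364,
               "USD/kg K2O" = 1 / 0.8301,
               "USD/Mg K2O" = 1e-3 / 0.8301,
               "USD/Mg CO2" = 1e-3,
               "USD/kg CO2" = 1)
  out <- factors[unit]
  if (anyNA(out))
    abort("unrecognized price unit(s): ",
          paste(unique(unit[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Validate price observations
#'
#' @param obs data.frame with columns `component`, `price`, `stratum` and
#'   optionally `unit` (defaults to USD/kg internal) and `source`.
#' @return the observations with prices converted to internal USD/kg.
#' @export
as_price_observations <- function(obs) {
  stopifnot(is.data.frame(obs), all(c("component", "price") %in% names(obs)))
  bad <- setdiff(unique(obs$component), price_components())
  if (length(bad))
    abort("unknown price component(s): ", paste(bad, collapse = ", "),
          "; allowed: ", paste(price_components(), collapse = ", "))
  if (any(!is.finite(obs$price)) || any(obs$price <= 0))
    abort("prices must be positive finite numbers")
  if (!"stratum" %in% names(obs)) obs$stratum <- NA_character_
  known_strata <- c("National", "International")
  if (!all(is.na(obs$stratum) | obs$stratum %in% known_strata))
    abort("stratum must be 'National' or 'International'")
  if ("unit" %in% names(obs)) {
    obs$price <- obs$price * .price_unit_factor(obs$unit)
    obs$unit <- NULL
  }
  obs
}

#' Read price observations from CSV
#'
#' Schema: `component,price,unit,stratum,source`. Units are converted to
#' internal USD per kg of elemental component on read (see
#' `system.file("extdata", "schema.md", package = "hswvalue")`).
#'
#' @param path CSV file path.
#' @return validated observation data.frame with internal prices.
#' @export
read_prices <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  as_price_observations(utils::read.csv(path, stringsAsFactors = FALSE,
                                        encoding = "UTF-8"))
}

#' Empirical price quantiles per component
#'
#' Pools National and International observations per component and
#' computes empirical quantiles with linear interpolation between order
#' statistics (`h = (n - 1) p + 1` on the sorted values; the conventional
#' type-7 definition). Fewer than ten observations for a component draws a
#' warning — quantiles on a thinner base are unstable — and fewer than two
#' is an error.
#'
#' @param observations validated observations ([as_price_observations()]).
#' @param probs quantile probabilities, default `c(0.1, 0.25, 0.5, 0.75,
#'   0.9)`.
#' @return `price_quantiles` data.frame: `component`, `prob`, `price`
#'   (USD/kg internal), nondecreasing in `prob` within component.
#' @export
price_quantiles <- function(observations,
                            probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  observations <- as_price_observations(observations)
  if (nrow(observations) == 0) abort("no price observations")
  stopifnot(all(probs > 0 & probs < 1), !is.unsorted(probs))
  parts <- lapply(split(observations$price, observations$component),
                  function(x) x)
  rows <- list()
  for (comp in names(parts)) {
    x <- parts[[comp]]
    if (length(x) < 2)
      abort("component '", comp, "' has fewer than 2 price observations")
    if (length(x) < 10)
      warning("component '", comp, "' has only ", length(x),
              " price observations; quantiles are computed on at least ",
              "ten in the reference workflow", call. = FALSE)
    q <- stats::quantile(x, probs = probs, type = 7, names = FALSE)
    rows[[comp]] <- data.frame(component = comp, prob = probs, price = q,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("price_quantiles", "data.frame")
  out
}

# internal: price of one component at one probability, from a
# price_quantiles table; error if absent.
.price_at <- function(quantiles, component, prob) {
  hit <- quantiles$component == component & abs(quantiles$prob - prob) < 1e-12
  if (!any(hit))
    abort("no price quantile for component '", component,
          "' at probability ", prob)
  quantiles$price[hit][1]
}
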
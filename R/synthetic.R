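## Seeded synthetic-data generators: composition tables with linear
## temperature trends, two-stratum log-normal price observations, and
## benchmark amendments priced from known ground-truth N/P/K prices.

# run code under a private RNG state: seed explicitly, restore the
# caller's stream afterwards (no global-state leakage)
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generators
#'
#' The defaults emulate the study conditions: six thermochemical
#' treatments (200--700 degC), component concentrations trending linearly
#' in temperature through the tabulated 200 and 600 degC compositions
#' with 5 percent multiplicative noise, ten price observations per
#' component split over a low International and a high National stratum
#' (log-normal, National location +0.4 on the log scale), and eight
#' benchmark commercial amendments priced exactly from ratio-consistent
#' ground-truth N/P/K prices.
#'
#' @param seed integer seed; every generator output is bit-reproducible
#'   given the seed.
#' @param treatments highest heating temperatures (degC).
#' @param trends data.frame `field, intercept, slope, noise_sd`: linear
#'   trend `intercept + slope * HHT` in the internal unit of `field`,
#'   with multiplicative Gaussian noise of the given sd, truncated at 0.
#' @param prices data.frame `component, meanlog_international,
#'   meanlog_national, sdlog, n_international, n_national` describing the
#'   two log-normal strata (USD/kg internal units).
#' @param benchmarks list with `n`, `names`, uniform NPK ranges
#'   (`n_range`, `p_range`, `k_range`, kg/Mg), ground-truth `p_p` (USD/kg
#'   P) with ratios `r_pn`, `r_pk`, observation count `n_prices`, and
#'   `noise_sd` (0 = exact pricing).
#' @return `synthesis_config` list.
#' @export
synthesis_config <- function(seed = 1L,
                             treatments = c(200, 300, 400, 500, 600, 700),
                             trends = NULL, prices = NULL,
                             benchmarks = NULL) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (is.null(trends)) {
    trends <- data.frame(
      field = c("available_n", "p", "k", "ca", "mg", "s",
                "micronutrients", "cec", "caco3_equiv", "h_total",
                "c_total", "c_inorg", "mass_yield"),
      intercept = c(1168.9, 6965, 10400, 3500, 3130, -119, 327, 260,
                    -1.9, 0.0903, 0.413, 0.003, 1.1825),
      slope = c(-1.9445, 3.675, 19, 0, 5.5, 0.695, -0.15, -0.36,
                0.012, -1.054e-4, 4.5e-4, 0, -1.4e-3),
      noise_sd = c(rep(0.05, 9), 0.02, 0.02, 0, 0),
      stringsAsFactors = FALSE)
  }
  if (is.null(prices)) {
    comp <- price_components()
    meanlog_int <- c(available_n = 0, p = log(2.75), k = 0,
                     ca = log(0.15), mg = 0, s = log(0.3),
                     micronutrients = log(2), caco3 = log(0.05),
                     co2 = log(0.03))
    prices <- data.frame(component = comp,
                         meanlog_international = unname(meanlog_int[comp]),
                         meanlog_national = unname(meanlog_int[comp]) + 0.4,
                         sdlog = 0.2, n_international = 5L, n_national = 5L,
                         stringsAsFactors = FALSE)
  }
  if (is.null(benchmarks)) {
    benchmarks <- list(
      n = 8L,
      names = c("animal manure", "compost", "vermicompost", "Milorganite",
                "soybean meal", "alfalfa meal", "cottonseed meal",
                "bone meal"),
      n_range = c(5, 80), p_range = c(2, 40), k_range = c(2, 40),
      p_p = 2.75, r_pn = 2.8, r_pk = 2.75, n_prices = 10L, noise_sd = 0)
  }
  stopifnot(benchmarks$n >= 1, benchmarks$n_prices >= 1,
            all(prices$sdlog >= 0),
            all(prices$n_international + prices$n_national >= 1))
  structure(list(seed = as.integer(seed), treatments = treatments,
                 trends = trends, prices = prices,
                 benchmarks = benchmarks),
            class = "synthesis_config")
}

#' Generate a synthetic amendment composition table
#'
#' One record per configured treatment; each configured field follows its
#' linear-in-temperature trend with multiplicative noise truncated at
#' zero. Mass yields and fractions are additionally clamped to their
#' domains. Deterministic under the configuration seed.
#'
#' @param config a [synthesis_config()].
#' @return amendment data.frame in internal units (passes
#'   [validate_amendments()]).
#' @export
gen_compositions <- function(config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  .with_seed(config$seed, {
    tr <- config$trends
    hht <- config$treatments
    out <- data.frame(treatment_id = sprintf("synthetic_%d", hht),
                      hht_celsius = hht, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(tr))) {
      mu <- tr$intercept[i] + tr$slope[i] * hht
      noise <- if (tr$noise_sd[i] > 0)
        pmax(0, 1 + stats::rnorm(length(hht), 0, tr$noise_sd[i])) else 1
      v <- pmax(0, mu) * noise
      f <- tr$field[i]
      if (f %in% c("h_total", "c_total", "c_inorg")) v <- pmin(v, 1)
      if (f == "mass_yield") v <- pmin(pmax(v, 1e-3), 1)
      out[[f]] <- v
    }
    if (all(c("c_total", "c_inorg") %in% names(out)))
      out$c_inorg <- pmin(out$c_inorg, out$c_total)
    validate_amendments(out)
    out
  })
}

#' Generate synthetic two-stratum price observations
#'
#' Log-normal draws per component and stratum; the National stratum sits
#' above the International one when so configured (locations are used as
#' given — set `meanlog_national >= meanlog_international` to emulate the
#' high/low market structure).
#'
#' @param config a [synthesis_config()].
#' @return validated price-observation data.frame (USD/kg internal).
#' @export
gen_prices <- function(config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  .with_seed(config$seed + 1L, {
    pr <- config$prices
    rows <- list()
    for (i in seq_len(nrow(pr))) {
      draw <- function(n, meanlog) {
        if (n < 1) return(numeric())
        exp(meanlog + stats::rnorm(n, 0, pr$sdlog[i]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        component = pr$component[i],
        price = c(draw(pr$n_international[i], pr$meanlog_international[i]),
                  draw(pr$n_national[i], pr$meanlog_national[i])),
        stratum = rep(c("International", "National"),
                      c(pr$n_international[i], pr$n_national[i])),
        source = "synthetic", stringsAsFactors = FALSE)
    }
    as_price_observations(do.call(rbind, rows))
  })
}

#' Generate synthetic benchmark amendments with known ground truth
#'
#' N/P/K contents are uniform draws over the configured ranges (redrawn in
#' the degenerate all-zero case) and market prices are
#' `n p_N + p p_P + k p_K`, optionally with multiplicative noise. The
#' ground-truth prices (consistent with the configured ratios) are
#' attached as `attr(-, "truth")` for recovery tests.
#'
#' @param config a [synthesis_config()].
#' @return benchmark data.frame with a `market_prices` list-column.
#' @export
gen_benchmarks <- function(config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  bm <- config$benchmarks
  truth <- c(n = bm$p_p / bm$r_pn, p = bm$p_p, k = bm$p_p / bm$r_pk)
  if (!is.null(bm$p_n) && bm$noise_sd == 0 &&
      abs(bm$p_n - truth[["n"]]) > 1e-9 * max(1, truth[["n"]]))
    abort("exact-pricing mode requires ground-truth prices consistent ",
          "with r_pn and r_pk")
  .with_seed(config$seed + 2L, {
    n <- bm$n
    runif2 <- function(r) stats::runif(n, r[1], r[2])
    npk <- cbind(n = runif2(bm$n_range), p = runif2(bm$p_range),
                 k = runif2(bm$k_range))
    while (any(rowSums(npk) == 0))   # exclude the degenerate zero benchmark
      npk[rowSums(npk) == 0, ] <- cbind(runif2(bm$n_range),
                                        runif2(bm$p_range),
                                        runif2(bm$k_range))
    exact <- as.vector(npk %*% truth)
    prices <- lapply(seq_len(n), function(i) {
      noise <- if (bm$noise_sd > 0)
        pmax(0.01, 1 + stats::rnorm(bm$n_prices, 0, bm$noise_sd)) else 1
      exact[i] * rep(noise, length.out = bm$n_prices)
    })
    names_ <- if (length(bm$names) >= n) bm$names[seq_len(n)]
              else sprintf("benchmark_%d", seq_len(n))
    out <- data.frame(name = names_, n_total = npk[, "n"],
                      p_total = npk[, "p"], k_total = npk[, "k"],
                      stringsAsFactors = FALSE)
    out$market_prices <- prices
    validate_benchmarks(out)
    attr(out, "truth") <- truth
    out
  })
}
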
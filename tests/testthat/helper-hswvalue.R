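# Shared fixtures and independent oracles.

# a complete, internally consistent amendment record (internal units);
# override any field through ...
make_record <- function(treatment_id = "toy", hht_celsius = 400, ...) {
  rec <- data.frame(
    treatment_id = treatment_id, hht_celsius = hht_celsius,
    available_n = 100, p = 7000, k = 15000, ca = 3000, mg = 4000,
    s = 200, micronutrients = 180, cec = 100, caco3_equiv = 3,
    h_total = 0.03, c_total = 0.55, c_inorg = 0.004, bc100 = NA_real_,
    mass_yield = 0.5, cd = 0.2, cr = 5, cu = 50, ni = 10, pb = 5,
    zn = 300, pah_total = 500, pcb_total = 1, pcddf_teq = 0.1,
    stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

# constant-price quantile table: one price per component, equal at every
# probability (so quantile choice cannot matter)
flat_quantiles <- function(prices, probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  stopifnot(!is.null(names(prices)))
  out <- expand.grid(component = names(prices), prob = probs,
                     stringsAsFactors = FALSE)
  out$price <- prices[out$component]
  out
}

# independent bottom-up oracle: direct transcription of the component sum
# for one record under constant prices (USD/kg), amendment basis
oracle_bottom_up <- function(rec, prices) {
  corg <- rec$c_total - rec$c_inorg
  bc <- if (!is.na(rec$bc100)) rec$bc100 else {
    hc <- (rec$h_total / 1.008) / (corg / 12.011)
    min(max(-61.6 * hc + 105, 0), 100)
  }
  conc <- c(rec$k, rec$ca, rec$mg)
  share <- if (sum(conc) > 0) conc / sum(conc) else c(0, 0, 0)
  ret_kg <- share * rec$cec / c(1, 2, 2) * c(39.10, 40.08, 24.31) * 1e-3
  rec$available_n * 1e-3 * prices[["available_n"]] +
    rec$p * 1e-3 * prices[["p"]] + rec$k * 1e-3 * prices[["k"]] +
    rec$ca * 1e-3 * prices[["ca"]] + rec$mg * 1e-3 * prices[["mg"]] +
    rec$s * 1e-3 * prices[["s"]] +
    rec$micronutrients * 1e-3 * prices[["micronutrients"]] +
    sum(ret_kg * c(prices[["k"]], prices[["ca"]], prices[["mg"]])) +
    rec$caco3_equiv * 10 * prices[["caco3"]] +
    (bc / 100) * corg * 1000 * 44 / 12 * prices[["co2"]]
}

# brute-force l1 quantile-regression oracle: an optimal line passes
# through at least two data points, so enumerate all point pairs
pair_enum_loss <- function(x, y, tau) {
  n <- length(x)
  best <- Inf
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (x[i] == x[j]) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    a <- y[i] - b * x[i]
    best <- min(best, check_loss(y - a - b * x, tau))
  }
  best
}

# brute-force scalar grid oracle for the constrained N/P/K price solve
grid_nutrient_objective <- function(benchmarks, r_pn, r_pk, k,
                                    n_grid = 200001L) {
  m <- vapply(benchmarks$market_prices, function(p)
    stats::quantile(p, k, type = 7, names = FALSE), 0)
  load <- benchmarks$n_total / r_pn + benchmarks$p_total +
    benchmarks$k_total / r_pk
  hi <- 2 * max(m) / min(load[load > 0])
  grid <- seq(0, hi, length.out = n_grid)
  obj <- vapply(grid, function(p) sum(abs(m - load * p)), 0)
  list(p = grid[which.min(obj)], objective = min(obj))
}
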
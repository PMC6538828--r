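## End-to-end pipeline: inputs -> chemistry -> toxicity screen ->
## two-track valuation -> quantile trends -> CSV report bundle + manifest.

#' Pipeline run configuration
#'
#' @param input `"fixture"` (packaged tables), `"synthetic"` (generated
#'   via [synthesis_config()]), or a directory containing
#'   `amendments.csv`, `prices.csv` and optionally `benchmarks.csv`,
#'   `thresholds.csv`, `wastestreams.csv` per the documented schemas.
#' @param out_dir output directory for the report bundle (created if
#'   absent).
#' @param probs price-quantile probabilities: in (0, 1), sorted, unique.
#' @param r_pn,r_pk fixed P/N and P/K price ratios for the top-down
#'   solve.
#' @param basis valuation bases to report (`"amendment"`, `"feedstock"`,
#'   or both).
#' @param include_compost_in_trend include the 60 degC compost point in
#'   the value-versus-temperature regression (default FALSE).
#' @param include_biochar include a benchmark named like "biochar" in the
#'   top-down solve (default FALSE, mirroring its exclusion as a rare,
#'   unusually priced product).
#' @param seed seed for synthetic inputs (also used when the fixture
#'   lacks prices and synthetic price observations stand in).
#' @param quiet suppress per-stage log lines.
#' @return `run_config` list.
#' @export
run_config <- function(input = "fixture", out_dir = tempfile("hswrun"),
                       probs = c(0.1, 0.25, 0.5, 0.75, 0.9),
                       r_pn = 2.8, r_pk = 2.75,
                       basis = c("amendment", "feedstock"),
                       include_compost_in_trend = FALSE,
                       include_biochar = FALSE, seed = 1L, quiet = FALSE) {
  if (any(probs <= 0 | probs >= 1) || is.unsorted(probs, strictly = TRUE))
    abort("probs must be strictly increasing probabilities in (0, 1)")
  basis <- match.arg(basis, several.ok = TRUE)
  structure(list(input = input, out_dir = out_dir, probs = probs,
                 r_pn = r_pn, r_pk = r_pk, basis = basis,
                 include_compost_in_trend = include_compost_in_trend,
                 include_biochar = include_biochar, seed = as.integer(seed),
                 quiet = quiet),
            class = "run_config")
}

# internal: resolve pipeline inputs per the configuration
.pipeline_inputs <- function(config) {
  if (identical(config$input, "synthetic")) {
    sc <- synthesis_config(seed = config$seed)
    return(list(amendments = gen_compositions(sc),
                prices = gen_prices(sc),
                benchmarks = gen_benchmarks(sc),
                thresholds = NULL, waste_streams = NULL,
                label = "synthetic"))
  }
  if (identical(config$input, "fixture")) {
    fx <- hsw_fixture(warn_reconciled = !config$quiet)
    sc <- synthesis_config(seed = config$seed)
    if (!config$quiet)
      message("fixture bundles no market prices or benchmarks; ",
              "synthetic price observations and benchmarks (seed ",
              config$seed, ") stand in")
    return(list(amendments = fx$amendments, prices = gen_prices(sc),
                benchmarks = gen_benchmarks(sc),
                thresholds = fx$thresholds,
                waste_streams = fx$waste_streams, label = "fixture"))
  }
  if (!dir.exists(config$input)) abort("input not resolvable: ",
                                       config$input)
  p <- function(f) file.path(config$input, f)
  if (!file.exists(p("amendments.csv")))
    abort("missing input: ", p("amendments.csv"))
  if (!file.exists(p("prices.csv")))
    abort("missing input: ", p("prices.csv"))
  list(amendments = read_amendments(p("amendments.csv")),
       prices = read_prices(p("prices.csv")),
       benchmarks = if (file.exists(p("benchmarks.csv")))
         read_benchmarks(p("benchmarks.csv")),
       thresholds = if (file.exists(p("thresholds.csv")))
         utils::read.csv(p("thresholds.csv"), stringsAsFactors = FALSE),
       waste_streams = if (file.exists(p("wastestreams.csv")))
         utils::read.csv(p("wastestreams.csv"), stringsAsFactors = FALSE),
       label = config$input)
}

#' Run the full valuation pipeline
#'
#' Loads or generates inputs, derives the chemistry table (organic C,
#' H/C_org, BC+100, cation retention, per-ton supply), screens
#' contaminants, performs the bottom-up valuation on the requested bases
#' with the 0.9 - 0.1 sensitivity, solves the top-down N/P/K prices per
#' quantile, fits the value-versus-temperature quantile trends, scales
#' waste streams, and writes a CSV report bundle plus a JSON manifest
#' (package version, configuration, input checksums). Outputs are
#' deterministic given identical inputs and configuration; report files
#' round to one decimal, machine-precision columns sit alongside.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with all stage results and `files`, the paths
#'   written.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_ <- function(...) if (!config$quiet) message("[hswvalue] ", ...)
  inputs <- .pipeline_inputs(config)
  amendments <- inputs$amendments
  if (is.null(amendments) || nrow(amendments) == 0)
    abort("stage datamodel_io: empty amendment table from input '",
          inputs$label, "'")
  log_("inputs: ", nrow(amendments), " amendments, ",
       nrow(inputs$prices), " price observations")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    f <- file.path(config$out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files[[name]] <<- f
    f
  }

  # chemistry stage
  chem <- do.call(rbind, lapply(seq_len(nrow(amendments)), function(i) {
    r <- amendments[i, , drop = FALSE]
    g <- function(cn) if (cn %in% names(r) && !is.na(r[[cn]]))
      r[[cn]] else NA_real_
    corg <- if (!is.na(g("c_total")) && !is.na(g("c_inorg")))
      organic_carbon(r$c_total, r$c_inorg) else NA_real_
    hc <- if (!is.na(corg) && corg > 0 && !is.na(g("h_total")))
      h_over_corg(r$h_total, corg) else NA_real_
    bc <- if (!is.na(g("bc100"))) r$bc100
          else if (!is.na(hc)) bc100(hc)$bc100 else NA_real_
    cec <- if (!is.na(g("cec"))) r$cec
           else if (!is.na(g("cec_cations")))
             cec_from_retained_total(r$cec_cations, r$k, r$ca, r$mg)
           else NA_real_
    ret <- if (!is.na(cec)) cation_retention(r$k, r$ca, r$mg, cec)
           else list(retention_mg_kg = c(k = NA, ca = NA, mg = NA),
                     total_g_per_kg = NA)
    data.frame(treatment_id = r$treatment_id, hht_celsius = r$hht_celsius,
               c_org_frac = corg, h_over_corg = hc, bc100_pct = bc,
               cec_mmolc_kg = cec,
               retained_k_mg_kg = unname(ret$retention_mg_kg["k"]),
               retained_ca_mg_kg = unname(ret$retention_mg_kg["ca"]),
               retained_mg_mg_kg = unname(ret$retention_mg_kg["mg"]),
               retained_total_g_kg = ret$total_g_per_kg,
               p_kg_per_mg = per_ton_supply(r$p),
               k_kg_per_mg = per_ton_supply(r$k),
               available_n_kg_per_mg = per_ton_supply(r$available_n),
               stringsAsFactors = FALSE)
  }))
  emit(chem, "chemistry.csv")
  log_("chemistry: ", nrow(chem), " treatments")

  # toxicity stage
  screen <- NULL
  if (!is.null(inputs$thresholds)) {
    screen <- screen_all(amendments, inputs$thresholds)
    emit(screen, "screen_report.csv")
    log_("toxicity screen: ", sum(screen$status == "exceed"),
         " exceedances over ", nrow(screen), " comparisons")
  }

  # waste-stream stage
  streams <- NULL
  if (!is.null(inputs$waste_streams)) {
    streams <- waste_stream(inputs$waste_streams)
    streams$dry_mg_day_reported <- round_half_up(streams$dry_mg_day, 1)
    streams$urine_m3_day_reported <- round_half_up(streams$urine_m3_day, 1)
    emit(streams, "waste_streams.csv")
  }

  # bottom-up valuation stage
  quant <- price_quantiles(inputs$prices, probs = config$probs)
  emit(quant, "price_quantiles.csv")
  valuations <- list()
  for (b in config$basis) {
    v <- bottom_up_value(amendments, quant, basis = b)
    valuations[[b]] <- v
    emit(as.data.frame(v), paste0("valuation_", b, ".csv"))
  }
  sens <- price_sensitivity(valuations[[config$basis[1]]])
  emit(sens, "sensitivity.csv")
  log_("bottom-up valuation: bases ",
       paste(config$basis, collapse = ", "))

  # top-down stage
  topdown <- NULL
  fits <- NULL
  if (!is.null(inputs$benchmarks)) {
    bm <- inputs$benchmarks
    if (!config$include_biochar)
      bm <- bm[!grepl("biochar", bm$name, ignore.case = TRUE), ,
               drop = FALSE]
    fits <- lapply(config$probs, function(k)
      nutrient_price_fit(bm, r_pn = config$r_pn, r_pk = config$r_pk, k = k))
    names(fits) <- config$probs
    np <- do.call(rbind, lapply(fits, function(f)
      data.frame(k = f$k, price_n = f$prices[["n"]],
                 price_p = f$prices[["p"]], price_k = f$prices[["k"]],
                 objective = f$objective)))
    emit(np, "nutrient_prices.csv")
    log_("top-down solve at ", length(fits), " quantiles")
  }

  # quantile-trend stage (amendment basis when present)
  trend_basis <- if ("amendment" %in% config$basis) "amendment"
                 else config$basis[1]
  slopes <- quantile_slopes(valuations[[trend_basis]],
                            include_compost = config$include_compost_in_trend)
  emit(slopes, "quantile_slopes.csv")

  # manifest
  checksum <- function(x) unname(tools::md5sum(x))
  manifest <- list(
    package = "hswvalue",
    version = as.character(utils::packageVersion("hswvalue")),
    config = config[setdiff(names(config), "quiet")],
    input_label = inputs$label,
    input_checksums = if (dir.exists(config$input %||% ""))
      as.list(checksum(list.files(config$input, full.names = TRUE))) else
        list(),
    config_hash = substr(paste(
      checksum(local({ f <- tempfile(); saveRDS(
        config[setdiff(names(config), c("out_dir", "quiet"))], f); f }))),
      1, 32),
    outputs = as.list(files))
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  files[["manifest.json"]] <- mf
  log_("report bundle written to ", config$out_dir)
  invisible(list(amendments = amendments, chemistry = chem,
                 screen = screen, waste_streams = streams,
                 quantiles = quant, valuations = valuations,
                 sensitivity = sens, nutrient_price_fits = fits,
                 quantile_slopes = slopes, files = files,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
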
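## Top-down valuation: least-absolute-deviation inverse solve for N/P/K
## unit prices against benchmark commercial amendments, under fixed P/N
## and P/K price ratios, and bulk pricing of an amendment from its total
## N/P/K.

#' Validate a benchmark amendment table
#'
#' @param x data.frame with columns `name`, `n_total`, `p_total`,
#'   `k_total` (kg per Mg of product) and either a numeric `market_price`
#'   column or a list-column `market_prices` of price observations
#'   (USD/Mg).
#' @return `x`, invisibly.
#' @export
validate_benchmarks <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("name", "n_total", "p_total", "k_total")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort("benchmark table missing column(s): ",
                          paste(miss, collapse = ", "))
  for (cn in c("n_total", "p_total", "k_total"))
    if (any(x[[cn]] < 0, na.rm = TRUE)) abort("negative ", cn)
  if (!"market_prices" %in% names(x) && !"market_price" %in% names(x))
    abort("benchmark table needs market_price or market_prices")
  prices <- .benchmark_prices(x)
  if (any(vapply(prices, length, 1L) < 1))
    abort("every benchmark needs at least one market price")
  if (any(unlist(prices) <= 0)) abort("market prices must be positive")
  invisible(x)
}

# internal: list of market-price vectors, one per benchmark
.benchmark_prices <- function(x) {
  if ("market_prices" %in% names(x)) lapply(x$market_prices, as.numeric)
  else as.list(x$market_price)
}

#' Read benchmark amendments from CSV
#'
#' Schema: `name,n_total,p_total,k_total,market_price` — one row per
#' market-price observation; rows sharing a `name` are collapsed into one
#' benchmark with several price observations.
#'
#' @param path CSV file path.
#' @return benchmark data.frame with a `market_prices` list-column.
#' @export
read_benchmarks <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  sp <- split(raw, raw$name)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(name = d$name[1], n_total = d$n_total[1],
               p_total = d$p_total[1], k_total = d$k_total[1],
               stringsAsFactors = FALSE)
  }))
  out$market_prices <- lapply(sp, function(d) d$market_price)
  rownames(out) <- NULL
  validate_benchmarks(out)
  out
}

# internal: exact scalar weighted-median LAD. Minimizes
# sum_b w_b |t_b - p| over p >= 0, ties broken toward the smaller p
# (the infimum of the argmin interval).
.weighted_median_lad <- function(t, w) {
  o <- order(t)
  t <- t[o]; w <- w[o]
  half <- sum(w) / 2
  cw <- cumsum(w)
  i <- which(cw >= half - 1e-12)[1]
  p <- t[i]
  max(p, 0)
}

#' Inverse-solve N/P/K unit prices against benchmark amendments
#'
#' Estimates the unit prices of total N, P and K that best reproduce the
#' market prices of a set of benchmark commercial amendments, minimizing
#' the sum of absolute deviations
#' `sum_b | marketprice_k(b) - (n_b p_N + p_b p_P + k_b p_K) |`
#' at market-price quantile `k`, subject to fixed price ratios
#' `r_pn = p_P / p_N` and `r_pk = p_P / p_K` and `p_P >= 0`. Under the
#' ratio constraints the problem reduces to one scalar unknown, solved
#' exactly as a weighted median (ties toward the smaller price).
#'
#' @param benchmarks benchmark table (see [validate_benchmarks()]); each
#'   benchmark's market price at quantile `k` is the empirical type-7
#'   quantile of its price observations.
#' @param r_pn,r_pk fixed positive price ratios P/N and P/K. Defaults 2.8
#'   and 2.75 follow representative 2016--17 East African single-nutrient
#'   fertilizer prices (urea, triple super phosphate, muriate of potash on
#'   an elemental basis); override with your own ratio table.
#' @param k market-price quantile probability, default 0.5.
#' @return object of class `nutrient_price_fit` with `coef()` (USD/kg for
#'   N, P, K), `predict()`, `fitted()`, `residuals()`, `print()` and
#'   `summary()` methods; `$objective` is the minimized absolute deviation
#'   sum (USD/Mg).
#' @export
nutrient_price_fit <- function(benchmarks, r_pn = 2.8, r_pk = 2.75,
                               k = 0.5) {
  validate_benchmarks(benchmarks)
  if (!(r_pn > 0 && r_pk > 0)) abort("r_pn and r_pk must be positive")
  if (!(k > 0 && k < 1)) abort("quantile probability k must lie in (0, 1)")
  m <- vapply(.benchmark_prices(benchmarks), function(p)
    stats::quantile(p, k, type = 7, names = FALSE), 0)
  # effective loading per USD/kg of p_P: p_N = p_P / r_pn, p_K = p_P / r_pk
  load <- benchmarks$n_total / r_pn + benchmarks$p_total +
    benchmarks$k_total / r_pk
  pos <- load > 0
  if (!any(pos)) abort("all benchmarks have zero N, P and K")
  # sum |m - load * p| = sum load * |m/load - p| over positive loadings
  p_p <- .weighted_median_lad(m[pos] / load[pos], load[pos])
  prices <- c(n = p_p / r_pn, p = p_p, k = p_p / r_pk)
  fitted <- load * p_p
  structure(list(prices = prices, k = k, r_pn = r_pn, r_pk = r_pk,
                 objective = sum(abs(m - fitted)),
                 benchmarks = benchmarks$name, market = m,
                 loadings = load, fitted = fitted,
                 residuals = m - fitted),
            class = "nutrient_price_fit")
}

#' @export
coef.nutrient_price_fit <- function(object, ...) object$prices

#' @export
fitted.nutrient_price_fit <- function(object, ...) {
  stats::setNames(object$fitted, object$benchmarks)
}

#' @export
residuals.nutrient_price_fit <- function(object, ...) {
  stats::setNames(object$residuals, object$benchmarks)
}

#' Predict a bulk amendment price from total N/P/K
#'
#' @param object a `nutrient_price_fit`.
#' @param newdata data.frame with `n_total`, `p_total`, `k_total` (kg/Mg).
#' @param ... unused.
#' @return predicted USD/Mg.
#' @export
predict.nutrient_price_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  pr <- object$prices
  newdata$n_total * pr[["n"]] + newdata$p_total * pr[["p"]] +
    newdata$k_total * pr[["k"]]
}

#' @export
print.nutrient_price_fit <- function(x, ...) {
  cat("Top-down N/P/K price fit (LAD, market-price quantile k = ",
      x$k, ")\n", sep = "")
  cat(sprintf("  p_N = %.4f  p_P = %.4f  p_K = %.4f  USD/kg\n",
              x$prices[["n"]], x$prices[["p"]], x$prices[["k"]]))
  cat(sprintf("  ratio constraints: p_P/p_N = %g, p_P/p_K = %g\n",
              x$r_pn, x$r_pk))
  cat(sprintf("  objective (sum |residual|): %.4f USD/Mg over %d benchmarks\n",
              x$objective, length(x$benchmarks)))
  invisible(x)
}

#' @export
summary.nutrient_price_fit <- function(object, ...) {
  print(object)
  cat("\nPer-benchmark fit (USD/Mg):\n")
  print(data.frame(benchmark = object$benchmarks,
                   market = round(object$market, 2),
                   fitted = round(object$fitted, 2),
                   residual = round(object$residuals, 2)),
        row.names = FALSE)
  invisible(object)
}

#' Top-down bulk value of an amendment from its total N/P/K
#'
#' `n p_N + p p_P + k p_K` with the median-quantile (`k = 0.5`) nutrient
#' prices from [nutrient_price_fit()].
#'
#' @param n_total,p_total,k_total total N, P, K in kg per Mg amendment.
#' @param fit a `nutrient_price_fit` solved at `k = 0.5`.
#' @return USD per Mg amendment.
#' @export
top_down_value <- function(n_total, p_total, k_total, fit) {
  stopifnot(inherits(fit, "nutrient_price_fit"))
  if (abs(fit$k - 0.5) > 1e-12)
    abort("bulk valuation uses the median-quantile fit (k = 0.5)")
  predict(fit, data.frame(n_total = n_total, p_total = p_total,
                          k_total = k_total))
}
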
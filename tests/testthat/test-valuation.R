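base_prices <- c(available_n = 1, p = 2.75, k = 1, ca = 0.15, mg = 1,
                 s = 0.3, micronutrients = 2, caco3 = 0.05, co2 = 0.03)

test_that("component value is concentration times price", {
  expect_equal(component_value(9, 2), 18)
  expect_equal(component_value(0, 5), 0)
  expect_equal(component_value(9, 0), 0)
  expect_error(component_value(-1, 2), "nonnegative")
})

test_that("two-component toy record totals to the hand sum", {
  rec <- make_record(available_n = 0, p = 9000, k = 20000, ca = 0, mg = 0,
                     s = 0, micronutrients = 0, cec = 0, caco3_equiv = 0,
                     bc100 = 0)
  q <- flat_quantiles(c(available_n = 1e-9, p = 2, k = 1, ca = 1e-9,
                        mg = 1e-9, s = 1e-9, micronutrients = 1e-9,
                        caco3 = 1e-9, co2 = 1e-9))
  v <- bottom_up_value(rec, q)
  expect_equal(unname(v$totals[1, ]), rep(9 * 2 + 20 * 1, 5),
               tolerance = 1e-6)
})

test_that("zero prices give zero value at every quantile", {
  q <- flat_quantiles(stats::setNames(rep(0, 9), names(base_prices)))
  v <- bottom_up_value(make_record(), q)
  expect_equal(unname(v$totals[1, ]), rep(0, 5))
})

test_that("totals equal the sum over components", {
  q <- flat_quantiles(base_prices)
  v <- bottom_up_value(rbind(make_record("a"), make_record("b", p = 9170)), q)
  expect_equal(v$totals, apply(v$values, c(1, 3), sum))
})

test_that("feedstock basis scales every entry by the mass yield", {
  rec <- make_record(mass_yield = 0.5)
  q <- flat_quantiles(base_prices)
  va <- bottom_up_value(rec, q, basis = "amendment")
  vf <- bottom_up_value(rec, q, basis = "feedstock")
  expect_equal(vf$values, va$values * 0.5)
  expect_equal(vf$totals, va$totals * 0.5)
})

test_that("valuation matches the direct component-sum oracle", {
  set.seed(21)
  for (i in 1:20) {
    rec <- make_record(available_n = stats::runif(1, 0, 1000),
                       p = stats::runif(1, 0, 2e4),
                       k = stats::runif(1, 0, 2e4),
                       ca = stats::runif(1, 0, 6e3),
                       mg = stats::runif(1, 0, 7e3),
                       s = stats::runif(1, 0, 400),
                       micronutrients = stats::runif(1, 0, 400),
                       cec = stats::runif(1, 0, 300),
                       caco3_equiv = stats::runif(1, 0, 8))
    pr <- stats::setNames(stats::runif(9, 0.01, 5), names(base_prices))
    v <- bottom_up_value(rec, flat_quantiles(pr))
    expect_equal(unname(v$totals[1, 3]), oracle_bottom_up(rec, pr),
                 tolerance = 1e-12)
  }
})

test_that("valuation is homogeneous and monotone in prices", {
  rec <- make_record()
  v1 <- bottom_up_value(rec, flat_quantiles(base_prices))
  v3 <- bottom_up_value(rec, flat_quantiles(3 * base_prices))
  expect_equal(v3$values, 3 * v1$values)
  for (comp in names(base_prices)) {
    up <- base_prices; up[comp] <- up[comp] + 1
    vu <- bottom_up_value(rec, flat_quantiles(up))
    expect_true(all(vu$totals >= v1$totals - 1e-12), label = comp)
  }
})

test_that("quantile totals are nondecreasing when component prices are", {
  set.seed(31)
  probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  q <- do.call(rbind, lapply(names(base_prices), function(comp)
    data.frame(component = comp, prob = probs,
               price = sort(stats::runif(5, 0.01, 4)))))
  v <- bottom_up_value(make_record(), q)
  expect_true(all(diff(v$totals[1, ]) >= -1e-12))
})

test_that("a missing component price series is fatal and named", {
  q <- flat_quantiles(base_prices[names(base_prices) != "co2"])
  expect_error(bottom_up_value(make_record(), q), "co2")
})

test_that("sensitivity is the 0.9 minus 0.1 quantile value", {
  probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  q <- do.call(rbind, lapply(names(base_prices), function(comp)
    data.frame(component = comp, prob = probs,
               price = base_prices[[comp]] * c(1, 1.2, 1.5, 2, 3.5))))
  rec <- make_record()
  v <- bottom_up_value(rec, q)
  s <- price_sensitivity(v)
  expect_equal(s[[2]],
               unname(v$values[1, , 5] - v$values[1, , 1]))
  # linearity: P sensitivity = concentration (kg/Mg) * price spread
  dp <- base_prices[["p"]] * (3.5 - 1)
  expect_equal(s[[2]][s$component == "p"], rec$p * 1e-3 * dp)
  # constant-price components have zero sensitivity
  vflat <- bottom_up_value(rec, flat_quantiles(base_prices))
  sflat <- price_sensitivity(vflat)
  expect_equal(sflat[[2]], rep(0, 10))
  v2 <- bottom_up_value(rec, q[abs(q$prob - 0.5) < 0.3, ])
  expect_error(price_sensitivity(v2), "0\\.1|0\\.9")
})

test_that("valuation methods print and summarise coherently", {
  v <- bottom_up_value(make_record(), flat_quantiles(base_prices))
  expect_output(print(v), "USD/Mg amendment")
  expect_output(print(summary(v)), "Median")
  df <- as.data.frame(v)
  expect_equal(nrow(df), 1 * 10 * 5)
  expect_equal(sum(df$value[abs(df$prob - 0.5) < 1e-12]),
               unname(v$totals[1, 3]))
})
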
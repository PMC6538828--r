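test_that("a single consistent benchmark is solved exactly", {
  bm <- data.frame(name = "b1", n_total = 50, p_total = 20, k_total = 30,
                   market_price = 130)
  fit <- nutrient_price_fit(bm, r_pn = 2, r_pk = 1.5, k = 0.5)
  expect_equal(unname(coef(fit)), c(1, 2, 2 / 1.5), tolerance = 1e-12)
  expect_equal(fit$objective, 0)
  expect_equal(unname(fitted(fit)), 130)
})

test_that("ratio-consistent exactly priced benchmarks are recovered", {
  cfg <- synthesis_config(seed = 99)
  bm <- gen_benchmarks(cfg)
  truth <- attr(bm, "truth")
  fit <- nutrient_price_fit(bm, r_pn = cfg$benchmarks$r_pn,
                            r_pk = cfg$benchmarks$r_pk, k = 0.5)
  expect_equal(coef(fit), truth, tolerance = 1e-9)
  expect_lt(fit$objective, 1e-9)
  expect_equal(unname(residuals(fit)), rep(0, 8), tolerance = 1e-9)
})

test_that("solver attains the dense grid-search optimum on noisy data", {
  for (seed in c(7, 23)) {
    cfg <- synthesis_config(seed = seed)
    cfg$benchmarks$noise_sd <- 0.15
    bm <- gen_benchmarks(cfg)
    for (k in c(0.1, 0.5, 0.9)) {
      fit <- nutrient_price_fit(bm, k = k)
      grid <- grid_nutrient_objective(bm, fit$r_pn, fit$r_pk, k)
      expect_lte(fit$objective, grid$objective + 1e-6)
    }
  }
})

test_that("ratio constraints hold in the solution", {
  bm <- gen_benchmarks(synthesis_config(3))
  fit <- nutrient_price_fit(bm, r_pn = 4, r_pk = 2)
  pr <- coef(fit)
  expect_equal(pr[["p"]] / pr[["n"]], 4, tolerance = 1e-12)
  expect_equal(pr[["p"]] / pr[["k"]], 2, tolerance = 1e-12)
  expect_true(all(pr >= 0))
})

test_that("degenerate and invalid benchmark sets are rejected", {
  zero <- data.frame(name = "z", n_total = 0, p_total = 0, k_total = 0,
                     market_price = 10)
  expect_error(nutrient_price_fit(zero), "zero N, P and K")
  expect_error(nutrient_price_fit(data.frame(name = "a", n_total = 1,
                                             p_total = 1, k_total = 1,
                                             market_price = -5)),
               "positive")
  bm <- data.frame(name = "b", n_total = 10, p_total = 5, k_total = 5,
                   market_price = 50)
  expect_error(nutrient_price_fit(bm, r_pn = 0), "positive")
  expect_error(nutrient_price_fit(bm, k = 1), "0, 1")
})

test_that("benchmark market-price quantiles feed the solve", {
  bm <- data.frame(name = "b1", n_total = 0, p_total = 10, k_total = 0)
  bm$market_prices <- list(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100))
  f50 <- nutrient_price_fit(bm, k = 0.5)
  expect_equal(coef(f50)[["p"]], 5.5)     # median 55 / 10 kg P
  f10 <- nutrient_price_fit(bm, k = 0.1)
  expect_equal(coef(f10)[["p"]], 1.9)
})

test_that("bulk top-down value prices an amendment from total N/P/K", {
  bm <- gen_benchmarks(synthesis_config(12))
  fit <- nutrient_price_fit(bm)
  expect_equal(top_down_value(0, 0, 0, fit), 0)
  unit <- data.frame(name = "u", n_total = 10, p_total = 5, k_total = 5,
                     market_price = 1)
  fit1 <- nutrient_price_fit(unit, r_pn = 1, r_pk = 1)
  p1 <- coef(fit1)[["p"]]
  expect_equal(top_down_value(10, 5, 5, fit1), 20 * p1)
  # an amendment matching a benchmark's NPK recovers its exact price
  expect_equal(top_down_value(bm$n_total[3], bm$p_total[3], bm$k_total[3],
                              fit),
               bm$market_prices[[3]][1], tolerance = 1e-9)
  fit9 <- nutrient_price_fit(bm, k = 0.9)
  expect_error(top_down_value(1, 1, 1, fit9), "k = 0.5")
})

test_that("read_benchmarks collapses repeated names into price lists", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,n_total,p_total,k_total,market_price",
               "bone meal,40,60,0,800", "bone meal,40,60,0,900",
               "compost,10,3,5,60"), f)
  bm <- read_benchmarks(f)
  expect_equal(nrow(bm), 2)
  expect_equal(unname(sort(vapply(bm$market_prices, length, 1L))),
               c(1L, 2L))
})
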
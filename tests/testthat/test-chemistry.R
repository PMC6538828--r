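test_that("organic carbon is total minus inorganic, guarded", {
  expect_equal(organic_carbon(0.50, 0.00), 0.50)
  expect_equal(organic_carbon(0.50, 0.02), 0.48)
  expect_error(organic_carbon(0.30, 0.31), "exceeds")
})

test_that("H/C_org molar ratio uses atomic masses 1.008 and 12.011", {
  expect_equal(h_over_corg(0.008397, 0.12011),
               (0.008397 / 1.008) / (0.12011 / 12.011))
  expect_equal(h_over_corg(0, 0.5), 0)
  expect_equal(h_over_corg(1.008 / 100, 12.011 / 100), 1.0)
  expect_error(h_over_corg(0.01, 0), "positive")
})

test_that("BC+100 is the clamped linear function of H/C_org", {
  expect_equal(bc100(0.5)$raw, -61.6 * 0.5 + 105)
  expect_equal(bc100(0.5)$bc100, 74.2)
  expect_equal(bc100(0)$raw, 105)
  expect_equal(bc100(0)$bc100, 100)
  expect_equal(bc100(105 / 61.6)$bc100, 0)
  expect_error(bc100(-0.1), "nonnegative")
  # strictly decreasing before clamping, bounded after
  r <- seq(0, 3, by = 0.05)
  out <- bc100(r)
  expect_true(all(diff(out$raw) < 0))
  expect_true(all(out$bc100 >= 0 & out$bc100 <= 100))
})

test_that("cation retention apportions CEC by mass share", {
  ret <- cation_retention(2000, 1000, 1000, 100)
  expect_equal(unname(ret$retention_mg_kg["k"]), 0.5 * 100 / 1 * 39.10)
  expect_equal(unname(ret$retention_mg_kg["ca"]), 0.25 * 100 / 2 * 40.08)
  expect_equal(unname(ret$retention_mg_kg["mg"]), 0.25 * 100 / 2 * 24.31)
  expect_equal(cation_retention(2000, 1000, 1000, 0)$total_g_per_kg, 0)
  one <- cation_retention(500, 0, 0, 80)
  expect_equal(unname(one$retention_mg_kg["k"]), 80 * 39.10)
  expect_error(cation_retention(0, 0, 0, 10), "undefined")
})

test_that("retained charge balances the CEC on randomized inputs", {
  set.seed(101)
  for (i in 1:200) {
    conc <- stats::runif(3, 0, 3e4)
    cec <- stats::runif(1, 0, 500)
    ret <- cation_retention(conc[1], conc[2], conc[3], cec)$retention_mg_kg
    charge <- sum(ret * c(1, 2, 2) / c(39.10, 40.08, 24.31))
    expect_equal(charge, cec, tolerance = 1e-9)
  }
})

test_that("feedstock basis scales by mass yield", {
  expect_equal(round(per_feedstock(52.7, 0.501), 1), 26.4)
  expect_equal(per_feedstock(7, 1), 7)
  expect_equal(per_feedstock(0, 0.3), 0)
  expect_error(per_feedstock(1, 0), "0, 1")
  expect_error(per_feedstock(1, 1.1), "0, 1")
  set.seed(5)
  y <- stats::runif(50, 0.05, 1)
  v <- stats::runif(50, 0, 100)
  expect_true(all(per_feedstock(v, y) <= v))
})

test_that("one ton of amendment supplies concentration/1000 kg", {
  expect_equal(per_ton_supply(9170), 9.17)
  expect_equal(round(per_ton_supply(9170), 1), 9.2)
  expect_equal(per_ton_supply(21800), 21.8)
  expect_equal(per_ton_supply(0), 0)
})

test_that("fold changes reproduce the per-amendment comparisons", {
  expect_equal(fold_change(780, 2.1), 371.4286, tolerance = 1e-6)
  expect_equal(fold_change(7.70, 9.17), 0.8397, tolerance = 1e-4)
  expect_equal(fold_change(9.43, 3.75), 2.515, tolerance = 1e-3)
  expect_error(fold_change(1, 0), "zero")
})

test_that("waste stream scaling is linear in population", {
  base <- data.frame(population = 255094, dry_g_per_person_day = 48.4,
                     urine_ml_per_person_day = 1000)
  one <- waste_stream(base)
  expect_equal(one$dry_mg_day, 255094 * 48.4e-6)
  dbl <- base; dbl$population <- 2 * base$population
  expect_equal(waste_stream(dbl)$dry_mg_day, 2 * one$dry_mg_day)
  zero <- base; zero$population <- 0
  expect_equal(unlist(waste_stream(zero)[c("dry_mg_day", "urine_m3_day")]),
               c(dry_mg_day = 0, urine_m3_day = 0))
})

test_that("waste-stream specs must be internally consistent", {
  bad <- data.frame(population = 100, fresh_g_per_person_day = 161.3,
                    water_content = 0.7, dry_g_per_person_day = 80,
                    urine_ml_per_person_day = 1000)
  expect_error(validate_waste_stream(bad), "inconsistent")
  bad$dry_g_per_person_day <- 48.4
  expect_silent(validate_waste_stream(bad))
})
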
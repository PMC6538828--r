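test_that("an interpolating line is recovered exactly at any tau", {
  x <- c(200, 300, 400, 500, 600, 700)
  y <- 2 + 0.1 * x
  for (tau in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    fit <- quantile_trend(x, y, tau)
    expect_equal(unname(coef(fit)), c(2, 0.1), tolerance = 1e-9)
    expect_equal(fit$check_loss, 0, tolerance = 1e-9)
  }
})

test_that("the fit attains the point-pair enumeration optimum", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    x <- sample(seq(100, 700, by = 50), n)
    y <- 0.05 * x + stats::rnorm(n, 0, 20)
    tau <- sample(c(0.1, 0.25, 0.5, 0.75, 0.9), 1)
    fit <- quantile_trend(x, y, tau)
    oracle <- pair_enum_loss(x, y, tau)
    expect_equal(fit$check_loss, oracle, tolerance = 1e-8)
    expect_gte(fit$check_loss, 0)
  }
})

test_that("tau = 0.5 minimizes least absolute deviations", {
  set.seed(8)
  x <- seq(100, 700, by = 100)
  y <- 10 + 0.02 * x + stats::rnorm(7, 0, 5)
  fit <- quantile_trend(x, y, 0.5)
  expect_equal(2 * fit$check_loss, sum(abs(residuals(fit))))
  expect_equal(2 * fit$check_loss, pair_enum_loss(x, y, 0.5) * 2,
               tolerance = 1e-8)
})

test_that("constant response gives zero slope and a quantile intercept", {
  x <- c(200, 300, 400, 500)
  fit <- quantile_trend(x, rep(7, 4), 0.3)
  expect_equal(unname(coef(fit)), c(7, 0), tolerance = 1e-9)
  expect_equal(fit$check_loss, 0, tolerance = 1e-9)
})

test_that("fits are equivariant to response scaling and regressor shift", {
  set.seed(19)
  x <- seq(200, 700, by = 100)
  y <- 1 + 0.03 * x + stats::rnorm(6, 0, 3)
  f0 <- quantile_trend(x, y, 0.25)
  fy <- quantile_trend(x, 5 * y, 0.25)
  expect_equal(fy$check_loss, 5 * f0$check_loss, tolerance = 1e-8)
  expect_equal(unname(coef(fy)), 5 * unname(coef(f0)), tolerance = 1e-6)
  fx <- quantile_trend(x + 100, y, 0.25)
  expect_equal(coef(fx)[["slope"]], coef(f0)[["slope"]], tolerance = 1e-6)
  expect_equal(fx$check_loss, f0$check_loss, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  expect_error(quantile_trend(c(1, 2), c(1, 2), 0.5), "3 points")
  expect_error(quantile_trend(rep(5, 4), 1:4, 0.5), "unidentifiable")
  expect_error(quantile_trend(1:4, 1:4, 0), "tau")
  expect_error(quantile_trend(1:4, c(1, NA, 3, 4), 0.5), "missing")
})

test_that("slope ratios compare high and low quantile trends", {
  x <- c(200, 300, 400, 500, 600, 700)
  fit_low <- quantile_trend(x, 1 + 0.01 * x, 0.1)
  fit_high <- quantile_trend(x, 1 + 0.083 * x, 0.9)
  expect_equal(slope_ratio(fit_high, fit_low), 8.3, tolerance = 1e-6)
  expect_equal(slope_ratio(fit_low, fit_low), 1)
  flat <- quantile_trend(x, rep(3, 6), 0.5)
  expect_error(slope_ratio(fit_high, flat), "zero")
})

test_that("prices spread by a known ratio yield that slope ratio", {
  # concentrations linear in temperature, component priced at p_lo for
  # quantile 0.1 and R * p_lo at 0.9: value slopes scale by exactly R
  x <- c(200, 300, 400, 500, 600, 700)
  conc <- 5 + 0.02 * x                     # kg/Mg
  R <- 7.3
  p_lo <- 1.4
  f_lo <- quantile_trend(x, conc * p_lo, 0.1)
  f_hi <- quantile_trend(x, conc * p_lo * R, 0.9)
  expect_equal(slope_ratio(f_hi, f_lo), R, tolerance = 1e-6)
})

test_that("per-component slopes exclude compost unless asked", {
  q <- flat_quantiles(c(available_n = 1, p = 2.75, k = 1, ca = 0.15,
                        mg = 1, s = 0.3, micronutrients = 2,
                        caco3 = 0.05, co2 = 0.03))
  # thermochemical P values collinear in temperature; compost far off-line
  recs <- rbind(make_record("comp", 60, p = 20000),
                make_record("t2", 200, p = 10 * 200),
                make_record("t3", 400, p = 10 * 400),
                make_record("t4", 600, p = 10 * 600),
                make_record("t5", 700, p = 10 * 700))
  v <- bottom_up_value(recs, q)
  sl <- quantile_slopes(v)
  expect_equal(nrow(sl), 10 * 5)
  p_loss <- sl$check_loss[sl$component == "p" & sl$tau == 0.5]
  expect_equal(p_loss, 0, tolerance = 1e-9)
  sl_all <- quantile_slopes(v, include_compost = TRUE)
  p_loss_all <- sl_all$check_loss[sl_all$component == "p" &
                                    sl_all$tau == 0.5]
  expect_gt(p_loss_all, 1)   # the off-line compost point now contributes
})
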
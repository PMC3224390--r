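# Dynamic mass-balance rate estimation: smoothing, the q_p estimator,
# companion balances, generation counting.

mini_table <- function(df, D = 0.03, gdw = 24.6, t_switch = 0,
                       feed_ethanol = 0.25) {
  timeseries_table(df, metadata = list(D = D, gdw_per_cmol = gdw,
                                       t_switch = t_switch,
                                       feed_ethanol = feed_ethanol,
                                       feed_paa = 4))
}

test_that("a degree-3 polynomial is interpolated exactly, derivative included", {
  t <- seq(0, 10, by = 0.5)
  y <- 2 - 0.3 * t + 0.05 * t^2 - 0.002 * t^3
  tab <- mini_table(data.frame(time = t, biomass = 1, peng = y, paa = 1,
                               ethanol = 0.1))
  fit <- fit_smooth(tab, "peng", degree = 3)
  expect_lt(max(abs(fit$residuals)), 1e-12)
  tt <- seq(0.5, 9.5, by = 0.25)
  expect_equal(fit$value(tt), 2 - 0.3 * tt + 0.05 * tt^2 - 0.002 * tt^3,
               tolerance = 1e-10)
  expect_equal(fit$deriv(tt), -0.3 + 0.1 * tt - 0.006 * tt^2,
               tolerance = 1e-9)
})

test_that("a constant series fits to the constant with zero derivative", {
  t <- seq(0, 60, by = 12)
  tab <- mini_table(data.frame(time = t, biomass = 3, peng = 1.5, paa = 2,
                               ethanol = 0.05))
  for (m in c("poly", "spline")) {
    fit <- fit_smooth(tab, "peng", degree = 3, method = m)
    expect_equal(fit$value(c(6, 30, 54)), rep(1.5, 3), tolerance = 1e-8)
    expect_lt(max(abs(fit$deriv(c(6, 30, 54)))), 1e-7)
  }
})

test_that("under-determined fits are refused with the required point count", {
  t <- seq(0, 48, by = 12)
  tab <- mini_table(data.frame(time = t, biomass = 3, peng = 1, paa = 2,
                               ethanol = 0.05))
  expect_error(fit_smooth(tab, "peng", degree = 5), "at least 7 points")
  expect_error(fit_smooth(tab, "nope", degree = 2), "no column")
})

test_that("fit derivatives agree with finite differences of fitted values", {
  tab <- fixture_table()
  for (m in c("poly", "spline")) {
    fit <- fit_smooth(tab, "peng", degree = 5, method = m)
    tt <- seq(fit$window[1] + 20, fit$window[2] - 20, length.out = 50)
    h <- 1e-3
    fd <- (fit$value(tt + h) - fit$value(tt - h)) / (2 * h)
    an <- fit$deriv(tt)
    expect_lt(max(abs(an - fd) / pmax(abs(an), 1e-8)), 1e-6)
  }
})

test_that("steady state reduces the estimator to q_p = D Cp/Cx", {
  # constant Cp = 2 mmol/L and Cx = 0.122 Cmol/L at D = 0.03 1/h force
  # q_p = 0.03*2/0.122 = 0.4918 mmol/Cmol/h
  t <- seq(0, 120, by = 12)
  tab <- mini_table(data.frame(time = t, biomass = 0.122 * 24.6, peng = 2,
                               paa = 2, ethanol = 1e-4))
  prof <- qp_profile(fit_smooth(tab, "peng", 3), fit_smooth(tab, "biomass", 3),
                     D = 0.03)
  expect_equal(prof$qp, rep(0.03 * 2 / 0.122, nrow(prof)), tolerance = 1e-9)
})

test_that("steady-state identity holds across random states", {
  set.seed(7)
  for (k in 1:25) {
    cp <- stats::runif(1, 0.1, 5)
    cx_g <- stats::runif(1, 1, 6)
    D <- stats::runif(1, 0.01, 0.1)
    gdw <- stats::runif(1, 20, 28)
    t <- seq(0, 96, by = 12)
    tab <- mini_table(data.frame(time = t, biomass = cx_g, peng = cp,
                                 paa = 1, ethanol = 1e-4), D = D, gdw = gdw)
    prof <- qp_profile(fit_smooth(tab, "peng", 2),
                       fit_smooth(tab, "biomass", 2), D = D,
                       gdw_per_cmol = gdw, n = 11)
    expect_equal(prof$qp, rep(D * cp / (cx_g / gdw), 11), tolerance = 1e-8)
  }
})

test_that("the estimator reproduces the generator's production peak and decline", {
  tab <- fixture_table()
  pk <- qp_peak(tab)
  expect_equal(pk$qp_max, 0.52, tolerance = 0.02 / 0.52)
  expect_gt(pk$t_max, 40)
  expect_lt(pk$t_max, 100)
  expect_gte(fold_decline(tab, t_ref = 500), 10)
})

test_that("estimated q_p tracks the simulator within 3% away from the edges", {
  sim <- fixture_sim()
  tab <- fixture_table()
  prof <- estimate_rates(tab, method = "spline")
  truth <- stats::approx(sim$times, sim$rates$qp, xout = prof$time)$y
  interior <- prof$time > sim$t_switch + 30 &
    prof$time < max(prof$time) - 30
  rel <- abs(prof$qp - truth) / truth
  expect_lt(max(rel[interior]), 0.03)
})

test_that("companion balances return mu = D at steady state and the true q_s", {
  t <- seq(0, 120, by = 12)
  tab <- mini_table(data.frame(time = t, biomass = 3.0012, peng = 2,
                               paa = 2, ethanol = 1e-4))
  prof <- companion_rates(tab, degree = 2)
  expect_equal(prof$mu, rep(0.03, nrow(prof)), tolerance = 1e-6)
  sim <- fixture_sim()
  prof2 <- estimate_rates(fixture_table(), method = "spline")
  qs_true <- stats::approx(sim$times, sim$rates$qs, xout = prof2$time)$y
  interior <- prof2$time > sim$t_switch + 30 &
    prof2$time < max(prof2$time) - 30
  expect_lt(max(abs(prof2$qs - qs_true)[interior] / qs_true[interior]), 0.02)
})

test_that("batch-phase growth rate is recovered from a batch slice", {
  sim <- fixture_sim()
  tab <- sample_timeseries(sim, noise_model(relative_sd = 0,
                                            sampling_interval = 4))
  prof <- companion_rates(tab, D = 0,
                          window = c(2, sim$t_switch - 2), degree = 3)
  mid <- prof$time > 10 & prof$time < 30
  expect_equal(stats::median(prof$mu[mid]), 0.088, tolerance = 0.03)
})

test_that("generation counting uses the doubling convention", {
  expect_equal(generations(500, 0.03), 15 / log(2), tolerance = 1e-12)
  expect_identical(generations(0, 0.03), 0)
  expect_equal(generations(log(2) / 0.03, 0.03), 1, tolerance = 1e-12)
  expect_error(generations(-1, 0.03), "t must be")
  expect_error(generations(10, 0), "D must be")
})
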
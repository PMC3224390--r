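# Mechanistic model: kinetics, two-strain competition, steady state.

pr_default <- function(...) strain_params(qp_cell_max = 0.78,
                                          Yps_burden = 0.0320512821,
                                          k_induction = 0.03, ...)
np_default <- function(...) strain_params(qp_cell_max = 0, ...)

test_that("parameter and state validation rejects unphysical inputs", {
  expect_error(strain_params(mu_max = -0.1), "negative")
  expect_error(strain_params(Yxs_max = 1.2), "carbon conservation")
  expect_error(strain_params(paa_side_fraction = 1), "paa_side_fraction")
  expect_error(chemostat_config(f0 = 1.5), "f0")
  expect_error(chemostat_config(t_switch = 100, horizon = 50), "horizon")
  expect_error(culture_state(s = -1), "negative value for s")
  expect_error(culture_state(e = 2), "e must be")
  st <- culture_state(x_p = 0.1, s = 0.01)
  st["x_p"] <- -0.1
  cfg <- chemostat_config(t_switch = 0)
  expect_error(derivative(st, cfg, pr_default(), np_default()),
               "negative state component: x_p")
})

test_that("washout limit: with zero biomass only dilution acts", {
  cfg <- chemostat_config(t_switch = 0)
  st <- culture_state(s = 0.1, paa = 2)
  d <- derivative(st, cfg, pr_default(), np_default(), t = 10)
  expect_identical(unname(d[c("x_p", "x_np")]), c(0, 0))
  expect_equal(unname(d[["s"]]), cfg$D * (cfg$feed_ethanol - 0.1))
  expect_equal(unname(d[["paa"]]), cfg$D * (cfg$feed_paa - 2))
})

test_that("growth-rate gap between the strains equals the burden closed form", {
  # mu_np - mu_p = Yxs_max * Yps_burden * qp_cell, scaled by the lysis
  # diversion for the net biomass accretion rates
  cfg <- chemostat_config(t_switch = 0)
  pr <- pr_default()
  st <- culture_state(x_p = 0.05, x_np = 0.05, s = 2e-4, e = 1,
                      paa = 3, p = 1)
  d <- derivative(st, cfg, pr, np_default(), t = 10)
  gap <- d[["x_np"]] / st[["x_np"]] - d[["x_p"]] / st[["x_p"]]
  expect_equal(gap,
               (1 - cfg$toc_fraction) * pr$Yxs_max * pr$Yps_burden *
                 pr$qp_cell_max,
               tolerance = 1e-12)
})

test_that("pure producer culture shows no decline over the horizon", {
  p <- fixture_preset()
  cfg <- p$config
  cfg$f0 <- 0
  cfg$horizon <- 400
  sim <- simulate_culture(cfg, p$producer, p$nonproducer, dt = 1)
  expect_true(all(sim$rates$producer_fraction == 1))
  chem <- sim$times > sim$t_switch + 150
  qp_late <- sim$rates$qp[chem]
  expect_gt(min(qp_late) / max(sim$rates$qp), 0.95)
})

test_that("population q_p peaks 40-80 h after feed start and then declines", {
  sim <- fixture_sim()
  i <- which.max(sim$rates$qp)
  t_peak <- sim$times[i] - sim$t_switch
  expect_gt(t_peak, 40)
  expect_lt(t_peak, 80)
  expect_lt(sim$rates$qp[length(sim$times)], max(sim$rates$qp) / 10)
})

test_that("producer fraction follows the exponential selection oracle", {
  # with fast induction the enzyme level saturates immediately after feed
  # start, so the producer/non-producer odds decay at the constant rate
  # (1 - toc_fraction) * Yxs * Yps * qp_cell
  p <- fixture_preset()
  pr <- p$producer
  pr$k_induction <- 5
  cfg <- p$config
  cfg$horizon <- 360
  sim <- simulate_culture(cfg, pr, p$nonproducer, dt = 1)
  delta <- (1 - cfg$toc_fraction) * pr$Yxs_max * pr$Yps_burden *
    pr$qp_cell_max
  chem <- sim$times >= sim$t_switch + 5 & sim$times <= sim$t_switch + 300
  odds <- sim$states[chem, "x_p"] / sim$states[chem, "x_np"]
  tt <- sim$times[chem] - sim$times[chem][1]
  oracle <- odds[1] * exp(-delta * tt)
  expect_lt(max(abs(odds / oracle - 1)), 0.02)
})

test_that("single-strain steady state matches the chemostat observables", {
  ss <- steady_state(chemostat_config(), strain_params(qp_cell_max = 0))
  expect_equal(attr(ss, "biomass_gdw_l"), 3, tolerance = 0.05)
  # no maintenance, no production, no lysis: x = Yxs * (feed - s) exactly
  cfg0 <- chemostat_config(toc_fraction = 0)
  par0 <- strain_params(qp_cell_max = 0, ms = 0)
  ss0 <- steady_state(cfg0, par0)
  expect_equal(ss0[["x_np"]],
               par0$Yxs_max * (cfg0$feed_ethanol -
                                 attr(ss0, "residual_ethanol")),
               tolerance = 1e-12)
  expect_error(steady_state(chemostat_config(D = 0.1),
                            strain_params(mu_max = 0.088)), "washout")
})

test_that("steady state is a fixed point of the derivative", {
  cfg <- chemostat_config(t_switch = 0)
  for (par in list(strain_params(qp_cell_max = 0),
                   pr_default())) {
    ss <- steady_state(cfg, par)
    d <- derivative(ss, cfg, par, par, t = 10)
    expect_lt(max(abs(d)), 1e-10)
  }
})

test_that("simulated single-strain chemostat converges to the algebraic solve", {
  p <- fixture_preset()
  cfg <- p$config
  cfg$f0 <- 1          # non-producer only
  cfg$horizon <- 720   # > 20 residence times of chemostat operation
  sim <- simulate_culture(cfg, p$producer, p$nonproducer, dt = 2)
  ss <- steady_state(cfg, p$nonproducer)
  t20 <- sim$t_switch + 20 / cfg$D
  x_sim <- stats::approx(sim$times,
                         sim$states[, "x_p"] + sim$states[, "x_np"],
                         xout = t20)$y
  expect_equal(x_sim, unname(ss[["x_np"]]), tolerance = 1e-3)
})

test_that("chemostat-phase carbon flows balance at every sampled state", {
  sim <- fixture_sim()
  cfg <- sim$config
  idx <- which(sim$times > sim$t_switch + 1)
  idx <- idx[seq(1, length(idx), length.out = 25)]
  for (i in idx) {
    st <- sim$states[i, ]
    d <- derivative(st, cfg, sim$producer, sim$nonproducer,
                    t = sim$times[i])
    dC <- d[["x_p"]] + d[["x_np"]] + d[["s"]] + d[["toc"]] +
      0.016 * d[["p"]] + 0.008 * (d[["paa"]] + d[["ohpaa"]])
    c_state <- st[["x_p"]] + st[["x_np"]] + st[["s"]] + st[["toc"]] +
      0.016 * st[["p"]] + 0.008 * (st[["paa"]] + st[["ohpaa"]])
    inflow <- cfg$D * (cfg$feed_ethanol + 0.008 * cfg$feed_paa)
    # CO2 leaves as gas: closure means dC/dt = in - overflow - CER
    cer <- stats::approx(sim$times, sim$rates$cer, xout = sim$times[i])$y
    expect_lt(abs(inflow - cfg$D * c_state - cer / 1000 - dC), 1e-9)
  }
})

test_that("time to 10-fold decline shrinks as the non-producer share grows", {
  p <- fixture_preset()
  t10 <- vapply(c(0.05, 0.15, 0.30), function(f0) {
    cfg <- p$config
    cfg$f0 <- f0
    sim <- simulate_culture(cfg, p$producer, p$nonproducer, dt = 1,
                            rtol = 1e-7, atol = 1e-9)
    i <- which.max(sim$rates$qp)
    j <- which(sim$rates$qp < sim$rates$qp[i] / 10 &
                 seq_along(sim$times) > i)[1]
    sim$times[j] - sim$t_switch
  }, numeric(1))
  expect_true(all(diff(t10) < 0))
})

test_that("removing the production burden removes selection", {
  p <- fixture_preset()
  pr <- p$producer
  pr$Yps_burden <- 0
  cfg <- p$config
  cfg$horizon <- 300
  sim <- simulate_culture(cfg, pr, p$nonproducer, dt = 2)
  fr <- sim$rates$producer_fraction[sim$times > sim$t_switch]
  expect_lt(max(abs(fr - fr[1])), 1e-6)
})
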
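# Pseudo-steady-state MFA: parsing, validation, the WLS solver, ratios.

write_toy_network <- function(rxn_lines, met_lines) {
  rf <- tempfile(fileext = ".tsv")
  mf <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation\treversible\tmeasured", rxn_lines), rf)
  writeLines(c("id\tc\th\to\tn\ts\tbalanced\texempt", met_lines), mf)
  list(reactions = rf, metabolites = mf)
}

toy_mets <- c("A\t1\t2\t1\t0\t0\t0\t0",
              "B\t1\t2\t1\t0\t0\t1\t0",
              "C\t1\t2\t1\t0\t0\t0\t0")

test_that("a two-step linear chain parses into one balanced metabolite", {
  fs <- write_toy_network(c("r1\t1 A -> 1 B\t0\t1",
                            "r2\t1 B -> 1 C\t0\t0"), toy_mets)
  net <- load_network(fs$reactions, fs$metabolites)
  expect_equal(ncol(net$S), 2)
  expect_identical(net$balanced, "B")
  sol <- solve_fluxes(net, data.frame(reaction_id = "r1", value = 1,
                                      se = 0.05))
  expect_equal(unname(sol$fluxes[c("r1", "r2")]), c(1, 1),
               tolerance = 1e-10)
  expect_identical(sol$solvability, "determined")
})

test_that("elemental imbalance and unknown metabolites are caught", {
  fs <- write_toy_network("r1\t1 A -> 2 B\t0\t1", toy_mets)
  expect_error(load_network(fs$reactions, fs$metabolites),
               "unbalanced")
  fs2 <- write_toy_network("r1\t1 A -> 1 Z\t0\t1", toy_mets)
  expect_error(load_network(fs2$reactions, fs2$metabolites),
               "unknown metabolite")
  # a balanced metabolite used by no reaction is an orphan
  fs3 <- write_toy_network("r1\t1 A -> 1 C\t0\t1",
                           c(toy_mets, "D\t1\t2\t1\t0\t0\t1\t0"))
  expect_error(load_network(fs3$reactions, fs3$metabolites), "orphan")
})

test_that("a measured branch point splits flux as solved by hand", {
  # uptake 1.0 into B; branch B -> C (measured 0.3) and B -> D: the
  # remaining 0.7 must leave through D
  mets <- c("A\t1\t2\t1\t0\t0\t0\t0",
            "B\t1\t2\t1\t0\t0\t1\t0",
            "C\t1\t2\t1\t0\t0\t0\t0",
            "D\t1\t2\t1\t0\t0\t0\t0")
  fs <- write_toy_network(c("upt\t1 A -> 1 B\t0\t1",
                            "b1\t1 B -> 1 C\t0\t1",
                            "b2\t1 B -> 1 D\t0\t0"), mets)
  net <- load_network(fs$reactions, fs$metabolites)
  sol <- solve_fluxes(net, data.frame(reaction_id = c("upt", "b1"),
                                      value = c(1, 0.3), se = c(0.05, 0.02)))
  expect_equal(unname(sol$fluxes[["b2"]]), 0.7, tolerance = 1e-10)
})

test_that("underdetermined systems report non-estimable fluxes, never guess", {
  mets <- c("A\t1\t2\t1\t0\t0\t0\t0",
            "B\t1\t2\t1\t0\t0\t1\t0",
            "C\t1\t2\t1\t0\t0\t0\t0",
            "D\t1\t2\t1\t0\t0\t0\t0")
  fs <- write_toy_network(c("upt\t1 A -> 1 B\t0\t1",
                            "b1\t1 B -> 1 C\t0\t0",
                            "b2\t1 B -> 1 D\t0\t0"), mets)
  net <- load_network(fs$reactions, fs$metabolites)
  sol <- solve_fluxes(net, data.frame(reaction_id = "upt", value = 1,
                                      se = 0.05))
  expect_identical(sol$solvability, "underdetermined")
  expect_setequal(sol$non_estimable, c("b1", "b2"))
})

test_that("random determined networks are recovered exactly (oracle check)", {
  for (seed in 1:20) {
    case <- random_flux_case(seed)
    sol <- solve_fluxes(case$net, case$measured)
    expect_lt(max(abs(sol$fluxes - case$v_true)), 1e-8)
    expect_lt(sol$residual_inf, 1e-8)
    expect_identical(length(sol$non_estimable), 0L)
  }
})

test_that("scaling all measurements scales all fluxes (equivariance)", {
  case <- random_flux_case(101)
  sol1 <- solve_fluxes(case$net, case$measured)
  m2 <- case$measured
  m2$value <- m2$value * 3.7
  sol2 <- solve_fluxes(case$net, m2)
  expect_equal(sol2$fluxes, sol1$fluxes * 3.7, tolerance = 1e-9)
})

test_that("the bundled reduced network loads and carries the PenG pathway", {
  net <- load_network()
  expect_gte(ncol(net$S), 25)
  expect_true(all(c("acvs", "ipns", "aat", "pcl", "cyss", "vals", "aaas")
                  %in% colnames(net$S)))
  expect_gte(length(net$measured), 8)
  # steady-state residual on the bundled scenario solution
  m75 <- mfa_scenario_rates(fixture_sim(), 75)
  sol <- solve_fluxes(net, m75)
  expect_lt(sol$residual_inf, 1e-8)
  expect_identical(sol$solvability, "overdetermined")
  expect_lt(sol$wrss / max(sol$redundancy, 1), 1e-6)
})

test_that("peak vs degenerated scenarios give a >=10-fold cysteine flux drop", {
  net <- load_network()
  sim <- fixture_sim()
  f75 <- solve_fluxes(net, mfa_scenario_rates(sim, 75))
  f500 <- solve_fluxes(net, mfa_scenario_rates(sim, 500))
  expect_gte(flux_ratio(f75, f500, "cyss"), 10)
  # the PenG formation ratio tracks the measured q_p ratio linearly
  m75 <- mfa_scenario_rates(sim, 75)
  m500 <- mfa_scenario_rates(sim, 500)
  qp_ratio <- m75$value[m75$reaction_id == "t_peng"] /
    m500$value[m500$reaction_id == "t_peng"]
  expect_equal(flux_ratio(f75, f500, "t_peng"), qp_ratio,
               tolerance = 1e-6)
  # NADPH supply through the oxidative PPP shrinks in the degenerated state
  expect_gt(f75$fluxes[["ppp"]], f500$fluxes[["ppp"]])
})

test_that("flux ratios behave as ratios", {
  case <- random_flux_case(55)
  sol <- solve_fluxes(case$net, case$measured)
  m2 <- case$measured
  m2$value <- 2 * m2$value
  sol2 <- solve_fluxes(case$net, m2)
  rid <- names(which(abs(sol$fluxes) > 1e-6))[1]
  expect_equal(flux_ratio(sol, sol, rid), 1)
  expect_equal(flux_ratio(sol2, sol, rid), 2, tolerance = 1e-9)
  zero <- sol
  zero$fluxes[rid] <- 0
  expect_error(flux_ratio(sol, zero, rid), "zero denominator")
  expect_error(flux_ratio(sol, sol, "nope"), "not in estimate")
})

test_that("grossly inconsistent measurements in a redundant system error out", {
  net <- load_network()
  m75 <- mfa_scenario_rates(fixture_sim(), 75)
  m75$value[m75$reaction_id == "t_co2"] <-
    m75$value[m75$reaction_id == "t_co2"] * 3
  expect_error(solve_fluxes(net, m75), "inconsistent")
})
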
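# FBA, the mixed-integer thermodynamic program, and flux variability.

chain_net <- function(lb_uptake = -5, ub_chain = 100) {
  mets <- data.frame(id = c("A", "B"), compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_A", "R1", "EX_B"),
                     lower_bound = c(lb_uptake, 0, 0),
                     upper_bound = c(0, ub_chain, ub_chain),
                     objective_coeff = c(0, 0, 1), stringsAsFactors = FALSE)
  S <- matrix(c(-1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(mets$id, rxns$id))
  metabolic_network(mets, rxns, S)
}

test_that("FBA solves the hand-checkable chain LP", {
  sol <- solve_fba(chain_net())
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 5)
  expect_lt(max(abs(chain_net()$S %*% sol$fluxes)), 1e-6)
  # zero uptake bound gives zero objective
  expect_equal(solve_fba(chain_net(lb_uptake = 0))$objective, 0)
})

test_that("FBA reports unbounded and infeasible statuses", {
  unb <- chain_net(lb_uptake = -Inf, ub_chain = Inf)
  expect_identical(solve_fba(unb)$status, "unbounded")
  # a forced internal flux with no source is infeasible
  net <- chain_net()
  net$rxns$lower_bound[net$rxns$id == "R1"] <- 3
  net$rxns$upper_bound[net$rxns$id == "EX_A"] <- 0
  net$rxns$lower_bound[net$rxns$id == "EX_A"] <- 0
  expect_identical(solve_fba(net)$status, "infeasible")
})

test_that("with no known thermodynamics TMFA is exactly FBA", {
  fx <- make_network_fixture("futile_cycle", seed = 4)
  all_unknown <- thermo_table(data.frame(
    id = fx$network$mets$id, value = NA_real_, se = 0, unknown = TRUE))
  th <- assemble_reaction_thermo(fx$network, all_unknown)
  expect_false(any(th$known))
  p <- build_tmfa(fx$network, th, NULL, thermo_config())
  fba <- solve_fba(fx$network)
  tmfa <- solve_tmfa(p)
  expect_equal(tmfa$objective, fba$objective)
  fva_a <- flux_variability(build_tmfa(fx$network))
  fva_b <- flux_variability(p)
  expect_equal(fva_a$v_min, fva_b$v_min, tolerance = 1e-9)
  expect_equal(fva_a$v_max, fva_b$v_max, tolerance = 1e-9)
})

test_that("thermodynamic constraints eliminate the planted futile cycle", {
  fx <- make_network_fixture("futile_cycle", seed = 1)
  b <- tf_build(fx)
  fba_p <- build_tmfa(fx$network)
  cyc <- fx$truth$cycle_reactions
  fva_fba <- flux_variability(fba_p, reactions = cyc)
  fva_tmfa <- flux_variability(b$problem, reactions = cyc)
  # FBA lets the cycle spin up to its bound; TMFA pins it at the
  # pathway-required throughput (zero: the export route bypasses the cycle)
  expect_equal(fva_fba$v_max, rep(fx$truth$cycle_upper_bound, 3))
  expect_equal(fva_tmfa$v_max, rep(0, 3), tolerance = 1e-9)
  expect_equal(fva_tmfa$v_min, rep(0, 3), tolerance = 1e-9)
  # the objective itself is unaffected: feasible pathways still carry flux
  expect_equal(solve_tmfa(b$problem)$objective, solve_fba(fx$network)$objective)
})

test_that("an all-downhill pathway is not restricted by TMFA", {
  fx <- make_network_fixture("linear_chain", n_reactions = 5, seed = 9)
  b <- tf_build(fx)
  expect_equal(solve_tmfa(b$problem)$objective,
               solve_fba(fx$network)$objective)
})

test_that("TMFA never beats FBA and collapsing activities can kill required flux", {
  for (seed in c(3, 8)) {
    fx <- make_network_fixture("branched", seed = seed)
    b <- tf_build(fx)
    expect_lte(solve_tmfa(b$problem)$objective,
               solve_fba(fx$network)$objective + 1e-9)
  }
  # force flux through an uphill step with activities pinned to a point
  mets <- data.frame(id = c("A", "B"), compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_A", "R1", "EX_B"),
                     lower_bound = c(-5, 1, 1), upper_bound = c(0, 10, 10),
                     objective_coeff = c(0, 0, 1), stringsAsFactors = FALSE)
  S <- matrix(c(-1, 0, -1, 1, 0, -1), 2, 3, dimnames = list(mets$id, rxns$id))
  net <- metabolic_network(mets, rxns, S)
  tab <- thermo_table(data.frame(id = c("A", "B"), value = c(-10, -5),
                                 se = 0, unknown = FALSE))  # R1 uphill (+5)
  th <- assemble_reaction_thermo(net, tab)
  cfg <- thermo_config(ln_activity_min = -9, ln_activity_max = -9 + 1e-9)
  p <- build_tmfa(net, th, NULL, cfg)
  expect_identical(solve_tmfa(p)$status, "infeasible")
})

test_that("tightening activity bounds never increases the TMFA optimum", {
  fx <- make_network_fixture("mini_core", seed = 1)
  th <- assemble_reaction_thermo(fx$network, fx$thermo)
  wide <- solve_tmfa(build_tmfa(fx$network, th, NULL, thermo_config()))
  narrow <- solve_tmfa(build_tmfa(fx$network, th, NULL,
                                  thermo_config(ln_activity_min = log(1e-4),
                                                ln_activity_max = log(2e-3))))
  expect_lte(narrow$objective, wide$objective + 1e-9)
})

test_that("TMFA optima match exhaustive binary enumeration", {
  cfg <- thermo_config()
  for (fx in fixture_suite(n = 6, seed = 100)) {
    b <- tf_build(fx, cfg)
    sol <- solve_tmfa(b$problem)
    orc <- oracle_enumerate(fx$network, b$th, cfg,
                            objective = fx$truth$objective_reaction,
                            do_tva = FALSE)
    expect_equal(sol$objective, orc$optimum, tolerance = 1e-6)
  }
})

test_that("optimal solutions always pass the second-law audit", {
  cfg <- thermo_config()
  for (fx in fixture_suite(n = 5, seed = 40)) {
    b <- tf_build(fx, cfg)
    sol <- solve_tmfa(b$problem)
    expect_identical(sol$status, "optimal")
    expect_identical(nrow(audit_second_law(sol, cfg)), 0L)
  }
})

test_that("relaxing the objective to zero reduces FVA to bound propagation", {
  fx <- make_network_fixture("futile_cycle", seed = 1)
  fva <- flux_variability(build_tmfa(fx$network), fix_objective_at = 0)
  got <- stats::setNames(split(as.matrix(fva[, 2:3]), seq_len(nrow(fva))),
                         fva$reaction_id)
  expect_equal(unname(unlist(got[["AB"]])), c(0, 5))    # limited by uptake
  expect_equal(unname(unlist(got[["BC"]])), c(0, 100))  # free to circulate
  expect_equal(unname(unlist(got[["EX_A"]])), c(-5, 0))
})
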
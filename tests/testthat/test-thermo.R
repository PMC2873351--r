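# Assembly of reaction energies, the activity correction, and lumping.

two_step_net <- function() {
  mets <- data.frame(id = c("A", "B", "X"), compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("RAB", "RAX", "EX_A"),
                     lower_bound = c(0, 0, -10), upper_bound = c(10, 10, 10),
                     stringsAsFactors = FALSE)
  S <- matrix(c(-1, 1, 0,  -1, 0, 1,  -1, 0, 0), 3, 3,
              dimnames = list(mets$id, rxns$id))
  metabolic_network(mets, rxns, S)
}

test_that("reaction energies are stoichiometric sums with quadrature errors", {
  net <- two_step_net()
  tab <- thermo_table(data.frame(id = c("A", "B"), value = c(-10, -14),
                                 se = c(0.3, 0.4), unknown = FALSE))
  th <- assemble_reaction_thermo(net, tab)
  expect_equal(th$drG0[th$reaction_id == "RAB"], -4)
  expect_equal(th$se[th$reaction_id == "RAB"], 0.5)  # sqrt(0.09 + 0.16)
  # X has no formation energy: RAX is unknown, not an error
  expect_false(th$known[th$reaction_id == "RAX"])
  # exchange reactions are never thermodynamically constrained
  expect_false(th$constrained[th$reaction_id == "EX_A"])
})

test_that("an UNKNOWN participant marks the reaction unknown; overrides win", {
  net <- two_step_net()
  tab <- thermo_table(
    data.frame(id = c("A", "B", "X"), value = c(-10, -14, NA),
               se = c(0, 0, 0), unknown = c(FALSE, FALSE, TRUE)),
    reaction = data.frame(id = "RAX", value = -7.25, se = 0.9))
  th <- assemble_reaction_thermo(net, tab)
  expect_true(th$known[th$reaction_id == "RAX"])
  expect_equal(th$drG0[th$reaction_id == "RAX"], -7.25)
  expect_equal(th$se[th$reaction_id == "RAX"], 0.9)
})

test_that("delta_g_prime adds the RT-weighted mixing term", {
  cfg <- thermo_config()
  st <- c(A = -1, B = 1)
  # all activities 1: the mixing term vanishes
  expect_equal(delta_g_prime(-4, st, c(A = 0, B = 0), cfg), -4)
  # A -> B at x_A = 0.02, x_B = 1e-5: RT ln(5e-4)
  got <- delta_g_prime(0, st, c(A = log(0.02), B = log(1e-5)), cfg)
  expect_equal(got, 1.9859e-3 * 298.15 * log(5e-4), tolerance = 1e-12)
  expect_equal(got, -4.5006, tolerance = 1e-4)
  # doubling the stoichiometry doubles both terms
  expect_equal(delta_g_prime(-8, 2 * st, c(A = log(0.02), B = log(1e-5)), cfg),
               2 * delta_g_prime(-4, st, c(A = log(0.02), B = log(1e-5)), cfg))
  expect_error(delta_g_prime(0, st, c(A = 0), cfg), "B",
               class = "thermoflux_validation_error")
})

test_that("delta_g_prime is monotone with slope RT per unit stoichiometry", {
  cfg <- thermo_config()
  st <- c(A = -2, B = 1)
  base <- delta_g_prime(-1, st, c(A = -5, B = -5), cfg)
  up_b <- delta_g_prime(-1, st, c(A = -5, B = -4), cfg)
  dn_a <- delta_g_prime(-1, st, c(A = -4, B = -5), cfg)
  expect_equal(up_b - base, cfg$RT * 1)     # product: increasing
  expect_equal(dn_a - base, -cfg$RT * 2)    # substrate: decreasing, slope RT|n|
})

test_that("water and protons stay out of the mixing term", {
  mets <- data.frame(id = c("A", "B", "h2o", "h"), compartment = "c",
                     is_water = c(FALSE, FALSE, TRUE, FALSE),
                     is_proton = c(FALSE, FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = "R", lower_bound = 0, upper_bound = 10,
                     stringsAsFactors = FALSE)
  S <- matrix(c(-1, 1, 1, 1), 4, 1, dimnames = list(mets$id, "R"))
  net <- metabolic_network(mets, rxns, S)
  tab <- thermo_table(data.frame(id = c("A", "B", "h2o"),
                                 value = c(-10, -4, -56), se = 0,
                                 unknown = FALSE))
  th <- assemble_reaction_thermo(net, tab)
  # water's formation energy enters drG0; the proton never does
  expect_equal(th$drG0[1], -4 - 56 + 10)
  cfg <- thermo_config()
  p <- build_tmfa(net, th, NULL, cfg)
  expect_false(any(grepl("lnx.h2o|lnx.h$", p$milp$var_names)))
})

test_that("fixture thermodynamics obey the loop law", {
  # every nullspace vector of the internal stoichiometry has zero
  # energy-weighted sum, because reaction energies derive from formation
  # energies
  for (kind in c("futile_cycle", "mini_core")) {
    fx <- make_network_fixture(kind, seed = 11)
    th <- assemble_reaction_thermo(fx$network, fx$thermo)
    internal <- !fx$network$rxns$is_exchange & th$known
    N <- pracma::nullspace(fx$network$S[, internal, drop = FALSE])
    if (is.null(N)) next
    for (k in seq_len(ncol(N))) {
      w <- N[, k]
      expect_lt(abs(sum(w * th$drG0[internal])), 1e-9)
    }
  }
  # and the planted cycle specifically sums to zero
  fx <- make_network_fixture("futile_cycle", seed = 5)
  th <- assemble_reaction_thermo(fx$network, fx$thermo)
  cyc <- match(fx$truth$cycle_reactions, th$reaction_id)
  expect_lt(abs(sum(th$drG0[cyc])), 1e-12)
})

test_that("lumping cancels unknown metabolites with integer multipliers", {
  # pairwise cancellation: R1 A->X, R2 X->B
  fx <- make_network_fixture("unknown_metabolite", seed = 2)  # multiplier 1
  th <- assemble_reaction_thermo(fx$network, fx$thermo)
  lum <- build_lumped_reactions(fx$network, th, fx$thermo)
  expect_length(lum$lumps, 1)
  expect_identical(lum$unlumpable, character(0))
  l <- lum$lumps[[1]]
  expect_equal(stats::setNames(l$members$coeff, l$members$reaction_id),
               c(R1 = 1, R2 = 1))
  expect_false("X" %in% names(l$net_stoich))
  # non-unit multiplier: R1 A->2X needs R2 twice
  fx2 <- make_network_fixture("unknown_metabolite", seed = 3)
  th2 <- assemble_reaction_thermo(fx2$network, fx2$thermo)
  lum2 <- build_lumped_reactions(fx2$network, th2, fx2$thermo)
  l2 <- lum2$lumps[[1]]
  expect_equal(stats::setNames(l2$members$coeff, l2$members$reaction_id),
               c(R1 = 1, R2 = 2))
  expect_equal(l2$net_stoich, fx2$truth$expected_lump$net)
  # lump energy comes from the (known) net stoichiometry
  expect_equal(l2$drG0, -12)
})

test_that("lump net stoichiometry equals the member-weighted sum exactly", {
  for (seed in 2:5) {
    fx <- make_network_fixture("unknown_metabolite", seed = seed)
    th <- assemble_reaction_thermo(fx$network, fx$thermo)
    lum <- build_lumped_reactions(fx$network, th, fx$thermo)
    for (l in lum$lumps) {
      w <- l$members$coeff * l$members$direction
      recon <- drop(fx$network$S[, l$members$reaction_id, drop = FALSE] %*% w)
      expect_identical(recon[recon != 0], l$net_stoich)
    }
  }
})

test_that("no unknown metabolites means no lumps; uncancellable reactions are reported", {
  fx <- make_network_fixture("linear_chain", seed = 1)
  th <- assemble_reaction_thermo(fx$network, fx$thermo)
  lum <- build_lumped_reactions(fx$network, th, fx$thermo)
  expect_length(lum$lumps, 0)
  # a lone reaction producing an unknown metabolite has no cancelling partner
  mets <- data.frame(id = c("A", "X"), compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_A", "R1"), lower_bound = c(-5, 0),
                     upper_bound = c(0, 10), stringsAsFactors = FALSE)
  S <- matrix(c(-1, 0, -1, 1), 2, 2, dimnames = list(mets$id, rxns$id))
  net <- metabolic_network(mets, rxns, S)
  tab <- thermo_table(data.frame(id = c("A", "X"), value = c(-10, NA), se = 0,
                                 unknown = c(FALSE, TRUE)))
  th2 <- assemble_reaction_thermo(net, tab)
  lum2 <- build_lumped_reactions(net, th2, tab)
  expect_identical(lum2$unlumpable, "R1")
})
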
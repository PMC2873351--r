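# Thermodynamic variability analysis and reaction classification.

test_that("TVA ranges match exhaustive enumeration at fixed growth", {
  cfg <- thermo_config()
  for (fx in fixture_suite(n = 3, seed = 60)) {
    b <- tf_build(fx, cfg)
    opt <- solve_tmfa(b$problem)$objective
    tva <- run_tva(b$problem, fx$truth$objective_reaction, opt,
                   with_uncertainty = FALSE)
    orc <- oracle_enumerate(fx$network, b$th, cfg,
                            growth = list(rxn = fx$truth$objective_reaction,
                                          value = opt),
                            do_tva = TRUE, with_uncertainty = FALSE)
    m <- merge(tva, orc$tva, by = "reaction_id")
    expect_gt(nrow(m), 0)
    expect_equal(m$drG_min.x, m$drG_min.y, tolerance = 1e-6)
    expect_equal(m$drG_max.x, m$drG_max.y, tolerance = 1e-6)
  }
})

test_that("TVA output order is network order and ranges are finite", {
  fx <- make_network_fixture("mini_core", seed = 1)
  b <- tf_build(fx)
  tva <- run_tva(b$problem, "BIOMASS", 1.25)
  con_order <- intersect(fx$network$rxns$id, tva$reaction_id)
  expect_identical(tva$reaction_id, con_order)
  expect_true(all(is.finite(tva$drG_min) & is.finite(tva$drG_max)))
  expect_true(all(tva$drG_min <= tva$drG_max + 1e-9))
})

test_that("pinning all activities collapses each range to a point", {
  fx <- make_network_fixture("linear_chain", n_reactions = 4, seed = 2)
  cfg <- thermo_config(ln_activity_min = -9, ln_activity_max = -9 + 1e-9)
  b <- tf_build(fx, cfg)
  opt <- solve_tmfa(b$problem)$objective
  tva <- run_tva(b$problem, fx$truth$objective_reaction, opt)
  expect_true(all(tva$drG_max - tva$drG_min < 1e-6))
})

test_that("uncertainty widens ranges; dropping the growth constraint never narrows them", {
  cfg <- thermo_config()
  fx <- make_network_fixture("linear_chain", n_reactions = 5, seed = 13)
  b <- tf_build(fx, cfg)
  opt <- solve_tmfa(b$problem)$objective
  fixed <- run_tva(b$problem, fx$truth$objective_reaction, opt,
                   with_uncertainty = FALSE)
  wide <- run_tva(b$problem, fx$truth$objective_reaction, opt,
                  with_uncertainty = TRUE)
  expect_true(all(wide$drG_min <= fixed$drG_min + 1e-9))
  expect_true(all(wide$drG_max >= fixed$drG_max - 1e-9))
  # free-growth ranges (by enumeration) contain the fixed-growth ranges
  free <- oracle_enumerate(fx$network, b$th, cfg, growth = NULL,
                           do_tva = TRUE, with_uncertainty = FALSE)
  m <- merge(fixed, free$tva, by = "reaction_id")
  expect_true(all(m$drG_min.y <= m$drG_min.x + 1e-6))
  expect_true(all(m$drG_max.y >= m$drG_max.x - 1e-6))
})

test_that("every feasible solution's free energies lie inside the TVA envelope", {
  fx <- make_network_fixture("mini_core", seed = 1)
  # fix growth through the bounds so ordinary solves sample the same set
  net <- fx$network
  j <- match("BIOMASS", net$rxns$id)
  net$rxns$lower_bound[j] <- net$rxns$upper_bound[j] <- 1.25
  th <- assemble_reaction_thermo(net, fx$thermo)
  p <- build_tmfa(net, th, NULL, thermo_config())
  # plain solves keep the uncertainty slack active, so compare against the
  # with-uncertainty envelope
  tva <- run_tva(p, "BIOMASS", 1.25, with_uncertainty = TRUE)
  lo <- stats::setNames(tva$drG_min, tva$reaction_id)
  hi <- stats::setNames(tva$drG_max, tva$reaction_id)
  for (obj in list("EX_co2", "MDH", c(MDH = -1), "DXPS")) {
    sol <- solve_tmfa(p, objective = obj)
    expect_identical(sol$status, "optimal")
    drG <- sol$drG[!is.na(sol$drG)]
    expect_true(all(drG >= lo[names(drG)] - 1e-6))
    expect_true(all(drG <= hi[names(drG)] + 1e-6))
  }
})

test_that("TVA refuses an infeasible growth fixing with a clear error", {
  fx <- make_network_fixture("linear_chain", n_reactions = 4, seed = 3)
  b <- tf_build(fx)
  expect_error(run_tva(b$problem, fx$truth$objective_reaction, 1e6),
               "infeasible", class = "thermoflux_infeasible")
})

test_that("classification follows the near/far-equilibrium rules", {
  tva <- data.frame(reaction_id = c("spans", "farneg", "nearneg", "farpos"),
                    drG_min = c(-1, -40, -10, 3),
                    drG_max = c(1, -10, -3, 9))
  cl <- classify_reactions(tva, eps_eq = 2, eps_far = 5)
  expect_identical(stats::setNames(cl$label, cl$reaction_id),
                   c(spans = "bottleneck", farneg = "regulatory_candidate",
                     nearneg = "threshold_of_regulation",
                     farpos = "unclassified"))
  expect_error(classify_reactions(tva, eps_eq = 5, eps_far = 2))
})

test_that("classification partitions exhaustively, exclusively and order-invariantly", {
  set.seed(7)
  n <- 200L
  lo <- stats::runif(n, -30, 10)
  tva <- data.frame(reaction_id = sprintf("r%03d", 1:n), drG_min = lo,
                    drG_max = lo + stats::runif(n, 0, 15))
  cl <- classify_reactions(tva)
  expect_identical(nrow(cl), n)
  expect_true(all(cl$label %in% c("bottleneck", "regulatory_candidate",
                                  "threshold_of_regulation", "unclassified")))
  perm <- sample(n)
  cl2 <- classify_reactions(tva[perm, ])
  expect_identical(cl2$label, cl$label[perm])
  # the three defining conditions are mutually exclusive by construction
  reg <- tva$drG_max < -5
  thr <- !reg & tva$drG_max < -2
  btl <- !reg & !thr & tva$drG_min <= 2
  expect_identical(cl$label == "regulatory_candidate", reg)
  expect_identical(cl$label == "threshold_of_regulation", thr)
  expect_identical(cl$label == "bottleneck", btl)
})

test_that("class overlap reports intersections per label", {
  a <- data.frame(reaction_id = c("MDH", "FUM", "CS"),
                  label = c("bottleneck", "bottleneck", "regulatory_candidate"))
  expect_identical(compare_class_overlap(a, a)$summary$n_intersection,
                   compare_class_overlap(a, a)$summary$n_union)
  b <- data.frame(reaction_id = c("X1", "X2"),
                  label = c("bottleneck", "regulatory_candidate"))
  ov <- compare_class_overlap(a, b)
  expect_true(all(ov$summary$n_intersection == 0))
  c3 <- data.frame(reaction_id = c("CS", "MDH"),
                   label = c("regulatory_candidate", "regulatory_candidate"))
  ov3 <- compare_class_overlap(a, c3)
  expect_identical(
    ov3$summary$n_intersection[ov3$summary$label == "regulatory_candidate"], 1L)
  expect_identical(ov3$shared$regulatory_candidate, "CS")
})
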
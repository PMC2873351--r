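# Seeded generators for synthetic networks and expression datasets.
#
# Network fixtures are built by assigning formation energies first and
# deriving every reaction energy from them, so the thermodynamics are
# loop-consistent by construction: any internal cycle's standard energies
# sum to zero to machine precision.  Each fixture returns its ground truth
# (planted cycles, unknown metabolites, expected lumps and classes) so the
# pipeline's behaviour can be checked against construction.

# Evaluate expr under a seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.mk_mets <- function(ids, compartment = "c") {
  data.frame(id = ids, name = ids, compartment = compartment,
             is_water = FALSE, is_proton = FALSE, stringsAsFactors = FALSE)
}

.mk_net <- function(met_ids, rxn_defs, compartments = NULL) {
  mets <- .mk_mets(met_ids)
  if (!is.null(compartments)) mets$compartment <- compartments
  rxns <- data.frame(id = vapply(rxn_defs, `[[`, "", "id"),
                     lower_bound = vapply(rxn_defs, `[[`, 0, "lb"),
                     upper_bound = vapply(rxn_defs, `[[`, 0, "ub"),
                     objective_coeff = vapply(rxn_defs, function(r)
                       r$obj %||% 0, 0),
                     gpr = vapply(rxn_defs, function(r) r$gpr %||% "", ""),
                     stringsAsFactors = FALSE)
  S <- matrix(0, length(met_ids), length(rxn_defs),
              dimnames = list(met_ids, rxns$id))
  for (k in seq_along(rxn_defs))
    S[names(rxn_defs[[k]]$stoich), k] <- rxn_defs[[k]]$stoich
  metabolic_network(mets, rxns, S)
}

.mk_thermo <- function(gf, se, unknown = character(0)) {
  ids <- names(gf)
  thermo_table(data.frame(id = ids, value = unname(gf),
                          se = unname(se[ids]),
                          unknown = ids %in% unknown,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic network fixture with known ground truth
#'
#' Kinds:
#' \describe{
#'   \item{linear_chain}{An uptake-chain-export pathway with jittered,
#'     clearly negative reaction energies; one interior step is reversible.}
#'   \item{branched}{A chain splitting at an interior node into two export
#'     branches.}
#'   \item{futile_cycle}{A linear pathway plus a planted three-reaction
#'     internal cycle whose standard energies sum to zero, so it can carry
#'     arbitrary flux under FBA but none under TMFA.}
#'   \item{unknown_metabolite}{A two-step pathway through an intermediate
#'     whose formation energy is unknown, so the two steps must be lumped.}
#'   \item{mini_core}{A deterministic ~19-reaction acetate-fed network with
#'     a TCA-like loop, planted near-equilibrium steps (MDH, FUM), planted
#'     far-from-equilibrium first-committed steps, and one step (DXPS) on
#'     the threshold of regulation; exercises every class label.}
#' }
#'
#' Formation energies are assigned first and reaction energies derived, so
#' fixture thermodynamics are loop-consistent to machine precision.
#' Generation is a pure function of `(kind, n_reactions, seed)`.
#'
#' @param kind Fixture kind (see above).
#' @param n_reactions Total reaction count for the chain kinds (ignored by
#'   `futile_cycle`, `unknown_metabolite` and `mini_core`).
#' @param seed Mandatory integer seed.
#' @return List `network` (a `metabolic_network`), `thermo` (a
#'   `thermo_table`), `truth` (list describing the planted structure).
#' @export
make_network_fixture <- function(kind = c("linear_chain", "branched",
                                          "futile_cycle", "unknown_metabolite",
                                          "mini_core"),
                                 n_reactions = 5, seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("seed is a mandatory argument")
  .with_seed(seed, switch(kind,
    linear_chain = .fixture_linear_chain(n_reactions),
    branched = .fixture_branched(n_reactions),
    futile_cycle = .fixture_futile_cycle(),
    unknown_metabolite = .fixture_unknown_metabolite(seed),
    mini_core = .fixture_mini_core()))
}

.fixture_linear_chain <- function(n_reactions) {
  k <- max(n_reactions - 2L, 1L)  # interior steps
  mets <- paste0("M", seq_len(k + 1L))
  defs <- list(list(id = "EX_M1", stoich = c(M1 = -1), lb = -5, ub = 0))
  dg <- -(4 + 6 * stats::runif(k))
  rev_step <- if (k >= 3) 2L else 0L
  if (rev_step) dg[rev_step] <- -1.5
  for (i in seq_len(k)) {
    st <- stats::setNames(c(-1, 1), mets[c(i, i + 1L)])
    defs[[length(defs) + 1L]] <-
      list(id = paste0("R", i), stoich = st,
           lb = if (i == rev_step) -100 else 0, ub = 100)
  }
  defs[[length(defs) + 1L]] <-
    list(id = "EX_out", stoich = stats::setNames(-1, mets[k + 1L]),
         lb = 0, ub = 100, obj = 1)
  gf <- stats::setNames(numeric(k + 1L), mets)
  gf[1] <- -50 + stats::runif(1, -2, 2)
  for (i in seq_len(k)) gf[i + 1L] <- gf[i] + dg[i]
  se <- stats::setNames(stats::runif(k + 1L, 0.1, 0.5), mets)
  list(network = .mk_net(mets, defs), thermo = .mk_thermo(gf, se),
       truth = list(kind = "linear_chain", fba_objective = 5,
                    tmfa_objective = 5, objective_reaction = "EX_out",
                    cycle_reactions = character(0),
                    unknown_metabolites = character(0)))
}

.fixture_branched <- function(n_reactions) {
  # M1 -> M2, then M2 -> M3 (objective export) and M2 -> M4 (side export)
  mets <- c("M1", "M2", "M3", "M4")
  dg <- -(4 + 6 * stats::runif(3))
  defs <- list(
    list(id = "EX_M1", stoich = c(M1 = -1), lb = -5, ub = 0),
    list(id = "R1", stoich = c(M1 = -1, M2 = 1), lb = 0, ub = 100),
    list(id = "R2", stoich = c(M2 = -1, M3 = 1), lb = 0, ub = 100),
    list(id = "R3", stoich = c(M2 = -1, M4 = 1), lb = 0, ub = 100),
    list(id = "EX_M3", stoich = c(M3 = -1), lb = 0, ub = 100, obj = 1),
    list(id = "EX_M4", stoich = c(M4 = -1), lb = 0, ub = 100))
  gf <- c(M1 = -50 + stats::runif(1, -2, 2))
  gf["M2"] <- gf["M1"] + dg[1]
  gf["M3"] <- gf["M2"] + dg[2]
  gf["M4"] <- gf["M2"] + dg[3]
  se <- stats::setNames(stats::runif(4, 0.1, 0.5), mets)
  list(network = .mk_net(mets, defs), thermo = .mk_thermo(gf, se),
       truth = list(kind = "branched", fba_objective = 5, tmfa_objective = 5,
                    objective_reaction = "EX_M3",
                    cycle_reactions = character(0),
                    unknown_metabolites = character(0)))
}

.fixture_futile_cycle <- function() {
  # pathway A -> B (exported) plus planted internal cycle B -> C -> D -> B;
  # the cycle's standard energies telescope to zero, so FBA can circulate
  # flux up to the bounds while TMFA forbids it entirely.  Formation
  # standard errors are zero: the planted truth is stated for exact
  # energies (uncertainty slack would licence small cycle fluxes).
  mets <- c("A", "B", "C", "D")
  d1 <- -(3 + 4 * stats::runif(1))
  d2 <- -(3 + 4 * stats::runif(1))
  defs <- list(
    list(id = "EX_A", stoich = c(A = -1), lb = -5, ub = 0),
    list(id = "AB", stoich = c(A = -1, B = 1), lb = 0, ub = 100),
    list(id = "EX_B", stoich = c(B = -1), lb = 0, ub = 100, obj = 1),
    list(id = "BC", stoich = c(B = -1, C = 1), lb = 0, ub = 100),
    list(id = "CD", stoich = c(C = -1, D = 1), lb = 0, ub = 100),
    list(id = "DB", stoich = c(D = -1, B = 1), lb = 0, ub = 100))
  gf <- c(A = -50 + stats::runif(1, -2, 2))
  gf["B"] <- gf["A"] - 10
  gf["C"] <- gf["B"] + d1
  gf["D"] <- gf["C"] + d2
  se <- stats::setNames(rep(0, 4), mets)
  list(network = .mk_net(mets, defs), thermo = .mk_thermo(gf, se),
       truth = list(kind = "futile_cycle", fba_objective = 5,
                    tmfa_objective = 5, objective_reaction = "EX_B",
                    cycle_reactions = c("BC", "CD", "DB"),
                    cycle_upper_bound = 100,
                    unknown_metabolites = character(0)))
}

.fixture_unknown_metabolite <- function(seed) {
  cc <- 1L + seed %% 2L  # stoichiometric multiplier of the unknown intermediate
  mets <- c("A", "X", "B")
  defs <- list(
    list(id = "EX_A", stoich = c(A = -1), lb = -5, ub = 0),
    list(id = "R1", stoich = c(A = -1, X = cc), lb = 0, ub = 100),
    list(id = "R2", stoich = c(X = -1, B = 1), lb = 0, ub = 100),
    list(id = "EX_B", stoich = c(B = -1), lb = 0, ub = 100, obj = 1))
  gf <- c(A = -50, X = NA_real_, B = NA_real_)
  gf["B"] <- (gf["A"] - 12) / cc  # lump net  A -> cc B  clearly downhill
  se <- c(A = 0.3, X = 0, B = 0.4)
  list(network = .mk_net(mets, defs), thermo = .mk_thermo(gf, se, unknown = "X"),
       truth = list(kind = "unknown_metabolite", fba_objective = 5 * cc,
                    objective_reaction = "EX_B",
                    unknown_metabolites = "X",
                    expected_lump = list(members = c(R1 = 1, R2 = cc),
                                         net = stats::setNames(c(-1, cc),
                                                               c("A", "B"))),
                    cycle_reactions = character(0)))
}

.fixture_mini_core <- function() {
  # Acetate-fed core: uptake/activation, an anaplerotic entry, a TCA-like
  # loop with near-equilibrium MDH and FUM, first-committed biosynthetic
  # steps (ACLS, DHDPS, CYSTL, ...) placed far from equilibrium, and DXPS
  # placed so its feasible upper bound falls between the near-equilibrium
  # and far-from-equilibrium cutoffs.  Formation energies are chosen so
  # that the implied standard reaction energies hit those targets; the
  # lone non-tree energy (MDH) is tuned to +0.5 kcal/mol through co2.
  gf <- c(ac_e = -88)
  gf["ac"]    <- gf["ac_e"] - 12          # ACt   -12
  gf["coa"]   <- -10
  gf["co2"]   <- -87.4                    # tunes MDH to +0.5
  gf["accoa"] <- gf["ac"] + gf["coa"] - 18        # ACS   -18
  gf["oaa"]   <- gf["ac"] + gf["co2"] - 20        # ANA   -20
  gf["pyr"]   <- gf["ac"] + gf["co2"] - 20        # PYRS  -20
  gf["cit"]   <- gf["accoa"] + gf["oaa"] - gf["coa"] - 20   # CS -20
  gf["akg"]   <- gf["cit"] - gf["co2"] - 12       # ICD   -12
  gf["succ"]  <- gf["akg"] - gf["co2"] - 15       # AKGD  -15
  gf["fum"]   <- gf["succ"] - 10                  # SUCD  -10
  gf["mal"]   <- gf["fum"] - 0.3                  # FUM   -0.3
  gf["aclac"] <- 2 * gf["pyr"] - gf["co2"] - 18   # ACLS  -18
  gf["dhdp"]  <- gf["pyr"] + gf["oaa"] - 19       # DHDPS -19
  gf["cysta"] <- gf["mal"] - 12                   # CYSS  -12
  gf["hcys"]  <- gf["cysta"] - gf["pyr"] - 12     # CYSTL -12
  gf["dxp"]   <- gf["pyr"] - 7.5                  # DXPS  -7.5
  mets <- names(gf)
  comp <- ifelse(mets == "ac_e", "e", "c")
  defs <- list(
    list(id = "EX_ac", stoich = c(ac_e = -1), lb = -5, ub = 0),
    list(id = "EX_co2", stoich = c(co2 = -1), lb = -100, ub = 100),
    list(id = "EX_dxp", stoich = c(dxp = -1), lb = 0, ub = 100),
    list(id = "ACt", stoich = c(ac_e = -1, ac = 1), lb = 0, ub = 100,
         gpr = "g_act"),
    list(id = "ACS", stoich = c(ac = -1, coa = -1, accoa = 1), lb = 0,
         ub = 100, gpr = "g_acs"),
    list(id = "ANA", stoich = c(ac = -1, co2 = -1, oaa = 1), lb = 0,
         ub = 100, gpr = "g_ana"),
    list(id = "PYRS", stoich = c(ac = -1, co2 = -1, pyr = 1), lb = 0,
         ub = 100, gpr = "g_pyrs"),
    list(id = "CS", stoich = c(accoa = -1, oaa = -1, cit = 1, coa = 1),
         lb = 0, ub = 100, gpr = "g_cs"),
    list(id = "ICD", stoich = c(cit = -1, akg = 1, co2 = 1), lb = 0,
         ub = 100, gpr = "g_icd"),
    list(id = "AKGD", stoich = c(akg = -1, succ = 1, co2 = 1), lb = 0,
         ub = 100, gpr = "g_akgd1 and g_akgd2"),
    list(id = "SUCD", stoich = c(succ = -1, fum = 1), lb = 0, ub = 100,
         gpr = "g_sucd"),
    list(id = "FUM", stoich = c(fum = -1, mal = 1), lb = -100, ub = 100,
         gpr = "g_fuma or g_fumb"),
    list(id = "MDH", stoich = c(mal = -1, oaa = 1), lb = -100, ub = 100,
         gpr = "g_mdh"),
    list(id = "ACLS", stoich = c(pyr = -2, aclac = 1, co2 = 1), lb = 0,
         ub = 100, gpr = "g_acls1 or g_acls2"),
    list(id = "DHDPS", stoich = c(pyr = -1, oaa = -1, dhdp = 1), lb = 0,
         ub = 100, gpr = "g_dhdps"),
    list(id = "CYSS", stoich = c(mal = -1, cysta = 1), lb = 0, ub = 100,
         gpr = "g_cyss"),
    list(id = "CYSTL", stoich = c(cysta = -1, hcys = 1, pyr = 1), lb = 0,
         ub = 100, gpr = "g_cystl"),
    list(id = "DXPS", stoich = c(pyr = -1, dxp = 1), lb = 0, ub = 100,
         gpr = "g_dxps"),
    list(id = "BIOMASS",
         stoich = c(akg = -1, aclac = -0.5, dhdp = -0.5, hcys = -0.3),
         lb = 0, ub = 100, obj = 1))
  se <- stats::setNames(rep(0.25, length(mets)), mets)
  expected <- c(MDH = "bottleneck", FUM = "bottleneck",
                DXPS = "threshold_of_regulation",
                ACt = "regulatory_candidate", ACS = "regulatory_candidate",
                ANA = "regulatory_candidate", PYRS = "regulatory_candidate",
                CS = "regulatory_candidate", ICD = "regulatory_candidate",
                AKGD = "regulatory_candidate", SUCD = "regulatory_candidate",
                ACLS = "regulatory_candidate", DHDPS = "regulatory_candidate",
                CYSS = "regulatory_candidate", CYSTL = "regulatory_candidate")
  list(network = .mk_net(mets, defs, compartments = comp),
       thermo = .mk_thermo(gf, se),
       truth = list(kind = "mini_core", fba_objective = 1.25,
                    objective_reaction = "BIOMASS",
                    growth_reaction = "BIOMASS",
                    expected_classes = expected,
                    cycle_reactions = character(0),
                    unknown_metabolites = character(0)))
}

#' Write a network fixture to a directory
#'
#' Writes `metabolites.tsv`, `reactions.tsv` and `thermo.tsv` in the
#' package's tabular dialect.  Output is deterministic: the same fixture
#' writes byte-identical files.
#'
#' @param fixture Output of [make_network_fixture()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_network_fixture <- function(fixture, dir) {
  write_network(fixture$network, dir)
  write_thermo_table(fixture$thermo, file.path(dir, "thermo.tsv"))
  invisible(dir)
}

#' A seeded suite of small fixtures for enumeration cross-checks
#'
#' Rotates through the chain, branched and futile-cycle kinds with varying
#' sizes, giving fixtures whose constrained direction counts stay small
#' enough for exhaustive binary enumeration.
#'
#' @param n Number of fixtures.
#' @param seed Base seed; fixture k uses `seed + k`.
#' @return List of fixtures as returned by [make_network_fixture()].
#' @export
fixture_suite <- function(n = 25, seed = 1) {
  kinds <- rep(c("linear_chain", "branched", "futile_cycle"), length.out = n)
  sizes <- rep(c(5, 6, 6, 7, 6), length.out = n)
  lapply(seq_len(n), function(k)
    make_network_fixture(kinds[k], n_reactions = sizes[k], seed = seed + k))
}

#' Generate a synthetic expression dataset with planted classes
#'
#' Per-gene, per-experiment log2 fold changes are drawn from a zero-centred
#' normal whose standard deviation is the class dispersion — the planted
#' contrast is in range width, not direction, mirroring how regulated
#' genes show wider fold-change dispersion across perturbations than genes
#' of near-equilibrium reactions.  CV values are drawn so that a
#' `cv_noise` fraction of measurements fails the strict `cv < 0.2` filter.
#'
#' @param n_genes_per_class Genes per class (ignored for a class whose gene
#'   ids are supplied explicitly).
#' @param n_experiments Number of experiments (at least 2; default 21,
#'   matching a typical compendium of perturbation microarrays).
#' @param dispersion_regulated,dispersion_bottleneck Log2 standard
#'   deviations; regulated must exceed bottleneck.
#' @param cv_noise Fraction of measurements drawn with cv >= 0.2.
#' @param seed Mandatory integer seed.
#' @param genes_regulated,genes_bottleneck Optional explicit gene ids
#'   (e.g. from a network's GPR rules).
#' @return List `expr` (an `expression_dataset`) and `labels` (named
#'   character vector gene -> class).
#' @export
make_expression_fixture <- function(n_genes_per_class = 10, n_experiments = 21,
                                    dispersion_regulated = 3,
                                    dispersion_bottleneck = 1,
                                    cv_noise = 0.25, seed,
                                    genes_regulated = NULL,
                                    genes_bottleneck = NULL) {
  if (missing(seed)) stop("seed is a mandatory argument")
  if (n_experiments < 2) stop("n_experiments must be at least 2")
  stopifnot(dispersion_regulated >= dispersion_bottleneck,
            dispersion_bottleneck > 0)
  .with_seed(seed, {
    if (is.null(genes_regulated))
      genes_regulated <- sprintf("reg_g%02d", seq_len(n_genes_per_class))
    if (is.null(genes_bottleneck))
      genes_bottleneck <- sprintf("btl_g%02d", seq_len(n_genes_per_class))
    genes <- c(genes_regulated, genes_bottleneck)
    sds <- c(rep(dispersion_regulated, length(genes_regulated)),
             rep(dispersion_bottleneck, length(genes_bottleneck)))
    experiments <- sprintf("exp%02d", seq_len(n_experiments))
    rows <- list()
    for (e in experiments) {
      fail <- stats::runif(length(genes)) < cv_noise
      rows[[e]] <- data.frame(
        gene = genes, experiment = e,
        fold_change = stats::rnorm(length(genes), 0, sds),
        cv = ifelse(fail, stats::runif(length(genes), 0.2, 0.5),
                    stats::runif(length(genes), 0, 0.2)),
        stringsAsFactors = FALSE)
    }
    expr <- structure(list(experiments = experiments,
                           data = do.call(rbind, c(rows, make.row.names = FALSE))),
                      class = "expression_dataset")
    labels <- stats::setNames(
      c(rep("regulatory_candidate", length(genes_regulated)),
        rep("bottleneck", length(genes_bottleneck))), genes)
    list(expr = expr, labels = labels)
  })
}
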
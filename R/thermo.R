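# Per-reaction standard transformed free energies, activity-corrected
# Delta_r G', and lumping of reactions containing metabolites whose
# formation energy is unknown.

#' Thermodynamic configuration
#'
#' Physical constants and modelling knobs shared by every thermodynamic
#' computation.  Standard transformed energies are used throughout, so the
#' proton is excluded from both the standard term and the mixing term, and
#' water is excluded from the mixing term (activity 1).
#'
#' @param R Gas constant, kcal/(mol K).
#' @param T Temperature, K (so `R * T` is about 0.5922 kcal/mol).
#' @param ln_activity_min,ln_activity_max Bounds on the natural log of
#'   metabolite activities; the defaults correspond to a 1e-5 to 0.02 M
#'   concentration range.
#' @param n_se Multiplier on standard errors: each reaction's standard
#'   energy may vary within `n_se` standard errors of its estimate
#'   (default 2).
#' @param eps_thermo Margin (kcal/mol) used to implement the strict
#'   inequality "Delta_r G' < 0 for an active reaction" as a closed
#'   constraint `<= -eps_thermo`.
#' @param flux_eps Flux magnitude below which a reaction is treated as
#'   inactive (mmol/gdw/hr).
#' @return An object of class `thermo_config`.
#' @export
thermo_config <- function(R = 1.9859e-3, T = 298.15,
                          ln_activity_min = log(1e-5),
                          ln_activity_max = log(0.02),
                          n_se = 2, eps_thermo = 1e-6, flux_eps = 1e-6) {
  stopifnot(ln_activity_min < ln_activity_max, n_se >= 0, eps_thermo > 0)
  structure(list(R = R, T = T, RT = R * T,
                 ln_activity_min = ln_activity_min,
                 ln_activity_max = ln_activity_max,
                 n_se = n_se, eps_thermo = eps_thermo, flux_eps = flux_eps),
            class = "thermo_config")
}

# Metabolites excluded from the mixing term: water (activity 1) and protons
# (transformed energies are defined at fixed pH).
.mixing_excluded <- function(net) net$mets$is_water | net$mets$is_proton

#' Assemble per-reaction standard transformed free energies
#'
#' For every reaction whose non-water, non-proton participants all have
#' known formation energies, the standard transformed reaction energy is
#' the stoichiometry-weighted sum of formation energies and the standard
#' error is combined in quadrature (formation errors treated as
#' independent).  A reaction-level entry in the table overrides both.
#' Exchange reactions and reactions carrying objective weight (biomass) are
#' flagged as thermodynamically unconstrained.
#'
#' @param net A `metabolic_network`.
#' @param tab A `thermo_table`.
#' @return Data frame with one row per reaction: `reaction_id`, `drG0`
#'   (kcal/mol), `se` (kcal/mol), `known`, `constrained`.
#' @export
assemble_reaction_thermo <- function(net, tab) {
  f <- tab$formation
  gf <- stats::setNames(f$value, f$id)
  gse <- stats::setNames(f$se, f$id)
  unknown_ids <- f$id[f$unknown]
  override <- stats::setNames(tab$reaction$value, tab$reaction$id)
  override_se <- stats::setNames(tab$reaction$se, tab$reaction$id)
  excl_proton <- net$mets$is_proton
  n <- ncol(net$S)
  drG0 <- se <- rep(NA_real_, n)
  known <- logical(n)
  for (j in seq_len(n)) {
    id <- net$rxns$id[j]
    if (id %in% names(override)) {
      drG0[j] <- override[[id]]
      se[j] <- override_se[[id]]
      known[j] <- TRUE
      next
    }
    part <- which(net$S[, j] != 0 & !excl_proton)
    ids <- net$mets$id[part]
    relevant <- ids[!net$mets$is_water[part]]
    if (any(relevant %in% unknown_ids) || any(!relevant %in% f$id)) next
    have <- ids[ids %in% f$id & !ids %in% unknown_ids]
    coefs <- net$S[have, j]
    drG0[j] <- sum(coefs * gf[have])
    se[j] <- sqrt(sum((coefs * gse[have])^2))
    known[j] <- TRUE
  }
  data.frame(reaction_id = net$rxns$id, drG0 = drG0, se = se, known = known,
             constrained = known & !net$rxns$is_exchange &
               net$rxns$objective_coeff == 0,
             stringsAsFactors = FALSE)
}

#' Activity-corrected reaction free energy
#'
#' Evaluates `Delta_r G' = Delta_r G'0 + R T sum_i n_i ln x_i`, the
#' standard transformed reaction energy plus the concentration-dependent
#' mixing term, excluding water and protons from the sum.
#'
#' @param drG0 Standard transformed reaction energy, kcal/mol.
#' @param stoich Named numeric stoichiometry (metabolite id -> coefficient).
#' @param ln_activities Named numeric vector of log activities.
#' @param config A `thermo_config`.
#' @param exclude Character vector of metabolite ids excluded from the
#'   mixing term (water/proton ids).
#' @return Delta_r G' in kcal/mol.
#' @export
delta_g_prime <- function(drG0, stoich, ln_activities, config = thermo_config(),
                          exclude = character(0)) {
  stoich <- stoich[stoich != 0]
  use <- setdiff(names(stoich), exclude)
  missing <- setdiff(use, names(ln_activities))
  if (length(missing))
    .validation_error("missing ln-activity for metabolite: ", missing[1])
  drG0 + config$RT * sum(stoich[use] * ln_activities[use])
}

# ---------------------------------------------------------------------------
# lumped reactions

# Snap a numeric vector to small rationals (denominators <= max_den) and
# rescale to the smallest positive integer multipliers.
.snap_integer_multipliers <- function(w, max_den = 48) {
  w <- w / max(abs(w))
  fr <- MASS::fractions(w, cycles = 10, max.denominator = max_den)
  txt <- attr(fr, "fracs")
  num <- den <- integer(length(w))
  for (k in seq_along(txt)) {
    parts <- strsplit(txt[k], "/")[[1]]
    num[k] <- as.integer(parts[1])
    den[k] <- if (length(parts) == 2) as.integer(parts[2]) else 1L
  }
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  lcm_all <- Reduce(function(a, b) a * b / gcd2(a, b), den, accumulate = FALSE)
  ints <- num * (lcm_all / den)
  g <- Reduce(gcd2, abs(ints[ints != 0]))
  ints / g
}

#' Build lumped reactions eliminating unknown-energy metabolites
#'
#' Reactions whose standard energy is unknown (because a participant's
#' formation energy could not be estimated) cannot carry an individual
#' thermodynamic constraint.  This operation searches, within the set of
#' unknown-energy reactions, for positive combinations whose net
#' stoichiometry cancels every unknown metabolite, so that the combination
#' can be constrained instead.  Combinations are taken from the nullspace
#' of the unknown-metabolite submatrix, snapped to the smallest integer
#' multipliers, with members ordered (and signs normalised) by
#' lexicographic reaction id.  A member with a negative weight participates
#' through its reverse direction (`direction = -1`).
#'
#' @param net A `metabolic_network`.
#' @param thermo Output of [assemble_reaction_thermo()].
#' @param tab The `thermo_table` used to compute lump energies.
#' @return A list with `lumps` (list of lumped reactions: `id`, `members`
#'   data frame of `reaction_id`, `coeff`, `direction`, `net_stoich` named
#'   vector, `drG0`, `se`) and `unlumpable` (ids of unknown-energy
#'   reactions no combination could cancel; these carry no thermodynamic
#'   constraint).
#' @export
build_lumped_reactions <- function(net, thermo, tab) {
  unknown_mets <- tab$formation$id[tab$formation$unknown]
  unknown_rxns <- thermo$reaction_id[!thermo$known & !net$rxns$is_exchange]
  unknown_rxns <- sort(unknown_rxns)
  if (!length(unknown_rxns) || !length(unknown_mets))
    return(list(lumps = list(), unlumpable = unknown_rxns))
  U <- net$S[intersect(unknown_mets, rownames(net$S)), unknown_rxns,
             drop = FALSE]
  ns <- pracma::nullspace(U)
  if (is.null(ns) || ncol(as.matrix(ns)) == 0)
    return(list(lumps = list(), unlumpable = unknown_rxns))
  ns <- as.matrix(ns)
  lumps <- list()
  seen <- character(0)
  for (k in seq_len(ncol(ns))) {
    w <- .snap_integer_multipliers(ns[, k])
    if (max(abs(U %*% w)) > 1e-9) next  # snapping failed; not a valid lump
    supp <- which(w != 0)
    if (!length(supp)) next
    # sign convention: first member (lexicographic order) participates forward
    if (w[supp[1]] < 0) w <- -w
    key <- paste(unknown_rxns[supp], w[supp], collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    members <- data.frame(reaction_id = unknown_rxns[supp],
                          coeff = abs(w[supp]),
                          direction = sign(w[supp]),
                          stringsAsFactors = FALSE)
    net_stoich <- drop(net$S[, unknown_rxns[supp], drop = FALSE] %*% w[supp])
    net_stoich[abs(net_stoich) < 1e-9] <- 0
    # lump energy from the net stoichiometry's (all known) formation energies
    gf <- stats::setNames(tab$formation$value, tab$formation$id)
    gse <- stats::setNames(tab$formation$se, tab$formation$id)
    act <- names(net_stoich)[net_stoich != 0 &
                               !net$mets$is_proton[match(names(net_stoich),
                                                         net$mets$id)]]
    if (any(!act %in% names(gf)) || anyNA(gf[act])) next
    drG0 <- sum(net_stoich[act] * gf[act])
    se <- sqrt(sum((net_stoich[act] * gse[act])^2))
    lumps[[length(lumps) + 1L]] <-
      list(id = paste0("LUMP", length(lumps) + 1L), members = members,
           net_stoich = net_stoich[net_stoich != 0], drG0 = drG0, se = se)
  }
  covered <- unique(unlist(lapply(lumps, function(l) l$members$reaction_id)))
  list(lumps = lumps, unlumpable = setdiff(unknown_rxns, covered))
}

#' Write a lump report as TSV
#' @param lumping Output of [build_lumped_reactions()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lump_report <- function(lumping, path) {
  rows <- lapply(lumping$lumps, function(l) {
    data.frame(lump_id = l$id,
               members = paste(sprintf("%g*%s%s", l$members$coeff,
                                       ifelse(l$members$direction < 0, "-", ""),
                                       l$members$reaction_id), collapse = "; "),
               net_formula = format_formula(l$net_stoich),
               drG0 = l$drG0, se = l$se, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lump_id = character(0), members = character(0),
               net_formula = character(0), drG0 = numeric(0), se = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(lumping$unlumpable))
    cat(paste0("# unlumpable: ", paste(lumping$unlumpable, collapse = ", "), "\n"),
        file = path, append = TRUE)
  invisible(path)
}
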
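# Thermodynamic variability analysis: per-reaction min/max of Delta_r G'
# over the TMFA-feasible set at fixed growth, and classification of
# reactions into thermodynamic bottlenecks, regulatory candidates, and
# reactions on the threshold of regulation.

#' Run thermodynamic variability analysis
#'
#' With growth fixed (as an equality) at `growth_value`, minimizes and
#' maximizes every thermodynamically constrained reaction's Delta_r G'
#' expression subject to mass balance and the mixed-integer thermodynamic
#' constraints — two MILP solves per reaction.  With
#' `with_uncertainty = FALSE` (the default) the standard-error slack
#' variables are pinned to zero, so the ranges reflect only the freedom in
#' metabolite activities.
#'
#' @param problem A `tmfa_problem` built with thermodynamic constraints.
#' @param growth_reaction Reaction id whose flux is fixed (1/hr for a
#'   biomass reaction).
#' @param growth_value Value at which it is fixed.
#' @param with_uncertainty Logical; allow the drG0 estimates to move within
#'   their `n_se` standard-error band.
#' @param reactions Reaction ids to scan (default: every constrained
#'   reaction, in network order).
#' @return Data frame `reaction_id`, `drG_min`, `drG_max` (kcal/mol),
#'   `with_uncertainty`, `growth_fixed_at`.
#' @export
run_tva <- function(problem, growth_reaction, growth_value,
                    with_uncertainty = FALSE, reactions = NULL) {
  if (!length(problem$vars$dg))
    stop("problem has no thermodynamic constraints; build it with thermo")
  if (!growth_reaction %in% problem$net$rxns$id)
    .validation_error("unknown growth reaction: ", growth_reaction)
  if (is.null(reactions))
    reactions <- intersect(problem$net$rxns$id, names(problem$vars$dg))
  growth_con <- list(
    coefs = stats::setNames(c(1, -1), c(problem$vars$vf[[growth_reaction]],
                                        problem$vars$vr[[growth_reaction]])),
    sense = "=", rhs = growth_value, name = "tva.growth")
  bounds <- list()
  if (!with_uncertainty)
    for (sl in problem$vars$slack) bounds[[sl]] <- c(0, 0)
  .with_modified(problem, cons = list(growth_con), bounds = bounds,
                 fn = function() {
    feas <- milp_solve(problem$milp, objective = NULL, maximize = TRUE)
    # feasibility pre-check with the stored (possibly zero) objective
    if (feas$status != "optimal")
      .tf_stop("thermoflux_infeasible",
               "TMFA problem infeasible at growth ", growth_value,
               "; run a feasibility check (solve_tmfa) before TVA")
    out <- data.frame(reaction_id = reactions, drG_min = NA_real_,
                      drG_max = NA_real_, with_uncertainty = with_uncertainty,
                      growth_fixed_at = growth_value, stringsAsFactors = FALSE)
    for (k in seq_along(reactions)) {
      dg <- problem$vars$dg[[reactions[k]]]
      lo <- milp_solve(problem$milp, objective = stats::setNames(1, dg),
                       maximize = FALSE)
      hi <- milp_solve(problem$milp, objective = stats::setNames(1, dg),
                       maximize = TRUE)
      if (lo$status != "optimal" || hi$status != "optimal")
        .tf_stop("thermoflux_infeasible", "TVA solve failed for ", reactions[k])
      out$drG_min[k] <- lo$objective
      out$drG_max[k] <- hi$objective
    }
    out
  })
}

#' Classify reactions from their TVA free-energy ranges
#'
#' A reaction whose feasible `[drG_min, drG_max]` interval reaches the
#' near-equilibrium neighbourhood `[-eps_eq, +eps_eq]` from below (or spans
#' it) is a thermodynamic bottleneck: it operates close to equilibrium and
#' small activity changes can stall or reverse it.  A reaction whose upper
#' bound stays below `-eps_far` can never approach equilibrium under the
#' activity ranges studied and is a candidate for regulatory control.
#' Between the two (`-eps_far <= drG_max < -eps_eq`) the reaction is on the
#' threshold of regulation.  Anything else (a strictly positive range far
#' from equilibrium) is left unclassified.  The partition is exhaustive and
#' exclusive.
#'
#' @param tva Data frame from [run_tva()].
#' @param eps_eq Near-equilibrium half-width, kcal/mol (default 2).
#' @param eps_far Far-from-equilibrium cutoff, kcal/mol (default 5).
#' @return Data frame `reaction_id`, `label`, plus the input ranges and the
#'   thresholds used (echoed so every report is self-describing).
#' @export
classify_reactions <- function(tva, eps_eq = 2, eps_far = 5) {
  stopifnot(eps_eq > 0, eps_far > eps_eq)
  label <- ifelse(tva$drG_max < -eps_far, "regulatory_candidate",
           ifelse(tva$drG_max < -eps_eq, "threshold_of_regulation",
           ifelse(tva$drG_min <= eps_eq, "bottleneck", "unclassified")))
  data.frame(reaction_id = tva$reaction_id, label = label,
             drG_min = tva$drG_min, drG_max = tva$drG_max,
             eps_eq = eps_eq, eps_far = eps_far, stringsAsFactors = FALSE)
}

#' Compare two classifications label by label
#'
#' Per-label intersection/union counts and shared reaction ids for two
#' classified reaction sets (for instance, the same network under two
#' threshold choices, or two organisms sharing reaction identifiers).
#'
#' @param classes_a,classes_b Data frames from [classify_reactions()].
#' @return List with `summary` (data frame `label`, `n_a`, `n_b`,
#'   `n_intersection`, `n_union`) and `shared` (named list of shared ids
#'   per label).
#' @export
compare_class_overlap <- function(classes_a, classes_b) {
  labels <- sort(unique(c(classes_a$label, classes_b$label)))
  shared <- list()
  summary <- data.frame(label = labels, n_a = NA_integer_, n_b = NA_integer_,
                        n_intersection = NA_integer_, n_union = NA_integer_,
                        stringsAsFactors = FALSE)
  for (k in seq_along(labels)) {
    a <- classes_a$reaction_id[classes_a$label == labels[k]]
    b <- classes_b$reaction_id[classes_b$label == labels[k]]
    shared[[labels[k]]] <- intersect(a, b)
    summary$n_a[k] <- length(a)
    summary$n_b[k] <- length(b)
    summary$n_intersection[k] <- length(intersect(a, b))
    summary$n_union[k] <- length(union(a, b))
  }
  list(summary = summary, shared = shared)
}
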
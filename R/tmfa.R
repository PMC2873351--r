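# FBA and TMFA: construction and solution of the flux-balance LP and the
# mixed-integer thermodynamic program, plus flux variability analysis under
# either constraint set.
#
# Every reaction is split into non-negative forward and reverse components
# (v = vf - vr).  A directed component with known thermodynamics gets a
# binary Z; flux is permitted only when Z = 1, and Z = 1 forces the
# directed Delta_r G' below zero through a per-reaction big-M constant.
# Lumped reactions get an inactivity binary y with the complementary pair
# of constraints: y = 0 forces the lump's Delta_r G' below zero, and y
# must drop to 0 whenever all member directions are simultaneously active.

#' Build a TMFA (or plain FBA) problem
#'
#' Constructs the mixed-integer program coupling mass balance,
#' directionality binaries and transformed reaction energies.  With
#' `thermo = NULL` no thermodynamic constraints are added and the feasible
#' set is exactly the FBA polytope.
#'
#' For every directed reaction j with known, constrained thermodynamics the
#' problem contains: (i) `v_j <= Z_j vmax_j`; (ii)
#' `dG_j + (K_j + eps) Z_j <= K_j` (so `Z_j = 1` forces `dG_j <= -eps`);
#' (iii) the defining equality `dG_j = drG0_j + slack_j + RT sum n_ij ln x_i`
#' with `slack_j` bounded by `n_se` standard errors.  For every lump i:
#' (iv) `dG_lump_i - (K_i + eps) y_i <= -eps` and (v)
#' `y_i + sum_j alpha_ij Z_j <= N_i` with `N_i` the member count.
#' Exchange reactions and reactions with objective weight (biomass) carry
#' no thermodynamic constraint; unknown-energy reactions not covered by any
#' lump are left unconstrained and recorded.
#'
#' @param net A `metabolic_network`.
#' @param thermo Output of [assemble_reaction_thermo()], or `NULL` for FBA.
#' @param lumps Output of [build_lumped_reactions()], or `NULL`.
#' @param config A `thermo_config`.
#' @return An object of class `tmfa_problem`.
#' @export
build_tmfa <- function(net, thermo = NULL, lumps = NULL,
                       config = thermo_config()) {
  p <- milp_new()
  rids <- net$rxns$id
  vf <- stats::setNames(paste0("vf.", rids), rids)
  vr <- stats::setNames(paste0("vr.", rids), rids)
  for (j in seq_along(rids)) {
    lb <- net$rxns$lower_bound[j]; ub <- net$rxns$upper_bound[j]
    milp_add_var(p, vf[[j]], lb = max(lb, 0), ub = max(ub, 0))
    milp_add_var(p, vr[[j]], lb = max(-ub, 0), ub = max(-lb, 0))
  }
  for (i in seq_len(nrow(net$S))) {
    nz <- which(net$S[i, ] != 0)
    if (!length(nz)) next
    coefs <- c(stats::setNames(net$S[i, nz], vf[nz]),
               stats::setNames(-net$S[i, nz], vr[nz]))
    milp_add_con(p, coefs, "=", 0, name = paste0("mb.", net$mets$id[i]))
  }

  vars <- list(vf = vf, vr = vr, dg = character(0), lnx = character(0),
               z = data.frame(reaction_id = character(0), direction = integer(0),
                              var = character(0), stringsAsFactors = FALSE),
               slack = character(0), y = character(0), dgl = character(0))
  unconstrained <- character(0)

  if (!is.null(thermo)) {
    excl <- net$mets$id[.mixing_excluded(net)]
    known_con <- thermo$reaction_id[thermo$constrained]
    lump_list <- if (is.null(lumps)) list() else lumps$lumps
    lump_members <- unique(unlist(lapply(lump_list, function(l)
      l$members$reaction_id)))
    unconstrained <- if (is.null(lumps)) character(0) else lumps$unlumpable

    # metabolites needing a log-activity variable
    need_lnx <- character(0)
    for (id in known_con)
      need_lnx <- union(need_lnx,
                        setdiff(names(which(net$S[, id] != 0)), excl))
    for (l in lump_list)
      need_lnx <- union(need_lnx, setdiff(names(l$net_stoich), excl))
    lnx <- stats::setNames(paste0("lnx.", need_lnx), need_lnx)
    for (m in need_lnx)
      milp_add_var(p, lnx[[m]], lb = config$ln_activity_min,
                   ub = config$ln_activity_max)
    vars$lnx <- lnx

    span <- max(abs(config$ln_activity_min), abs(config$ln_activity_max))
    add_z <- function(rid, dir) {
      zname <- paste0(if (dir > 0) "zf." else "zr.", rid)
      milp_add_var(p, zname, type = "B")
      vflux <- if (dir > 0) vf[[rid]] else vr[[rid]]
      vmax <- if (dir > 0) max(net$rxns$upper_bound[match(rid, rids)], 0) else
        max(-net$rxns$lower_bound[match(rid, rids)], 0)
      milp_add_con(p, stats::setNames(c(1, -vmax), c(vflux, zname)), "<=", 0,
                   name = paste0("link.", zname))
      vars$z <<- rbind(vars$z, data.frame(reaction_id = rid, direction = dir,
                                          var = zname, stringsAsFactors = FALSE))
      zname
    }

    for (id in known_con) {
      j <- match(id, rids)
      row <- thermo[match(id, thermo$reaction_id), ]
      stoich <- net$S[, j]
      mix <- stoich[stoich != 0 & !names(stoich) %in% excl]
      dgname <- paste0("dg.", id)
      slname <- paste0("sl.", id)
      milp_add_var(p, dgname, lb = -Inf, ub = Inf)
      milp_add_var(p, slname, lb = -config$n_se * row$se,
                   ub = config$n_se * row$se)
      vars$dg <- c(vars$dg, stats::setNames(dgname, id))
      vars$slack <- c(vars$slack, stats::setNames(slname, id))
      milp_add_con(p, c(stats::setNames(1, dgname), stats::setNames(-1, slname),
                        stats::setNames(-config$RT * unname(mix),
                                        lnx[names(mix)])),
                   "=", row$drG0, name = paste0("def.", id))
      K <- abs(row$drG0) + config$n_se * row$se +
        config$RT * sum(abs(mix)) * span + 1
      if (max(net$rxns$upper_bound[j], 0) > 0) {
        z <- add_z(id, 1L)
        milp_add_con(p, stats::setNames(c(1, K + config$eps_thermo),
                                        c(dgname, z)), "<=", K,
                     name = paste0("thermo.f.", id))
      }
      if (net$rxns$lower_bound[j] < 0) {
        z <- add_z(id, -1L)
        milp_add_con(p, stats::setNames(c(-1, K + config$eps_thermo),
                                        c(dgname, z)), "<=", K,
                     name = paste0("thermo.r.", id))
      }
    }

    # member-direction binaries for lump members (flux gated, no own dG)
    member_z <- list()
    for (l in lump_list) {
      for (k in seq_len(nrow(l$members))) {
        rid <- l$members$reaction_id[k]
        dir <- l$members$direction[k]
        key <- paste0(rid, ".", dir)
        if (is.null(member_z[[key]])) {
          existing <- vars$z$var[vars$z$reaction_id == rid &
                                   vars$z$direction == dir]
          member_z[[key]] <- if (length(existing)) existing[1] else add_z(rid, dir)
        }
      }
    }

    for (l in lump_list) {
      mix <- l$net_stoich[!names(l$net_stoich) %in% excl]
      dgname <- paste0("dg.", l$id)
      slname <- paste0("sl.", l$id)
      yname <- paste0("y.", l$id)
      milp_add_var(p, dgname, lb = -Inf, ub = Inf)
      milp_add_var(p, slname, lb = -config$n_se * l$se, ub = config$n_se * l$se)
      milp_add_var(p, yname, type = "B")
      vars$dgl <- c(vars$dgl, stats::setNames(dgname, l$id))
      vars$slack <- c(vars$slack, stats::setNames(slname, l$id))
      vars$y <- c(vars$y, stats::setNames(yname, l$id))
      milp_add_con(p, c(stats::setNames(1, dgname), stats::setNames(-1, slname),
                        stats::setNames(-config$RT * unname(mix),
                                        lnx[names(mix)])),
                   "=", l$drG0, name = paste0("def.", l$id))
      K <- abs(l$drG0) + config$n_se * l$se +
        config$RT * sum(abs(mix)) * span + 1
      milp_add_con(p, stats::setNames(c(1, -(K + config$eps_thermo)),
                                      c(dgname, yname)),
                   "<=", -config$eps_thermo, name = paste0("thermo.", l$id))
      zs <- vapply(seq_len(nrow(l$members)), function(k)
        member_z[[paste0(l$members$reaction_id[k], ".", l$members$direction[k])]],
        character(1))
      milp_add_con(p, c(stats::setNames(1, yname),
                        stats::setNames(rep(1, length(zs)), zs)),
                   "<=", nrow(l$members), name = paste0("count.", l$id))
    }
    # unknown, non-exchange reactions not covered by any lump
    unknown_rxns <- thermo$reaction_id[!thermo$known & !net$rxns$is_exchange &
                                         net$rxns$objective_coeff == 0]
    unconstrained <- union(unconstrained, setdiff(unknown_rxns, lump_members))
  }

  structure(list(milp = p, net = net, thermo = thermo,
                 lumps = if (is.null(lumps)) list() else lumps$lumps,
                 config = config, vars = vars,
                 unconstrained = unconstrained),
            class = "tmfa_problem")
}

#' @export
print.tmfa_problem <- function(x, ...) {
  cat(sprintf("tmfa_problem: %d variables, %d constraints, %d binaries\n",
              length(x$milp$var_names), length(x$milp$cons),
              sum(x$milp$vtype == "B")))
  if (length(x$unconstrained))
    cat("  thermodynamically unconstrained:",
        paste(x$unconstrained, collapse = ", "), "\n")
  invisible(x)
}

# Translate a reaction-id (or named coefficient map) objective into
# coefficients on the split flux variables.
.objective_coefs <- function(problem, objective) {
  net <- problem$net
  if (is.null(objective)) {
    w <- stats::setNames(net$rxns$objective_coeff, net$rxns$id)
    objective <- w[w != 0]
    if (!length(objective)) stop("network has no objective reaction")
  }
  if (is.character(objective))
    objective <- stats::setNames(rep(1, length(objective)), objective)
  bad <- setdiff(names(objective), net$rxns$id)
  if (length(bad)) .validation_error("objective references unknown reaction: ",
                                     bad[1])
  c(stats::setNames(unname(objective), problem$vars$vf[names(objective)]),
    stats::setNames(-unname(objective), problem$vars$vr[names(objective)]))
}

# Extract a flux_solution from raw solver output.
.extract_solution <- function(problem, res) {
  net <- problem$net
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective = res$objective,
                          fluxes = NULL, ln_activities = NULL, drG = NULL,
                          binaries = NULL), class = "flux_solution"))
  }
  v <- res$values
  fluxes <- stats::setNames(
    v[problem$vars$vf] - v[problem$vars$vr], net$rxns$id)
  drG <- stats::setNames(rep(NA_real_, nrow(net$rxns)), net$rxns$id)
  if (length(problem$vars$dg))
    drG[names(problem$vars$dg)] <- v[problem$vars$dg]
  lnx <- if (length(problem$vars$lnx))
    stats::setNames(v[problem$vars$lnx], names(problem$vars$lnx)) else
      numeric(0)
  binaries <- problem$vars$z
  if (nrow(binaries)) binaries$value <- round(v[binaries$var])
  structure(list(status = "optimal", objective = res$objective,
                 fluxes = fluxes, ln_activities = lnx, drG = drG,
                 binaries = binaries), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: status=%s, objective=%s\n", x$status,
              format(x$objective)))
  invisible(x)
}

#' Solve a TMFA problem
#'
#' @param problem A `tmfa_problem`.
#' @param objective Reaction id (or character vector of ids, or named
#'   coefficient map); `NULL` uses the network's objective coefficients.
#' @param maximize Logical.
#' @return A `flux_solution`: `status`, `objective`, `fluxes`,
#'   `ln_activities`, `drG` (per reaction, NA where unconstrained),
#'   `binaries`.
#' @export
solve_tmfa <- function(problem, objective = NULL, maximize = TRUE) {
  res <- milp_solve(problem$milp, objective = .objective_coefs(problem, objective),
                    maximize = maximize)
  .extract_solution(problem, res)
}

#' Solve a flux balance analysis problem
#'
#' Maximizes the objective subject to mass balance `S v = 0` and flux
#' bounds only.
#'
#' @param net A `metabolic_network`.
#' @param objective As in [solve_tmfa()].
#' @return A `flux_solution`.
#' @export
solve_fba <- function(net, objective = NULL) {
  solve_tmfa(build_tmfa(net, thermo = NULL), objective = objective)
}

# Run fn() with extra constraints/bounds pushed onto the problem, then
# restore it.  Bounds are given as list(name = c(lb, ub)).
.with_modified <- function(problem, fn, cons = list(), bounds = list()) {
  p <- problem$milp
  saved_cons <- p$cons
  saved_lb <- p$lb
  saved_ub <- p$ub
  on.exit({ p$cons <- saved_cons; p$lb <- saved_lb; p$ub <- saved_ub })
  for (con in cons) milp_add_con(p, con$coefs, con$sense, con$rhs, con$name)
  for (nm in names(bounds)) milp_set_bounds(p, nm, bounds[[nm]][1], bounds[[nm]][2])
  fn()
}

#' Flux variability analysis
#'
#' Minimizes and maximizes each reaction's net flux with the objective
#' constrained to a fraction of its optimum (or to a fixed value).  Works
#' on both FBA problems (`thermo = NULL`) and full TMFA problems, so the
#' two feasible sets can be compared reaction by reaction.
#'
#' @param problem A `tmfa_problem`.
#' @param fix_objective_at Fraction of the optimal objective (default 1.0)
#'   or, with `how = "value"`, an absolute objective value.
#' @param how `"fraction"` or `"value"`.
#' @param reactions Reaction ids to scan (default: all).
#' @param objective As in [solve_tmfa()].
#' @return Data frame `reaction_id`, `v_min`, `v_max`.
#' @export
flux_variability <- function(problem, fix_objective_at = 1.0,
                             how = c("fraction", "value"),
                             reactions = NULL, objective = NULL) {
  how <- match.arg(how)
  obj <- .objective_coefs(problem, objective)
  target <- if (how == "value") fix_objective_at else {
    base <- milp_solve(problem$milp, objective = obj, maximize = TRUE)
    if (base$status != "optimal")
      .tf_stop("thermoflux_infeasible", "base problem not optimal: ", base$status)
    fix_objective_at * base$objective
  }
  if (is.null(reactions)) reactions <- problem$net$rxns$id
  con <- list(coefs = obj, sense = ">=", rhs = target, name = "fva.obj")
  .with_modified(problem, cons = list(con), fn = function() {
    out <- data.frame(reaction_id = reactions, v_min = NA_real_,
                      v_max = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_along(reactions)) {
      rid <- reactions[k]
      rc <- stats::setNames(c(1, -1),
                            c(problem$vars$vf[[rid]], problem$vars$vr[[rid]]))
      lo <- milp_solve(problem$milp, objective = rc, maximize = FALSE)
      hi <- milp_solve(problem$milp, objective = rc, maximize = TRUE)
      if (lo$status != "optimal" || hi$status != "optimal")
        .tf_stop("thermoflux_infeasible",
                 "flux variability infeasible for reaction ", rid)
      out$v_min[k] <- lo$objective
      out$v_max[k] <- hi$objective
    }
    out
  })
}

#' Audit the second law on an optimal solution
#'
#' Flags directed reactions carrying flux above tolerance whose
#' Delta_r G' in that direction is not below zero: such pairs must never
#' occur in a feasible TMFA solution.
#'
#' @param solution An optimal `flux_solution`.
#' @param config The `thermo_config` used to build the problem.
#' @return Data frame of violations (zero rows when the audit passes).
#' @export
audit_second_law <- function(solution, config = thermo_config()) {
  stopifnot(solution$status == "optimal")
  out <- data.frame(reaction_id = character(0), flux = numeric(0),
                    drG = numeric(0))
  ids <- names(solution$drG)[!is.na(solution$drG)]
  for (id in ids) {
    v <- solution$fluxes[[id]]
    g <- solution$drG[[id]]
    directed_g <- if (v >= 0) g else -g
    if (abs(v) > config$flux_eps && directed_g > -config$flux_eps)
      out <- rbind(out, data.frame(reaction_id = id, flux = v, drG = g))
  }
  out
}
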
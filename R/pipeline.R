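# End-to-end pipeline: load -> assemble thermodynamics -> lump -> TMFA ->
# TVA -> classify -> expression validation, with every report written as
# TSV plus a JSON manifest that serialises the full configuration
# (including every defaulted threshold), so a run directory is a complete
# reproducibility record.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every knob at its default;
#' user values are merged over it.  All thresholds the analysis depends on
#' (activity bounds, `n_se`, `eps_eq`, `eps_far`, `cv_max`) appear
#' explicitly so the manifest never hides a default.
#'
#' @param ... Named overrides.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  config <- list(
    model_dir = NULL,            # directory with metabolites.tsv/reactions.tsv
    thermo_path = NULL,          # thermo.tsv
    expression_paths = NULL,     # character vector of expression TSVs
    exchange_table_path = NULL,  # optional reaction_id/coefficient TSV
    out_dir = NULL,
    objective = NULL,            # default: network objective coefficients
    growth_reaction = NULL,      # default: the objective reaction
    growth_value = NULL,         # default: growth_frac * FBA optimum
    growth_frac = 1.0,
    with_uncertainty = FALSE,
    eps_eq = 2, eps_far = 5,
    cv_max = 0.2,
    R = 1.9859e-3, T = 298.15,
    ln_activity_min = log(1e-5), ln_activity_max = log(0.02),
    n_se = 2, eps_thermo = 1e-6,
    seed = 1)
  user <- list(...)
  bad <- setdiff(names(user), names(config))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  config[names(user)] <- user
  config
}

.pipeline_log <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .tf_stop(class(e)[1], "stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full thermodynamic analysis pipeline
#'
#' Executes load, thermodynamic assembly, lumping, FBA, TMFA, TVA at fixed
#' growth, classification, and (when expression data is configured)
#' expression-range validation, writing `tva.tsv`, `classes.tsv`,
#' `lumps.tsv`, `ranges.tsv`, `comparison.tsv`, `manifest.json` and
#' `run.log` into the output directory.  Re-running with an identical
#' configuration and seed reproduces identical reports.  If no expression
#' paths are configured the pipeline stops cleanly after classification
#' with the earlier reports intact.
#'
#' @param config List from [pipeline_config()] (or any list with the same
#'   names).
#' @return Invisibly, a list with the in-memory stage results
#'   (`network`, `thermo`, `lumping`, `fba`, `tmfa`, `tva`, `classes`,
#'   `ranges`, `comparison`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  config <- do.call(pipeline_config, config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  assert_solver()

  tc <- thermo_config(R = config$R, T = config$T,
                      ln_activity_min = config$ln_activity_min,
                      ln_activity_max = config$ln_activity_max,
                      n_se = config$n_se, eps_thermo = config$eps_thermo)
  .pipeline_log(log_path, "config: ",
                "ln activity bounds [", sprintf("%.4f", tc$ln_activity_min),
                ", ", sprintf("%.4f", tc$ln_activity_max), "], n_se=", tc$n_se,
                ", eps_eq=", config$eps_eq, ", eps_far=", config$eps_far,
                ", cv_max=", config$cv_max,
                " (defaults unless overridden; all echoed in manifest.json)")

  net <- .stage("load", read_network(config$model_dir, format = "tsv"))
  .pipeline_log(log_path, "load: ", nrow(net$mets), " metabolites, ",
                nrow(net$rxns), " reactions")
  tab <- .stage("load", read_thermo_table(config$thermo_path, network = net))

  thermo <- .stage("thermo", assemble_reaction_thermo(net, tab))
  .pipeline_log(log_path, "thermo: ", sum(thermo$known), " known, ",
                sum(!thermo$known), " unknown reaction energies")
  lumping <- .stage("thermo", build_lumped_reactions(net, thermo, tab))
  write_lump_report(lumping, file.path(config$out_dir, "lumps.tsv"))
  if (length(lumping$unlumpable))
    .pipeline_log(log_path, "thermo: unlumpable (left unconstrained): ",
                  paste(lumping$unlumpable, collapse = ", "))

  problem <- .stage("tmfa", build_tmfa(net, thermo, lumping, tc))
  fba <- .stage("fba", solve_fba(net, objective = config$objective))
  if (fba$status != "optimal")
    .tf_stop("thermoflux_infeasible", "stage 'fba' failed: status ", fba$status)
  .pipeline_log(log_path, "fba: objective ", format(fba$objective))
  tmfa <- .stage("tmfa", solve_tmfa(problem, objective = config$objective))
  if (tmfa$status != "optimal")
    .tf_stop("thermoflux_infeasible", "stage 'tmfa' failed: status ",
             tmfa$status)
  .pipeline_log(log_path, "tmfa: objective ", format(tmfa$objective))

  growth_rxn <- config$growth_reaction %||%
    net$rxns$id[net$rxns$objective_coeff != 0][1]
  growth_value <- config$growth_value %||% (config$growth_frac * tmfa$objective)
  tva <- .stage("tva", run_tva(problem, growth_rxn, growth_value,
                               with_uncertainty = config$with_uncertainty))
  utils::write.table(tva, file.path(config$out_dir, "tva.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .pipeline_log(log_path, "tva: ", nrow(tva), " reactions at growth ",
                format(growth_value),
                if (config$with_uncertainty) " (with uncertainty)" else
                  " (no uncertainty)")

  classes <- .stage("classify",
                    classify_reactions(tva, eps_eq = config$eps_eq,
                                       eps_far = config$eps_far))
  if (!is.null(config$exchange_table_path)) {
    xt <- utils::read.delim(config$exchange_table_path,
                            stringsAsFactors = FALSE)
    classes <- annotate_with_exchange_coefficients(classes, xt)
  }
  utils::write.table(classes, file.path(config$out_dir, "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .pipeline_log(log_path, "classify: ",
                paste(names(table(classes$label)), table(classes$label),
                      sep = "=", collapse = ", "))

  ranges <- comparison <- NULL
  if (is.null(config$expression_paths) || !length(config$expression_paths)) {
    .pipeline_log(log_path,
                  "expression: no expression paths configured; stopping ",
                  "after classification (earlier reports are complete)")
  } else {
    expr <- .stage("expression", read_expression(config$expression_paths))
    ranges <- .stage("expression",
                     fold_change_ranges(expr, classes, net,
                                        cv_max = config$cv_max))
    utils::write.table(ranges, file.path(config$out_dir, "ranges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comparison <- .stage("expression", compare_class_widths(ranges))
    utils::write.table(comparison, file.path(config$out_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .pipeline_log(log_path, "expression: rank-sum p=",
                  format(comparison$p_value[1]), ", Welch p=",
                  format(comparison$p_value[2]))
  }

  manifest <- config
  manifest$growth_reaction <- growth_rxn
  manifest$growth_value <- growth_value
  manifest$fba_objective <- fba$objective
  manifest$tmfa_objective <- tmfa$objective
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(network = net, thermo = thermo, lumping = lumping,
                 problem = problem, fba = fba, tmfa = tmfa, tva = tva,
                 classes = classes, ranges = ranges, comparison = comparison,
                 out_dir = config$out_dir))
}
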
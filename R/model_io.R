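# Readers, writers and validators for metabolic networks, thermodynamic
# tables, expression tables and gene-reaction (GPR) rules.
#
# Tabular dialect (tab-separated, documented in the README):
#   metabolites.tsv: id  name  compartment  is_water  is_proton
#   reactions.tsv:   id  name  formula  lower_bound  upper_bound
#                    objective_coeff  gpr
#   thermo.tsv:      type  id  value  se       (type in {metabolite, reaction};
#                    value is kcal/mol or the literal UNKNOWN)
# Reaction formulas are signed-coefficient term lists such as
# "-1 ac_c + 1 actp_c"; metabolite ids carry their compartment suffix.

.tf_stop <- function(class, ...) {
  stop(structure(class = c(class, "thermoflux_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.parse_error <- function(...) .tf_stop("thermoflux_parse_error", ...)
.validation_error <- function(...) .tf_stop("thermoflux_validation_error", ...)

# ---------------------------------------------------------------------------
# network container

#' Construct a metabolic network
#'
#' The central container of the package: a stoichiometric matrix `S`
#' (metabolites x reactions) together with per-reaction flux bounds
#' (mmol/gdw/hr), objective coefficients, GPR rules, and per-metabolite
#' annotation.  Exchange reactions are recognised as reactions touching
#' exactly one metabolite; transport reactions as reactions spanning more
#' than one compartment.
#'
#' @param mets Data frame with columns `id`, `name`, `compartment`,
#'   `is_water`, `is_proton` (missing annotation columns are defaulted).
#' @param rxns Data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `objective_coeff`, `gpr`.
#' @param S Numeric matrix, `nrow(mets)` x `nrow(rxns)`, with dimnames set
#'   to the metabolite and reaction ids.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(mets, rxns, S) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$is_water)) mets$is_water <- FALSE
  if (is.null(mets$is_proton)) mets$is_proton <- FALSE
  if (is.null(rxns$name)) rxns$name <- rxns$id
  if (is.null(rxns$objective_coeff)) rxns$objective_coeff <- 0
  if (is.null(rxns$gpr)) rxns$gpr <- ""
  rxns$gpr[is.na(rxns$gpr)] <- ""
  S <- as.matrix(S)
  dimnames(S) <- list(mets$id, rxns$id)
  n_active <- colSums(S != 0)
  rxns$is_exchange <- n_active == 1L
  comp_span <- vapply(seq_len(ncol(S)), function(j) {
    length(unique(mets$compartment[S[, j] != 0]))
  }, integer(1))
  rxns$is_transport <- comp_span > 1L
  net <- structure(list(mets = mets, rxns = rxns, S = S),
                   class = "metabolic_network")
  validate_network(net)
  net
}

#' Validate a metabolic network's invariants
#'
#' Checks id uniqueness, non-empty compartments, bound ordering, non-empty
#' stoichiometries and dimension consistency; signals a
#' `thermoflux_validation_error` on the first violation.
#'
#' @param net A `metabolic_network`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  mets <- net$mets; rxns <- net$rxns; S <- net$S
  if (anyDuplicated(mets$id))
    .validation_error("duplicate metabolite id: ",
                      mets$id[duplicated(mets$id)][1])
  if (anyDuplicated(rxns$id))
    .validation_error("duplicate reaction id: ",
                      rxns$id[duplicated(rxns$id)][1])
  if (any(!nzchar(mets$compartment) | is.na(mets$compartment)))
    .validation_error("metabolite with empty compartment")
  bad <- which(rxns$lower_bound > rxns$upper_bound)
  if (length(bad))
    .validation_error("lower_bound > upper_bound for reaction ", rxns$id[bad[1]])
  if (nrow(S) != nrow(mets) || ncol(S) != nrow(rxns))
    .validation_error("stoichiometric matrix dimensions inconsistent with lists")
  empty <- which(colSums(S != 0) == 0L)
  if (length(empty))
    .validation_error("reaction with empty stoichiometry: ", rxns$id[empty[1]])
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d metabolites x %d reactions\n",
              nrow(x$mets), nrow(x$rxns)))
  cat(sprintf("  exchange: %d, transport: %d, objective: %s\n",
              sum(x$rxns$is_exchange), sum(x$rxns$is_transport),
              paste(x$rxns$id[x$rxns$objective_coeff != 0], collapse = ", ")))
  invisible(x)
}

#' Numbers of metabolites and reactions
#' @param net A `metabolic_network`.
#' @return Named integer vector `c(m =, n =)`.
#' @export
network_dim <- function(net) c(m = nrow(net$mets), n = nrow(net$rxns))

# ---------------------------------------------------------------------------
# formula strings

#' Parse a reaction formula string
#'
#' @param formula A signed-coefficient term list, e.g. `"-1 ac_c + 1 actp_c"`.
#' @param line Optional line number used in error messages.
#' @return Named numeric vector of stoichiometric coefficients.
#' @export
parse_formula <- function(formula, line = NA) {
  formula <- trimws(formula)
  if (!nzchar(formula)) .parse_error("empty reaction formula",
                                     if (!is.na(line)) paste0(" at line ", line))
  terms <- strsplit(formula, "\\s+\\+\\s+")[[1]]
  coefs <- numeric(0)
  for (t in terms) {
    tok <- strsplit(trimws(t), "\\s+")[[1]]
    if (length(tok) != 2 || is.na(suppressWarnings(as.numeric(tok[1]))))
      .parse_error("malformed formula term '", t, "'",
                   if (!is.na(line)) paste0(" at line ", line))
    coefs[tok[2]] <- (if (tok[2] %in% names(coefs)) coefs[[tok[2]]] else 0) +
      as.numeric(tok[1])
  }
  coefs
}

#' Format a stoichiometry as a formula string
#' @param coefs Named numeric vector of coefficients.
#' @return A string parseable by [parse_formula()].
#' @export
format_formula <- function(coefs) {
  coefs <- coefs[coefs != 0]
  paste(sprintf("%.10g %s", unname(coefs), names(coefs)), collapse = " + ")
}

# ---------------------------------------------------------------------------
# network reader/writer

#' Read a metabolic network
#'
#' For `format = "tsv"`, `path` is a directory containing `metabolites.tsv`
#' and `reactions.tsv` in the package's tabular dialect.  For
#' `format = "sbml"`, `path` is an SBML Level 3 core file (with optional
#' `fbc` bounds, objectives and gene associations).  Row order in the file
#' is preserved, so two reads of the same file give identical networks.
#'
#' @param path Directory (tsv) or file (sbml).
#' @param format `"tsv"` or `"sbml"`.
#' @return A `metabolic_network`.
#' @export
read_network <- function(path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "sbml") return(read_network_sbml(path))
  met_file <- file.path(path, "metabolites.tsv")
  rxn_file <- file.path(path, "reactions.tsv")
  for (f in c(met_file, rxn_file))
    if (!file.exists(f)) .parse_error("missing file: ", f)
  mets <- utils::read.delim(met_file, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("id", "compartment")
  if (!all(need %in% names(mets)))
    .parse_error("metabolites.tsv must have columns id, compartment")
  mets$is_water <- if (is.null(mets$is_water)) FALSE else
    as.logical(as.integer(as.numeric(mets$is_water) != 0))
  mets$is_proton <- if (is.null(mets$is_proton)) FALSE else
    as.logical(as.integer(as.numeric(mets$is_proton) != 0))
  rxn_raw <- utils::read.delim(rxn_file, stringsAsFactors = FALSE,
                               colClasses = "character")
  need <- c("id", "formula", "lower_bound", "upper_bound")
  if (!all(need %in% names(rxn_raw)))
    .parse_error("reactions.tsv must have columns ", paste(need, collapse = ", "))
  n <- nrow(rxn_raw)
  num <- function(col, default) {
    if (is.null(rxn_raw[[col]])) return(rep(default, n))
    v <- suppressWarnings(as.numeric(rxn_raw[[col]]))
    bad <- which(is.na(v) & nzchar(rxn_raw[[col]]))
    if (length(bad)) .parse_error("non-numeric ", col, " at line ", bad[1] + 1L)
    v[is.na(v)] <- default
    v
  }
  rxns <- data.frame(id = rxn_raw$id,
                     name = rxn_raw$name %||% rxn_raw$id,
                     lower_bound = num("lower_bound", 0),
                     upper_bound = num("upper_bound", 0),
                     objective_coeff = num("objective_coeff", 0),
                     gpr = rxn_raw$gpr %||% "",
                     stringsAsFactors = FALSE)
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, rxns$id))
  for (j in seq_len(n)) {
    coefs <- parse_formula(rxn_raw$formula[j], line = j + 1L)
    unknown <- setdiff(names(coefs), mets$id)
    if (length(unknown))
      .validation_error("reaction ", rxns$id[j],
                        " references undeclared metabolite: ", unknown[1])
    S[names(coefs), j] <- coefs
  }
  metabolic_network(mets, rxns, S)
}

#' Write a metabolic network in the tabular dialect
#'
#' @param net A `metabolic_network`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mets <- net$mets[, c("id", "name", "compartment", "is_water", "is_proton")]
  mets$is_water <- as.integer(mets$is_water)
  mets$is_proton <- as.integer(mets$is_proton)
  utils::write.table(mets, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  formulas <- vapply(seq_len(ncol(net$S)), function(j)
    format_formula(net$S[, j]), character(1))
  rxns <- data.frame(id = net$rxns$id, name = net$rxns$name,
                     formula = formulas,
                     lower_bound = net$rxns$lower_bound,
                     upper_bound = net$rxns$upper_bound,
                     objective_coeff = net$rxns$objective_coeff,
                     gpr = net$rxns$gpr, stringsAsFactors = FALSE)
  utils::write.table(rxns, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# ---------------------------------------------------------------------------
# thermodynamic table

#' Construct a thermodynamic table
#'
#' Standard transformed formation energies (kcal/mol) per metabolite with
#' standard errors and unknown flags, plus optional per-reaction standard
#' transformed reaction energies that override formation-derived values.
#'
#' @param formation Data frame with columns `id`, `value`, `se`, `unknown`.
#' @param reaction Optional data frame with columns `id`, `value`, `se`.
#' @return An object of class `thermo_table`.
#' @export
thermo_table <- function(formation,
                         reaction = data.frame(id = character(0),
                                               value = numeric(0),
                                               se = numeric(0))) {
  formation <- as.data.frame(formation, stringsAsFactors = FALSE)
  reaction <- as.data.frame(reaction, stringsAsFactors = FALSE)
  if (is.null(formation$unknown)) formation$unknown <- !is.finite(formation$value)
  if (is.null(formation$se)) formation$se <- 0
  if (is.null(reaction$se)) reaction$se <- 0
  if (any(formation$se < 0, na.rm = TRUE) || any(reaction$se < 0, na.rm = TRUE))
    .validation_error("negative standard error in thermodynamic table")
  bad <- !formation$unknown & !is.finite(formation$value)
  if (any(bad))
    .validation_error("metabolite ", formation$id[bad][1],
                      " has neither a finite value nor an UNKNOWN flag")
  formation$value[formation$unknown] <- NA_real_
  formation$se[is.na(formation$se)] <- 0
  structure(list(formation = formation, reaction = reaction,
                 units = "kcal/mol"), class = "thermo_table")
}

#' Read a thermodynamic table
#'
#' Reads the `thermo.tsv` dialect: columns `type` (`metabolite` or
#' `reaction`), `id`, `value` (kcal/mol, or the literal `UNKNOWN`), `se`.
#' `UNKNOWN` rows are preserved as unknown, never coerced to zero.  If the
#' `se` column is omitted every standard error defaults to 0 and a warning
#' is issued.
#'
#' @param path Path to the TSV file.
#' @param network Optional `metabolic_network`; ids absent from it are
#'   collected into the `unmatched` attribute and reported as a warning.
#' @return A `thermo_table`.
#' @export
read_thermo_table <- function(path, network = NULL) {
  if (!file.exists(path)) .parse_error("missing file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("type", "id", "value") %in% names(raw)))
    .parse_error("thermo table must have columns type, id, value")
  if (is.null(raw$se)) {
    warning("thermo table has no 'se' column; all standard errors default to 0")
    raw$se <- "0"
  }
  unknown <- toupper(trimws(raw$value)) == "UNKNOWN"
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(!unknown & is.na(value))
  if (length(bad)) .parse_error("non-numeric value at line ", bad[1] + 1L)
  se <- suppressWarnings(as.numeric(raw$se))
  se[is.na(se)] <- 0
  is_met <- raw$type == "metabolite"
  tab <- thermo_table(
    formation = data.frame(id = raw$id[is_met], value = value[is_met],
                           se = se[is_met], unknown = unknown[is_met],
                           stringsAsFactors = FALSE),
    reaction = data.frame(id = raw$id[!is_met], value = value[!is_met],
                          se = se[!is_met], stringsAsFactors = FALSE))
  if (!is.null(network)) {
    unmatched <- setdiff(tab$formation$id, network$mets$id)
    if (length(unmatched))
      warning("thermo table ids absent from network: ",
              paste(unmatched, collapse = ", "))
    attr(tab, "unmatched") <- unmatched
  }
  tab
}

#' Write a thermodynamic table in the tabular dialect
#' @param tab A `thermo_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_thermo_table <- function(tab, path) {
  f <- tab$formation
  rows <- data.frame(type = c(rep("metabolite", nrow(f)),
                              rep("reaction", nrow(tab$reaction))),
                     id = c(f$id, tab$reaction$id),
                     value = c(ifelse(f$unknown, "UNKNOWN",
                                      sprintf("%.10g", f$value)),
                               sprintf("%.10g", tab$reaction$value)),
                     se = sprintf("%.10g", c(f$se, tab$reaction$se)),
                     stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# expression datasets

#' Read gene-expression fold-change tables
#'
#' Each file holds one experiment as a TSV with columns `gene`,
#' `fold_change` (log2) and `cv` (coefficient of variation of the
#' measurement).  Experiments are keyed by file name stem; a gene may be
#' present in only some experiments.
#'
#' @param paths Character vector of file paths (may be empty).
#' @return An `expression_dataset`: list with `experiments` (character) and
#'   `data` (long data frame `gene`, `experiment`, `fold_change`, `cv`).
#' @export
read_expression <- function(paths) {
  rows <- list()
  stems <- character(0)
  for (path in paths) {
    if (!file.exists(path)) .parse_error("missing file: ", path)
    stem <- tools::file_path_sans_ext(basename(path))
    stems <- c(stems, stem)
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("gene", "fold_change", "cv") %in% names(raw)))
      .parse_error(path, " must have columns gene, fold_change, cv")
    fc <- suppressWarnings(as.numeric(raw$fold_change))
    bad <- which(is.na(fc))
    if (length(bad)) .parse_error("non-numeric fold change in ", path,
                                  " at line ", bad[1] + 1L)
    cv <- suppressWarnings(as.numeric(raw$cv))
    if (anyNA(cv)) .parse_error("non-numeric cv in ", path)
    if (any(cv < 0)) .validation_error("negative cv in ", path)
    rows[[stem]] <- data.frame(gene = raw$gene, experiment = stem,
                               fold_change = fc, cv = cv,
                               stringsAsFactors = FALSE)
  }
  data <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(gene = character(0), experiment = character(0),
               fold_change = numeric(0), cv = numeric(0))
  structure(list(experiments = stems, data = data), class = "expression_dataset")
}

#' Write an expression dataset as per-experiment TSV files
#' @param expr An `expression_dataset`.
#' @param dir Output directory; one `<experiment>.tsv` per experiment.
#' @return Character vector of the files written, invisibly.
#' @export
write_expression <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (e in expr$experiments) {
    d <- expr$data[expr$data$experiment == e,
                   c("gene", "fold_change", "cv"), drop = FALSE]
    f <- file.path(dir, paste0(e, ".tsv"))
    utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

# ---------------------------------------------------------------------------
# GPR rules

#' Genes associated with a reaction
#'
#' Flattens the boolean structure of the reaction's gene-protein-reaction
#' rule to the set of gene identifiers it mentions.  `and`/`or` keywords
#' (case-insensitive) and parentheses are structure; everything else is a
#' gene id.
#'
#' @param net A `metabolic_network`.
#' @param reaction_id Reaction id.
#' @return Character vector of gene ids (possibly empty), in order of first
#'   appearance.
#' @export
genes_for_reaction <- function(net, reaction_id) {
  j <- match(reaction_id, net$rxns$id)
  if (is.na(j)) .validation_error("unknown reaction: ", reaction_id)
  parse_gpr(net$rxns$gpr[j])
}

#' Flatten a GPR rule to its gene set
#' @param gpr GPR rule string, e.g. `"(g1 and g2) or g3"`.
#' @return Character vector of gene ids.
#' @export
parse_gpr <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character(0))
  open <- lengths(regmatches(gpr, gregexpr("\\(", gpr)))
  close <- lengths(regmatches(gpr, gregexpr("\\)", gpr)))
  if (open != close)
    .parse_error("unbalanced parentheses in GPR rule: ", gpr)
  tok <- strsplit(gsub("[()]", " ", gpr), "\\s+")[[1]]
  tok <- tok[nzchar(tok)]
  genes <- tok[!tolower(tok) %in% c("and", "or")]
  if (!length(genes)) return(character(0))
  dangling <- tolower(tok[length(tok)]) %in% c("and", "or")
  if (dangling) .parse_error("dangling boolean operator in GPR rule: ", gpr)
  unique(genes)
}
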
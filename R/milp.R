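# Thin LP/MILP layer over the GLPK standalone solver (glpsol).
#
# Problems are built as mutable environments holding parallel vectors of
# variable metadata plus a list of linear constraints, serialised to a
# CPLEX-LP file and solved by shelling out to glpsol.  Variables get short
# aliases (x1, x2, ...) in the file so names never hit the solver's
# column-name width limits; results are mapped back to the original names.

#' Create an empty mixed-integer linear program
#'
#' Returns a mutable problem object (an environment) to which variables and
#' constraints are added with [milp_add_var()] and [milp_add_con()], and
#' which is solved with [milp_solve()].  This is the thin
#' build-solve-extract contract behind all optimisation in the package; any
#' MILP backend honouring it could be substituted.
#'
#' @return An object of class `milp_problem`.
#' @seealso [milp_solve()]
#' @export
milp_new <- function() {
  p <- new.env(parent = emptyenv())
  p$var_names <- character(0)
  p$lb <- numeric(0)
  p$ub <- numeric(0)
  p$vtype <- character(0)   # "C" continuous, "B" binary
  p$obj <- numeric(0)
  p$cons <- list()          # list of list(coefs = named numeric, sense, rhs, name)
  class(p) <- "milp_problem"
  p
}

#' Add a variable to a MILP
#'
#' @param p A `milp_problem`.
#' @param name Unique variable name.
#' @param lb,ub Bounds (may be `-Inf`/`Inf` for continuous variables).
#' @param obj Objective coefficient (default 0).
#' @param type `"C"` (continuous) or `"B"` (binary).
#' @return The variable name, invisibly.
#' @export
milp_add_var <- function(p, name, lb = 0, ub = Inf, obj = 0, type = c("C", "B")) {
  type <- match.arg(type)
  if (name %in% p$var_names) stop("duplicate variable name: ", name)
  p$var_names <- c(p$var_names, name)
  p$lb <- c(p$lb, lb)
  p$ub <- c(p$ub, ub)
  p$vtype <- c(p$vtype, type)
  p$obj <- c(p$obj, obj)
  invisible(name)
}

#' Add a linear constraint to a MILP
#'
#' @param p A `milp_problem`.
#' @param coefs Named numeric vector of nonzero coefficients (names are
#'   variable names already added to `p`).
#' @param sense One of `"<="`, `">="`, `"="`.
#' @param rhs Right-hand side constant.
#' @param name Optional row name (for diagnostics only).
#' @return Invisibly, the row index.
#' @export
milp_add_con <- function(p, coefs, sense = c("<=", ">=", "="), rhs, name = NULL) {
  sense <- match.arg(sense)
  coefs <- coefs[coefs != 0]
  missing <- setdiff(names(coefs), p$var_names)
  if (length(missing)) stop("constraint references unknown variables: ",
                            paste(missing, collapse = ", "))
  p$cons[[length(p$cons) + 1L]] <-
    list(coefs = coefs, sense = sense, rhs = rhs,
         name = name %||% paste0("r", length(p$cons) + 1L))
  invisible(length(p$cons))
}

#' Change the bounds of an existing variable
#'
#' @inheritParams milp_add_var
#' @export
milp_set_bounds <- function(p, name, lb, ub) {
  i <- match(name, p$var_names)
  if (is.na(i)) stop("unknown variable: ", name)
  p$lb[i] <- lb
  p$ub[i] <- ub
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a number for the LP file.
.lp_num <- function(x) sprintf("%.15g", x)

# Serialise a linear expression term-by-term, wrapping long lines.
.lp_expr <- function(coefs, alias) {
  terms <- vapply(seq_along(coefs), function(k) {
    v <- coefs[[k]]
    sprintf("%s %s %s", if (v < 0) "-" else "+", .lp_num(abs(v)),
            alias[[names(coefs)[k]]])
  }, character(1))
  lines <- character(0)
  cur <- ""
  for (t in terms) {
    if (nchar(cur) + nchar(t) > 200) { lines <- c(lines, cur); cur <- "" }
    cur <- paste(cur, t)
  }
  c(lines, cur)
}

.milp_write_lp <- function(p, path, objective, maximize) {
  alias <- stats::setNames(paste0("x", seq_along(p$var_names)), p$var_names)
  out <- character(0)
  out <- c(out, if (maximize) "Maximize" else "Minimize")
  if (all(objective == 0)) {
    obj_expr <- paste(" obj: 0", alias[[1]])
  } else {
    nz <- objective[objective != 0]
    obj_expr <- .lp_expr(nz, alias)
    obj_expr[1] <- paste0(" obj:", obj_expr[1])
  }
  out <- c(out, obj_expr, "Subject To")
  for (i in seq_along(p$cons)) {
    con <- p$cons[[i]]
    if (length(con$coefs) == 0) {
      # constant row: check consistency at write time
      ok <- switch(con$sense, "<=" = 0 <= con$rhs, ">=" = 0 >= con$rhs,
                   "=" = con$rhs == 0)
      if (!ok) stop("inconsistent constant constraint: ", con$name)
      next
    }
    expr <- .lp_expr(con$coefs, alias)
    expr[1] <- paste0(" c", i, ":", expr[1])
    expr[length(expr)] <- paste(expr[length(expr)], con$sense, .lp_num(con$rhs))
    out <- c(out, expr)
  }
  out <- c(out, "Bounds")
  for (i in seq_along(p$var_names)) {
    if (p$vtype[i] == "B") next
    l <- p$lb[i]; u <- p$ub[i]
    a <- alias[[p$var_names[i]]]
    line <- if (is.finite(l) && is.finite(u) && l == u) {
      sprintf(" %s = %s", a, .lp_num(l))
    } else {
      sprintf(" %s <= %s <= %s",
              if (is.finite(l)) .lp_num(l) else "-inf", a,
              if (is.finite(u)) .lp_num(u) else "+inf")
    }
    out <- c(out, line)
  }
  bins <- alias[p$vtype == "B"]
  if (length(bins)) out <- c(out, "Binaries", paste(" ", bins))
  out <- c(out, "End")
  writeLines(out, path)
  alias
}

# Parse the printable solution file written by glpsol --output.
.milp_parse_output <- function(lines, alias) {
  status_line <- grep("^Status:", lines, value = TRUE)
  objective_line <- grep("^Objective:", lines, value = TRUE)
  objective <- NA_real_
  if (length(objective_line)) {
    m <- regmatches(objective_line[1],
                    regexec("=\\s*([-+0-9.eE]+)", objective_line[1]))[[1]]
    if (length(m) == 2) objective <- as.numeric(m[2])
  }
  # columns section
  hdr <- grep("Column name", lines)
  values <- stats::setNames(rep(NA_real_, length(alias)), names(alias))
  if (length(hdr)) {
    i <- hdr[1] + 2L
    rev_alias <- stats::setNames(names(alias), alias)
    while (i <= length(lines) && nzchar(trimws(lines[i]))) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) >= 3 && grepl("^[0-9]+$", tok[1])) {
        nm <- tok[2]
        rest <- tok[-(1:2)]
        rest <- rest[!rest %in% c("B", "NL", "NU", "NF", "NS", "*")]
        act <- suppressWarnings(as.numeric(rest[1]))
        if (!is.na(act) && nm %in% names(rev_alias)) values[rev_alias[[nm]]] <- act
      }
      i <- i + 1L
    }
  }
  list(status_text = if (length(status_line)) status_line[1] else "",
       objective = objective, values = values)
}

#' Solve a MILP with glpsol
#'
#' Writes the problem to a temporary CPLEX-LP file, invokes `glpsol`, and
#' parses the printable solution back.  Solves are deterministic: GLPK's
#' branch-and-cut has no randomised components.
#'
#' @param p A `milp_problem`.
#' @param objective Optional named numeric vector overriding the objective
#'   coefficients stored on the variables (names are variable names;
#'   unmentioned variables get 0).
#' @param maximize Logical; maximize (default) or minimize.
#' @param mip_gap Relative MIP gap tolerance passed to glpsol.
#' @return A list with elements `status` (one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`, `"error"`), `objective` (numeric), and
#'   `values` (named numeric vector of variable values).
#' @export
milp_solve <- function(p, objective = NULL, maximize = TRUE, mip_gap = 1e-6) {
  obj <- stats::setNames(p$obj, p$var_names)
  if (!is.null(objective)) {
    obj[] <- 0
    obj[names(objective)] <- objective
  }
  lp_file <- tempfile(fileext = ".lp")
  sol_file <- tempfile(fileext = ".sol")
  on.exit(unlink(c(lp_file, sol_file)), add = TRUE)
  alias <- .milp_write_lp(p, lp_file, obj, maximize)
  has_int <- any(p$vtype == "B")
  args <- c("--lp", lp_file, "--output", sol_file)
  if (has_int) args <- c(args, "--mipgap", format(mip_gap, scientific = TRUE))
  log <- suppressWarnings(system2("glpsol", args, stdout = TRUE, stderr = TRUE))
  log_all <- paste(log, collapse = "\n")
  # the presolver reports an unbounded primal as dual infeasibility
  if (grepl("UNBOUNDED", log_all) || grepl("HAS NO DUAL FEASIBLE", log_all)) {
    return(list(status = "unbounded", objective = NA_real_,
                values = stats::setNames(rep(NA_real_, length(alias)), names(alias))))
  }
  if (grepl("HAS NO.*FEASIBLE", log_all)) {
    return(list(status = "infeasible", objective = NA_real_,
                values = stats::setNames(rep(NA_real_, length(alias)), names(alias))))
  }
  if (!file.exists(sol_file)) {
    return(list(status = "error", objective = NA_real_,
                values = stats::setNames(rep(NA_real_, length(alias)), names(alias)),
                log = log_all))
  }
  parsed <- .milp_parse_output(readLines(sol_file), alias)
  status <- if (grepl("OPTIMAL", parsed$status_text)) "optimal" else "error"
  list(status = status, objective = parsed$objective, values = parsed$values)
}

#' Check that the GLPK solver is available
#'
#' @return `TRUE` invisibly, or an error if `glpsol` is not on the PATH.
#' @export
assert_solver <- function() {
  if (Sys.which("glpsol") == "")
    stop("the GLPK standalone solver 'glpsol' was not found on the PATH")
  invisible(TRUE)
}
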
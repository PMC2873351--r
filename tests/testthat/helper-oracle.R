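# Independent oracle for TMFA/TVA on small networks: exhaustive enumeration
# of all directionality-binary patterns, each reduced to a plain LP.  The
# LP is constructed directly from the network tables here, sharing no code
# with the package's MILP builder: the oracle writes free-MPS files (the
# package writes CPLEX-LP), parses only status and objective, and replaces
# the solver's branch-and-cut MILP search by explicit enumeration.

# Solve max/min c'x s.t. A x (sense) b, lb <= x <= ub via glpsol/free-MPS.
oracle_lp <- function(obj, A, sense, rhs, lb, ub, maximize = TRUE) {
  n <- length(obj)
  m <- nrow(A)
  lines <- c("NAME ORACLE", "ROWS", " N COST")
  rtype <- c("<=" = "L", ">=" = "G", "=" = "E")[sense]
  lines <- c(lines, sprintf(" %s R%d", rtype, seq_len(m)), "COLUMNS")
  for (j in seq_len(n)) {
    entries <- sprintf("R%d %.15g", which(A[, j] != 0), A[A[, j] != 0, j])
    if (obj[j] != 0) entries <- c(sprintf("COST %.15g", obj[j]), entries)
    if (length(entries))
      lines <- c(lines, sprintf(" X%d %s", j, entries))
  }
  lines <- c(lines, "RHS",
             sprintf(" RHS R%d %.15g", which(rhs != 0), rhs[rhs != 0]),
             "BOUNDS",
             sprintf(" LO BND X%d %.15g", seq_len(n), lb),
             sprintf(" UP BND X%d %.15g", seq_len(n), ub),
             "ENDATA")
  f <- tempfile(fileext = ".mps")
  out <- tempfile(fileext = ".out")
  on.exit(unlink(c(f, out)))
  writeLines(lines, f)
  log <- suppressWarnings(system2(
    "glpsol", c("--freemps", f, if (maximize) "--max" else "--min",
                "--output", out), stdout = TRUE, stderr = TRUE))
  if (any(grepl("HAS NO.*FEASIBLE", log)))
    return(list(status = "infeasible", objective = NA_real_))
  if (any(grepl("UNBOUNDED", log)))
    return(list(status = "unbounded", objective = NA_real_))
  sol <- readLines(out)
  st <- grep("^Status:", sol, value = TRUE)
  if (!length(st) || !grepl("OPTIMAL", st))
    return(list(status = "error", objective = NA_real_))
  ol <- grep("^Objective:", sol, value = TRUE)[1]
  v <- regmatches(ol, regexec("=\\s*([-+0-9.eE]+)", ol))[[1]][2]
  list(status = "optimal", objective = as.numeric(v))
}

# Enumerate all directionality patterns of the thermodynamic program and
# solve each as an LP.  Returns the best objective over patterns and, per
# constrained reaction, the union of feasible [dG_min, dG_max].
oracle_enumerate <- function(net, th, config, objective = NULL,
                             growth = NULL, do_tva = TRUE,
                             with_uncertainty = TRUE) {
  S <- net$S
  rxns <- net$rxns
  excl <- net$mets$is_water | net$mets$is_proton
  con_ids <- th$reaction_id[th$constrained]
  mix_mets <- unique(unlist(lapply(con_ids, function(id)
    rownames(S)[S[, id] != 0 & !excl])))
  n <- nrow(rxns)
  nl <- length(mix_mets); nc <- length(con_ids)
  nvar <- n + nl + 2 * nc
  idg <- n + nl + seq_len(nc)
  isl <- n + nl + nc + seq_len(nc)
  bigB <- 1e3
  lb <- c(rxns$lower_bound, rep(config$ln_activity_min, nl), rep(-bigB, nc),
          -config$n_se * th$se[match(con_ids, th$reaction_id)])
  ub <- c(rxns$upper_bound, rep(config$ln_activity_max, nl), rep(bigB, nc),
          config$n_se * th$se[match(con_ids, th$reaction_id)])
  if (!with_uncertainty) { lb[isl] <- 0; ub[isl] <- 0 }

  rows <- list(); senses <- character(0); rhs <- numeric(0)
  add_row <- function(coefs_idx, coefs_val, sense, b) {
    r <- numeric(nvar); r[coefs_idx] <- coefs_val
    rows[[length(rows) + 1L]] <<- r
    senses <<- c(senses, sense); rhs <<- c(rhs, b)
  }
  for (i in seq_len(nrow(S))) {
    nz <- which(S[i, ] != 0)
    if (length(nz)) add_row(nz, S[i, nz], "=", 0)
  }
  for (k in seq_len(nc)) {
    id <- con_ids[k]
    mix <- which(S[, id] != 0 & !excl)
    mcols <- n + match(rownames(S)[mix], mix_mets)
    add_row(c(idg[k], isl[k], mcols),
            c(1, -1, -config$RT * S[mix, id]), "=",
            th$drG0[match(id, th$reaction_id)])
  }
  if (!is.null(growth))
    add_row(match(growth$rxn, rxns$id), 1, "=", growth$value)
  base_rows <- rows; base_senses <- senses; base_rhs <- rhs

  dirs <- list()
  for (k in seq_len(nc)) {
    j <- match(con_ids[k], rxns$id)
    if (rxns$upper_bound[j] > 0)
      dirs[[length(dirs) + 1L]] <- list(k = k, j = j, dir = 1L)
    if (rxns$lower_bound[j] < 0)
      dirs[[length(dirs) + 1L]] <- list(k = k, j = j, dir = -1L)
  }
  nd <- length(dirs)
  stopifnot(nd <= 14)
  obj_vec <- numeric(nvar)
  if (!is.null(objective)) {
    w <- if (is.character(objective))
      stats::setNames(rep(1, length(objective)), objective) else objective
    obj_vec[match(names(w), rxns$id)] <- w
  }
  best <- -Inf
  tva_min <- rep(Inf, nc); tva_max <- rep(-Inf, nc)
  eps <- config$eps_thermo
  ks <- vapply(dirs, `[[`, 0L, "k")
  for (mask in 0:(2^nd - 1)) {
    z <- if (nd) as.integer(intToBits(mask))[seq_len(nd)] else integer(0)
    if (nd && any(tapply(z, ks, sum) > 1)) next
    rows <- base_rows; senses <- base_senses; rhs <- base_rhs
    for (d in seq_len(nd)) {
      k <- dirs[[d]]$k; j <- dirs[[d]]$j
      if (dirs[[d]]$dir > 0) {
        if (z[d] == 1) add_row(idg[k], 1, "<=", -eps) else add_row(j, 1, "<=", 0)
      } else {
        if (z[d] == 1) add_row(idg[k], 1, ">=", eps) else add_row(j, 1, ">=", 0)
      }
    }
    A <- do.call(rbind, rows)
    feas <- oracle_lp(obj_vec, A, senses, rhs, lb, ub, maximize = TRUE)
    if (feas$status != "optimal") next
    if (!is.null(objective) && feas$objective > best) best <- feas$objective
    if (do_tva) {
      for (k in seq_len(nc)) {
        ov <- numeric(nvar); ov[idg[k]] <- 1
        lo <- oracle_lp(ov, A, senses, rhs, lb, ub, maximize = FALSE)
        hi <- oracle_lp(ov, A, senses, rhs, lb, ub, maximize = TRUE)
        if (lo$status == "optimal") tva_min[k] <- min(tva_min[k], lo$objective)
        if (hi$status == "optimal") tva_max[k] <- max(tva_max[k], hi$objective)
      }
    }
  }
  list(optimum = best,
       tva = data.frame(reaction_id = con_ids, drG_min = tva_min,
                        drG_max = tva_max, stringsAsFactors = FALSE))
}
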
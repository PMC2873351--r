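# Validation of predicted reaction classes against gene-expression
# fold-change ranges: per-gene ranges after a coefficient-of-variation
# filter, a two-sided Wilcoxon rank-sum test and a Welch two-sample t-test
# comparing range widths between regulatory candidates and bottlenecks,
# and annotation of bottlenecks with literature exchange coefficients.

#' Filtered fold-change ranges per gene and reaction class
#'
#' For every gene associated (through the GPR rules) with a classified
#' reaction, discards (gene, experiment) measurements whose coefficient of
#' variation is not strictly below `cv_max`, and reports the range
#' `[min, max]` of the retained log2 fold changes.  Genes with no retained
#' experiment (or absent from the expression data entirely) get a null
#' range and are excluded from downstream tests; absent genes additionally
#' raise a warning.
#'
#' @param expr An `expression_dataset`.
#' @param classes Data frame from [classify_reactions()].
#' @param net The `metabolic_network` supplying GPR rules.
#' @param cv_max Strict CV threshold (default 0.2).
#' @param labels Class labels to include (default: bottlenecks, regulatory
#'   candidates, and threshold reactions).
#' @return Data frame `gene`, `reaction_id`, `label`, `fc_min`, `fc_max`,
#'   `width`, `n_experiments_retained`.
#' @export
fold_change_ranges <- function(expr, classes, net, cv_max = 0.2,
                               labels = c("bottleneck", "regulatory_candidate",
                                          "threshold_of_regulation")) {
  stopifnot(cv_max > 0)
  keep <- classes[classes$label %in% labels, , drop = FALSE]
  rows <- list()
  missing_genes <- character(0)
  for (k in seq_len(nrow(keep))) {
    rid <- keep$reaction_id[k]
    for (gene in genes_for_reaction(net, rid)) {
      d <- expr$data[expr$data$gene == gene, , drop = FALSE]
      if (!nrow(d)) missing_genes <- union(missing_genes, gene)
      d <- d[d$cv < cv_max, , drop = FALSE]
      n_ret <- nrow(d)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, reaction_id = rid, label = keep$label[k],
        fc_min = if (n_ret) min(d$fold_change) else NA_real_,
        fc_max = if (n_ret) max(d$fold_change) else NA_real_,
        width = if (n_ret) max(d$fold_change) - min(d$fold_change) else NA_real_,
        n_experiments_retained = n_ret, stringsAsFactors = FALSE)
    }
  }
  if (length(missing_genes))
    warning("genes absent from all expression files: ",
            paste(missing_genes, collapse = ", "))
  if (!length(rows))
    return(data.frame(gene = character(0), reaction_id = character(0),
                      label = character(0), fc_min = numeric(0),
                      fc_max = numeric(0), width = numeric(0),
                      n_experiments_retained = integer(0)))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Two-sided Wilcoxon rank-sum test on range widths
#'
#' Uses the exact rank-sum distribution when the smaller sample has at most
#' 8 observations and there are no ties, and the normal approximation with
#' tie correction (and continuity correction) otherwise.  Returns the
#' method actually used alongside the p value.
#'
#' @param widths_a,widths_b Non-empty numeric vectors.
#' @return List `p_value`, `statistic` (the rank-sum W), `method`,
#'   `n_a`, `n_b`.
#' @export
rank_sum_test <- function(widths_a, widths_b) {
  stopifnot(length(widths_a) > 0, length(widths_b) > 0)
  if (length(unique(c(widths_a, widths_b))) == 1L)
    return(list(p_value = 1, statistic = NA_real_,
                method = "degenerate (all values identical)",
                n_a = length(widths_a), n_b = length(widths_b)))
  ties <- any(duplicated(c(widths_a, widths_b)))
  exact <- !ties && min(length(widths_a), length(widths_b)) <= 8
  wt <- suppressWarnings(stats::wilcox.test(widths_a, widths_b,
                                            alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(p_value = unname(wt$p.value), statistic = unname(wt$statistic),
       method = if (exact) "exact rank-sum distribution" else
         "normal approximation with tie/continuity correction",
       n_a = length(widths_a), n_b = length(widths_b))
}

#' Welch two-sample t-test on range widths
#'
#' Two-sample t statistic assuming unequal variances, with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value.
#'
#' @param widths_a,widths_b Numeric vectors of length at least 2.
#' @return List `p_value`, `statistic`, `df`, `n_a`, `n_b`.
#' @export
welch_t_test <- function(widths_a, widths_b) {
  stopifnot(length(widths_a) >= 2, length(widths_b) >= 2)
  if (stats::var(widths_a) == 0 && stats::var(widths_b) == 0) {
    if (mean(widths_a) == mean(widths_b))
      return(list(p_value = 1, statistic = 0, df = NA_real_,
                  n_a = length(widths_a), n_b = length(widths_b)))
    return(list(p_value = 0, statistic = Inf, df = NA_real_,
                n_a = length(widths_a), n_b = length(widths_b)))
  }
  tt <- stats::t.test(widths_a, widths_b, var.equal = FALSE)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       n_a = length(widths_a), n_b = length(widths_b))
}

#' Compare fold-change range widths between reaction classes
#'
#' Runs both global tests of the pipeline — the two-sided Wilcoxon
#' rank-sum test and the Welch t-test — on per-gene range widths of the
#' regulatory-candidate class versus the bottleneck class.
#'
#' @param ranges Data frame from [fold_change_ranges()].
#' @return Data frame with one row per statistic: `statistic_name`,
#'   `statistic`, `p_value`, `n_regulatory`, `n_bottleneck`, `method`.
#' @export
compare_class_widths <- function(ranges) {
  ok <- !is.na(ranges$width)
  wa <- ranges$width[ok & ranges$label == "regulatory_candidate"]
  wb <- ranges$width[ok & ranges$label == "bottleneck"]
  if (!length(wa) || !length(wb))
    .tf_stop("thermoflux_validation_error",
             "no genes with retained experiments in one of the classes; ",
             "cannot test range widths")
  rs <- rank_sum_test(wa, wb)
  wt <- welch_t_test(wa, wb)
  data.frame(statistic_name = c("wilcoxon_rank_sum_two_sided",
                                "welch_t_two_sample"),
             statistic = c(rs$statistic, wt$statistic),
             p_value = c(rs$p_value, wt$p_value),
             n_regulatory = length(wa), n_bottleneck = length(wb),
             method = c(rs$method, "Welch-Satterthwaite"),
             stringsAsFactors = FALSE)
}

#' Annotate bottleneck reactions with exchange coefficients
#'
#' Joins externally supplied (literature) exchange coefficients — a
#' reversibility measure from C13 isotope-labeling flux studies — onto the
#' classified reactions, flagging bottlenecks whose coefficient exceeds a
#' reporting threshold.  Coefficients are treated as opaque annotations;
#' reactions without one are left blank.
#'
#' @param classes Data frame from [classify_reactions()].
#' @param exchange_table Named numeric vector or data frame
#'   (`reaction_id`, `coefficient`).
#' @param threshold Reporting threshold for the `significant` flag.
#' @return `classes` with `exchange_coefficient` and `significant` columns.
#' @export
annotate_with_exchange_coefficients <- function(classes, exchange_table,
                                                threshold = 0.01) {
  if (is.data.frame(exchange_table)) {
    coefs <- stats::setNames(exchange_table$coefficient,
                             exchange_table$reaction_id)
  } else coefs <- exchange_table
  out <- classes
  out$exchange_coefficient <- unname(coefs[out$reaction_id])
  out$significant <- !is.na(out$exchange_coefficient) &
    out$exchange_coefficient > threshold & out$label == "bottleneck"
  out
}
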
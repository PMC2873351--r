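# CV-filtered fold-change ranges and the two class-comparison tests.

mk_expr <- function(df) {
  structure(list(experiments = unique(df$experiment), data = df),
            class = "expression_dataset")
}

mk_classnet <- function() {
  mets <- data.frame(id = c("A", "B", "C"), compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("RB", "RR"), lower_bound = 0, upper_bound = 10,
                     gpr = c("gb1 and gb2", "gr1 or gr2"),
                     stringsAsFactors = FALSE)
  S <- matrix(c(-1, 1, 0, 0, -1, 1), 3, 2, dimnames = list(mets$id, rxns$id))
  net <- metabolic_network(mets, rxns, S)
  classes <- data.frame(reaction_id = c("RB", "RR"),
                        label = c("bottleneck", "regulatory_candidate"),
                        stringsAsFactors = FALSE)
  list(net = net, classes = classes)
}

test_that("ranges are min/max of CV-retained log2 fold changes", {
  cn <- mk_classnet()
  df <- data.frame(gene = "gb1", experiment = c("e1", "e2", "e3"),
                   fold_change = c(-1.2, 0.8, 2.0), cv = c(0.1, 0.15, 0.19),
                   stringsAsFactors = FALSE)
  r <- suppressWarnings(fold_change_ranges(mk_expr(df), cn$classes, cn$net))
  g <- r[r$gene == "gb1", ]
  expect_equal(c(g$fc_min, g$fc_max, g$width), c(-1.2, 2.0, 3.2))
  expect_identical(g$n_experiments_retained, 3L)
  # a single retained experiment gives a degenerate width of zero
  df1 <- df[1, ]
  r1 <- suppressWarnings(fold_change_ranges(mk_expr(df1), cn$classes, cn$net))
  expect_equal(r1$width[r1$gene == "gb1"], 0)
})

test_that("the CV threshold is strict and the filter is idempotent", {
  cn <- mk_classnet()
  df <- data.frame(gene = "gb1", experiment = c("e1", "e2"),
                   fold_change = c(1, 5), cv = c(0.19, 0.21),
                   stringsAsFactors = FALSE)
  r <- suppressWarnings(fold_change_ranges(mk_expr(df), cn$classes, cn$net))
  expect_identical(r$n_experiments_retained[r$gene == "gb1"], 1L)
  expect_equal(r$fc_max[r$gene == "gb1"], 1)
  # filtering an already-filtered dataset changes nothing
  pre <- df[df$cv < 0.2, ]
  r2 <- suppressWarnings(fold_change_ranges(mk_expr(pre), cn$classes, cn$net))
  expect_equal(r2[c("fc_min", "fc_max", "width", "n_experiments_retained")],
               r[c("fc_min", "fc_max", "width", "n_experiments_retained")])
})

test_that("genes missing from the data give null records and a warning", {
  cn <- mk_classnet()
  df <- data.frame(gene = "gb1", experiment = "e1", fold_change = 1, cv = 0.1,
                   stringsAsFactors = FALSE)
  expect_warning(r <- fold_change_ranges(mk_expr(df), cn$classes, cn$net),
                 "gr1")
  expect_true(all(is.na(r$width[r$gene %in% c("gr1", "gr2")])))
  expect_identical(r$n_experiments_retained[r$gene == "gr1"], 0L)
})

# brute-force two-sided rank-sum p by enumerating all rank splits
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  W_obs <- sum(r[seq_along(a)])
  splits <- utils::combn(length(pooled), length(a))
  Ws <- apply(splits, 2, function(idx) sum(r[idx]))
  mu <- length(a) * (length(pooled) + 1) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
}

test_that("exact rank-sum p values equal rank-split enumeration", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p_value, 0.1)  # 2 of the C(6,3)=20 splits are as extreme
  expect_equal(rs$p_value, enum_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_match(rs$method, "exact")
  rs2 <- rank_sum_test(1:5, 6:10)
  expect_equal(rs2$p_value, enum_ranksum_p(1:5, 6:10))
  expect_equal(rs2$p_value, 2 / choose(10, 5))
  set.seed(42)
  for (k in 1:5) {
    a <- stats::rnorm(sample(3:6, 1))
    b <- stats::rnorm(sample(3:8, 1), mean = stats::runif(1, 0, 2))
    expect_equal(rank_sum_test(a, b)$p_value, enum_ranksum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum test is symmetric and degenerates to p = 1", {
  set.seed(1)
  a <- stats::rnorm(7); b <- stats::rnorm(9, 1)
  expect_equal(rank_sum_test(a, b)$p_value, rank_sum_test(b, a)$p_value)
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("Welch t-test matches the closed-form statistic to high precision", {
  a <- c(0.62, 1.84, 2.91, 0.15, 1.33, 2.05)
  b <- c(3.81, 5.02, 4.17, 6.25)
  wt <- welch_t_test(a, b)
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(wt$statistic, tstat, tolerance = 1e-10)
  expect_equal(wt$df, df, tolerance = 1e-10)
  expect_equal(wt$p_value, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-10)
  expect_equal(welch_t_test(a, a)$p_value, 1)
  expect_lt(welch_t_test(c(0, 0, 0, 0), c(5, 5, 5, 5.0001))$p_value, 1e-6)
})

test_that("exchange coefficients join as opaque annotations", {
  classes <- data.frame(reaction_id = c("MDH", "FUM", "CS"),
                        label = c("bottleneck", "bottleneck",
                                  "regulatory_candidate"),
                        stringsAsFactors = FALSE)
  ann <- annotate_with_exchange_coefficients(classes,
                                             c(MDH = 0.29, FUM = 0.37))
  expect_equal(ann$exchange_coefficient, c(0.29, 0.37, NA))
  expect_identical(ann$significant, c(TRUE, TRUE, FALSE))
  empty <- annotate_with_exchange_coefficients(classes, numeric(0))
  expect_true(all(is.na(empty$exchange_coefficient)))
})

test_that("class width comparison runs both tests and refuses empty classes", {
  cn <- mk_classnet()
  set.seed(3)
  df <- rbind(
    data.frame(gene = rep(c("gb1", "gb2"), each = 8),
               experiment = sprintf("e%d", 1:8),
               fold_change = stats::rnorm(16, 0, 0.5), cv = 0.1),
    data.frame(gene = rep(c("gr1", "gr2"), each = 8),
               experiment = sprintf("e%d", 1:8),
               fold_change = stats::rnorm(16, 0, 3), cv = 0.1))
  r <- suppressWarnings(fold_change_ranges(mk_expr(df), cn$classes, cn$net))
  cmp <- compare_class_widths(r)
  expect_identical(cmp$statistic_name,
                   c("wilcoxon_rank_sum_two_sided", "welch_t_two_sample"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  all_fail <- df; all_fail$cv <- 0.5
  r2 <- suppressWarnings(fold_change_ranges(mk_expr(all_fail), cn$classes,
                                            cn$net))
  expect_error(compare_class_widths(r2), "retained",
               class = "thermoflux_validation_error")
})
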
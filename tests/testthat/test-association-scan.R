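test_that("degenerate designs and one-class responses give NA p-values", {
  x <- matrix(numeric(0), nrow = 6, ncol = 0)
  f <- fit_logistic(x, c(0, 0, 0, 1, 1, 1))
  expect_true(is.na(f$p_value))
  expect_identical(f$reason, "degenerate")
  f2 <- fit_logistic(matrix(rnorm(6)), rep(0, 6))
  expect_identical(f2$reason, "no_events")
  f3 <- fit_logistic(matrix(rnorm(6)), rep(1, 6))
  expect_identical(f3$reason, "no_events")
})

test_that("single-predictor Wald p matches an independent IRLS oracle", {
  set.seed(11)
  for (i in 1:50) {
    n <- 40
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.5)  # slope 0 truth, balanced
    if (length(unique(y)) < 2) next
    f <- fit_logistic(matrix(x, dimnames = list(NULL, "x")), y)
    expect_identical(f$method, "wald")
    expect_lt(abs(f$p_value - oracle_logistic_wald(x, y)), 1e-6)
  }
})

test_that("multi-predictor LRT p matches the deviance difference of glm", {
  set.seed(12)
  for (i in 1:10) {
    n <- 43
    x <- matrix(rnorm(3 * n), n, dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    f <- fit_logistic(x, y)
    if (f$method != "lrt") next
    ref <- stats::glm(y ~ x, family = stats::binomial())
    stat <- ref$null.deviance - ref$deviance
    expect_equal(f$p_value, stats::pchisq(stat, 3, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("separated data fall back to a finite penalized-likelihood p", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- matrix(scale(1:6), dimnames = list(NULL, "x"))
  f <- fit_logistic(x, y)
  expect_identical(f$method, "firth_lrt")
  expect_false(f$converged)
  expect_true(is.finite(f$p_value))
  expect_gt(f$p_value, 0)
  expect_equal(f$p_value, oracle_firth_p(drop(x), y), tolerance = 1e-4)
})

test_that("aliased columns are dropped in declared order before fitting", {
  set.seed(13)
  n <- 30
  a <- rnorm(n)
  x <- cbind(a = a, b = rnorm(n), a2 = 2 * a)  # a2 aliased with a
  y <- rbinom(n, 1, 0.5)
  f <- fit_logistic(x, y)
  expect_equal(f$df, 2L)
  expect_false("a2" %in% names(f$coefficients))
})

test_that("min-p aggregation takes the minimum and ignores NA", {
  res <- tibble::tibble(
    unit_id = rep(c("gA", "gB"), each = 3),
    pair_id = rep(c("p1", "p2", "p3"), 2),
    p_value = c(0.3, 0.01, 0.2, NA, NA, NA)
  )
  ov <- aggregate_min_p(res)
  expect_equal(ov$overall_p[ov$unit_id == "gA"], 0.01)
  expect_identical(ov$argmin[ov$unit_id == "gA"], "p2")
  expect_true(is.na(ov$overall_p[ov$unit_id == "gB"]))
  # the minimum never exceeds any contributing p; adding a pair only lowers it
  expect_true(all(ov$overall_p[1] <= res$p_value[1:3]))
  res2 <- dplyr::bind_rows(res, tibble::tibble(unit_id = "gA", pair_id = "p4",
                                               p_value = 0.001))
  ov2 <- aggregate_min_p(res2)
  expect_lte(ov2$overall_p[ov2$unit_id == "gA"],
             ov$overall_p[ov$unit_id == "gA"])
})

test_that("gene scan fits one model per gene x pair and aggregates by min-p", {
  b <- get_fixture("tiny")
  syn <- score_synergy(b$dose)
  syn <- syn[syn$cell_line_id %in% b$train_cells, ]
  pairs <- unique(syn$pair_id)
  genes <- rownames(b$expression)[1:5]
  sc <- gene_scan(b$expression[genes, b$train_cells], syn, pairs)
  expect_equal(nrow(sc$results), length(genes) * length(pairs))
  expect_equal(nrow(sc$overall), length(genes))
  ok <- !is.na(sc$overall$overall_p)
  for (g in sc$overall$unit_id[ok]) {
    contributing <- sc$results$p_value[sc$results$unit_id == g]
    expect_equal(sc$overall$overall_p[sc$overall$unit_id == g],
                 min(contributing, na.rm = TRUE))
  }
})

test_that("pathway scan produces the expected model counts per analysis", {
  b <- get_fixture("tiny")
  syn <- score_synergy(b$dose)
  syn <- syn[syn$cell_line_id %in% b$train_cells, ]
  pairs <- unique(syn$pair_id)
  active <- call_active(b$presence)[, b$train_cells]
  essential <- call_essential(b$d2)
  tf <- build_target_features(b$pairs, b$targets, active, essential)
  pf <- build_pathway_features(b$pathways, active, essential)
  pws <- names(b$pathways)

  s1 <- pathway_scan("PA1", "expression", tf, pf, syn, pairs)
  expect_equal(nrow(s1$results), length(pairs))
  expect_equal(nrow(s1$overall), length(pairs))
  # PA1's single p passes through min-p unchanged
  expect_equal(s1$overall$overall_p,
               s1$results$p_value[match(s1$overall$pair_id, s1$results$pair_id)])

  s2 <- pathway_scan("PA2", "expression", tf, pf, syn, pairs, pws)
  expect_equal(nrow(s2$results), length(pairs) * length(pws))
  for (pr in pairs) {
    sub <- s2$results$p_value[s2$results$pair_id == pr]
    if (all(is.na(sub))) next
    expect_equal(s2$overall$overall_p[s2$overall$pair_id == pr],
                 min(sub, na.rm = TRUE))
  }
})

test_that("Bonferroni thresholds are exact alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 3024), 0.05 / 3024)
  expect_equal(bonferroni_threshold(0.05, 3024), 1.653e-5, tolerance = 1e-3)
  expect_equal(bonferroni_threshold(0.05, 165 * 114), 2.6582e-6,
               tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("FDR tables divide rounded expected counts by observed counts", {
  t1 <- fdr_from_counts(62, 0.001, 114)
  expect_equal(t1$n_expected, 0.11)
  expect_equal(signif(t1$fdr, 3), 1.77e-3)
  t2 <- fdr_from_counts(423, 0.001, 18810)
  expect_equal(t2$n_expected, 18.81)
  expect_equal(signif(t2$fdr, 2), 0.044)
  t3 <- fdr_from_counts(0, 0.001, 114)
  expect_true(is.na(t3$fdr))
})

test_that("FDR observed counts match a naive scan and respect NA rules", {
  set.seed(14)
  for (i in 1:10) {
    p <- runif(200)
    p[sample(200, 20)] <- NA
    tab <- fdr_table(p, thresholds = c(1e-3, 1e-2, 0.05, 0.5), n_tests = 200)
    for (j in seq_len(nrow(tab))) {
      expect_identical(tab$n_observed[j],
                       as.integer(oracle_fdr_observed(p, tab$threshold[j])))
      expect_equal(tab$n_expected[j], round(tab$threshold[j] * 200, 2))
    }
  }
  expect_error(fdr_table(runif(10), n_tests = 5))
})

test_that("modality overlap produces Venn counts", {
  oe <- tibble::tibble(unit_id = c("a", "b"), overall_p = c(1e-4, 1e-4))
  os <- tibble::tibble(unit_id = c("b", "c"), overall_p = c(1e-4, 1e-4))
  expect_equal(significant_overlap(oe, os),
               tibble::tibble(n_expr_only = 1L, n_ess_only = 1L, n_both = 1L),
               ignore_attr = TRUE)
  os2 <- tibble::tibble(unit_id = c("x", "y"), overall_p = c(1e-4, 1e-4))
  expect_equal(significant_overlap(oe, os2)$n_both, 0L)
  expect_equal(significant_overlap(oe, oe)$n_expr_only, 0L)
  # threshold respected
  oe$overall_p <- c(1e-4, 0.5)
  expect_equal(significant_overlap(oe, oe, threshold = 0.001)$n_both, 1L)
})

test_that("p-value correlations behave at the edges and under the null", {
  x <- c(0.1, 0.2, 0.5, 0.9)
  mc <- modality_correlation(x, x)
  expect_equal(mc$pearson_r, 1)
  expect_equal(mc$spearman_rho, 1)
  rev_ranks <- modality_correlation(1:10 / 10, 10:1 / 10)
  expect_equal(rev_ranks$spearman_rho, -1)
  expect_true(is.na(modality_correlation(c(0.1, 0.2), c(0.3, 0.4))$pearson_r))
  set.seed(15)
  null_mc <- modality_correlation(runif(1000), runif(1000))
  expect_lt(abs(null_mc$pearson_r), 0.07)
  expect_lt(abs(null_mc$spearman_rho), 0.07)
})

test_that("target/non-target labeling is deterministic set membership", {
  pairs_df <- tibble::tibble(pair_id = "p1", drug_a = "A", drug_b = "B")
  targets <- list(A = c("g1", "g2"), B = "g3")
  pathways <- list(pw1 = c("g3", "g9"), pw2 = c("g7", "g8"))
  res <- tibble::tibble(pair_id = "p1", unit_id = c("pw1", "pw2"),
                        p_value = c(0.01, 0.5))
  cmp <- compare_target_groups(res, pairs_df, targets, pathways)
  expect_setequal(cmp$summary$group, c("target", "non_target"))
  expect_equal(cmp$summary$n, c(1L, 1L))
  # gene-level labeling
  res_g <- tibble::tibble(pair_id = "p1", unit_id = c("g1", "g7"),
                          p_value = c(0.2, 0.3))
  cmp_g <- compare_target_groups(res_g, pairs_df, targets)
  expect_equal(sum(cmp_g$summary$group == "target"), 1L)
})

test_that("equal-effect groups give a uniform-looking rank-sum null", {
  set.seed(16)
  ps <- replicate(200, {
    res <- tibble::tibble(
      pair_id = "p1",
      unit_id = c(paste0("t", 1:25), paste0("n", 1:25)),
      p_value = runif(50)
    )
    cmp <- compare_target_groups(
      res, tibble::tibble(pair_id = "p1", drug_a = "A", drug_b = "B"),
      targets = list(A = paste0("t", 1:25), B = character(0))
    )
    cmp$p_value
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_gt(min(ps), 0)
})
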
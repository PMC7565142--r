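small_profiles <- function() {
  genes <- paste0("g", 1:6)
  cells <- c("c1", "c2")
  active <- matrix(0L, 6, 2, dimnames = list(genes, cells))
  active[c("g1", "g3", "g5"), "c1"] <- 1L
  active[c("g2", "g3"), "c2"] <- 1L
  essential <- matrix(0L, 6, 2, dimnames = list(genes, cells))
  essential[c("g2", "g3"), "c1"] <- 1L
  essential["g1", "c2"] <- 1L
  list(active = active, essential = essential,
       targets = list(A = c("g1", "g2"), B = c("g2", "g3"), C = "g6"))
}

test_that("type-1 features reduce to set arithmetic", {
  pr <- small_profiles()
  tf <- target_features("A", "B", pr$targets, pr$active, pr$essential)
  expect_equal(tf$n_D_union_ab, c(3, 3))
  expect_equal(tf$n_D_intersection_ab, c(1, 1))
  r1 <- tf[tf$cell_line_id == "c1", ]
  # active set c1 = {g1,g3,g5}; union {g1,g2,g3} overlaps {g1,g3}
  expect_equal(r1$n_cell_c_expression, 3L)
  expect_equal(r1$n_cell_c_expression_D_union_ab, 2L)
  expect_equal(r1$ratio_expr_union, 2 / 3)
  # essential set c1 = {g2,g3}; intersection {g2} overlaps {g2}
  expect_equal(r1$n_cell_c_essentiality, 2L)
  expect_equal(r1$n_cell_c_essentiality_D_intersection_ab, 1L)
  expect_equal(r1$ratio_ess_intersection, 1 / 2)
  # empty target intersection gives zero counts and ratios
  tf2 <- target_features("A", "C", pr$targets, pr$active, pr$essential)
  expect_equal(tf2$n_D_intersection_ab, c(0, 0))
  expect_equal(tf2$n_cell_c_expression_D_intersection_ab, c(0L, 0L))
  expect_equal(tf2$ratio_expr_intersection, c(0, 0))
  expect_error(target_features("A", "Z", pr$targets, pr$active, pr$essential),
               "drug absent.*Z")
})

test_that("type-2 features count pathway genes per cell line", {
  pr <- small_profiles()
  pf <- pathway_features(c("g1", "g2", "g5"), pr$active, pr$essential)
  r1 <- pf[pf$cell_line_id == "c1", ]
  expect_equal(r1$n_k, 3L)
  expect_equal(r1$n_cell_c_expression_kegg_k, 2L)   # g1, g5 of 3 active
  expect_equal(r1$ratio_expr_kegg_k, 2 / 3)
  expect_equal(r1$n_cell_c_essentiality_kegg_k, 1L) # g2 of {g2,g3}
  expect_equal(r1$ratio_ess_kegg_k, 1 / 2)
  # disjoint pathway
  pf0 <- pathway_features("g6", pr$active, pr$essential)
  expect_true(all(pf0$n_cell_c_expression_kegg_k == 0L))
  expect_true(all(pf0$ratio_expr_kegg_k == 0))
  # pathway covering every active gene normalizes to 1
  pf1 <- pathway_features(paste0("g", 1:6), pr$active, pr$essential)
  expect_true(all(pf1$ratio_expr_kegg_k == 1))
})

test_that("features are invariant to gene ordering in the inputs", {
  pr <- small_profiles()
  perm <- c(4, 2, 6, 1, 5, 3)
  tf1 <- target_features("A", "B", pr$targets, pr$active, pr$essential)
  tf2 <- target_features("A", "B", pr$targets, pr$active[perm, ],
                         pr$essential[perm, ])
  expect_equal(tf1, tf2)
  pf1 <- pathway_features(c("g3", "g1"), pr$active, pr$essential)
  pf2 <- pathway_features(c("g1", "g3"), pr$active[perm, ], pr$essential[perm, ])
  expect_equal(pf1, pf2)
})

test_that("feature rows match a brute-force set-intersection oracle", {
  b <- get_fixture("tiny")
  active <- call_active(b$presence)[, b$train_cells]
  essential <- call_essential(b$d2)
  tf <- build_target_features(b$pairs, b$targets, active, essential)
  pf <- build_pathway_features(b$pathways, active, essential)
  for (i in seq_len(nrow(b$pairs))) {
    ta <- b$targets[[b$pairs$drug_a[i]]]
    tb <- b$targets[[b$pairs$drug_b[i]]]
    for (cell in b$train_cells) {
      act_set <- rownames(active)[active[, cell] == 1]
      ess_set <- rownames(essential)[essential[, cell] == 1]
      row <- tf[tf$pair_id == b$pairs$pair_id[i] & tf$cell_line_id == cell, ]
      expect_equal(row$n_cell_c_expression_D_union_ab,
                   length(intersect(union(ta, tb), act_set)))
      expect_equal(row$n_cell_c_essentiality_D_union_ab,
                   length(intersect(union(ta, tb), ess_set)))
      expect_equal(row$ratio_expr_union,
                   length(intersect(union(ta, tb), act_set)) /
                     max(1, length(act_set)))
    }
  }
  for (pw in names(b$pathways)) {
    for (cell in b$train_cells) {
      act_set <- rownames(active)[active[, cell] == 1]
      row <- pf[pf$pathway_id == pw & pf$cell_line_id == cell, ]
      expect_equal(row$n_cell_c_expression_kegg_k,
                   length(intersect(b$pathways[[pw]], act_set)))
    }
  }
})

test_that("ratio features always equal count over cell-line total", {
  b <- get_fixture("tiny")
  active <- call_active(b$presence)[, b$train_cells]
  essential <- call_essential(b$d2)
  pf <- build_pathway_features(b$pathways, active, essential)
  totals <- tibble::tibble(cell_line_id = colnames(active),
                           tot_e = colSums(active),
                           tot_s = colSums(essential))
  j <- dplyr::inner_join(pf, totals, by = "cell_line_id")
  expect_equal(j$ratio_expr_kegg_k,
               unname(ifelse(j$tot_e > 0, j$n_cell_c_expression_kegg_k / j$tot_e, 0)))
  expect_equal(j$ratio_ess_kegg_k,
               unname(ifelse(j$tot_s > 0, j$n_cell_c_essentiality_kegg_k / j$tot_s, 0)))
  expect_true(all(j$ratio_expr_kegg_k >= 0 & j$ratio_expr_kegg_k <= 1))
})

test_that("design assembly selects, drops and standardizes columns", {
  b <- get_fixture("tiny")
  syn <- score_synergy(b$dose)
  syn <- syn[syn$cell_line_id %in% b$train_cells, ]
  active <- call_active(b$presence)[, b$train_cells]
  essential <- call_essential(b$d2)
  tf <- build_target_features(b$pairs, b$targets, active, essential)
  pf <- build_pathway_features(b$pathways, active, essential)
  pair <- b$pairs$pair_id[1]
  pw <- names(b$pathways)[1]

  d2e <- assemble_design(tf, pf, syn, pair, "PA2", "expression", pw)
  expect_true(all(colnames(d2e$x) %in%
                    c("n_cell_c_expression_kegg_k", "ratio_expr_kegg_k")))
  expect_true("n_k" %in% d2e$dropped_constant)
  if (ncol(d2e$x) > 0) {
    expect_equal(unname(colMeans(d2e$x)), rep(0, ncol(d2e$x)),
                 tolerance = 1e-12)
    expect_equal(unname(apply(d2e$x, 2, sd)), rep(1, ncol(d2e$x)))
  }

  d1 <- assemble_design(tf, pf, syn, pair, "PA1", "combined")
  expect_true(all(c("n_D_union_ab", "n_D_intersection_ab") %in%
                    d1$dropped_constant))

  d3 <- assemble_design(tf, pf, syn, pair, "PA3", "combined", pw)
  expect_setequal(
    c(colnames(d3$x), d3$dropped_constant),
    c(type1_cols <- synergyscan:::type1_feature_cols(),
      synergyscan:::type2_feature_cols())
  )
  expect_error(assemble_design(tf, pf, syn, pair, "PA2", "expression"),
               "requires a pathway")
})

test_that("an all-constant design is flagged degenerate", {
  syn <- tibble::tibble(pair_id = "p1", cell_line_id = c("c1", "c2", "c3"),
                        status = c(0L, 1L, 0L))
  tf <- tibble::tibble(pair_id = "p1", cell_line_id = c("c1", "c2", "c3"))
  for (col in synergyscan:::type1_feature_cols()) tf[[col]] <- 1
  d <- assemble_design(tf, NULL, syn, "p1", "PA1", "combined")
  expect_true(d$degenerate)
  fit <- fit_logistic(d)
  expect_true(is.na(fit$p_value))
  expect_identical(fit$reason, "degenerate")
})
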
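# Feature-name registries. Type 1 = drug-target x cell-line features,
# type 2 = pathway x cell-line features. "neutral" columns do not depend
# on expression or essentiality (and are constant within a pair, so they
# never survive design assembly — kept for completeness of the table).
type1_feature_cols <- function() {
  c("n_D_union_ab", "n_D_intersection_ab",
    "n_cell_c_expression", "n_cell_c_essentiality",
    "n_cell_c_expression_D_union_ab", "n_cell_c_expression_D_intersection_ab",
    "ratio_expr_union", "ratio_expr_intersection",
    "n_cell_c_essentiality_D_union_ab", "n_cell_c_essentiality_D_intersection_ab",
    "ratio_ess_union", "ratio_ess_intersection")
}

type2_feature_cols <- function() {
  c("n_k",
    "n_cell_c_expression_kegg_k", "ratio_expr_kegg_k",
    "n_cell_c_essentiality_kegg_k", "ratio_ess_kegg_k")
}

essentiality_feature_cols <- function() {
  c("n_cell_c_essentiality",
    "n_cell_c_essentiality_D_union_ab", "n_cell_c_essentiality_D_intersection_ab",
    "ratio_ess_union", "ratio_ess_intersection",
    "n_cell_c_essentiality_kegg_k", "ratio_ess_kegg_k")
}

expression_feature_cols <- function() {
  c("n_cell_c_expression",
    "n_cell_c_expression_D_union_ab", "n_cell_c_expression_D_intersection_ab",
    "ratio_expr_union", "ratio_expr_intersection",
    "n_cell_c_expression_kegg_k", "ratio_expr_kegg_k")
}

mode_feature_cols <- function(cols, mode) {
  switch(mode,
    expression = setdiff(cols, essentiality_feature_cols()),
    essentiality = setdiff(cols, expression_feature_cols()),
    combined = cols,
    stop("unknown mode: ", mode, call. = FALSE)
  )
}

safe_ratio <- function(num, den) unname(ifelse(den > 0, num / den, 0))

#' Drug-target (type 1) features for one drug pair
#'
#' For each cell line, counts the drug-target genes of the pair (union and
#' intersection of the two drugs' target sets) that are active or
#' essential, plus per-cell totals and the four count/total ratios.
#' Counts are taken over the gene universe of the supplied call matrices
#' (typically the post-filter gene sets); target genes outside that
#' universe contribute nothing.
#'
#' @param drug_a,drug_b Drug identifiers (keys of `targets`).
#' @param targets Named list mapping drug id to a character vector of
#'   target gene symbols.
#' @param active 0/1 genes x cell-lines matrix from [call_active()].
#' @param essential 0/1 genes x cell-lines matrix from [call_essential()].
#' @return Tibble with one row per cell line and the type-1 feature
#'   columns.
#' @export
target_features <- function(drug_a, drug_b, targets, active, essential) {
  for (d in c(drug_a, drug_b)) {
    if (is.null(targets[[d]])) {
      stop("drug absent from target map: ", d, call. = FALSE)
    }
  }
  t_union <- union(targets[[drug_a]], targets[[drug_b]])
  t_inter <- intersect(targets[[drug_a]], targets[[drug_b]])
  cells <- colnames(active)

  count_in <- function(mat, genes) {
    genes <- intersect(genes, rownames(mat))
    if (length(genes) == 0L) return(stats::setNames(rep(0L, ncol(mat)), colnames(mat)))
    colSums(mat[genes, , drop = FALSE])
  }
  n_expr_tot <- colSums(active)
  n_ess_tot <- colSums(essential[, cells, drop = FALSE])
  n_expr_un <- count_in(active, t_union)
  n_expr_in <- count_in(active, t_inter)
  n_ess_un <- count_in(essential[, cells, drop = FALSE], t_union)
  n_ess_in <- count_in(essential[, cells, drop = FALSE], t_inter)

  tibble::tibble(
    cell_line_id = cells,
    n_D_union_ab = length(t_union),
    n_D_intersection_ab = length(t_inter),
    n_cell_c_expression = as.integer(n_expr_tot),
    n_cell_c_essentiality = as.integer(n_ess_tot),
    n_cell_c_expression_D_union_ab = as.integer(n_expr_un),
    n_cell_c_expression_D_intersection_ab = as.integer(n_expr_in),
    ratio_expr_union = safe_ratio(n_expr_un, n_expr_tot),
    ratio_expr_intersection = safe_ratio(n_expr_in, n_expr_tot),
    n_cell_c_essentiality_D_union_ab = as.integer(n_ess_un),
    n_cell_c_essentiality_D_intersection_ab = as.integer(n_ess_in),
    ratio_ess_union = safe_ratio(n_ess_un, n_ess_tot),
    ratio_ess_intersection = safe_ratio(n_ess_in, n_ess_tot)
  )
}

#' Pathway (type 2) features for one gene set
#'
#' For each cell line, counts the pathway's genes that are active or
#' essential and normalizes by the per-cell totals of active/essential
#' genes.
#'
#' @param pathway_genes Character vector of gene symbols in the pathway.
#' @param active,essential 0/1 genes x cell-lines matrices.
#' @return Tibble with one row per cell line and the type-2 feature
#'   columns (including `n_k`, the pathway size).
#' @export
pathway_features <- function(pathway_genes, active, essential) {
  cells <- colnames(active)
  in_expr <- intersect(pathway_genes, rownames(active))
  in_ess <- intersect(pathway_genes, rownames(essential))
  n_expr <- if (length(in_expr)) colSums(active[in_expr, , drop = FALSE]) else
    stats::setNames(rep(0L, length(cells)), cells)
  n_ess_cells <- colnames(essential)
  n_ess <- if (length(in_ess)) colSums(essential[in_ess, n_ess_cells, drop = FALSE]) else
    stats::setNames(rep(0L, length(n_ess_cells)), n_ess_cells)
  n_expr_tot <- colSums(active)
  n_ess_tot <- colSums(essential)

  tibble::tibble(
    cell_line_id = cells,
    n_k = length(pathway_genes),
    n_cell_c_expression_kegg_k = as.integer(n_expr[cells]),
    ratio_expr_kegg_k = safe_ratio(n_expr[cells], n_expr_tot[cells]),
    n_cell_c_essentiality_kegg_k = as.integer(n_ess[cells]),
    ratio_ess_kegg_k = safe_ratio(n_ess[cells], n_ess_tot[cells])
  )
}

#' Type-1 features for every drug pair
#'
#' @param pairs_df Tibble with columns `pair_id`, `drug_a`, `drug_b`.
#' @inheritParams target_features
#' @return Long tibble: one row per (pair, cell line) with type-1 columns.
#' @export
build_target_features <- function(pairs_df, targets, active, essential) {
  purrr::pmap_dfr(
    pairs_df[, c("pair_id", "drug_a", "drug_b")],
    function(pair_id, drug_a, drug_b) {
      dplyr::mutate(
        target_features(drug_a, drug_b, targets, active, essential),
        pair_id = pair_id, .before = 1
      )
    }
  )
}

#' Type-2 features for every pathway
#'
#' @param pathways Named list mapping pathway id to gene symbol vectors.
#' @inheritParams pathway_features
#' @return Long tibble: one row per (pathway, cell line) with type-2
#'   columns.
#' @export
build_pathway_features <- function(pathways, active, essential) {
  purrr::imap_dfr(pathways, function(genes, pid) {
    dplyr::mutate(pathway_features(genes, active, essential),
                  pathway_id = pid, .before = 1)
  })
}

#' Keep pathways containing at least one drug-target gene
#'
#' Only pathways that contain a target of some drug in the map enter the
#' pathway analyses.
#'
#' @param pathways Named list of gene sets.
#' @param targets Named list mapping drug id to target gene vectors.
#' @return The filtered named list.
#' @export
keep_target_pathways <- function(pathways, targets) {
  all_targets <- unique(unlist(targets, use.names = FALSE))
  pathways[purrr::map_lgl(pathways, ~ length(intersect(.x, all_targets)) > 0L)]
}

#' Assemble a per-pair design matrix for logistic fitting
#'
#' Selects the feature columns for the requested analysis (PA1 = type 1,
#' PA2 = type 2, PA3 = both) and mode (expression / essentiality /
#' combined), aligns rows with the pair's synergy calls, drops columns
#' that are constant across cell lines (e.g. `n_D_union_ab`, `n_k`, which
#' never vary within a pair) and standardizes the remainder to zero mean
#' and unit variance. Fitted p-values are invariant to the affine
#' rescaling; standardization only conditions the optimization.
#'
#' @param target_feats Tibble from [build_target_features()] (may be
#'   `NULL` for PA2).
#' @param pathway_feats Tibble from [build_pathway_features()] (may be
#'   `NULL` for PA1).
#' @param synergy_df Tibble from [score_synergy()].
#' @param pair One `pair_id`.
#' @param analysis `"PA1"`, `"PA2"` or `"PA3"`.
#' @param mode `"expression"`, `"essentiality"` or `"combined"`.
#' @param pathway One `pathway_id` (required for PA2/PA3).
#' @return An object of class `synergy_design`: list with `x`
#'   (standardized numeric matrix, possibly zero columns), `response`
#'   (0/1 vector), `cell_lines`, `dropped_constant`, `degenerate` flag
#'   and the identifying metadata.
#' @export
assemble_design <- function(target_feats, pathway_feats, synergy_df, pair,
                            analysis = c("PA1", "PA2", "PA3"),
                            mode = c("expression", "essentiality", "combined"),
                            pathway = NULL) {
  analysis <- match.arg(analysis)
  mode <- match.arg(mode)
  if (analysis %in% c("PA2", "PA3") && is.null(pathway)) {
    stop(analysis, " requires a pathway id", call. = FALSE)
  }

  syn <- synergy_df[synergy_df$pair_id == pair, ]
  if (nrow(syn) == 0L) stop("no synergy records for pair ", pair, call. = FALSE)

  feats <- NULL
  if (analysis %in% c("PA1", "PA3")) {
    t1 <- target_feats[target_feats$pair_id == pair,
                       c("cell_line_id", type1_feature_cols())]
    feats <- t1
  }
  if (analysis %in% c("PA2", "PA3")) {
    t2 <- pathway_feats[pathway_feats$pathway_id == pathway,
                        c("cell_line_id", type2_feature_cols())]
    feats <- if (is.null(feats)) t2 else dplyr::inner_join(feats, t2, by = "cell_line_id")
  }

  keep_cols <- mode_feature_cols(setdiff(names(feats), "cell_line_id"), mode)
  merged <- dplyr::inner_join(syn[, c("cell_line_id", "status")], feats,
                              by = "cell_line_id")
  x <- as.matrix(merged[, keep_cols, drop = FALSE])
  rownames(x) <- merged$cell_line_id

  sds <- apply(x, 2, stats::sd)
  constant <- is.na(sds) | sds == 0
  dropped <- colnames(x)[constant]
  x <- x[, !constant, drop = FALSE]
  if (ncol(x) > 0L) x <- scale(x)

  structure(
    list(
      x = x,
      response = merged$status,
      cell_lines = merged$cell_line_id,
      dropped_constant = dropped,
      degenerate = ncol(x) == 0L,
      pair_id = pair, analysis = analysis, mode = mode,
      pathway_id = pathway %||% NA_character_
    ),
    class = "synergy_design"
  )
}

#' @export
print.synergy_design <- function(x, ...) {
  cat(sprintf("synergy_design %s/%s pair=%s%s: %d cells x %d columns",
              x$analysis, x$mode, x$pair_id,
              if (!is.na(x$pathway_id)) paste0(" pathway=", x$pathway_id) else "",
              length(x$response), ncol(x$x)))
  if (length(x$dropped_constant)) {
    cat("\n  dropped constant:", paste(x$dropped_constant, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}
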
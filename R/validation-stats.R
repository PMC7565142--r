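#' Two-sided Wilcoxon rank-sum test
#'
#' Wraps the Mann-Whitney/Wilcoxon rank-sum test with an explicit
#' exact/approximate switch: the exact null distribution is used when the
#' pooled sample is tie-free and has at most `exact_limit` observations,
#' otherwise the normal approximation with tie and continuity corrections
#' is used. The method actually applied is always reported.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_limit Largest pooled sample size for the exact method;
#'   default 20.
#' @return List of class `wilcoxon_result`: `statistic` (the
#'   Mann-Whitney U for `x`), `p_two_sided`, `method` (`"exact"` or
#'   `"normal_approx"`), `n1`, `n2`. Empty input gives `NA` results.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))      # exact p = 1/3
#' wilcoxon_rank_sum(1:3, 4:6)              # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 20) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) {
    return(structure(list(statistic = NA_real_, p_two_sided = NA_real_,
                          method = NA_character_, n1 = n1, n2 = n2),
                     class = "wilcoxon_result"))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !has_ties && (n1 + n2) <= exact_limit
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  structure(
    list(statistic = unname(wt$statistic),
         p_two_sided = min(wt$p.value, 1),
         method = if (use_exact) "exact" else "normal_approx",
         n1 = n1, n2 = n2),
    class = "wilcoxon_result"
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: U = %s, two-sided p = %.4g (%s; n1 = %d, n2 = %d)\n",
              format(x$statistic), x$p_two_sided, x$method, x$n1, x$n2))
  invisible(x)
}

#' @method glance wilcoxon_result
#' @export
glance.wilcoxon_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_two_sided = x$p_two_sided,
                 method = x$method, n1 = x$n1, n2 = x$n2)
}

#' Validate a pathway signal on a hold-out cohort
#'
#' Compares the number of active pathway genes per cell line between the
#' synergistic and non-synergistic cell lines of one drug pair with a
#' two-sided Wilcoxon rank-sum test. The validation cohort has
#' expression data only, so the single feature tested is the pathway
#' active-gene count (not the ratio).
#'
#' @param pair One `pair_id`.
#' @param pathway_genes Character vector of the pathway's gene symbols.
#' @param active 0/1 genes x cell-lines matrix for the cohort.
#' @param synergy_df Synergy calls from [score_synergy()] for the same
#'   cohort.
#' @return Tibble with `pair_id`, `n_synergy`, `n_no_synergy`,
#'   `statistic`, `p`, `method`. If either group is empty the test
#'   columns are `NA` and a warning is raised.
#' @export
validate_pathway <- function(pair, pathway_genes, active, synergy_df) {
  syn <- synergy_df[synergy_df$pair_id == pair, ]
  cells <- intersect(syn$cell_line_id, colnames(active))
  syn <- syn[match(cells, syn$cell_line_id), ]
  genes <- intersect(pathway_genes, rownames(active))
  counts <- if (length(genes)) colSums(active[genes, cells, drop = FALSE]) else
    stats::setNames(rep(0, length(cells)), cells)
  x <- counts[syn$status == 1]
  y <- counts[syn$status == 0]
  if (length(x) == 0L || length(y) == 0L) {
    warning("pair ", pair, ": a synergy group is empty (",
            length(x), " synergistic, ", length(y), " non-synergistic); ",
            "no test performed", call. = FALSE)
    return(tibble::tibble(pair_id = pair, n_synergy = length(x),
                          n_no_synergy = length(y), statistic = NA_real_,
                          p = NA_real_, method = NA_character_))
  }
  wt <- wilcoxon_rank_sum(x, y)
  tibble::tibble(pair_id = pair, n_synergy = length(x),
                 n_no_synergy = length(y), statistic = wt$statistic,
                 p = wt$p_two_sided, method = wt$method)
}
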
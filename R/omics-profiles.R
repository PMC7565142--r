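#' Gene activity calls from presence/marginal/absent codes
#'
#' A gene is active in a cell line when its detection call is present
#' (`"P"`). Marginal (`"M"`) calls are treated as inactive by default —
#' only confident detection counts as activity — but can be flipped with
#' `marginal_active`.
#'
#' @param presence Character matrix (genes x cell lines) of `P`/`M`/`A`
#'   calls, with dimnames.
#' @param marginal_active Treat `M` as active? Default `FALSE`.
#' @return Integer 0/1 matrix with the same dimnames.
#' @export
call_active <- function(presence, marginal_active = FALSE) {
  presence <- as.matrix(presence)
  bad <- setdiff(unique(as.vector(presence)), c("P", "M", "A"))
  if (length(bad) > 0L) {
    stop("unknown presence call code(s): ", paste(bad, collapse = ", "),
         " (expected P, M or A)", call. = FALSE)
  }
  codes <- if (marginal_active) c("P", "M") else "P"
  out <- matrix(as.integer(presence %in% codes), nrow = nrow(presence),
                dimnames = dimnames(presence))
  out
}

#' Essentiality calls from D2 dependency scores
#'
#' A gene is essential in a cell line when its D2 dependency score falls
#' strictly below the threshold (default -0.5). D2 scores are normalized
#' so reference essential genes average about -1 and controls about 0;
#' a score of exactly -0.5 is non-essential.
#'
#' @param d2 Numeric matrix (genes x cell lines) of D2 scores.
#' @param threshold Essentiality cutoff; default -0.5.
#' @return Integer 0/1 matrix with the same dimnames.
#' @export
call_essential <- function(d2, threshold = -0.5) {
  d2 <- as.matrix(d2)
  out <- matrix(as.integer(d2 < threshold), nrow = nrow(d2),
                dimnames = dimnames(d2))
  out
}

#' Filter genes for association analysis
#'
#' Expression genes are kept when they are active in more than
#' `min_active_fraction` of the cell lines (strictly more than 0.2 x 43 =
#' 8.6, i.e. at least 9 of 43) AND their coefficient of variation
#' (sd/mean of the normalized expression values across cell lines) is at
#' least `min_cv`. Genes whose mean expression is non-positive have no
#' defined CV and are excluded under the CV rule. Essentiality genes are
#' kept when essential in at least one cell line (`essential_rule =
#' "any"`); `"all"` keeps only pan-essential genes.
#'
#' @param values Numeric matrix (genes x cell lines) of normalized
#'   expression.
#' @param active 0/1 matrix from [call_active()], same shape as `values`.
#' @param essential 0/1 matrix from [call_essential()] (genes x cell
#'   lines; gene universe may differ from `values`).
#' @param min_active_fraction Minimum active fraction (exclusive bound);
#'   default 0.2.
#' @param min_cv Minimum coefficient of variation (inclusive bound);
#'   default 0.1.
#' @param essential_rule `"any"` (default) or `"all"`.
#' @return A list of class `gene_filter_report` with
#'   `retained_expression`, `retained_essentiality` (character vectors)
#'   and `excluded`, a tibble of per-rule exclusion counts
#'   (`low_presence`, `low_cv`, `never_essential`).
#' @export
filter_genes <- function(values, active, essential,
                         min_active_fraction = 0.2, min_cv = 0.1,
                         essential_rule = c("any", "all")) {
  essential_rule <- match.arg(essential_rule)
  values <- as.matrix(values)
  active <- as.matrix(active)
  stopifnot(identical(dim(values), dim(active)))
  n_cells <- ncol(values)

  n_active <- rowSums(active)
  pass_presence <- n_active > min_active_fraction * n_cells
  mu <- rowMeans(values)
  cv <- ifelse(mu > 0, apply(values, 1, stats::sd) / mu, NA_real_)
  pass_cv <- !is.na(cv) & cv >= min_cv

  retained_expression <- rownames(values)[pass_presence & pass_cv]
  low_presence <- sum(!pass_presence)
  # CV rule counted on genes that survive the presence rule
  low_cv <- sum(pass_presence & !pass_cv)

  essential <- as.matrix(essential)
  n_ess <- rowSums(essential)
  pass_ess <- if (essential_rule == "any") n_ess >= 1L else n_ess == ncol(essential)
  retained_essentiality <- rownames(essential)[pass_ess]
  never_essential <- sum(!pass_ess)

  structure(
    list(
      retained_expression = retained_expression,
      retained_essentiality = retained_essentiality,
      excluded = tibble::tibble(
        rule = c("low_presence", "low_cv", "never_essential"),
        n_excluded = c(low_presence, low_cv, never_essential)
      )
    ),
    class = "gene_filter_report"
  )
}

#' @export
print.gene_filter_report <- function(x, ...) {
  cat("Gene filter report\n")
  cat("  retained expression genes:  ", length(x$retained_expression), "\n")
  cat("  retained essentiality genes:", length(x$retained_essentiality), "\n")
  ex <- x$excluded
  for (i in seq_len(nrow(ex))) {
    cat(sprintf("  excluded (%s): %d\n", ex$rule[i], ex$n_excluded[i]))
  }
  invisible(x)
}
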
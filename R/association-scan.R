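# Firth-penalized logistic regression (Jeffreys-prior bias reduction).
# Used as fallback when the plain ML fit separates or fails to converge:
# the penalized likelihood always has a finite maximizer. X includes the
# intercept column.
firth_fit <- function(X, y, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen_loglik <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X * w, X)
    ld <- determinant(info, logarithm = TRUE)
    sum(y * eta - log1p(exp(eta))) + 0.5 * as.numeric(ld$modulus)
  }
  ll <- pen_loglik(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((XW %*% inv) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    delta <- drop(inv %*% score)
    # step-halving to keep the penalized likelihood increasing
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- pen_loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta <- beta + step * delta
    ll <- pen_loglik(beta)
  }
  list(coefficients = beta, pen_loglik = ll, converged = converged)
}

#' Fit a per-pair logistic association model and extract one p-value
#'
#' Fits `status ~ features` by maximum likelihood. With a single predictor
#' the reported p-value is the two-sided Wald test of its slope; with
#' several predictors it is the likelihood-ratio test of the full model
#' against the intercept-only model. When the ML fit separates or fails
#' to converge (common at 43 cell lines with few synergy events), the
#' model is refit with Firth's Jeffreys-prior penalization and a
#' penalized likelihood-ratio p is reported with `converged = FALSE` on
#' the ML path flagged via `method = "firth_lrt"`.
#'
#' @param design A [`synergy_design`][assemble_design] object, or a
#'   numeric matrix of predictors.
#' @param response 0/1 vector (ignored when `design` is a
#'   `synergy_design`).
#' @return Object of class `synergy_logit`: list with `p_value`, `df`,
#'   `method` (`"wald"`, `"lrt"`, `"firth_lrt"` or `NA`), `converged`,
#'   `n_events`, `coefficients` and `reason` (NA, `"degenerate"` or
#'   `"no_events"`).
#' @export
fit_logistic <- function(design, response = NULL) {
  if (inherits(design, "synergy_design")) {
    x <- design$x
    y <- design$response
  } else {
    x <- as.matrix(design)
    y <- response
  }
  res <- list(p_value = NA_real_, df = NA_integer_, method = NA_character_,
              converged = NA, n_events = sum(y == 1),
              coefficients = NULL, reason = NA_character_)
  class(res) <- "synergy_logit"

  # drop any residual constant columns, then aliased ones in declared order
  if (ncol(x) > 0L) {
    sds <- apply(x, 2, stats::sd)
    x <- x[, !(is.na(sds) | sds == 0), drop = FALSE]
  }
  if (ncol(x) > 1L) {
    keep <- logical(ncol(x))
    X_acc <- matrix(1, nrow(x), 1)
    for (j in seq_len(ncol(x))) {
      cand <- cbind(X_acc, x[, j])
      if (qr(cand)$rank == ncol(cand)) {
        keep[j] <- TRUE
        X_acc <- cand
      }
    }
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L) { res$reason <- "degenerate"; return(res) }
  if (length(unique(y)) < 2L) { res$reason <- "no_events"; return(res) }

  X <- cbind(`(Intercept)` = 1, x)
  k <- ncol(x)

  separated <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = 100)),
      error = function(e) NULL
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  ok <- !is.null(fit) && fit$converged && !separated &&
    max(abs(fit$coefficients), na.rm = TRUE) < 15

  if (ok) {
    res$converged <- TRUE
    res$coefficients <- fit$coefficients
    res$df <- k
    if (k == 1L) {
      rank <- fit$rank
      covmat <- chol2inv(fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE])
      se <- sqrt(diag(covmat))
      z <- fit$coefficients[2] / se[2]
      res$p_value <- 2 * stats::pnorm(-abs(z))
      res$method <- "wald"
    } else {
      stat <- fit$null.deviance - fit$deviance
      res$p_value <- stats::pchisq(max(stat, 0), df = k, lower.tail = FALSE)
      res$method <- "lrt"
    }
    return(res)
  }

  # Firth fallback: penalized LRT of full vs intercept-only model
  full <- firth_fit(X, y)
  null <- firth_fit(matrix(1, length(y), 1), y)
  res$converged <- FALSE
  res$method <- "firth_lrt"
  res$coefficients <- stats::setNames(full$coefficients, colnames(X))
  res$df <- k
  stat <- 2 * (full$pen_loglik - null$pen_loglik)
  res$p_value <- stats::pchisq(max(stat, 0), df = k, lower.tail = FALSE)
  res
}

#' @export
print.synergy_logit <- function(x, ...) {
  cat("synergy_logit:",
      if (is.na(x$p_value)) paste0("p = NA (", x$reason, ")")
      else sprintf("p = %.4g (%s, df = %d)", x$p_value, x$method, x$df),
      "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy synergy_logit
#' @export
tidy.synergy_logit <- function(x, ...) {
  if (is.null(x$coefficients)) return(tibble::tibble(term = character(), estimate = numeric()))
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @method glance synergy_logit
#' @export
glance.synergy_logit <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, df = x$df, method = x$method,
                 converged = x$converged, n_events = x$n_events,
                 reason = x$reason)
}

fit_to_row <- function(fit) {
  tibble::tibble(p_value = fit$p_value, df = fit$df, method = fit$method,
                 converged = fit$converged, n_events = fit$n_events)
}

#' Minimum-p aggregation over a grouping key
#'
#' Summarizes a results table to one row per unit, carrying the minimum
#' p-value over the other key (`NA` p-values are ignored; all-`NA` groups
#' yield `NA`). The minimum never exceeds any contributing p-value.
#'
#' @param results Tibble with a `p_value` column.
#' @param unit Name of the column defining the unit (e.g. `"unit_id"` for
#'   genes, `"pair_id"` for drug pairs).
#' @param argmin Name of the column identifying the minimizer (e.g.
#'   `"pair_id"` or `"unit_id"`).
#' @return Tibble with columns `<unit>`, `overall_p`, `argmin`.
#' @export
aggregate_min_p <- function(results, unit = "unit_id", argmin = "pair_id") {
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(unit))) |>
    dplyr::summarise(
      overall_p = if (all(is.na(.data$p_value))) NA_real_ else
        min(.data$p_value, na.rm = TRUE),
      argmin = if (all(is.na(.data$p_value))) NA_character_ else
        as.character(.data[[argmin]][which.min(.data$p_value)]),
      .groups = "drop"
    )
}

#' Gene-level association scan
#'
#' For each retained gene and each selected drug pair, fits a
#' single-predictor logistic model of synergy status on the gene's score
#' (normalized expression or D2 essentiality) across the training cell
#' lines, and aggregates per gene by minimum p over pairs.
#'
#' @param values Numeric genes x cell-lines matrix of gene scores,
#'   restricted to the retained gene set.
#' @param synergy_df Tibble from [score_synergy()] for the training
#'   cohort.
#' @param pairs Character vector of pair ids (from
#'   [select_combinations()]).
#' @param mode Label stored in the results (`"expression"` or
#'   `"essentiality"`).
#' @return Object of class `synergy_scan`: list with `results` (one row
#'   per gene x pair) and `overall` (one row per gene, min-p).
#' @export
gene_scan <- function(values, synergy_df, pairs, mode = "expression") {
  genes <- rownames(values)
  rows <- purrr::map_dfr(pairs, function(pr) {
    syn <- synergy_df[synergy_df$pair_id == pr, ]
    cells <- intersect(syn$cell_line_id, colnames(values))
    y <- syn$status[match(cells, syn$cell_line_id)]
    purrr::map_dfr(genes, function(g) {
      x <- matrix(values[g, cells], ncol = 1, dimnames = list(cells, g))
      fit <- fit_logistic(scale_if_var(x), y)
      dplyr::mutate(fit_to_row(fit), level = "gene", mode = mode,
                    pair_id = pr, unit_id = g, .before = 1)
    })
  })
  new_synergy_scan(rows, aggregate_min_p(rows, "unit_id", "pair_id"),
                   level = "gene", analysis = "gene", mode = mode)
}

scale_if_var <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x)
  scale(x)
}

new_synergy_scan <- function(results, overall, level, analysis, mode) {
  structure(list(results = results, overall = overall),
            class = "synergy_scan",
            level = level, analysis = analysis, mode = mode)
}

#' @export
print.synergy_scan <- function(x, ...) {
  cat(sprintf("synergy_scan (%s, %s, %s): %d fits, %d units\n",
              attr(x, "analysis"), attr(x, "mode"), attr(x, "level"),
              nrow(x$results), nrow(x$overall)))
  invisible(x)
}

#' @method tidy synergy_scan
#' @export
tidy.synergy_scan <- function(x, ...) x$results

#' @method glance synergy_scan
#' @export
glance.synergy_scan <- function(x, ...) {
  tibble::tibble(
    analysis = attr(x, "analysis"), mode = attr(x, "mode"),
    n_fits = nrow(x$results),
    n_na = sum(is.na(x$results$p_value)),
    min_p = suppressWarnings(min(x$results$p_value, na.rm = TRUE))
  )
}

#' Pathway association scan (Pathway Analyses 1-3)
#'
#' PA1 fits one model per drug pair on the type-1 (drug-target) features;
#' PA2 one model per (pair, pathway) on the type-2 (pathway) features;
#' PA3 one model per (pair, pathway) on both feature families. The
#' drug-pair (DD) level p-value is the minimum over pathways for each
#' pair (PA1's single p passes through).
#'
#' @param analysis `"PA1"`, `"PA2"` or `"PA3"`.
#' @param mode `"expression"`, `"essentiality"` or `"combined"`.
#' @param target_feats Tibble from [build_target_features()] (`NULL` ok
#'   for PA2).
#' @param pathway_feats Tibble from [build_pathway_features()] (`NULL` ok
#'   for PA1).
#' @param synergy_df Training synergy calls from [score_synergy()].
#' @param pairs Character vector of pair ids.
#' @param pathways Character vector of pathway ids (ignored for PA1).
#' @return Object of class `synergy_scan`: `results` holds the
#'   pair-pathway (DDP) level rows, `overall` the pair (DD) level min-p
#'   rows.
#' @export
pathway_scan <- function(analysis, mode, target_feats, pathway_feats,
                         synergy_df, pairs, pathways = NULL) {
  analysis <- match.arg(analysis, c("PA1", "PA2", "PA3"))
  mode <- match.arg(mode, c("expression", "essentiality", "combined"))
  units <- if (analysis == "PA1") NA_character_ else pathways
  rows <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(units, function(pw) {
      d <- assemble_design(target_feats, pathway_feats, synergy_df, pr,
                           analysis, mode,
                           pathway = if (is.na(pw)) NULL else pw)
      fit <- fit_logistic(d)
      dplyr::mutate(fit_to_row(fit), level = "DDP", mode = mode,
                    analysis = analysis, pair_id = pr, unit_id = pw,
                    .before = 1)
    })
  })
  overall <- aggregate_min_p(rows, "pair_id", "unit_id")
  new_synergy_scan(rows, overall, level = "DD", analysis = analysis,
                   mode = mode)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate; default 0.05.
#' @param m Number of tests.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 165 * 114)
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Expected/observed FDR from counts
#'
#' For a p-value threshold `t` over `n_tests` tests, the expected number
#' of significant results under the global null is `t * n_tests` (rounded
#' to two decimals, the precision of the reported tables) and the FDR is
#' expected / observed. `fdr_raw` uses the unrounded expected count.
#'
#' @param n_observed Count of results with p at or below the threshold.
#' @param threshold The p-value threshold.
#' @param n_tests Number of tests in the family (the design count, not
#'   the non-`NA` count).
#' @return Tibble with `threshold`, `n_observed`, `n_expected`, `fdr`,
#'   `fdr_raw` (both `NA` when nothing is observed).
#' @export
fdr_from_counts <- function(n_observed, threshold, n_tests) {
  n_expected <- round(threshold * n_tests, 2)
  tibble::tibble(
    threshold = threshold,
    n_observed = as.integer(n_observed),
    n_expected = n_expected,
    fdr = ifelse(n_observed > 0, n_expected / n_observed, NA_real_),
    fdr_raw = ifelse(n_observed > 0, threshold * n_tests / n_observed, NA_real_)
  )
}

#' Expected/observed FDR table for a p-value collection
#'
#' @param p_values Numeric vector of p-values (`NA` entries are excluded
#'   from the observed counts but `n_tests` stays at the design count).
#' @param thresholds P-value thresholds; default `c(1e-4, 1e-3, 1e-2)`.
#' @param n_tests Number of tests; defaults to `length(p_values)`.
#' @return Tibble with one row per threshold: `threshold`, `n_observed`
#'   (count of p at or below the threshold), `n_expected`
#'   (`threshold * n_tests`, rounded to 2 decimals), `fdr`
#'   (expected/observed, `NA` when nothing observed) and `fdr_raw`
#'   (unrounded expected over observed).
#' @export
fdr_table <- function(p_values, thresholds = c(1e-4, 1e-3, 1e-2),
                      n_tests = length(p_values)) {
  stopifnot(n_tests >= sum(!is.na(p_values)))
  purrr::map_dfr(thresholds, function(t) {
    fdr_from_counts(sum(p_values <= t, na.rm = TRUE), t, n_tests)
  })
}

#' Venn counts of significant units across modalities
#'
#' Counts units with overall p at or below the threshold in the
#' expression scan, the essentiality scan, and both.
#'
#' @param overall_expr,overall_ess Tibbles with `unit_id`-like first key
#'   column and `overall_p` (the `overall` element of a
#'   [`synergy_scan`][gene_scan]), or `synergy_scan` objects.
#' @param threshold Significance threshold; default 0.001.
#' @return Tibble with `n_expr_only`, `n_ess_only`, `n_both`.
#' @export
significant_overlap <- function(overall_expr, overall_ess, threshold = 0.001) {
  get_sig <- function(x) {
    if (inherits(x, "synergy_scan")) x <- x$overall
    key <- names(x)[1]
    as.character(x[[key]][!is.na(x$overall_p) & x$overall_p <= threshold])
  }
  sig_e <- get_sig(overall_expr)
  sig_s <- get_sig(overall_ess)
  tibble::tibble(
    n_expr_only = length(setdiff(sig_e, sig_s)),
    n_ess_only = length(setdiff(sig_s, sig_e)),
    n_both = length(intersect(sig_e, sig_s))
  )
}

#' Correlation of p-values between expression and essentiality
#'
#' @param p_expr,p_ess Paired numeric p-value vectors over matched
#'   (pair, pathway) keys; pairs with an `NA` in either are dropped.
#' @return Tibble with `pearson_r`, `spearman_rho` and the number of
#'   complete pairs `n` (`NA` coefficients when `n < 3`).
#' @export
modality_correlation <- function(p_expr, p_ess) {
  stopifnot(length(p_expr) == length(p_ess))
  keep <- !is.na(p_expr) & !is.na(p_ess)
  x <- p_expr[keep]; y <- p_ess[keep]
  n <- length(x)
  if (n < 3L) {
    return(tibble::tibble(pearson_r = NA_real_, spearman_rho = NA_real_, n = n))
  }
  tibble::tibble(
    pearson_r = stats::cor(x, y, method = "pearson"),
    spearman_rho = stats::cor(x, y, method = "spearman"),
    n = n
  )
}

#' Compare association strength between target and non-target units
#'
#' For each drug pair, units (genes or pathways) are labeled "target"
#' when they belong to — or, for pathways, contain at least one gene of —
#' the union of the pair's two target sets, and "non_target" otherwise.
#' Summarizes the -log10 p distributions per group and compares them with
#' a two-sided Wilcoxon rank-sum test.
#'
#' @param results Tibble with `pair_id`, `unit_id`, `p_value` (the
#'   `results` element of a [`synergy_scan`][gene_scan]).
#' @param pairs_df Tibble with `pair_id`, `drug_a`, `drug_b`.
#' @param targets Named list mapping drug id to target gene vectors.
#' @param pathways Named list of pathway gene sets; supply when
#'   `unit_id` is a pathway id, leave `NULL` for gene units.
#' @return List of class `target_group_comparison`: `summary` (per-group
#'   n and quartiles of -log10 p), `p_value`, `statistic`, `method`.
#' @export
compare_target_groups <- function(results, pairs_df, targets, pathways = NULL) {
  if (inherits(results, "synergy_scan")) results <- results$results
  lab <- purrr::pmap_chr(
    results[, c("pair_id", "unit_id")],
    function(pair_id, unit_id) {
      row <- pairs_df[pairs_df$pair_id == pair_id, ]
      t_union <- union(targets[[row$drug_a[1]]], targets[[row$drug_b[1]]])
      is_target <- if (is.null(pathways)) {
        unit_id %in% t_union
      } else {
        length(intersect(pathways[[unit_id]], t_union)) > 0L
      }
      if (is_target) "target" else "non_target"
    }
  )
  df <- tibble::tibble(group = lab, neglog10_p = -log10(results$p_value))
  df <- df[!is.na(df$neglog10_p), ]
  smry <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$neglog10_p, 0.25),
      median = stats::median(.data$neglog10_p),
      q3 = stats::quantile(.data$neglog10_p, 0.75),
      .groups = "drop"
    )
  x <- df$neglog10_p[df$group == "target"]
  y <- df$neglog10_p[df$group == "non_target"]
  wt <- if (length(x) == 0L || length(y) == 0L) {
    list(statistic = NA_real_, p_two_sided = NA_real_, method = NA_character_)
  } else {
    wilcoxon_rank_sum(x, y)
  }
  structure(list(summary = smry, statistic = wt$statistic,
                 p_value = wt$p_two_sided, method = wt$method),
            class = "target_group_comparison")
}

#' @export
print.target_group_comparison <- function(x, ...) {
  cat("Target vs non-target comparison (-log10 p)\n")
  print(x$summary)
  cat(sprintf("rank-sum p = %.4g (%s)\n", x$p_value, x$method))
  invisible(x)
}
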
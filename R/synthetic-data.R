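#' Configuration for the synthetic drug-combination study
#'
#' Defaults mirror the dimensions of the real study: 43 training and 16
#' validation cell lines, 165 pathways, 69 drugs, 114 drug pairs, a 3x3
#' dose grid. Synergy is planted at the (pair, cell line) level through a
#' causal pathway's active-gene count (a type-2 expression feature):
#' `logit P(S = 1) = beta0 + beta1 * z`, where `z` is the standardized
#' count, and combination wells deviate from Bliss expectation by `delta`
#' score units when `S = 1`.
#'
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param n_train_cells,n_valid_cells Cohort sizes (43 / 16).
#' @param n_genes,n_pathways,n_drugs,n_pairs Universe sizes
#'   (3000 / 165 / 69 / 114).
#' @param pathway_size_range Uniform range of pathway sizes (20-200).
#' @param targets_per_drug Uniform range of targets per drug (1-6).
#' @param dose_grid Integer vector `c(p, q)` of dose levels per drug.
#' @param presence_shape1,presence_shape2 Beta parameters of the per-gene
#'   probability of a present (`P`) call.
#' @param marginal_fraction Fraction of non-present calls coded `M`.
#' @param expr_meanlog_range,expr_sdlog_range Per-gene log-normal
#'   location/scale ranges for expression intensities.
#' @param d2_background_mean,d2_background_sd D2 score distribution in
#'   non-essential cells (-0.1, 0.25).
#' @param d2_essential_mean,d2_essential_sd D2 scores in essential cells
#'   (-0.8, 0.2).
#' @param essential_fraction_shape1,essential_fraction_shape2 Beta
#'   parameters of the per-gene fraction of cells where it is essential.
#' @param causal_fraction Share of pairs with a planted causal pathway.
#' @param beta0,beta1 Logit intercept and slope on the standardized
#'   causal pathway feature.
#' @param delta Bliss-deviation magnitude (score units) in synergistic
#'   wells; default 30.
#' @param well_noise_sd Gaussian noise added to combination wells
#'   (growth-fraction units); default 5.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_train_cells = 43, n_valid_cells = 16,
                       n_genes = 3000, n_pathways = 165,
                       pathway_size_range = c(20, 200),
                       n_drugs = 69, targets_per_drug = c(1, 6),
                       n_pairs = 114, dose_grid = c(3, 3),
                       presence_shape1 = 2, presence_shape2 = 2,
                       marginal_fraction = 0.05,
                       expr_meanlog_range = c(4, 8),
                       expr_sdlog_range = c(0.2, 0.8),
                       d2_background_mean = -0.1, d2_background_sd = 0.25,
                       d2_essential_mean = -0.8, d2_essential_sd = 0.2,
                       essential_fraction_shape1 = 1,
                       essential_fraction_shape2 = 9,
                       causal_fraction = 0.3,
                       beta0 = -1.5, beta1 = 1.2,
                       delta = 30, well_noise_sd = 5) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_train_cells >= 1, n_valid_cells >= 0, n_genes >= 1,
              n_pathways >= 1, n_drugs >= 2, n_pairs >= 1,
              all(dose_grid >= 1), causal_fraction >= 0, causal_fraction <= 1,
              marginal_fraction >= 0, marginal_fraction <= 1,
              delta >= 0, well_noise_sd >= 0)
  })
  if (max(cfg$pathway_size_range) > cfg$n_genes) {
    stop("infeasible config: pathway_size_range exceeds n_genes", call. = FALSE)
  }
  if (cfg$n_pairs > choose(cfg$n_drugs, 2)) {
    stop("infeasible config: more pairs requested than distinct drug pairs",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a complete synthetic drug-combination study
#'
#' Generates expression values with presence calls, D2 essentiality
#' scores (training cohort only — the validation cohort has expression
#' data alone), drug-target sets, pathway gene sets, and a long-format
#' dose-response table with planted pathway-driven synergy, together with
#' a ground-truth record. Monotherapy growth fractions come from
#' per-(drug, cell) decreasing logistic dose-response curves and lie in
#' (0, 100); combination wells equal the Bliss expectation plus
#' `delta * S` plus Gaussian noise, so a synergistic (pair, cell) scores
#' about `+delta` and scoring recovers the planted labels up to noise.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, all input files plus the
#'   ground-truth sidecar are written there (see [write_bundle()]).
#' @return List of class `synergy_bundle` with elements `expression`,
#'   `presence` (genes x all cells), `d2` (genes x training cells),
#'   `targets`, `pathways` (named lists), `pairs` (tibble), `dose`
#'   (long tibble), `train_cells`, `valid_cells`, `truth` (list with
#'   `causal`, `labels`, `genes`, `frac_negative_wells`) and `config`.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  c(n_genes, n_pathways, n_drugs, n_pairs) %<-% config[
    c("n_genes", "n_pathways", "n_drugs", "n_pairs")]

  genes <- sprintf("g%04d", seq_len(n_genes))
  train_cells <- sprintf("TCL%02d", seq_len(config$n_train_cells))
  valid_cells <- if (config$n_valid_cells > 0)
    sprintf("VCL%02d", seq_len(config$n_valid_cells)) else character(0)
  cells <- c(train_cells, valid_cells)
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  pw_ids <- sprintf("pw%03d", seq_len(n_pathways))

  # expression + presence calls
  prevalence <- stats::rbeta(n_genes, config$presence_shape1, config$presence_shape2)
  pres_draw <- matrix(stats::runif(n_genes * length(cells)), n_genes)
  marg_draw <- matrix(stats::runif(n_genes * length(cells)), n_genes)
  presence <- matrix("A", n_genes, length(cells), dimnames = list(genes, cells))
  presence[pres_draw < prevalence] <- "P"
  presence[pres_draw >= prevalence & marg_draw < config$marginal_fraction] <- "M"

  meanlog <- stats::runif(n_genes, config$expr_meanlog_range[1],
                          config$expr_meanlog_range[2])
  sdlog <- stats::runif(n_genes, config$expr_sdlog_range[1],
                        config$expr_sdlog_range[2])
  expression <- matrix(
    stats::rlnorm(n_genes * length(cells), meanlog, sdlog),
    n_genes, length(cells), dimnames = list(genes, cells)
  )

  # D2 essentiality, training cohort only
  ess_frac <- stats::rbeta(n_genes, config$essential_fraction_shape1,
                           config$essential_fraction_shape2)
  ess_draw <- matrix(stats::runif(n_genes * length(train_cells)), n_genes)
  is_ess <- ess_draw < ess_frac
  d2 <- matrix(
    stats::rnorm(n_genes * length(train_cells),
                 mean = ifelse(is_ess, config$d2_essential_mean,
                               config$d2_background_mean),
                 sd = ifelse(is_ess, config$d2_essential_sd,
                             config$d2_background_sd)),
    n_genes, length(train_cells), dimnames = list(genes, train_cells)
  )

  # drug targets and pathways (each pathway seeded with >=1 target gene)
  targets <- stats::setNames(lapply(drugs, function(d) {
    sample(genes, sample(seq(config$targets_per_drug[1],
                             config$targets_per_drug[2]), 1))
  }), drugs)
  all_targets <- unique(unlist(targets, use.names = FALSE))
  pathways <- stats::setNames(lapply(pw_ids, function(p) {
    size <- sample(seq(config$pathway_size_range[1],
                       config$pathway_size_range[2]), 1)
    gs <- sample(genes, size)
    if (length(intersect(gs, all_targets)) == 0L) {
      gs[1] <- sample(all_targets, 1)
    }
    gs
  }), pw_ids)

  # drug pairs and causal pathway assignment
  pair_idx <- sample(choose(n_drugs, 2), n_pairs)
  all_pairs <- utils::combn(drugs, 2)
  pairs <- tibble::tibble(
    drug_a = all_pairs[1, pair_idx],
    drug_b = all_pairs[2, pair_idx]
  )
  pairs$pair_id <- paste0(pairs$drug_a, "_", pairs$drug_b)
  pairs <- pairs[order(pairs$pair_id), c("pair_id", "drug_a", "drug_b")]
  n_causal <- round(config$causal_fraction * n_pairs)
  causal_pw <- rep(NA_character_, n_pairs)
  if (n_causal > 0) {
    causal_pw[sample(n_pairs, n_causal)] <- sample(pw_ids, n_causal,
                                                   replace = TRUE)
  }
  causal <- tibble::tibble(pair_id = pairs$pair_id, causal_pathway = causal_pw)

  # planted synergy labels via the causal pathway's active-gene count
  active <- presence == "P"
  base_p <- stats::plogis(config$beta0)
  labels <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    pw <- causal_pw[i]
    if (is.na(pw)) {
      p <- rep(base_p, length(cells))
    } else {
      count <- colSums(active[pathways[[pw]], , drop = FALSE])
      mu <- mean(count[train_cells]); s <- stats::sd(count[train_cells])
      z <- if (is.na(s) || s == 0) rep(0, length(cells)) else (count - mu) / s
      p <- stats::plogis(config$beta0 + config$beta1 * z)
    }
    tibble::tibble(pair_id = pairs$pair_id[i], cell_line_id = cells,
                   s_true = stats::rbinom(length(cells), 1, p))
  })
  labels$delta <- config$delta * labels$s_true

  # dose-response wells
  p_doses <- config$dose_grid[1]
  q_doses <- config$dose_grid[2]
  slope <- matrix(stats::runif(n_drugs * length(cells), 0.5, 1.5),
                  n_drugs, dimnames = list(drugs, cells))
  d50 <- matrix(stats::runif(n_drugs * length(cells), 0.5,
                             max(p_doses, q_doses) + 0.5),
                n_drugs, dimnames = list(drugs, cells))
  mono_y <- function(drug, dose) {
    100 * stats::plogis(slope[drug, ] * (d50[drug, ] - dose))
  }
  t0_val <- 100; t10_val <- 300
  to_raw <- function(y) t0_val + y / 100 * (t10_val - t0_val)

  dose <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    pr <- pairs$pair_id[i]
    da <- pairs$drug_a[i]; db <- pairs$drug_b[i]
    lab <- labels[labels$pair_id == pr, ]
    s_vec <- lab$s_true[match(cells, lab$cell_line_id)]
    ya <- vapply(seq_len(p_doses), function(p) mono_y(da, p), numeric(length(cells)))
    yb <- vapply(seq_len(q_doses), function(q) mono_y(db, q), numeric(length(cells)))
    fixed <- tibble::tibble(
      pair_id = pr, cell_line_id = rep(cells, 2), drug_a = da, drug_b = db,
      dose_index_a = 0L, dose_index_b = 0L,
      role = rep(c("t0", "control"), each = length(cells)),
      value = rep(c(t0_val, t10_val), each = length(cells))
    )
    mono_a <- purrr::map_dfr(seq_len(p_doses), function(p) tibble::tibble(
      pair_id = pr, cell_line_id = cells, drug_a = da, drug_b = db,
      dose_index_a = p, dose_index_b = 0L, role = "mono_a",
      value = to_raw(ya[, p])
    ))
    mono_b <- purrr::map_dfr(seq_len(q_doses), function(q) tibble::tibble(
      pair_id = pr, cell_line_id = cells, drug_a = da, drug_b = db,
      dose_index_a = 0L, dose_index_b = q, role = "mono_b",
      value = to_raw(yb[, q])
    ))
    combo <- purrr::map_dfr(seq_len(p_doses), function(p) {
      purrr::map_dfr(seq_len(q_doses), function(q) {
        z <- expected_combo_growth(ya[, p], yb[, q])
        # planted synergy shifts observed growth by +delta so that the
        # ComboScore (mean observed - expected) of a synergistic well is
        # approximately +delta, matching the synergy convention Y_AB > 10
        y <- z + config$delta * s_vec +
          stats::rnorm(length(cells), 0, config$well_noise_sd)
        tibble::tibble(pair_id = pr, cell_line_id = cells, drug_a = da,
                       drug_b = db, dose_index_a = p, dose_index_b = q,
                       role = "combo", value = to_raw(y))
      })
    })
    out <- dplyr::bind_rows(fixed, mono_a, mono_b, combo)
    out$value <- unname(out$value)
    out
  })

  combo_y <- growth_fraction(t0_val, dose$value[dose$role == "combo"], t10_val)
  truth <- list(
    causal = causal,
    labels = labels,
    genes = tibble::tibble(gene = genes, prevalence = prevalence,
                           essential_fraction = ess_frac),
    frac_negative_wells = mean(combo_y < 0)
  )

  bundle <- structure(
    list(expression = expression, presence = presence, d2 = d2,
         targets = targets, pathways = pathways, pairs = pairs,
         dose = dose, train_cells = train_cells, valid_cells = valid_cells,
         truth = truth, config = config),
    class = "synergy_bundle"
  )
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

# tiny destructuring helper for readability above
`%<-%` <- function(lhs, rhs) {
  vars <- as.list(substitute(lhs))[-1]
  for (i in seq_along(vars)) {
    assign(deparse(vars[[i]]), rhs[[i]], envir = parent.frame())
  }
  invisible(NULL)
}

#' @export
print.synergy_bundle <- function(x, ...) {
  cat(sprintf(paste0("synergy_bundle: %d genes x %d cells (%d train, %d validation),\n",
                     "  %d drugs, %d pairs, %d pathways, %d dose-response rows\n"),
              nrow(x$expression), ncol(x$expression), length(x$train_cells),
              length(x$valid_cells), length(x$targets), nrow(x$pairs),
              length(x$pathways), nrow(x$dose)))
  invisible(x)
}

#' Named study fixtures
#'
#' Three ready-made study configurations: `tiny` (6 training + 4
#' validation cells, 30 genes, 4 pathways, 3 pairs — small enough to
#' check features by hand), `null` (no pathway-driven effect: the synergy
#' labels are random with respect to every feature, though synergy itself
#' is still planted so that scoring and pair selection work), and
#' `strong_signal` (large planted effect: Bliss deviation 40 and
#' odds-ratio about 3.5 per standardized unit of the causal pathway
#' feature).
#'
#' @param name One of `"tiny"`, `"null"`, `"strong_signal"`.
#' @param seed Seed forwarded to [sim_config()].
#' @return A [`synergy_bundle`][simulate_study].
#' @export
make_fixture <- function(name = c("tiny", "null", "strong_signal"), seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(
      seed = seed, n_train_cells = 6, n_valid_cells = 4, n_genes = 30,
      n_pathways = 4, pathway_size_range = c(4, 10), n_drugs = 6,
      targets_per_drug = c(1, 3), n_pairs = 3, dose_grid = c(2, 2),
      causal_fraction = 1 / 3, delta = 30, well_noise_sd = 2
    ),
    null = sim_config(
      seed = seed, n_genes = 600, n_pathways = 50,
      pathway_size_range = c(10, 60), n_drugs = 40, n_pairs = 48,
      causal_fraction = 0, beta1 = 0, delta = 30, well_noise_sd = 5
    ),
    strong_signal = sim_config(
      seed = seed, n_genes = 500, n_pathways = 12,
      pathway_size_range = c(10, 80), n_drugs = 20, n_pairs = 10,
      causal_fraction = 0.5, beta1 = log(3.5), delta = 40,
      well_noise_sd = 4
    )
  )
  simulate_study(cfg)
}
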
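#' Run the full synergy association pipeline
#'
#' Deterministic stage order: score dose-response, select recurrent
#' pairs, filter genes, build type-1/type-2 features, run the requested
#' pathway analyses, tabulate expected/observed FDR, validate top
#' pathway signals on the hold-out cohort, and write a run manifest
#' last. All intermediate tables are persisted as TSV under `out_dir`.
#'
#' @param bundle A [`synergy_bundle`][simulate_study] (from
#'   [simulate_study()] or [read_inputs()]).
#' @param out_dir Output directory.
#' @param analyses Subset of `c("PA1", "PA2", "PA3")`.
#' @param modes Subset of `c("expression", "essentiality", "combined")`.
#' @param synergy_threshold ComboScore cutoff for synergy; default 10.
#' @param min_synergistic Minimum synergistic cell lines per pair;
#'   default 5.
#' @param essentiality_threshold D2 cutoff; default -0.5.
#' @param min_active_fraction,min_cv Gene filter settings (0.2 / 0.1).
#' @param fdr_thresholds P-value grid for the FDR tables.
#' @param n_validate Number of top (pair, pathway) signals to test on
#'   the validation cohort; default 2.
#' @param include_gene_scan Also run the gene-level scans (one fit per
#'   retained gene per pair — expensive); default `FALSE`.
#' @return List of class `synergy_run`: `synergy`, `selected_pairs`,
#'   `filter_report`, `scans` (named list of
#'   [`synergy_scan`][pathway_scan]s), `fdr` (combined tibble),
#'   `validation` (tibble or `NULL`), `manifest`.
#' @export
run_pipeline <- function(bundle, out_dir,
                         analyses = c("PA1", "PA2", "PA3"),
                         modes = c("expression", "essentiality", "combined"),
                         synergy_threshold = 10, min_synergistic = 5,
                         essentiality_threshold = -0.5,
                         min_active_fraction = 0.2, min_cv = 0.1,
                         fdr_thresholds = c(1e-4, 1e-3, 1e-2),
                         n_validate = 2, include_gene_scan = FALSE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  modes <- match.arg(modes, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # score + select
  synergy <- stage("score", score_synergy(bundle$dose, synergy_threshold))
  write_synergy(synergy, p("synergy.tsv"))
  train_synergy <- synergy[synergy$cell_line_id %in% bundle$train_cells, ]
  selected <- stage("select", select_combinations(train_synergy, min_synergistic))
  writeLines(selected, p("selected_pairs.txt"))
  if (length(selected) == 0L) {
    stop("pipeline stage 'select' failed: no drug pair is synergistic in at least ",
         min_synergistic, " training cell lines", call. = FALSE)
  }

  # calls + filter (training cohort)
  train <- bundle$train_cells
  active_all <- stage("filter", call_active(bundle$presence))
  essential_all <- call_essential(bundle$d2, essentiality_threshold)
  report <- filter_genes(bundle$expression[, train, drop = FALSE],
                         active_all[, train, drop = FALSE],
                         essential_all,
                         min_active_fraction, min_cv)
  readr::write_tsv(report$excluded, p("gene_filter.tsv"))

  # post-filter feature universes
  active_tr <- active_all[report$retained_expression, train, drop = FALSE]
  essential_tr <- essential_all[report$retained_essentiality, , drop = FALSE]
  pathways <- keep_target_pathways(bundle$pathways, bundle$targets)

  pairs_df <- bundle$pairs[bundle$pairs$pair_id %in% selected, ]
  feats1 <- stage("features",
                  build_target_features(pairs_df, bundle$targets,
                                        active_tr, essential_tr))
  feats2 <- build_pathway_features(pathways, active_tr, essential_tr)
  readr::write_tsv(feats1, p("features_type1.tsv"))
  readr::write_tsv(feats2, p("features_type2.tsv"))

  # association scans
  scans <- list()
  for (an in analyses) {
    for (mo in modes) {
      key <- paste(an, mo, sep = "_")
      scans[[key]] <- stage(paste0("scan_", key),
        pathway_scan(an, mo, feats1, feats2, train_synergy, selected,
                     names(pathways)))
      readr::write_tsv(scans[[key]]$results, p(paste0("results_", key, ".tsv")))
    }
  }
  if (include_gene_scan) {
    if ("expression" %in% modes) {
      scans[["gene_expression"]] <- stage("scan_gene_expression",
        gene_scan(bundle$expression[report$retained_expression, train,
                                    drop = FALSE],
                  train_synergy, selected, "expression"))
    }
    if ("essentiality" %in% modes) {
      scans[["gene_essentiality"]] <- stage("scan_gene_essentiality",
        gene_scan(bundle$d2[report$retained_essentiality, , drop = FALSE],
                  train_synergy, selected, "essentiality"))
    }
  }

  # FDR tables at DD and DDP level
  fdr <- stage("fdr", purrr::imap_dfr(scans, function(sc, key) {
    dplyr::bind_rows(
      dplyr::mutate(
        fdr_table(sc$overall$overall_p, fdr_thresholds,
                  n_tests = nrow(sc$overall)),
        scan = key, level = "DD", .before = 1),
      dplyr::mutate(
        fdr_table(sc$results$p_value, fdr_thresholds,
                  n_tests = nrow(sc$results)),
        scan = key, level = "DDP", .before = 1)
    )
  }))
  readr::write_tsv(fdr, p("fdr_tables.tsv"))

  # hold-out validation of the strongest pathway signals
  validation <- NULL
  if (length(bundle$valid_cells) > 0L && n_validate > 0L) {
    src <- scans[["PA3_expression"]] %||% scans[["PA2_expression"]]
    if (!is.null(src)) {
      top <- src$overall |>
        dplyr::filter(!is.na(.data$overall_p)) |>
        dplyr::arrange(.data$overall_p) |>
        utils::head(n_validate)
      active_val <- active_all[, bundle$valid_cells, drop = FALSE]
      valid_synergy <- synergy[synergy$cell_line_id %in% bundle$valid_cells, ]
      validation <- stage("validate", purrr::map_dfr(seq_len(nrow(top)), function(i) {
        pr <- top$pair_id[i]; pw <- top$argmin[i]
        dplyr::bind_rows(
          dplyr::mutate(
            validate_pathway(pr, bundle$pathways[[pw]],
                             active_all[, train, drop = FALSE], train_synergy),
            pathway_id = pw, cohort = "train", .before = 2),
          dplyr::mutate(
            validate_pathway(pr, bundle$pathways[[pw]], active_val,
                             valid_synergy),
            pathway_id = pw, cohort = "validation", .before = 2)
        )
      }))
      readr::write_tsv(validation, p("validation.tsv"))
    }
  }

  manifest <- write_manifest(bundle, out_dir, list(
    analyses = analyses, modes = modes,
    synergy_threshold = synergy_threshold,
    min_synergistic = min_synergistic,
    essentiality_threshold = essentiality_threshold,
    min_active_fraction = min_active_fraction, min_cv = min_cv,
    n_selected_pairs = length(selected),
    n_retained_expression = length(report$retained_expression),
    n_retained_essentiality = length(report$retained_essentiality),
    n_pathways = length(pathways)
  ))

  structure(
    list(synergy = synergy, selected_pairs = selected,
         filter_report = report, scans = scans, fdr = fdr,
         validation = validation, manifest = manifest,
         out_dir = out_dir),
    class = "synergy_run"
  )
}

# Manifest: run settings, per-stage row counts and md5 checksums of every
# file in the output directory; written last so its presence marks a
# completed run.
write_manifest <- function(bundle, out_dir, settings) {
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- dplyr::bind_rows(
    tibble::tibble(key = paste0("setting:", names(settings)),
                   value = vapply(settings, function(v)
                     paste(format(v), collapse = ","), "")),
    tibble::tibble(key = paste0("md5:", files), value = unname(sums))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}

#' @export
print.synergy_run <- function(x, ...) {
  cat("synergy_run:", length(x$selected_pairs), "selected pairs,",
      length(x$scans), "scans ->", x$out_dir, "\n")
  invisible(x)
}
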
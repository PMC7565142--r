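# File formats are fixed: UTF-8; tab-separated matrices with genes as
# rows and a leading `gene` column; comma-separated dose-response; '.'
# decimal; literal "NA" for missing values.

matrix_to_tbl <- function(m) {
  tibble::as_tibble(m, rownames = "gene")
}

tbl_to_matrix <- function(df, path, mode = "numeric") {
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene rows in ", path, ": ",
         paste(utils::head(unique(df$gene[duplicated(df$gene)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- if (mode == "numeric") "double" else "character"
  m
}

#' Read / write a long-format dose-response table
#'
#' Comma-separated with columns `pair_id`, `cell_line_id`, `drug_a`,
#' `drug_b`, `dose_index_a`, `dose_index_b`, `role` (`t0`, `control`,
#' `mono_a`, `mono_b`, `combo`), `value`.
#'
#' @param path File path.
#' @return `read_dose_response()` returns a tibble.
#' @export
read_dose_response <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          pair_id = "c", cell_line_id = "c", drug_a = "c",
                          drug_b = "c", dose_index_a = "i",
                          dose_index_b = "i", role = "c", value = "d"))
  bad_roles <- setdiff(unique(df$role),
                       c("t0", "control", "mono_a", "mono_b", "combo"))
  if (length(bad_roles) > 0L) {
    stop("unknown role(s) in ", path, ": ",
         paste(bad_roles, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_dose_response
#' @param dose_df Tibble as returned by [read_dose_response()].
#' @export
write_dose_response <- function(dose_df, path) {
  readr::write_csv(dose_df, path)
  invisible(path)
}

#' Read expression values with presence calls
#'
#' Both files are tab-separated, genes as rows (leading `gene` column),
#' cell lines as columns, and must agree exactly in shape and labels.
#'
#' @param values_path Path to the normalized expression matrix.
#' @param presence_path Path to the `P`/`M`/`A` call matrix.
#' @return List with numeric matrix `values` and character matrix
#'   `presence`.
#' @export
read_expression <- function(values_path, presence_path) {
  values <- tbl_to_matrix(
    readr::read_tsv(values_path, show_col_types = FALSE), values_path)
  presence <- tbl_to_matrix(
    readr::read_tsv(presence_path, show_col_types = FALSE,
                    col_types = readr::cols(.default = "c")),
    presence_path, mode = "character")
  if (!identical(dim(values), dim(presence)) ||
      !identical(rownames(values), rownames(presence)) ||
      !identical(colnames(values), colnames(presence))) {
    stop("expression/presence shape mismatch between ", values_path,
         " (", nrow(values), "x", ncol(values), ") and ", presence_path,
         " (", nrow(presence), "x", ncol(presence), ")", call. = FALSE)
  }
  list(values = values, presence = presence)
}

#' Read / write a gene x cell-line matrix (TSV)
#'
#' @param path File path.
#' @return `read_matrix_tsv()` returns a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tbl_to_matrix(readr::read_tsv(path, show_col_types = FALSE), path)
}

#' @rdname read_matrix_tsv
#' @param m Matrix with dimnames (or character matrix for presence
#'   calls).
#' @export
write_matrix_tsv <- function(m, path) {
  readr::write_tsv(matrix_to_tbl(m), path)
  invisible(path)
}

#' Read / write a drug-target table
#'
#' Long-format TSV with columns `drug_id`, `gene_symbol`.
#'
#' @param path File path.
#' @return `read_targets()` returns a named list: drug id to character
#'   vector of target gene symbols.
#' @export
read_targets <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(drug_id = "c",
                                                gene_symbol = "c"))
  if (anyDuplicated(df)) {
    stop("duplicate drug-target rows in ", path, call. = FALSE)
  }
  split(df$gene_symbol, df$drug_id)
}

#' @rdname read_targets
#' @param targets Named list of target gene vectors.
#' @export
write_targets <- function(targets, path) {
  df <- tibble::tibble(
    drug_id = rep(names(targets), lengths(targets)),
    gene_symbol = unlist(targets, use.names = FALSE)
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write pathway gene sets (GMT)
#'
#' Standard GMT: one pathway per line, tab-separated
#' `id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of gene symbol vectors; the
#'   descriptions are kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("GMT parse error in ", path, ": line ", short[1],
         " has fewer than 3 fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway ids in ", path, call. = FALSE)
  }
  out <- lapply(fields, function(f) f[-(1:2)])
  names(out) <- ids
  attr(out, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), ids)
  out
}

#' @rdname read_gmt
#' @param pathways Named list of gene symbol vectors.
#' @param descriptions Optional named character vector of descriptions.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  desc <- descriptions %||% attr(pathways, "descriptions") %||%
    stats::setNames(names(pathways), names(pathways))
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, desc[[id]], pathways[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a synergy score table
#'
#' Tab-separated: `pair_id`, `cell_line_id`, `combo_score`, `status`.
#'
#' @param synergy_df Tibble from [score_synergy()].
#' @param path File path.
#' @export
write_synergy <- function(synergy_df, path) {
  readr::write_tsv(synergy_df, path)
  invisible(path)
}

#' Write every input file of a simulated study
#'
#' Emits `expression.tsv`, `presence.tsv`, `d2.tsv`, `targets.tsv`,
#' `pathways.gmt`, `dose_response.csv` plus the ground-truth sidecars
#' `truth_labels.tsv` and `truth_causal.tsv` (never read by the
#' pipeline).
#'
#' @param bundle A [`synergy_bundle`][simulate_study].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(bundle$expression, p("expression.tsv"))
  write_matrix_tsv(bundle$presence, p("presence.tsv"))
  write_matrix_tsv(bundle$d2, p("d2.tsv"))
  write_targets(bundle$targets, p("targets.tsv"))
  write_gmt(bundle$pathways, p("pathways.gmt"))
  write_dose_response(bundle$dose, p("dose_response.csv"))
  readr::write_tsv(bundle$truth$labels, p("truth_labels.tsv"))
  readr::write_tsv(bundle$truth$causal, p("truth_causal.tsv"))
  invisible(dir)
}

#' Read and cross-validate all pipeline inputs
#'
#' Loads every input file and enforces cross-file consistency: identical
#' expression/presence shapes, D2 cell lines forming a subset of the
#' expression cell lines, and every drug appearing in the dose-response
#' table present in the target map.
#'
#' @param paths Named list with elements `dose`, `expression`,
#'   `presence`, `d2`, `targets`, `gmt` (file paths); `d2` may be `NULL`
#'   for an expression-only cohort.
#' @return List of class `synergy_bundle` (without ground truth).
#' @export
read_inputs <- function(paths) {
  needed <- c("dose", "expression", "presence", "targets", "gmt")
  missing_keys <- setdiff(needed, names(paths))
  if (length(missing_keys) > 0L) {
    stop("paths lacks element(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  expr <- read_expression(paths$expression, paths$presence)
  d2 <- if (!is.null(paths$d2)) read_matrix_tsv(paths$d2) else NULL
  targets <- read_targets(paths$targets)
  pathways <- read_gmt(paths$gmt)
  dose <- read_dose_response(paths$dose)

  if (!is.null(d2)) {
    extra <- setdiff(colnames(d2), colnames(expr$values))
    if (length(extra) > 0L) {
      stop("D2 cell line(s) absent from expression data: ",
           paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
    }
  }
  pairs <- dplyr::distinct(dose[, c("pair_id", "drug_a", "drug_b")])
  unknown <- setdiff(unique(c(pairs$drug_a, pairs$drug_b)), names(targets))
  if (length(unknown) > 0L) {
    stop("unknown drug(s) in dose-response pairs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  train_cells <- if (!is.null(d2)) colnames(d2) else character(0)
  structure(
    list(expression = expr$values, presence = expr$presence, d2 = d2,
         targets = targets, pathways = pathways, pairs = pairs, dose = dose,
         train_cells = train_cells,
         valid_cells = setdiff(colnames(expr$values), train_cells),
         truth = NULL, config = NULL),
    class = "synergy_bundle"
  )
}
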
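#' Growth fraction relative to control, anchored at time zero
#'
#' Converts raw assay endpoints to the percent growth fraction
#' \eqn{Y = 100 (T_1 - T_0) / (T_{10} - T_0)}, where \eqn{T_0} is the
#' time-zero measurement, \eqn{T_1} the treated endpoint and \eqn{T_{10}}
#' the untreated control endpoint. Values below 0 indicate net cell kill;
#' values above 100 indicate growth beyond the control.
#'
#' @param t0 Numeric vector, time-zero measurement (assay units).
#' @param t1 Numeric vector, endpoint measurement after treatment.
#' @param t10 Numeric vector, control (untreated) endpoint.
#' @return Numeric vector of growth fractions in percent.
#' @examples
#' growth_fraction(100, 250, 400) # 50
#' growth_fraction(100, 40, 400)  # -20, net kill
#' @export
growth_fraction <- function(t0, t1, t10) {
  bad <- which(t10 == t0)
  if (length(bad) > 0L) {
    stop("degenerate control well(s): t10 == t0 at record(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "",
         call. = FALSE)
  }
  100 * (t1 - t0) / (t10 - t0)
}

#' Bliss-expected growth fraction for a drug combination
#'
#' Under Bliss independence the expected combination growth fraction is the
#' product of the monotherapy fractions (each truncated at 100) divided by
#' 100. When either monotherapy fraction is non-positive the expectation is
#' the smaller of the two (the more lethal drug dominates).
#'
#' @param y_ap,y_bq Numeric vectors of monotherapy growth fractions
#'   (percent), recycled to a common length.
#' @return Numeric vector of expected combination growth fractions.
#' @examples
#' expected_combo_growth(60, 50)   # 30
#' expected_combo_growth(-10, 40)  # -10
#' expected_combo_growth(120, 50)  # 50: truncation at 100
#' @export
expected_combo_growth <- function(y_ap, y_bq) {
  n <- max(length(y_ap), length(y_bq))
  y_ap <- rep_len(y_ap, n)
  y_bq <- rep_len(y_bq, n)
  out <- pmin(y_ap, 100) * pmin(y_bq, 100) / 100
  nonpos <- y_ap <= 0 | y_bq <= 0
  out[nonpos] <- pmin(y_ap, y_bq)[nonpos]
  out
}

#' ComboScore: mean Bliss deviation over a dose grid
#'
#' The ComboScore for one (drug pair, cell line) is the mean over all dose
#' combinations of observed minus Bliss-expected growth,
#' \eqn{Y_{AB} = (1/n) \sum_{p,q} (Y_{A_pB_q} - Z_{A_pB_q})}. Positive
#' scores indicate synergy (more kill than expected). `NA` wells are
#' dropped and `n` reduced accordingly.
#'
#' @param y_a Numeric vector of monotherapy growth fractions for drug A,
#'   one per dose level (length `p`).
#' @param y_b Same for drug B (length `q`).
#' @param y_ab Numeric `p x q` matrix of observed combination growth
#'   fractions; rows follow `y_a`, columns follow `y_b`.
#' @return A single numeric score. When all growth fractions lie in
#'   \[0, 100\] the score lies in \[-100, 100\].
#' @examples
#' combo_score(60, 50, matrix(20)) # observed 20 vs expected 30: -10
#' @export
combo_score <- function(y_a, y_b, y_ab) {
  y_ab <- as.matrix(y_ab)
  if (length(y_a) == 0L || length(y_b) == 0L || length(y_ab) == 0L) {
    stop("empty dose grid: need at least one dose level per drug", call. = FALSE)
  }
  if (nrow(y_ab) != length(y_a) || ncol(y_ab) != length(y_b)) {
    stop("y_ab must be length(y_a) x length(y_b): got ",
         nrow(y_ab), "x", ncol(y_ab), " for ",
         length(y_a), "x", length(y_b), call. = FALSE)
  }
  z <- outer(y_a, y_b, expected_combo_growth)
  diffs <- y_ab - z
  if (all(is.na(diffs))) return(NA_real_)
  mean(diffs, na.rm = TRUE)
}

#' Binary synergy status from a ComboScore
#'
#' A (pair, cell line) is called synergistic when its ComboScore strictly
#' exceeds the threshold (default 10); a score exactly at the threshold is
#' non-synergistic.
#'
#' @param score Numeric vector of ComboScores.
#' @param threshold Score threshold; default 10.
#' @return Integer vector of 0/1 synergy calls (`NA` propagates).
#' @export
synergy_status <- function(score, threshold = 10) {
  as.integer(score > threshold)
}

#' Score a long-format dose-response table
#'
#' Converts raw endpoint records into growth fractions and ComboScores, one
#' row per (pair, cell line). The input is the long dose-response layout
#' produced by [read_dose_response()] or [simulate_study()]: per
#' (pair, cell line) one `t0` row, one `control` row, `mono_a` rows keyed by
#' `dose_index_a`, `mono_b` rows keyed by `dose_index_b`, and `combo` rows
#' keyed by both. Replicate wells for the same key are averaged upstream;
#' this function expects a single value per well.
#'
#' @param dose_df Data frame with columns `pair_id`, `cell_line_id`,
#'   `role` (one of `t0`, `control`, `mono_a`, `mono_b`, `combo`),
#'   `dose_index_a`, `dose_index_b`, `value`.
#' @param threshold Synergy threshold passed to [synergy_status()].
#' @return A tibble with columns `pair_id`, `cell_line_id`, `combo_score`,
#'   `status`, `n_dose_pairs`.
#' @export
score_synergy <- function(dose_df, threshold = 10) {
  needed <- c("pair_id", "cell_line_id", "role", "dose_index_a",
              "dose_index_b", "value")
  missing_cols <- setdiff(needed, names(dose_df))
  if (length(missing_cols) > 0L) {
    stop("dose-response table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dose_df |>
    dplyr::group_by(.data$pair_id, .data$cell_line_id) |>
    dplyr::group_modify(~ score_one_block(.x, .y)) |>
    dplyr::ungroup() |>
    dplyr::mutate(status = synergy_status(.data$combo_score, threshold)) |>
    dplyr::select("pair_id", "cell_line_id", "combo_score", "status",
                  "n_dose_pairs") |>
    dplyr::arrange(.data$pair_id, .data$cell_line_id)
}

score_one_block <- function(block, key) {
  lab <- paste0(key$pair_id, "/", key$cell_line_id)
  t0 <- block$value[block$role == "t0"]
  t10 <- block$value[block$role == "control"]
  if (length(t0) != 1L || length(t10) != 1L) {
    stop("expected exactly one t0 and one control row for ", lab, call. = FALSE)
  }
  if (t10 == t0) stop("degenerate control (t10 == t0) for ", lab, call. = FALSE)
  gf <- function(t1) growth_fraction(t0, t1, t10)

  mono_a <- block[block$role == "mono_a", ]
  mono_b <- block[block$role == "mono_b", ]
  combo <- block[block$role == "combo", ]
  if (nrow(mono_a) == 0L || nrow(mono_b) == 0L || nrow(combo) == 0L) {
    stop("missing mono_a/mono_b/combo wells for ", lab, call. = FALSE)
  }
  y_a <- gf(mono_a$value)[order(mono_a$dose_index_a)]
  names(y_a) <- sort(mono_a$dose_index_a)
  y_b <- gf(mono_b$value)[order(mono_b$dose_index_b)]
  names(y_b) <- sort(mono_b$dose_index_b)

  ya <- y_a[as.character(combo$dose_index_a)]
  yb <- y_b[as.character(combo$dose_index_b)]
  if (anyNA(ya) || anyNA(yb)) {
    stop("combo well with no matching monotherapy dose for ", lab, call. = FALSE)
  }
  diffs <- gf(combo$value) - expected_combo_growth(ya, yb)
  keep <- !is.na(diffs)
  tibble::tibble(
    combo_score = if (any(keep)) mean(diffs[keep]) else NA_real_,
    n_dose_pairs = sum(keep)
  )
}

#' Select drug pairs with recurrent synergy
#'
#' Keeps drug pairs that are synergistic (`status == 1`) in at least
#' `min_synergistic` cell lines; the study design requires recurrence
#' across cell lines before a pair enters association analysis.
#'
#' @param synergy_df Tibble from [score_synergy()] (needs `pair_id`,
#'   `status`).
#' @param min_synergistic Minimum number of synergistic cell lines
#'   (default 5).
#' @return Character vector of retained `pair_id`s, sorted.
#' @export
select_combinations <- function(synergy_df, min_synergistic = 5) {
  if (nrow(synergy_df) == 0L) return(character(0))
  counts <- synergy_df |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(n_syn = sum(.data$status == 1, na.rm = TRUE),
                     .groups = "drop")
  sort(as.character(counts$pair_id[counts$n_syn >= min_synergistic]))
}
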
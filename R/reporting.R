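#' Render a per-item validity table
#'
#' Formats computed validity indices as the conventional per-item table:
#' one row per item with CVI, kappa, Aiken's V and its confidence
#' interval rendered as `(L-U)`. All numerics are rounded half-up to 3
#' decimals at render time only; the underlying results stay unrounded.
#' CSV and markdown renderings carry identical numeric content.
#'
#' @param results Tibble with columns `item_id`, `cvi`, `kappa`, `v`,
#'   `ci_lower`, `ci_upper`, and optionally `item_text` (e.g. from
#'   [evaluate_items()] or [run_round()]).
#' @param format `"csv"` or `"markdown"`.
#' @param dash Dash used inside the CI column: `"en"` (U+2013, the
#'   typographic convention) or `"hyphen"` for ASCII-only pipelines.
#' @return Character vector, one element per output line (header first).
#' @examples
#' render_validity_table(tibble::tibble(
#'   item_id = "1", cvi = 0.9, kappa = 0.9, v = 0.9,
#'   ci_lower = 0.8333, ci_upper = 0.9416))
#' @export
render_validity_table <- function(results, format = c("csv", "markdown"),
                                  dash = c("en", "hyphen")) {
  format <- match.arg(format)
  dash <- switch(match.arg(dash), en = "–", hyphen = "-")
  has_text <- "item_text" %in% names(results)
  fmt3 <- function(x) sprintf("%.3f", round_half_up(x, 3))
  header <- c("item_id", if (has_text) "item_text",
              "cvi", "kappa", "aiken_v", "ci_95")
  if (nrow(results) == 0) {
    body <- character()
  } else {
    cells <- cbind(
      results$item_id,
      if (has_text) results$item_text,
      fmt3(results$cvi), fmt3(results$kappa), fmt3(results$v),
      sprintf("(%s%s%s)", fmt3(results$ci_lower), dash, fmt3(results$ci_upper))
    )
    body <- apply(cells, 1, paste,
                  collapse = if (format == "csv") "," else " | ")
  }
  if (format == "csv") {
    c(paste(header, collapse = ","), body)
  } else {
    c(paste("|", paste(header, collapse = " | "), "|"),
      paste("|", paste(rep("---", length(header)), collapse = " | "), "|"),
      if (length(body) > 0) paste("|", body, "|"))
  }
}

#' Render a flow summary as text
#'
#' Human-readable per-round account of the item flow: entering counts,
#' retention percentage, and eliminations by cause.
#'
#' @param flow A [flow_summary()] tibble.
#' @return Character vector of lines.
#' @export
render_flow_summary <- function(flow) {
  vapply(seq_len(nrow(flow)), function(i) {
    f <- flow[i, ]
    sprintf(paste0("round %d: %d entering, %d retained (%.1f%%); ",
                   "eliminated: %d index, %d comprehension, ",
                   "%d merged, %d relevance"),
            f$round, f$entering, f$retained, f$pct_retained,
            f$eliminated_index, f$eliminated_comprehension,
            f$merged_duplicate, f$excluded_relevance)
  }, character(1))
}

#' Reference validity values for the Chem-Sex Inventory items
#'
#' Per-item content-validity results reported for the 42 retained items
#' of the Chem-Sex Inventory (CSI), a Spanish questionnaire on
#' chemsex-associated risk behaviors whose item bank was reduced by a
#' two-round Delphi panel (30 experts in the final round, 1-5 Likert
#' scale). Columns: first-round and final item numbers, the English item
#' text, and the printed (3-decimal) CVI, modified kappa, Aiken's V and
#' its 95% score-interval bounds. Used as a regression surface: all
#' printed kappas and interval bounds are recoverable from the package's
#' own formulas given `N = 30` and the reconstructed unrounded inputs
#' (see [reconstruct_reference()]).
#'
#' @return Tibble with 42 rows.
#' @export
csi_validity <- function() {
  path <- system.file("extdata", "csi_item_validity.csv",
                      package = "delphivalidity", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    item_round1 = readr::col_character(),
    item_final = readr::col_character(),
    item_text = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Recompute validity indices from printed table values
#'
#' Reconstructs the unrounded inputs behind a printed per-item validity
#' table and recomputes kappa and the V interval with the package's
#' formulas. With `N` experts on a scale of range `R`:
#' * the endorsement count is `A = round(CVI * N)` — exact because `A`
#'   is an integer and printed CVI has 3 decimals;
#' * the unrounded V is `round(V * N * R) / (N * R)` — exact because
#'   `V = (S - N * scale_min) / (N * R)` for an integer rating sum `S`.
#'
#' @param tbl Table with columns `cvi` and `v` (e.g. [csi_validity()]).
#' @param n_experts Panel size behind the printed values (default 30).
#' @param scale_range Scale range (default 4).
#' @param z Normal quantile (default 1.96).
#' @return `tbl` with added columns `A`, `v_exact`, `kappa_rec`,
#'   `ci_lower_rec`, `ci_upper_rec` (all unrounded except `A`).
#' @export
reconstruct_reference <- function(tbl, n_experts = 30, scale_range = 4,
                                  z = 1.96) {
  a <- round(tbl$cvi * n_experts)
  v_exact <- round(tbl$v * n_experts * scale_range) / (n_experts * scale_range)
  ci <- aiken_ci(v_exact, n_experts = n_experts, scale_range = scale_range,
                 z = z)
  dplyr::mutate(tbl, A = a, v_exact = v_exact,
                kappa_rec = kappa_from_counts(a, n_experts),
                ci_lower_rec = ci$lower, ci_upper_rec = ci$upper)
}
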
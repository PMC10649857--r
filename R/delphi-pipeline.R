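#' Run one Delphi evaluation round
#'
#' Applies the retention logic to every item rated in one consultation
#' round and returns a disposition ledger row per item. Rules are applied
#' in a fixed order:
#'
#' 1. compute all validity indices ([evaluate_items()]);
#' 2. index rule — eliminate items whose I-CVI / Aiken's V fail the
#'    cut-off under the configured indicator rule;
#' 3. comprehension rule — among survivors with comprehensibility
#'    ratings, eliminate items whose mean falls below the "high" bound,
#'    unless listed for reformulation (kept as `reformulated_retained`);
#' 4. duplicate merges — the designated duplicate of each merged pair is
#'    removed (`merged_duplicate`);
#' 5. relevance exclusions — surviving items judged off-topic by the
#'    panel are removed (`excluded_relevance`);
#' 6. forced inclusions — reverse eliminations from steps 2-3 only;
#'    they never resurrect merged duplicates or relevance exclusions.
#'
#' Items are processed in stable item-id order and the round is fully
#' deterministic.
#'
#' @param ratings Validated ratings tibble for a single round.
#' @param rules A [decision_rules()] object.
#' @param overrides An [override_ledger()], or `NULL` for none.
#' @return Ledger tibble: one row per item with `round`, `item_id`,
#'   `status`, `reason`, and the index columns of [evaluate_items()].
#' @export
run_round <- function(ratings, rules = decision_rules(), overrides = NULL) {
  if (length(unique(ratings$round)) != 1) {
    stop("`ratings` must contain exactly one round", call. = FALSE)
  }
  overrides <- overrides %||% override_ledger()
  stopifnot(inherits(overrides, "override_ledger"))
  idx <- evaluate_items(ratings, rules)

  referenced <- c(overrides$duplicate_merges$kept,
                  overrides$duplicate_merges$removed,
                  overrides$relevance_exclusions$item,
                  overrides$forced_inclusions$item,
                  overrides$reformulations$item)
  unknown <- setdiff(referenced, idx$item_id)
  if (length(unknown) > 0) {
    stop("override references item(s) with no ratings: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  cut <- rules$index_cutoff
  passes_index <- if (rules$indicator_rule == "both_ge_cutoff") {
    idx$cvi >= cut & idx$v >= cut
  } else {
    idx$cvi >= cut | idx$v >= cut
  }

  status <- ifelse(passes_index, "retained", "eliminated_index")
  reason <- ifelse(passes_index, "met index criteria",
                   sprintf("index rule failed (CVI %.3f, V %.3f < %.2f under %s)",
                           idx$cvi, idx$v, cut, rules$indicator_rule))

  has_comp <- !is.na(idx$mean_comprehension)
  low_comp <- has_comp & idx$mean_comprehension < rules$comprehension_high
  reform <- idx$item_id %in% overrides$reformulations$item
  drop_comp <- status == "retained" & low_comp & !reform
  status[drop_comp] <- "eliminated_comprehension"
  reason[drop_comp] <- sprintf("mean comprehension %.2f below %.1f",
                               idx$mean_comprehension[drop_comp],
                               rules$comprehension_high)
  keep_reform <- status == "retained" & low_comp & reform
  status[keep_reform] <- "reformulated_retained"
  reason[keep_reform] <- "reformulated; retained for re-evaluation"

  merged <- idx$item_id %in% overrides$duplicate_merges$removed
  resolvable <- merged & status %in% c("retained", "reformulated_retained")
  if (any(merged & !resolvable)) {
    warning("duplicate-merge target(s) already eliminated: ",
            paste(idx$item_id[merged & !resolvable], collapse = ", "),
            call. = FALSE)
  }
  status[resolvable] <- "merged_duplicate"
  kept_of <- overrides$duplicate_merges$kept[
    match(idx$item_id[resolvable], overrides$duplicate_merges$removed)]
  reason[resolvable] <- sprintf("merged into item %s", kept_of)

  excl <- idx$item_id %in% overrides$relevance_exclusions$item &
    status %in% c("retained", "reformulated_retained")
  status[excl] <- "excluded_relevance"
  reason[excl] <- "excluded by panel as not relevant to the topic"

  forced <- idx$item_id %in% overrides$forced_inclusions$item &
    status %in% c("eliminated_index", "eliminated_comprehension")
  status[forced] <- "retained"
  reason[forced] <- "forced inclusion by panel judgment"

  dplyr::bind_cols(idx[, c("item_id", "round")],
                   tibble::tibble(status = status, reason = reason),
                   idx[, setdiff(names(idx), c("item_id", "round"))])
}

#' Run a multi-round Delphi item selection
#'
#' Chains [run_round()] across consultation rounds. Items retained (or
#' reformulated and retained) in round *r* form the candidate set for
#' round *r + 1*; ratings supplied for already-eliminated items are
#' dropped with a warning. The result carries the full audit trail and
#' the final retained item set; it is deterministic given its inputs.
#'
#' @param rounds A list with one element per round: either a validated
#'   ratings tibble, or a list with elements `ratings` and optionally
#'   `overrides` (an [override_ledger()]).
#' @param rules A [decision_rules()] object.
#' @return An object of class `delphi_result`: a list with `ledger`
#'   (all rounds' disposition rows), `final_items` (character vector),
#'   and `rules`.
#' @export
run_delphi <- function(rounds, rules = decision_rules()) {
  stopifnot(length(rounds) >= 1)
  ledgers <- list()
  surviving <- NULL
  for (r in seq_along(rounds)) {
    el <- rounds[[r]]
    if (is.data.frame(el)) el <- list(ratings = el)
    ratings <- el$ratings
    if (!is.null(surviving)) {
      stray <- setdiff(unique(ratings$item_id), surviving)
      if (length(stray) > 0) {
        warning(sprintf("round %d ratings include %d item(s) already eliminated; ignored",
                        r, length(stray)), call. = FALSE)
        ratings <- ratings[ratings$item_id %in% surviving, , drop = FALSE]
      }
    }
    if (nrow(ratings) == 0) {
      surviving <- character()
      break
    }
    led <- run_round(ratings, rules, el$overrides)
    ledgers[[r]] <- led
    surviving <- led$item_id[led$status %in%
                               c("retained", "reformulated_retained")]
  }
  structure(
    list(ledger = dplyr::bind_rows(ledgers),
         final_items = sort(surviving %||% character()),
         rules = rules),
    class = "delphi_result"
  )
}

#' @export
print.delphi_result <- function(x, ...) {
  fs <- flow_summary(x$ledger)
  cat(sprintf("<delphi_result> %d round(s), %d item(s) retained\n",
              nrow(fs), length(x$final_items)))
  print(fs)
  invisible(x)
}

#' Per-round flow summary of a disposition ledger
#'
#' Counts, per round, the items entering, retained (including
#' reformulated-and-retained), and eliminated by each cause, with the
#' retention percentage (truncated to one decimal, see
#' [retention_pct()]).
#'
#' @param ledger A disposition ledger tibble (from [run_round()] or a
#'   `delphi_result$ledger`).
#' @return Tibble with one row per round: `round`, `entering`,
#'   `retained`, `eliminated_index`, `eliminated_comprehension`,
#'   `merged_duplicate`, `excluded_relevance`, `pct_retained`.
#' @export
flow_summary <- function(ledger) {
  stopifnot(nrow(ledger) > 0)
  out <- ledger |>
    dplyr::group_by(round = .data$round) |>
    dplyr::summarise(
      entering = dplyr::n(),
      retained = sum(.data$status %in% c("retained", "reformulated_retained")),
      eliminated_index = sum(.data$status == "eliminated_index"),
      eliminated_comprehension = sum(.data$status == "eliminated_comprehension"),
      merged_duplicate = sum(.data$status == "merged_duplicate"),
      excluded_relevance = sum(.data$status == "excluded_relevance"),
      .groups = "drop"
    )
  out$pct_retained <- mapply(retention_pct, out$retained, out$entering)
  out
}

#' Write / read a disposition ledger CSV
#'
#' Persists the ledger in a plain CSV with the documented column set so a
#' selection run can be audited or re-reported later.
#'
#' @param ledger Ledger tibble.
#' @param path File path.
#' @return `path` invisibly (write); the ledger tibble (read).
#' @export
write_ledger <- function(ledger, path) {
  readr::write_csv(ledger, path)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) stop("ledger file not found: ", path, call. = FALSE)
  readr::read_csv(path, col_types = readr::cols(
    item_id = readr::col_character(),
    round = readr::col_integer(),
    status = readr::col_character(),
    reason = readr::col_character(),
    comprehension_band = readr::col_character(),
    .default = readr::col_double()
  ))
}
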
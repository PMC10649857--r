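#' Ratings for one item, dimension and round
#'
#' Bundle of the Likert ratings one expert panel gave a single item on a
#' single dimension ("relevance" or "comprehensibility") in a single
#' consultation round, together with the scale bounds. This is the unit
#' of computation for every validity index: `N` is the number of ratings
#' (one per expert who rated the item), `A` the number of top-box
#' endorsements, and the scale range `R = scale_max - scale_min` rescales
#' the mean rating for Aiken's V.
#'
#' @param ratings Integer vector of Likert ratings, one per expert.
#' @param item_id Item identifier (coerced to character; opaque).
#' @param round_id Positive integer consultation round.
#' @param dimension `"relevance"` or `"comprehensibility"`.
#' @param scale_min,scale_max Integer scale bounds (default 1 and 5).
#' @return An object of class `item_ratings`.
#' @examples
#' item_ratings(c(5, 5, 4), item_id = "q1")
#' @export
item_ratings <- function(ratings, item_id, round_id = 1L,
                         dimension = c("relevance", "comprehensibility"),
                         scale_min = 1L, scale_max = 5L) {
  dimension <- match.arg(dimension)
  scale_min <- assert_count(scale_min, "scale_min", min = -1000L)
  scale_max <- assert_count(scale_max, "scale_max", min = -1000L)
  if (scale_max <= scale_min) {
    stop("`scale_max` must exceed `scale_min`", call. = FALSE)
  }
  round_id <- assert_count(round_id, "round_id", min = 1L)
  if (length(ratings) < 1 || anyNA(ratings)) {
    stop("`ratings` must contain at least one non-missing rating", call. = FALSE)
  }
  if (any(ratings != trunc(ratings))) {
    stop("ratings must be integers on the Likert scale", call. = FALSE)
  }
  if (any(ratings < scale_min | ratings > scale_max)) {
    stop(sprintf("ratings must lie in [%d, %d]", scale_min, scale_max),
         call. = FALSE)
  }
  structure(
    list(item_id = as.character(item_id), round_id = round_id,
         dimension = dimension, ratings = as.integer(ratings),
         scale_min = scale_min, scale_max = scale_max,
         scale_range = scale_max - scale_min),
    class = "item_ratings"
  )
}

#' @export
print.item_ratings <- function(x, ...) {
  cat(sprintf("<item_ratings> item %s, round %d, %s: N = %d, mean = %.3f [%d-%d]\n",
              x$item_id, x$round_id, x$dimension, length(x$ratings),
              mean(x$ratings), x$scale_min, x$scale_max))
  invisible(x)
}

#' Number of experts behind an item's ratings
#' @param item An [item_ratings()] object.
#' @return Integer count of ratings (one per responding expert).
#' @export
n_experts <- function(item) length(item$ratings)

#' Top-box endorsement count
#'
#' Number of ratings at or above the endorsement threshold (4 on the
#' usual 1-5 scale): the `A` in the I-CVI numerator.
#'
#' @param item An [item_ratings()] object.
#' @param top_box_min Smallest rating counted as an endorsement.
#' @return Integer count `A` with `0 <= A <= N`.
#' @export
top_box_count <- function(item, top_box_min = 4) {
  sum(item$ratings >= top_box_min)
}

#' Decision rules for item retention
#'
#' Thresholds and retention logic applied each Delphi round. The index
#' cut-off (default 0.6) is compared against I-CVI and Aiken's V; under
#' `both_ge_cutoff` an item must clear the cut-off on both indicators,
#' under `either_ge_cutoff` on at least one. Comprehensibility bands are
#' set by `comprehension_low` and `comprehension_high` on the rating
#' scale. `z_value` is the standard-normal quantile for the Aiken's V
#' score interval; it defaults to the conventional 1.96 at 95%
#' confidence, and is otherwise derived from `confidence_level`.
#'
#' @param index_cutoff Retention cut-off for I-CVI and V, in (0, 1).
#' @param indicator_rule `"both_ge_cutoff"` or `"either_ge_cutoff"`.
#' @param comprehension_high Mean rating at/above which comprehensibility
#'   is "high" (default 4).
#' @param comprehension_low Mean rating at/above which it is "medium"
#'   (default 3.5); below is "low".
#' @param confidence_level Confidence level for intervals (default 0.95).
#' @param z_value Normal quantile used in intervals; default 1.96 when
#'   `confidence_level` is 0.95.
#' @param top_box_min Smallest rating counted as endorsement (default 4).
#' @return An object of class `decision_rules`.
#' @export
decision_rules <- function(index_cutoff = 0.6,
                           indicator_rule = c("both_ge_cutoff", "either_ge_cutoff"),
                           comprehension_high = 4,
                           comprehension_low = 3.5,
                           confidence_level = 0.95,
                           z_value = NULL,
                           top_box_min = 4) {
  indicator_rule <- match.arg(indicator_rule)
  stopifnot(index_cutoff > 0, index_cutoff < 1,
            comprehension_low < comprehension_high,
            confidence_level > 0, confidence_level < 1)
  if (is.null(z_value)) {
    z_value <- if (isTRUE(all.equal(confidence_level, 0.95))) 1.96 else
      stats::qnorm(1 - (1 - confidence_level) / 2)
  }
  stopifnot(z_value >= 0)
  structure(
    list(index_cutoff = index_cutoff, indicator_rule = indicator_rule,
         comprehension_high = comprehension_high,
         comprehension_low = comprehension_low,
         confidence_level = confidence_level, z_value = z_value,
         top_box_min = top_box_min),
    class = "decision_rules"
  )
}

#' @export
print.decision_rules <- function(x, ...) {
  cat(sprintf(paste0("<decision_rules> cutoff %.2f (%s), comprehension bands ",
                     "[%.1f, %.1f), z = %.3f, top box >= %d\n"),
              x$index_cutoff, x$indicator_rule, x$comprehension_low,
              x$comprehension_high, x$z_value, x$top_box_min))
  invisible(x)
}

# canonical long-format header, fixed by the interchange contract
RATINGS_COLS <- c("round", "item_id", "expert_id", "dimension", "rating")

#' Read a long-format expert ratings table
#'
#' Reads the canonical tidy interchange format: one row per
#' (round, item, expert, dimension, rating), UTF-8 CSV with header
#' `round,item_id,expert_id,dimension,rating`. Each expert's rating of
#' each item on each dimension is one row, so panel attrition simply
#' produces fewer rows (and a lower per-item `N`); missing ratings are
#' never imputed.
#'
#' @param path Path to the CSV file.
#' @param scale_min,scale_max Likert scale bounds used for validation.
#' @return A validated tibble with the five canonical columns (`round`
#'   integer, `rating` integer, others character) and scale bounds
#'   stored in attributes `scale_min` / `scale_max`.
#' @export
read_ratings <- function(path, scale_min = 1L, scale_max = 5L) {
  if (!file.exists(path)) stop("ratings file not found: ", path, call. = FALSE)
  tbl <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      round = readr::col_integer(),
      item_id = readr::col_character(),
      expert_id = readr::col_character(),
      dimension = readr::col_character(),
      rating = readr::col_integer()
    )
  ))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed ratings file %s: row %d, %s", path,
                 probs$row[1], probs$expected[1]), call. = FALSE)
  }
  if (!identical(names(tbl), RATINGS_COLS)) {
    stop("ratings file must have header: ", paste(RATINGS_COLS, collapse = ","),
         call. = FALSE)
  }
  validate_ratings(tbl, scale_min = scale_min, scale_max = scale_max)
}

#' Validate an in-memory ratings table
#'
#' Applies the same checks as [read_ratings()]: known dimensions, integer
#' ratings within the scale, and no duplicated
#' (round, item, expert, dimension) cell.
#'
#' @inheritParams read_ratings
#' @param tbl Data frame with the canonical ratings columns.
#' @return The validated tibble with scale bounds attached as attributes.
#' @export
validate_ratings <- function(tbl, scale_min = 1L, scale_max = 5L) {
  tbl <- tibble::as_tibble(tbl)[RATINGS_COLS]
  bad_dim <- setdiff(unique(tbl$dimension), c("relevance", "comprehensibility"))
  if (length(bad_dim) > 0) {
    stop("unknown dimension value(s): ", paste(bad_dim, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(tbl)) stop("ratings table contains missing values", call. = FALSE)
  off <- which(tbl$rating < scale_min | tbl$rating > scale_max)
  if (length(off) > 0) {
    stop(sprintf("rating %d outside scale [%d, %d] (data row %d)",
                 tbl$rating[off[1]], scale_min, scale_max, off[1]),
         call. = FALSE)
  }
  key <- paste(tbl$round, tbl$item_id, tbl$expert_id, tbl$dimension, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate rating for round %s, item %s, expert %s, %s",
                 tbl$round[d], tbl$item_id[d], tbl$expert_id[d],
                 tbl$dimension[d]), call. = FALSE)
  }
  attr(tbl, "scale_min") <- as.integer(scale_min)
  attr(tbl, "scale_max") <- as.integer(scale_max)
  tbl
}

#' Write a ratings table to the canonical CSV format
#'
#' Inverse of [read_ratings()]: `read_ratings(write_ratings(x, f))`
#' reproduces `x` exactly.
#'
#' @param tbl Validated ratings tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(tbl, path) {
  readr::write_csv(tbl[RATINGS_COLS], path)
  invisible(path)
}

#' Split a ratings table into per-item rating sets
#'
#' Groups a long ratings table by (round, item, dimension) and returns one
#' [item_ratings()] object per group; `N` for each is the number of experts
#' who actually rated that combination.
#'
#' @param tbl Validated ratings tibble (see [read_ratings()]).
#' @return A list of `item_ratings`, ordered by round then item id.
#' @export
as_item_ratings <- function(tbl) {
  scale_min <- attr(tbl, "scale_min") %||% 1L
  scale_max <- attr(tbl, "scale_max") %||% 5L
  tbl <- dplyr::arrange(tbl, .data$round, .data$item_id, .data$dimension,
                        .data$expert_id)
  groups <- split(tbl, paste(tbl$round, tbl$item_id, tbl$dimension, sep = "\r"),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    item_ratings(g$rating, item_id = g$item_id[1], round_id = g$round[1],
                 dimension = g$dimension[1],
                 scale_min = scale_min, scale_max = scale_max)
  })
  names(out) <- NULL
  ord <- order(vapply(out, function(x) x$round_id, integer(1)),
               vapply(out, function(x) x$item_id, character(1)),
               vapply(out, function(x) x$dimension, character(1)))
  out[ord]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# override ledger ------------------------------------------------------------

#' Manual override ledger
#'
#' Encodes the qualitative, expert-judgment decisions of a Delphi round as
#' data rather than code: duplicate merges (one of a pair of near-identical
#' items is dropped), topic-relevance exclusions of items that cleared the
#' numeric cut-offs, forced inclusions of items that failed them, and
#' reformulated items that are retained for re-evaluation of their wording.
#' No item may be listed in more than one role.
#'
#' @param duplicate_merges Data frame with columns `kept`, `removed`,
#'   and optionally `note`.
#' @param relevance_exclusions,forced_inclusions,reformulations Data
#'   frames with columns `item` and optionally `note`.
#' @return An object of class `override_ledger`.
#' @export
override_ledger <- function(duplicate_merges = NULL,
                            relevance_exclusions = NULL,
                            forced_inclusions = NULL,
                            reformulations = NULL) {
  pair_tbl <- function(x) {
    if (is.null(x) || NROW(x) == 0) {
      return(tibble::tibble(kept = character(), removed = character(),
                            note = character()))
    }
    x <- tibble::as_tibble(x)
    if (!all(c("kept", "removed") %in% names(x))) {
      stop("duplicate_merges needs columns `kept` and `removed`", call. = FALSE)
    }
    note <- if ("note" %in% names(x)) x$note else rep("", nrow(x))
    tibble::tibble(kept = as.character(x$kept),
                   removed = as.character(x$removed),
                   note = as.character(note))
  }
  item_tbl <- function(x, what) {
    if (is.null(x) || NROW(x) == 0) {
      return(tibble::tibble(item = character(), note = character()))
    }
    x <- tibble::as_tibble(x)
    if (!"item" %in% names(x)) {
      stop(what, " needs a column `item`", call. = FALSE)
    }
    note <- if ("note" %in% names(x)) x$note else rep("", nrow(x))
    tibble::tibble(item = as.character(x$item), note = as.character(note))
  }
  out <- structure(
    list(duplicate_merges = pair_tbl(duplicate_merges),
         relevance_exclusions = item_tbl(relevance_exclusions,
                                         "relevance_exclusions"),
         forced_inclusions = item_tbl(forced_inclusions, "forced_inclusions"),
         reformulations = item_tbl(reformulations, "reformulations")),
    class = "override_ledger"
  )
  roles <- list(merged = out$duplicate_merges$removed,
                excluded = out$relevance_exclusions$item,
                forced = out$forced_inclusions$item,
                reformulated = out$reformulations$item)
  all_ids <- unlist(roles, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    dup <- all_ids[duplicated(all_ids)][1]
    stop(sprintf("item %s appears in more than one override list", dup),
         call. = FALSE)
  }
  out
}

#' @export
print.override_ledger <- function(x, ...) {
  cat(sprintf("<override_ledger> %d merges, %d exclusions, %d forced, %d reformulations\n",
              nrow(x$duplicate_merges), nrow(x$relevance_exclusions),
              nrow(x$forced_inclusions), nrow(x$reformulations)))
  invisible(x)
}

#' Read an override ledger from a YAML file
#'
#' The file maps each override role to a list of entries:
#' ```yaml
#' duplicate_merges:
#'   - kept: "11"
#'     removed: "81"
#'     note: near-identical wording
#' relevance_exclusions:
#'   - item: "26"
#' forced_inclusions: []
#' reformulations:
#'   - item: "13"
#'     note: reworded for clarity
#' ```
#' An empty file yields an empty ledger. When the file has a top-level
#' `rounds:` key, each round's section is read as its own ledger and a
#' named list of ledgers (by round number) is returned.
#'
#' @param path Path to the YAML file.
#' @return An `override_ledger`, or a named list of them keyed by round.
#' @export
read_overrides <- function(path) {
  if (!file.exists(path)) stop("overrides file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(override_ledger())
  from_list <- function(lst) {
    entries <- function(key) {
      e <- lst[[key]]
      if (is.null(e) || length(e) == 0) NULL else dplyr::bind_rows(e)
    }
    known <- c("duplicate_merges", "relevance_exclusions",
               "forced_inclusions", "reformulations")
    extra <- setdiff(names(lst), known)
    if (length(extra) > 0) {
      stop("unknown override section(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    override_ledger(duplicate_merges = entries("duplicate_merges"),
                    relevance_exclusions = entries("relevance_exclusions"),
                    forced_inclusions = entries("forced_inclusions"),
                    reformulations = entries("reformulations"))
  }
  if ("rounds" %in% names(raw)) {
    out <- lapply(raw$rounds, from_list)
    names(out) <- names(raw$rounds)
    return(out)
  }
  from_list(raw)
}

#' Read a run-configuration file
#'
#' YAML file holding the [decision_rules()] fields plus scale bounds and
#' an optional output directory. Unspecified fields take their defaults.
#'
#' @param path Path to the YAML config.
#' @return A list with elements `rules` (a `decision_rules`), `scale_min`,
#'   `scale_max`, and `output_dir` (possibly `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path) %||% list()
  rule_fields <- c("index_cutoff", "indicator_rule", "comprehension_high",
                   "comprehension_low", "confidence_level", "z_value",
                   "top_box_min")
  rules <- do.call(decision_rules, raw[intersect(names(raw), rule_fields)])
  list(rules = rules,
       scale_min = as.integer(raw$scale_min %||% 1L),
       scale_max = as.integer(raw$scale_max %||% 5L),
       output_dir = raw$output_dir)
}
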
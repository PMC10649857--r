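#' Item-level content validity index (I-CVI)
#'
#' Proportion of panel experts who endorsed the item, i.e. rated it in the
#' top boxes of the Likert scale (4 or 5 on a 1-5 scale):
#' \deqn{CVI = A / N}
#' where `A` counts ratings at or above `rules$top_box_min` and `N` is the
#' number of experts who rated the item.
#'
#' @param item An [item_ratings()] object (usually the relevance dimension).
#' @param rules A [decision_rules()] object; only `top_box_min` is used.
#' @return The I-CVI, a fraction in `[0, 1]`.
#' @examples
#' q <- item_ratings(c(rep(5, 20), rep(4, 7), rep(2, 3)), "q1")
#' compute_icvi(q) # 27/30 = 0.9
#' @export
compute_icvi <- function(item, rules = decision_rules()) {
  stopifnot(inherits(item, "item_ratings"))
  top_box_count(item, rules$top_box_min) / n_experts(item)
}

#' Probability of chance agreement on an endorsement count
#'
#' Probability that exactly `A` of `N` experts would endorse an item if
#' each judged relevant/not-relevant by a fair coin: the binomial(N, 1/2)
#' point mass
#' \deqn{P_c = \binom{N}{A} \, 0.5^N.}
#' Evaluated in the log domain (via [lchoose()]), so it is exact to
#' double precision and stable for panels far larger than any realistic
#' Delphi study (N up to at least 1000).
#'
#' @param A Endorsement count(s), `0 <= A <= N`.
#' @param N Panel size(s), `N >= 1`. Vectorized over both arguments.
#' @return Probability in (0, 1).
#' @examples
#' chance_agreement(18, 30) # choose(30, 18) / 2^30
#' @export
chance_agreement <- function(A, N) {
  if (any(N < 1) || any(A < 0) || any(A > N) ||
      any(A != trunc(A)) || any(N != trunc(N))) {
    stop("need integer counts with 0 <= A <= N and N >= 1", call. = FALSE)
  }
  exp(lchoose(N, A) - N * log(2))
}

#' Modified kappa from endorsement counts
#'
#' Chance-corrected I-CVI computed directly from the endorsement count `A`
#' and panel size `N`:
#' \deqn{\kappa = \frac{CVI - P_c}{1 - P_c}}
#' with `CVI = A/N` and `Pc = chance_agreement(A, N)`. All intermediates
#' are unrounded.
#'
#' @inheritParams chance_agreement
#' @return Modified kappa; always `<= CVI`, with equality only when
#'   `Pc = 0` in the limit.
#' @examples
#' kappa_from_counts(18, 30) # 0.56495..., printed as 0.565
#' @export
kappa_from_counts <- function(A, N) {
  pc <- chance_agreement(A, N)
  (A / N - pc) / (1 - pc)
}

#' Modified kappa for an item
#'
#' Applies [kappa_from_counts()] to an item's ratings under the given
#' endorsement threshold.
#'
#' @inheritParams compute_icvi
#' @return Modified kappa (unrounded).
#' @export
modified_kappa <- function(item, rules = decision_rules()) {
  stopifnot(inherits(item, "item_ratings"))
  kappa_from_counts(top_box_count(item, rules$top_box_min), n_experts(item))
}

#' Aiken's V
#'
#' Mean expert rating rescaled to `[0, 1]`:
#' \deqn{V = \frac{\bar X - l}{R}}
#' where `l` is the lowest possible score and `R` the scale range
#' (4 for a 1-5 scale).
#'
#' @inheritParams compute_icvi
#' @return Aiken's V in `[0, 1]`.
#' @examples
#' aiken_v(item_ratings(c(3, 4, 5), "q1")) # mean 4 -> 0.75
#' @export
aiken_v <- function(item) {
  stopifnot(inherits(item, "item_ratings"))
  (mean(item$ratings) - item$scale_min) / item$scale_range
}

#' Score-method confidence interval for Aiken's V
#'
#' Wilson-type interval obtained by inverting the normal score test with
#' `n * R` effective trials (`n` raters on a scale of range `R`):
#' \deqn{L, U = \frac{2nRV + z^2 \mp z\sqrt{4nRV(1-V) + z^2}}{2(nR + z^2)}}
#' The endpoints are exactly the two roots `p` of
#' `(V - p)^2 nR = z^2 p (1 - p)`, so the interval always contains `V`
#' and stays inside `[0, 1]`. With `z = 0` it collapses to the point `V`.
#'
#' @param v Aiken's V (fraction in `[0, 1]`; vectorized).
#' @param n_experts Number of raters.
#' @param scale_range Scale range `R` (default 4 for a 1-5 scale).
#' @param z Standard-normal quantile (default 1.96 for 95%).
#' @return A tibble with columns `lower` and `upper` (unrounded).
#' @examples
#' aiken_ci(0.9, 30) # (0.8333, 0.9416): prints as (0.833, 0.942)
#' @export
aiken_ci <- function(v, n_experts, scale_range = 4, z = 1.96) {
  if (any(v < 0 | v > 1) || anyNA(v)) {
    stop("`v` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_experts >= 1, scale_range >= 1, z >= 0)
  nk <- n_experts * scale_range
  half <- z * sqrt(4 * nk * v * (1 - v) + z^2)
  denom <- 2 * (nk + z^2)
  tibble::tibble(lower = (2 * nk * v + z^2 - half) / denom,
                 upper = (2 * nk * v + z^2 + half) / denom)
}

#' Wilson interval around the I-CVI
#'
#' Companion interval for the content validity index itself, treating the
#' `N` expert endorsements as binomial trials. Provided for comparison
#' with the Aiken's V score interval, which uses `N * R` effective trials;
#' per-item validity tables conventionally print the latter.
#'
#' @param cvi I-CVI (fraction; vectorized).
#' @param n_experts Panel size `N`.
#' @param z Standard-normal quantile (default 1.96).
#' @return A tibble with columns `lower` and `upper`.
#' @export
cvi_wilson_ci <- function(cvi, n_experts, z = 1.96) {
  if (any(cvi < 0 | cvi > 1)) stop("`cvi` must lie in [0, 1]", call. = FALSE)
  aiken_ci(cvi, n_experts = n_experts, scale_range = 1, z = z)
}

#' Comprehensibility band of a mean clarity rating
#'
#' Classifies an item's mean comprehensibility score: "high" at or above
#' `rules$comprehension_high` (default 4), "medium" from
#' `rules$comprehension_low` (default 3.5) up to that bound, "low" below.
#' The boundary value 4 counts as high by default; pass rules with a
#' different `comprehension_high` to move it.
#'
#' @param mean_score Mean rating(s) on the Likert scale.
#' @param rules A [decision_rules()] object.
#' @param scale_min,scale_max Scale bounds used to validate `mean_score`.
#' @return Character vector of `"high"`, `"medium"`, `"low"`.
#' @examples
#' comprehension_band(c(4.2, 3.7, 3.0)) # high, medium, low
#' @export
comprehension_band <- function(mean_score, rules = decision_rules(),
                               scale_min = 1, scale_max = 5) {
  if (any(mean_score < scale_min | mean_score > scale_max) || anyNA(mean_score)) {
    stop(sprintf("mean score outside scale [%s, %s]", scale_min, scale_max),
         call. = FALSE)
  }
  ifelse(mean_score >= rules$comprehension_high, "high",
         ifelse(mean_score >= rules$comprehension_low, "medium", "low"))
}

#' All validity indices for one item
#'
#' Computes the full per-item bundle from the relevance ratings — I-CVI,
#' chance agreement, modified kappa, Aiken's V and its score interval —
#' plus, when comprehensibility ratings are supplied, their mean and
#' band. Every index is computed from unrounded intermediates; rounding
#' to 3 decimals is applied only when rendering reports.
#'
#' @param relevance [item_ratings()] for the relevance dimension.
#' @param comprehension Optional [item_ratings()] for comprehensibility.
#' @param rules A [decision_rules()] object.
#' @return A one-row tibble: `item_id`, `round`, `n_experts`,
#'   `mean_rating`, `cvi`, `pc`, `kappa`, `v`, `ci_lower`, `ci_upper`,
#'   `mean_comprehension`, `comprehension_band`.
#' @examples
#' rel <- item_ratings(c(rep(5, 15), rep(4, 5), rep(3, 10)), "q1")
#' evaluate_item(rel)
#' @export
evaluate_item <- function(relevance, comprehension = NULL,
                          rules = decision_rules()) {
  stopifnot(inherits(relevance, "item_ratings"))
  n <- n_experts(relevance)
  a <- top_box_count(relevance, rules$top_box_min)
  v <- aiken_v(relevance)
  ci <- aiken_ci(v, n_experts = n, scale_range = relevance$scale_range,
                 z = rules$z_value)
  if (!is.null(comprehension)) {
    stopifnot(inherits(comprehension, "item_ratings"))
    mc <- mean(comprehension$ratings)
    band <- comprehension_band(mc, rules, comprehension$scale_min,
                               comprehension$scale_max)
  } else {
    mc <- NA_real_
    band <- NA_character_
  }
  tibble::tibble(
    item_id = relevance$item_id, round = relevance$round_id,
    n_experts = n, mean_rating = mean(relevance$ratings),
    cvi = a / n, pc = chance_agreement(a, n), kappa = kappa_from_counts(a, n),
    v = v, ci_lower = ci$lower, ci_upper = ci$upper,
    mean_comprehension = mc, comprehension_band = band
  )
}

#' Validity indices for every item in a ratings table
#'
#' Batch form of [evaluate_item()]: groups a long ratings table by
#' (round, item), pairs each item's relevance ratings with its
#' comprehensibility ratings when present, and returns one row per item
#' per round.
#'
#' @param tbl Validated ratings tibble (see [read_ratings()]).
#' @param rules A [decision_rules()] object.
#' @return Tibble with one row per (round, item), columns as in
#'   [evaluate_item()], ordered by round then item id.
#' @export
evaluate_items <- function(tbl, rules = decision_rules()) {
  items <- as_item_ratings(tbl)
  key <- vapply(items, function(x) paste(x$round_id, x$item_id, sep = "\r"),
                character(1))
  dims <- vapply(items, function(x) x$dimension, character(1))
  rows <- lapply(unique(key), function(k) {
    rel <- items[key == k & dims == "relevance"]
    com <- items[key == k & dims == "comprehensibility"]
    if (length(rel) == 0) {
      stop("item ", sub("^.*\r", "", k), " has no relevance ratings",
           call. = FALSE)
    }
    evaluate_item(rel[[1]], if (length(com) > 0) com[[1]] else NULL, rules)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$round, .data$item_id)
}
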
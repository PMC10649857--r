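# builders for small in-memory panels used across the test files

# long table in the canonical format from explicit per-expert ratings
ratings_rows <- function(item_id, ratings, dimension = "relevance",
                         round = 1L, experts = NULL) {
  experts <- experts %||% sprintf("e%02d", seq_along(ratings))
  tibble::tibble(round = as.integer(round), item_id = as.character(item_id),
                 expert_id = experts, dimension = dimension,
                 rating = as.integer(ratings))
}

# one item rated on both dimensions by the same panel
item_rows <- function(item_id, relevance, comprehension = NULL, round = 1L) {
  out <- ratings_rows(item_id, relevance, "relevance", round)
  if (!is.null(comprehension)) {
    out <- dplyr::bind_rows(
      out, ratings_rows(item_id, comprehension, "comprehensibility", round))
  }
  out
}

# a bank in which every expert gives item k the same rating pair;
# rel/com are per-item scalars recycled over n_experts
uniform_bank <- function(item_ids, rel, com = 5L, round = 1L, n_experts = 30L) {
  rel <- rep_len(rel, length(item_ids))
  com <- rep_len(com, length(item_ids))
  dplyr::bind_rows(lapply(seq_along(item_ids), function(k) {
    item_rows(item_ids[k], rep(rel[k], n_experts), rep(com[k], n_experts),
              round = round)
  }))
}

# ratings vector with a given top-box count A, size N and integer sum
# (fails loudly if the three are inconsistent)
ratings_with <- function(A, N, total) {
  top <- rep(4L, A)
  extra <- total - 4L * A - (N - A)  # distribute above the floor
  i <- 1
  while (extra > 0 && i <= A) {
    bump <- min(1L, extra); top[i] <- top[i] + bump
    extra <- extra - bump; i <- i + 1
  }
  bottom <- rep(1L, N - A)
  i <- 1
  while (extra > 0 && i <= N - A) {
    bump <- min(2L, extra); bottom[i] <- bottom[i] + bump
    extra <- extra - bump; i <- i + 1
  }
  stopifnot(extra == 0, all(top <= 5), all(bottom <= 3))
  r <- c(top, bottom)
  stopifnot(sum(r) == total, sum(r >= 4) == A)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
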
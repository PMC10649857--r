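rules <- decision_rules()

# three items: clear pass, clear index failure, pass
toy_bank <- function() {
  validate_ratings(dplyr::bind_rows(
    item_rows("i1", ratings_with(27, 30, 135), rep(5L, 30)),  # mean 4.5
    item_rows("i2", ratings_with(12, 30, 96), rep(5L, 30)),   # mean 3.2
    item_rows("i3", ratings_with(20, 30, 123), rep(5L, 30))   # mean 4.1
  ))
}

test_that("index rule retains and eliminates as evaluated by hand", {
  led <- run_round(toy_bank(), rules)
  expect_equal(led$status[match(c("i1", "i2", "i3"), led$item_id)],
               c("retained", "eliminated_index", "retained"))
  expect_equal(led$cvi, c(0.9, 0.4, 20 / 30))
  expect_match(led$reason[led$item_id == "i2"], "index rule failed")
})

test_that("comprehension rule eliminates low-clarity survivors unless reformulated", {
  bank <- validate_ratings(dplyr::bind_rows(
    item_rows("a", rep(5L, 10), rep(4L, 10)),            # high comprehension
    item_rows("b", rep(5L, 10), rep(c(4L, 3L), 5)),      # mean 3.5: medium
    item_rows("c", rep(5L, 10), rep(3L, 10)),            # low
    item_rows("d", rep(2L, 10), rep(3L, 10))             # fails index first
  ))
  led <- run_round(bank, rules)
  expect_equal(led$status[match(c("a", "b", "c", "d"), led$item_id)],
               c("retained", "eliminated_comprehension",
                 "eliminated_comprehension", "eliminated_index"))

  reform <- override_ledger(reformulations = data.frame(item = "b"))
  led2 <- run_round(bank, rules, reform)
  expect_equal(led2$status[led2$item_id == "b"], "reformulated_retained")
})

test_that("overrides merge duplicates and exclude off-topic items after the index rule", {
  ovr <- override_ledger(
    duplicate_merges = data.frame(kept = "i1", removed = "i3"),
    relevance_exclusions = data.frame(item = "i1"))
  led <- run_round(toy_bank(), rules, ovr)
  expect_equal(led$status[led$item_id == "i3"], "merged_duplicate")
  # above cut-off yet excluded by the panel's topic judgment
  expect_equal(led$status[led$item_id == "i1"], "excluded_relevance")
  expect_gt(led$cvi[led$item_id == "i1"], rules$index_cutoff)

  expect_error(
    run_round(toy_bank(), rules,
              override_ledger(forced_inclusions = data.frame(item = "zz"))),
    "no ratings")
})

test_that("forced inclusions reverse index eliminations but never merges", {
  forced <- override_ledger(forced_inclusions = data.frame(item = "i2"))
  led <- run_round(toy_bank(), rules, forced)
  expect_equal(led$status[led$item_id == "i2"], "retained")
  expect_match(led$reason[led$item_id == "i2"], "forced")

  # a merged duplicate stays merged; forcing another item does not touch it
  both <- override_ledger(
    duplicate_merges = data.frame(kept = "i1", removed = "i3"),
    forced_inclusions = data.frame(item = "i2"))
  led2 <- run_round(toy_bank(), rules, both)
  expect_equal(led2$status[led2$item_id == "i3"], "merged_duplicate")
  # and the ledger itself refuses an item in two roles
  expect_error(
    override_ledger(duplicate_merges = data.frame(kept = "i1", removed = "i3"),
                    forced_inclusions = data.frame(item = "i3")),
    "more than one")
})

test_that("a merge targeting an already-eliminated item warns and keeps the elimination", {
  ovr <- override_ledger(duplicate_merges = data.frame(kept = "i1",
                                                       removed = "i2"))
  expect_warning(led <- run_round(toy_bank(), rules, ovr), "already eliminated")
  expect_equal(led$status[led$item_id == "i2"], "eliminated_index")
})

test_that("the indicator rule arbitrates items passing only one index", {
  # CVI 17/30 = 0.567 below cut-off, V = 73/120 = 0.608 above it
  bank <- validate_ratings(item_rows("q21", ratings_with(17, 30, 103)))
  both <- run_round(bank, decision_rules(indicator_rule = "both_ge_cutoff"))
  either <- run_round(bank, decision_rules(indicator_rule = "either_ge_cutoff"))
  expect_equal(both$status, "eliminated_index")
  expect_equal(either$status, "retained")
  expect_equal(round_half_up(either$v), 0.608)
})

test_that("multi-round runs conserve items and carry survivors forward", {
  r1 <- toy_bank()
  r2 <- validate_ratings(dplyr::bind_rows(
    item_rows("i1", ratings_with(25, 28, 130), round = 2),
    item_rows("i3", ratings_with(10, 28, 80), round = 2)))
  res <- run_delphi(list(r1, r2), rules)
  expect_s3_class(res, "delphi_result")
  expect_equal(res$final_items, "i1")
  fs <- flow_summary(res$ledger)
  expect_equal(fs$entering, c(3L, 2L))
  # conservation: every entering item has exactly one terminal status
  expect_equal(fs$entering,
               fs$retained + fs$eliminated_index + fs$eliminated_comprehension +
                 fs$merged_duplicate + fs$excluded_relevance)

  # ratings for an already-eliminated item are warned about and ignored
  r2_stray <- validate_ratings(dplyr::bind_rows(
    r2, item_rows("i2", rep(5L, 28), round = 2)))
  expect_warning(res2 <- run_delphi(list(r1, r2_stray), rules),
                 "already eliminated")
  expect_equal(res2$final_items, "i1")
})

test_that("re-running survivors with the same rules changes nothing", {
  led <- run_round(toy_bank(), rules)
  keep <- led$item_id[led$status == "retained"]
  again <- run_round(validate_ratings(
    toy_bank()[toy_bank()$item_id %in% keep, ]), rules)
  expect_true(all(again$status == "retained"))
  expect_equal(sort(again$item_id), sort(keep))
})

test_that("degenerate rounds complete: all retained, or an empty surviving set", {
  all_good <- validate_ratings(uniform_bank(c("a", "b"), 5L))
  res <- run_delphi(list(all_good), rules)
  expect_equal(sort(res$final_items), c("a", "b"))
  expect_equal(flow_summary(res$ledger)$pct_retained, 100.0)

  all_bad <- validate_ratings(uniform_bank(c("a", "b"), 2L))
  expect_warning(
    res2 <- run_delphi(list(all_bad,
                            validate_ratings(uniform_bank("a", 5L, round = 2))),
                       rules),
    "already eliminated")
  expect_length(res2$final_items, 0)
})

test_that("flow percentages reproduce the published truncation convention", {
  expect_equal(retention_pct(56, 114), 49.1)
  expect_equal(retention_pct(52, 56), 92.8)
  expect_equal(retention_pct(7, 7), 100.0)
})

test_that("ledgers round-trip through CSV", {
  led <- run_round(toy_bank(), rules)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger(led, path)
  back <- read_ledger(path)
  expect_equal(back$status, led$status)
  expect_equal(back$cvi, led$cvi, tolerance = 1e-12)
})
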